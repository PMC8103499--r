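# Demo configuration: a small allopolyploid complex that runs end-to-end in
# well under a minute on one CPU. All omitted keys take their documented
# defaults (see ?sim_config and ?validate_config).
seed: 42
sim:
  n_ancestral_genes: 100
  n_scaffolds: 2
  n_dmg: 4
  n_lineage_specific: 4
  n_meth_replicates: 2
  n_accessions:
    G: 3
    Q: 3
    J: 3
    "N": 3
  ssd_counts:
    tandem: 3
    proximal: 3
    transposed: 3
    dispersed: 3
    segmental: 1
  dmg_contrasts:
    - [G, "N"]
    - [G, Q]
dmg:
  alpha: 0.01
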