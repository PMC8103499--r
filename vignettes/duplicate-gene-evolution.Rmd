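---
title: "Models and methods: duplicated-gene evolution in an allopolyploid complex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: duplicated-gene evolution in an allopolyploid complex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupevol)
library(dplyr)
```

## The scientific problem

An allotetraploid lineage carries two parental subgenomes (tagged A and B
here). After the tetraploidization, redundant gene copies are lost
("fractionation"), often unequally between subgenomes; meanwhile small-scale
duplication (SSD) keeps adding copies by tandem, proximal, transposed,
dispersed and segmental events. Comparative studies of such complexes — one
diploid outgroup plus several tetraploid sister species descending from a
single tetraploidization — ask how these different duplication routes shape
nucleotide diversity (π), interspecific divergence (dxy), selection pressure
(dN/dS) and gene-body cytosine methylation (CG/CHG/CHH), and whether
genetic/epigenetic asymmetry between subgenomes was established once in the
common tetraploid ancestor.

`dupevol` implements that full analysis as composable, data-frame-first
functions — synteny-based classification, per-gene population-genetic and
methylation statistics, stratified differential-methylation calling, and
class-wise comparative summaries — together with a synthetic-data generator
that plants every effect the analysis is meant to detect, so each stage can
be verified against a known truth table at desk scale.

## Duplicate-gene classification

**Anchor chaining.** Collinear blocks are found by weighted
longest-collinear-chain dynamic programming over gene *rank* space (the
ordinal position of a gene on its scaffold), the approach popularised by
MCScanX. A chain must be strictly monotone in rank on both sides, with
consecutive anchors at most `max_gene_gap` (default 25) ranks apart; its
score is the sum of anchor similarity scores minus a linear gap penalty
(default 0.05 per skipped rank). Chains shorter than `min_block_anchors`
(default 5) are discarded. The block-size and gap limits are the
community-conventional values; the gap penalty is set high enough that a
chain cannot profitably absorb a stray anchor across a large rank gap
(which matters at toy densities), and no threshold in this family is
dictated by theory. Ties are broken by
smaller total rank gap, then the lexicographically smallest starting gene
id, then "same" orientation, so output is deterministic. For small anchor
sets (≤ 12) the test suite proves the DP score equals an exhaustive search
over every monotone chain.

**Orthogroups.** Genes are connected through block-assigned anchors
(diploid–tetraploid blocks plus tetraploid A–B self blocks) and each
connected component is resolved into at most one diploid gene and one copy
per subgenome (best total anchor score wins ties). Categories are mutually
exclusive here: *singleton* (one subgenome copy, diploid evidence present),
*doublet* (both subgenome copies, diploid copy lost) and *triplet* (both
copies plus the diploid ortholog). The classical literature counts triplets
inside doublets; `orthogroup_counts()` reports both conventions. We simulate
a small diploid loss probability so the doublet/triplet distinction is real
rather than vacuous.

**SSD modes.** Duplicate pairs from the tetraploid self-anchor table are
classified by a fixed priority: pairs inside an intra-genome collinear
block are WGD homoeologs when the two sides lie in different subgenomes
(excluded from SSD) and *segmental* when in the same subgenome; then
*tandem* (rank gap exactly 1), *proximal* (gap ≤ 10, same scaffold),
*transposed* (exactly one copy collinear with the outgroup — the
novel-locus copy takes the label), and *dispersed* as the fall-through. A
gene with several pairs takes its single highest-priority label. One
refinement protects the segmental class: a same-scaffold self block whose
anchors all lie within the proximal rank window of the self-comparison
diagonal is a string of local duplicates masquerading as collinearity
(tandem/proximal pairs of nearby genes chain with *each other*), so such
blocks are not accepted as segmental evidence. The outgroup-based
transposed rule is our documented choice; tools in this space differ and
rarely state theirs.

**Ancient collinearity.** Genes covered by more than four distinct
collinear blocks against a panel of conserved reference genomes are
*ancient collinear* (strict > 4, i.e. at least five blocks — the boundary
case at exactly four is excluded); one block suffices for
*conserved eudicot*. Gene families are connected components of the
reciprocal best-scoring hit graph across all taxa; families confined to the
focal taxa are *lineage specific*.

## Population-genetic statistics

Sites first pass the hard filter MQ > 30 and depth > 3 (both strict). π is
the mean per-site pairwise difference among haplotypes over the *full* gene
length — variant files omit invariant sites, so the gene length is the
correct monomorphic-inclusive denominator. Missing genotypes use pairwise
deletion per site; a site with fewer than two called haplotypes is skipped.
dxy applies the same logic to between-population pairs on the shared
surviving site set, and is symmetric by construction.

dN/dS uses the Nei–Gojobori counting estimator: synonymous site counts
averaged over both sequences, multi-difference codons averaged over
mutational pathways (pathways through stop codons excluded when any
stop-free ordering exists), and Jukes–Cantor correction
d = −(3/4)·ln(1 − (4/3)p). Changes that create a stop codon count as
nonsynonymous. ds = 0 flags the ratio undefined rather than inventing a
value. A counting estimator was chosen over ML codon models deliberately:
it is exact, dependency-free, fast at desk scale, and entirely adequate for
the class-wise *distributional* comparisons this package performs; it is
not intended for per-gene selection inference on deep divergences.

Gene presence in a resequenced species uses mean read depth relative to the
genome median (default threshold 0.2) — a deliberately simple rule for a
step whose published descriptions are rarely quantitative.

## Methylation and DMG calling

The per-gene methylation level is count-weighted: total methylated reads
over total reads across the gene's retained sites of one context — robust
to uneven coverage, unlike averaging per-site fractions. A site is retained
only when its total depth exceeds 10 in *every* sample of the comparison;
a gene enters a contrast only if it keeps at least one site ("fully
mapped").

Differential methylation between two species is tested with the classical
Cochran–Mantel–Haenszel statistic (no continuity correction, so the
single-stratum case reduces exactly to the chi-square score statistic).
Strata pair replicate i of one species with replicate i of the other — the
stratification is configurable because published pipelines rarely state
theirs. A gene (per context) is a DMG iff:

1. no within-species replicate pair shows a *real* intraspecific
   difference. We read "intraspecific difference smaller than 10% (Fisher
   exact P < 0.01)" as a conjunction for flagging a difference as real:
   a replicate pair violates the criterion only when its level difference
   is ≥ 10 percentage points *and* Fisher-significant. The alternative
   reading (require Fisher non-significance outright) degenerates at
   realistic depth: with thousands of reads per gene, a 1–2% replicate
   difference is always "significant", and no gene would ever pass.
2. the interspecific weighted-level difference exceeds 50 percentage
   points (strict >, so a 0.49 difference fails regardless of p-value);
3. more than 10% of the gene-body windows are CMH-significant at
   BH-adjusted q < 0.01. The gene body is the annotated start–end with no
   flanks, tiled into 20 equal-width windows (the natural granularity for
   a 10% rule); windows with no retained site are excluded from the
   denominator. One BH family per context spans all gene × window tests.

Spearman correlations of per-gene levels quantify profile similarity
between samples, and — for doublet pairs — between (species, subgenome)
profiles, partitioned into within-species/between-subgenome versus
between-species/same-subgenome comparisons. Shared ancestral asymmetry
shows up as the second partition exceeding the first.

## Class-wise comparisons

Every class (SSD modes, collinear classes, orthogroup categories,
lineage-specific) is compared against the overall gene set per statistic
with the Wilcoxon rank-sum test: exact enumeration (average ranks, ties
included) when the combined n is at most 12, otherwise the normal
approximation with tie-corrected variance and continuity correction. The
cutover at 12 keeps exactness where it is cheap. BH correction is applied
within each statistic family; direction labels come from the median
difference and are reported only when q < 0.05. Biased fractionation is
tested on singleton groups only — doublets carry no loss signal — with a
two-sided exact binomial test against equal loss. Enrichment of any gene
set against user-supplied category labels uses the upper hypergeometric
tail with BH correction; no live pathway databases are consulted.

Comparisons use per-gene species-level values (a species' replicates are
averaged first); per-accession resolution is not preserved into the
comparison tables.

## The synthetic-data generator

The generator is first-class, tested code, not a fixture. Its defaults are
the study conditions: one tetraploidization shared by three tetraploid
species G, Q, J plus diploid outgroup N; per-copy fractionation probability
0.2 per subgenome (configurable per subgenome for biased-loss studies) and
diploid loss 0.05; planted SSD events of all five modes; two windows of
genes preserved collinear in all six emulated reference genomes (ancient
collinear, depth 6 > 4) and 40% of remaining gene windows preserved in
exactly two (conserved eudicot, depth 2); target diversities
π(G) = 0.0004 < π(Q) = 0.0022 < π(J) = 0.0039 (the published rank
structure, used as planted values) with N at 0.002; Jukes–Cantor
divergence on the fixed ((G,Q,J),N) topology with configurable branch
scales; 4 accessions per species; 3 bisulfite replicates per species at
mean coverage 30.

Methylation composes additively on the level scale: a class mean per
context (ancient-collinear hypomethylated, dispersed hypermethylated,
background CG/CHG/CHH = 0.60/0.40/0.15), an orthogroup effect (singletons
+0.12 with gene-level SD 0.10; doublets/triplets −0.08 with SD 0.03 — the
hypermethylated, higher-variance singleton pattern), a per-copy ancestral
deviation shared by every species (SD 0.06), per-(species, copy) deviations
(SD 0.03 among tetraploids, 0.08 for the diploid — making the tetraploids
mutually more similar), planted DMGs (0.78 vs 0.12 across contexts), a
planted subgenome offset of 0.4 with random sign applied identically in
G, Q and J for 20% of doublet pairs, and replicate noise (SD 0.01; the
within-species replicate variance of real bisulfite panels is essentially
a free parameter, so it is exposed as one). Site counts are binomial at
Poisson coverage; CG/CHG/CHH context is read from the sequence on both
strands. Within-species polymorphism is added per haplotype at rate π/2,
which makes expected pairwise diversity π up to O(π²); 5% of sites per gene
receive failing MQ/DP metadata together with scrambled genotypes so the
hard filters are load-bearing.

Two emulation choices matter for interpretation. First, all four species'
methylomes are generated on the tetraploid gene coordinates, as if every
sample were mapped to the tetraploid reference; a diploid-reference
methylome is not produced. Second, anchor tables emulate *pre-filtered*
syntenic homolog candidates: the eudicot-panel table only lists anchors
inside windows that taxon preserves, and the ortho/self tables list
primary-copy orthologs and structural duplicate pairs. At toy scale this is
a necessity, not just a convenience — a few hundred genes on two scaffolds
are so dense in rank space that an unfiltered all-vs-all table against a
shuffled genome would chain spurious "blocks" (the longest increasing
subsequence of a random permutation of n elements grows like 2√n), which
real 40 000-gene genomes do not suffer at MCScanX-scale thresholds.
Consequently the passing tests certify the *classifiers and statistics*
against planted truth, not the robustness of block detection to noisy
genome-scale anchor inputs.

What the generator does not emulate: realistic codon usage or selection,
indels, linkage and demography (sites are independent), the ancient
paleotriplications as explicit events (ancient-collinear depth is planted
directly), bisulfite conversion failure, or read-level artefacts.

## Numerical and degenerate-input conventions

Undefined is `NA` plus a flag, never silently 0: π with fewer than two
haplotypes, dN/dS with ds = 0 or a saturated Jukes–Cantor proportion,
methylation level with no retained site, Spearman on a constant profile,
CMH with all strata degenerate (zero-margin strata are dropped with a
warning first). Integer count matrices are promoted to double before the
CMH variance product, which otherwise overflows 32-bit arithmetic at
realistic depths. All simulation randomness derives from the single config
seed (sub-stages use fixed offsets), so identical configurations are
byte-identical, and the pipeline writes no timestamps, making run manifests
checksum-stable.

## Problem sizes

The shipped demo configuration uses 100 ancestral genes and completes in
well under a minute; the test-suite simulations use 60–500 ancestral genes,
and the classification recovery study uses 1 000 genes with 20 planted
events per SSD mode. These sizes were chosen so each planted effect is
estimated with comfortable statistical margin (e.g. ≥ 50 planted DMGs for a
recall estimate, ≥ 100 doublet pairs for correlation partitions) while the
whole suite stays desk-scale. The 20%-of-target tolerance for realized π is
honest only for total gene space of a few hundred kilobases or more;
smaller toy runs check rank order, not absolute recovery.

## Known limitations

* Orthogroup resolution keeps one best copy per slot; tandem arrays
  collinear to the same diploid gene resolve to the strongest anchor, so
  orthogroup membership of array members is conservative.
* The transposed/dispersed distinction depends entirely on outgroup block
  membership; in genomes where the outgroup itself is heavily rearranged
  the transposed class will leak into dispersed.
* dxy is computed on sites retained in *both* species; a fixed difference
  at a site that fails QC in one species is not counted (the denominator
  convention makes this a small, documented downward bias).
* The CMH windows inherit the gene-body-only convention; promoter or
  flanking methylation differences are invisible by design.
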