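# Simulation configuration: the study conditions of the synthetic
# allopolyploid complex. One allotetraploidization shared by three descendant
# tetraploid species (G, Q, J) plus a diploid outgroup (N); biased
# fractionation; five SSD modes; species-ranked nucleotide diversity;
# class-dependent methylation means; planted DMGs and shared subgenome
# methylation asymmetry.

#' Default per-class gene-body methylation means
#'
#' Mean weighted methylation fraction per duplicate-gene class and cytosine
#' context used by [simulate_methylomes()]: ancient-collinear genes
#' hypomethylated, dispersed duplicates hypermethylated, other SSD modes
#' mildly hypomethylated, against a high overall background.
#'
#' @return tibble with columns `class`, `CG`, `CHG`, `CHH`.
#' @export
default_meth_class_means <- function() {
  tribble(
    ~class,               ~CG,  ~CHG, ~CHH,
    "background",         0.60, 0.40, 0.15,
    "conserved_eudicot",  0.45, 0.30, 0.12,
    "ancient_collinear",  0.25, 0.15, 0.06,
    "dispersed",          0.85, 0.70, 0.35,
    "tandem",             0.50, 0.33, 0.12,
    "proximal",           0.50, 0.33, 0.12,
    "transposed",         0.52, 0.35, 0.13,
    "segmental",          0.48, 0.32, 0.12
  )
}

#' @importFrom tibble tribble
NULL

#' Simulation configuration for the synthetic allopolyploid complex
#'
#' Builds and validates the configuration driving [simulate_genomes()],
#' [simulate_population_variants()] and [simulate_methylomes()]. Defaults
#' emulate the ginseng-complex study design at desk scale: a single
#' allotetraploidization (subgenomes A/B) shared by three tetraploid species
#' G, Q, J with diploid outgroup N; post-WGD fractionation; the five SSD
#' modes; species-ranked nucleotide diversity (G < Q < J); class-dependent
#' methylation; planted DMGs; and subgenome methylation asymmetry inherited
#' identically by the three tetraploids.
#'
#' @param seed integer RNG seed.
#' @param n_ancestral_genes number of ancestral genes before the WGD.
#' @param n_scaffolds ancestral scaffolds (each becomes one A and one B
#'   tetraploid scaffold).
#' @param gene_length_bp gene length (multiple of 3; genes are in-frame CDS).
#' @param intergenic_bp spacer between adjacent genes.
#' @param fractionation_prob per-copy post-WGD loss probability; scalar or
#'   named vector `c(A = , B = )` for biased fractionation.
#' @param diploid_loss_prob per-gene loss probability in the diploid lineage
#'   (so doublet and triplet orthogroups differ).
#' @param ssd_counts named counts of planted SSD events:
#'   tandem/proximal/transposed/dispersed/segmental.
#' @param segment_genes genes per segmental duplication event.
#' @param n_ref_taxa conserved eudicot reference genomes emulated.
#' @param ancient_windows,ancient_window_genes number and size of gene
#'   windows preserved collinear in all reference taxa (ancient-collinear
#'   genes, depth > 4).
#' @param conserved_frac fraction of remaining gene windows preserved
#'   collinear in exactly two reference taxa (conserved-eudicot only).
#' @param conserved_window_genes size of those windows.
#' @param n_lineage_specific planted focal-only (lineage-specific) families.
#' @param species_pi target nucleotide diversity per species
#'   (differences/site); defaults use the published rank structure
#'   G < N < Q < J.
#' @param divergence_scale branch-length multipliers on the fixed topology
#'   ((G,Q,J),N).
#' @param base_divergence terminal-branch divergence (substitutions/site) of
#'   each tetraploid species from the tetraploid ancestor, before scaling.
#' @param outgroup_divergence diploid terminal divergence before scaling.
#' @param low_qual_frac fraction of sites per gene given failing MQ/DP
#'   metadata plus genotype noise, to exercise the variant filters.
#' @param n_accessions sequenced accessions per species (2 haplotypes each).
#' @param n_meth_replicates bisulfite replicate samples per species.
#' @param read_depth_mean mean per-site bisulfite coverage (Poisson).
#' @param meth_class_means per-class, per-context mean methylation table
#'   (see [default_meth_class_means()]).
#' @param meth_singleton_shift,meth_doublet_shift additive shifts for genes
#'   in singleton vs doublet/triplet orthogroups (singletons
#'   hypermethylated).
#' @param meth_singleton_sd,meth_doublet_sd gene-level spread of those two
#'   classes (singletons higher-variance).
#' @param meth_copy_sd per-gene-copy methylation deviation shared by all
#'   species (ancestral state).
#' @param meth_species_sd per-(species, copy) deviation among tetraploids.
#' @param meth_diploid_sd the diploid's (larger) species deviation.
#' @param meth_rep_sd replicate-level deviation (free parameter; the study
#'   design does not constrain within-species replicate variance).
#' @param n_dmg planted differentially methylated genes per contrast.
#' @param dmg_contrasts list of species pairs receiving planted DMGs.
#' @param dmg_levels high/low species means for planted DMGs (all contexts).
#' @param asym_frac fraction of doublet pairs with planted subgenome
#'   methylation asymmetry.
#' @param asym_offset planted A-minus-B methylation offset (random sign per
#'   gene, identical in all three tetraploids).
#' @param n_absent named count of genes planted absent (near-zero read
#'   depth) per species, for presence/absence calling.
#' @return validated list of class `dupevol_config`.
#' @export
sim_config <- function(seed = 1,
                       n_ancestral_genes = 200,
                       n_scaffolds = 2,
                       gene_length_bp = 300,
                       intergenic_bp = 200,
                       fractionation_prob = c(A = 0.2, B = 0.2),
                       diploid_loss_prob = 0.05,
                       ssd_counts = c(tandem = 5, proximal = 5,
                                      transposed = 5, dispersed = 5,
                                      segmental = 1),
                       segment_genes = 6,
                       n_ref_taxa = 6,
                       ancient_windows = 2,
                       ancient_window_genes = 12,
                       conserved_frac = 0.4,
                       conserved_window_genes = 15,
                       n_lineage_specific = 8,
                       species_pi = c(G = 0.0004, Q = 0.0022, J = 0.0039,
                                      N = 0.0020),
                       divergence_scale = c(G = 1, Q = 1, J = 1, N = 1),
                       base_divergence = 0.004,
                       outgroup_divergence = 0.02,
                       low_qual_frac = 0.05,
                       n_accessions = c(G = 4, Q = 4, J = 4, N = 4),
                       n_meth_replicates = 3,
                       read_depth_mean = 30,
                       meth_class_means = default_meth_class_means(),
                       meth_singleton_shift = 0.12,
                       meth_doublet_shift = -0.08,
                       meth_singleton_sd = 0.10,
                       meth_doublet_sd = 0.03,
                       meth_copy_sd = 0.06,
                       meth_species_sd = 0.03,
                       meth_diploid_sd = 0.08,
                       meth_rep_sd = 0.01,
                       n_dmg = 8,
                       dmg_contrasts = list(c("G", "N"), c("Q", "N"),
                                            c("J", "N"), c("G", "Q")),
                       dmg_levels = c(high = 0.78, low = 0.12),
                       asym_frac = 0.2,
                       asym_offset = 0.4,
                       n_absent = c(Q = 3, J = 3)) {
  if (length(fractionation_prob) == 1) {
    fractionation_prob <- c(A = unname(fractionation_prob),
                            B = unname(fractionation_prob))
  }
  cfg <- list(seed = as.integer(seed),
              n_ancestral_genes = as.integer(n_ancestral_genes),
              n_scaffolds = as.integer(n_scaffolds),
              gene_length_bp = as.integer(gene_length_bp),
              intergenic_bp = as.integer(intergenic_bp),
              fractionation_prob = fractionation_prob,
              diploid_loss_prob = diploid_loss_prob,
              ssd_counts = ssd_counts,
              segment_genes = as.integer(segment_genes),
              n_ref_taxa = as.integer(n_ref_taxa),
              ancient_windows = as.integer(ancient_windows),
              ancient_window_genes = as.integer(ancient_window_genes),
              conserved_frac = conserved_frac,
              conserved_window_genes = as.integer(conserved_window_genes),
              n_lineage_specific = as.integer(n_lineage_specific),
              species_pi = species_pi,
              divergence_scale = divergence_scale,
              base_divergence = base_divergence,
              outgroup_divergence = outgroup_divergence,
              low_qual_frac = low_qual_frac,
              n_accessions = n_accessions,
              n_meth_replicates = as.integer(n_meth_replicates),
              read_depth_mean = read_depth_mean,
              meth_class_means = meth_class_means,
              meth_singleton_shift = meth_singleton_shift,
              meth_doublet_shift = meth_doublet_shift,
              meth_singleton_sd = meth_singleton_sd,
              meth_doublet_sd = meth_doublet_sd,
              meth_copy_sd = meth_copy_sd,
              meth_species_sd = meth_species_sd,
              meth_diploid_sd = meth_diploid_sd,
              meth_rep_sd = meth_rep_sd,
              n_dmg = as.integer(n_dmg),
              dmg_contrasts = dmg_contrasts,
              dmg_levels = dmg_levels,
              asym_frac = asym_frac,
              asym_offset = asym_offset,
              n_absent = n_absent)
  validate_sim_config(cfg)
  class(cfg) <- "dupevol_config"
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) abort(paste0("configuration error: ", msg))
  for (key in c("fractionation_prob", "diploid_loss_prob", "conserved_frac",
                "low_qual_frac", "asym_frac")) {
    chk(all(cfg[[key]] >= 0 & cfg[[key]] <= 1),
        paste0(key, " must lie in [0, 1]"))
  }
  counts <- c(cfg$n_ancestral_genes, cfg$n_scaffolds, cfg$gene_length_bp,
              cfg$intergenic_bp, cfg$ssd_counts, cfg$segment_genes,
              cfg$n_ref_taxa, cfg$ancient_windows, cfg$ancient_window_genes,
              cfg$n_lineage_specific, cfg$n_meth_replicates, cfg$n_dmg,
              cfg$n_accessions, cfg$n_absent)
  chk(all(counts >= 0), "all counts must be >= 0")
  chk(cfg$n_ancestral_genes >= 1 && cfg$n_scaffolds >= 1,
      "need at least one gene and one scaffold")
  chk(cfg$gene_length_bp %% 3 == 0,
      "gene_length_bp must be a multiple of 3 (genes are in-frame CDS)")
  need_modes <- c("tandem", "proximal", "transposed", "dispersed", "segmental")
  chk(all(need_modes %in% names(cfg$ssd_counts)),
      paste("ssd_counts needs named entries:", paste(need_modes, collapse = ", ")))
  chk(all(c("A", "B") %in% names(cfg$fractionation_prob)),
      "fractionation_prob needs entries A and B")
  chk(sum(cfg$ssd_counts) < cfg$n_ancestral_genes,
      "ssd counts must sum to less than n_ancestral_genes")
  chk(all(c("G", "Q", "J", "N") %in% names(cfg$species_pi)),
      "species_pi needs entries G, Q, J, N")
  chk(all(cfg$species_pi >= 0 & cfg$species_pi <= 0.75),
      "species_pi must lie in [0, 0.75]")
  chk(all(c("G", "Q", "J", "N") %in% names(cfg$n_accessions)),
      "n_accessions needs entries G, Q, J, N")
  chk(all(cfg$n_accessions >= 1), "every species needs at least one accession")
  chk(is.data.frame(cfg$meth_class_means) &&
        all(c("class", "CG", "CHG", "CHH") %in% names(cfg$meth_class_means)),
      "meth_class_means needs columns class, CG, CHG, CHH")
  mm <- as.matrix(cfg$meth_class_means[, c("CG", "CHG", "CHH")])
  chk(all(mm >= 0 & mm <= 1), "methylation means must lie in [0, 1]")
  chk(all(cfg$dmg_levels >= 0 & cfg$dmg_levels <= 1) &&
        all(c("high", "low") %in% names(cfg$dmg_levels)),
      "dmg_levels needs high/low entries in [0, 1]")
  chk(cfg$asym_offset >= 0 && cfg$asym_offset <= 1,
      "asym_offset must lie in [0, 1]")
  chk(cfg$read_depth_mean > 0, "read_depth_mean must be positive")
  invisible(cfg)
}

#' @export
print.dupevol_config <- function(x, ...) {
  cat("dupevol simulation config\n")
  cat(sprintf("  seed %d | %d ancestral genes on %d scaffold(s), %d bp each\n",
              x$seed, x$n_ancestral_genes, x$n_scaffolds, x$gene_length_bp))
  cat(sprintf("  fractionation A=%.2f B=%.2f | diploid loss %.2f\n",
              x$fractionation_prob[["A"]], x$fractionation_prob[["B"]],
              x$diploid_loss_prob))
  cat("  ssd events:", paste(names(x$ssd_counts), x$ssd_counts, sep = "=",
                             collapse = " "), "\n")
  cat("  species_pi:", paste(names(x$species_pi),
                             format(x$species_pi, digits = 2),
                             sep = "=", collapse = " "), "\n")
  invisible(x)
}
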