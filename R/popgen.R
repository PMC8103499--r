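# Per-gene population-genetic statistics from haplotype-by-site allele
# matrices. A genotype set is a tibble with one row per (gene, species):
# columns gene_id, species, geno (list of character matrices, haplotypes x
# variant sites, values A/C/G/T or NA), sites (list of tibbles pos/MQ/DP),
# gene_length. Monomorphic sites are not stored; they enter through the
# gene_length denominator.

validate_genotype_set <- function(x) {
  need <- c("gene_id", "species", "geno", "sites", "gene_length")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    abort(paste("genotype set needs columns:", paste(need, collapse = ", ")))
  }
  invisible(x)
}

#' Filter variant sites on mapping quality and read depth
#'
#' Retains only sites with `MQ > min_mq` and `DP > min_dp` (both strict, the
#' conventional hard-filter reading of "MQ > 30, RD > 3"). The gene length is
#' unchanged, so the monomorphic-site denominator of pi and dxy is preserved.
#'
#' @param genotypes genotype-set tibble (see [simulate_population_variants()]).
#' @param min_mq,min_dp strict lower thresholds (defaults 30 and 3).
#' @return the genotype set with failing site columns removed.
#' @export
filter_variants <- function(genotypes, min_mq = 30, min_dp = 3) {
  validate_genotype_set(genotypes)
  if (nrow(genotypes) == 0) return(genotypes)
  genotypes$geno <- map2(genotypes$geno, genotypes$sites, function(g, s) {
    g[, s$MQ > min_mq & s$DP > min_dp, drop = FALSE]
  })
  genotypes$sites <- map(genotypes$sites, function(s) {
    s[s$MQ > min_mq & s$DP > min_dp, , drop = FALSE]
  })
  genotypes
}

# per-site mean mismatch fraction over called pairs within one matrix,
# summed over sites (sites with < 2 called haplotypes skipped)
pi_numerator <- function(geno) {
  if (is.null(dim(geno)) || ncol(geno) == 0) return(0)
  tot <- 0
  for (j in seq_len(ncol(geno))) {
    al <- geno[, j]
    al <- al[!is.na(al)]
    nc <- length(al)
    if (nc < 2) next
    cnt <- tabulate(factor(al, levels = c("A", "C", "G", "T")), nbins = 4)
    pairs <- choose(nc, 2)
    same <- sum(choose(cnt, 2))
    tot <- tot + (pairs - same) / pairs
  }
  tot
}

#' Nucleotide diversity (pi) of one gene
#'
#' Average per-site pairwise difference among haplotypes, over the full gene
#' length: `pi = sum over haplotype pairs of per-site mismatches /
#' (n_pairs x gene_length_bp)`. Missing genotypes are handled by pairwise
#' deletion per site; sites with fewer than two called haplotypes are
#' skipped. With fewer than two haplotypes in total the statistic is
#' undefined (`NA`).
#'
#' @param geno character matrix, haplotypes x variant sites (A/C/G/T/NA).
#'   Monomorphic sites may be omitted; they are covered by `gene_length`.
#' @param gene_length gene length in bp (the denominator).
#' @return pi in differences/site, or `NA` if undefined.
#' @examples
#' g <- rbind(c("A"), c("A"), c("C"), c("C"))
#' nucleotide_diversity(g, gene_length = 10)  # (2*2)/(6*10)
#' @export
nucleotide_diversity <- function(geno, gene_length) {
  stopifnot(gene_length > 0)
  if (is.null(dim(geno))) geno <- matrix(geno, ncol = 1)
  if (nrow(geno) < 2) return(NA_real_)
  pi_numerator(geno) / gene_length
}

#' Absolute divergence (dxy) between two populations at one gene
#'
#' Average per-site difference over all between-population haplotype pairs,
#' over the full gene length. The two matrices must be aligned to the same
#' site columns (same positions in the same order). Missing genotypes use
#' pairwise deletion; sites with no called haplotype in either population are
#' skipped. Symmetric in its arguments.
#'
#' @param geno_a,geno_b character matrices (haplotypes x shared variant
#'   sites).
#' @param gene_length gene length in bp.
#' @return dxy in differences/site, or `NA` when undefined (zero length).
#' @export
dxy <- function(geno_a, geno_b, gene_length) {
  if (is.null(dim(geno_a))) geno_a <- matrix(geno_a, ncol = 1)
  if (is.null(dim(geno_b))) geno_b <- matrix(geno_b, ncol = 1)
  if (ncol(geno_a) != ncol(geno_b)) {
    abort("dxy() needs matrices aligned to the same sites")
  }
  if (gene_length <= 0) return(NA_real_)
  if (nrow(geno_a) < 1 || nrow(geno_b) < 1) return(NA_real_)
  tot <- 0
  for (j in seq_len(ncol(geno_a))) {
    a <- geno_a[, j]; a <- a[!is.na(a)]
    b <- geno_b[, j]; b <- b[!is.na(b)]
    if (length(a) == 0 || length(b) == 0) next
    ca <- tabulate(factor(a, levels = c("A", "C", "G", "T")), nbins = 4)
    cb <- tabulate(factor(b, levels = c("A", "C", "G", "T")), nbins = 4)
    tot <- tot + (length(a) * length(b) - sum(ca * cb)) / (length(a) * length(b))
  }
  tot / gene_length
}

#' Gene presence from relative read depth
#'
#' A gene is called present in a species when its mean read depth reaches
#' `rel_threshold` times the genome-wide median depth.
#'
#' @param per_gene_mean_depth mean mapped read depth over the gene (>= 0).
#' @param genome_median_depth genome-wide median depth (> 0).
#' @param rel_threshold relative presence threshold (default 0.2).
#' @return logical.
#' @export
gene_presence_by_depth <- function(per_gene_mean_depth, genome_median_depth,
                                   rel_threshold = 0.2) {
  if (any(genome_median_depth <= 0)) abort("genome median depth must be > 0")
  if (any(per_gene_mean_depth < 0)) abort("depths must be >= 0")
  per_gene_mean_depth >= rel_threshold * genome_median_depth
}

#' Per-gene population-genetic summary table
#'
#' Applies the variant filter, then computes pi per (gene, species) and dxy
#' for every species pair sharing a gene's coordinate frame, returning one
#' tidy row per gene x statistic.
#'
#' @param genotypes genotype-set tibble.
#' @param min_mq,min_dp variant filter thresholds (see [filter_variants()]).
#' @param dxy_species species compared pairwise for dxy; defaults to all
#'   species that share gene ids.
#' @return list of two tibbles: `pi` (gene_id, species, pi) and `dxy`
#'   (gene_id, species_a, species_b, dxy).
#' @export
popgen_gene_stats <- function(genotypes, min_mq = 30, min_dp = 3,
                              dxy_species = NULL) {
  validate_genotype_set(genotypes)
  gt <- filter_variants(genotypes, min_mq = min_mq, min_dp = min_dp)
  pi_tbl <- gt |>
    mutate(pi = map2_dbl(.data$geno, .data$gene_length, nucleotide_diversity)) |>
    select("gene_id", "species", "pi")
  # dxy needs per-gene matrices aligned to shared coordinates; genotype sets
  # built by the simulator store, per gene, the same site columns in every
  # species that carries the gene
  sp <- dxy_species %||% unique(gt$species)
  pairs <- if (length(sp) >= 2) combn(sort(sp), 2) else matrix(nrow = 2, ncol = 0)
  dxy_rows <- list()
  if (ncol(pairs) > 0) {
    by_gene <- split(gt, gt$gene_id)
    for (g in names(by_gene)) {
      sub <- by_gene[[g]]
      for (k in seq_len(ncol(pairs))) {
        ia <- which(sub$species == pairs[1, k])
        ib <- which(sub$species == pairs[2, k])
        if (length(ia) != 1 || length(ib) != 1) next
        # per-species QC filters may retain different sites; align on the
        # shared surviving positions (a site filtered out in either species
        # contributes only through the monomorphic denominator)
        pa <- sub$sites[[ia]]$pos
        pb <- sub$sites[[ib]]$pos
        shared <- intersect(pa, pb)
        ga <- sub$geno[[ia]][, match(shared, pa), drop = FALSE]
        gb <- sub$geno[[ib]][, match(shared, pb), drop = FALSE]
        dxy_rows[[length(dxy_rows) + 1]] <- tibble(
          gene_id = g, species_a = pairs[1, k], species_b = pairs[2, k],
          dxy = dxy(ga, gb, sub$gene_length[[ia]]))
      }
    }
  }
  list(pi = pi_tbl,
       dxy = if (length(dxy_rows)) list_rbind(dxy_rows) else
         tibble(gene_id = character(), species_a = character(),
                species_b = character(), dxy = double()))
}

#' @importFrom purrr map2_dbl
NULL
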