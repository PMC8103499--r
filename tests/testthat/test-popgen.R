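test_that("variant filter applies strict MQ/DP thresholds and keeps length", {
  gt <- tibble::tibble(
    gene_id = "g1", species = "G",
    geno = list(matrix(c("A", "C", "A", "C", "G", "G"), nrow = 2)),
    sites = list(tibble::tibble(pos = c(3L, 7L, 9L),
                                MQ = c(30, 31, 45), DP = c(10, 4, 3))),
    gene_length = 100L)
  f <- filter_variants(gt, min_mq = 30, min_dp = 3)
  # MQ = 30 removed (strict >), DP = 3 removed (strict >), MQ 31 / DP 4 kept
  expect_equal(f$sites[[1]]$pos, 7L)
  expect_equal(dim(f$geno[[1]]), c(2L, 1L))
  expect_equal(f$gene_length, 100L)
  empty <- gt[0, ]
  expect_equal(nrow(filter_variants(empty)), 0L)
})

test_that("pi matches the hand example and brute force, with invariances", {
  g <- matrix(c("A", "A", "C", "C"), ncol = 1)
  expect_equal(nucleotide_diversity(g, 10), (2 * 2) / (6 * 10))
  expect_equal(nucleotide_diversity(matrix("A", 4, 3), 50), 0)
  # doubling the length halves pi
  expect_equal(nucleotide_diversity(g, 20), nucleotide_diversity(g, 10) / 2)
  expect_true(is.na(nucleotide_diversity(matrix("A", 1, 3), 10)))
  set.seed(21)
  for (rep in 1:40) {
    m <- random_geno_matrix(sample(2:10, 1), sample(1:20, 1),
                            missing_frac = sample(c(0, 0.2), 1))
    expect_equal(nucleotide_diversity(m, 30), oracle_pi(m, 30),
                 tolerance = 1e-12)
    # invariant under haplotype and site reordering
    expect_equal(nucleotide_diversity(m[sample(nrow(m)), , drop = FALSE], 30),
                 nucleotide_diversity(m, 30))
    expect_equal(nucleotide_diversity(m[, sample(ncol(m)), drop = FALSE], 30),
                 nucleotide_diversity(m, 30))
  }
})

test_that("dxy matches brute force, is symmetric, handles fixed differences", {
  a <- matrix("C", 4, 1)
  b <- matrix("T", 4, 1)
  expect_equal(dxy(a, b, 10), 0.1)
  expect_equal(dxy(matrix("A", 3, 2), matrix("A", 5, 2), 10), 0)
  set.seed(22)
  for (rep in 1:40) {
    ns <- sample(1:15, 1)
    ga <- random_geno_matrix(sample(2:8, 1), ns, missing_frac = 0.1)
    gb <- random_geno_matrix(sample(2:8, 1), ns, missing_frac = 0.1)
    expect_equal(dxy(ga, gb, 25), oracle_dxy(ga, gb, 25), tolerance = 1e-12)
    expect_equal(dxy(ga, gb, 25), dxy(gb, ga, 25), tolerance = 1e-12)
  }
  expect_error(dxy(matrix("A", 2, 3), matrix("A", 2, 2), 10), "aligned")
})

test_that("pi equals cross-half dxy when a population is duplicated", {
  set.seed(23)
  m <- random_geno_matrix(6, 12)
  # split two identical copies of the population into the two groups:
  # every inter-group pair mirrors a within-population comparison plus
  # self-pairs, which contribute zero differences
  d <- dxy(m, m, 40)
  p <- nucleotide_diversity(m, 40)
  # inter-group pairs: n^2 pairs = n(n-1) ordered (mismatching like pi) + n
  # identical self-pairs, so dxy = pi * (n-1)/n
  n <- nrow(m)
  expect_equal(d, p * (n - 1) / n, tolerance = 1e-12)
})

test_that("gene presence uses the relative depth rule", {
  expect_false(gene_presence_by_depth(0, 30))
  expect_true(gene_presence_by_depth(30, 30, 0.2))
  expect_false(gene_presence_by_depth(5, 30, 0.2))  # 5 < 6
  expect_true(gene_presence_by_depth(6, 30, 0.2))
  expect_error(gene_presence_by_depth(5, 0), "median")
})

test_that("simulated species recover the planted diversity rank order", {
  g <- fixture_genomes()
  v <- simulate_population_variants(g, g$config)
  stats <- popgen_gene_stats(
    dplyr::filter(v$genotypes, species %in% c("G", "Q", "J")),
    dxy_species = character(0))
  mp <- stats$pi |>
    dplyr::group_by(species) |>
    dplyr::summarise(pi = mean(pi, na.rm = TRUE))
  pis <- setNames(mp$pi, mp$species)
  expect_lt(pis[["G"]], pis[["Q"]])
  expect_lt(pis[["Q"]], pis[["J"]])
  # realized within 20% of target at this genome size
  tr <- v$truth$pi
  expect_true(all(abs(tr$realized - tr$target) <= 0.2 * pmax(tr$target, 1e-6)))
  # per-gene sign test: J > G for most genes (planted rank structure)
  wide <- stats$pi |>
    tidyr::pivot_wider(names_from = "species", values_from = "pi")
  diffs <- wide$J - wide$G
  diffs <- diffs[!is.na(diffs) & diffs != 0]
  bt <- stats::binom.test(sum(diffs > 0), length(diffs))
  expect_gt(mean(diffs > 0), 0.5)
  expect_lt(bt$p.value, 0.01)
})

test_that("zero target diversity gives identical haplotypes within species", {
  cfg <- sim_config(seed = 3, n_ancestral_genes = 60,
                    species_pi = c(G = 0, Q = 0, J = 0, N = 0),
                    low_qual_frac = 0)
  g <- simulate_genomes(cfg)
  v <- simulate_population_variants(g, cfg)
  same <- vapply(v$genotypes$geno, function(m) {
    ncol(m) == 0 || all(apply(m, 2, function(col) length(unique(col)) == 1))
  }, logical(1))
  expect_true(all(same))
})

test_that("doubling a branch scale increases dxy involving that species", {
  base <- sim_config(seed = 9, n_ancestral_genes = 60, low_qual_frac = 0)
  up <- sim_config(seed = 9, n_ancestral_genes = 60, low_qual_frac = 0,
                   divergence_scale = c(G = 1, Q = 2, J = 1, N = 1))
  g1 <- simulate_genomes(base)
  g2 <- simulate_genomes(up)
  d1 <- popgen_gene_stats(
    dplyr::filter(simulate_population_variants(g1, base)$genotypes,
                  species %in% c("G", "Q")),
    dxy_species = c("G", "Q"))$dxy
  d2 <- popgen_gene_stats(
    dplyr::filter(simulate_population_variants(g2, up)$genotypes,
                  species %in% c("G", "Q")),
    dxy_species = c("G", "Q"))$dxy
  expect_gt(mean(d2$dxy, na.rm = TRUE), mean(d1$dxy, na.rm = TRUE))
})
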