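test_that("class comparisons recover planted directions; self-compare is ns", {
  set.seed(71)
  n <- 120
  gid <- sprintf("g%03d", 1:n)
  hypo <- gid[1:30]
  hyper <- gid[31:50]
  value <- c(rnorm(30, 0.2, 0.05), rnorm(20, 0.85, 0.05),
             rnorm(70, 0.5, 0.08))
  gene_stats <- tibble::tibble(gene_id = gid, statistic = "meth_CG",
                               value = value)
  classes <- dplyr::bind_rows(
    tibble::tibble(gene_id = hypo, class = "ancient_collinear"),
    tibble::tibble(gene_id = hyper, class = "dispersed"),
    tibble::tibble(gene_id = gid, class = "overall"))
  res <- compare_classes(gene_stats, classes)
  anc <- res[res$class == "ancient_collinear", ]
  dsp <- res[res$class == "dispersed", ]
  ovl <- res[res$class == "overall", ]
  expect_equal(anc$direction, "lower")
  expect_lt(anc$q, 0.05)
  expect_equal(dsp$direction, "higher")
  expect_lt(dsp$q, 0.05)
  expect_equal(ovl$direction, "ns")
  expect_equal(ovl$p, 1)
  # empty class is untestable
  res2 <- compare_classes(gene_stats,
                          tibble::tibble(gene_id = "absent", class = "ghost"))
  expect_true(res2$untestable)
  # output invariant to gene input order
  perm <- sample(n)
  res3 <- compare_classes(gene_stats[perm, ], classes)
  expect_equal(res, res3)
})

test_that("BH q-values are monotone in p within each family", {
  set.seed(72)
  gene_stats <- tidyr::expand_grid(gene_id = sprintf("g%02d", 1:40),
                                   statistic = c("s1", "s2")) |>
    dplyr::mutate(value = runif(dplyr::n()))
  classes <- tibble::tibble(gene_id = rep(sprintf("g%02d", 1:40), 2),
                            class = rep(c("c1", "c2"), each = 40))
  res <- compare_classes(gene_stats, classes)
  for (s in unique(res$statistic)) {
    sub <- res[res$statistic == s & !is.na(res$p), ]
    o <- order(sub$p)
    expect_true(all(diff(sub$q[o]) >= -1e-12))
  }
})

test_that("planted shared asymmetry is detected; the null sits near chance", {
  set.seed(73)
  n <- 150
  pair_id <- sprintf("p%03d", 1:n)
  planted <- rep(c(TRUE, FALSE), c(50, 100))
  sgn <- ifelse(runif(n) < 0.5, 1, -1)
  mk_levels <- function(species) {
    a <- 0.5 + ifelse(planted, sgn * 0.2, 0) + rnorm(n, 0, 0.05)
    b <- 0.5 - ifelse(planted, sgn * 0.2, 0) + rnorm(n, 0, 0.05)
    dplyr::bind_rows(
      tibble::tibble(gene_id = paste0(pair_id, "_A"), species = species,
                     value = pmin(pmax(a, 0), 1)),
      tibble::tibble(gene_id = paste0(pair_id, "_B"), species = species,
                     value = pmin(pmax(b, 0), 1)))
  }
  levels <- dplyr::bind_rows(mk_levels("G"), mk_levels("Q"), mk_levels("J"))
  pairs <- tibble::tibble(pair_id = pair_id,
                          gene_a = paste0(pair_id, "_A"),
                          gene_b = paste0(pair_id, "_B"))
  res <- subgenome_asymmetry(levels, pairs)
  pg <- res$per_gene
  expect_gte(mean(pg$sign_consistent[pg$pair_id %in% pair_id[planted]]), 0.95)
  # with independent per-species noise, three species agree by chance 1/4
  null_rate <- mean(pg$sign_consistent[pg$pair_id %in% pair_id[!planted]])
  expect_lt(abs(null_rate - 0.25), 3 * sqrt(0.25 * 0.75 / 100) + 0.02)
  # shared asymmetry makes same-subgenome between-species profiles cohere
  pm <- setNames(res$partition_means$mean_rho, res$partition_means$partition)
  expect_gt(pm[["between_species_same_subgenome"]],
            pm[["within_species_between_subgenome"]])
})

test_that("single-species input: consistency undefined, correlations intact", {
  set.seed(74)
  n <- 30
  pairs <- tibble::tibble(pair_id = sprintf("p%02d", 1:n),
                          gene_a = sprintf("p%02d_A", 1:n),
                          gene_b = sprintf("p%02d_B", 1:n))
  levels <- dplyr::bind_rows(
    tibble::tibble(gene_id = pairs$gene_a, species = "G", value = runif(n)),
    tibble::tibble(gene_id = pairs$gene_b, species = "G", value = runif(n)))
  res <- subgenome_asymmetry(levels, pairs)
  expect_true(all(res$per_gene$n_species == 1))
  expect_true(is.na(res$sign_consistency))
  expect_equal(nrow(res$correlations), 1L)
  expect_false(is.na(res$correlations$rho))
})

test_that("a subgenome-biased loss simulation is detected as biased", {
  cfg <- sim_config(seed = 75, n_ancestral_genes = 700,
                    fractionation_prob = c(A = 0.35, B = 0.15),
                    diploid_loss_prob = 0)
  g <- simulate_genomes(cfg)
  res <- fractionation_bias_test(
    g$truth$orthogroups |>
      dplyr::filter(!is.na(category)) |>
      dplyr::select(category, subgenome))
  expect_gt(res$lost_from_a, res$lost_from_b)
  expect_lt(res$p, 0.05)
})
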