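test_that("CMH matches the frozen hand-computed example and the formula", {
  strata <- list(matrix(c(30, 10, 5, 25), 2), matrix(c(28, 12, 7, 23), 2))
  res <- cmh_test(strata)
  # value computed independently from the defining sums before the build
  expect_equal(res$statistic, 37.26, tolerance = 1e-12)
  expect_equal(res$p.value, 1.033834991e-09, tolerance = 1e-6)
  expect_equal(res$statistic, oracle_cmh(strata))
  expect_equal(tidy(res)$n_strata, 2L)
})

test_that("CMH agrees with mantelhaen.test without continuity correction", {
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    strata <- replicate(k, matrix(rpois(4, 20) + 1, 2), simplify = FALSE)
    arr <- array(unlist(lapply(strata, t)), dim = c(2, 2, k))
    ref <- stats::mantelhaen.test(aperm(arr, c(2, 1, 3)), correct = FALSE)
    res <- cmh_test(strata)
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p.value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("CMH handles identical proportions, single strata and degeneracy", {
  # equal methylation proportions at equal margins: a_k = E a_k, statistic 0
  eq <- matrix(c(10, 10, 30, 30), 2)
  res <- cmh_test(list(eq, eq))
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
  # single stratum equals the uncorrected chi-square score statistic
  t1 <- matrix(c(12, 3, 8, 17), 2)
  res1 <- cmh_test(list(t1))
  cs <- stats::chisq.test(t1, correct = FALSE)
  expect_equal(res1$statistic * sum(t1) / (sum(t1) - 1),
               unname(cs$statistic), tolerance = 1e-10)
  # statistic invariant under stratum reordering
  s3 <- list(matrix(c(5, 9, 11, 2), 2), matrix(c(7, 7, 3, 12), 2),
             matrix(c(1, 8, 9, 4), 2))
  expect_equal(cmh_test(s3)$statistic, cmh_test(rev(s3))$statistic)
  # zero-margin strata dropped with a warning; all-degenerate is undefined
  expect_warning(res2 <- cmh_test(list(t1, matrix(c(0, 0, 5, 5), 2))),
                 "degenerate")
  expect_equal(res2$n_strata, 1L)
  expect_warning(res3 <- cmh_test(matrix(c(0, 0, 5, 5), 2)), "degenerate")
  expect_true(res3$undefined)
})

test_that("Fisher exact p matches full enumeration and is row-symmetric", {
  t1 <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(fisher_exact_2x2(t1), oracle_fisher(t1), tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  set.seed(7)
  for (rep in 1:25) {
    t <- matrix(rpois(4, 6), 2)
    if (sum(t) == 0) next
    p <- fisher_exact_2x2(t)
    expect_equal(p, oracle_fisher(t), tolerance = 1e-9)
    expect_equal(p, fisher_exact_2x2(t[2:1, ]), tolerance = 1e-12)
  }
  expect_warning(p0 <- fisher_exact_2x2(matrix(0L, 2, 2)), "all-zero")
  expect_equal(p0, 1)
})

test_that("Wilcoxon exact regime matches enumeration, including ties", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res$p.value, 2 / choose(6, 3))
  expect_equal(res$method, "exact")
  # symmetry: exchanging samples preserves p, reflects W
  res2 <- wilcoxon_rank_sum(c(10, 11, 12), c(1, 2, 3))
  expect_equal(res2$p.value, res$p.value)
  expect_equal(res$statistic + res2$statistic, 9)
  set.seed(11)
  for (rep in 1:30) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- sample(1:5, nx, replace = TRUE)  # heavy ties on purpose
    y <- sample(1:5, ny, replace = TRUE)
    expect_equal(wilcoxon_rank_sum(x, y)$p.value, oracle_wilcoxon(x, y),
                 tolerance = 1e-12)
  }
  # tie-free exact regime agrees with wilcox.test
  set.seed(12)
  for (rep in 1:10) {
    x <- runif(5); y <- runif(6)
    expect_equal(wilcoxon_rank_sum(x, y)$p.value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # identical multisets sit at the null centre
  expect_gt(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p.value, 0.9)
  expect_equal(wilcoxon_rank_sum(rep(2, 5), rep(2, 7))$p.value, 1)
})

test_that("Wilcoxon normal regime matches wilcox.test with correction", {
  set.seed(13)
  for (rep in 1:10) {
    x <- round(rnorm(15), 1); y <- round(rnorm(20, 0.4), 1)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    res <- wilcoxon_rank_sum(x, y)
    expect_equal(res$method, "normal")
    expect_equal(res$statistic, unname(ref$statistic))
    expect_equal(res$p.value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("Spearman correlation handles ties, reversals and degeneracy", {
  expect_equal(profile_correlation(1:10, 1:10), 1)
  expect_equal(profile_correlation(1:10, 10:1), -1)
  x <- c(1, 2, 2, 3, 5, 5)
  y <- c(2, 1, 4, 4, 6, 7)
  expect_equal(profile_correlation(x, y), oracle_spearman(x, y))
  expect_warning(r <- profile_correlation(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r))
  expect_warning(r2 <- profile_correlation(c(1, 2, NA), c(1, NA, 3)),
                 "fewer than 3")
  expect_true(is.na(r2))
})

test_that("hypergeometric enrichment matches tail summation and BH", {
  universe <- sprintf("g%03d", 1:100)
  ann <- tibble::tibble(
    gene_id = universe,
    category = rep(c("K1", "K2", "K3", "K4", "K5"), each = 20))
  set.seed(5)
  gs <- c(sample(universe[1:20], 8), sample(universe[21:100], 12))
  res <- enrichment_hypergeometric(gs, ann, universe)
  for (i in seq_len(nrow(res))) {
    expect_equal(res$p[i],
                 oracle_hyper_tail(res$k[i], res$K[i], res$n[i], res$N[i]),
                 tolerance = 1e-12)
  }
  expect_equal(res$q, oracle_bh(res$p), tolerance = 1e-12)
  # the fully contained category is the most enriched
  expect_equal(res$category[1], "K1")
  # a category absent from the set is never enriched
  k5 <- res[res$category == "K5", ]
  if (nrow(k5) == 1) expect_gte(k5$p, 0.5)
  # errors
  expect_error(enrichment_hypergeometric("nope", ann, universe), "subset")
})

test_that("fractionation bias test equals the exact binomial enumeration", {
  og <- tibble::tibble(category = c(rep("singleton", 10), "doublet"),
                       subgenome = c(rep("B", 9), "A", NA))
  res <- fractionation_bias_test(og)
  expect_equal(res$lost_from_a, 9L)
  # 2 * sum_{k>=9} C(10,k) / 2^10, the two-sided exact binomial
  expect_equal(res$p, 2 * sum(choose(10, 9:10)) / 2^10, tolerance = 1e-12)
  balanced <- tibble::tibble(category = rep("singleton", 100),
                             subgenome = rep(c("A", "B"), 50))
  expect_gt(fractionation_bias_test(balanced)$p, 0.9)
  empty <- fractionation_bias_test(tibble::tibble(category = "doublet",
                                                  subgenome = NA))
  expect_true(empty$untestable)
})
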