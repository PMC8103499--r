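toy_methylome <- function(total, meth, context = "CG",
                          species = c("X", "X", "Y", "Y"),
                          gene_len = 100L) {
  n <- nrow(total)
  samples <- tibble::tibble(
    sample = paste0("s", seq_len(ncol(total))),
    species = species,
    replicate = stats::ave(seq_along(species), species, FUN = seq_along))
  colnames(total) <- samples$sample
  colnames(meth) <- samples$sample
  sites <- tibble::tibble(gene_id = "g1", scaffold = "s1",
                          pos = seq_len(n) * 3L,
                          strand = "+", context = context)
  out <- list(sites = sites, samples = samples,
              meth = meth, total = total)
  class(out) <- "dupevol_methylome"
  out
}

test_that("site depth filter is strict and requires every sample", {
  total <- rbind(c(10, 30, 30, 30),   # depth exactly 10 in one sample: out
                 c(11, 11, 11, 11),   # strictly above everywhere: kept
                 c(30, 30, 9, 30))    # fails in one sample: out
  m <- toy_methylome(total, total * 0)
  f <- filter_sites(m, min_total_depth = 10)
  expect_equal(nrow(f$sites), 1L)
  expect_equal(unname(f$total[1, 1]), 11)
  f2 <- filter_sites(m, min_total_depth = 10, samples = m$samples$sample[2:4])
  expect_equal(nrow(f2$sites), 2L)
  expect_error(filter_sites(m, samples = "nope"), "unknown sample")
  empty <- filter_sites(m, min_total_depth = 100)
  expect_equal(nrow(empty$sites), 0L)
})

test_that("weighted level is count-weighted, and absence is NA not zero", {
  expect_equal(weighted_methylation_level(c(5, 0), c(10, 10)), 0.25)
  expect_equal(weighted_methylation_level(c(10, 10), c(10, 10)), 1)
  expect_true(is.na(weighted_methylation_level(numeric(0), numeric(0))))
  total <- rbind(c(20, 20, 20, 20), c(20, 20, 20, 20))
  meth <- rbind(c(5, 20, 0, 10), c(0, 20, 0, 10))
  m <- toy_methylome(total, meth)
  lev <- gene_methylation(m)
  expect_equal(nrow(lev), 4L)
  expect_equal(lev$level[lev$sample == "s1"], 5 / 40)
  expect_equal(lev$level[lev$sample == "s2"], 1)
  expect_equal(lev$n_sites, rep(2L, 4))
})

test_that("planted DMGs pass all three criteria; near-threshold genes fail", {
  set.seed(51)
  n_sites <- 60
  lv <- function(p, depth = 30) {
    cov <- rpois(n_sites, depth)
    rbind(meth = rbinom(n_sites, cov, p), total = cov)
  }
  mk <- function(pa, pb) {
    cols <- list(lv(pa), lv(pa + 0.02), lv(pb), lv(pb - 0.02))
    total <- do.call(cbind, purrr::map(cols, ~ .x["total", ]))
    meth <- do.call(cbind, purrr::map(cols, ~ .x["meth", ]))
    toy_methylome(total, meth)
  }
  genes <- tibble::tibble(gene_id = "g1", start = 1L, end = 200L)
  # planted difference 0.6, within-species difference 0.02
  m <- mk(0.75, 0.15)
  call <- call_dmgs(m, genes, c("X", "Y"))
  expect_true(all(call$is_dmg))
  expect_gt(min(call$frac_sig_windows), 0.1)
  # between-species difference below 0.5 fails regardless of significance
  m2 <- mk(0.60, 0.15)
  call2 <- call_dmgs(m2, genes, c("X", "Y"))
  expect_false(any(call2$is_dmg))
  expect_false(any(call2$crit_between))
  expect_true(all(call2$crit_windows))  # still highly significant
})

test_that("a real intraspecific difference blocks the DMG call", {
  set.seed(52)
  n_sites <- 60
  cov <- function() rpois(n_sites, 40)
  mk_col <- function(p) { cv <- cov(); rbind(rbinom(n_sites, cv, p), cv) }
  cols <- list(mk_col(0.9), mk_col(0.55), mk_col(0.1), mk_col(0.1))
  m <- toy_methylome(do.call(cbind, purrr::map(cols, ~ .x[2, ])),
                     do.call(cbind, purrr::map(cols, ~ .x[1, ])))
  genes <- tibble::tibble(gene_id = "g1", start = 1L, end = 200L)
  call <- call_dmgs(m, genes, c("X", "Y"))
  expect_false(any(call$crit_within))
  expect_false(any(call$is_dmg))
})

test_that("species with a single replicate downgrades criterion 1", {
  set.seed(53)
  n_sites <- 40
  cv <- rpois(n_sites, 30)
  total <- cbind(cv, cv, cv)
  meth <- cbind(rbinom(n_sites, cv, 0.8), rbinom(n_sites, cv, 0.1),
                rbinom(n_sites, cv, 0.1))
  m <- toy_methylome(total, meth, species = c("X", "Y", "Y"))
  genes <- tibble::tibble(gene_id = "g1", start = 1L, end = 120L)
  call <- call_dmgs(m, genes, c("X", "Y"))
  expect_true(all(call$within_downgraded))
  expect_true(all(call$is_dmg))
})

test_that("methylome simulation is seed-reproducible and plants recallable DMGs", {
  cfg <- sim_config(seed = 61, n_ancestral_genes = 80, n_dmg = 6,
                    dmg_contrasts = list(c("G", "N")))
  g <- simulate_genomes(cfg)
  m1 <- simulate_methylomes(g, cfg)
  m2 <- simulate_methylomes(g, cfg)
  expect_identical(m1$meth, m2$meth)
  expect_identical(m1$total, m2$total)
  tet <- dplyr::filter(g$genes, taxon == "tetraploid")
  call <- call_dmgs(m1, tet, c("G", "N"))
  truth <- m1$truth$dmg$gene_id
  recalled <- truth %in% call$gene_id[call$is_dmg]
  expect_gte(mean(recalled), 0.9)
  # requesting more DMGs than eligible genes is a configuration error
  cfg_bad <- cfg
  cfg_bad$n_dmg <- 10000L
  expect_error(simulate_methylomes(g, cfg_bad), "configuration error")
})

test_that("contexts are assigned from the sequence", {
  cfg <- sim_config(seed = 62, n_ancestral_genes = 60)
  g <- simulate_genomes(cfg)
  m <- simulate_methylomes(g, cfg)
  tet <- dplyr::filter(g$genes, taxon == "tetraploid")
  st <- m$sites |> dplyr::left_join(tet, by = c("gene_id", "scaffold"))
  off <- st$pos - st$start + 1L
  for (i in sample(nrow(st), 50)) {
    b <- strsplit(g$sequences[[st$gene_id[i]]], "")[[1]]
    if (st$strand.x[i] == "+") {
      expect_equal(b[off[i]], "C")
      want <- if (b[off[i] + 1] == "G") "CG" else
        if (b[off[i] + 2] == "G") "CHG" else "CHH"
    } else {
      expect_equal(b[off[i]], "G")
      want <- if (b[off[i] - 1] == "C") "CG" else
        if (b[off[i] - 2] == "C") "CHG" else "CHH"
    }
    expect_equal(st$context[i], want)
  }
})

test_that("intraspecific profile correlations exceed interspecific ones", {
  g <- fixture_genomes()
  m <- simulate_methylomes(g, g$config)
  corr <- sample_profile_correlations(filter_sites(m))
  agg <- corr |>
    dplyr::group_by(context, comparison) |>
    dplyr::summarise(rho = mean(rho), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "comparison", values_from = "rho")
  expect_true(all(agg$intraspecific > agg$interspecific))
})
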