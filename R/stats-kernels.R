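#' Cochran-Mantel-Haenszel test for stratified 2x2 tables
#'
#' Classical CMH chi-square statistic (1 df, no continuity correction) for a
#' set of 2x2 tables sharing a common association, used here to combine
#' methylated/unmethylated counts across replicate-pair strata when comparing
#' two species. With a single stratum the statistic reduces exactly to the
#' uncorrected chi-square score statistic of that table.
#'
#' Each stratum is a 2x2 matrix with rows = the two groups (species) and
#' columns = (methylated, unmethylated). The statistic is
#' `M2 = (sum_k (a_k - E a_k))^2 / sum_k Var a_k` with
#' `E a_k = n1k m1k / nk` and `Var a_k = n1k n2k m1k m2k / (nk^2 (nk - 1))`,
#' where `a_k` is the top-left cell. Strata with a zero margin carry no
#' information and are dropped with a warning.
#'
#' @param strata a list of 2x2 numeric matrices (or a single matrix).
#' @return A list of class `dupevol_cmh` with elements `statistic`, `p.value`,
#'   `df`, `n_strata` (used), `n_dropped`.
#' @examples
#' cmh_test(list(matrix(c(30, 10, 5, 25), 2), matrix(c(28, 12, 7, 23), 2)))
#' @export
cmh_test <- function(strata) {
  if (is.matrix(strata)) strata <- list(strata)
  if (length(strata) < 1) abort("cmh_test() needs at least one stratum")
  ok <- vapply(strata, function(t) {
    is.matrix(t) && all(dim(t) == 2) && all(t >= 0) &&
      all(rowSums(t) > 0) && all(colSums(t) > 0)
  }, logical(1))
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    warn(sprintf("dropping %d degenerate stratum/strata with a zero margin", n_dropped))
  }
  strata <- strata[ok]
  if (length(strata) == 0) {
    out <- list(statistic = NA_real_, p.value = NA_real_, df = 1L,
                n_strata = 0L, n_dropped = n_dropped, undefined = TRUE)
    class(out) <- "dupevol_cmh"
    return(out)
  }
  a  <- vapply(strata, function(t) t[1, 1], numeric(1))
  n1 <- vapply(strata, function(t) sum(t[1, ]), numeric(1))
  n2 <- vapply(strata, function(t) sum(t[2, ]), numeric(1))
  m1 <- vapply(strata, function(t) sum(t[, 1]), numeric(1))
  m2 <- vapply(strata, function(t) sum(t[, 2]), numeric(1))
  nk <- n1 + n2
  ea <- n1 * m1 / nk
  va <- n1 * n2 * m1 * m2 / (nk^2 * (nk - 1))
  m2stat <- sum(a - ea)^2 / sum(va)
  out <- list(statistic = m2stat,
              p.value = pchisq(m2stat, df = 1, lower.tail = FALSE),
              df = 1L, n_strata = length(strata), n_dropped = n_dropped,
              undefined = FALSE)
  class(out) <- "dupevol_cmh"
  out
}

#' @export
print.dupevol_cmh <- function(x, ...) {
  cat("Cochran-Mantel-Haenszel test (no continuity correction)\n")
  cat(sprintf("  M^2 = %.4f, df = 1, p = %.4g (%d strata used, %d dropped)\n",
              x$statistic, x$p.value, x$n_strata, x$n_dropped))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dupevol_cmh <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value, df = x$df,
         n_strata = x$n_strata, n_dropped = x$n_dropped)
}

# vectorised CMH over many tests: inputs are matrices [tests x strata] of the
# top-left cell and the three margins. Returns the M^2 statistic per test.
cmh_stat_vec <- function(a, n1, n2, m1, m2) {
  # counts arrive as integers; the variance term overflows 32-bit
  a <- a + 0.0; n1 <- n1 + 0.0; n2 <- n2 + 0.0; m1 <- m1 + 0.0; m2 <- m2 + 0.0
  nk <- n1 + n2
  ea <- n1 * m1 / nk
  va <- n1 * n2 * m1 * m2 / (nk^2 * (nk - 1))
  bad <- !is.finite(va) | n1 == 0 | n2 == 0 | m1 == 0 | m2 == 0
  d <- a - ea
  d[bad] <- 0
  va[bad] <- 0
  num <- rowSums(d)^2
  den <- rowSums(va)
  ifelse(den > 0, num / den, NA_real_)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p-value summing hypergeometric probabilities of all tables (with
#' the observed margins) no more probable than the observed one. Thin wrapper
#' over [stats::fisher.test()]; an all-zero table returns `p = 1` with a
#' warning.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value (double).
#' @export
fisher_exact_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2))
  if (any(table < 0) || any(table != round(table))) {
    abort("fisher_exact_2x2() needs non-negative integer counts")
  }
  if (sum(table) == 0) {
    warn("all-zero table; returning p = 1")
    return(1)
  }
  fisher.test(table)$p.value
}

#' Wilcoxon two-sample rank-sum test
#'
#' Rank-sum (Mann-Whitney) test with average ranks for ties. The p-value is
#' computed by exact enumeration of all rank assignments when the combined
#' sample size is at most `exact_max` (ties included), and otherwise by the
#' normal approximation with tie-corrected variance and continuity correction.
#' The reported `W` is the Mann-Whitney statistic of `x`
#' (rank sum of `x` minus `nx (nx + 1) / 2`), as in [stats::wilcox.test()].
#'
#' @param x,y numeric vectors (non-empty).
#' @param exact_max combined-size cutover for exact enumeration (default 12).
#' @return list with `statistic` (W), `p.value`, `method`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))$p.value  # 2 / choose(6, 3)
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (length(unique(c(x, y))) == 1) {
    return(list(statistic = w, p.value = 1, method = "degenerate"))
  }
  if (n <= exact_max) {
    idx <- combn(n, nx)
    ws <- colSums(matrix(r[idx], nrow = nx)) - nx * (nx + 1) / 2
    mu <- nx * ny / 2
    p <- min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
    return(list(statistic = w, p.value = p, method = "exact"))
  }
  mu <- nx * ny / 2
  tie <- table(r)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(statistic = w, p.value = 1, method = "normal"))
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  list(statistic = w, p.value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}

#' Spearman rank correlation of two methylation or diversity profiles
#'
#' Spearman's rho computed as the Pearson correlation of average-ranked
#' values (ties receive average ranks). Pairs with a missing value in either
#' profile are dropped. A constant profile has no rank order and returns `NA`
#' with a warning.
#'
#' @param x,y numeric vectors of equal length (>= 3 shared finite pairs).
#' @return rho in \[-1, 1\], or `NA` if undefined.
#' @export
profile_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) {
    warn("fewer than 3 shared finite values; correlation undefined")
    return(NA_real_)
  }
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warn("constant profile; Spearman correlation undefined")
    return(NA_real_)
  }
  cor(rank(x), rank(y), method = "pearson")
}

#' Hypergeometric enrichment of a gene set against category labels
#'
#' For each annotation category, the upper hypergeometric tail
#' `P(X >= k)` of drawing `k` category members in a set of size `n` from a
#' universe of size `N` containing `K` category members, with
#' Benjamini-Hochberg adjustment across categories.
#'
#' @param gene_set character vector of gene ids (subset of `universe`).
#' @param annotation data frame with columns `gene_id`, `category`.
#' @param universe character vector of all gene ids under consideration.
#' @return tibble with one row per category: `category`, `k`, `K`, `n`, `N`,
#'   `p`, `q`, sorted by `p`.
#' @export
enrichment_hypergeometric <- function(gene_set, annotation, universe) {
  stopifnot(is.data.frame(annotation),
            all(c("gene_id", "category") %in% names(annotation)))
  universe <- unique(universe)
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% universe)) {
    abort("gene_set must be a subset of universe")
  }
  ann <- annotation |>
    filter(.data$gene_id %in% universe) |>
    distinct(.data$gene_id, .data$category)
  if (nrow(ann) == 0) abort("annotation covers no universe gene")
  if (length(gene_set) == 0) {
    return(tibble(category = character(), k = integer(), K = integer(),
                  n = integer(), N = integer(), p = double(), q = double()))
  }
  n <- length(gene_set); N <- length(universe)
  ann |>
    group_by(.data$category) |>
    summarise(K = dplyr::n_distinct(.data$gene_id),
              k = sum(unique(.data$gene_id) %in% gene_set),
              .groups = "drop") |>
    mutate(n = n, N = N,
           p = phyper(.data$k - 1L, .data$K, N - .data$K, n, lower.tail = FALSE),
           q = p.adjust(.data$p, method = "BH")) |>
    select("category", "k", "K", "n", "N", "p", "q") |>
    arrange(.data$p)
}

#' Exact binomial test for biased fractionation between subgenomes
#'
#' Counts, among singleton orthogroups, how many lost the copy from each
#' subgenome and tests the split against an equal-loss null with a two-sided
#' exact binomial test ([stats::binom.test()]).
#'
#' @param orthogroups tibble as returned by [classify_wgd_groups()]; only
#'   `category == "singleton"` rows are used, with the surviving copy's
#'   subgenome taken from `subgenome`.
#' @return one-row tibble: `n_singleton`, `lost_from_a`, `lost_from_b`,
#'   `prop_lost_a`, `p`, `untestable`.
#' @export
fractionation_bias_test <- function(orthogroups) {
  stopifnot(is.data.frame(orthogroups))
  s <- filter(orthogroups, .data$category == "singleton", !is.na(.data$subgenome))
  n <- nrow(s)
  if (n == 0) {
    return(tibble(n_singleton = 0L, lost_from_a = NA_integer_,
                  lost_from_b = NA_integer_, prop_lost_a = NA_real_,
                  p = NA_real_, untestable = TRUE))
  }
  # the surviving copy sits in one subgenome; the loss hit the other
  lost_a <- sum(s$subgenome == "B")
  lost_b <- sum(s$subgenome == "A")
  tibble(n_singleton = n, lost_from_a = lost_a, lost_from_b = lost_b,
         prop_lost_a = lost_a / n,
         p = binom.test(lost_a, n, p = 0.5)$p.value,
         untestable = FALSE)
}

# BH across a vector, preserving NA
bh <- function(p) p.adjust(p, method = "BH")
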