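# Gene-body cytosine methylation quantification and differential-methylation
# calling. A methylome object (as built by simulate_methylomes() or
# read_cx_reports()) holds a site table (gene_id, scaffold, pos, strand,
# context), a sample sheet (sample, species, replicate) and two integer
# matrices meth/total of per-site counts (sites x samples).

validate_methylome <- function(x) {
  need <- c("sites", "samples", "meth", "total")
  if (!all(need %in% names(x))) {
    abort("methylome object needs elements sites, samples, meth, total")
  }
  stopifnot(nrow(x$sites) == nrow(x$meth),
            nrow(x$samples) == ncol(x$meth),
            all(dim(x$meth) == dim(x$total)))
  invisible(x)
}

#' Filter cytosine sites on total read depth across samples
#'
#' Retains a site only when its total depth (methylated + unmethylated) is
#' strictly greater than `min_total_depth` in every listed sample, the
#' all-accessions depth rule of cross-species methylome comparisons.
#'
#' @param meth methylome object.
#' @param min_total_depth strict lower depth bound (default 10).
#' @param samples sample names that must all pass; default all samples.
#' @return the methylome object restricted to passing sites.
#' @export
filter_sites <- function(meth, min_total_depth = 10, samples = NULL) {
  validate_methylome(meth)
  samples <- samples %||% meth$samples$sample
  missing <- setdiff(samples, meth$samples$sample)
  if (length(missing) > 0) {
    abort(paste0("unknown sample(s): ", paste(missing, collapse = ", ")))
  }
  keep <- rowSums(meth$total[, samples, drop = FALSE] > min_total_depth) ==
    length(samples)
  meth$sites <- meth$sites[keep, , drop = FALSE]
  meth$meth <- meth$meth[keep, , drop = FALSE]
  meth$total <- meth$total[keep, , drop = FALSE]
  meth
}

#' Weighted methylation level
#'
#' The count-weighted gene-body methylation level: total methylated reads
#' over total reads across a gene's retained sites of one context (not the
#' mean of per-site fractions, so unevenly covered sites do not dominate).
#' With no retained site the level is undefined (`NA`), never 0.
#'
#' @param methylated,total vectors of per-site methylated and total counts.
#' @return level in \[0, 1\], or `NA` for empty input.
#' @export
weighted_methylation_level <- function(methylated, total) {
  if (length(methylated) == 0 || sum(total) == 0) return(NA_real_)
  sum(methylated) / sum(total)
}

#' Per-gene weighted methylation levels for every context and sample
#'
#' @param meth methylome object (filter it first with [filter_sites()] if a
#'   depth rule applies).
#' @return tibble: `gene_id`, `context`, `sample`, `level`, `n_sites`.
#' @export
gene_methylation <- function(meth) {
  validate_methylome(meth)
  if (nrow(meth$sites) == 0) {
    return(tibble(gene_id = character(), context = character(),
                  sample = character(), level = double(),
                  n_sites = integer()))
  }
  key <- paste(meth$sites$gene_id, meth$sites$context, sep = "\r")
  msum <- rowsum(meth$meth, key)
  tsum <- rowsum(meth$total, key)
  nsite <- as.vector(rowsum(rep(1L, nrow(meth$sites)), key))
  parts <- do.call(rbind, strsplit(rownames(msum), "\r", fixed = TRUE))
  lev <- msum / tsum
  tibble(gene_id = rep(parts[, 1], ncol(lev)),
         context = rep(parts[, 2], ncol(lev)),
         sample = rep(colnames(meth$meth), each = nrow(lev)),
         level = as.vector(lev),
         n_sites = rep(nsite, ncol(lev))) |>
    arrange(.data$gene_id, .data$context, .data$sample)
}

#' Call differentially methylated genes between two species
#'
#' Implements the stratified CMH procedure with three-criterion filtering.
#' After the all-sample depth filter, a gene (per context) is fully mapped
#' when it retains at least one site; it is a DMG iff
#' 1. no within-species replicate pair shows a real intraspecific
#'    difference, i.e. no pair with |level difference| >=
#'    `delta_within_max` that is also Fisher-exact significant at `alpha`;
#' 2. the interspecific weighted-level difference exceeds
#'    `delta_between_min`;
#' 3. more than `frac_windows_min` of its gene-body windows are CMH
#'    significant at BH-adjusted q < `alpha` (one BH family per context
#'    across all gene windows).
#' CMH strata pair replicate i of species A with replicate i of species B.
#' A species with fewer than two replicates skips criterion 1 (flagged in
#' `within_downgraded`).
#'
#' @param meth methylome object (unfiltered; the depth rule is applied to
#'   the two species' samples here).
#' @param genes gene-model tibble with `gene_id`, `start`, `end` (window
#'   coordinates).
#' @param species_pair length-2 character vector, e.g. `c("G", "N")`.
#' @param delta_within_max,delta_between_min,frac_windows_min,alpha the
#'   three filter thresholds and significance level.
#' @param min_total_depth all-sample site depth rule (strict >).
#' @param n_windows equal-width gene-body windows (default 20).
#' @return tibble per gene x context: `cmh_statistic`, `p`, `q`,
#'   `delta_between`, `delta_within`, `frac_sig_windows`, `crit_within`,
#'   `crit_between`, `crit_windows`, `within_downgraded`, `is_dmg`.
#' @export
call_dmgs <- function(meth, genes, species_pair,
                      delta_within_max = 0.10, delta_between_min = 0.50,
                      frac_windows_min = 0.10, alpha = 0.01,
                      min_total_depth = 10, n_windows = 20) {
  validate_methylome(meth)
  stopifnot(length(species_pair) == 2)
  samp <- meth$samples |> filter(.data$species %in% species_pair)
  if (nrow(samp) == 0) abort("no samples for the requested species pair")
  reps_a <- samp |> filter(.data$species == species_pair[1]) |>
    arrange(.data$replicate)
  reps_b <- samp |> filter(.data$species == species_pair[2]) |>
    arrange(.data$replicate)
  if (nrow(reps_a) == 0 || nrow(reps_b) == 0) {
    abort("both species need at least one sample")
  }
  fm <- filter_sites(meth, min_total_depth, samp$sample)
  if (nrow(fm$sites) == 0) {
    return(empty_dmg_table())
  }
  gi <- genes |> select("gene_id", "start", "end")
  st <- fm$sites |> left_join(gi, by = "gene_id")
  glen <- st$end - st$start + 1L
  win <- pmin(pmax(ceiling((st$pos - st$start + 1L) / (glen / n_windows)), 1L),
              n_windows)

  a_cols <- reps_a$sample
  b_cols <- reps_b$sample
  n_strata <- min(length(a_cols), length(b_cols))

  ## gene x context levels and criteria 1-2
  key_g <- paste(st$gene_id, st$context, sep = "\r")
  msum <- rowsum(fm$meth[, c(a_cols, b_cols), drop = FALSE], key_g)
  tsum <- rowsum(fm$total[, c(a_cols, b_cols), drop = FALSE], key_g)
  lev <- msum / tsum
  parts <- do.call(rbind, strsplit(rownames(msum), "\r", fixed = TRUE))
  mean_a <- rowMeans(lev[, a_cols, drop = FALSE])
  mean_b <- rowMeans(lev[, b_cols, drop = FALSE])
  delta_between <- mean_a - mean_b

  within_check <- function(cols) {
    # returns list(max_delta, violated) per gene-context row
    if (length(cols) < 2) {
      return(list(max_delta = rep(NA_real_, nrow(lev)),
                  violated = rep(FALSE, nrow(lev)),
                  downgraded = TRUE))
    }
    prs <- combn(cols, 2, simplify = FALSE)
    maxd <- rep(0, nrow(lev))
    viol <- rep(FALSE, nrow(lev))
    for (pr in prs) {
      d <- abs(lev[, pr[1]] - lev[, pr[2]])
      maxd <- pmax(maxd, d)
      cand <- which(d >= delta_within_max)
      for (i in cand) {
        tb <- matrix(c(msum[i, pr[1]], tsum[i, pr[1]] - msum[i, pr[1]],
                       msum[i, pr[2]], tsum[i, pr[2]] - msum[i, pr[2]]),
                     2, byrow = TRUE)
        if (fisher.test(tb)$p.value < alpha) viol[i] <- TRUE
      }
    }
    list(max_delta = maxd, violated = viol, downgraded = FALSE)
  }
  wa <- within_check(a_cols)
  wb <- within_check(b_cols)
  delta_within <- pmax(wa$max_delta, wb$max_delta, na.rm = TRUE)
  delta_within[is.infinite(delta_within)] <- NA_real_
  crit_within <- !(wa$violated | wb$violated)
  downgraded <- wa$downgraded || wb$downgraded

  ## criterion 3: per-window CMH, BH per context over all gene windows
  key_w <- paste(st$gene_id, st$context, win, sep = "\r")
  mw <- rowsum(fm$meth[, c(a_cols, b_cols), drop = FALSE], key_w)
  tw <- rowsum(fm$total[, c(a_cols, b_cols), drop = FALSE], key_w)
  k <- seq_len(n_strata)
  a_mat <- mw[, a_cols[k], drop = FALSE]
  n1 <- tw[, a_cols[k], drop = FALSE]
  n2 <- tw[, b_cols[k], drop = FALSE]
  m1 <- mw[, a_cols[k], drop = FALSE] + mw[, b_cols[k], drop = FALSE]
  m2 <- n1 + n2 - m1
  w_stat <- cmh_stat_vec(a_mat, n1, n2, m1, m2)
  w_p <- pchisq(w_stat, df = 1, lower.tail = FALSE)
  wparts <- do.call(rbind, strsplit(rownames(mw), "\r", fixed = TRUE))
  wtab <- tibble(gene_id = wparts[, 1], context = wparts[, 2],
                 window = as.integer(wparts[, 3]), p = w_p) |>
    group_by(.data$context) |>
    mutate(q = bh(.data$p)) |>
    ungroup()
  wsum <- wtab |>
    group_by(.data$gene_id, .data$context) |>
    summarise(n_windows_data = sum(!is.na(.data$p)),
              n_sig = sum(.data$q < alpha, na.rm = TRUE),
              .groups = "drop") |>
    mutate(frac_sig_windows = dplyr::if_else(
      .data$n_windows_data > 0, .data$n_sig / .data$n_windows_data, NA_real_))

  ## gene-level CMH (pooled gene body), BH per context across genes
  ag <- mw[, a_cols[k], drop = FALSE]
  g_key <- paste(wparts[, 1], wparts[, 2], sep = "\r")
  a_g <- rowsum(ag, g_key)
  n1_g <- rowsum(n1, g_key)
  n2_g <- rowsum(n2, g_key)
  m1_g <- rowsum(m1, g_key)
  m2_g <- rowsum(m2, g_key)
  g_stat <- cmh_stat_vec(a_g, n1_g, n2_g, m1_g, m2_g)
  g_p <- pchisq(g_stat, df = 1, lower.tail = FALSE)
  gparts <- do.call(rbind, strsplit(rownames(a_g), "\r", fixed = TRUE))
  gtab <- tibble(gene_id = gparts[, 1], context = gparts[, 2],
                 cmh_statistic = g_stat, p = g_p) |>
    group_by(.data$context) |>
    mutate(q = bh(.data$p)) |>
    ungroup()

  out <- tibble(gene_id = parts[, 1], context = parts[, 2],
                species_a = species_pair[1], species_b = species_pair[2],
                level_a = mean_a, level_b = mean_b,
                delta_between = delta_between,
                delta_within = delta_within,
                crit_within = crit_within,
                within_downgraded = downgraded) |>
    left_join(gtab, by = c("gene_id", "context")) |>
    left_join(wsum |> select("gene_id", "context", "frac_sig_windows"),
              by = c("gene_id", "context")) |>
    mutate(crit_between = abs(.data$delta_between) > delta_between_min,
           crit_windows = !is.na(.data$frac_sig_windows) &
             .data$frac_sig_windows > frac_windows_min,
           is_dmg = .data$crit_within & .data$crit_between &
             .data$crit_windows) |>
    arrange(.data$context, .data$gene_id)
  attr(out, "params") <- list(delta_within_max = delta_within_max,
                              delta_between_min = delta_between_min,
                              frac_windows_min = frac_windows_min,
                              alpha = alpha,
                              min_total_depth = min_total_depth,
                              n_windows = n_windows,
                              n_strata = n_strata)
  out
}

empty_dmg_table <- function() {
  tibble(gene_id = character(), context = character(),
         species_a = character(), species_b = character(),
         level_a = double(), level_b = double(),
         delta_between = double(), delta_within = double(),
         crit_within = logical(), within_downgraded = logical(),
         cmh_statistic = double(), p = double(), q = double(),
         frac_sig_windows = double(), crit_between = logical(),
         crit_windows = logical(), is_dmg = logical())
}

#' Pairwise Spearman correlations of sample methylation profiles
#'
#' Correlates per-gene weighted methylation levels between every pair of
#' samples, per context, labelling pairs as intraspecific (same species) or
#' interspecific.
#'
#' @param meth methylome object (apply [filter_sites()] first if desired).
#' @return tibble: `context`, `sample1`, `sample2`, `species1`, `species2`,
#'   `comparison` (intraspecific/interspecific), `rho`, `n_genes`.
#' @export
sample_profile_correlations <- function(meth) {
  levels <- gene_methylation(meth)
  sp <- setNames(meth$samples$species, meth$samples$sample)
  out <- list()
  for (ctx in unique(levels$context)) {
    wide <- levels |>
      filter(.data$context == ctx) |>
      select("gene_id", "sample", "level") |>
      pivot_wider(names_from = "sample", values_from = "level")
    m <- as.matrix(wide[, -1, drop = FALSE])
    cols <- colnames(m)
    for (i in seq_along(cols)) for (j in seq_along(cols)) {
      if (j <= i) next
      out[[length(out) + 1]] <- tibble(
        context = ctx, sample1 = cols[i], sample2 = cols[j],
        species1 = unname(sp[cols[i]]), species2 = unname(sp[cols[j]]),
        comparison = dplyr::if_else(sp[cols[i]] == sp[cols[j]],
                                    "intraspecific", "interspecific"),
        rho = suppressWarnings(profile_correlation(m[, i], m[, j])),
        n_genes = sum(is.finite(m[, i]) & is.finite(m[, j])))
    }
  }
  list_rbind(out)
}
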