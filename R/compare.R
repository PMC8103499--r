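# Class-wise distribution comparisons (each duplicate-gene class against the
# overall gene set), subgenome-asymmetry consistency across the tetraploid
# species, and the correlation partition that contrasts same-subgenome
# between-species with between-subgenome within-species similarity.

#' Compare per-gene statistics between gene classes and the overall set
#'
#' For every class x statistic cell, a Wilcoxon two-sample rank-sum test of
#' the class members' values against the overall distribution (all genes
#' carrying that statistic), with BH adjustment within each statistic family
#' and a direction label from the median difference (ties give "ns").
#' Undefined (NA) values are dropped per cell; an empty class is marked
#' untestable.
#'
#' @param gene_stats long tibble: `gene_id`, `statistic`, `value`.
#' @param classes tibble: `gene_id`, `class` (a gene may appear under
#'   several classes; the "overall" baseline is every gene in `gene_stats`,
#'   not a row you need to provide).
#' @param exact_max passed to [wilcoxon_rank_sum()].
#' @return tibble: `class`, `statistic`, `n_class`, `n_overall`, `W`, `p`,
#'   `q`, `direction` (higher/lower/ns), `untestable`.
#' @export
compare_classes <- function(gene_stats, classes, exact_max = 12) {
  stopifnot(all(c("gene_id", "statistic", "value") %in% names(gene_stats)),
            all(c("gene_id", "class") %in% names(classes)))
  cells <- list()
  for (stat in sort(unique(gene_stats$statistic))) {
    sv <- gene_stats |> filter(.data$statistic == stat, !is.na(.data$value))
    overall <- sv$value
    for (cl in sort(unique(classes$class))) {
      gid <- classes$gene_id[classes$class == cl]
      x <- sv$value[sv$gene_id %in% gid]
      if (length(x) == 0 || length(overall) == 0) {
        cells[[length(cells) + 1]] <- tibble(
          class = cl, statistic = stat, n_class = length(x),
          n_overall = length(overall), W = NA_real_, p = NA_real_,
          direction = "ns", untestable = TRUE)
        next
      }
      if (cl == "overall" || identical(sort(x), sort(overall))) {
        # self-comparison: by construction not significant
        cells[[length(cells) + 1]] <- tibble(
          class = cl, statistic = stat, n_class = length(x),
          n_overall = length(overall), W = length(x) * length(overall) / 2,
          p = 1, direction = "ns", untestable = FALSE)
        next
      }
      wt <- wilcoxon_rank_sum(x, overall, exact_max = exact_max)
      md <- median(x) - median(overall)
      cells[[length(cells) + 1]] <- tibble(
        class = cl, statistic = stat, n_class = length(x),
        n_overall = length(overall), W = wt$statistic, p = wt$p.value,
        direction = dplyr::case_when(md > 0 ~ "higher", md < 0 ~ "lower",
                                     TRUE ~ "ns"),
        untestable = FALSE)
    }
  }
  list_rbind(cells) |>
    group_by(.data$statistic) |>
    mutate(q = bh(.data$p)) |>
    ungroup() |>
    mutate(direction = dplyr::if_else(.data$q >= 0.05 | is.na(.data$q),
                                      "ns", .data$direction)) |>
    select("class", "statistic", "n_class", "n_overall", "W", "p", "q",
           "direction", "untestable")
}

#' Subgenome methylation asymmetry across the tetraploid species
#'
#' For every doublet pair (subgenome-A copy vs subgenome-B copy), the
#' per-species A-minus-B difference of a per-gene statistic (typically a
#' methylation level) and whether its sign is consistent across all species
#' carrying the pair; plus the Spearman correlation matrix over all
#' (species, subgenome) profiles, partitioned into within-species
#' between-subgenome versus between-species same-subgenome comparisons.
#'
#' @param levels tibble: `gene_id`, `species`, `value` (per-copy statistic,
#'   one value per tetraploid gene copy and species).
#' @param pairs tibble: `pair_id`, `gene_a`, `gene_b` (subgenome A and B
#'   copies of each doublet).
#' @return list of class `dupevol_asymmetry`: `per_gene` (pair_id, species
#'   diffs wide, `n_species`, `sign_consistent`), `correlations` (long
#'   tibble of profile pairs with `partition` labels), `partition_means`
#'   (mean rho per partition), `sign_consistency` (fraction of pairs, with
#'   >= 2 species, whose diffs share one sign).
#' @export
subgenome_asymmetry <- function(levels, pairs) {
  stopifnot(all(c("gene_id", "species", "value") %in% names(levels)),
            all(c("pair_id", "gene_a", "gene_b") %in% names(pairs)))
  la <- levels |> rename(gene_a = "gene_id", value_a = "value")
  lb <- levels |> rename(gene_b = "gene_id", value_b = "value")
  d <- pairs |>
    inner_join(la, by = "gene_a", relationship = "many-to-many") |>
    inner_join(lb, by = c("gene_b", "species")) |>
    mutate(diff = .data$value_a - .data$value_b) |>
    filter(!is.na(.data$diff))
  per_gene <- d |>
    group_by(.data$pair_id) |>
    summarise(n_species = dplyr::n_distinct(.data$species),
              sign_consistent = dplyr::n_distinct(sign(.data$diff)) == 1 &&
                all(.data$diff != 0),
              mean_abs_diff = mean(abs(.data$diff)),
              .groups = "drop")
  dropped <- setdiff(pairs$pair_id, per_gene$pair_id)
  if (length(dropped) > 0) {
    warn(sprintf("%d pair(s) had no species with both copies measured",
                 length(dropped)))
  }
  ## correlation partition over (species, subgenome) profiles
  prof <- bind_rows(
    d |> select("pair_id", "species", value = "value_a") |>
      mutate(subgenome = "A"),
    d |> select("pair_id", "species", value = "value_b") |>
      mutate(subgenome = "B")) |>
    mutate(key = paste(.data$species, .data$subgenome, sep = "."))
  wide <- prof |>
    select("pair_id", "key", "value") |>
    pivot_wider(names_from = "key", values_from = "value")
  m <- as.matrix(wide[, -1, drop = FALSE])
  keys <- colnames(m)
  cors <- list()
  for (i in seq_along(keys)) for (j in seq_along(keys)) {
    if (j <= i) next
    s1 <- strsplit(keys[i], ".", fixed = TRUE)[[1]]
    s2 <- strsplit(keys[j], ".", fixed = TRUE)[[1]]
    part <- dplyr::case_when(
      s1[1] == s2[1] && s1[2] != s2[2] ~ "within_species_between_subgenome",
      s1[1] != s2[1] && s1[2] == s2[2] ~ "between_species_same_subgenome",
      TRUE ~ "between_species_between_subgenome")
    cors[[length(cors) + 1]] <- tibble(
      profile1 = keys[i], profile2 = keys[j], partition = part,
      rho = suppressWarnings(profile_correlation(m[, i], m[, j])))
  }
  correlations <- list_rbind(cors)
  partition_means <- correlations |>
    group_by(.data$partition) |>
    summarise(mean_rho = mean(.data$rho, na.rm = TRUE),
              n = dplyr::n(), .groups = "drop")
  multi <- per_gene |> filter(.data$n_species >= 2)
  out <- list(per_gene = per_gene,
              per_gene_species = d |>
                select("pair_id", "species", "diff"),
              correlations = correlations,
              partition_means = partition_means,
              sign_consistency = if (nrow(multi) > 0)
                mean(multi$sign_consistent) else NA_real_)
  class(out) <- "dupevol_asymmetry"
  out
}

#' @export
print.dupevol_asymmetry <- function(x, ...) {
  cat("subgenome asymmetry report\n")
  cat(sprintf("  %d doublet pairs; cross-species sign consistency %.3f\n",
              nrow(x$per_gene), x$sign_consistency))
  print(x$partition_means)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dupevol_asymmetry <- function(x, ...) x$per_gene

#' @exportS3Method generics::glance
glance.dupevol_asymmetry <- function(x, ...) {
  pm <- setNames(x$partition_means$mean_rho, x$partition_means$partition)
  tibble(n_pairs = nrow(x$per_gene),
         sign_consistency = x$sign_consistency,
         rho_within_species_between_subgenome =
           unname(pm["within_species_between_subgenome"]),
         rho_between_species_same_subgenome =
           unname(pm["between_species_same_subgenome"]))
}
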