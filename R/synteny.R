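# Collinear block detection: weighted longest-collinear-chain dynamic
# programming over gene rank space, in the spirit of MCScanX. Anchors are
# precomputed homolog pairs; chaining works per scaffold pair, extracting the
# best-scoring monotone chain repeatedly until no chain reaches
# min_block_anchors.

#' Chain homolog anchors into collinear synteny blocks
#'
#' For every scaffold pair, finds maximal-scoring chains of anchors whose gene
#' ranks are strictly increasing on side 1 and strictly monotone (increasing =
#' "same" orientation, decreasing = "inverted") on side 2, with consecutive
#' anchors at most `max_gene_gap` ranks apart on both sides. The chain score
#' is the sum of anchor scores minus a linear gap penalty
#' `gap_penalty * ((dr1 - 1) + (dr2 - 1))` per link. Chains are extracted
#' greedily (best first, anchors removed, repeat); chains with fewer than
#' `min_block_anchors` anchors are discarded, so each anchor belongs to at
#' most one block. Score ties prefer the chain with the smaller total rank
#' gap, then the lexicographically smallest starting gene id, then "same"
#' orientation, making the output deterministic.
#'
#' @param anchors tibble with columns `gene1`, `gene2`, `score` (>= 0).
#' @param genes gene-model tibble with columns `gene_id`, `scaffold`,
#'   `rank` (0-based, unique per taxon x scaffold).
#' @param min_block_anchors minimum anchors per block (default 5).
#' @param max_gene_gap maximum rank gap between consecutive chain anchors on
#'   either side (default 25).
#' @param gap_penalty linear per-rank gap penalty (default 0.05).
#' @return tibble of block-assigned anchors: `block_id`, `gene1`, `gene2`,
#'   `scaffold1`, `scaffold2`, `rank1`, `rank2`, `score`, `orientation`
#'   (same/inverted), `block_score`, `n_anchors`.
#' @export
chain_anchors <- function(anchors, genes, min_block_anchors = 5,
                          max_gene_gap = 25, gap_penalty = 0.05) {
  stopifnot(is.data.frame(anchors), is.data.frame(genes))
  if (nrow(anchors) == 0) return(empty_blocks())
  unknown <- setdiff(unique(c(anchors$gene1, anchors$gene2)), genes$gene_id)
  if (length(unknown) > 0) {
    abort(paste0("anchors reference unknown gene(s): ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  if (any(anchors$gene1 == anchors$gene2)) {
    abort("anchor pairs must join two distinct genes")
  }
  gi <- genes |> select("gene_id", "scaffold", "rank")
  a <- anchors |>
    inner_join(rename(gi, gene1 = "gene_id", scaffold1 = "scaffold",
                      rank1 = "rank"), by = "gene1") |>
    inner_join(rename(gi, gene2 = "gene_id", scaffold2 = "scaffold",
                      rank2 = "rank"), by = "gene2") |>
    distinct(.data$gene1, .data$gene2, .keep_all = TRUE)
  out <- list()
  for (sub in split(a, paste(a$scaffold1, a$scaffold2, sep = "\r"))) {
    repeat {
      ch <- best_chain(sub, max_gene_gap, gap_penalty)
      if (is.null(ch) || length(ch$idx) < min_block_anchors) break
      blk <- sub[ch$idx, , drop = FALSE]
      blk$orientation <- ch$orientation
      blk$block_score <- ch$score
      blk$n_anchors <- length(ch$idx)
      out[[length(out) + 1]] <- blk
      sub <- sub[-ch$idx, , drop = FALSE]
      if (nrow(sub) == 0) break
    }
  }
  if (length(out) == 0) return(empty_blocks())
  # deterministic block numbering by genomic position
  ord <- order(map_chr(out, ~ .x$scaffold1[1]),
               map_chr(out, ~ .x$scaffold2[1]),
               map_dbl(out, ~ min(.x$rank1)),
               map_dbl(out, ~ min(.x$rank2)))
  out <- out[ord]
  for (i in seq_along(out)) out[[i]]$block_id <- sprintf("B%04d", i)
  list_rbind(out) |>
    select("block_id", "gene1", "gene2", "scaffold1", "scaffold2",
           "rank1", "rank2", "score", "orientation", "block_score",
           "n_anchors") |>
    arrange(.data$block_id, .data$rank1)
}

empty_blocks <- function() {
  tibble(block_id = character(), gene1 = character(), gene2 = character(),
         scaffold1 = character(), scaffold2 = character(),
         rank1 = integer(), rank2 = integer(), score = double(),
         orientation = character(), block_score = double(),
         n_anchors = integer())
}

# best monotone chain over one scaffold-pair anchor set, trying both
# orientations; returns idx (row indices), score, orientation, or NULL
best_chain <- function(sub, max_gene_gap, gap_penalty) {
  if (nrow(sub) == 0) return(NULL)
  same <- chain_dp(sub$rank1, sub$rank2, sub$score, sub$gene1,
                   max_gene_gap, gap_penalty)
  inv <- chain_dp(sub$rank1, -sub$rank2, sub$score, sub$gene1,
                  max_gene_gap, gap_penalty)
  eps <- 1e-9
  pick_same <- same$score > inv$score + eps ||
    (abs(same$score - inv$score) <= eps &&
       (same$gaps < inv$gaps ||
          (same$gaps == inv$gaps && same$start <= inv$start)))
  ch <- if (pick_same) same else inv
  list(idx = ch$idx, score = ch$score,
       orientation = if (pick_same) "same" else "inverted")
}

# DP over anchors sorted by (rank1, rank2): strictly-monotone chain
# maximising sum(score) - gap penalties, consecutive gaps <= max_gene_gap on
# both sides. On score ties a smaller cumulative rank gap wins, then the
# smaller starting gene id; a fresh start (zero gaps) therefore beats an
# equal-scoring extension.
chain_dp <- function(r1, r2, s, g1, max_gene_gap, gap_penalty) {
  ord <- order(r1, r2)
  r1 <- r1[ord]; r2 <- r2[ord]; s <- s[ord]; g <- g1[ord]
  n <- length(r1)
  dp <- s                       # best chain score ending at i
  gaps <- numeric(n)            # its cumulative rank gap
  start <- g                    # its starting gene id
  prev <- rep(NA_integer_, n)
  eps <- 1e-9
  for (i in seq_len(n)) {
    cand <- which(r1 < r1[i] & r1 >= r1[i] - max_gene_gap)
    if (length(cand) > 0) {
      cand <- cand[r2[cand] < r2[i] & (r2[i] - r2[cand]) <= max_gene_gap]
    }
    if (length(cand) == 0) next
    extra <- (r1[i] - r1[cand] - 1) + (r2[i] - r2[cand] - 1)
    val <- dp[cand] - gap_penalty * extra + s[i]
    best_val <- max(val)
    if (best_val > dp[i] + eps ||
        (abs(best_val - dp[i]) <= eps && min(gaps[cand] + extra) < gaps[i])) {
      keep <- val >= best_val - eps
      cg <- gaps[cand] + extra
      cg[!keep] <- Inf
      keep2 <- cg <= min(cg) + eps
      st <- start[cand]
      st[!keep2] <- NA
      k <- cand[order(st, na.last = TRUE)[1]]
      dp[i] <- dp[k] - gap_penalty * ((r1[i] - r1[k] - 1) +
                                        (r2[i] - r2[k] - 1)) + s[i]
      gaps[i] <- gaps[k] + (r1[i] - r1[k] - 1) + (r2[i] - r2[k] - 1)
      start[i] <- start[k]
      prev[i] <- k
    }
  }
  top <- which(dp >= max(dp) - eps)
  tg <- gaps[top]
  top <- top[tg <= min(tg) + eps]
  end <- top[order(start[top])[1]]
  idx <- integer(0)
  i <- end
  while (!is.na(i)) {
    idx <- c(i, idx)
    i <- prev[i]
  }
  list(idx = ord[idx], score = dp[end], gaps = gaps[end], start = start[end])
}

#' Summarise synteny blocks
#'
#' One row per block with scaffolds, orientation, anchor count and score.
#' @param blocks anchor-level block tibble from [chain_anchors()].
#' @return tibble with one row per `block_id`.
#' @export
block_summary <- function(blocks) {
  blocks |>
    group_by(.data$block_id) |>
    summarise(scaffold1 = first(.data$scaffold1),
              scaffold2 = first(.data$scaffold2),
              orientation = first(.data$orientation),
              n_anchors = dplyr::n(),
              score = first(.data$block_score),
              .groups = "drop")
}

#' Collinear depth and ancient-collinear / conserved-eudicot labels
#'
#' Counts, for every gene, the number of distinct collinear blocks covering
#' it in the supplied block set (typically blocks against a panel of
#' conserved eudicot reference genomes). Genes covered by more than four
#' blocks are labelled ancient-collinear (retained through ancient WGDs);
#' genes in at least one block are conserved-eudicot.
#'
#' @param blocks anchor-level block tibble from [chain_anchors()].
#' @param genes gene-model tibble; `gene_id` defines the universe (depth 0
#'   for uncovered genes). Pass the focal-taxon genes.
#' @return tibble: `gene_id`, `depth`, `ancient_collinear`,
#'   `conserved_eudicot`.
#' @export
collinear_depth <- function(blocks, genes) {
  hits <- bind_rows(
    blocks |> select(gene_id = "gene1", "block_id"),
    blocks |> select(gene_id = "gene2", "block_id")
  ) |>
    distinct() |>
    count(.data$gene_id, name = "depth")
  tibble(gene_id = genes$gene_id) |>
    left_join(hits, by = "gene_id") |>
    mutate(depth = coalesce(.data$depth, 0L),
           ancient_collinear = .data$depth > 4,
           conserved_eudicot = .data$depth >= 1)
}
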