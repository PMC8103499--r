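# Nei-Gojobori (1986) counting estimator of dN/dS with Jukes-Cantor
# correction. Codon tables are built once and cached: per-codon synonymous
# site fractions, and for every ordered codon pair the pathway-averaged
# synonymous/nonsynonymous difference counts.

GENETIC_CODE_TBL <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- names(GENETIC_CODE_TBL)[GENETIC_CODE_TBL == "*"]
SENSE_CODONS <- setdiff(names(GENETIC_CODE_TBL), STOP_CODONS)

codon_neighbours <- function(codon) {
  out <- character(0)
  s <- strsplit(codon, "")[[1]]
  for (pos in 1:3) for (b in setdiff(BASES, s[pos])) {
    t <- s; t[pos] <- b
    out <- c(out, paste(t, collapse = ""))
  }
  out
}

# synonymous site count per codon: at each position, the fraction of the 3
# possible single-base changes that preserve the amino acid; changes to stop
# codons count as nonsynonymous
codon_syn_sites <- function() {
  vapply(names(GENETIC_CODE_TBL), function(cd) {
    aa <- GENETIC_CODE_TBL[[cd]]
    nb <- codon_neighbours(cd)
    sum(GENETIC_CODE_TBL[nb] == aa & GENETIC_CODE_TBL[nb] != "*") / 3
  }, numeric(1))
}

# pathway-averaged (Sd, Nd) between two codons: average over orderings of the
# differing positions; orderings passing through a stop codon are excluded
# unless every ordering does, in which case all are used with the stop steps
# counted as nonsynonymous
codon_pair_diff <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(pos)
  if (d == 0) return(c(sd = 0, nd = 0))
  perms <- if (d == 1) list(pos) else if (d == 2) {
    list(pos, rev(pos))
  } else {
    list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
         pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)])
  }
  walk <- function(ord) {
    cur <- strsplit(c1, "")[[1]]
    tgt <- strsplit(c2, "")[[1]]
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in ord) {
      prev <- paste(cur, collapse = "")
      cur[p] <- tgt[p]
      nxt <- paste(cur, collapse = "")
      if (GENETIC_CODE_TBL[[nxt]] == "*") blocked <- TRUE
      if (GENETIC_CODE_TBL[[prev]] == GENETIC_CODE_TBL[[nxt]] &&
          GENETIC_CODE_TBL[[nxt]] != "*") sd <- sd + 1 else nd <- nd + 1
    }
    c(sd = sd, nd = nd, blocked = as.numeric(blocked))
  }
  res <- vapply(perms, walk, numeric(3))
  ok <- res["blocked", ] == 0
  if (any(ok)) res <- res[, ok, drop = FALSE]
  c(sd = mean(res["sd", ]), nd = mean(res["nd", ]))
}

ng86_tables <- function() {
  if (!is.null(the$ng86)) return(the$ng86)
  syn <- codon_syn_sites()
  codons <- names(GENETIC_CODE_TBL)
  n <- length(codons)
  sd_mat <- matrix(0, n, n, dimnames = list(codons, codons))
  nd_mat <- sd_mat
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- codon_pair_diff(codons[i], codons[j])
    sd_mat[i, j] <- d[["sd"]]
    nd_mat[i, j] <- d[["nd"]]
  }
  the$ng86 <- list(syn = syn, sd = sd_mat, nd = nd_mat)
  the$ng86
}

split_codons <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) %% 3 != 0) abort("sequence length is not a multiple of 3")
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

#' Nei-Gojobori dN/dS for a pair of in-frame coding sequences
#'
#' Counting estimator of the nonsynonymous and synonymous substitution rates:
#' synonymous/nonsynonymous site counts are averaged over both sequences,
#' codons differing at several positions are averaged over all mutational
#' pathways (pathways through stop codons excluded when avoidable), and the
#' raw proportions are corrected with the Jukes-Cantor transform
#' `d = -(3/4) log(1 - (4/3) p)`. Changes creating a stop codon count as
#' nonsynonymous. When `ds = 0` the ratio is undefined and returned as `NA`
#' with `undefined = TRUE`.
#'
#' @param seq1,seq2 in-frame coding sequences (A/C/G/T strings) of equal
#'   length, a multiple of 3, without stop codons.
#' @return one-row tibble: `dn`, `ds`, `dn_ds`, `n_sites`, `s_sites`, `nd`,
#'   `sd`, `undefined`.
#' @examples
#' ng86_dnds("TTTGCT", "TTCGCT")  # one synonymous difference
#' @export
ng86_dnds <- function(seq1, seq2) {
  c1 <- split_codons(seq1)
  c2 <- split_codons(seq2)
  if (length(c1) != length(c2)) abort("sequences differ in length")
  if (!all(c(c1, c2) %in% names(GENETIC_CODE_TBL))) {
    abort("sequences must contain only A/C/G/T")
  }
  if (any(c(c1, c2) %in% STOP_CODONS)) abort("stop codon in coding sequence")
  tb <- ng86_tables()
  s_sites <- (sum(tb$syn[c1]) + sum(tb$syn[c2])) / 2
  n_sites <- 3 * length(c1) - s_sites
  idx <- cbind(match(c1, rownames(tb$sd)), match(c2, colnames(tb$sd)))
  sd_tot <- sum(tb$sd[idx])
  nd_tot <- sum(tb$nd[idx])
  ps <- if (s_sites > 0) sd_tot / s_sites else 0
  pn <- if (n_sites > 0) nd_tot / n_sites else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ds <- jc(ps); dn <- jc(pn)
  undefined <- is.na(ds) || is.na(dn) || ds == 0
  tibble(dn = dn, ds = ds,
         dn_ds = if (undefined) NA_real_ else dn / ds,
         n_sites = n_sites, s_sites = s_sites,
         nd = nd_tot, sd = sd_tot, undefined = undefined)
}
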