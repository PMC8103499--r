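# Independent brute-force oracles. Each re-derives a statistic from first
# principles with code structurally unlike the package implementation
# (explicit loops over pairs/pathways/enumerations), so agreement is
# evidence, not tautology.

# nucleotide diversity: loop over every haplotype pair and site, pairwise
# deletion per site (sites with < 2 called haplotypes contribute nothing)
oracle_pi <- function(geno, gene_length) {
  if (is.null(dim(geno))) geno <- matrix(geno, ncol = 1)
  H <- nrow(geno)
  if (H < 2) return(NA_real_)
  total <- 0
  for (j in seq_len(ncol(geno))) {
    mism <- 0; npair <- 0
    for (i1 in seq_len(H - 1)) for (i2 in (i1 + 1):H) {
      a <- geno[i1, j]; b <- geno[i2, j]
      if (is.na(a) || is.na(b)) next
      npair <- npair + 1
      if (a != b) mism <- mism + 1
    }
    if (npair > 0) total <- total + mism / npair
  }
  total / gene_length
}

oracle_dxy <- function(ga, gb, gene_length) {
  if (is.null(dim(ga))) ga <- matrix(ga, ncol = 1)
  if (is.null(dim(gb))) gb <- matrix(gb, ncol = 1)
  total <- 0
  for (j in seq_len(ncol(ga))) {
    mism <- 0; npair <- 0
    for (i1 in seq_len(nrow(ga))) for (i2 in seq_len(nrow(gb))) {
      a <- ga[i1, j]; b <- gb[i2, j]
      if (is.na(a) || is.na(b)) next
      npair <- npair + 1
      if (a != b) mism <- mism + 1
    }
    if (npair > 0) total <- total + mism / npair
  }
  total / gene_length
}

# NG86 oracle: genetic code from Biostrings (an independent source), explicit
# recursive pathway enumeration, same stated rules (stop targets are
# nonsynonymous; pathways through stops excluded when avoidable)
oracle_code <- local({
  gc <- NULL
  function() {
    if (is.null(gc)) {
      g <- Biostrings::GENETIC_CODE
      names(g) <- gsub("U", "T", names(g))
      gc <<- g
    }
    gc
  }
})

oracle_syn_sites <- function(codon) {
  g <- oracle_code()
  s <- 0
  cs <- strsplit(codon, "")[[1]]
  for (p in 1:3) for (b in c("A", "C", "G", "T")) {
    if (b == cs[p]) next
    mt <- cs; mt[p] <- b
    mt <- paste(mt, collapse = "")
    if (g[[mt]] != "*" && g[[mt]] == g[[codon]]) s <- s + 1 / 3
  }
  s
}

oracle_pathways <- function(c1, c2) {
  g <- oracle_code()
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  perm_list <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_list(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  res <- list()
  for (ord in perm_list(pos)) {
    cur <- strsplit(c1, "")[[1]]; tgt <- strsplit(c2, "")[[1]]
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in ord) {
      before <- paste(cur, collapse = "")
      cur[p] <- tgt[p]
      after <- paste(cur, collapse = "")
      if (g[[after]] == "*") blocked <- TRUE
      if (g[[after]] != "*" && g[[before]] == g[[after]]) sd <- sd + 1
      else nd <- nd + 1
    }
    res[[length(res) + 1]] <- c(sd, nd, blocked)
  }
  m <- do.call(rbind, res)
  ok <- m[, 3] == 0
  if (any(ok)) m <- m[ok, , drop = FALSE]
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

oracle_ng86 <- function(s1, s2) {
  sp <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  c1 <- sp(s1); c2 <- sp(s2)
  S <- (sum(vapply(c1, oracle_syn_sites, 0)) +
          sum(vapply(c2, oracle_syn_sites, 0))) / 2
  N <- 3 * length(c1) - S
  sd <- 0; nd <- 0
  for (i in seq_along(c1)) {
    d <- oracle_pathways(c1[i], c2[i])
    sd <- sd + d[["sd"]]; nd <- nd + d[["nd"]]
  }
  ps <- if (S > 0) sd / S else 0
  pn <- if (N > 0) nd / N else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(dn = jc(pn), ds = jc(ps), S = S, N = N, sd = sd, nd = nd)
}

# CMH from the defining sums, one term at a time
oracle_cmh <- function(strata) {
  num <- 0; den <- 0
  for (t in strata) {
    n <- sum(t)
    num <- num + (t[1, 1] - sum(t[1, ]) * sum(t[, 1]) / n)
    den <- den + sum(t[1, ]) * sum(t[2, ]) * sum(t[, 1]) * sum(t[, 2]) /
      (n^2 * (n - 1))
  }
  num^2 / den
}

# Fisher two-sided p by full enumeration of tables with fixed margins
oracle_fisher <- function(t) {
  r1 <- sum(t[1, ]); c1 <- sum(t[, 1]); n <- sum(t)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(ks, r1, n - r1, c1)
  obs <- stats::dhyper(t[1, 1], r1, n - r1, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Wilcoxon exact two-sided p by enumerating every assignment of the pooled
# ranks to the x-group
oracle_wilcoxon <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  sets <- combn(n, nx)
  ws <- apply(sets, 2, function(ix) sum(r[ix])) - nx * (nx + 1) / 2
  lo <- mean(ws <= w_obs + 1e-9)
  hi <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# upper hypergeometric tail by direct summation
oracle_hyper_tail <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Benjamini-Hochberg by the step-up definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# Spearman with average ranks, Pearson computed from the definition
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# exhaustive best monotone chain: DFS over every extension, both
# orientations, with the same gap rule and linear penalty
oracle_best_chain_score <- function(anchors, max_gene_gap, gap_penalty,
                                    min_len = 1) {
  n <- nrow(anchors)
  best <- -Inf
  for (orient in c(1, -1)) {
    r1 <- anchors$rank1
    r2 <- orient * anchors$rank2
    extend <- function(last, score, len) {
      if (len >= min_len) best <<- max(best, score)
      for (j in seq_len(n)) {
        if (r1[j] > r1[last] && r2[j] > r2[last] &&
            r1[j] - r1[last] <= max_gene_gap &&
            r2[j] - r2[last] <= max_gene_gap) {
          pen <- gap_penalty * ((r1[j] - r1[last] - 1) + (r2[j] - r2[last] - 1))
          extend(j, score + anchors$score[j] - pen, len + 1)
        }
      }
    }
    for (s in seq_len(n)) extend(s, anchors$score[s], 1)
  }
  best
}
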