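# Population variant simulation. Species consensus sequences evolve from the
# simulated gene sequences by Jukes-Cantor substitution along the fixed
# topology ((G,Q,J),N); within-species polymorphism is added per haplotype at
# a rate tuned so realized pairwise diversity matches the per-species target.
# A configurable fraction of sites receives failing MQ/DP metadata together
# with noisy genotype calls, so the hard filters have real work to do.

BASE_INT <- c(A = 1L, C = 2L, G = 3L, T = 4L)

seq_to_int <- function(seq) unname(BASE_INT[strsplit(seq, "")[[1]]])
int_to_base <- function(x) c("A", "C", "G", "T")[x]

# probability two sequences differ at a site after JC divergence d
jc_site_diff <- function(d) 0.75 * (1 - exp(-4 * d / 3))

mutate_sites <- function(x, idx) {
  if (length(idx) == 0) return(x)
  shift <- sample(1:3, length(idx), replace = TRUE)
  x[idx] <- ((x[idx] - 1L + shift) %% 4L) + 1L
  x
}

#' Simulate population genotype matrices with site-quality metadata
#'
#' For each tetraploid gene, species consensus sequences for G, Q and J
#' diverge from the (shared) tetraploid ancestor by their scaled terminal
#' branch; the diploid outgroup N diverges from the diploid annotation on its
#' own coordinates. Each accession contributes two haplotypes; per-haplotype
#' mutation at rate `species_pi / 2` yields expected pairwise diversity close
#' to the target. A fraction `low_qual_frac` of sites per gene receives
#' failing metadata (MQ <= 30 or DP <= 3) plus scrambled genotype calls.
#' Variant matrices store, per gene, the union of segregating or diverged
#' sites across the species sharing the coordinate frame, so between-species
#' dxy sees fixed differences.
#'
#' @param genomes output of [simulate_genomes()].
#' @param config the same [sim_config()].
#' @return list of class `dupevol_variants`: `genotypes` (genotype-set
#'   tibble: gene_id, species, geno, sites, gene_length), `depth`
#'   (per-gene mean read depth per species, with planted absences),
#'   `truth` (list `pi` = per-species target and realized diversity,
#'   `absent` = planted absent genes), `config`.
#' @export
simulate_population_variants <- function(genomes, config) {
  stopifnot(inherits(genomes, "dupevol_genomes"))
  set.seed(config$seed + 1L)
  if (any(config$n_accessions < 1)) {
    abort("configuration error: every species needs at least one accession")
  }
  len <- config$gene_length_bp
  tet_sp <- c("G", "Q", "J")
  d_term <- config$base_divergence *
    config$divergence_scale[tet_sp]
  names(d_term) <- tet_sp
  d_out <- config$outgroup_divergence * config$divergence_scale[["N"]]

  tet_genes <- genomes$genes |> filter(.data$taxon == "tetraploid")
  dip_genes <- genomes$genes |> filter(.data$taxon == "diploid")

  rows <- list()
  pi_num <- setNames(numeric(4), c(tet_sp, "N"))
  pi_den <- setNames(numeric(4), c(tet_sp, "N"))

  sim_gene_group <- function(ref_seq, species_list) {
    # returns per-species list(haps = int matrix H x L, meta = tibble)
    ref <- seq_to_int(ref_seq)
    L <- length(ref)
    out <- list()
    for (sp in names(species_list)) {
      d <- species_list[[sp]]
      cons <- mutate_sites(ref, which(runif(L) < jc_site_diff(d)))
      H <- 2L * config$n_accessions[[sp]]
      haps <- matrix(rep(cons, each = H), nrow = H)
      e <- config$species_pi[[sp]] / 2
      nmut <- rbinom(1L, H * L, e)
      if (nmut > 0) {
        slots <- sample.int(H * L, nmut)
        shift <- sample(1:3, nmut, replace = TRUE)
        haps[slots] <- ((haps[slots] - 1L + shift) %% 4L) + 1L
      }
      # realized diversity bookkeeping (before noise injection)
      pi_num[sp] <<- pi_num[sp] + pairwise_diff_sum(haps)
      pi_den[sp] <<- pi_den[sp] + L
      # low-quality sites: failing metadata + scrambled calls
      nq <- round(config$low_qual_frac * L)
      bad <- if (nq > 0) sort(sample.int(L, nq)) else integer(0)
      if (length(bad) > 0) {
        scram <- which(matrix(runif(H * length(bad)) < 0.5, nrow = H),
                       arr.ind = TRUE)
        if (nrow(scram) > 0) {
          haps[cbind(scram[, 1], bad[scram[, 2]])] <-
            sample(1:4, nrow(scram), replace = TRUE)
        }
      }
      mq <- round(runif(L, 31, 60), 1)
      dp <- 4L + rpois(L, config$read_depth_mean - 4)
      if (length(bad) > 0) {
        fail_mq <- runif(length(bad)) < 0.5
        mq[bad[fail_mq]] <- round(runif(sum(fail_mq), 5, 30), 1)
        dp[bad[!fail_mq]] <- sample(0:3, sum(!fail_mq), replace = TRUE)
      }
      out[[sp]] <- list(haps = haps, mq = mq, dp = dp, ref = ref)
    }
    out
  }

  extract_rows <- function(gid, group) {
    # shared variant positions: any haplotype anywhere differs from the ref
    ref <- group[[1]]$ref
    L <- length(ref)
    seg <- rep(FALSE, L)
    for (sp in names(group)) {
      h <- group[[sp]]$haps
      seg <- seg | colSums(h != matrix(rep(ref, each = nrow(h)),
                                       nrow = nrow(h))) > 0
    }
    pos <- which(seg)
    lapply(names(group), function(sp) {
      g <- group[[sp]]
      tibble(gene_id = gid, species = sp,
             geno = list(matrix(int_to_base(g$haps[, pos, drop = FALSE]),
                                nrow = nrow(g$haps))),
             sites = list(tibble(pos = pos, MQ = g$mq[pos], DP = g$dp[pos],
                                 ref = int_to_base(ref[pos]))),
             gene_length = L)
    })
  }

  for (i in seq_len(nrow(tet_genes))) {
    gid <- tet_genes$gene_id[i]
    grp <- sim_gene_group(genomes$sequences[[gid]], as.list(d_term))
    rows <- c(rows, extract_rows(gid, grp))
  }
  for (i in seq_len(nrow(dip_genes))) {
    gid <- dip_genes$gene_id[i]
    grp <- sim_gene_group(genomes$sequences[[gid]], list(N = d_out))
    rows <- c(rows, extract_rows(gid, grp))
  }
  genotypes <- list_rbind(rows)

  ## per-gene mean mapped depth with planted absences (presence calling)
  depth_rows <- list()
  absent <- list()
  for (sp in names(config$n_absent)) {
    gids <- tet_genes$gene_id
    md <- pmax(0.1, rnorm(length(gids), config$read_depth_mean,
                          config$read_depth_mean / 10))
    na <- min(config$n_absent[[sp]], length(gids))
    ab <- if (na > 0) sort(sample(gids, na)) else character(0)
    md[gids %in% ab] <- runif(length(ab), 0, 0.1) * config$read_depth_mean
    depth_rows[[sp]] <- tibble(gene_id = gids, species = sp, mean_depth = md)
    absent[[sp]] <- tibble(species = sp, gene_id = ab)
  }
  truth_pi <- tibble(species = names(pi_num),
                     target = unname(config$species_pi[names(pi_num)]),
                     realized = unname(pi_num / pi_den))
  out <- list(genotypes = genotypes,
              depth = if (length(depth_rows)) list_rbind(depth_rows) else
                tibble(gene_id = character(), species = character(),
                       mean_depth = double()),
              truth = list(pi = truth_pi,
                           absent = if (length(absent)) list_rbind(absent) else
                             tibble(species = character(), gene_id = character())),
              config = config)
  class(out) <- "dupevol_variants"
  out
}

# sum over sites of the mean pairwise difference fraction (all pairs called)
pairwise_diff_sum <- function(haps) {
  H <- nrow(haps)
  if (H < 2) return(0)
  pairs <- H * (H - 1) / 2
  sum_same <- 0
  for (b in 1:4) {
    cnt <- colSums(haps == b)
    sum_same <- sum_same + sum(cnt * (cnt - 1) / 2)
  }
  (ncol(haps) * pairs - sum_same) / pairs
}

#' @export
print.dupevol_variants <- function(x, ...) {
  cat(sprintf("dupevol population variants: %d gene x species matrices\n",
              nrow(x$genotypes)))
  print(x$truth$pi)
  invisible(x)
}
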