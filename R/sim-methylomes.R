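# Bisulfite methylome simulation on the tetraploid gene coordinates (all
# four species' reads mapped to the tetraploid reference, as in cross-species
# methylome comparisons). Gene-level means compose class effects
# (ancient-collinear hypo-, dispersed hypermethylated, singletons
# hypermethylated and higher-variance), an ancestral per-copy deviation
# shared by all species, per-species deviations (larger for the diploid),
# planted DMGs, and subgenome asymmetry inherited identically by the three
# tetraploids. Per-site counts are binomial draws around the gene mean at
# Poisson coverage; CG/CHG/CHH context is read from the sequence.

# cytosine sites (both strands) with context, from a gene's coding sequence;
# positions are 1-based within the gene, sites within 2 bp of either end are
# dropped so context is always defined
cytosine_sites <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  L <- length(b)
  if (L < 5) {
    return(tibble(offset = integer(), strand = character(),
                  context = character()))
  }
  plus <- which(b == "C")
  plus <- plus[plus <= L - 2]
  ctx_p <- dplyr::case_when(
    b[plus + 1] == "G" ~ "CG",
    b[plus + 2] == "G" ~ "CHG",
    TRUE ~ "CHH")
  minus <- which(b == "G")
  minus <- minus[minus >= 3]
  ctx_m <- dplyr::case_when(
    b[minus - 1] == "C" ~ "CG",
    b[minus - 2] == "C" ~ "CHG",
    TRUE ~ "CHH")
  bind_rows(tibble(offset = plus, strand = "+", context = ctx_p),
            tibble(offset = minus, strand = "-", context = ctx_m)) |>
    arrange(.data$offset, .data$strand)
}

#' Simulate replicate bisulfite methylomes with planted effects
#'
#' Generates per-cytosine methylated/unmethylated counts for
#' `n_meth_replicates` samples of each species (G, Q, J, N) over the
#' tetraploid gene bodies, together with the truth lists of planted DMGs and
#' planted subgenome-asymmetric doublet pairs.
#'
#' @param genomes output of [simulate_genomes()].
#' @param config the same [sim_config()].
#' @return list of class `dupevol_methylome`: `sites` (gene_id, scaffold,
#'   pos, strand, context), `samples` (sample, species, replicate), `meth`
#'   and `total` (integer matrices, sites x samples), `gene_means` (the
#'   underlying per gene x context x sample means), `truth` (list `dmg`,
#'   `asym`), `config`.
#' @export
simulate_methylomes <- function(genomes, config) {
  stopifnot(inherits(genomes, "dupevol_genomes"))
  set.seed(config$seed + 2L)
  species <- c("G", "Q", "J", "N")
  samples <- tidyr::expand_grid(species = species,
                                replicate = seq_len(config$n_meth_replicates)) |>
    mutate(sample = paste0(.data$species, "_r", .data$replicate)) |>
    select("sample", "species", "replicate")

  tet <- genomes$genes |> filter(.data$taxon == "tetraploid")
  truth_g <- genomes$truth$genes

  ## ---- per-gene class base means -----------------------------------------
  mm <- genomes$config$meth_class_means
  class_mean <- function(cls, ctx) {
    mm[[ctx]][match(cls, mm$class)]
  }
  og <- genomes$truth$orthogroups
  og_cat <- setNames(og$category, og$ancestral_id)
  base_class <- truth_g |>
    mutate(class = dplyr::case_when(
      !is.na(.data$ssd_mode) ~ .data$ssd_mode,
      .data$ancient ~ "ancient_collinear",
      .data$conserved ~ "conserved_eudicot",
      TRUE ~ "background"),
      og_category = unname(og_cat[.data$ancestral_id]))

  n_genes <- nrow(base_class)
  ctxs <- c("CG", "CHG", "CHH")

  # ancestral per-copy deviation, shared by every species
  copy_dev <- rnorm(n_genes, 0, config$meth_copy_sd)
  # orthogroup effects: singletons hypermethylated and higher-variance
  og_shift <- dplyr::case_when(
    base_class$og_category == "singleton" ~
      config$meth_singleton_shift + rnorm(n_genes, 0, config$meth_singleton_sd),
    base_class$og_category %in% c("doublet", "triplet") ~
      config$meth_doublet_shift + rnorm(n_genes, 0, config$meth_doublet_sd),
    TRUE ~ 0)

  ## planted subgenome asymmetry: shared by G, Q and J
  doublet_anc <- og$ancestral_id[og$category %in% c("doublet", "triplet")]
  n_asym <- floor(config$asym_frac * length(doublet_anc))
  asym_anc <- if (n_asym > 0) sort(sample(doublet_anc, n_asym)) else character(0)
  asym_sign <- setNames(sample(c(-1, 1), length(asym_anc), replace = TRUE),
                        asym_anc)
  asym_dev <- rep(0, n_genes)
  hit <- !is.na(base_class$ancestral_id) &
    base_class$ancestral_id %in% asym_anc & is.na(base_class$ssd_mode)
  asym_dev[hit] <- asym_sign[base_class$ancestral_id[hit]] *
    ifelse(base_class$subgenome[hit] == "A", 0.5, -0.5) * config$asym_offset

  ## planted DMGs: disjoint gene sets per contrast, background genes only
  pool <- base_class$gene_id[base_class$class == "background" &
                               !hit & !is.na(base_class$ancestral_id)]
  need <- config$n_dmg * length(config$dmg_contrasts)
  if (need > length(pool)) {
    abort(sprintf(
      "configuration error: %d planted DMGs requested but only %d eligible genes",
      need, length(pool)))
  }
  dmg_pick <- if (need > 0) sample(pool, need) else character(0)
  dmg_truth <- list()
  for (i in seq_along(config$dmg_contrasts)) {
    cpair <- config$dmg_contrasts[[i]]
    gid <- dmg_pick[seq.int((i - 1) * config$n_dmg + 1, length.out = config$n_dmg)]
    dmg_truth[[i]] <- tibble(species_a = cpair[1], species_b = cpair[2],
                             gene_id = gid,
                             level_a = config$dmg_levels[["high"]],
                             level_b = config$dmg_levels[["low"]])
  }
  dmg_truth <- if (length(dmg_truth)) list_rbind(dmg_truth) else
    tibble(species_a = character(), species_b = character(),
           gene_id = character(), level_a = double(), level_b = double())

  ## ---- gene x context x sample means -------------------------------------
  clamp <- function(x) pmin(0.98, pmax(0.02, x))
  gene_means <- list()
  for (ctx in ctxs) {
    base <- class_mean(base_class$class, ctx) + og_shift + copy_dev + asym_dev
    for (si in seq_len(nrow(samples))) {
      sp <- samples$species[si]
      sp_sd <- if (sp == "N") config$meth_diploid_sd else config$meth_species_sd
      # species deviation is per (species, copy): fixed across replicates
      set_sp <- paste(sp, ctx, sep = ".")
      if (is.null(the$meth_sp_dev)) the$meth_sp_dev <- list()
      m <- base + species_dev_cached(set_sp, n_genes, sp_sd)
      # planted DMGs override the two contrasted species
      for (k in seq_len(nrow(dmg_truth))) {
        gi <- match(dmg_truth$gene_id[k], base_class$gene_id)
        if (sp == dmg_truth$species_a[k]) m[gi] <- dmg_truth$level_a[k]
        if (sp == dmg_truth$species_b[k]) m[gi] <- dmg_truth$level_b[k]
      }
      m <- clamp(m + rnorm(n_genes, 0, config$meth_rep_sd))
      gene_means[[paste(ctx, samples$sample[si], sep = ".")]] <- m
    }
  }
  the$meth_sp_dev <- NULL

  ## ---- per-site counts ----------------------------------------------------
  site_list <- map(base_class$gene_id, function(g) {
    s <- cytosine_sites(genomes$sequences[[g]])
    s$gene_id <- g
    s
  })
  sites <- list_rbind(site_list) |>
    left_join(tet |> select("gene_id", "scaffold", "start"), by = "gene_id") |>
    mutate(pos = .data$start + .data$offset - 1L) |>
    select("gene_id", "scaffold", "pos", "strand", "context", "offset")
  gi_of_site <- match(sites$gene_id, base_class$gene_id)
  n_sites <- nrow(sites)
  meth <- matrix(0L, n_sites, nrow(samples),
                 dimnames = list(NULL, samples$sample))
  total <- meth
  for (si in seq_len(nrow(samples))) {
    p <- numeric(n_sites)
    for (ctx in ctxs) {
      sel <- sites$context == ctx
      p[sel] <- gene_means[[paste(ctx, samples$sample[si], sep = ".")]][
        gi_of_site[sel]]
    }
    cov <- rpois(n_sites, config$read_depth_mean)
    meth[, si] <- rbinom(n_sites, cov, p)
    total[, si] <- cov
  }

  out <- list(sites = sites |> select(-"offset"),
              samples = samples, meth = meth, total = total,
              gene_means = gene_means,
              truth = list(
                dmg = dmg_truth,
                asym = tibble(ancestral_id = asym_anc,
                              sign = unname(asym_sign),
                              offset = config$asym_offset)),
              config = config)
  class(out) <- "dupevol_methylome"
  out
}

# per-(species, context) gene-copy deviation, cached so replicates share it
species_dev_cached <- function(key, n, sd) {
  if (is.null(the$meth_sp_dev[[key]])) {
    the$meth_sp_dev[[key]] <- rnorm(n, 0, sd)
  }
  the$meth_sp_dev[[key]]
}

#' @export
print.dupevol_methylome <- function(x, ...) {
  cat(sprintf("dupevol methylome: %d cytosine sites x %d samples\n",
              nrow(x$sites), nrow(x$samples)))
  cat(sprintf("  planted DMGs: %d; asymmetric pairs: %d\n",
              nrow(x$truth$dmg), nrow(x$truth$asym)))
  invisible(x)
}
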