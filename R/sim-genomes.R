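# Genome simulation: one allotetraploidization (subgenomes A and B) shared
# by three descendant tetraploid species, a diploid outgroup, post-WGD
# fractionation, planted SSD events of the five modes, emulated ancient
# collinearity against a panel of conserved eudicot reference genomes, and
# planted lineage-specific families. Sequence content is ancestral at this
# stage; species divergence and polymorphism are added by
# simulate_population_variants().

random_cds <- function(n_codons) {
  paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
}

#' Simulate the annotated genomes of the allopolyploid complex
#'
#' Generates gene models for the tetraploid (subgenome-tagged, shared by the
#' three tetraploid species), the diploid outgroup, and `n_ref_taxa`
#' conserved eudicot reference genomes; in-frame CDS sequences; anchor
#' tables (diploid-vs-tetraploid orthologs, tetraploid self homologs,
#' eudicot-panel anchors, cross-taxa family hits); and a complete truth
#' table. All randomness derives from `config$seed`; the same configuration
#' reproduces byte-identical output.
#'
#' @param config a [sim_config()] object.
#' @return list of class `dupevol_genomes`: `genes` (gene models, all taxa),
#'   `sequences` (named character vector, tetraploid + diploid genes),
#'   `anchors` (list `ortho`, `self`, `eudicot`, `family_hits`),
#'   `truth` (list `genes`, `orthogroups`, `ssd_genes`, `ssd_events`,
#'   `lineage_specific`, `collinear`), `config`.
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "dupevol_config"))
  set.seed(config$seed)
  n <- config$n_ancestral_genes
  len <- config$gene_length_bp
  anc <- tibble(
    ancestral_id = sprintf("anc%04d", seq_len(n)),
    anc_scaffold = sort(rep_len(seq_len(config$n_scaffolds), n))) |>
    group_by(.data$anc_scaffold) |>
    mutate(anc_rank = dplyr::row_number() - 1L) |>
    ungroup()
  anc_seq <- setNames(vapply(seq_len(n), function(i) random_cds(len %/% 3),
                             character(1)), anc$ancestral_id)

  ## ---- collinear class windows -------------------------------------------
  # ancient windows: preserved in every reference taxon (depth > 4);
  # conserved windows: preserved in exactly two (depth 2)
  anc$window <- NA_integer_
  win_id <- 0L
  win_taxa <- list()
  win_type <- character(0)
  for (w in seq_len(config$ancient_windows)) {
    scaf <- ((w - 1L) %% config$n_scaffolds) + 1L
    cand <- which(anc$anc_scaffold == scaf & is.na(anc$window))
    runs <- cand[seq_len(min(config$ancient_window_genes, length(cand)))]
    if (length(runs) == 0) next
    win_id <- win_id + 1L
    anc$window[runs] <- win_id
    win_taxa[[win_id]] <- seq_len(config$n_ref_taxa)
    win_type[win_id] <- "ancient"
  }
  free <- which(is.na(anc$window))
  if (length(free) > 0 && config$conserved_window_genes > 0) {
    chunks <- split(free, ceiling(seq_along(free) / config$conserved_window_genes))
    for (ch in chunks) {
      if (runif(1) < config$conserved_frac && config$n_ref_taxa >= 2) {
        win_id <- win_id + 1L
        anc$window[ch] <- win_id
        win_taxa[[win_id]] <- sort(sample(config$n_ref_taxa, 2))
        win_type[win_id] <- "conserved"
      }
    }
  }
  anc$collinear_truth <- dplyr::case_when(
    !is.na(anc$window) & win_type[anc$window] == "ancient" ~ "ancient",
    !is.na(anc$window) ~ "conserved",
    TRUE ~ "none")

  ## ---- fractionation ------------------------------------------------------
  keep_dip <- runif(n) >= config$diploid_loss_prob
  keep_a <- runif(n) >= config$fractionation_prob[["A"]]
  keep_b <- runif(n) >= config$fractionation_prob[["B"]]

  tet_id <- function(sub, i) sprintf("tet%s_g%04d", sub, i)
  dip_id <- function(i) sprintf("dip_g%04d", i)

  # per-scaffold ordered gene lists for the tetraploid; events insert here
  scaffolds <- list()
  for (s in seq_len(config$n_scaffolds)) {
    idx <- which(anc$anc_scaffold == s)
    scaffolds[[paste0("A", s)]] <- tet_id("A", idx)[keep_a[idx]]
    scaffolds[[paste0("B", s)]] <- tet_id("B", idx)[keep_b[idx]]
  }
  gene_anc <- c(setNames(rep(anc$ancestral_id, 2),
                         c(tet_id("A", seq_len(n)), tet_id("B", seq_len(n)))))
  gene_seq_of <- function(gid) anc_seq[[gene_anc[[gid]]]]

  ## ---- SSD events ---------------------------------------------------------
  surviving <- unlist(scaffolds, use.names = FALSE)
  used <- character(0)
  events <- list()
  seqs_extra <- character(0)
  anc_extra <- character(0)   # ancestral id of event copies (NA for novel)
  self_pairs <- list()

  pick_donor <- function(pool, k, mode) {
    pool <- setdiff(pool, used)
    if (length(pool) < k) {
      abort(sprintf("configuration error: not enough eligible genes for %d %s event(s)",
                    k, mode))
    }
    sort(sample(pool, k))
  }
  insert_at <- function(scaf, gid, pos) {
    v <- scaffolds[[scaf]]
    scaffolds[[scaf]] <<- append(v, gid, after = pos)
  }
  scaffold_of <- function(gid) {
    for (nm in names(scaffolds)) if (gid %in% scaffolds[[nm]]) return(nm)
    NA_character_
  }

  ev <- 0L
  # tandem: copy adjacent to donor
  for (d in pick_donor(surviving, config$ssd_counts[["tandem"]], "tandem")) {
    ev <- ev + 1L
    cp <- paste0(d, "_td")
    scaf <- scaffold_of(d)
    insert_at(scaf, cp, match(d, scaffolds[[scaf]]))
    used <- c(used, d, cp)
    anc_extra[cp] <- gene_anc[[d]]
    events[[ev]] <- tibble(event_id = sprintf("E%03d", ev), mode = "tandem",
                           donor = d, copy = cp)
    self_pairs[[length(self_pairs) + 1]] <- c(d, cp)
  }
  # proximal: copy 2-5 ranks downstream of donor
  for (d in pick_donor(surviving, config$ssd_counts[["proximal"]], "proximal")) {
    ev <- ev + 1L
    cp <- paste0(d, "_px")
    scaf <- scaffold_of(d)
    gap <- sample(2:5, 1)
    pos <- min(match(d, scaffolds[[scaf]]) + gap - 1L, length(scaffolds[[scaf]]))
    insert_at(scaf, cp, pos)
    used <- c(used, d, cp)
    anc_extra[cp] <- gene_anc[[d]]
    events[[ev]] <- tibble(event_id = sprintf("E%03d", ev), mode = "proximal",
                           donor = d, copy = cp)
    self_pairs[[length(self_pairs) + 1]] <- c(d, cp)
  }
  # transposed: donor keeps its ancestral (outgroup-collinear) locus, the
  # copy lands at a random novel locus on a different scaffold
  tr_pool <- surviving[keep_dip[match(gene_anc[surviving], anc$ancestral_id)]]
  for (d in pick_donor(tr_pool, config$ssd_counts[["transposed"]], "transposed")) {
    ev <- ev + 1L
    cp <- paste0(d, "_tp")
    from <- scaffold_of(d)
    to <- sample(setdiff(names(scaffolds), from), 1)
    insert_at(to, cp, sample(0:length(scaffolds[[to]]), 1))
    used <- c(used, d, cp)
    anc_extra[cp] <- gene_anc[[d]]
    events[[ev]] <- tibble(event_id = sprintf("E%03d", ev), mode = "transposed",
                           donor = d, copy = cp)
    self_pairs[[length(self_pairs) + 1]] <- c(d, cp)
  }
  # dispersed: a novel two-gene family at random loci on different scaffolds
  for (k in seq_len(config$ssd_counts[["dispersed"]])) {
    ev <- ev + 1L
    g1 <- sprintf("tet_dsp%03da", k)
    g2 <- sprintf("tet_dsp%03db", k)
    s1 <- sample(names(scaffolds), 1)
    s2 <- sample(setdiff(names(scaffolds), s1), 1)
    insert_at(s1, g1, sample(0:length(scaffolds[[s1]]), 1))
    insert_at(s2, g2, sample(0:length(scaffolds[[s2]]), 1))
    used <- c(used, g1, g2)
    seqs_extra[g1] <- random_cds(len %/% 3)
    seqs_extra[g2] <- seqs_extra[g1]
    anc_extra[g1] <- NA_character_
    anc_extra[g2] <- NA_character_
    events[[ev]] <- tibble(event_id = sprintf("E%03d", ev), mode = "dispersed",
                           donor = g1, copy = g2)
    self_pairs[[length(self_pairs) + 1]] <- c(g1, g2)
  }
  # segmental: a run of consecutive genes duplicated to the sister scaffold
  # of the same subgenome (or appended far away when only one scaffold)
  for (k in seq_len(config$ssd_counts[["segmental"]])) {
    run <- NULL
    for (try_scaf in sample(names(scaffolds))) {
      v <- setdiff(scaffolds[[try_scaf]], used)
      v <- scaffolds[[try_scaf]][scaffolds[[try_scaf]] %in% v]
      pos <- match(v, scaffolds[[try_scaf]])
      ok <- which(diff(pos, lag = config$segment_genes - 1L) ==
                    config$segment_genes - 1L)
      if (length(ok) > 0) {
        st <- sample(ok, 1)
        run <- v[st:(st + config$segment_genes - 1L)]
        src <- try_scaf
        break
      }
    }
    if (is.null(run)) {
      abort("configuration error: no room for a segmental duplication event")
    }
    ev <- ev + 1L
    sub <- substr(src, 1, 1)
    dest_pool <- setdiff(grep(paste0("^", sub), names(scaffolds), value = TRUE),
                         src)
    dest <- if (length(dest_pool) > 0) sample(dest_pool, 1) else src
    cps <- paste0(run, "_sg")
    at <- if (dest == src) length(scaffolds[[dest]]) else
      sample(0:length(scaffolds[[dest]]), 1)
    scaffolds[[dest]] <- append(scaffolds[[dest]], cps, after = at)
    used <- c(used, run, cps)
    for (i in seq_along(run)) {
      anc_extra[cps[i]] <- gene_anc[[run[i]]]
      self_pairs[[length(self_pairs) + 1]] <- c(run[i], cps[i])
    }
    events[[ev]] <- tibble(event_id = sprintf("E%03d", ev), mode = "segmental",
                           donor = paste(run, collapse = ","),
                           copy = paste(cps, collapse = ","))
  }
  # lineage-specific families: novel gene in the diploid + tetraploid only
  ls_genes <- character(0)
  for (k in seq_len(config$n_lineage_specific)) {
    gt <- sprintf("tet_lsp%03d", k)
    gd <- sprintf("dip_lsp%03d", k)
    s1 <- sample(names(scaffolds), 1)
    insert_at(s1, gt, sample(0:length(scaffolds[[s1]]), 1))
    seqs_extra[gt] <- random_cds(len %/% 3)
    seqs_extra[gd] <- seqs_extra[gt]
    anc_extra[gt] <- NA_character_
    anc_extra[gd] <- NA_character_
    ls_genes <- c(ls_genes, gt, gd)
  }

  ## ---- materialise gene models -------------------------------------------
  step <- len + config$intergenic_bp
  tet_genes <- imap(scaffolds, function(v, scaf) {
    if (length(v) == 0) return(NULL)
    tibble(gene_id = v, taxon = "tetraploid", scaffold = scaf,
           rank = seq_along(v) - 1L,
           start = config$intergenic_bp + (seq_along(v) - 1L) * step + 1L,
           end = config$intergenic_bp + (seq_along(v) - 1L) * step + len,
           strand = "+", subgenome = substr(scaf, 1, 1))
  }) |> list_rbind()

  dip_keep <- anc$ancestral_id[keep_dip]
  dip_order <- split(which(keep_dip), anc$anc_scaffold[keep_dip])
  dip_genes <- imap(dip_order, function(idx, s) {
    v <- dip_id(idx)
    if (length(ls_genes) > 0 && s == names(dip_order)[1]) {
      v <- c(v, grep("^dip_lsp", ls_genes, value = TRUE))
    }
    tibble(gene_id = v, taxon = "diploid", scaffold = paste0("dChr", s),
           rank = seq_along(v) - 1L,
           start = config$intergenic_bp + (seq_along(v) - 1L) * step + 1L,
           end = config$intergenic_bp + (seq_along(v) - 1L) * step + len,
           strand = "+", subgenome = NA_character_)
  }) |> list_rbind()

  # reference taxa: window scaffolds preserve ancestral order; everything
  # else sits on a scrambled scaffold (homology without collinearity)
  ref_genes <- list()
  for (r in seq_len(config$n_ref_taxa)) {
    taxon <- paste0("ref", r)
    rows <- list()
    in_window <- rep(FALSE, n)
    if (win_id > 0) {
      for (w in seq_len(win_id)) {
        if (!r %in% win_taxa[[w]]) next
        idx <- which(anc$window == w)
        in_window[idx] <- TRUE
        rows[[length(rows) + 1]] <- tibble(
          gene_id = sprintf("%s_g%04d", taxon, idx), taxon = taxon,
          scaffold = sprintf("%s_w%02d", taxon, w),
          rank = seq_along(idx) - 1L, subgenome = NA_character_)
      }
    }
    rest <- sample(which(!in_window))
    rows[[length(rows) + 1]] <- tibble(
      gene_id = sprintf("%s_g%04d", taxon, rest), taxon = taxon,
      scaffold = paste0(taxon, "_s1"), rank = seq_along(rest) - 1L,
      subgenome = NA_character_)
    ref_genes[[r]] <- list_rbind(rows) |>
      mutate(start = config$intergenic_bp + .data$rank * step + 1L,
             end = config$intergenic_bp + .data$rank * step + len,
             strand = "+")
  }
  genes <- bind_rows(tet_genes, dip_genes, list_rbind(ref_genes)) |>
    select("gene_id", "taxon", "scaffold", "start", "end", "strand",
           "subgenome", "rank")

  ## ---- sequences ----------------------------------------------------------
  gene_anc_all <- c(gene_anc, setNames(anc$ancestral_id, dip_id(seq_len(n))),
                    anc_extra)
  seq_ids <- genes$gene_id[genes$taxon %in% c("tetraploid", "diploid")]
  sequences <- vapply(seq_ids, function(g) {
    if (!is.na(gene_anc_all[g] %||% NA_character_)) anc_seq[[gene_anc_all[[g]]]]
    else seqs_extra[[g]]
  }, character(1))

  ## ---- anchors -------------------------------------------------------------
  ancestral_of <- function(ids) unname(gene_anc_all[ids])
  tet_primary <- tet_genes$gene_id[tet_genes$gene_id %in%
                                     c(tet_id("A", seq_len(n)), tet_id("B", seq_len(n)))]
  dip_by_anc <- setNames(dip_id(seq_len(n)), anc$ancestral_id)
  ortho <- tibble(gene2 = tet_primary,
                  ancestral_id = ancestral_of(tet_primary)) |>
    filter(keep_dip[match(.data$ancestral_id, anc$ancestral_id)]) |>
    mutate(gene1 = unname(dip_by_anc[.data$ancestral_id]),
           score = round(runif(dplyr::n(), 0.7, 1), 4)) |>
    select("gene1", "gene2", "score") |>
    arrange(.data$gene1, .data$gene2)

  self_anchors <- list()
  both <- which(keep_a & keep_b)
  if (length(both) > 0) {
    self_anchors[[1]] <- tibble(gene1 = tet_id("A", both),
                                gene2 = tet_id("B", both),
                                score = round(runif(length(both), 0.7, 1), 4))
  }
  if (length(self_pairs) > 0) {
    sp <- do.call(rbind, self_pairs)
    self_anchors[[length(self_anchors) + 1]] <-
      tibble(gene1 = sp[, 1], gene2 = sp[, 2],
             score = round(runif(nrow(sp), 0.6, 0.95), 4))
  }
  self_anchors <- bind_rows(self_anchors) |>
    arrange(.data$gene1, .data$gene2)

  # eudicot-panel anchors emulate pre-filtered syntenic homolog candidates:
  # only genes inside a window preserved by that reference taxon carry an
  # anchor (deep divergence erodes both synteny and anchor detectability)
  eud <- list()
  for (r in seq_len(config$n_ref_taxa)) {
    taxon <- paste0("ref", r)
    tgt <- tibble(gene2 = tet_primary,
                  ancestral_id = ancestral_of(tet_primary)) |>
      mutate(window = anc$window[match(.data$ancestral_id, anc$ancestral_id)]) |>
      filter(!is.na(.data$window),
             map_lgl(.data$window, ~ r %in% win_taxa[[.x]]))
    eud[[r]] <- tgt |>
      mutate(gene1 = sprintf("%s_g%04d", taxon,
                             match(.data$ancestral_id, anc$ancestral_id)),
             score = round(runif(dplyr::n(), 0.6, 1), 4)) |>
      select("gene1", "gene2", "score")
  }
  eudicot <- list_rbind(eud) |> arrange(.data$gene1, .data$gene2)

  # family hits: all within-family unordered pairs across taxa
  fam_members <- bind_rows(
    genes |>
      filter(.data$taxon %in% c("tetraploid", "diploid")) |>
      mutate(ancestral_id = ancestral_of(.data$gene_id)),
    genes |>
      filter(startsWith(.data$taxon, "ref")) |>
      mutate(ancestral_id = anc$ancestral_id[
        as.integer(sub(".*_g", "", .data$gene_id))])) |>
    filter(!is.na(.data$ancestral_id))
  hits <- fam_members |>
    select("gene_id", "ancestral_id") |>
    inner_join(fam_members |> select(gene_id2 = "gene_id", "ancestral_id"),
               by = "ancestral_id", relationship = "many-to-many") |>
    filter(.data$gene_id < .data$gene_id2) |>
    transmute(gene1 = .data$gene_id, gene2 = .data$gene_id2,
              score = round(runif(dplyr::n(), 0.5, 1), 4))
  novel_fams <- c(map(seq_len(config$ssd_counts[["dispersed"]]), function(k) {
    c(sprintf("tet_dsp%03da", k), sprintf("tet_dsp%03db", k))
  }), map(seq_len(config$n_lineage_specific), function(k) {
    c(sprintf("tet_lsp%03d", k), sprintf("dip_lsp%03d", k))
  }))
  if (length(novel_fams) > 0) {
    nf <- do.call(rbind, novel_fams)
    hits <- bind_rows(hits, tibble(gene1 = pmin(nf[, 1], nf[, 2]),
                                   gene2 = pmax(nf[, 1], nf[, 2]),
                                   score = round(runif(nrow(nf), 0.8, 1), 4)))
  }
  hits <- arrange(hits, .data$gene1, .data$gene2)

  ## ---- truth ----------------------------------------------------------------
  ssd_events <- if (length(events) > 0) list_rbind(events) else
    tibble(event_id = character(), mode = character(), donor = character(),
           copy = character())
  ssd_genes <- purrr::pmap(ssd_events, function(event_id, mode, donor, copy) {
    gid <- if (mode == "dispersed") c(donor, strsplit(copy, ",")[[1]]) else
      strsplit(copy, ",")[[1]]
    tibble(event_id = event_id, mode = mode, gene_id = gid)
  }) |> list_rbind()
  if (nrow(ssd_events) == 0) {
    ssd_genes <- tibble(event_id = character(), mode = character(),
                        gene_id = character())
  }
  og_truth <- anc |>
    mutate(a_present = keep_a, b_present = keep_b, dip_present = keep_dip,
           category = dplyr::case_when(
             a_present & b_present & dip_present ~ "triplet",
             a_present & b_present ~ "doublet",
             xor(a_present, b_present) & dip_present ~ "singleton",
             TRUE ~ NA_character_),
           subgenome = dplyr::if_else(
             .data$category == "singleton",
             dplyr::if_else(.data$a_present, "A", "B"), NA_character_)) |>
    select("ancestral_id", "a_present", "b_present", "dip_present",
           "category", "subgenome")
  coll_truth <- bind_rows(
    tibble(gene_id = tet_id("A", seq_len(n))[keep_a],
           ancestral_id = anc$ancestral_id[keep_a]),
    tibble(gene_id = tet_id("B", seq_len(n))[keep_b],
           ancestral_id = anc$ancestral_id[keep_b])) |>
    left_join(anc |> select("ancestral_id", "collinear_truth"),
              by = "ancestral_id") |>
    mutate(ancient = .data$collinear_truth == "ancient",
           conserved = .data$collinear_truth != "none") |>
    select("gene_id", "ancestral_id", "ancient", "conserved")
  truth_genes <- genes |>
    filter(.data$taxon == "tetraploid") |>
    select("gene_id", "subgenome") |>
    mutate(ancestral_id = ancestral_of(.data$gene_id)) |>
    left_join(ssd_genes |> select("gene_id", ssd_mode = "mode"),
              by = "gene_id") |>
    left_join(coll_truth |> select("gene_id", "ancient", "conserved"),
              by = "gene_id") |>
    mutate(ancient = coalesce(.data$ancient, FALSE),
           conserved = coalesce(.data$conserved, FALSE))

  out <- list(
    genes = genes,
    sequences = sequences,
    anchors = list(ortho = ortho, self = self_anchors, eudicot = eudicot,
                   family_hits = hits),
    truth = list(
      genes = truth_genes,
      orthogroups = og_truth,
      ssd_genes = ssd_genes |> select("gene_id", "mode", "event_id"),
      ssd_events = ssd_events,
      lineage_specific = sort(c(ls_genes, unlist(novel_fams[
        seq_len(config$ssd_counts[["dispersed"]])]))),
      collinear = coll_truth,
      losses = tibble(ancestral_id = anc$ancestral_id,
                      lost_a = !keep_a, lost_b = !keep_b,
                      lost_dip = !keep_dip)),
    config = config)
  class(out) <- "dupevol_genomes"
  out
}

#' @export
print.dupevol_genomes <- function(x, ...) {
  tg <- sum(x$genes$taxon == "tetraploid")
  dg <- sum(x$genes$taxon == "diploid")
  cat(sprintf("dupevol synthetic genomes: %d tetraploid, %d diploid genes (+%d ref taxa)\n",
              tg, dg, x$config$n_ref_taxa))
  cat(sprintf("  anchors: %d ortho, %d self, %d eudicot, %d family hits\n",
              nrow(x$anchors$ortho), nrow(x$anchors$self),
              nrow(x$anchors$eudicot), nrow(x$anchors$family_hits)))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.dupevol_genomes <- function(x, ...) {
  og <- x$truth$orthogroups
  tibble(n_tetraploid_genes = sum(x$genes$taxon == "tetraploid"),
         n_diploid_genes = sum(x$genes$taxon == "diploid"),
         n_singleton = sum(og$category == "singleton", na.rm = TRUE),
         n_doublet = sum(og$category %in% c("doublet", "triplet")),
         n_triplet = sum(og$category == "triplet", na.rm = TRUE),
         n_ssd_events = nrow(x$truth$ssd_events),
         n_lineage_specific = length(x$truth$lineage_specific))
}
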