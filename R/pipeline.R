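# End-to-end pipeline: simulate -> classify -> popgen -> methylome ->
# compare, driven by one validated configuration, with every stage reading
# its inputs from, and writing its outputs to, a single output directory.
# The run returns a manifest of every file written with md5 checksums;
# identical configuration + seed reproduces identical checksums.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "classify", "popgen", "methylome", "compare"),
    sim = list(),
    chaining = list(min_block_anchors = 5, max_gene_gap = 25,
                    gap_penalty = 0.05),
    ssd = list(proximal_max_rank_gap = 10),
    popgen = list(min_mq = 30, min_dp = 3, presence_rel_threshold = 0.2,
                  dnds_pair = c("G", "J")),
    dmg = list(min_total_depth = 10, delta_within_max = 0.1,
               delta_between_min = 0.5, frac_windows_min = 0.1,
               alpha = 0.01, n_windows = 20))
}

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes an equivalent list), rejects unknown
#' keys, fills documented defaults, validates every parameter range (via
#' [sim_config()] for the simulation block) and returns the normalized
#' configuration. Duplicate YAML keys are an error, not a silent override.
#'
#' @param config path to a YAML file, or a named list.
#' @return list of class `dupevol_pipeline_config`: `seed`, `stages`,
#'   `sim` (a `dupevol_config`), `chaining`, `ssd`, `popgen`, `dmg`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- tryCatch(yaml::read_yaml(config), error = function(e) {
      abort(paste0("config parse error: ", conditionMessage(e)))
    })
  }
  stopifnot(is.list(config))
  defs <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  for (blk in c("chaining", "ssd", "popgen", "dmg")) {
    extra <- setdiff(names(config[[blk]]), names(defs[[blk]]))
    if (length(extra) > 0) {
      abort(paste0("unknown key(s) in '", blk, "': ",
                   paste(extra, collapse = ", ")))
    }
    defs[[blk]][names(config[[blk]])] <- config[[blk]]
  }
  if (!is.null(config$seed)) defs$seed <- as.integer(config$seed)
  if (!is.null(config$stages)) {
    bad <- setdiff(config$stages, pipeline_defaults()$stages)
    if (length(bad) > 0) {
      abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
    }
    defs$stages <- config$stages
  }
  sim_args <- config$sim %||% list()
  allowed_sim <- setdiff(names(formals(sim_config)), "meth_class_means")
  extra <- setdiff(names(sim_args), allowed_sim)
  if (length(extra) > 0) {
    abort(paste0("unknown key(s) in 'sim': ", paste(extra, collapse = ", ")))
  }
  # YAML maps arrive as named lists; the config vectors are atomic. YAML 1.1
  # also reads a bare N/Y as a boolean, so species keys and values are
  # normalised back to their letters.
  unbool <- function(x) {
    if (is.logical(x)) x <- ifelse(x, "Y", "N")
    x
  }
  vecs <- c("fractionation_prob", "ssd_counts", "species_pi",
            "divergence_scale", "n_accessions", "dmg_levels", "n_absent")
  for (v in intersect(vecs, names(sim_args))) {
    sim_args[[v]] <- unlist(sim_args[[v]])
    names(sim_args[[v]]) <- unbool(as.logical(names(sim_args[[v]]))) |>
      (\(l) ifelse(is.na(l), names(sim_args[[v]]), l))()
  }
  if (!is.null(sim_args$dmg_contrasts)) {
    sim_args$dmg_contrasts <- lapply(sim_args$dmg_contrasts, function(cp) {
      vapply(cp, function(x) if (is.logical(x)) unbool(x) else
        as.character(x), character(1))
    })
  }
  sim_args$seed <- defs$seed
  defs$sim <- do.call(sim_config, sim_args)
  class(defs) <- "dupevol_pipeline_config"
  defs
}

need_files <- function(outdir, files, producer) {
  miss <- files[!file.exists(file.path(outdir, files))]
  if (length(miss) > 0) {
    abort(paste0("dependency error: missing ", paste(miss, collapse = ", "),
                 " (run the '", producer, "' stage first)"))
  }
}

#' Run the duplicated-gene evolution pipeline
#'
#' Executes the enabled stages in dependency order
#' (simulate, classify, popgen, methylome, compare) inside `outdir`. Every
#' stage reads its inputs from files in `outdir`, so stages can be re-run or
#' supplied with externally produced inputs; a disabled upstream stage whose
#' outputs are absent raises a dependency error naming it.
#'
#' @param config a `dupevol_pipeline_config`, a path to a YAML file, or a
#'   plain list (both validated via [validate_config()]).
#' @param outdir output directory (created if needed; all outputs stay
#'   inside it).
#' @return tibble manifest (`file`, `md5`), invisibly also written as
#'   `manifest.tsv`.
#' @export
run_pipeline <- function(config, outdir) {
  if (!inherits(config, "dupevol_pipeline_config")) {
    config <- validate_config(config)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  put_tsv <- function(df, name) {
    f <- file.path(outdir, name)
    readr::write_tsv(df, f, progress = FALSE)
    written <<- c(written, name)
    f
  }
  note <- function(name) written <<- c(written, name)

  if ("simulate" %in% config$stages) {
    genomes <- simulate_genomes(config$sim)
    variants <- simulate_population_variants(genomes, config$sim)
    meth <- simulate_methylomes(genomes, config$sim)
    put_tsv(genomes$genes, "genes.tsv")
    write_gff3(genomes$genes |> filter(.data$taxon == "tetraploid"),
               file.path(outdir, "tetraploid.gff3")); note("tetraploid.gff3")
    write_gff3(genomes$genes |> filter(.data$taxon == "diploid"),
               file.path(outdir, "diploid.gff3")); note("diploid.gff3")
    write_fasta(genomes$sequences, file.path(outdir, "sequences.fasta"))
    note("sequences.fasta")
    put_tsv(genomes$anchors$ortho, "anchors_ortho.tsv")
    put_tsv(genomes$anchors$self, "anchors_self.tsv")
    put_tsv(genomes$anchors$eudicot, "anchors_eudicot.tsv")
    put_tsv(genomes$anchors$family_hits, "family_hits.tsv")
    for (sp in unique(variants$genotypes$species)) {
      f <- paste0("variants_", sp, ".vcf")
      write_vcf(variants$genotypes |> filter(.data$species == sp),
                genomes$genes, file.path(outdir, f),
                sample_prefix = paste0(sp, "acc"))
      note(f)
    }
    put_tsv(variants$depth, "depth.tsv")
    put_tsv(meth$samples, "sample_sheet.tsv")
    cx <- write_cx_reports(meth, outdir)
    for (f in cx) note(basename(f))
    put_tsv(genomes$truth$orthogroups, "truth_orthogroups.tsv")
    put_tsv(genomes$truth$ssd_genes, "truth_ssd_genes.tsv")
    put_tsv(tibble(gene_id = genomes$truth$lineage_specific),
            "truth_lineage_specific.tsv")
    put_tsv(genomes$truth$genes, "truth_genes.tsv")
    put_tsv(variants$truth$pi, "truth_pi.tsv")
    put_tsv(variants$truth$absent, "truth_absent.tsv")
    put_tsv(meth$truth$dmg, "truth_dmg.tsv")
    put_tsv(meth$truth$asym, "truth_asym.tsv")
    ann <- genomes$truth$genes |>
      mutate(category = dplyr::case_when(
        !is.na(.data$ssd_mode) ~ .data$ssd_mode,
        .data$ancient ~ "ancient_collinear",
        .data$conserved ~ "conserved_eudicot",
        TRUE ~ "background")) |>
      select("gene_id", "category")
    put_tsv(ann, "annotation.tsv")
  }

  if ("classify" %in% config$stages) {
    need_files(outdir, c("genes.tsv", "anchors_ortho.tsv", "anchors_self.tsv",
                         "anchors_eudicot.tsv", "family_hits.tsv"), "simulate")
    genes <- readr::read_tsv(file.path(outdir, "genes.tsv"),
                             show_col_types = FALSE)
    ch <- config$chaining
    rd <- function(f) readr::read_tsv(file.path(outdir, f),
                                      show_col_types = FALSE)
    ortho_blocks <- chain_anchors(rd("anchors_ortho.tsv"), genes,
                                  ch$min_block_anchors, ch$max_gene_gap,
                                  ch$gap_penalty)
    self_blocks <- chain_anchors(rd("anchors_self.tsv"), genes,
                                 ch$min_block_anchors, ch$max_gene_gap,
                                 ch$gap_penalty)
    eud_blocks <- chain_anchors(rd("anchors_eudicot.tsv"), genes,
                                ch$min_block_anchors, ch$max_gene_gap,
                                ch$gap_penalty)
    put_tsv(ortho_blocks, "blocks_ortho.tsv")
    put_tsv(self_blocks, "blocks_self.tsv")
    put_tsv(eud_blocks, "blocks_eudicot.tsv")
    og <- classify_wgd_groups(bind_rows(ortho_blocks, self_blocks), genes)
    put_tsv(og, "orthogroups.tsv")
    tet <- genes |> filter(.data$taxon == "tetraploid")
    ssd <- classify_ssd_modes(tet, rd("anchors_self.tsv"), self_blocks,
                              ortho_blocks,
                              config$ssd$proximal_max_rank_gap)
    put_tsv(ssd, "ssd_classes.tsv")
    put_tsv(collinear_depth(eud_blocks, tet), "collinear_depth.tsv")
    fam <- cluster_families(genes, rd("family_hits.tsv"),
                            focal_taxa = c("tetraploid", "diploid"))
    put_tsv(fam, "families.tsv")
  }

  if ("popgen" %in% config$stages) {
    need_files(outdir, c("genes.tsv", "sequences.fasta", "depth.tsv"),
               "simulate")
    genes <- readr::read_tsv(file.path(outdir, "genes.tsv"),
                             show_col_types = FALSE)
    seqs <- read_fasta(file.path(outdir, "sequences.fasta"))
    glen <- config$sim$gene_length_bp
    vcfs <- list.files(outdir, pattern = "^variants_.*\\.vcf$")
    if (length(vcfs) == 0) {
      abort("dependency error: missing variants_*.vcf (run the 'simulate' stage first)")
    }
    gts <- list()
    for (f in vcfs) {
      sp <- sub("^variants_(.*)\\.vcf$", "\\1", f)
      frame <- genes |> filter(.data$taxon ==
                                 if (sp == "N") "diploid" else "tetraploid")
      gts[[sp]] <- read_vcf_genotypes(file.path(outdir, f), frame, sp, glen)
    }
    genotypes <- list_rbind(unname(gts))
    tet_sp <- intersect(c("G", "Q", "J"), names(gts))
    stats <- popgen_gene_stats(
      genotypes |> filter(.data$species %in% tet_sp),
      min_mq = config$popgen$min_mq, min_dp = config$popgen$min_dp,
      dxy_species = tet_sp)
    pi_n <- if ("N" %in% names(gts)) {
      popgen_gene_stats(gts$N, min_mq = config$popgen$min_mq,
                        min_dp = config$popgen$min_dp,
                        dxy_species = character(0))$pi
    } else NULL
    put_tsv(bind_rows(stats$pi, pi_n), "popgen_pi.tsv")
    put_tsv(stats$dxy, "popgen_dxy.tsv")
    ## NG86 dN/dS between the major-allele consensus sequences of a species
    ## pair sharing the tetraploid coordinates
    pair <- config$popgen$dnds_pair
    cons <- function(sp, gid) {
      row <- genotypes |> filter(.data$species == sp, .data$gene_id == gid)
      s <- seqs[[gid]]
      if (nrow(row) == 0) return(s)
      g <- filter_variants(row, config$popgen$min_mq, config$popgen$min_dp)
      m <- g$geno[[1]]; st <- g$sites[[1]]
      if (nrow(st) == 0) return(s)
      b <- strsplit(s, "")[[1]]
      for (j in seq_len(nrow(st))) {
        al <- m[, j]; al <- al[!is.na(al)]
        if (length(al) > 0) {
          tab <- sort(table(al), decreasing = TRUE)
          b[st$pos[j]] <- names(tab)[1]
        }
      }
      paste(b, collapse = "")
    }
    tet_ids <- genes$gene_id[genes$taxon == "tetraploid"]
    dnds <- map(tet_ids, function(g) {
      res <- tryCatch(ng86_dnds(cons(pair[1], g), cons(pair[2], g)),
                      error = function(e) NULL)
      if (is.null(res)) return(NULL)
      res$gene_id <- g
      res
    }) |> purrr::compact() |> list_rbind()
    put_tsv(dnds |> select("gene_id", dplyr::everything()), "popgen_dnds.tsv")
    depth <- readr::read_tsv(file.path(outdir, "depth.tsv"),
                             show_col_types = FALSE)
    presence <- depth |>
      group_by(.data$species) |>
      mutate(present = gene_presence_by_depth(
        .data$mean_depth, median(.data$mean_depth),
        config$popgen$presence_rel_threshold)) |>
      ungroup()
    put_tsv(presence, "presence.tsv")
  }

  if ("methylome" %in% config$stages) {
    need_files(outdir, c("genes.tsv", "sample_sheet.tsv"), "simulate")
    genes <- readr::read_tsv(file.path(outdir, "genes.tsv"),
                             show_col_types = FALSE)
    samples <- readr::read_tsv(file.path(outdir, "sample_sheet.tsv"),
                               show_col_types = FALSE)
    cx_files <- setNames(file.path(outdir, paste0(samples$sample,
                                                  ".CX_report.txt")),
                         samples$sample)
    if (!all(file.exists(cx_files))) {
      abort("dependency error: missing CX report(s) (run the 'simulate' stage first)")
    }
    tet <- genes |> filter(.data$taxon == "tetraploid")
    meth <- read_cx_reports(cx_files, samples, tet)
    lev <- gene_methylation(
      filter_sites(meth, config$dmg$min_total_depth))
    put_tsv(lev, "gene_methylation.tsv")
    calls <- map(config$sim$dmg_contrasts, function(cp) {
      call_dmgs(meth, tet, cp,
                delta_within_max = config$dmg$delta_within_max,
                delta_between_min = config$dmg$delta_between_min,
                frac_windows_min = config$dmg$frac_windows_min,
                alpha = config$dmg$alpha,
                min_total_depth = config$dmg$min_total_depth,
                n_windows = config$dmg$n_windows)
    }) |> list_rbind()
    put_tsv(calls, "dmg_calls.tsv")
    put_tsv(sample_profile_correlations(
      filter_sites(meth, config$dmg$min_total_depth)),
      "sample_correlations.tsv")
  }

  if ("compare" %in% config$stages) {
    need_files(outdir, c("orthogroups.tsv", "ssd_classes.tsv",
                         "collinear_depth.tsv", "families.tsv"), "classify")
    need_files(outdir, c("popgen_pi.tsv", "popgen_dxy.tsv",
                         "popgen_dnds.tsv"), "popgen")
    need_files(outdir, c("gene_methylation.tsv", "dmg_calls.tsv"),
               "methylome")
    rd <- function(f) readr::read_tsv(file.path(outdir, f),
                                      show_col_types = FALSE)
    og <- rd("orthogroups.tsv")
    ssd <- rd("ssd_classes.tsv")
    cd <- rd("collinear_depth.tsv")
    fam <- rd("families.tsv")
    pi_tbl <- rd("popgen_pi.tsv")
    dxy_tbl <- rd("popgen_dxy.tsv")
    dnds <- rd("popgen_dnds.tsv")
    lev <- rd("gene_methylation.tsv")
    samples <- rd("sample_sheet.tsv")
    genes <- rd("genes.tsv")

    classes <- bind_rows(
      ssd |> select("gene_id", "class"),
      cd |> filter(.data$ancient_collinear) |>
        transmute(gene_id = .data$gene_id, class = "ancient_collinear"),
      cd |> filter(.data$conserved_eudicot) |>
        transmute(gene_id = .data$gene_id, class = "conserved_eudicot"),
      og |> filter(!is.na(.data$gene_a)) |>
        transmute(gene_id = .data$gene_a, class = .data$category),
      og |> filter(!is.na(.data$gene_b)) |>
        transmute(gene_id = .data$gene_b, class = .data$category),
      fam |> filter(.data$lineage_specific, .data$taxon == "tetraploid") |>
        transmute(gene_id = .data$gene_id, class = "lineage_specific"))
    put_tsv(classes, "gene_classes.tsv")

    sp_lev <- lev |>
      left_join(samples, by = "sample") |>
      group_by(.data$gene_id, .data$context, .data$species) |>
      summarise(level = mean(.data$level), .groups = "drop")
    gene_stats <- bind_rows(
      pi_tbl |> transmute(gene_id = .data$gene_id,
                          statistic = paste0("pi_", .data$species),
                          value = .data$pi),
      dxy_tbl |> transmute(gene_id = .data$gene_id,
                           statistic = paste0("dxy_", .data$species_a, "_",
                                              .data$species_b),
                           value = .data$dxy),
      dnds |> transmute(gene_id = .data$gene_id, statistic = "dn_ds",
                        value = .data$dn_ds),
      sp_lev |> transmute(gene_id = .data$gene_id,
                          statistic = paste0("meth_", .data$context, "_",
                                             .data$species),
                          value = .data$level))
    comp <- compare_classes(gene_stats, classes)
    put_tsv(comp, "class_comparison.tsv")

    pairs <- og |>
      filter(.data$category %in% c("doublet", "triplet")) |>
      transmute(pair_id = .data$group_id, gene_a = .data$gene_a,
                gene_b = .data$gene_b)
    tet_sp <- intersect(c("G", "Q", "J"), unique(samples$species))
    asym_lev <- sp_lev |>
      filter(.data$context == "CG", .data$species %in% tet_sp) |>
      select("gene_id", "species", value = "level")
    asym <- subgenome_asymmetry(asym_lev, pairs)
    put_tsv(asym$per_gene, "asymmetry_per_gene.tsv")
    put_tsv(asym$correlations, "asymmetry_correlations.tsv")
    put_tsv(glance(asym), "asymmetry_summary.tsv")

    put_tsv(fractionation_bias_test(og), "fractionation.tsv")

    if (file.exists(file.path(outdir, "annotation.tsv")) &&
        file.exists(file.path(outdir, "dmg_calls.tsv"))) {
      ann <- rd("annotation.tsv")
      calls <- rd("dmg_calls.tsv")
      dmg_set <- unique(calls$gene_id[calls$is_dmg])
      universe <- unique(genes$gene_id[genes$taxon == "tetraploid"])
      enr <- enrichment_hypergeometric(intersect(dmg_set, universe), ann,
                                       universe)
      put_tsv(enr, "enrichment_dmg.tsv")
    }
  }

  manifest <- tibble(file = sort(unique(written))) |>
    mutate(md5 = unname(tools::md5sum(file.path(outdir, .data$file))))
  readr::write_tsv(manifest, file.path(outdir, "manifest.tsv"),
                   progress = FALSE)
  invisible(manifest)
}
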