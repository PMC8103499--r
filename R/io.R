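# Readers and writers for the standard interchange formats: GFF3 (1-based,
# inclusive), FASTA, VCF 4.2 (GT, INFO MQ/DP), Bismark CX-report-style TSV,
# and plain TSV tables. Writers emit fully deterministic text (no
# timestamps), so identical seeds give identical checksums.

#' Write gene models as GFF3
#'
#' One `gene` feature per gene, 1-based inclusive coordinates, with
#' `ID`, `subgenome` and `rank` attributes.
#'
#' @param genes gene-model tibble (one taxon).
#' @param path output file.
#' @export
write_gff3 <- function(genes, path) {
  attrs <- sprintf("ID=%s;rank=%d%s", genes$gene_id, genes$rank,
                   ifelse(is.na(genes$subgenome), "",
                          paste0(";subgenome=", genes$subgenome)))
  lines <- c("##gff-version 3",
             sprintf("%s\tdupevol\tgene\t%d\t%d\t.\t%s\t.\t%s",
                     genes$scaffold, genes$start, genes$end, genes$strand,
                     attrs))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Reads `gene` features (via `rtracklayer::readGFF`) into the gene-model
#' tibble used throughout the package. `subgenome` and `rank` are taken from
#' attributes when present; ranks are otherwise assigned by start position
#' per scaffold.
#'
#' @param path GFF3 file.
#' @param taxon taxon label to attach.
#' @return gene-model tibble.
#' @export
read_gff3 <- function(path, taxon) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("read_gff3() needs the rtracklayer package")
  }
  g <- as.data.frame(rtracklayer::readGFF(path))
  g <- g[g$type == "gene", , drop = FALSE]
  out <- tibble(gene_id = as.character(g$ID), taxon = taxon,
                scaffold = as.character(g$seqid),
                start = as.integer(g$start), end = as.integer(g$end),
                strand = as.character(g$strand),
                subgenome = if ("subgenome" %in% names(g))
                  as.character(g$subgenome) else NA_character_,
                rank = if ("rank" %in% names(g)) as.integer(g$rank) else
                  NA_integer_)
  if (anyNA(out$rank)) {
    out <- out |>
      group_by(.data$scaffold) |>
      arrange(.data$start, .by_group = TRUE) |>
      mutate(rank = dplyr::row_number() - 1L) |>
      ungroup()
  }
  out
}

#' Write named sequences as FASTA
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(sequences)) {
    writeLines(c(paste0(">", nm),
                 gsub("(.{70})", "\\1\n", sequences[[nm]])), con)
  }
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  id <- sub("^>", "", lines[hdr])
  id <- sub("\\s.*$", "", id)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                 collapse = "")
  setNames(unname(seqs), id)
}

#' Write one species' genotype matrices as VCF 4.2
#'
#' Emits variant rows on the annotation coordinates (CHROM = scaffold,
#' POS = gene start + within-gene offset - 1), diploid `GT` per accession
#' (consecutive haplotype pairs), and per-site `MQ`/`DP` in INFO. The header
#' carries no date line so output is byte-stable.
#'
#' @param genotypes genotype-set tibble restricted to one species.
#' @param genes gene-model tibble supplying scaffold/start per gene.
#' @param path output file.
#' @param sample_prefix accession name prefix.
#' @export
write_vcf <- function(genotypes, genes, path, sample_prefix = "acc") {
  stopifnot(length(unique(genotypes$species)) == 1)
  n_hap <- nrow(genotypes$geno[[1]])
  n_acc <- n_hap %/% 2
  samples <- sprintf("%s%02d", sample_prefix, seq_len(n_acc))
  gmeta <- genes |> select("gene_id", "scaffold", "start")
  rows <- character(0)
  gt <- genotypes |> left_join(gmeta, by = "gene_id") |>
    arrange(.data$scaffold, .data$start)
  for (i in seq_len(nrow(gt))) {
    sites <- gt$sites[[i]]
    if (nrow(sites) == 0) next
    geno <- gt$geno[[i]]
    if (!"ref" %in% names(sites)) {
      abort("write_vcf() needs a 'ref' column in the site metadata")
    }
    for (j in seq_len(nrow(sites))) {
      al <- geno[, j]
      ref <- sites$ref[j]
      alt <- setdiff(unique(al[!is.na(al)]), ref)
      if (length(alt) == 0) alt <- "."
      code <- function(a) {
        ifelse(is.na(a), ".",
               ifelse(a == ref, "0", as.character(match(a, alt))))
      }
      idx <- code(al)
      gtf <- paste(idx[seq(1, n_hap, 2)], idx[seq(2, n_hap, 2)], sep = "|")
      rows <- c(rows, sprintf(
        "%s\t%d\t.\t%s\t%s\t.\tPASS\tMQ=%s;DP=%d\tGT\t%s",
        gt$scaffold[i], gt$start[i] + sites$pos[j] - 1L, ref,
        paste(alt, collapse = ","), format(sites$MQ[j], nsmall = 1),
        sites$DP[j], paste(gtf, collapse = "\t")))
    }
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=dupevol",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a dupevol VCF back into a genotype-set tibble
#'
#' Parses a VCF 4.2 file (via the vcfR package) written by [write_vcf()],
#' mapping variants back onto gene bodies.
#'
#' @param path VCF file.
#' @param genes gene-model tibble for the coordinate frame.
#' @param species species label to attach.
#' @param gene_length full gene length in bp (pi/dxy denominator).
#' @return genotype-set tibble.
#' @export
read_vcf_genotypes <- function(path, genes, species, gene_length) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("read_vcf_genotypes() needs the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gtm <- v@gt[, -1, drop = FALSE]
  info <- fix$INFO
  mq <- as.numeric(sub(".*MQ=([0-9.]+).*", "\\1", info))
  dp <- as.integer(sub(".*DP=([0-9]+).*", "\\1", info))
  pos <- as.integer(fix$POS)
  gmeta <- genes |> select("gene_id", "scaffold", "start", "end")
  rows <- list()
  for (k in seq_len(nrow(gmeta))) {
    sel <- which(fix$CHROM == gmeta$scaffold[k] & pos >= gmeta$start[k] &
                   pos <= gmeta$end[k])
    alleles_tab <- lapply(sel, function(j) {
      alts <- strsplit(fix$ALT[j], ",", fixed = TRUE)[[1]]
      c(fix$REF[j], alts[alts != "."])
    })
    H <- 2L * ncol(gtm)
    geno <- matrix(NA_character_, H, length(sel))
    for (jj in seq_along(sel)) {
      parts <- strsplit(gtm[sel[jj], ], "|", fixed = TRUE)
      idx <- suppressWarnings(as.integer(unlist(parts)))
      geno[, jj] <- alleles_tab[[jj]][idx + 1L]
    }
    rows[[k]] <- tibble(
      gene_id = gmeta$gene_id[k], species = species,
      geno = list(geno),
      sites = list(tibble(pos = pos[sel] - gmeta$start[k] + 1L,
                          MQ = mq[sel], DP = dp[sel],
                          ref = fix$REF[sel])),
      gene_length = gene_length)
  }
  list_rbind(rows)
}

#' Write per-sample Bismark-style CX reports
#'
#' One file per sample named `<prefix><sample>.CX_report.txt` with columns
#' scaffold, 1-based position, strand, context (CG/CHG/CHH),
#' count_methylated, count_unmethylated.
#'
#' @param meth methylome object.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return character vector of files written.
#' @export
write_cx_reports <- function(meth, dir, prefix = "") {
  validate_methylome(meth)
  files <- character(0)
  for (si in seq_len(nrow(meth$samples))) {
    s <- meth$samples$sample[si]
    f <- file.path(dir, paste0(prefix, s, ".CX_report.txt"))
    readr::write_tsv(
      tibble(scaffold = meth$sites$scaffold, pos = meth$sites$pos,
             strand = meth$sites$strand, context = meth$sites$context,
             count_methylated = meth$meth[, si],
             count_unmethylated = meth$total[, si] - meth$meth[, si]),
      f, col_names = FALSE)
    files <- c(files, f)
  }
  files
}

#' Read CX reports into a methylome object
#'
#' @param files named character vector: sample name -> CX report path.
#' @param samples sample sheet tibble (`sample`, `species`, `replicate`).
#' @param genes gene-model tibble used to assign sites to gene bodies
#'   (sites outside any gene are dropped).
#' @return methylome object.
#' @export
read_cx_reports <- function(files, samples, genes) {
  stopifnot(all(samples$sample %in% names(files)))
  first <- readr::read_tsv(
    files[[samples$sample[1]]],
    col_names = c("scaffold", "pos", "strand", "context",
                  "count_methylated", "count_unmethylated"),
    col_types = "ciccii", progress = FALSE)
  sites <- first |> select("scaffold", "pos", "strand", "context")
  # assign gene bodies by interval lookup per scaffold
  sites$gene_id <- NA_character_
  for (scaf in unique(genes$scaffold)) {
    g <- genes |> filter(.data$scaffold == scaf) |> arrange(.data$start)
    sel <- which(sites$scaffold == scaf)
    if (length(sel) == 0 || nrow(g) == 0) next
    k <- findInterval(sites$pos[sel], g$start)
    ok <- k >= 1 & sites$pos[sel] <= g$end[pmax(k, 1)]
    sites$gene_id[sel[ok]] <- g$gene_id[k[ok]]
  }
  keep <- !is.na(sites$gene_id)
  sites <- sites[keep, , drop = FALSE]
  n <- sum(keep)
  meth_m <- matrix(0L, n, nrow(samples),
                   dimnames = list(NULL, samples$sample))
  tot_m <- meth_m
  for (si in seq_len(nrow(samples))) {
    s <- samples$sample[si]
    d <- if (s == samples$sample[1]) first else
      readr::read_tsv(files[[s]],
                      col_names = c("scaffold", "pos", "strand", "context",
                                    "count_methylated", "count_unmethylated"),
                      col_types = "ciccii", progress = FALSE)
    meth_m[, si] <- d$count_methylated[keep]
    tot_m[, si] <- d$count_methylated[keep] + d$count_unmethylated[keep]
  }
  out <- list(sites = as_tibble(sites) |>
                select("gene_id", "scaffold", "pos", "strand", "context"),
              samples = samples, meth = meth_m, total = tot_m)
  class(out) <- "dupevol_methylome"
  out
}
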