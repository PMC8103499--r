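# Duplicate-gene taxonomy: WGD orthogroups (singleton/doublet/triplet), the
# five SSD modes (segmental, tandem, proximal, transposed, dispersed) and
# lineage-specific gene families.

#' Build WGD orthogroups and classify them singleton / doublet / triplet
#'
#' Connects genes through block-assigned anchors (diploid-vs-tetraploid
#' blocks plus tetraploid self blocks joining the two subgenome copies) and
#' resolves each connected component into an orthologous group with at most
#' one diploid gene and one copy per subgenome (ties broken by total anchor
#' score, then gene id). Categories are mutually exclusive:
#' * `singleton` - exactly one subgenome copy retained (diploid ortholog
#'   present as evidence);
#' * `doublet`  - copies retained in both subgenomes, diploid copy lost;
#' * `triplet`  - copies in both subgenomes and the diploid ortholog
#'   retained.
#' Summary counts that include triplets inside doublets (the
#' doublet-inclusive convention) are available via [orthogroup_counts()].
#'
#' @param blocks anchor-level block tibble ([chain_anchors()]); pass the
#'   union (`dplyr::bind_rows()`) of diploid-tetraploid blocks and tetraploid
#'   self blocks.
#' @param genes gene-model tibble with `gene_id`, `taxon`, `subgenome`.
#' @param diploid_taxon,tetraploid_taxon taxon labels in `genes`.
#' @return tibble: `group_id`, `diploid_gene`, `gene_a`, `gene_b`,
#'   `category`, `subgenome` (of the surviving copy for singletons, else NA).
#' @export
classify_wgd_groups <- function(blocks, genes, diploid_taxon = "diploid",
                                tetraploid_taxon = "tetraploid") {
  gmeta <- genes |> select("gene_id", "taxon", "subgenome")
  tet_in_blocks <- unique(c(blocks$gene1, blocks$gene2))
  tet_meta <- gmeta |> filter(.data$gene_id %in% tet_in_blocks,
                              .data$taxon == tetraploid_taxon)
  if (any(is.na(tet_meta$subgenome) | !tet_meta$subgenome %in% c("A", "B"))) {
    bad <- tet_meta$gene_id[is.na(tet_meta$subgenome) |
                              !tet_meta$subgenome %in% c("A", "B")]
    abort(paste0("tetraploid gene(s) without subgenome tag: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  edges <- blocks |>
    select("gene1", "gene2", "score") |>
    group_by(.data$gene1, .data$gene2) |>
    summarise(score = sum(.data$score), .groups = "drop")
  if (nrow(edges) == 0) {
    return(tibble(group_id = character(), diploid_gene = character(),
                  gene_a = character(), gene_b = character(),
                  category = character(), subgenome = character()))
  }
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
  comp <- igraph::components(g)$membership
  members <- tibble(gene_id = names(comp), comp = unname(comp)) |>
    left_join(gmeta, by = "gene_id") |>
    left_join(
      bind_rows(edges |> select(gene_id = "gene1", "score"),
                edges |> select(gene_id = "gene2", "score")) |>
        group_by(.data$gene_id) |>
        summarise(total_score = sum(.data$score), .groups = "drop"),
      by = "gene_id")
  slot_of <- function(taxon, subg) {
    dplyr::case_when(taxon == diploid_taxon ~ "diploid",
                     subg == "A" ~ "A", subg == "B" ~ "B",
                     TRUE ~ NA_character_)
  }
  members <- members |>
    mutate(slot = slot_of(.data$taxon, .data$subgenome)) |>
    filter(!is.na(.data$slot)) |>
    group_by(.data$comp, .data$slot) |>
    arrange(desc(.data$total_score), .data$gene_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  wide <- members |>
    select("comp", "slot", "gene_id") |>
    pivot_wider(names_from = "slot", values_from = "gene_id")
  for (col in c("diploid", "A", "B")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_character_
  }
  grp <- wide |>
    mutate(category = dplyr::case_when(
      !is.na(.data$A) & !is.na(.data$B) & !is.na(.data$diploid) ~ "triplet",
      !is.na(.data$A) & !is.na(.data$B) ~ "doublet",
      xor(!is.na(.data$A), !is.na(.data$B)) & !is.na(.data$diploid) ~ "singleton",
      TRUE ~ NA_character_),
      subgenome = dplyr::if_else(
        .data$category == "singleton",
        dplyr::if_else(!is.na(.data$A), "A", "B"), NA_character_)) |>
    filter(!is.na(.data$category))
  grp <- grp |>
    arrange(coalesce(.data$diploid, .data$A, .data$B)) |>
    mutate(group_id = sprintf("OG%05d", dplyr::row_number())) |>
    select("group_id", diploid_gene = "diploid", gene_a = "A",
           gene_b = "B", "category", "subgenome")
  grp
}

#' Orthogroup category counts (exclusive and doublet-inclusive)
#'
#' @param orthogroups output of [classify_wgd_groups()].
#' @return one-row tibble: `n_groups`, `n_singleton`, `n_doublet_only`,
#'   `n_triplet`, `n_doublet_incl` (doublet + triplet).
#' @export
orthogroup_counts <- function(orthogroups) {
  tibble(
    n_groups = nrow(orthogroups),
    n_singleton = sum(orthogroups$category == "singleton"),
    n_doublet_only = sum(orthogroups$category == "doublet"),
    n_triplet = sum(orthogroups$category == "triplet"),
    n_doublet_incl = sum(orthogroups$category %in% c("doublet", "triplet")))
}

#' Classify small-scale duplicates into the five SSD modes
#'
#' Applies the decision hierarchy over duplicate pairs drawn from the
#' tetraploid self-anchor table:
#' 1. pairs inside an intra-genome collinear block: inter-subgenome blocks
#'    are WGD homoeologs (`wgd`, excluded from SSD), same-subgenome blocks
#'    are `segmental`;
#' 2. `tandem` - same scaffold, rank gap exactly 1;
#' 3. `proximal` - same scaffold, rank gap in (1, `proximal_max_rank_gap`\];
#' 4. `transposed` - exactly one copy lies in a collinear block against the
#'    outgroup (the ancestral locus); the novel-locus copy gets the label;
#' 5. `dispersed` - remaining duplicate pairs.
#' A gene participating in several pairs receives its single
#' highest-priority label (segmental > tandem > proximal > transposed >
#' dispersed).
#'
#' @param genes gene-model tibble for the tetraploid (gene_id, scaffold,
#'   rank, subgenome).
#' @param self_anchors tetraploid self homolog pairs (`gene1`, `gene2`,
#'   `score`).
#' @param self_blocks blocks chained from `self_anchors`.
#' @param ortho_blocks blocks against the diploid outgroup.
#' @param proximal_max_rank_gap proximal threshold (default 10).
#' @return tibble: `gene_id`, `class`, `partner` (evidence partner of the
#'   deciding pair), `pair_mode` table attached as attribute "pairs".
#' @export
classify_ssd_modes <- function(genes, self_anchors, self_blocks,
                               ortho_blocks, proximal_max_rank_gap = 10) {
  if (nrow(self_anchors) == 0) {
    out <- tibble(gene_id = character(), class = character(),
                  partner = character())
    attr(out, "pairs") <- tibble()
    return(out)
  }
  gi <- genes |> select("gene_id", "scaffold", "rank", "subgenome")
  pairs <- self_anchors |>
    mutate(g1 = pmin(.data$gene1, .data$gene2),
           g2 = pmax(.data$gene1, .data$gene2)) |>
    distinct(.data$g1, .data$g2) |>
    inner_join(rename(gi, g1 = "gene_id", scaf1 = "scaffold",
                      rank1 = "rank", sub1 = "subgenome"), by = "g1") |>
    inner_join(rename(gi, g2 = "gene_id", scaf2 = "scaffold",
                      rank2 = "rank", sub2 = "subgenome"), by = "g2")
  # same-scaffold blocks lying along the self-comparison diagonal (every
  # anchor within the proximal rank window) are strings of local duplicates,
  # not segmental duplications; drop them from the block evidence
  diag_blocks <- self_blocks |>
    group_by(.data$block_id) |>
    summarise(trivial = first(.data$scaffold1) == first(.data$scaffold2) &&
                all(abs(.data$rank1 - .data$rank2) <= proximal_max_rank_gap),
              .groups = "drop") |>
    filter(.data$trivial)
  in_block <- self_blocks |>
    filter(!.data$block_id %in% diag_blocks$block_id) |>
    mutate(g1 = pmin(.data$gene1, .data$gene2),
           g2 = pmax(.data$gene1, .data$gene2)) |>
    distinct(.data$g1, .data$g2) |>
    mutate(in_self_block = TRUE)
  outgroup_genes <- unique(c(ortho_blocks$gene1, ortho_blocks$gene2))
  pairs <- pairs |>
    left_join(in_block, by = c("g1", "g2")) |>
    mutate(in_self_block = coalesce(.data$in_self_block, FALSE),
           coll1 = .data$g1 %in% outgroup_genes,
           coll2 = .data$g2 %in% outgroup_genes,
           gap = dplyr::if_else(.data$scaf1 == .data$scaf2,
                                abs(.data$rank1 - .data$rank2), NA_integer_),
           mode = dplyr::case_when(
             in_self_block & sub1 != sub2 ~ "wgd",
             in_self_block ~ "segmental",
             !is.na(gap) & gap == 1 ~ "tandem",
             !is.na(gap) & gap > 1 & gap <= proximal_max_rank_gap ~ "proximal",
             xor(coll1, coll2) ~ "transposed",
             TRUE ~ "dispersed"))
  prio <- c(segmental = 1, tandem = 2, proximal = 3, transposed = 4,
            dispersed = 5)
  # gene-level candidates: both genes of a pair except for transposed pairs,
  # where only the non-collinear (novel locus) copy is the transposed gene
  cand <- bind_rows(
    pairs |> filter(.data$mode != "wgd",
                    !(.data$mode == "transposed" & .data$coll1)) |>
      select(gene_id = "g1", partner = "g2", "mode"),
    pairs |> filter(.data$mode != "wgd",
                    !(.data$mode == "transposed" & .data$coll2)) |>
      select(gene_id = "g2", partner = "g1", "mode"))
  labels <- cand |>
    mutate(p = prio[.data$mode]) |>
    group_by(.data$gene_id) |>
    arrange(.data$p, .data$partner, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("gene_id", class = "mode", "partner") |>
    arrange(.data$gene_id)
  attr(labels, "pairs") <- pairs |>
    select("g1", "g2", "mode", "in_self_block", "gap", "coll1", "coll2")
  labels
}

#' Cluster genes into families and flag lineage-specific families
#'
#' Builds the reciprocal best-scoring hit graph (per gene and target taxon,
#' the best-scoring hit; an edge where best hits are mutual) and takes its
#' connected components as gene families. Families whose members all come
#' from the focal taxa are lineage-specific.
#'
#' @param genes gene-model tibble covering all taxa (gene_id, taxon).
#' @param hits cross-taxa similarity table (`gene1`, `gene2`, `score`).
#' @param focal_taxa taxa defining lineage specificity (e.g. the tetraploid
#'   and its diploid relative).
#' @return tibble: `gene_id`, `taxon`, `family_id`, `lineage_specific`.
#' @export
cluster_families <- function(genes, hits, focal_taxa) {
  gmeta <- genes |> select("gene_id", "taxon")
  if (nrow(hits) == 0) {
    warn("empty hit table: every gene becomes a singleton family")
    fam <- gmeta |>
      arrange(.data$gene_id) |>
      mutate(family_id = sprintf("F%05d", dplyr::row_number()),
             lineage_specific = .data$taxon %in% focal_taxa)
    return(fam)
  }
  h <- bind_rows(hits |> select(from = "gene1", to = "gene2", "score"),
                 hits |> select(from = "gene2", to = "gene1", "score")) |>
    distinct() |>
    left_join(rename(gmeta, to = "gene_id", taxon_to = "taxon"), by = "to")
  best <- h |>
    group_by(.data$from, .data$taxon_to) |>
    arrange(desc(.data$score), .data$to, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("from", "to")
  rbh <- best |>
    inner_join(rename(best, to = "from", from = "to"), by = c("from", "to")) |>
    mutate(g1 = pmin(.data$from, .data$to), g2 = pmax(.data$from, .data$to)) |>
    distinct(.data$g1, .data$g2)
  g <- igraph::graph_from_data_frame(
    rbh, directed = FALSE,
    vertices = sort(unique(gmeta$gene_id)))
  comp <- igraph::components(g)$membership
  fam <- tibble(gene_id = names(comp), comp = unname(comp)) |>
    left_join(gmeta, by = "gene_id")
  ids <- fam |>
    group_by(.data$comp) |>
    summarise(first_gene = min(.data$gene_id),
              lineage_specific = all(.data$taxon %in% focal_taxa),
              .groups = "drop") |>
    arrange(.data$first_gene) |>
    mutate(family_id = sprintf("F%05d", dplyr::row_number()))
  fam |>
    left_join(ids |> select("comp", "family_id", "lineage_specific"),
              by = "comp") |>
    select("gene_id", "taxon", "family_id", "lineage_specific") |>
    arrange(.data$family_id, .data$gene_id)
}
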