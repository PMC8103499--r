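test_that("orthogroup categories follow the singleton/doublet/triplet rules", {
  genes <- tibble::tibble(
    gene_id = c("d1", "d2", "a1", "b1", "a2", "a3", "b3"),
    taxon = c("diploid", "diploid", rep("tetraploid", 5)),
    scaffold = "s", start = 1L, end = 2L, strand = "+",
    subgenome = c(NA, NA, "A", "B", "A", "A", "B"),
    rank = 0:6)
  blocks <- tibble::tibble(
    block_id = c("B1", "B1", "B2", "B3"),
    gene1 = c("d1", "d1", "d2", "a3"),
    gene2 = c("a1", "b1", "a2", "b3"),
    score = 1)
  og <- classify_wgd_groups(blocks, genes)
  cat_of <- setNames(og$category, purrr::map_chr(seq_len(nrow(og)), function(i) {
    paste(na.omit(c(og$diploid_gene[i], og$gene_a[i], og$gene_b[i])),
          collapse = "+")
  }))
  # diploid collinear to copies in both subgenomes, diploid present: triplet
  expect_equal(unname(cat_of[["d1+a1+b1"]]), "triplet")
  # diploid collinear to an A copy only: singleton, surviving subgenome A
  expect_equal(unname(cat_of[["d2+a2"]]), "singleton")
  expect_equal(og$subgenome[og$diploid_gene == "d2" & !is.na(og$diploid_gene)],
               "A")
  # A-B pair with the diploid copy lost: doublet but not triplet
  expect_equal(unname(cat_of[["a3+b3"]]), "doublet")
  # a tetraploid gene without a subgenome tag is an input error
  genes_bad <- genes
  genes_bad$subgenome[3] <- NA
  expect_error(classify_wgd_groups(blocks, genes_bad), "subgenome")
})

test_that("the no-fractionation no-SSD limit yields only triplets", {
  cfg <- sim_config(seed = 5, n_ancestral_genes = 60,
                    fractionation_prob = 0, diploid_loss_prob = 0,
                    ssd_counts = c(tandem = 0, proximal = 0, transposed = 0,
                                   dispersed = 0, segmental = 0),
                    n_lineage_specific = 0)
  g <- simulate_genomes(cfg)
  expect_equal(sum(g$genes$taxon == "tetraploid"), 120L)
  expect_equal(sum(g$genes$taxon == "diploid"), 60L)
  expect_true(all(g$truth$orthogroups$category == "triplet"))
  ob <- chain_anchors(g$anchors$ortho, g$genes)
  sb <- chain_anchors(g$anchors$self, g$genes)
  og <- classify_wgd_groups(dplyr::bind_rows(ob, sb), g$genes)
  expect_equal(nrow(og), 60L)
  expect_true(all(og$category == "triplet"))
})

test_that("classifier orthogroup counts match the truth table exactly", {
  bl <- fixture_blocks()
  g <- bl$genomes
  og <- classify_wgd_groups(dplyr::bind_rows(bl$ortho, bl$self), g$genes)
  got <- orthogroup_counts(og)
  tr <- g$truth$orthogroups
  expect_equal(got$n_singleton, sum(tr$category == "singleton", na.rm = TRUE))
  expect_equal(got$n_doublet_only, sum(tr$category == "doublet", na.rm = TRUE))
  expect_equal(got$n_triplet, sum(tr$category == "triplet", na.rm = TRUE))
})

test_that("SSD mode rules follow the decision hierarchy", {
  genes <- tibble::tibble(
    gene_id = c(sprintf("t%02d", 1:15), "u01", "u02"),
    taxon = "tetraploid",
    scaffold = c(rep("A1", 15), "B1", "B1"),
    start = 1L, end = 2L, strand = "+",
    subgenome = c(rep("A", 15), "B", "B"),
    rank = c(0:14, 0:1))
  no_blocks <- chain_anchors(tibble::tibble(gene1 = character(),
                                            gene2 = character(),
                                            score = double())[0, ], genes)
  # adjacent ranks 7 and 8: tandem
  lab <- classify_ssd_modes(
    genes, tibble::tibble(gene1 = "t08", gene2 = "t09", score = 1),
    no_blocks, no_blocks)
  expect_equal(unique(lab$class), "tandem")
  # ranks 7 and 12 with threshold 10: proximal
  lab2 <- classify_ssd_modes(
    genes, tibble::tibble(gene1 = "t08", gene2 = "t13", score = 1),
    no_blocks, no_blocks, proximal_max_rank_gap = 10)
  expect_equal(unique(lab2$class), "proximal")
  # same pair with a tight threshold falls through to dispersed
  lab2b <- classify_ssd_modes(
    genes, tibble::tibble(gene1 = "t08", gene2 = "t13", score = 1),
    no_blocks, no_blocks, proximal_max_rank_gap = 3)
  expect_equal(unique(lab2b$class), "dispersed")
  # different scaffolds, no blocks, no outgroup evidence: dispersed
  lab3 <- classify_ssd_modes(
    genes, tibble::tibble(gene1 = "t01", gene2 = "u01", score = 1),
    no_blocks, no_blocks)
  expect_equal(unique(lab3$class), "dispersed")
  # one copy collinear with the outgroup, the other not: transposed, and
  # only the novel-locus copy carries the label
  ortho_blocks <- tibble::tibble(block_id = "B1", gene1 = "d1", gene2 = "t01",
                                 scaffold1 = "d", scaffold2 = "A1",
                                 rank1 = 0L, rank2 = 0L, score = 1,
                                 orientation = "same", block_score = 1,
                                 n_anchors = 5L)
  lab4 <- classify_ssd_modes(
    genes, tibble::tibble(gene1 = "t01", gene2 = "u01", score = 1),
    no_blocks, ortho_blocks)
  expect_equal(lab4$gene_id, "u01")
  expect_equal(lab4$class, "transposed")
})

test_that("planted SSD events are recovered at high accuracy", {
  bl <- fixture_blocks()
  g <- bl$genomes
  tet <- dplyr::filter(g$genes, taxon == "tetraploid")
  lab <- classify_ssd_modes(tet, g$anchors$self, bl$self, bl$ortho)
  cmp <- dplyr::inner_join(lab, g$truth$ssd_genes, by = "gene_id")
  expect_equal(nrow(cmp), nrow(g$truth$ssd_genes))
  expect_gte(mean(cmp$class == cmp$mode), 0.9)
})

test_that("families form from reciprocal best hits; focal-only flagged", {
  genes <- tibble::tibble(
    gene_id = c("p1", "p2", "g1", "x1", "x2"),
    taxon = c("tetraploid", "diploid", "grape", "tetraploid", "diploid"))
  hits <- tibble::tibble(gene1 = c("p1", "p1", "x1"),
                         gene2 = c("p2", "g1", "x2"),
                         score = c(0.9, 0.8, 0.9))
  fam <- cluster_families(genes, hits, focal_taxa = c("tetraploid", "diploid"))
  expect_equal(dplyr::n_distinct(fam$family_id), 2L)
  by_fam <- split(fam, fam$family_id)
  for (f in by_fam) {
    if ("g1" %in% f$gene_id) expect_false(any(f$lineage_specific))
    if ("x1" %in% f$gene_id) expect_true(all(f$lineage_specific))
  }
  expect_warning(
    fam0 <- cluster_families(genes, hits[0, ], c("tetraploid", "diploid")),
    "singleton")
  expect_equal(dplyr::n_distinct(fam0$family_id), 5L)
})

test_that("planted lineage-specific families are fully recovered", {
  cfg <- sim_config(seed = 19, n_ancestral_genes = 120,
                    n_lineage_specific = 50,
                    ssd_counts = c(tandem = 0, proximal = 0, transposed = 0,
                                   dispersed = 0, segmental = 0))
  g <- simulate_genomes(cfg)
  fam <- cluster_families(g$genes, g$anchors$family_hits,
                          focal_taxa = c("tetraploid", "diploid"))
  planted <- g$truth$lineage_specific
  got <- fam$gene_id[fam$lineage_specific]
  expect_true(all(planted %in% got))
  ls_fams <- unique(fam$family_id[fam$gene_id %in% planted])
  expect_equal(length(ls_fams), 50L)
  # no ancestral family is called lineage-specific
  anc_members <- fam |> dplyr::filter(!gene_id %in% planted)
  expect_false(any(anc_members$lineage_specific))
})
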