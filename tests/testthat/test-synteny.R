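toy_anchors <- function(r1, r2, score = 1) {
  tibble::tibble(gene1 = sprintf("a%02d", r1 + 1), gene2 = sprintf("b%02d", r2 + 1),
                 score = score)
}

test_that("a perfect diagonal chains into one same-orientation block", {
  genes <- toy_genes()
  blocks <- chain_anchors(toy_anchors(0:4, 0:4), genes, min_block_anchors = 5)
  expect_equal(dplyr::n_distinct(blocks$block_id), 1L)
  expect_equal(nrow(blocks), 5L)
  expect_equal(unique(blocks$orientation), "same")
})

test_that("an off-diagonal anchor beyond the gap limit is excluded", {
  genes <- dplyr::bind_rows(toy_genes(),
                            tibble::tibble(gene_id = "b41", taxon = "tx2",
                                           scaffold = "s2", start = 41000L,
                                           end = 41500L, strand = "+",
                                           subgenome = NA, rank = 40L))
  anchors <- dplyr::bind_rows(
    toy_anchors(0:4, 0:4),
    tibble::tibble(gene1 = "a03", gene2 = "b41", score = 1))
  blocks <- chain_anchors(anchors, genes, min_block_anchors = 5,
                          max_gene_gap = 5)
  expect_equal(nrow(blocks), 5L)
  expect_false("b41" %in% blocks$gene2)
  # the chained score equals the exhaustive optimum over all monotone chains
  a2 <- anchors |>
    dplyr::mutate(rank1 = c(0:4, 2L), rank2 = c(0:4, 40L))
  expect_equal(unique(blocks$block_score),
               oracle_best_chain_score(a2, 5, 0.01))
})

test_that("an anti-diagonal chains as one inverted block", {
  genes <- toy_genes()
  blocks <- chain_anchors(toy_anchors(0:4, 4:0), genes, min_block_anchors = 5)
  expect_equal(dplyr::n_distinct(blocks$block_id), 1L)
  expect_equal(unique(blocks$orientation), "inverted")
})

test_that("anchors referencing unknown genes fail loudly, naming the gene", {
  genes <- toy_genes()
  bad <- tibble::tibble(gene1 = "a01", gene2 = "ghost", score = 1)
  expect_error(chain_anchors(bad, genes), "ghost")
  expect_error(chain_anchors(tibble::tibble(gene1 = "a01", gene2 = "a01",
                                            score = 1), genes), "distinct")
})

test_that("DP chain score equals exhaustive search on random instances", {
  set.seed(41)
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    genes <- toy_genes(30, 30)
    a <- tibble::tibble(r1 = sample(0:29, n, replace = FALSE),
                        r2 = sample(0:29, n, replace = FALSE),
                        score = round(runif(n, 0.5, 1), 3))
    anchors <- tibble::tibble(gene1 = sprintf("a%02d", a$r1 + 1),
                              gene2 = sprintf("b%02d", a$r2 + 1),
                              score = a$score)
    gap <- sample(c(5, 10, 25), 1)
    blocks <- chain_anchors(anchors, genes, min_block_anchors = 1,
                            max_gene_gap = gap, gap_penalty = 0.01)
    best_dp <- max(blocks$block_score)
    want <- oracle_best_chain_score(
      a |> dplyr::rename(rank1 = r1, rank2 = r2), gap, 0.01)
    expect_equal(best_dp, want, tolerance = 1e-9)
  }
})

test_that("block monotonicity and single-assignment invariants hold", {
  bl <- fixture_blocks()
  for (blocks in list(bl$ortho, bl$self, bl$eudicot)) {
    per <- split(blocks, blocks$block_id)
    for (b in per) {
      o <- order(b$rank1)
      expect_true(all(diff(b$rank1[o]) > 0))
      d2 <- diff(b$rank2[o])
      expect_true(all(d2 > 0) || all(d2 < 0))
    }
    # each anchor in at most one block
    expect_false(any(duplicated(paste(blocks$gene1, blocks$gene2))))
  }
})

test_that("collinear depth applies the strict more-than-four rule", {
  genes <- toy_genes(3, 3)
  mk <- function(n_blocks, gene) {
    purrr::map(seq_len(n_blocks), function(i) {
      tibble::tibble(block_id = sprintf("%s_B%02d", gene, i), gene1 = gene,
                     gene2 = sprintf("b%02d", i %% 3 + 1))
    }) |> purrr::list_rbind()
  }
  blocks <- dplyr::bind_rows(mk(5, "a01"), mk(4, "a02"))
  d <- collinear_depth(blocks, genes |> dplyr::filter(taxon == "tx1"))
  expect_equal(d$depth[d$gene_id == "a01"], 5L)
  expect_true(d$ancient_collinear[d$gene_id == "a01"])
  expect_equal(d$depth[d$gene_id == "a02"], 4L)
  expect_false(d$ancient_collinear[d$gene_id == "a02"])
  expect_true(d$conserved_eudicot[d$gene_id == "a02"])
  expect_equal(d$depth[d$gene_id == "a03"], 0L)
  expect_false(d$conserved_eudicot[d$gene_id == "a03"])
})

test_that("chaining is deterministic and order-invariant", {
  g <- fixture_genomes()
  a <- g$anchors$ortho
  b1 <- chain_anchors(a, g$genes)
  b2 <- chain_anchors(a[sample(nrow(a)), ], g$genes)
  expect_equal(b1, b2 |> dplyr::arrange(block_id, rank1))
})
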