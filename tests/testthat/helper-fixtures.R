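# Shared simulation fixtures, built once per test run and memoised (the
# generator is deterministic, so caching changes nothing but the runtime).

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- build()
  fixture_env[[name]]
}

fixture_genomes <- function() {
  fixture("genomes", function() simulate_genomes(sim_config(seed = 101)))
}

fixture_blocks <- function() {
  fixture("blocks", function() {
    g <- fixture_genomes()
    list(genomes = g,
         ortho = chain_anchors(g$anchors$ortho, g$genes),
         self = chain_anchors(g$anchors$self, g$genes),
         eudicot = chain_anchors(g$anchors$eudicot, g$genes))
  })
}

# small gene set laid out on one or two scaffolds for hand-built anchor tests
toy_genes <- function(n1 = 10, n2 = 10, taxon1 = "tx1", taxon2 = "tx2") {
  dplyr::bind_rows(
    tibble::tibble(gene_id = sprintf("a%02d", seq_len(n1)), taxon = taxon1,
                   scaffold = "s1", start = seq_len(n1) * 1000L,
                   end = seq_len(n1) * 1000L + 500L, strand = "+",
                   subgenome = NA_character_, rank = seq_len(n1) - 1L),
    tibble::tibble(gene_id = sprintf("b%02d", seq_len(n2)), taxon = taxon2,
                   scaffold = "s2", start = seq_len(n2) * 1000L,
                   end = seq_len(n2) * 1000L + 500L, strand = "+",
                   subgenome = NA_character_, rank = seq_len(n2) - 1L))
}

random_codon_seq <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  sense <- setdiff(codons, stops)
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

random_geno_matrix <- function(n_hap, n_sites, missing_frac = 0) {
  m <- matrix(sample(c("A", "C", "G", "T"), n_hap * n_sites, replace = TRUE),
              nrow = n_hap)
  if (missing_frac > 0) {
    m[sample(length(m), round(missing_frac * length(m)))] <- NA
  }
  m
}
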