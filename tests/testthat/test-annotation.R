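test_that("TSS/TES anchors follow strand and multi-transcript ends accumulate", {
  tx <- data.frame(
    gene_id = c("gp", "gm", "g2", "g2"),
    transcript_id = c("gp.1", "gm.1", "g2.1", "g2.2"),
    chrom = "chr1",
    start = c(1000L, 1000L, 20000L, 20000L),
    end = c(5000L, 5000L, 25000L, 25400L),
    strand = c("+", "-", "+", "+"))
  gm <- genes_from_tx(tx)
  anch <- function(g, k) sort(gm$anchors$pos[gm$anchors$gene_id == g &
                                             gm$anchors$end_kind == k])
  expect_equal(anch("gp", "TSS"), 1000L)
  expect_equal(anch("gp", "TES"), 5000L)
  expect_equal(anch("gm", "TSS"), 5000L)
  expect_equal(anch("gm", "TES"), 1000L)
  expect_equal(anch("g2", "TES"), c(25000L, 25400L))
  expect_equal(anch("g2", "TSS"), 20000L)
})

test_that("near-identical anchors are merged toward the outermost position", {
  tx <- data.frame(gene_id = "g", transcript_id = c("g.1", "g.2"),
                   chrom = "chr1", start = c(1000L, 1006L),
                   end = c(9000L, 9008L), strand = "+")
  gm <- genes_from_tx(tx)
  expect_equal(gm$anchors$pos[gm$anchors$end_kind == "TSS"], 1000L)
  expect_equal(gm$anchors$pos[gm$anchors$end_kind == "TES"], 9008L)
  # and the same ends 11 bp apart stay distinct
  tx$start[2] <- 1011L
  gm2 <- genes_from_tx(tx)
  expect_equal(sort(gm2$anchors$pos[gm2$anchors$end_kind == "TSS"]),
               c(1000L, 1011L))
})

test_that("malformed or strandless records are rejected informatively", {
  path <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tt\ttranscript\t100\t900\t.\t+\t.\tgene_id "a"; transcript_id "a.1";',
    'chr1\tt\ttranscript\t5000\t4000\t.\t+\t.\tgene_id "b"; transcript_id "b.1";'),
    path)
  expect_error(load_annotation(path), "line 2")
  writeLines(c(
    'chr1\tt\ttranscript\t100\t900\t.\t+\t.\tgene_id "a"; transcript_id "a.1";',
    'chr1\tt\ttranscript\t4000\t5000\t.\t.\t.\tgene_id "b"; transcript_id "b.1";'),
    path)
  expect_warning(gm <- load_annotation(path), "strand")
  expect_equal(gm$genes$gene_id, "a")
})

test_that("pairwise orientations follow strand geometry", {
  tx <- data.frame(
    gene_id = c("a", "b", "c", "d", "e", "f"),
    transcript_id = paste0(c("a", "b", "c", "d", "e", "f"), ".1"),
    chrom = "chr1",
    start = c(1000L, 12000L, 60000L, 71000L, 120000L, 131000L),
    end = c(9000L, 20000L, 68000L, 79000L, 128000L, 139000L),
    strand = c("+", "+", "-", "+", "+", "-"))
  rel <- pair_relations(genes_from_tx(tx), max_gap = 5000L)
  orient <- function(a, b) rel$orientation[rel$gene_a == a & rel$gene_b == b]
  expect_equal(orient("a", "b"), "head_to_tail")
  expect_equal(orient("c", "d"), "head_to_head")
  expect_equal(orient("e", "f"), "tail_to_tail")
  # head-to-tail roles name the TES- and TSS-contributing genes
  ht <- rel[rel$orientation == "head_to_tail", ]
  expect_equal(ht$tes_gene, "a")
  expect_equal(ht$tss_gene, "b")
  # gap beyond max_gap suppresses the b-c relation
  expect_false(any(rel$gene_a == "b"))
})

test_that("pair_relations matches the brute-force all-pairs oracle", {
  for (seed in c(11L, 23L)) {
    gm <- random_genes(100L, seed = seed)
    got <- pair_relations(gm, max_gap = 5000L)
    want <- oracle_relations(gm, max_gap = 5000L)
    cols <- c("gene_a", "gene_b", "orientation", "end_gap")
    got <- got[order(got$gene_a), cols]
    want <- want[order(want$gene_a), cols]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("anchor derivation mirrors under strand flip plus reflection", {
  tx <- data.frame(gene_id = "g", transcript_id = c("g.1", "g.2"),
                   chrom = "chr1", start = c(2000L, 2500L),
                   end = c(9000L, 8400L), strand = "+")
  gm <- genes_from_tx(tx)
  M <- 100000L
  txm <- tx
  txm$start <- M - tx$end; txm$end <- M - tx$start; txm$strand <- "-"
  gmm <- genes_from_tx(txm)
  for (k in c("TSS", "TES")) {
    a <- sort(gm$anchors$pos[gm$anchors$end_kind == k])
    b <- sort(M - gmm$anchors$pos[gmm$anchors$end_kind == k])
    expect_equal(a, b)
  }
})
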