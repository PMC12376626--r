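two_gene_tt <- function() {
  # tail-to-tail pair, TES anchors 1 kb apart
  genes_from_tx(data.frame(
    gene_id = c("L", "R"), transcript_id = c("L.1", "R.1"), chrom = "chr1",
    start = c(1000L, 11000L), end = c(10000L, 20000L), strand = c("+", "-")))
}

test_that("summit at an anchor assigns with offset zero", {
  gm <- two_gene_tt()
  a <- assign_peaks(make_peaks("chr1", 10000L), gm)
  row <- a[a$gene_id == "L" & a$end_kind == "TES", ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$offset, 0L)
})

test_that("a summit midway between facing TES anchors assigns to both genes", {
  gm <- two_gene_tt()
  a <- assign_peaks(make_peaks("chr1", 10500L), gm)
  tes <- a[a$end_kind == "TES", ]
  expect_setequal(tes$gene_id, c("L", "R"))
  expect_equal(tes$offset[tes$gene_id == "L"], 500L)   # downstream of L
  expect_equal(tes$offset[tes$gene_id == "R"], 500L)   # downstream of R too
})

test_that("head-to-tail shared peaks are flagged ambiguous on both rows, others not", {
  # L(+) then R(+): L TES faces R TSS across a 1 kb gap
  gm <- genes_from_tx(data.frame(
    gene_id = c("L", "R"), transcript_id = c("L.1", "R.1"), chrom = "chr1",
    start = c(1000L, 11000L), end = c(10000L, 20000L), strand = "+"))
  rel <- pair_relations(gm)
  a <- flag_ambiguous(assign_peaks(make_peaks("chr1", 10500L), gm), rel)
  shared <- a[a$gene_id == "L" & a$end_kind == "TES" |
              a$gene_id == "R" & a$end_kind == "TSS", ]
  expect_equal(nrow(shared), 2L)
  expect_true(all(shared$ambiguous))

  # tail-to-tail shared peak: both TES, not ambiguous
  gmtt <- two_gene_tt()
  att <- flag_ambiguous(assign_peaks(make_peaks("chr1", 10500L), gmtt),
                        pair_relations(gmtt))
  expect_false(any(att$ambiguous))

  # isolated gene: never ambiguous
  gi <- genes_from_tx(data.frame(gene_id = "I", transcript_id = "I.1",
    chrom = "chr1", start = 1000L, end = 10000L, strand = "+"))
  ai <- flag_ambiguous(assign_peaks(make_peaks("chr1", 10200L), gi),
                       pair_relations(gi))
  expect_false(any(ai$ambiguous))
})

test_that("flagging never removes assignments, only marks them", {
  gm <- genes_from_tx(data.frame(
    gene_id = c("L", "R"), transcript_id = c("L.1", "R.1"), chrom = "chr1",
    start = c(1000L, 11000L), end = c(10000L, 20000L), strand = "+"))
  set.seed(5)
  pk <- make_peaks("chr1", sample(500:21000, 80))
  a0 <- assign_peaks(pk, gm)
  a1 <- flag_ambiguous(a0, pair_relations(gm))
  expect_equal(nrow(a1), nrow(a0))
  expect_equal(a1[, setdiff(names(a1), "ambiguous")],
               a0[, setdiff(names(a0), "ambiguous")])
})

test_that("assignment is monotone in radius and matches the exhaustive oracle", {
  gm <- random_genes(60L, seed = 3L)
  set.seed(4)
  span <- range(gm$genes$start, gm$genes$end)
  pk <- make_peaks("chrT", sort(sample(span[1]:span[2], 400)))
  key <- function(a) paste(a$peak_id, a$gene_id, a$end_kind)
  a1 <- assign_peaks(pk, gm, radius = 1000L)
  a2 <- assign_peaks(pk, gm, radius = 2500L)
  expect_true(all(key(a1) %in% key(a2)))

  want <- oracle_assign(pk, gm, radius = 2500L)
  cols <- c("peak_id", "gene_id", "end_kind", "anchor", "offset")
  got <- a2[, cols]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want[, cols])
})

test_that("site counts preserve multiplicity while classification ignores it", {
  gm <- genes_from_tx(data.frame(gene_id = "g", transcript_id = "g.1",
    chrom = "chr1", start = 5000L, end = 15000L, strand = "+"))
  pk <- make_peaks("chr1", c(4500L, 5100L, 5900L))
  a <- assign_peaks(pk, gm)
  sc <- site_counts(a)
  expect_equal(sc$n_sites[sc$end_kind == "TSS"], 3L)
  calls <- classify_end_binding(a, gm)
  expect_equal(calls$state_5p, "a_only")
  # empty end
  expect_false("TES" %in% sc$end_kind)
  # random tally oracle
  gm2 <- random_genes(30L, seed = 9L)
  set.seed(10)
  pk2 <- make_peaks("chrT", sample(min(gm2$genes$start):max(gm2$genes$end), 200))
  a2 <- assign_peaks(pk2, gm2)
  sc2 <- site_counts(a2)
  for (i in sample(nrow(sc2), min(10, nrow(sc2)))) {
    n_brute <- length(unique(a2$peak_id[a2$gene_id == sc2$gene_id[i] &
                                        a2$end_kind == sc2$end_kind[i]]))
    expect_equal(sc2$n_sites[i], n_brute)
  }
})

test_that("narrowPeak reading converts coordinates and summit offsets", {
  path <- tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t999\t1300\tp1\t100\t.\t7.5\t-1\t-1\t50",
               "chr1\t1999\t2300\tp2\t100\t.\t3.25\t-1\t-1\t-1"), path)
  pk <- read_narrowpeak(path, factor = "MYC", sample = "s")
  expect_equal(pk$start, c(1000L, 2000L))
  expect_equal(pk$end, c(1300L, 2300L))
  expect_equal(pk$summit[1], 1050L)           # start + offset
  expect_equal(pk$summit[2], 2150L)           # -1 -> interval midpoint
  expect_equal(pk$signal, c(7.5, 3.25))
  expect_error(assign_peaks(pk, random_genes(5L), radius = 0), "radius")
})
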