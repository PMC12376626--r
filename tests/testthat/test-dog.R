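single_gene <- function(strand = "+") {
  genes_from_tx(data.frame(gene_id = "g", transcript_id = "g.1",
    chrom = "chr1", start = 10000L, end = 20000L, strand = strand))
}

flat_cov <- function(from, to, value, strand = "+", tile = 50L) {
  st <- seq(from, to - tile + 1L, by = tile)
  data.frame(chrom = "chr1", start = st, end = st + tile - 1L,
             value = value, strand = strand, stringsAsFactors = FALSE)
}

test_that("flat coverage gives fraction 0 without and 1 with read-through", {
  gm <- single_gene()
  cov0 <- flat_cov(10000L, 20000L, 10)
  rec0 <- count_dog_windows(cov0, gm)
  expect_equal(rec0$fraction, 0)
  expect_equal(rec0$upstream_count, 100)
  cov1 <- rbind(cov0, flat_cov(20001L, 23000L, 10))
  expect_equal(count_dog_windows(cov1, gm)$fraction, 1)
})

test_that("fractions are invariant to depth scaling and to mirrored strand flip", {
  gm <- random_genes(30L, seed = 31L)
  set.seed(32)
  frac <- runif(30, 0.05, 0.6)
  cov <- sim_coverage(gm, frac)
  rec <- count_dog_windows(cov, gm)
  cov10 <- cov; cov10$value <- cov10$value * 10
  expect_equal(count_dog_windows(cov10, gm)$fraction, rec$fraction)
  # reflect everything about a point and flip strands
  M <- 10000000L
  g <- gm$genes
  txm <- data.frame(gene_id = g$gene_id, transcript_id = paste0(g$gene_id, ".1"),
                    chrom = g$chrom, start = M - g$end, end = M - g$start,
                    strand = ifelse(g$strand == "+", "-", "+"))
  gmm <- genes_from_tx(txm)
  covm <- data.frame(chrom = cov$chrom, start = M - cov$end,
                     end = M - cov$start, value = cov$value,
                     strand = ifelse(cov$strand == "+", "-", "+"))
  recm <- count_dog_windows(covm, gmm)
  expect_equal(recm$fraction[match(rec$gene_id, recm$gene_id)], rec$fraction)
})

test_that("the estimator is unbiased at planted fractions under Poisson coverage", {
  gm <- random_genes(200L, seed = 41L)
  set.seed(42)
  frac <- rep(0.2, 200)
  rec <- count_dog_windows(sim_coverage(gm, frac), gm)
  expect_lt(abs(mean(rec$fraction, na.rm = TRUE) - 0.2) / 0.2, 0.1)
})

test_that("low-expression and neighbour-masked genes are flagged undefined", {
  gm <- single_gene()
  rec <- count_dog_windows(flat_cov(10000L, 20000L, 0.05), gm)
  expect_equal(rec$flag, "low_expression")
  expect_true(is.na(rec$fraction))
  # same-strand gene right past the TES masks the downstream window
  gm2 <- genes_from_tx(data.frame(gene_id = c("g", "n"),
    transcript_id = c("g.1", "n.1"), chrom = "chr1",
    start = c(10000L, 20300L), end = c(20000L, 28000L), strand = "+"))
  rec2 <- count_dog_windows(flat_cov(10000L, 20000L, 10), gm2)
  expect_equal(rec2$flag[rec2$gene_id == "g"], "masked")
  expect_true(is.na(rec2$fraction[rec2$gene_id == "g"]))
  # an opposite-strand neighbour does not mask
  gm3 <- genes_from_tx(data.frame(gene_id = c("g", "n"),
    transcript_id = c("g.1", "n.1"), chrom = "chr1",
    start = c(10000L, 20300L), end = c(20000L, 28000L), strand = c("+", "-")))
  rec3 <- count_dog_windows(flat_cov(10000L, 20000L, 10), gm3)
  expect_equal(rec3$flag[rec3$gene_id == "g"], "")
  expect_error(count_dog_windows(within(flat_cov(1, 100, 1),
                                        rm(strand)), gm),
               "strand")
})

test_that("group comparison requires two populated groups and detects shifts", {
  rec <- data.frame(gene_id = sprintf("g%03d", 1:200),
                    fraction = c(rbeta(100, 3, 7), rbeta(100, 1.5, 13.5)))
  grp <- setNames(rep(c("TES_bound", "TES_unbound"), each = 100), rec$gene_id)
  res <- compare_dog_groups(rec, grp)
  expect_lt(res$p_value, 0.01)
  expect_match(res$direction, "TES_bound > TES_unbound")
  one <- rec[c(1, 101), ]
  expect_error(compare_dog_groups(one, grp), ">= 2 genes")
})

test_that("condition deltas are zero for identical conditions and track planted shifts", {
  gm <- random_genes(100L, seed = 51L)
  set.seed(52)
  frac <- runif(100, 0.1, 0.3)
  cov <- sim_coverage(gm, frac)
  rec <- count_dog_windows(cov, gm)
  d0 <- dog_condition_delta(list(ctrl = rec, same = rec))
  expect_true(all(d0$log2_ratio == 0, na.rm = TRUE))
  # plant a 2x read-through increase for half the genes
  cov2 <- sim_coverage(gm, pmin(1, frac * c(rep(2, 50), rep(1, 50))))
  rec2 <- count_dog_windows(cov2, gm)
  d <- dog_condition_delta(list(ctrl = rec, heat = rec2))
  up <- d$log2_ratio[d$gene_id %in% gm$genes$gene_id[1:50]]
  expect_equal(median(up, na.rm = TRUE), 1, tolerance = 0.35)
  flat <- d$log2_ratio[d$gene_id %in% gm$genes$gene_id[51:100]]
  expect_lt(abs(median(flat, na.rm = TRUE)), 0.3)
  expect_error(dog_condition_delta(list(rec, rec2)), "baseline")
})
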