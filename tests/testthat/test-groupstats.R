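test_that("test statistics match hand-computed closed forms on toy inputs", {
  expr <- c(a1 = 3, a2 = 7, a3 = 15, b1 = 1, b2 = 3, b3 = 7)
  grp <- setNames(c("A", "A", "A", "B", "B", "B"), names(expr))
  res <- compare_expression(expr, grp, test = "t_unpaired")
  # Welch t on log2(x + 1): hand closed form
  x <- log2(expr[1:3] + 1); y <- log2(expr[4:6] + 1)
  tstat <- (mean(x) - mean(y)) / sqrt(var(x) / 3 + var(y) / 3)
  expect_equal(res$statistic, tstat)
  expect_equal(res$n_a, 3L)
  # Wilcoxon rank-sum W: ranks of A among pooled values
  resw <- compare_expression(expr, grp, test = "wilcoxon_ranksum")
  pooled <- rank(c(x, y))
  W <- sum(pooled[1:3]) - 3 * 4 / 2
  expect_equal(resw$statistic, W)
})

test_that("a group compared with its own duplicate sits at the null center", {
  set.seed(8)
  expr <- c(rlnorm(50, 3, 1), rlnorm(50, 3, 1))
  names(expr) <- sprintf("g%03d", 1:100)
  expr[51:100] <- expr[1:50]
  grp <- setNames(rep(c("A", "Adup"), each = 50), names(expr))
  res <- compare_expression(expr, grp, test = "wilcoxon_ranksum")
  expect_gt(res$p_value, 0.99)
})

test_that("type-I error is controlled and planted shifts are detected", {
  set.seed(9)
  # null: identical lognormal groups, n = 200 each
  rej <- vapply(1:300, function(i) {
    expr <- rlnorm(400, 3, 1)
    names(expr) <- sprintf("g%03d", 1:400)
    grp <- setNames(rep(c("A", "B"), each = 200), names(expr))
    compare_expression(expr, grp)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03 - 0.015)
  expect_lte(mean(rej), 0.07 + 0.015)
  # power: 2x mean shift, n = 100
  pow <- vapply(1:100, function(i) {
    expr <- c(rlnorm(100, 3 + log(2), 1), rlnorm(100, 3, 1))
    names(expr) <- sprintf("g%03d", 1:200)
    grp <- setNames(rep(c("hi", "lo"), each = 100), names(expr))
    compare_expression(expr, grp)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(pow), 0.9)
})

test_that("FDR adjustment accompanies every comparison and skips tiny groups", {
  set.seed(10)
  expr <- rlnorm(90, 3, 1)
  names(expr) <- sprintf("g%03d", 1:90)
  grp <- setNames(c(rep("A", 40), rep("B", 40), rep("C", 9), "tiny"),
                  names(expr))
  expect_message(res <- compare_expression(expr, grp), "tiny")
  expect_equal(nrow(res), 3L)
  expect_true(all(res$fdr >= res$p_value - 1e-12))
})

test_that("biotype fractions and their comparisons behave at the boundaries", {
  gm <- genes_from_tx(data.frame(
    gene_id = sprintf("g%02d", 1:6), transcript_id = sprintf("g%02d.1", 1:6),
    chrom = "chr1", start = seq(10000L, 510000L, by = 100000L),
    end = seq(18000L, 518000L, by = 100000L), strand = "+",
    biotype = rep(c("protein_coding", "lncRNA"), 3)))
  # all genes bound at both ends
  anch <- gm$anchors
  pk <- make_peaks("chr1", anch$pos, peak_id = sprintf("p%02d", seq_len(nrow(anch))))
  calls <- classify_end_binding(assign_peaks(pk, gm), gm)
  bb <- biotype_binding_fractions(calls, gm)
  fr <- bb$fractions
  expect_equal(fr$frac_tss_bound[fr$biotype %in% c("protein_coding", "lncRNA")],
               c(1, 1))
  expect_equal(fr$frac_tes_bound[fr$biotype %in% c("protein_coding", "lncRNA")],
               c(1, 1))
  pc_ln <- bb$tests[bb$tests$biotype_a == "protein_coding" &
                    bb$tests$biotype_b == "lncRNA", ]
  expect_equal(pc_ln$p_value, c(1, 1))
  expect_equal(unique(pc_ln$method), "fisher_exact")  # zero unbound cells
})

test_that("a planted lncRNA TES-binding enrichment is detected at n = 1000", {
  set.seed(11)
  n <- 1000L
  bt <- sample(c("protein_coding", "lncRNA"), n, replace = TRUE,
               prob = c(0.7, 0.3))
  p_tes <- ifelse(bt == "lncRNA", 0.4, 0.2)
  calls <- data.frame(gene_id = sprintf("g%04d", 1:n), state_5p = "none",
                      state_3p = ifelse(runif(n) < p_tes, "a_only", "none"),
                      category = NA_integer_, stringsAsFactors = FALSE)
  genes <- list(genes = data.frame(gene_id = calls$gene_id, biotype = bt,
                                   stringsAsFactors = FALSE))
  class(genes) <- "gene_models"
  bb <- biotype_binding_fractions(calls, genes)
  hit <- bb$tests[bb$tests$biotype_a == "protein_coding" &
                  bb$tests$biotype_b == "lncRNA" & bb$tests$side == "TES", ]
  expect_lt(hit$p_value, 0.001)
  fr <- bb$fractions
  expect_gt(fr$frac_tes_bound[fr$biotype == "lncRNA"],
            fr$frac_tes_bound[fr$biotype == "protein_coding"])
})
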