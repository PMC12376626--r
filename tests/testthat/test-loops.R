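loops_df <- function(a1, a2, chrom1 = "chr1", chrom2 = chrom1, half = 200L) {
  data.frame(loop_id = sprintf("lp%03d", seq_along(a1)),
             chrom1 = chrom1, start1 = a1 - half, end1 = a1 + half,
             chrom2 = chrom2, start2 = a2 - half, end2 = a2 + half,
             score = 1, stringsAsFactors = FALSE)
}

test_that("anchor midpoints assign to gene ends and define the contact flags", {
  gm <- genes_from_tx(data.frame(gene_id = "g", transcript_id = "g.1",
    chrom = "chr1", start = 10000L, end = 30000L, strand = "+"))
  # TSS-TES loop, a TSS-to-distal loop, and a self-loop inside one window
  lp <- loops_df(c(10100L, 10200L, 9900L), c(29950L, 60000L, 10400L))
  le <- assign_loop_ends(lp, gm)
  pr <- contact_profiles(le, gm)
  expect_true(pr$tss_tes_loop)
  expect_true(pr$tss_other)
  expect_false(pr$tes_other)   # the self-loop must not count
  expect_equal(pr$group, "B")
})

test_that("groups D and H arise from a lone loop and from no loops", {
  gm <- genes_from_tx(data.frame(gene_id = c("g", "h"),
    transcript_id = c("g.1", "h.1"), chrom = "chr1",
    start = c(10000L, 100000L), end = c(30000L, 120000L), strand = "+"))
  lp <- loops_df(10100L, 29900L)
  pr <- contact_profiles(assign_loop_ends(lp, gm), gm)
  expect_equal(pr$group[pr$gene_id == "g"], "D")
  expect_equal(pr$group[pr$gene_id == "h"], "H")
})

test_that("inter-chromosomal loops are excluded with a message", {
  gm <- genes_from_tx(data.frame(gene_id = "g", transcript_id = "g.1",
    chrom = "chr1", start = 10000L, end = 30000L, strand = "+"))
  lp <- loops_df(10100L, 50000L, chrom2 = "chr2")
  expect_message(le <- assign_loop_ends(lp, gm), "inter-chromosomal")
  expect_equal(nrow(le), 0L)
})

test_that("loop-end assignment matches the brute-force anchor scan", {
  gm <- random_genes(40L, seed = 61L)
  set.seed(62)
  span <- range(gm$genes$start, gm$genes$end)
  mids1 <- sample(span[1]:span[2], 120)
  mids2 <- sample(span[1]:span[2], 120)
  lp <- loops_df(mids1, mids2, chrom1 = "chrT")
  le <- assign_loop_ends(lp, gm)
  anch <- gm$anchors
  for (k in 1:2) {
    mids <- if (k == 1) mids1 else mids2
    want <- list()
    for (i in seq_along(mids)) for (j in seq_len(nrow(anch))) {
      if (abs(mids[i] - anch$pos[j]) <= 2500L)
        want[[length(want) + 1L]] <- paste(lp$loop_id[i], k,
                                           anch$gene_id[j], anch$end_kind[j])
    }
    got <- paste(le$loop_id, le$anchor_idx, le$gene_id,
                 le$end_kind)[le$anchor_idx == k]
    expect_setequal(got, unique(unlist(want)))
  }
})

test_that("planted loop groups are recovered and extra loops never demote", {
  b <- shared_bundle()
  le <- assign_loop_ends(b$loops, b$genes)
  pr <- contact_profiles(le, b$genes)
  tr <- b$truth$genes
  m <- merge(pr, tr, by = "gene_id")
  expect_equal(m$group, m$loop_group)
  # every gene gets exactly one group
  expect_setequal(pr$gene_id, b$genes$genes$gene_id)
  expect_true(all(pr$group %in% LETTERS[1:8]))
  # adding loops is monotone: no gene moves from A-D to E-H
  pb <- perturb_bundle(b, add_noise_loops = 60L, seed = 9L)
  pr2 <- contact_profiles(assign_loop_ends(pb$loops, b$genes), b$genes)
  had_loop <- pr$gene_id[pr$group %in% LETTERS[1:4]]
  expect_true(all(pr2$group[pr2$gene_id %in% had_loop] %in% LETTERS[1:4]))
})

test_that("category-by-group matrix marginals equal the independent summaries", {
  b <- shared_bundle()
  a <- assign_peaks(b$peaks[b$peaks$sample == "t0", ], b$genes)
  calls <- classify_end_binding(a, b$genes)
  le <- assign_loop_ends(b$loops, b$genes)
  pr <- contact_profiles(le, b$genes)
  expr <- setNames(b$expression[, "t0"], rownames(b$expression))
  mat <- category_group_matrix(calls, pr, expression = expr, loop_ends = le)
  expect_equal(sum(mat$counts), nrow(calls))
  expect_equal(as.integer(rowSums(mat$counts)), category_summary(calls)$n)
  expect_equal(as.integer(colSums(mat$counts)),
               as.integer(table(factor(pr$group, levels = LETTERS[1:8]))))
  lf <- mat$looping_frequency
  expect_true(all(lf$frac_genes_looping >= 0 & lf$frac_genes_looping <= 1,
                  na.rm = TRUE))
  # mean expression suppressed for thin cells
  thin <- mat$counts < 5L
  expect_true(all(is.na(mat$mean_expression[thin])))
})

test_that("the RNAPII gate keeps double-bound genes and splits the TES states", {
  b <- shared_bundle()
  pk0 <- b$peaks[b$peaks$sample == "t0", ]
  a <- assign_peaks(pk0, b$genes)
  gate <- rnapii_gate(b$genes, a[a$factor == "POLR2A", ],
                      a[a$factor != "POLR2A", ])
  expect_setequal(gate$gene_id, b$truth$rnapii_genes)
  tr <- b$truth$genes
  m <- merge(gate, tr, by = "gene_id")
  want <- ifelse(m$state_3p == "both", "both",
          ifelse(m$state_3p == "a_only", "a_only",
          ifelse(m$state_3p == "b_only", "b_only", "neither")))
  expect_equal(m$tes_group, want)
})
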