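test_that("region classes are disjoint, exhaustive and match the position-rule oracle", {
  b <- shared_bundle()
  pk <- b$peaks[b$peaks$sample == "t0", ]
  strat <- stratify_signal(pk, b$genes)
  cls <- strat$peaks$region_class
  expect_false(any(is.na(cls)))          # all peaks on annotated chromosome
  expect_equal(sort(unique(cls)),
               sort(c("TSS", "TES", "intragenic", "distal")))
  expect_equal(cls, oracle_region_class(pk, b$genes, 2500L))
  # summaries carry n per class and sum to the peak count
  expect_equal(sum(strat$summary$n), nrow(pk))
})

test_that("peaks deep inside a long gene are intragenic; empty classes report n = 0", {
  gm <- genes_from_tx(data.frame(gene_id = "g", transcript_id = "g.1",
    chrom = "chr1", start = 10000L, end = 30000L, strand = "+"))
  strat <- stratify_signal(make_peaks("chr1", 13000L), gm)
  expect_equal(strat$peaks$region_class, "intragenic")
  st <- stratify_signal(make_peaks("chr1", 10000L), gm)$summary
  expect_equal(st$n[st$region_class == "TSS"], 1L)
  expect_equal(st$n[st$region_class == "TES"], 0L)
  expect_true(is.na(st$mean[st$region_class == "TES"]))
})

test_that("distance strata follow the gene-oriented offset sign", {
  gm <- genes_from_tx(data.frame(gene_id = "g", transcript_id = "g.1",
    chrom = "chr1", start = 10000L, end = 30000L, strand = "+"))
  pk <- make_peaks("chr1", c(9200L, 10000L, 10950L), signal = c(5, 7, 9))
  a <- assign_peaks(pk, gm)
  st <- distance_strata(a)
  get <- function(s) st[st$end_kind == "TSS" & st$stratum == s, ]
  expect_equal(get("upstream")$n, 1L)       # offset -800
  expect_equal(get("upstream")$mean, 5)
  expect_equal(get("overlapping")$n, 1L)    # offset 0
  expect_equal(get("downstream")$n, 1L)     # offset +950
  # planted separation detectable: strata with different planted means
  set.seed(2)
  up <- make_peaks("chr1", 10000L - sample(200:2400, 40),
                   signal = rlnorm(40, 3, 0.3),
                   peak_id = sprintf("u%03d", 1:40))
  dn <- make_peaks("chr1", 10000L + sample(200:2400, 40),
                   signal = rlnorm(40, 1.5, 0.3),
                   peak_id = sprintf("d%03d", 1:40))
  a2 <- assign_peaks(rbind(up, dn), gm)
  stratum <- ifelse(a2$offset < 0, "up", "down")
  tt <- t.test(a2$signal[stratum == "up"], a2$signal[stratum == "down"])
  expect_lt(tt$p.value, 0.01)
})

test_that("retention is (1,1) at baseline and tracks site loss exactly", {
  gm <- random_genes(40L, seed = 21L)
  set.seed(22)
  anch <- gm$anchors
  idx <- sample(nrow(anch), 30)
  pk <- make_peaks("chrT", anch$pos[idx] + sample(-300:300, 30, replace = TRUE),
                   signal = rlnorm(30, 2, 0.5))
  a0 <- assign_peaks(pk, gm)
  ident <- retention_kinetics(list(t0 = a0, t1 = a0))
  expect_true(all(ident$frac_bound == 1))
  expect_true(all(ident$rel_signal == 1))
  # drop half of the baseline *sites* deterministically
  sites <- unique(paste(a0$gene_id, a0$end_kind, a0$anchor))
  keep_sites <- sites[seq_along(sites) %% 2 == 0]
  a1 <- a0[paste(a0$gene_id, a0$end_kind, a0$anchor) %in% keep_sites, ]
  ret <- retention_kinetics(list(t0 = a0, t1 = a1))
  r1 <- ret[ret$timepoint == "t1", ]
  overall <- sum(r1$frac_bound * r1$n_baseline) / sum(r1$n_baseline)
  expect_equal(overall, length(keep_sites) / length(sites), tolerance = 1e-9)
  expect_error(retention_kinetics(list(a0, a1)), "baseline")
})

test_that("frac_bound is non-increasing under removal-only perturbation", {
  b <- shared_bundle()
  pk0 <- b$peaks[b$peaks$sample == "t0", ]
  a0 <- assign_peaks(pk0, b$genes)
  set.seed(3)
  pk1 <- pk0[runif(nrow(pk0)) > 0.3, ]
  pk2 <- pk1[runif(nrow(pk1)) > 0.3, ]
  ret <- retention_kinetics(list(t0 = a0,
                                 t1 = assign_peaks(pk1, b$genes),
                                 t2 = assign_peaks(pk2, b$genes)))
  wide <- reshape(ret, idvar = c("factor", "end_kind", "tier"),
                  timevar = "timepoint", direction = "wide")
  expect_true(all(wide$frac_bound.t1 >= wide$frac_bound.t2, na.rm = TRUE))
})
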