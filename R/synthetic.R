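#' Simulation configuration
#'
#' Defines the statistical structure of a synthetic fixture bundle: gene
#' layout (isolated genes and adjacent pairs in all three orientations, with
#' variable intergenic spacing), the 16-category end-binding mix, lognormal
#' binding-signal tiers, Poisson stranded coverage with gene-specific
#' read-through fractions, loop groups A-H, cofactor planting for
#' co-occupancy profiles, and category-dependent expression. The seed fully
#' determines every output.
#'
#' @param seed integer seed (default 42).
#' @param n_genes number of genes (default 500).
#' @param radius end-window half-width the truth is planted against (2500).
#' @param orientation_mix probabilities over unit types.
#' @param category_probs named/numeric length-16 distribution over categories
#'   of the default map (category 9, two-factor 5' binding, is the most
#'   common bound configuration; 16, unbound, dominates overall).
#' @param dyad_fraction fraction of head-to-tail pairs planted as dyads with
#'   a solitary intergenic site.
#' @param gene_length_range,pair_gap_range,dyad_gap_range,unit_gap_range
#'   layout ranges in bp.
#' @param signal_meanlog,signal_sdlog lognormal signal parameters, named
#'   high/low affinity tiers.
#' @param summit_jitter_sd summit jitter (bp) around the drawn offset.
#' @param dog_beta_bound,dog_beta_unbound beta shape pairs for read-through
#'   fractions of TES-bound vs unbound genes (means 0.3 and 0.1).
#' @param depth mean coverage mass per 500 bp window.
#' @param dog_window read-through window length (500 bp).
#' @param loop_group_probs distribution over contact groups A-H.
#' @param rnapii_fraction fraction of genes with RNAPII at both ends.
#' @param n_cofactors cofactors emitted for co-occupancy (class-planted).
#' @param cofactor_p_pref,cofactor_p_other planting probabilities for a
#'   cofactor at regions of its preferred / other classes.
#' @param intragenic_myc_fraction fraction of eligible genes given a
#'   mid-gene anchor-factor peak; n_distal_myc distal anchor peaks.
#' @param biotype_probs distribution over the 3-way biotype.
#' @param expr_meanlog named lognormal meanlog of TPM by 5' state.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 42L,
                       n_genes = 500L,
                       radius = 2500L,
                       orientation_mix = c(isolated = 0.34, head_to_head = 0.2,
                                           head_to_tail = 0.26,
                                           tail_to_tail = 0.2),
                       category_probs = NULL,
                       dyad_fraction = 0.3,
                       gene_length_range = c(7000L, 15000L),
                       pair_gap_range = c(800L, 4000L),
                       dyad_gap_range = c(800L, 2000L),
                       unit_gap_range = c(12000L, 20000L),
                       signal_meanlog = c(high = 3, low = 1.5),
                       signal_sdlog = 0.5,
                       summit_jitter_sd = 50,
                       dog_beta_bound = c(3, 7),
                       dog_beta_unbound = c(1.5, 13.5),
                       depth = 100,
                       dog_window = 500L,
                       loop_group_probs = c(A = 0.08, B = 0.08, C = 0.06,
                                            D = 0.08, E = 0.10, F = 0.10,
                                            G = 0.08, H = 0.42),
                       rnapii_fraction = 0.8,
                       n_cofactors = 20L,
                       cofactor_p_pref = 0.8,
                       cofactor_p_other = 0.05,
                       intragenic_myc_fraction = 0.15,
                       n_distal_myc = 40L,
                       biotype_probs = c(protein_coding = 0.7, lncRNA = 0.2,
                                         other = 0.1),
                       expr_meanlog = c(both = 4, a_only = 3, b_only = 3,
                                        none = 2)) {
  if (is.null(category_probs)) {
    category_probs <- c(0.02, 0.02, 0.004, 0.003, 0.02, 0.02, 0.03, 0.003,
                        0.18, 0.03, 0.03, 0.07, 0.03, 0.015, 0.015, 0)
    category_probs[16] <- 1 - sum(category_probs)
  }
  stopifnot(length(category_probs) == 16L,
            abs(sum(category_probs) - 1) < 1e-8,
            abs(sum(orientation_mix) - 1) < 1e-8,
            abs(sum(loop_group_probs) - 1) < 1e-8)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# offset placement rule: free ends draw anywhere in the window (minus a
# margin); the facing end of a paired gene draws on the outer side with
# magnitude >= radius - gap + margin so the site stays out of the partner's
# window and planted truth is exact.
PLACE_MARGIN <- 150L

draw_goff <- function(place, radius, jitter_sd) {
  m <- PLACE_MARGIN
  if (place$mode == "free") {
    o <- stats::runif(1, -(radius - m), radius - m)
  } else {
    lo <- max(m, radius - place$gap + m)
    o <- place$sign * stats::runif(1, lo, radius - m)
  }
  o <- o + stats::rnorm(1, 0, jitter_sd)
  # clamp back into the legal band
  if (place$mode == "free") {
    o <- max(-(radius - m), min(radius - m, o))
  } else {
    lo <- max(m, radius - place$gap + m)
    o <- place$sign * max(lo, min(radius - m, abs(o)))
  }
  as.integer(round(o))
}

#' Simulate a complete fixture bundle with recorded ground truth
#'
#' Generates an internally consistent annotation, per-factor/per-timepoint
#' narrowPeak files, per-strand bedGraph coverage, BEDPE loops, cofactor BED
#' files, an expression table, and a JSON ground-truth record sufficient to
#' score every downstream analysis exactly. Two timepoints are emitted: t0
#' (baseline) and t1 (induced); low-affinity dyad sites exist only at t1, so
#' baseline category truth reflects t0 occupancy.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created; default a tempdir subdirectory).
#' @param write write fixture files (default TRUE); the in-memory bundle is
#'   returned either way.
#' @return list of class \code{endbind_bundle}: genes (gene_models), peaks,
#'   coverage, loops, cofactors, expression, truth, files, config.
#' @export
simulate_bundle <- function(config = sim_config(), dir = NULL, write = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  r <- config$radius
  chrom <- "chrS"

  ## ---- layout -------------------------------------------------------------
  units <- character(0)
  n <- 0L
  while (n < config$n_genes) {
    u <- sample(names(config$orientation_mix), 1L,
                prob = config$orientation_mix)
    if (u != "isolated" && n + 2L > config$n_genes) u <- "isolated"
    units <- c(units, u)
    n <- n + if (u == "isolated") 1L else 2L
  }
  is_dyad_unit <- units == "head_to_tail" &
    stats::runif(length(units)) < config$dyad_fraction

  glen <- function() as.integer(round(stats::runif(1,
    config$gene_length_range[1], config$gene_length_range[2])))
  genes <- list(); place <- list(); pos <- 10000L
  unit_of <- integer(0)
  for (ui in seq_along(units)) {
    u <- units[ui]
    if (u == "isolated") {
      len <- glen()
      gid <- sprintf("G%04d", length(genes) + 1L)
      genes[[gid]] <- list(gene_id = gid, start = pos, end = pos + len - 1L,
                           strand = sample(c("+", "-"), 1L), unit = u)
      place[[gid]] <- list(TSS = list(mode = "free"),
                           TES = list(mode = "free"))
      pos <- pos + len - 1L
    } else {
      gap <- if (is_dyad_unit[ui])
        as.integer(round(stats::runif(1, config$dyad_gap_range[1],
                                      config$dyad_gap_range[2])))
      else
        as.integer(round(stats::runif(1, config$pair_gap_range[1],
                                      config$pair_gap_range[2])))
      len1 <- glen(); len2 <- glen()
      s12 <- switch(u,
        head_to_tail = { s <- sample(c("+", "-"), 1L); c(s, s) },
        head_to_head = c("-", "+"),
        tail_to_tail = c("+", "-"))
      g1 <- sprintf("G%04d", length(genes) + 1L)
      g2 <- sprintf("G%04d", length(genes) + 2L)
      start1 <- pos; end1 <- pos + len1 - 1L
      start2 <- end1 + gap; end2 <- start2 + len2 - 1L
      genes[[g1]] <- list(gene_id = g1, start = start1, end = end1,
                          strand = s12[1], unit = u)
      genes[[g2]] <- list(gene_id = g2, start = start2, end = end2,
                          strand = s12[2], unit = u)
      f1 <- facing_end(s12[1], "left"); f2 <- facing_end(s12[2], "right")
      p1 <- list(TSS = list(mode = "free"), TES = list(mode = "free"))
      p2 <- p1
      p1[[f1]] <- list(mode = "outer", sign = -1, gap = gap)
      p2[[f2]] <- list(mode = "outer", sign = +1, gap = gap)
      place[[g1]] <- p1; place[[g2]] <- p2
      pos <- end2
    }
    unit_of <- c(unit_of, rep(ui, if (u == "isolated") 1L else 2L))
    pos <- pos + as.integer(round(stats::runif(1, config$unit_gap_range[1],
                                               config$unit_gap_range[2])))
  }
  gdf <- do.call(rbind, lapply(genes, function(x)
    data.frame(gene_id = x$gene_id, start = x$start, end = x$end,
               strand = x$strand, unit = x$unit, stringsAsFactors = FALSE)))
  gdf$unit_idx <- unit_of
  gdf$biotype <- sample(names(config$biotype_probs), nrow(gdf),
                        replace = TRUE, prob = config$biotype_probs)
  distal_start <- max(gdf$end) + 30000L
  distal_end <- distal_start + 200000L
  other_zone_start <- distal_end + 50000L

  ## ---- transcripts (interior-shifted secondary anchors) -------------------
  tx <- do.call(rbind, lapply(seq_len(nrow(gdf)), function(i) {
    gr <- gdf[i, ]
    rows <- data.frame(gene_id = gr$gene_id,
                       transcript_id = paste0(gr$gene_id, ".1"),
                       chrom = chrom, start = gr$start, end = gr$end,
                       strand = gr$strand, biotype = gr$biotype,
                       stringsAsFactors = FALSE)
    if (stats::runif(1) < 0.3) {
      shift5 <- as.integer(round(stats::runif(1, 200, 800)))
      shift3 <- as.integer(round(stats::runif(1, 200, 800)))
      s2 <- gr$start + if (gr$strand == "+") shift5 else shift3
      e2 <- gr$end - if (gr$strand == "+") shift3 else shift5
      rows <- rbind(rows, data.frame(
        gene_id = gr$gene_id, transcript_id = paste0(gr$gene_id, ".2"),
        chrom = chrom, start = s2, end = e2, strand = gr$strand,
        biotype = gr$biotype, stringsAsFactors = FALSE))
    }
    rows
  }))
  gm <- build_gene_models(tx)

  ## ---- dyads and categories ----------------------------------------------
  dyad_units <- which(is_dyad_unit)
  dyads <- NULL
  dyad_gene <- character(0)
  if (length(dyad_units)) {
    dyads <- do.call(rbind, lapply(dyad_units, function(ui) {
      pair <- gdf$gene_id[gdf$unit_idx == ui]
      s <- gdf$strand[gdf$gene_id == pair[1]]
      if (s == "+") data.frame(upstream_gene = pair[1],
                               downstream_gene = pair[2])
      else data.frame(upstream_gene = pair[2], downstream_gene = pair[1])
    }))
    dyads$affinity <- sample(c("high", "low"), nrow(dyads), replace = TRUE)
    dyads$response_up <- sample(c("positive", "none", "negative"),
                                nrow(dyads), replace = TRUE)
    dyads$response_down <- sample(c("positive", "none", "negative"),
                                  nrow(dyads), replace = TRUE)
    dyad_gene <- c(dyads$upstream_gene, dyads$downstream_gene)
  }

  cmap <- default_category_map()
  cat_draw <- sample(1:16, nrow(gdf), replace = TRUE,
                     prob = config$category_probs)
  gdf$state_5p <- cmap$state_5p[cat_draw]
  gdf$state_3p <- cmap$state_3p[cat_draw]
  if (length(dyad_gene)) {
    # dyad genes: baseline binding only at the shared intergenic site
    up_hi <- dyads$upstream_gene[dyads$affinity == "high"]
    dn_hi <- dyads$downstream_gene[dyads$affinity == "high"]
    lo <- setdiff(dyad_gene, c(up_hi, dn_hi))
    gdf$state_5p[gdf$gene_id %in% dyad_gene] <- "none"
    gdf$state_3p[gdf$gene_id %in% dyad_gene] <- "none"
    gdf$state_3p[gdf$gene_id %in% up_hi] <- "a_only"
    gdf$state_5p[gdf$gene_id %in% dn_hi] <- "a_only"
  }
  gdf$category <- cmap$category[match(paste(gdf$state_5p, gdf$state_3p),
                                      paste(cmap$state_5p, cmap$state_3p))]

  ## ---- peaks --------------------------------------------------------------
  pk <- list()
  pid <- 0L
  add_peak <- function(factor, summit, signal, sample,
                       planted_class = NA_character_) {
    pid <<- pid + 1L
    half <- 150L + as.integer(round(abs(stats::rnorm(1, 0, 40))))
    pk[[length(pk) + 1L]] <<- data.frame(
      peak_id = sprintf("%s_%05d", factor, pid), factor = factor,
      chrom = chrom, start = summit - half, end = summit + half,
      summit = as.integer(summit), signal = round(signal, 4),
      sample = sample, planted_class = planted_class,
      stringsAsFactors = FALSE)
  }
  draw_signal <- function(tier)
    stats::rlnorm(1, config$signal_meanlog[[tier]], config$signal_sdlog)
  state_factors <- function(st)
    switch(st, none = character(0), a_only = "MYC", b_only = "MAX",
           both = c("MYC", "MAX"))

  primary_anchor <- function(gid, kind) {
    gr <- gdf[gdf$gene_id == gid, ]
    if ((kind == "TSS") == (gr$strand == "+")) gr$start else gr$end
  }

  for (i in seq_len(nrow(gdf))) {
    gid <- gdf$gene_id[i]
    if (gid %in% dyad_gene) next  # dyad peaks handled below
    for (kind in END_KINDS) {
      st <- if (kind == "TSS") gdf$state_5p[i] else gdf$state_3p[i]
      for (fac in state_factors(st)) {
        nsite <- sample(1:3, 1L, prob = c(0.6, 0.3, 0.1))
        for (s in seq_len(nsite)) {
          goff <- draw_goff(place[[gid]][[kind]], r, config$summit_jitter_sd)
          summit <- primary_anchor(gid, kind) + goff
          tier <- sample(c("high", "low"), 1L)
          sig <- draw_signal(tier)
          cls <- if (s == 1L && fac == "MYC") kind else NA
          add_peak(fac, summit, sig, "t0", planted_class = cls)
          add_peak(fac, summit, sig * stats::rlnorm(1, 0, 0.05), "t1")
        }
      }
    }
  }

  # shared intergenic dyad peaks (factor MYC): mid-gap, within radius of both
  # facing anchors; low-affinity sites appear only at t1
  if (length(dyad_gene)) for (j in seq_len(nrow(dyads))) {
    up <- dyads$upstream_gene[j]; dn <- dyads$downstream_gene[j]
    tes <- primary_anchor(up, "TES"); tss <- primary_anchor(dn, "TSS")
    mid <- as.integer(round((tes + tss) / 2 +
                              stats::rnorm(1, 0, config$summit_jitter_sd)))
    gap <- abs(tss - tes)
    mid <- max(min(tes, tss) + 50L, min(max(tes, tss) - 50L, mid))
    tier <- if (dyads$affinity[j] == "high") "high" else "low"
    sig <- draw_signal(tier)
    if (dyads$affinity[j] == "high") {
      add_peak("MYC", mid, sig, "t0")
      add_peak("MYC", mid, sig * 1.5, "t1")
    } else {
      add_peak("MYC", mid, sig, "t1")
    }
  }

  # RNAPII at both ends of a fraction of genes (never dyad genes, whose
  # vicinity must stay clean of any other binding)
  rnapii_genes <- character(0)
  for (i in seq_len(nrow(gdf))) {
    gid <- gdf$gene_id[i]
    if (gid %in% dyad_gene) next
    if (stats::runif(1) < config$rnapii_fraction) {
      rnapii_genes <- c(rnapii_genes, gid)
      for (kind in END_KINDS) {
        goff <- draw_goff(place[[gid]][[kind]], r, config$summit_jitter_sd)
        sig <- draw_signal("high")
        summit <- primary_anchor(gid, kind) + goff
        add_peak("POLR2A", summit, sig, "t0")
        add_peak("POLR2A", summit, sig, "t1")
      }
    }
  }

  # intragenic and distal anchor-factor peaks (never on dyad genes)
  eligible <- gdf$gene_id[!(gdf$gene_id %in% dyad_gene) &
                          (gdf$end - gdf$start + 1L) >= 8000L]
  intra_genes <- eligible[stats::runif(length(eligible)) <
                          config$intragenic_myc_fraction]
  for (gid in intra_genes) {
    gr <- gdf[gdf$gene_id == gid, ]
    centre <- as.integer(round((gr$start + gr$end) / 2 +
                                 stats::runif(1, -500, 500)))
    sig <- draw_signal(sample(c("high", "low"), 1L))
    add_peak("MYC", centre, sig, "t0", planted_class = "intragenic")
    add_peak("MYC", centre, sig, "t1")
  }
  distal_pos <- as.integer(round(seq(distal_start + 5000L,
                                     distal_end - 5000L,
                                     length.out = config$n_distal_myc))) +
    as.integer(round(stats::runif(config$n_distal_myc, -1000, 1000)))
  for (p in distal_pos) {
    sig <- draw_signal(sample(c("high", "low"), 1L))
    add_peak("MYC", p, sig, "t0", planted_class = "distal")
    add_peak("MYC", p, sig, "t1")
  }
  peaks <- do.call(rbind, pk)
  rownames(peaks) <- NULL

  ## ---- coverage (per-strand Poisson tiles + read-through tails) -----------
  gdf$dog_bound <- gdf$state_3p != "none"
  gdf$dog_fraction <- ifelse(gdf$dog_bound,
    stats::rbeta(nrow(gdf), config$dog_beta_bound[1], config$dog_beta_bound[2]),
    stats::rbeta(nrow(gdf), config$dog_beta_unbound[1],
                 config$dog_beta_unbound[2]))
  tile <- 50L
  lam_body <- config$depth * tile / config$dog_window
  cov <- list()
  for (i in seq_len(nrow(gdf))) {
    gr <- gdf[i, ]
    starts <- seq(gr$start, gr$end - tile + 1L, by = tile)
    vals <- stats::rpois(length(starts), lam_body)
    tail_len <- config$dog_window +
      min(4000L, as.integer(round(stats::rexp(1, 1 / 2000))))
    nt <- tail_len %/% tile
    if (gr$strand == "+") {
      tstarts <- seq(gr$end + 1L, by = tile, length.out = nt)
    } else {
      tstarts <- seq(gr$start - tile, by = -tile, length.out = nt)
    }
    tvals <- stats::rpois(nt, lam_body * gr$dog_fraction)
    st <- c(starts, tstarts); va <- c(vals, tvals)
    keep <- va > 0
    if (any(keep))
      cov[[length(cov) + 1L]] <- data.frame(
        chrom = chrom, start = st[keep], end = st[keep] + tile - 1L,
        value = va[keep], strand = gr$strand, stringsAsFactors = FALSE)
  }
  coverage <- do.call(rbind, cov)
  coverage <- coverage[order(coverage$strand, coverage$start), ]
  rownames(coverage) <- NULL

  ## ---- loops --------------------------------------------------------------
  gdf$loop_group <- sample(names(config$loop_group_probs), nrow(gdf),
                           replace = TRUE, prob = config$loop_group_probs)
  loops <- list(); lid <- 0L
  other_cursor <- other_zone_start
  add_loop <- function(a1, a2) {
    lid <<- lid + 1L
    if (a1 > a2) { tmp <- a1; a1 <- a2; a2 <- tmp }  # canonical anchor order
    loops[[length(loops) + 1L]] <<- data.frame(
      loop_id = sprintf("loop_%05d", lid), chrom1 = chrom,
      start1 = a1 - 200L, end1 = a1 + 200L, chrom2 = chrom,
      start2 = a2 - 200L, end2 = a2 + 200L, score = 1,
      stringsAsFactors = FALSE)
  }
  end_anchor_point <- function(gid, kind) {
    goff <- draw_goff(place[[gid]][[kind]], r, config$summit_jitter_sd)
    primary_anchor(gid, kind) + goff
  }
  for (i in seq_len(nrow(gdf))) {
    gid <- gdf$gene_id[i]
    grp <- gdf$loop_group[i]
    has_loop <- grp %in% c("A", "B", "C", "D")
    tss_other <- grp %in% c("A", "B", "E", "F")
    tes_other <- grp %in% c("A", "C", "E", "G")
    if (has_loop)
      add_loop(end_anchor_point(gid, "TSS"), end_anchor_point(gid, "TES"))
    if (tss_other) {
      other_cursor <- other_cursor + 10000L
      add_loop(end_anchor_point(gid, "TSS"), other_cursor)
    }
    if (tes_other) {
      other_cursor <- other_cursor + 10000L
      add_loop(end_anchor_point(gid, "TES"), other_cursor)
    }
  }
  loops <- do.call(rbind, loops)
  rownames(loops) <- NULL

  ## ---- cofactors for co-occupancy -----------------------------------------
  myc_regions <- peaks[peaks$factor == "MYC" & peaks$sample == "t0" &
                       !is.na(peaks$planted_class), ]
  cof_names <- sprintf("COF%02d", seq_len(config$n_cofactors))
  pref <- rep(COOC_CLASSES, length.out = config$n_cofactors)
  pref_of <- stats::setNames(pref, cof_names)
  region_cls <- myc_regions$planted_class
  region_cls[region_cls == "intragenic"] <- "intragenic_enhancer"
  region_cls[region_cls == "distal"] <- "distal_enhancer"
  cofactors <- lapply(cof_names, function(cf) {
    p <- ifelse(region_cls == pref_of[[cf]], config$cofactor_p_pref,
                config$cofactor_p_other)
    hit <- stats::runif(nrow(myc_regions)) < p
    if (!any(hit)) return(data.frame(chrom = character(), start = integer(),
                                     end = integer()))
    centre <- myc_regions$summit[hit] +
      as.integer(round(stats::rnorm(sum(hit), 0, 300)))
    data.frame(chrom = chrom, start = centre - 100L, end = centre + 100L,
               stringsAsFactors = FALSE)
  })
  names(cofactors) <- cof_names

  ## ---- expression ---------------------------------------------------------
  base_expr <- stats::rlnorm(nrow(gdf),
                             config$expr_meanlog[gdf$state_5p], 1)
  t1_factor <- exp(stats::rnorm(nrow(gdf), 0, 0.05 * log(2)))
  if (length(dyad_gene)) {
    resp_mult <- c(positive = 4, none = 1, negative = 0.25)
    for (j in seq_len(nrow(dyads))) {
      iu <- match(dyads$upstream_gene[j], gdf$gene_id)
      idn <- match(dyads$downstream_gene[j], gdf$gene_id)
      t1_factor[iu] <- resp_mult[[dyads$response_up[j]]] *
        exp(stats::rnorm(1, 0, 0.03 * log(2)))
      t1_factor[idn] <- resp_mult[[dyads$response_down[j]]] *
        exp(stats::rnorm(1, 0, 0.03 * log(2)))
    }
  }
  expression <- cbind(t0 = base_expr, t1 = base_expr * t1_factor)
  rownames(expression) <- gdf$gene_id

  ## ---- truth --------------------------------------------------------------
  truth <- list(
    genes = gdf[, c("gene_id", "strand", "unit", "biotype", "state_5p",
                    "state_3p", "category", "dog_bound", "dog_fraction",
                    "loop_group")],
    rnapii_genes = rnapii_genes,
    dyads = dyads,
    cofactor_preference = as.list(pref_of),
    myc_regions = data.frame(peak_id = myc_regions$peak_id,
                             region_class = region_cls,
                             stringsAsFactors = FALSE),
    config = list(seed = config$seed, n_genes = config$n_genes,
                  radius = config$radius, depth = config$depth,
                  dog_window = config$dog_window))

  bundle <- structure(list(
    genes = gm, gene_table = gdf, peaks = peaks, coverage = coverage,
    loops = loops, cofactors = cofactors, expression = expression,
    truth = truth, config = config, dir = dir, files = NULL),
    class = "endbind_bundle")
  if (write) bundle <- write_bundle(bundle, dir)
  bundle
}

#' @export
print.endbind_bundle <- function(x, ...) {
  cat("endbind_bundle: ", nrow(x$gene_table), " genes, ",
      nrow(x$peaks), " peak records, ", nrow(x$loops), " loops, ",
      length(x$cofactors), " cofactors\n", sep = "")
  if (!is.null(x$dir)) cat("files under: ", x$dir, "\n", sep = "")
  invisible(x)
}

## ---- writers --------------------------------------------------------------

#' Write a fixture bundle to disk
#'
#' Emits GTF annotation, narrowPeak files per (factor, timepoint), per-strand
#' bedGraph coverage, a BEDPE loop file, one BED per cofactor, the expression
#' TSV, and the ground truth as JSON. File contents depend only on the
#' simulation seed (no timestamps), so identical configurations give
#' byte-identical bundles.
#'
#' @param bundle from [simulate_bundle()].
#' @param dir output directory; created if needed.
#' @return the bundle with \code{$dir} and \code{$files} filled in.
#' @export
write_bundle <- function(bundle, dir = NULL) {
  if (is.null(dir)) dir <- file.path(tempdir(), paste0("endbind_bundle_",
                                      bundle$config$seed))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "cofactors"), showWarnings = FALSE)
  files <- list()

  # GTF: gene + transcript records, 1-based closed
  gtf <- file.path(dir, "genes.gtf")
  g <- bundle$genes$genes
  a <- bundle$genes$anchors
  lines <- c("#!genome-build endbind-sim")
  for (i in seq_len(nrow(g))) {
    gi <- g[i, ]
    lines <- c(lines, paste(gi$chrom, "endbind_sim", "gene", gi$start, gi$end,
      ".", gi$strand, ".",
      sprintf('gene_id "%s"; gene_type "%s";', gi$gene_id, gi$biotype),
      sep = "\t"))
    tss <- a$pos[a$gene_id == gi$gene_id & a$end_kind == "TSS"]
    tes <- a$pos[a$gene_id == gi$gene_id & a$end_kind == "TES"]
    k <- 0L
    for (t5 in tss) for (t3 in tes) {
      k <- k + 1L
      lines <- c(lines, paste(gi$chrom, "endbind_sim", "transcript",
        min(t5, t3), max(t5, t3), ".", gi$strand, ".",
        sprintf('gene_id "%s"; transcript_id "%s.%d"; gene_type "%s";',
                gi$gene_id, gi$gene_id, k, gi$biotype),
        sep = "\t"))
    }
  }
  writeLines(lines, gtf)
  files$annotation <- gtf

  # narrowPeak per factor/timepoint
  pk <- bundle$peaks
  for (fac in unique(pk$factor)) for (tp in unique(pk$sample)) {
    d <- pk[pk$factor == fac & pk$sample == tp, ]
    if (!nrow(d)) next
    f <- file.path(dir, sprintf("peaks_%s_%s.narrowPeak", fac, tp))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.\t%s\t-1\t-1\t%d",
                       d$chrom, d$start - 1L, d$end, d$peak_id,
                       pmin(1000L, as.integer(round(d$signal))),
                       sprintf("%.4f", d$signal),
                       d$summit - d$start), f)
    files[[paste0("peaks_", fac, "_", tp)]] <- f
  }

  # per-strand bedGraph
  for (s in c("+", "-")) {
    d <- bundle$coverage[bundle$coverage$strand == s, ]
    f <- file.path(dir, sprintf("coverage_%s.bedGraph",
                                if (s == "+") "plus" else "minus"))
    writeLines(sprintf("%s\t%d\t%d\t%g", d$chrom, d$start - 1L, d$end,
                       d$value), f)
    files[[paste0("coverage_", if (s == "+") "plus" else "minus")]] <- f
  }

  # BEDPE
  lp <- bundle$loops
  f <- file.path(dir, "loops.bedpe")
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%g",
                     lp$chrom1, lp$start1 - 1L, lp$end1,
                     lp$chrom2, lp$start2 - 1L, lp$end2,
                     lp$loop_id, lp$score), f)
  files$loops <- f

  # cofactor BEDs
  for (cf in names(bundle$cofactors)) {
    d <- bundle$cofactors[[cf]]
    f <- file.path(dir, "cofactors", paste0(cf, ".bed"))
    writeLines(if (nrow(d)) sprintf("%s\t%d\t%d", d$chrom, d$start - 1L,
                                    d$end) else character(0), f)
    files[[paste0("cofactor_", cf)]] <- f
  }

  # expression TSV
  f <- file.path(dir, "expression.tsv")
  ex <- data.frame(gene_id = rownames(bundle$expression),
                   bundle$expression, check.names = FALSE)
  utils::write.table(format(ex, digits = 8, trim = TRUE), f, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files$expression <- f

  # ground truth JSON
  f <- file.path(dir, "truth.json")
  jsonlite::write_json(bundle$truth, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files$truth <- f

  bundle$dir <- dir
  bundle$files <- files
  bundle
}

#' Perturb a bundle (site loss, signal decay, noise loops)
#'
#' Supports retention-kinetics and robustness tests: drops a random fraction
#' of peak records, scales all remaining signals, and/or appends random
#' decoy loops. Deterministic given \code{seed}. The returned bundle carries a
#' \code{truth$perturbation} record (dropped peak ids, decay factor, added
#' loop ids).
#'
#' @param bundle from [simulate_bundle()].
#' @param drop_peaks fraction of peak records to drop, in [0, 1].
#' @param signal_decay multiplicative factor on remaining signals.
#' @param add_noise_loops number of random loops to append.
#' @param seed seed for the perturbation draws.
#' @return a new \code{endbind_bundle} (not written to disk).
#' @export
perturb_bundle <- function(bundle, drop_peaks = 0, signal_decay = 1,
                           add_noise_loops = 0L, seed = 1L) {
  if (drop_peaks < 0 || drop_peaks > 1)
    stop("drop_peaks must be in [0, 1]")
  set.seed(seed)
  out <- bundle
  pk <- bundle$peaks
  dropped <- character(0)
  if (drop_peaks > 0) {
    drop <- stats::runif(nrow(pk)) < drop_peaks
    dropped <- pk$peak_id[drop]
    pk <- pk[!drop, , drop = FALSE]
  }
  pk$signal <- pk$signal * signal_decay
  out$peaks <- pk
  added <- character(0)
  if (add_noise_loops > 0) {
    span <- range(bundle$gene_table$start, bundle$gene_table$end)
    a1 <- as.integer(round(stats::runif(add_noise_loops, span[1], span[2])))
    a2 <- as.integer(round(stats::runif(add_noise_loops, span[1], span[2])))
    added <- sprintf("noise_%04d", seq_len(add_noise_loops))
    out$loops <- rbind(bundle$loops, data.frame(
      loop_id = added, chrom1 = "chrS", start1 = a1 - 200L, end1 = a1 + 200L,
      chrom2 = "chrS", start2 = a2 - 200L, end2 = a2 + 200L, score = 1,
      stringsAsFactors = FALSE))
  }
  out$truth$perturbation <- list(dropped_peaks = dropped,
                                 signal_decay = signal_decay,
                                 added_loops = added)
  out$dir <- NULL; out$files <- NULL
  out
}
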