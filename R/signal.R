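summ_stats <- function(x) {
  n <- length(x)
  data.frame(n = n,
             mean = if (n) mean(x) else NA_real_,
             se = if (n > 1L) stats::sd(x) / sqrt(n) else NA_real_)
}

REGION_CLASSES <- c("TSS", "TES", "intragenic", "distal")

# Region class per peak summit: end windows take precedence (TSS over TES),
# then intragenic (inside a gene span, > radius downstream of all its TSS
# anchors and > radius upstream of all its TES anchors), then distal (outside
# all gene spans and all end windows). Off-annotation chromosomes -> NA.
region_class <- function(peaks, genes, radius = 2500L) {
  anch <- genes$anchors
  g <- genes$genes
  cls <- rep(NA_character_, nrow(peaks))
  on_chrom <- peaks$chrom %in% unique(g$chrom)
  if (!any(on_chrom)) return(cls)
  idx <- which(on_chrom)
  pt <- GenomicRanges::GRanges(peaks$chrom[idx],
          IRanges::IRanges(peaks$summit[idx], peaks$summit[idx]))
  for (kind in c("TSS", "TES")) {
    ak <- anch[anch$end_kind == kind, ]
    win <- GenomicRanges::GRanges(ak$chrom,
             IRanges::IRanges(ak$pos - radius, ak$pos + radius))
    hit <- idx[unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(pt, win)))]
    cls[hit[is.na(cls[hit])]] <- kind
  }
  todo <- idx[is.na(cls[idx])]
  if (length(todo)) {
    spans <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end))
    pt2 <- GenomicRanges::GRanges(peaks$chrom[todo],
             IRanges::IRanges(peaks$summit[todo], peaks$summit[todo]))
    inside <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(pt2, spans)))
    cls[todo[inside]] <- "intragenic"
    cls[todo[-inside]] <- if (length(inside)) "distal" else NA
    if (!length(inside)) cls[todo] <- "distal"
  }
  cls
}

#' Binding-signal summaries by region class
#'
#' Every peak falls into exactly one of four disjoint classes: TSS window,
#' TES window, intragenic (inside a gene but beyond both end windows), or
#' distal (outside all gene spans and end windows). Peaks on chromosomes
#' absent from the annotation are unclassified and excluded. Summaries report
#' the mean signal, its standard error, and n per (region_class, factor).
#'
#' When `assignments` is supplied (typically after [flag_ambiguous()]), peaks
#' whose every end assignment is flagged ambiguous are excluded from the TSS
#' and TES classes.
#'
#' @param peaks data.frame of peaks.
#' @param genes gene_models object.
#' @param radius end-window half-width (default 2500 bp).
#' @param assignments optional assignment table used for the ambiguity filter.
#' @return list with `$peaks` (input plus region_class column) and `$summary`
#'   (region_class, factor, n, mean, se).
#' @export
stratify_signal <- function(peaks, genes, radius = 2500L, assignments = NULL) {
  cls <- region_class(peaks, genes, radius)
  if (!is.null(assignments) && nrow(assignments)) {
    amb <- tapply(assignments$ambiguous,
                  paste(assignments$peak_id, assignments$sample), all)
    key <- paste(peaks$peak_id, peaks$sample)
    drop <- key %in% names(amb)[amb]
    cls[drop & cls %in% c("TSS", "TES")] <- NA
  }
  pk <- cbind(peaks, region_class = cls)
  grid <- expand.grid(region_class = REGION_CLASSES,
                      factor = unique(peaks$factor),
                      stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    x <- pk$signal[!is.na(cls) & cls == grid$region_class[i] &
                   pk$factor == grid$factor[i]]
    cbind(grid[i, ], summ_stats(x))
  }))
  rownames(summ) <- NULL
  list(peaks = pk, summary = summ)
}

#' Signal summaries by distance stratum around gene ends
#'
#' Assignments are stratified by the sign of their gene-oriented offset:
#' upstream (offset < -overlap_halfwidth), overlapping
#' (|offset| <= overlap_halfwidth), or downstream. Summaries are per
#' (end_kind, stratum, factor).
#'
#' @param assignments data.frame from [assign_peaks()].
#' @param overlap_halfwidth half-width of the anchor-overlapping stratum
#'   (default 100 bp).
#' @return data.frame end_kind, stratum, factor, n, mean, se.
#' @export
distance_strata <- function(assignments, overlap_halfwidth = 100L) {
  a <- assignments
  stratum <- ifelse(abs(a$offset) <= overlap_halfwidth, "overlapping",
                    ifelse(a$offset < 0, "upstream", "downstream"))
  grid <- expand.grid(end_kind = END_KINDS,
                      stratum = c("upstream", "overlapping", "downstream"),
                      factor = unique(a$factor),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    x <- a$signal[a$end_kind == grid$end_kind[i] &
                  stratum == grid$stratum[i] & a$factor == grid$factor[i]]
    cbind(grid[i, ], summ_stats(x))
  }))
  rownames(out) <- NULL
  out
}

#' Binding-site retention kinetics across a time course
#'
#' Sites are matched across timepoints by their (gene, end, anchor) key --
#' summit jitter between timepoints would break peak-interval identity, and
#' retention tracks sites, not peak calls. For each later timepoint,
#' `frac_bound` is the fraction of baseline sites that still carry any called
#' peak (presence/absence), and `rel_signal` is the mean signal at the
#' retained sites divided by the mean baseline signal at those same sites.
#' Baseline sites are split into high/low affinity tiers at a signal quantile
#' (default the median) within each (factor, end_kind).
#'
#' @param timecourse named list of assignment tables, one per timepoint, in
#'   temporal order; the first element (or `baseline`) is the reference.
#' @param baseline name of the baseline timepoint.
#' @param tier_quantile baseline-signal quantile splitting high from low
#'   affinity (default 0.5).
#' @return data.frame factor, end_kind, tier, timepoint, n_baseline,
#'   frac_bound, rel_signal. Baseline rows have frac_bound = rel_signal = 1.
#' @export
retention_kinetics <- function(timecourse, baseline = names(timecourse)[1],
                               tier_quantile = 0.5) {
  if (is.null(names(timecourse)) || !nzchar(baseline) ||
      !baseline %in% names(timecourse))
    stop("a named baseline timepoint is required")
  base <- timecourse[[baseline]]
  if (nrow(base) == 0L) stop("baseline has no assignments")
  base$site <- paste(base$gene_id, base$end_kind, base$anchor)
  # one signal per site: strongest peak at the site
  bsite <- do.call(rbind, lapply(split(base, paste(base$factor, base$site)),
    function(d) d[which.max(d$signal), ]))
  out <- list()
  for (fac in unique(bsite$factor)) for (kind in END_KINDS) {
    b <- bsite[bsite$factor == fac & bsite$end_kind == kind, ]
    if (nrow(b) == 0L) next
    cut <- stats::quantile(b$signal, tier_quantile)
    b$tier <- ifelse(b$signal > cut, "high", "low")
    for (tier in c("high", "low")) {
      bt <- b[b$tier == tier, ]
      if (nrow(bt) == 0L) next
      for (tp in names(timecourse)) {
        cur <- timecourse[[tp]]
        cur <- cur[cur$factor == fac & cur$end_kind == kind, , drop = FALSE]
        cur_site <- paste(cur$gene_id, cur$end_kind, cur$anchor)
        retained <- bt$site %in% cur_site
        rel <- if (any(retained)) {
          cur_sig <- vapply(bt$site[retained], function(s)
            max(cur$signal[cur_site == s]), numeric(1))
          mean(cur_sig) / mean(bt$signal[retained])
        } else NA_real_
        out[[length(out) + 1L]] <- data.frame(
          factor = fac, end_kind = kind, tier = tier, timepoint = tp,
          n_baseline = nrow(bt),
          frac_bound = mean(retained),
          rel_signal = rel,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
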