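COOC_CLASSES <- c("TSS", "TES", "intragenic_enhancer", "distal_enhancer")

#' Build region sets anchored on bound positions
#'
#' Each peak of the anchor factor (canonically MYC) defines one region of
#' \code{summit +/- halfwidth}, classified by position into four disjoint
#' sets: TSS window, TES window, intragenic enhancer (inside a gene, beyond
#' both end windows) or distal enhancer (outside all gene spans and end
#' windows), with precedence TSS > TES > intragenic > distal. When an
#' enhancer annotation (cCRE-style intervals) is supplied, enhancer-class
#' regions must overlap one of its intervals; without it the position rules
#' alone define the classes.
#'
#' @param anchor_peaks data.frame of peaks of the anchor factor.
#' @param genes gene_models object.
#' @param halfwidth region half-width in bp; 2500 by default, 500 is the
#'   narrow preset that minimizes inclusion of enhancer sequence around ends.
#' @param enhancers optional data.frame chrom, start, end of enhancer
#'   intervals.
#' @param radius end-window half-width used for classification (default 2500).
#' @return data.frame region_id, region_class, chrom, center, start, end.
#' @export
build_region_sets <- function(anchor_peaks, genes, halfwidth = 2500L,
                              enhancers = NULL, radius = 2500L) {
  cls <- region_class(anchor_peaks, genes, radius)
  cls[cls == "intragenic"] <- "intragenic_enhancer"
  cls[cls == "distal"] <- "distal_enhancer"
  keep <- !is.na(cls)
  pk <- anchor_peaks[keep, , drop = FALSE]; cls <- cls[keep]
  if (!is.null(enhancers)) {
    enh_cls <- cls %in% c("intragenic_enhancer", "distal_enhancer")
    eg <- GenomicRanges::GRanges(enhancers$chrom,
            IRanges::IRanges(enhancers$start, enhancers$end))
    pt <- GenomicRanges::GRanges(pk$chrom,
            IRanges::IRanges(pk$summit, pk$summit))
    hit <- rep(FALSE, nrow(pk))
    ov <- GenomicRanges::findOverlaps(pt, eg)
    hit[unique(S4Vectors::queryHits(ov))] <- TRUE
    drop <- enh_cls & !hit
    pk <- pk[!drop, , drop = FALSE]; cls <- cls[!drop]
  }
  data.frame(region_id = paste0("region_", seq_len(nrow(pk))),
             region_class = cls,
             chrom = pk$chrom,
             center = pk$summit,
             start = pk$summit - as.integer(halfwidth),
             end = pk$summit + as.integer(halfwidth),
             stringsAsFactors = FALSE)
}

#' Co-occupancy z-score matrix over region classes
#'
#' For every factor and every signed-distance bin within each region class,
#' computes the percentage of the class's regions whose bin interval is
#' overlapped by at least one peak of the factor, then z-scores each factor's
#' row across all bins of all classes. Rows with zero variance (a factor
#' present everywhere or nowhere) are returned as zeros and flagged.
#'
#' @param region_sets data.frame from [build_region_sets()].
#' @param factor_peaks named list: factor -> peak data.frame (chrom, start,
#'   end columns suffice).
#' @param bin_width bin size in bp (default 250; 20 bins across +/- 2.5 kb).
#' @return matrix (factors x class:bin) of z-scores, with attributes
#'   "percent" (the raw percentage matrix) and "flagged_factors"
#'   (zero-variance rows).
#' @export
occupancy_zscores <- function(region_sets, factor_peaks, bin_width = 250L) {
  halfwidth <- region_sets$end[1] - region_sets$center[1]
  nbin <- as.integer(2 * halfwidth / bin_width)
  if (nbin < 2L) stop("need >= 2 bins per class; reduce bin_width")
  edges <- seq(-halfwidth, halfwidth, by = bin_width)
  classes <- intersect(COOC_CLASSES, unique(region_sets$region_class))
  cols <- as.vector(t(outer(classes, seq_len(nbin),
                            function(cl, b) paste0(cl, ":bin", b))))
  pct <- matrix(NA_real_, length(factor_peaks), length(cols),
                dimnames = list(names(factor_peaks), cols))
  for (fac in names(factor_peaks)) {
    fp <- factor_peaks[[fac]]
    fg <- GenomicRanges::GRanges(fp$chrom, IRanges::IRanges(fp$start, fp$end))
    for (cl in classes) {
      rs <- region_sets[region_sets$region_class == cl, , drop = FALSE]
      for (b in seq_len(nbin)) {
        bs <- rs$center + edges[b] + 1L
        be <- rs$center + edges[b + 1L]
        bg <- GenomicRanges::GRanges(rs$chrom, IRanges::IRanges(bs, be))
        hit <- unique(S4Vectors::queryHits(suppressWarnings(
          GenomicRanges::findOverlaps(bg, fg))))
        pct[fac, paste0(cl, ":bin", b)] <- 100 * length(hit) / nrow(rs)
      }
    }
  }
  z <- pct
  flagged <- character(0)
  for (fac in rownames(pct)) {
    s <- stats::sd(pct[fac, ])
    if (is.na(s) || s == 0) {
      z[fac, ] <- 0
      flagged <- c(flagged, fac)
    } else {
      z[fac, ] <- (pct[fac, ] - mean(pct[fac, ])) / s
    }
  }
  attr(z, "percent") <- pct
  attr(z, "flagged_factors") <- flagged
  class(z) <- c("cooccupancy_matrix", class(z))
  z
}

#' @export
print.cooccupancy_matrix <- function(x, ...) {
  cat("cooccupancy_matrix: ", nrow(x), " factors x ", ncol(x), " bins\n",
      sep = "")
  fl <- attr(x, "flagged_factors")
  if (length(fl)) cat("zero-variance factors: ", paste(fl, collapse = ", "),
                      "\n", sep = "")
  print(unclass(x)[seq_len(min(4L, nrow(x))),
                   seq_len(min(6L, ncol(x))), drop = FALSE])
  invisible(x)
}
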