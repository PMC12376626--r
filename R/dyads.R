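#' Find head-to-tail dyads with solitary intergenic binding
#'
#' A dyad is a head-to-tail gene pair for which some peak summit lies within
#' \code{radius} of BOTH the upstream gene's TES anchor and the downstream
#' gene's TSS anchor, and for which neither gene carries any other binding in
#' its vicinity at \emph{any} timepoint -- so any expression change can only
#' come from the shared intergenic site. Site affinity is \code{high} when the
#' shared site carries a peak at baseline and \code{low} when it appears only
#' after induction.
#'
#' "Vicinity" defaults to the gene span extended by \code{radius} on both
#' sides (\code{vicinity = "span_radius"}); \code{"window"} restricts the
#' exclusivity check to the two end windows (i.e. to end assignments).
#'
#' @param relations data.frame from [pair_relations()].
#' @param peaks_by_time named list of peak data.frames, one per timepoint, in
#'   temporal order; the first (or `baseline`) is the pre-induction state.
#' @param genes gene_models object.
#' @param baseline name of the baseline timepoint.
#' @param radius window half-width (default 2500).
#' @param factor restrict to peaks of this factor (default "MYC"); NULL uses
#'   all peaks.
#' @param vicinity exclusivity-zone rule, see above.
#' @return data.frame upstream_gene, downstream_gene, site_affinity,
#'   site_summit (baseline or first-seen summit), response_up, response_down
#'   (NA until [classify_dyad_responses()]).
#' @export
find_dyads <- function(relations, peaks_by_time, genes,
                       baseline = names(peaks_by_time)[1],
                       radius = 2500L, factor = "MYC",
                       vicinity = c("span_radius", "window")) {
  vicinity <- match.arg(vicinity)
  if (is.null(names(peaks_by_time)) || !baseline %in% names(peaks_by_time))
    stop("a named baseline timepoint is required")
  if (length(peaks_by_time) < 2L)
    stop("need >= 2 timepoints (baseline plus induction)")
  ht <- relations[relations$orientation == "head_to_tail", , drop = FALSE]
  if (!nrow(ht)) return(empty_dyads())
  pk_all <- do.call(rbind, lapply(names(peaks_by_time), function(tp) {
    d <- peaks_by_time[[tp]]
    if (!is.null(factor)) d <- d[d$factor == factor, , drop = FALSE]
    d$timepoint <- rep(tp, nrow(d))
    d
  }))
  if (is.null(pk_all) || !nrow(pk_all)) return(empty_dyads())
  g <- genes$genes
  anch <- genes$anchors
  out <- list()
  for (i in seq_len(nrow(ht))) {
    up <- ht$tes_gene[i]; down <- ht$tss_gene[i]
    tes_pos <- anch$pos[anch$gene_id == up & anch$end_kind == "TES"]
    tss_pos <- anch$pos[anch$gene_id == down & anch$end_kind == "TSS"]
    chrom <- g$chrom[g$gene_id == up]
    pk <- pk_all[pk_all$chrom == chrom, , drop = FALSE]
    if (!nrow(pk)) next
    shared <- vapply(pk$summit, function(s)
      any(abs(s - tes_pos) <= radius) && any(abs(s - tss_pos) <= radius),
      logical(1))
    if (!any(shared)) next
    # exclusivity: no non-shared peak in either gene's vicinity, any timepoint
    zone <- if (vicinity == "span_radius") {
      rbind(c(g$start[g$gene_id == up] - radius,
              g$end[g$gene_id == up] + radius),
            c(g$start[g$gene_id == down] - radius,
              g$end[g$gene_id == down] + radius))
    } else {
      cbind(c(anch$pos[anch$gene_id %in% c(up, down)] - radius),
            c(anch$pos[anch$gene_id %in% c(up, down)] + radius))
    }
    in_zone <- vapply(pk$summit, function(s)
      any(s >= zone[, 1] & s <= zone[, 2]), logical(1))
    if (any(in_zone & !shared)) next
    base_here <- any(shared & pk$timepoint == baseline)
    first <- pk[shared, ][1L, ]
    out[[length(out) + 1L]] <- data.frame(
      upstream_gene = up, downstream_gene = down,
      site_affinity = if (base_here) "high" else "low",
      site_summit = first$summit,
      response_up = NA_character_, response_down = NA_character_,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_dyads())
  res <- do.call(rbind, out)
  dup <- c(res$upstream_gene, res$downstream_gene)
  shared_genes <- unique(dup[duplicated(dup)])
  res$multi_dyad <- res$upstream_gene %in% shared_genes |
                    res$downstream_gene %in% shared_genes
  res
}

empty_dyads <- function() {
  data.frame(upstream_gene = character(), downstream_gene = character(),
             site_affinity = character(), site_summit = integer(),
             response_up = character(), response_down = character(),
             multi_dyad = logical(), stringsAsFactors = FALSE)
}

#' Classify dyad expression responses
#'
#' For each dyad gene, computes log2 fold changes of expression versus the
#' baseline timepoint, summarizes the post-induction response at the
#' timepoint of maximal |log2FC|, and labels it \code{positive} when that
#' change exceeds \code{log2(fold_threshold)} upward, \code{negative}
#' downward, and \code{none} otherwise. Labels are invariant to global
#' expression scaling. Dyads missing expression for either gene are dropped
#' with a message.
#'
#' @param dyads data.frame from [find_dyads()].
#' @param expression numeric matrix, genes x timepoints (column names are
#'   timepoint labels including the baseline).
#' @param baseline baseline column name.
#' @param fold_threshold fold-change calling threshold (default 1.5).
#' @return list: `dyads` (completed records), `log2fc` (per dyad-gene x
#'   timepoint matrix), `quadrants` (counts by affinity x flank x response).
#' @export
classify_dyad_responses <- function(dyads, expression,
                                    baseline = colnames(expression)[1],
                                    fold_threshold = 1.5) {
  if (!baseline %in% colnames(expression))
    stop("baseline column missing from expression")
  need <- unique(c(dyads$upstream_gene, dyads$downstream_gene))
  have <- need %in% rownames(expression)
  if (any(!have)) {
    message(sum(!have), " dyad gene(s) missing expression; dyads dropped")
    keep <- dyads$upstream_gene %in% need[have] &
            dyads$downstream_gene %in% need[have]
    dyads <- dyads[keep, , drop = FALSE]
  }
  post <- setdiff(colnames(expression), baseline)
  call_one <- function(gene) {
    lfc <- log2(expression[gene, post] / expression[gene, baseline])
    k <- which.max(abs(lfc))
    peak_lfc <- lfc[k]
    resp <- if (abs(peak_lfc) >= log2(fold_threshold)) {
      if (peak_lfc > 0) "positive" else "negative"
    } else "none"
    list(resp = resp, lfc = lfc)
  }
  lfc_rows <- list()
  for (i in seq_len(nrow(dyads))) {
    u <- call_one(dyads$upstream_gene[i])
    d <- call_one(dyads$downstream_gene[i])
    dyads$response_up[i] <- u$resp
    dyads$response_down[i] <- d$resp
    lfc_rows[[dyads$upstream_gene[i]]] <- u$lfc
    lfc_rows[[dyads$downstream_gene[i]]] <- d$lfc
  }
  lfc <- if (length(lfc_rows)) do.call(rbind, lfc_rows) else NULL
  quadrants <- if (nrow(dyads)) {
    as.data.frame(table(
      affinity = rep(dyads$site_affinity, 2L),
      flank = rep(c("upstream", "downstream"), each = nrow(dyads)),
      response = c(dyads$response_up, dyads$response_down)))
  } else NULL
  list(dyads = dyads, log2fc = lfc, quadrants = quadrants)
}
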