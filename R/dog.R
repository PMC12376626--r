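#' Read strand-specific coverage from a bedGraph file
#'
#' BED half-open intervals are converted to 1-based closed at ingestion and a
#' strand label is attached; read-through analyses require one file per strand.
#'
#' @param path bedGraph file.
#' @param strand "+" or "-".
#' @return data.frame chrom, start, end, value, strand (1-based closed).
#' @export
read_bedgraph <- function(path, strand) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-'; for unstranded coverage use a ",
         "merged boundary set (unstranded mode is a separate analysis)")
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr),
             end = BiocGenerics::end(gr),
             value = as.numeric(S4Vectors::mcols(gr)$score),
             strand = strand,
             stringsAsFactors = FALSE)
}

# Coverage mass in 1-based closed windows, prorating interval values by the
# overlapped length. windows: data.frame chrom, start, end, strand.
window_mass <- function(coverage, windows) {
  out <- numeric(nrow(windows))
  if (nrow(coverage) == 0L || nrow(windows) == 0L) return(out)
  cg <- GenomicRanges::GRanges(coverage$chrom,
          IRanges::IRanges(coverage$start, coverage$end),
          strand = coverage$strand)
  wg <- GenomicRanges::GRanges(windows$chrom,
          IRanges::IRanges(windows$start, windows$end),
          strand = windows$strand)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(wg, cg))
  if (!length(hits)) return(out)
  wi <- S4Vectors::queryHits(hits); ci <- S4Vectors::subjectHits(hits)
  ov <- pmin(windows$end[wi], coverage$end[ci]) -
        pmax(windows$start[wi], coverage$start[ci]) + 1L
  width <- coverage$end[ci] - coverage$start[ci] + 1L
  mass <- coverage$value[ci] * ov / width
  for (k in seq_along(wi)) out[wi[k]] <- out[wi[k]] + mass[k]
  out
}

#' Quantify downstream-of-gene read-through per gene
#'
#' For each gene, counts coverage mass on the gene's own strand in two
#' equal-length windows flanking the TES: the window just downstream of the
#' TES (read-through) and the window just upstream of it, excluding the TES
#' base itself (gene expression). The
#' read-through fraction is downstream/upstream; with equal windows the count
#' ratio equals the density ratio. The TES used is by default the
#' most-downstream annotated TES anchor, so read-through is measured past all
#' annotated ends.
#'
#' Genes whose upstream count falls below `min_upstream` are flagged
#' `low_expression` and their fraction left undefined; genes whose downstream
#' window overlaps another annotated gene on the same strand are flagged
#' `masked` (a neighbour's transcription must not be attributed to
#' read-through) and likewise left undefined.
#'
#' @param coverage data.frame from [read_bedgraph()] (both strands may be
#'   row-bound); must carry a strand column.
#' @param genes gene_models object.
#' @param window window length in bp (default 500).
#' @param min_upstream minimum upstream count for a defined fraction
#'   (default 10).
#' @param tes_choice "most_downstream" (default) or "most_upstream" TES anchor.
#' @return data.frame gene_id, tes, downstream_count, upstream_count,
#'   fraction, flag ("" / "low_expression" / "masked").
#' @export
count_dog_windows <- function(coverage, genes, window = 500L,
                              min_upstream = 10,
                              tes_choice = c("most_downstream",
                                             "most_upstream")) {
  tes_choice <- match.arg(tes_choice)
  stopifnot(window > 0)
  if (is.null(coverage$strand) || any(!coverage$strand %in% c("+", "-")))
    stop("coverage must be strand-resolved ('+'/'-'); for unstranded data ",
         "use a merged boundary set")
  g <- genes$genes
  anch <- genes$anchors[genes$anchors$end_kind == "TES", ]
  tes <- vapply(g$gene_id, function(id) {
    p <- anch$pos[anch$gene_id == id]
    s <- g$strand[g$gene_id == id]
    downstream_most <- if (s == "+") max(p) else min(p)
    upstream_most <- if (s == "+") min(p) else max(p)
    if (tes_choice == "most_downstream") downstream_most else upstream_most
  }, numeric(1))
  plus <- g$strand == "+"
  down <- data.frame(chrom = g$chrom,
                     start = ifelse(plus, tes + 1L, tes - window),
                     end = ifelse(plus, tes + window, tes - 1L),
                     strand = g$strand)
  # upstream window excludes the TES base itself so the two windows are
  # exact mirror images under strand flip + coordinate reflection
  up <- data.frame(chrom = g$chrom,
                   start = ifelse(plus, tes - window, tes + 1L),
                   end = ifelse(plus, tes - 1L, tes + window),
                   strand = g$strand)
  dmass <- window_mass(coverage, down)
  umass <- window_mass(coverage, up)

  # mask downstream windows that overlap another gene on the same strand
  spans <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                                  strand = g$strand)
  dw <- GenomicRanges::GRanges(down$chrom,
          IRanges::IRanges(down$start, down$end), strand = down$strand)
  hits <- GenomicRanges::findOverlaps(dw, spans)
  masked <- rep(FALSE, nrow(g))
  if (length(hits)) {
    wi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    masked[unique(wi[wi != si])] <- TRUE
  }

  flag <- ifelse(masked, "masked",
                 ifelse(umass < min_upstream, "low_expression", ""))
  frac <- ifelse(flag == "", dmass / umass, NA_real_)
  data.frame(gene_id = g$gene_id, tes = tes,
             downstream_count = dmass, upstream_count = umass,
             fraction = frac, flag = flag,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare read-through fractions between gene groups
#'
#' Two-sided Wilcoxon rank-sum test between the defined fractions of two gene
#' groups (canonically TES-bound versus TES-unbound), with per-group medians
#' and the direction of the difference.
#'
#' @param records data.frame from [count_dog_windows()].
#' @param groups named character/factor vector: names are gene_ids, values the
#'   two group labels.
#' @return list: group_labels, n (per group), medians, statistic, p_value,
#'   direction ("group1 > group2" style).
#' @export
compare_dog_groups <- function(records, groups) {
  rec <- records[!is.na(records$fraction), ]
  lab <- groups[rec$gene_id]
  keep <- !is.na(lab)
  rec <- rec[keep, ]; lab <- lab[keep]
  lv <- sort(unique(as.character(lab)))
  if (length(lv) != 2L) stop("exactly two groups required")
  x <- rec$fraction[lab == lv[1]]
  y <- rec$fraction[lab == lv[2]]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs >= 2 genes with defined fractions")
  wt <- stats::wilcox.test(x, y, exact = FALSE)
  med <- c(stats::median(x), stats::median(y))
  list(group_labels = lv, n = c(length(x), length(y)),
       medians = stats::setNames(med, lv),
       statistic = unname(wt$statistic), p_value = wt$p.value,
       direction = paste(lv[if (med[1] >= med[2]) c(1, 2) else c(2, 1)],
                         collapse = " > "))
}

#' Per-gene read-through change across conditions
#'
#' For each non-baseline condition, the per-gene log2 ratio of
#' pseudocount-stabilized fractions, (down + pc) / (up + pc), relative to the
#' baseline condition. Genes flagged or with zero upstream counts in either
#' condition are excluded and reported.
#'
#' @param records_by_condition named list of [count_dog_windows()] tables.
#' @param baseline baseline condition name.
#' @param pseudocount added to both window counts (default 0.5).
#' @return data.frame condition, gene_id, log2_ratio plus a per-condition
#'   summary attribute "summary" (condition, n, median_log2_ratio).
#' @export
dog_condition_delta <- function(records_by_condition,
                                baseline = names(records_by_condition)[1],
                                pseudocount = 0.5) {
  if (is.null(names(records_by_condition)) ||
      !baseline %in% names(records_by_condition))
    stop("baseline condition missing from records_by_condition")
  base <- records_by_condition[[baseline]]
  stab <- function(d) (d$downstream_count + pseudocount) /
                      (d$upstream_count + pseudocount)
  fb <- stats::setNames(stab(base), base$gene_id)
  okb <- stats::setNames(base$flag == "", base$gene_id)
  out <- list()
  for (cond in setdiff(names(records_by_condition), baseline)) {
    d <- records_by_condition[[cond]]
    common <- intersect(d$gene_id, names(fb))
    d <- d[match(common, d$gene_id), ]
    ok <- d$flag == "" & okb[common]
    out[[length(out) + 1L]] <- data.frame(
      condition = cond, gene_id = common,
      log2_ratio = ifelse(ok, log2(stab(d) / fb[common]), NA_real_),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  summ <- do.call(rbind, lapply(split(res, res$condition), function(d) {
    data.frame(condition = d$condition[1], n = sum(!is.na(d$log2_ratio)),
               median_log2_ratio = stats::median(d$log2_ratio, na.rm = TRUE))
  }))
  attr(res, "summary") <- summ
  res
}
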