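#' Read ChIP peaks in narrowPeak format
#'
#' ENCODE narrowPeak is BED6+4: signalValue in column 7 and the 0-based summit
#' offset in column 10. BED half-open coordinates are converted to 1-based
#' closed at ingestion. A summit offset of -1 means no called summit; the
#' interval midpoint is used instead.
#'
#' @param path narrowPeak file.
#' @param factor factor (antibody target) label attached to every peak.
#' @param sample sample / timepoint label attached to every peak.
#' @return data.frame of peaks: peak_id, factor, chrom, start, end, summit,
#'   signal, sample. 1-based closed coordinates.
#' @export
read_narrowpeak <- function(path, factor, sample = "default") {
  if (!file.exists(path)) stop("peak file not found: ", path)
  gr <- rtracklayer::import(path, format = "bed",
    extraCols = c(signalValue = "numeric", pValue = "numeric",
                  qValue = "numeric", peak = "integer"))
  md <- S4Vectors::mcols(gr)
  start <- BiocGenerics::start(gr)
  end <- BiocGenerics::end(gr)
  offs <- md$peak
  summit <- ifelse(is.na(offs) | offs < 0L,
                   as.integer(floor((start + end) / 2)),
                   start + offs)
  nm <- md$name
  if (is.null(nm) || all(is.na(nm))) nm <- sprintf("peak_%06d", seq_along(gr))
  data.frame(peak_id = as.character(nm),
             factor = factor,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = start, end = end,
             summit = as.integer(summit),
             signal = as.numeric(md$signalValue),
             sample = sample,
             stringsAsFactors = FALSE)
}

empty_assignments <- function() {
  data.frame(peak_id = character(), gene_id = character(),
             end_kind = character(), anchor = integer(),
             offset = integer(), factor = character(),
             signal = numeric(), sample = character(),
             ambiguous = logical(), same_gene_dual = logical(),
             stringsAsFactors = FALSE)
}

#' Assign ChIP peaks to TSS/TES anchor windows
#'
#' A peak is assigned to a gene end when its summit (default) or its interval
#' (\code{mode = "overlap"}) lies within \code{radius} bp of one of the gene's
#' TSS or TES anchors. A peak within radius of anchors of two genes is assigned
#' to both genes; a peak within radius of several anchors of the \emph{same}
#' gene end yields one assignment against the nearest anchor. Offsets are
#' gene-oriented: positive means downstream of the anchor in the gene's
#' reading direction.
#'
#' Peaks whose TSS and TES windows of one short gene both capture them receive
#' two assignments with \code{same_gene_dual} set. The \code{ambiguous} column
#' is initialized FALSE; see [flag_ambiguous()].
#'
#' @param peaks data.frame as from [read_narrowpeak()].
#' @param genes gene_models object.
#' @param radius window half-width in bp. Default 2500; 1000 is the preset for
#'   compact genomes such as D. melanogaster.
#' @param mode "summit" (point membership, default) or "overlap" (any base of
#'   the peak interval within the window).
#' @return data.frame of assignments (see [empty_assignments()] columns),
#'   ordered by chrom, gene_id, end_kind, peak_id.
#' @export
assign_peaks <- function(peaks, genes, radius = 2500L,
                         mode = c("summit", "overlap")) {
  mode <- match.arg(mode)
  stopifnot(inherits(genes, "gene_models"))
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  if (nrow(peaks) == 0L) return(empty_assignments())

  anch <- genes$anchors
  shared <- intersect(unique(peaks$chrom), unique(anch$chrom))
  off_chrom <- setdiff(unique(peaks$chrom), shared)
  if (length(off_chrom))
    message("peaks on ", length(off_chrom),
            " chromosome(s) absent from annotation left unassigned")

  pk <- peaks[peaks$chrom %in% shared, , drop = FALSE]
  if (nrow(pk) == 0L) return(empty_assignments())

  win <- GenomicRanges::GRanges(anch$chrom,
           IRanges::IRanges(anch$pos - radius, anch$pos + radius))
  qry <- if (mode == "summit")
    GenomicRanges::GRanges(pk$chrom, IRanges::IRanges(pk$summit, pk$summit))
  else
    GenomicRanges::GRanges(pk$chrom, IRanges::IRanges(pk$start, pk$end))
  hits <- GenomicRanges::findOverlaps(qry, win)
  if (length(hits) == 0L) return(empty_assignments())

  pi <- S4Vectors::queryHits(hits); ai <- S4Vectors::subjectHits(hits)
  dist <- abs(pk$summit[pi] - anch$pos[ai])
  df <- data.frame(pi = pi, ai = ai, dist = dist)
  df$gene_id <- anch$gene_id[ai]
  df$end_kind <- anch$end_kind[ai]
  # collapse multiple same-end anchors of one gene to the nearest
  key <- paste(pk$peak_id[df$pi], pk$sample[df$pi], df$gene_id, df$end_kind)
  df <- df[order(key, df$dist), ]
  df <- df[!duplicated(paste(pk$peak_id[df$pi], pk$sample[df$pi],
                             df$gene_id, df$end_kind)), ]

  strand <- anch$strand[df$ai]
  anchor_pos <- anch$pos[df$ai]
  summit <- pk$summit[df$pi]
  offset <- ifelse(strand == "+", summit - anchor_pos, anchor_pos - summit)

  out <- data.frame(peak_id = pk$peak_id[df$pi],
                    gene_id = df$gene_id,
                    end_kind = df$end_kind,
                    anchor = anchor_pos,
                    offset = as.integer(offset),
                    factor = pk$factor[df$pi],
                    signal = pk$signal[df$pi],
                    sample = pk$sample[df$pi],
                    ambiguous = FALSE,
                    stringsAsFactors = FALSE)
  dup <- paste(out$peak_id, out$sample, out$gene_id)
  out$same_gene_dual <- dup %in% dup[duplicated(dup)]
  out <- out[order(out$gene_id, out$end_kind, out$peak_id, out$sample), ]
  rownames(out) <- NULL
  out
}

#' Flag assignments ambiguous between head-to-tail neighbours
#'
#' A peak assigned both to the TES of one gene and to the TSS of its
#' head-to-tail partner cannot be attributed to either end; such assignment
#' pairs are flagged on \emph{both} rows. No other assignment is touched, and
#' no assignment is removed: callers drop flagged rows when the analysis
#' requires it (signal comparison and TES-specific analyses) and keep them for
#' category classification.
#'
#' @param assignments data.frame from [assign_peaks()].
#' @param relations data.frame from [pair_relations()] on the same gene set.
#' @return assignments with the \code{ambiguous} column set.
#' @export
flag_ambiguous <- function(assignments, relations) {
  if (nrow(assignments) == 0L || nrow(relations) == 0L) return(assignments)
  ht <- relations[relations$orientation == "head_to_tail", , drop = FALSE]
  if (nrow(ht) == 0L) return(assignments)
  a <- assignments
  akey <- paste(a$peak_id, a$sample, a$gene_id, a$end_kind)
  for (i in seq_len(nrow(ht))) {
    tes_rows <- a$gene_id == ht$tes_gene[i] & a$end_kind == "TES"
    tss_rows <- a$gene_id == ht$tss_gene[i] & a$end_kind == "TSS"
    shared <- intersect(paste(a$peak_id, a$sample)[tes_rows],
                        paste(a$peak_id, a$sample)[tss_rows])
    if (length(shared)) {
      hit <- paste(a$peak_id, a$sample) %in% shared & (tes_rows | tss_rows)
      a$ambiguous[hit] <- TRUE
    }
  }
  a
}

#' Count distinct binding sites per gene end and factor
#'
#' Exact peak multiplicities are kept for reporting; downstream category
#' classification uses presence/absence only.
#'
#' @param assignments data.frame from [assign_peaks()].
#' @return data.frame gene_id, end_kind, factor, n_sites.
#' @export
site_counts <- function(assignments) {
  if (nrow(assignments) == 0L)
    return(data.frame(gene_id = character(), end_kind = character(),
                      factor = character(), n_sites = integer(),
                      stringsAsFactors = FALSE))
  agg <- stats::aggregate(
    list(n_sites = assignments$peak_id),
    by = list(gene_id = assignments$gene_id,
              end_kind = assignments$end_kind,
              factor = assignments$factor),
    FUN = function(p) length(unique(p)))
  agg[order(agg$gene_id, agg$end_kind, agg$factor), ]
}

#' Write end assignments to TSV
#' @param assignments data.frame from [assign_peaks()]
#' @param path output file
#' @export
write_assignments <- function(assignments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# endbind peak-to-end assignments; coordinates 1-based closed", con)
  utils::write.table(assignments, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
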