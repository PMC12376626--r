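#' Default biotype mapping
#'
#' Maps source annotation biotype strings onto the three-way split used
#' throughout the package: protein-coding genes, lncRNAs, and everything else.
#' Source labels not present in the map fall into \code{"other"}.
#'
#' @return Named character vector: names are source labels, values are one of
#'   \code{"protein_coding"}, \code{"lncRNA"}, \code{"other"}.
#' @export
default_biotype_map <- function() {
  c(protein_coding = "protein_coding",
    lncRNA = "lncRNA",
    lincRNA = "lncRNA",
    antisense = "lncRNA")
}

BIOTYPE_LEVELS <- c("protein_coding", "lncRNA", "other")
END_KINDS <- c("TSS", "TES")

#' Build gene models from per-transcript coordinates
#'
#' Internal constructor shared by `load_annotation()` and the synthetic
#' generator. Transcripts are collapsed per gene: the gene span is the union of
#' transcript spans, and the TSS/TES anchor sets are the deduplicated transcript
#' start/end sites (strand-aware). Anchors of the same gene end closer than
#' `dedup_bp` are merged to the most upstream (TSS) / most downstream (TES)
#' position in the gene's reading direction, to avoid double-counting
#' near-identical transcript ends.
#'
#' @param tx data.frame with columns gene_id, transcript_id, chrom, start, end,
#'   strand, biotype (already mapped to the 3-way split).
#' @param dedup_bp anchors within this many bp on one gene end are merged.
#' @return A `gene_models` object.
#' @keywords internal
build_gene_models <- function(tx, dedup_bp = 10L) {
  stopifnot(all(c("gene_id", "transcript_id", "chrom", "start", "end",
                  "strand", "biotype") %in% names(tx)))
  if (nrow(tx) == 0L) stop("no transcript records")
  tx$start <- as.integer(tx$start)
  tx$end <- as.integer(tx$end)

  # per-transcript anchors: TSS is the 5' end, TES the 3' end, by strand
  tss <- ifelse(tx$strand == "+", tx$start, tx$end)
  tes <- ifelse(tx$strand == "+", tx$end, tx$start)

  ord <- order(tx$chrom, tx$gene_id)
  tx <- tx[ord, ]; tss <- tss[ord]; tes <- tes[ord]

  split_idx <- split(seq_len(nrow(tx)), tx$gene_id)
  genes <- do.call(rbind, lapply(names(split_idx), function(g) {
    i <- split_idx[[g]]
    data.frame(gene_id = g,
               chrom = tx$chrom[i[1L]],
               strand = tx$strand[i[1L]],
               start = min(tx$start[i]),
               end = max(tx$end[i]),
               biotype = tx$biotype[i[1L]],
               stringsAsFactors = FALSE)
  }))

  anchors <- do.call(rbind, lapply(names(split_idx), function(g) {
    i <- split_idx[[g]]
    strand <- tx$strand[i[1L]]
    rbind(
      data.frame(gene_id = g, end_kind = "TSS",
                 pos = dedup_anchors(unique(tss[i]), strand, "TSS", dedup_bp)),
      data.frame(gene_id = g, end_kind = "TES",
                 pos = dedup_anchors(unique(tes[i]), strand, "TES", dedup_bp))
    )
  }))
  anchors <- merge(anchors,
                   genes[, c("gene_id", "chrom", "strand")],
                   by = "gene_id", sort = FALSE)
  anchors <- anchors[order(anchors$chrom, anchors$gene_id,
                           anchors$end_kind, anchors$pos), ]
  rownames(anchors) <- NULL
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), ]
  rownames(genes) <- NULL

  structure(list(genes = genes, anchors = anchors), class = "gene_models")
}

# Merge anchors closer than dedup_bp: keep the most upstream TSS / most
# downstream TES in the gene's reading direction.
dedup_anchors <- function(pos, strand, end_kind, dedup_bp) {
  pos <- sort(unique(as.integer(pos)))
  if (length(pos) <= 1L) return(pos)
  grp <- cumsum(c(TRUE, diff(pos) > dedup_bp))
  keep_min <- (end_kind == "TSS") == (strand == "+")
  as.integer(tapply(pos, grp, if (keep_min) min else max))
}

#' Load a gene annotation and derive TSS/TES anchors
#'
#' Parses a GTF/GFF file (1-based closed coordinates), keeps transcript-level
#' records, and builds one gene model per \code{gene_id} carrying the gene span,
#' strand, a 3-way biotype, and the deduplicated per-transcript TSS and TES
#' anchor positions.
#'
#' Records with malformed coordinates (start > end) abort with the offending
#' line number; records without a usable strand are rejected with a warning.
#'
#' @param path GTF/GFF file. Attributes \code{gene_id} and \code{transcript_id}
#'   are required; \code{gene_type} or \code{gene_biotype} is used for the
#'   biotype when present.
#' @param biotype_map named character vector mapping source biotype labels to
#'   \code{protein_coding}/\code{lncRNA}/\code{other}; see
#'   [default_biotype_map()].
#' @param dedup_bp anchors within this distance on the same gene end are merged
#'   (default 10).
#' @return A \code{gene_models} object: list with \code{$genes} (one row per
#'   gene: gene_id, chrom, strand, start, end, biotype) and \code{$anchors}
#'   (gene_id, end_kind, pos, chrom, strand). All coordinates 1-based closed.
#' @export
load_annotation <- function(path, biotype_map = default_biotype_map(),
                            dedup_bp = 10L) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  check_gtf_coordinates(path)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  feat <- as.character(md$type)
  is_tx <- feat %in% c("transcript", "mRNA")
  if (!any(is_tx)) {
    # fall back to exon records aggregated per transcript
    is_tx <- feat == "exon"
    if (!any(is_tx)) stop("no transcript or exon records in ", path)
  }
  gr <- gr[is_tx]
  md <- S4Vectors::mcols(gr)
  if (is.null(md$gene_id) || is.null(md$transcript_id))
    stop("annotation lacks gene_id/transcript_id attributes")

  strand <- as.character(BiocGenerics::strand(gr))
  bad_strand <- !strand %in% c("+", "-")
  if (any(bad_strand)) {
    warning(sum(bad_strand), " record(s) without usable strand rejected")
    gr <- gr[!bad_strand]; md <- S4Vectors::mcols(gr)
    strand <- strand[!bad_strand]
  }
  if (length(gr) == 0L) stop("no stranded transcript records in ", path)

  src_bio <- if (!is.null(md$gene_type)) as.character(md$gene_type)
             else if (!is.null(md$gene_biotype)) as.character(md$gene_biotype)
             else rep(NA_character_, length(gr))
  bio <- unname(biotype_map[src_bio])
  bio[is.na(bio)] <- "other"

  tx <- data.frame(gene_id = as.character(md$gene_id),
                   transcript_id = as.character(md$transcript_id),
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr),
                   end = BiocGenerics::end(gr),
                   strand = strand,
                   biotype = bio,
                   stringsAsFactors = FALSE)
  # exon fallback: one record per transcript spanning its exons
  if (anyDuplicated(tx$transcript_id)) {
    sp <- split(tx, tx$transcript_id)
    tx <- do.call(rbind, lapply(sp, function(d) {
      d$start[1L] <- min(d$start); d$end[1L] <- max(d$end); d[1L, ]
    }))
  }
  build_gene_models(tx, dedup_bp = dedup_bp)
}

# Record-level coordinate sanity scan so a malformed line is reported by
# number rather than as an opaque import failure.
check_gtf_coordinates <- function(path) {
  lines <- readLines(path)
  data_ln <- which(!startsWith(lines, "#") & nzchar(lines))
  if (!length(data_ln)) return(invisible(TRUE))
  fields <- strsplit(lines[data_ln], "\t", fixed = TRUE)
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    if (length(f) < 8L) next
    s <- suppressWarnings(as.integer(f[4L])); e <- suppressWarnings(as.integer(f[5L]))
    if (!is.na(s) && !is.na(e) && s > e)
      stop("malformed coordinate (start > end) at line ", data_ln[k])
  }
  invisible(TRUE)
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models: ", nrow(x$genes), " genes, ",
      nrow(x$anchors), " anchors on ",
      length(unique(x$genes$chrom)), " chromosome(s)\n", sep = "")
  print(utils::head(x$genes, 5))
  invisible(x)
}

# Facing end kind of the left/right member of an adjacent pair, from strands.
# Left gene faces right with its high-coordinate end; right gene with its low.
facing_end <- function(strand, side) {
  if (side == "left") if (strand == "+") "TES" else "TSS"
  else                if (strand == "+") "TSS" else "TES"
}

#' Orientation relations between adjacent genes
#'
#' Walks each chromosome in coordinate order and emits one relation per
#' adjacent gene pair whose facing anchors are within \code{max_gap}:
#' facing 5' ends give \code{head_to_head}, facing 3' ends
#' \code{tail_to_tail}, and a 3' end facing the next gene's 5' end
#' \code{head_to_tail}. \code{end_gap} is the signed distance between the
#' nearest facing anchors (negative when the spans overlap; such relations are
#' flagged). Columns \code{tes_gene}/\code{tss_gene} name, for head-to-tail
#' pairs, which member contributes its TES / TSS to the shared gap.
#'
#' @param genes a \code{gene_models} object.
#' @param max_gap maximum facing-anchor gap (bp) for a relation to be emitted.
#'   Default 5000 = twice the standard 2.5 kb end window, so any peak that can
#'   be dual-assigned implies a relation.
#' @return data.frame: gene_a, gene_b (left/right by coordinate), orientation,
#'   end_gap, end_a, end_b (facing end kinds), tes_gene, tss_gene (head-to-tail
#'   only, else NA), overlapping flag.
#' @export
pair_relations <- function(genes, max_gap = 5000L) {
  stopifnot(inherits(genes, "gene_models"))
  g <- genes$genes
  out <- list()
  for (chr in unique(g$chrom)) {
    gc <- g[g$chrom == chr, ]
    gc <- gc[order(gc$start, gc$end, gc$gene_id), ]
    if (nrow(gc) < 2L) next
    for (i in seq_len(nrow(gc) - 1L)) {
      a <- gc[i, ]; b <- gc[i + 1L, ]
      end_a <- facing_end(a$strand, "left")
      end_b <- facing_end(b$strand, "right")
      anch_a <- genes$anchors[genes$anchors$gene_id == a$gene_id &
                              genes$anchors$end_kind == end_a, "pos"]
      anch_b <- genes$anchors[genes$anchors$gene_id == b$gene_id &
                              genes$anchors$end_kind == end_b, "pos"]
      gap <- min(anch_b) - max(anch_a)
      if (gap > max_gap) next
      orientation <-
        if (end_a == "TES" && end_b == "TSS") "head_to_tail"
        else if (end_a == "TSS" && end_b == "TES") "head_to_tail"
        else if (end_a == "TSS") "head_to_head" else "tail_to_tail"
      ht <- orientation == "head_to_tail"
      out[[length(out) + 1L]] <- data.frame(
        gene_a = a$gene_id, gene_b = b$gene_id,
        orientation = orientation, end_gap = gap,
        end_a = end_a, end_b = end_b,
        tes_gene = if (ht) (if (end_a == "TES") a$gene_id else b$gene_id) else NA_character_,
        tss_gene = if (ht) (if (end_a == "TSS") a$gene_id else b$gene_id) else NA_character_,
        overlapping = gap <= 0L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_a = character(), gene_b = character(),
                      orientation = character(), end_gap = integer(),
                      end_a = character(), end_b = character(),
                      tes_gene = character(), tss_gene = character(),
                      overlapping = logical(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Write gene models to a TSV
#'
#' One row per gene with comma-joined anchor lists. Coordinates are 1-based
#' closed, stated in the header.
#' @param genes gene_models object
#' @param path output file
#' @export
write_gene_models <- function(genes, path) {
  a <- genes$anchors
  tss <- vapply(genes$genes$gene_id, function(g)
    paste(a$pos[a$gene_id == g & a$end_kind == "TSS"], collapse = ","), "")
  tes <- vapply(genes$genes$gene_id, function(g)
    paste(a$pos[a$gene_id == g & a$end_kind == "TES"], collapse = ","), "")
  df <- cbind(genes$genes, tss_anchors = tss, tes_anchors = tes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# endbind gene models; coordinates 1-based closed", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
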