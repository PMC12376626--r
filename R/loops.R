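#' Read chromatin interaction loops in BEDPE format
#'
#' Tolerates the 10+ column dialect (name, score, strands, extra columns
#' ignored). BED half-open anchor coordinates are converted to 1-based closed,
#' and anchors are ordered canonically (anchor1 leftmost on the lower-ranked
#' chromosome).
#'
#' @param path BEDPE file.
#' @return data.frame loop_id, chrom1, start1, end1, chrom2, start2, end2,
#'   score.
#' @export
read_bedpe <- function(path) {
  if (!file.exists(path)) stop("BEDPE file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("BEDPE needs at least 6 columns")
  out <- data.frame(loop_id = if (ncol(df) >= 7L) as.character(df[[7L]])
                              else sprintf("loop_%06d", seq_len(nrow(df))),
                    chrom1 = as.character(df[[1L]]),
                    start1 = as.integer(df[[2L]]) + 1L,
                    end1 = as.integer(df[[3L]]),
                    chrom2 = as.character(df[[4L]]),
                    start2 = as.integer(df[[5L]]) + 1L,
                    end2 = as.integer(df[[6L]]),
                    score = if (ncol(df) >= 8L)
                      suppressWarnings(as.numeric(df[[8L]])) else NA_real_,
                    stringsAsFactors = FALSE)
  swap <- out$chrom1 > out$chrom2 |
    (out$chrom1 == out$chrom2 & out$start1 > out$start2)
  if (any(swap)) {
    tmp <- out[swap, c("chrom2", "start2", "end2")]
    out[swap, c("chrom2", "start2", "end2")] <-
      out[swap, c("chrom1", "start1", "end1")]
    out[swap, c("chrom1", "start1", "end1")] <- tmp
  }
  out
}

#' Assign loop anchors to gene ends
#'
#' An anchor assigns to a gene end when its midpoint lies within
#' \code{radius} of a TSS/TES anchor position -- the same convention as peak
#' assignment. One loop may touch the ends of several genes.
#' Inter-chromosomal loops are excluded (their count is messaged).
#'
#' @param loops data.frame from [read_bedpe()].
#' @param genes gene_models object.
#' @param radius window half-width (default 2500, as for peaks).
#' @return data.frame loop_id, anchor_idx (1 or 2), gene_id, end_kind,
#'   midpoint.
#' @export
assign_loop_ends <- function(loops, genes, radius = 2500L) {
  inter <- loops$chrom1 != loops$chrom2
  if (any(inter))
    message(sum(inter), " inter-chromosomal loop(s) excluded")
  lp <- loops[!inter, , drop = FALSE]
  anch <- genes$anchors
  res <- list()
  for (k in 1:2) {
    mid <- as.integer(floor((lp[[paste0("start", k)]] +
                             lp[[paste0("end", k)]]) / 2))
    pt <- GenomicRanges::GRanges(lp[[paste0("chrom", k)]],
            IRanges::IRanges(mid, mid))
    win <- GenomicRanges::GRanges(anch$chrom,
             IRanges::IRanges(anch$pos - radius, anch$pos + radius))
    hits <- GenomicRanges::findOverlaps(pt, win)
    if (!length(hits)) next
    li <- S4Vectors::queryHits(hits); ai <- S4Vectors::subjectHits(hits)
    d <- data.frame(loop_id = lp$loop_id[li], anchor_idx = k,
                    gene_id = anch$gene_id[ai], end_kind = anch$end_kind[ai],
                    midpoint = mid[li], dist = abs(mid[li] - anch$pos[ai]),
                    stringsAsFactors = FALSE)
    d <- d[order(d$loop_id, d$gene_id, d$end_kind, d$dist), ]
    d <- d[!duplicated(paste(d$loop_id, d$anchor_idx, d$gene_id, d$end_kind)), ]
    res[[length(res) + 1L]] <- d[, setdiff(names(d), "dist")]
  }
  if (!length(res))
    return(data.frame(loop_id = character(), anchor_idx = integer(),
                      gene_id = character(), end_kind = character(),
                      midpoint = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-gene contact profiles and loop groups A-H
#'
#' For each gene three flags are derived from anchor-to-end assignments:
#' \code{tss_tes_loop} (a loop joins the gene's own TSS and TES windows),
#' \code{tss_other} (a TSS anchor loops to some other locus), and
#' \code{tes_other}. "Other" contacts require the second anchor \emph{not} to
#' fall in the same gene's opposite end window, and loops whose two anchors
#' land in the same single window (self-loops) are discarded. The flags define
#' eight groups: A-D have a direct TSS-TES loop (A both extra contacts, B TSS
#' extra only, C TES extra only, D neither) and E-H mirror A-D without it.
#'
#' @param loop_ends data.frame from [assign_loop_ends()].
#' @param genes gene_models object (defines the gene universe).
#' @return data.frame gene_id, tss_tes_loop, tss_other, tes_other, group.
#' @export
contact_profiles <- function(loop_ends, genes) {
  gid <- genes$genes$gene_id
  tss_tes <- tss_other <- tes_other <- stats::setNames(
    rep(FALSE, length(gid)), gid)
  if (nrow(loop_ends)) {
    le <- loop_ends
    for (g in unique(le$gene_id)) {
      lg <- le[le$gene_id == g, ]
      for (lid in unique(lg$loop_id)) {
        ll <- lg[lg$loop_id == lid, ]
        kinds1 <- ll$end_kind[ll$anchor_idx == 1L]
        kinds2 <- ll$end_kind[ll$anchor_idx == 2L]
        both_ends <- (("TSS" %in% kinds1 && "TES" %in% kinds2) ||
                      ("TES" %in% kinds1 && "TSS" %in% kinds2))
        if (both_ends) { tss_tes[g] <- TRUE; next }
        # loop touches this gene with one anchor only (or a self-loop)
        for (side in 1:2) {
          kinds <- ll$end_kind[ll$anchor_idx == side]
          other <- ll$end_kind[ll$anchor_idx == (3L - side)]
          if (!length(kinds)) next
          if (length(other)) next  # both anchors in this gene's windows:
                                   # same-window self-loop, discard
          if ("TSS" %in% kinds) tss_other[g] <- TRUE
          if ("TES" %in% kinds) tes_other[g] <- TRUE
        }
      }
    }
  }
  df <- data.frame(gene_id = gid,
                   tss_tes_loop = unname(tss_tes[gid]),
                   tss_other = unname(tss_other[gid]),
                   tes_other = unname(tes_other[gid]),
                   stringsAsFactors = FALSE)
  df$group <- classify_loop_groups(df)
  df
}

#' Loop group letter from contact flags
#' @param profiles data.frame with tss_tes_loop, tss_other, tes_other columns.
#' @return character vector of groups A-H.
#' @export
classify_loop_groups <- function(profiles) {
  sub <- ifelse(profiles$tss_other & profiles$tes_other, 1L,
         ifelse(profiles$tss_other, 2L,
         ifelse(profiles$tes_other, 3L, 4L)))
  ifelse(profiles$tss_tes_loop, c("A", "B", "C", "D")[sub],
         c("E", "F", "G", "H")[sub])
}

#' Cross-tabulate binding categories with loop groups
#'
#' Builds the 16 x 8 gene-count matrix of binding category by contact group,
#' the matching mean-expression matrix (cells with fewer than `min_cell` genes
#' suppressed), and per-category looping frequencies reported under both
#' denominators: fraction of the category's genes in groups A-D, and mean
#' number of distinct TSS-TES loops per gene.
#'
#' @param calls data.frame from [classify_end_binding()].
#' @param profiles data.frame from [contact_profiles()].
#' @param expression named numeric vector (gene_id -> expression), optional.
#' @param min_cell minimum genes per cell for a reported mean (default 5).
#' @param loop_ends optional [assign_loop_ends()] table for the loops-per-gene
#'   denominator.
#' @return list: counts (16x8 matrix), mean_expression (16x8 matrix or NULL),
#'   looping_frequency (data.frame category, n, frac_genes_looping,
#'   loops_per_gene).
#' @export
category_group_matrix <- function(calls, profiles, expression = NULL,
                                  min_cell = 5L, loop_ends = NULL) {
  common <- intersect(calls$gene_id, profiles$gene_id)
  cl <- calls[match(common, calls$gene_id), ]
  pr <- profiles[match(common, profiles$gene_id), ]
  groups <- LETTERS[1:8]
  counts <- matrix(0L, 16L, 8L, dimnames = list(category = 1:16,
                                                group = groups))
  tab <- table(factor(cl$category, levels = 1:16),
               factor(pr$group, levels = groups))
  counts[] <- as.integer(tab)
  me <- NULL
  if (!is.null(expression)) {
    me <- matrix(NA_real_, 16L, 8L, dimnames = dimnames(counts))
    for (k in 1:16) for (g in groups) {
      ids <- common[cl$category == k & pr$group == g]
      ex <- expression[ids]; ex <- ex[!is.na(ex)]
      if (length(ex) >= min_cell) me[k, g] <- mean(ex)
    }
  }
  lpg <- rep(NA_real_, 16)
  if (!is.null(loop_ends)) {
    # distinct loops per gene joining its own two ends
    tt <- loop_ends
    n_tt <- vapply(common, function(g) {
      lg <- tt[tt$gene_id == g, ]
      if (!nrow(lg)) return(0)
      sum(vapply(unique(lg$loop_id), function(lid) {
        ll <- lg[lg$loop_id == lid, ]
        k1 <- ll$end_kind[ll$anchor_idx == 1L]
        k2 <- ll$end_kind[ll$anchor_idx == 2L]
        ("TSS" %in% k1 && "TES" %in% k2) || ("TES" %in% k1 && "TSS" %in% k2)
      }, logical(1)))
    }, numeric(1))
    lpg <- vapply(1:16, function(k) {
      i <- cl$category == k
      if (!any(i)) NA_real_ else mean(n_tt[i])
    }, numeric(1))
  }
  lf <- data.frame(
    category = 1:16,
    n = as.integer(rowSums(counts)),
    frac_genes_looping = ifelse(rowSums(counts) > 0,
                                rowSums(counts[, 1:4]) / rowSums(counts),
                                NA_real_),
    loops_per_gene = lpg)
  list(counts = counts, mean_expression = me, looping_frequency = lf)
}

#' Restrict the gene universe to RNAPII-bound genes
#'
#' Keeps genes with an RNAPII assignment at both the TSS and the TES, and
#' splits that universe into four groups by TES-proximal binding of the two
#' factors (both, A only, B only, neither) for looping-frequency comparisons.
#'
#' @param genes gene_models object.
#' @param rnapii_assignments assignment table for the RNAPII factor (e.g.
#'   POLR2A) from [assign_peaks()].
#' @param tf_assignments assignment table for the two factors of interest.
#' @param factor_a,factor_b factor labels (defaults MYC/MAX).
#' @return data.frame gene_id, tes_group
#'   (\code{both}/\code{a_only}/\code{b_only}/\code{neither}).
#' @export
rnapii_gate <- function(genes, rnapii_assignments, tf_assignments,
                        factor_a = "MYC", factor_b = "MAX") {
  r <- rnapii_assignments
  has_tss <- unique(r$gene_id[r$end_kind == "TSS"])
  has_tes <- unique(r$gene_id[r$end_kind == "TES"])
  universe <- intersect(genes$genes$gene_id, intersect(has_tss, has_tes))
  a3 <- universe %in% tf_assignments$gene_id[
    tf_assignments$factor == factor_a & tf_assignments$end_kind == "TES"]
  b3 <- universe %in% tf_assignments$gene_id[
    tf_assignments$factor == factor_b & tf_assignments$end_kind == "TES"]
  grp <- ifelse(a3 & b3, "both",
         ifelse(a3, "a_only", ifelse(b3, "b_only", "neither")))
  data.frame(gene_id = universe, tes_group = grp, stringsAsFactors = FALSE)
}
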