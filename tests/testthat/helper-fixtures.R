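# Fixture builders and independent brute-force oracles. The oracles scan every
# (peak, anchor) / (gene, gene) pair with plain arithmetic and never call the
# interval machinery they check.

# Write a minimal GTF for a transcript table and load it through the package
# reader; tx: data.frame gene_id, transcript_id, chrom, start, end, strand,
# optionally biotype.
genes_from_tx <- function(tx, dedup_bp = 10L) {
  if (is.null(tx$biotype)) tx$biotype <- "protein_coding"
  path <- tempfile(fileext = ".gtf")
  writeLines(sprintf(
    '%s\ttest\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_type "%s";',
    tx$chrom, tx$start, tx$end, tx$strand, tx$gene_id, tx$transcript_id,
    tx$biotype), path)
  load_annotation(path, dedup_bp = dedup_bp)
}

# Quick peak table (no file round-trip needed).
make_peaks <- function(chrom, summit, factor = "MYC", signal = 1,
                       sample = "t0", half = 150L,
                       peak_id = sprintf("pk%04d", seq_along(summit))) {
  if (!length(summit))
    return(data.frame(peak_id = character(), factor = character(),
                      chrom = character(), start = integer(),
                      end = integer(), summit = integer(),
                      signal = numeric(), sample = character(),
                      stringsAsFactors = FALSE))
  data.frame(peak_id = peak_id, factor = factor, chrom = chrom,
             start = summit - half, end = summit + half,
             summit = as.integer(summit), signal = signal, sample = sample,
             stringsAsFactors = FALSE)
}

# Random non-overlapping gene layout on one chromosome.
random_genes <- function(n, seed = 1L, chrom = "chrT",
                         gap_range = 3000:15000) {
  set.seed(seed)
  len <- sample(2000:9000, n, replace = TRUE)
  gap <- sample(gap_range, n, replace = TRUE)
  start <- cumsum(c(10000L, (len + gap)[-n]))
  tx <- data.frame(gene_id = sprintf("R%04d", 1:n),
                   transcript_id = sprintf("R%04d.1", 1:n),
                   chrom = chrom, start = start, end = start + len,
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   stringsAsFactors = FALSE)
  genes_from_tx(tx)
}

# Exhaustive (peak x anchor) assignment oracle: for every peak and gene end,
# keep the nearest in-radius anchor; gene-oriented offset.
oracle_assign <- function(peaks, genes, radius) {
  anch <- genes$anchors
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    for (g in unique(anch$gene_id)) {
      for (kind in c("TSS", "TES")) {
        a <- anch[anch$gene_id == g & anch$end_kind == kind, ]
        if (a$chrom[1] != peaks$chrom[i]) next
        d <- abs(peaks$summit[i] - a$pos)
        if (min(d) > radius) next
        j <- which.min(d)
        off <- if (a$strand[j] == "+") peaks$summit[i] - a$pos[j]
               else a$pos[j] - peaks$summit[i]
        rows[[length(rows) + 1L]] <- data.frame(
          peak_id = peaks$peak_id[i], sample = peaks$sample[i],
          gene_id = g, end_kind = kind, anchor = a$pos[j],
          offset = as.integer(off), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$gene_id, out$end_kind, out$peak_id, out$sample), ]
}

# Independent adjacency + orientation oracle over all ordered gene pairs.
oracle_relations <- function(genes, max_gap) {
  g <- genes$genes
  rows <- list()
  for (i in seq_len(nrow(g))) {
    cand <- which(g$chrom == g$chrom[i] &
                  (g$start > g$start[i] |
                   (g$start == g$start[i] & g$end > g$end[i])))
    if (!length(cand)) next
    j <- cand[order(g$start[cand], g$end[cand])][1]
    end_a <- if (g$strand[i] == "+") "TES" else "TSS"
    end_b <- if (g$strand[j] == "+") "TSS" else "TES"
    pa <- genes$anchors[genes$anchors$gene_id == g$gene_id[i] &
                        genes$anchors$end_kind == end_a, "pos"]
    pb <- genes$anchors[genes$anchors$gene_id == g$gene_id[j] &
                        genes$anchors$end_kind == end_b, "pos"]
    gap <- min(pb) - max(pa)
    if (gap > max_gap) next
    orient <- if (end_a == "TES" && end_b == "TSS") "head_to_tail"
      else if (end_a == "TSS" && end_b == "TES") "head_to_tail"
      else if (end_a == "TSS" && end_b == "TSS") "head_to_head"
      else "tail_to_tail"
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = g$gene_id[i], gene_b = g$gene_id[j],
      orientation = orient, end_gap = gap, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

# Position-rule oracle for region classes.
oracle_region_class <- function(peaks, genes, radius) {
  anch <- genes$anchors
  g <- genes$genes
  vapply(seq_len(nrow(peaks)), function(i) {
    s <- peaks$summit[i]
    if (!peaks$chrom[i] %in% g$chrom) return(NA_character_)
    near <- function(kind) any(abs(s - anch$pos[anch$end_kind == kind &
                                     anch$chrom == peaks$chrom[i]]) <= radius)
    if (near("TSS")) return("TSS")
    if (near("TES")) return("TES")
    inside <- any(g$chrom == peaks$chrom[i] & g$start <= s & s <= g$end)
    if (inside) "intragenic" else "distal"
  }, character(1))
}

# Uniform-tile Poisson coverage for a gene set with planted per-gene
# read-through fractions (tail always covers the downstream window).
sim_coverage <- function(genes, fraction, depth = 100, window = 500L,
                         tile = 50L, tail_extra = 2000L) {
  g <- genes$genes
  lam <- depth * tile / window
  out <- list()
  for (i in seq_len(nrow(g))) {
    starts <- seq(g$start[i], g$end[i] - tile + 1L, by = tile)
    nt <- (window + tail_extra) %/% tile
    tstarts <- if (g$strand[i] == "+")
      seq(g$end[i] + 1L, by = tile, length.out = nt)
    else seq(g$start[i] - tile, by = -tile, length.out = nt)
    st <- c(starts, tstarts)
    va <- c(stats::rpois(length(starts), lam),
            stats::rpois(nt, lam * fraction[i]))
    out[[i]] <- data.frame(chrom = g$chrom[i], start = st,
                           end = st + tile - 1L, value = va,
                           strand = g$strand[i], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# One shared small bundle reused across test files (cheap to build once).
shared_bundle <- local({
  b <- NULL
  function() {
    if (is.null(b)) b <<- simulate_bundle(sim_config(n_genes = 200L,
                                                     seed = 202L),
                                          write = FALSE)
    b
  }
})
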