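#' Compare expression distributions between gene groups
#'
#' All pairwise comparisons between group labels, with the chosen test on
#' log2(expression + pseudocount). Benjamini-Hochberg adjusted p-values are
#' emitted alongside the raw ones. Groups with fewer than two members are
#' skipped with a message.
#'
#' @param expression named numeric vector (gene_id -> expression, TPM-like).
#' @param grouping named character vector (gene_id -> group label).
#' @param test "t_unpaired" (default) or "wilcoxon_ranksum".
#' @param pseudocount added before the log2 transform (default 1).
#' @return data.frame group_a, group_b, n_a, n_b, statistic, p_value, fdr,
#'   test, mean_a, mean_b (means on the log scale).
#' @export
compare_expression <- function(expression, grouping,
                               test = c("t_unpaired", "wilcoxon_ranksum"),
                               pseudocount = 1) {
  test <- match.arg(test)
  common <- intersect(names(expression), names(grouping))
  x <- log2(expression[common] + pseudocount)
  lab <- as.character(grouping[common])
  groups <- sort(unique(lab))
  sizes <- table(lab)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    message("group(s) skipped with < 2 genes: ", paste(small, collapse = ", "))
    groups <- setdiff(groups, small)
  }
  if (length(groups) < 2L) stop("need >= 2 usable groups")
  pairs <- utils::combn(groups, 2L)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- x[lab == pairs[1L, j]]; b <- x[lab == pairs[2L, j]]
    res <- if (test == "t_unpaired") stats::t.test(a, b)
           else stats::wilcox.test(a, b, exact = FALSE)
    data.frame(group_a = pairs[1L, j], group_b = pairs[2L, j],
               n_a = length(a), n_b = length(b),
               statistic = unname(res$statistic), p_value = res$p.value,
               test = test, mean_a = mean(a), mean_b = mean(b),
               stringsAsFactors = FALSE)
  }))
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Binding fractions by gene biotype
#'
#' Per biotype (protein-coding, lncRNA, other): fraction of genes with any
#' 5'-side binding and with any 3'-side binding, plus pairwise chi-squared
#' comparisons of the TES-binding (and TSS-binding) fractions between
#' biotypes. Cells with zero counts fall back to Fisher's exact test and are
#' flagged.
#'
#' @param calls data.frame from [classify_end_binding()].
#' @param genes gene_models object (supplies biotypes).
#' @return list: `fractions` (biotype, n, frac_tss_bound, frac_tes_bound),
#'   `tests` (biotype_a, biotype_b, side, statistic, p_value, method).
#' @export
biotype_binding_fractions <- function(calls, genes) {
  bt <- genes$genes$biotype[match(calls$gene_id, genes$genes$gene_id)]
  bt[is.na(bt) | !bt %in% BIOTYPE_LEVELS] <- "other"
  tss_bound <- calls$state_5p != "none"
  tes_bound <- calls$state_3p != "none"
  fractions <- do.call(rbind, lapply(BIOTYPE_LEVELS, function(b) {
    i <- bt == b
    data.frame(biotype = b, n = sum(i),
               frac_tss_bound = if (any(i)) mean(tss_bound[i]) else NA_real_,
               frac_tes_bound = if (any(i)) mean(tes_bound[i]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  present <- fractions$biotype[fractions$n > 0]
  tests <- NULL
  if (length(present) >= 2L) {
    pairs <- utils::combn(present, 2L)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      do.call(rbind, lapply(c(TSS = "TSS", TES = "TES"), function(side) {
        bound <- if (side == "TSS") tss_bound else tes_bound
        i <- bt %in% pairs[, j]
        tab <- table(factor(bt[i], levels = pairs[, j]),
                     factor(bound[i], levels = c(FALSE, TRUE)))
        if (any(tab == 0L)) {
          ft <- stats::fisher.test(tab)
          data.frame(biotype_a = pairs[1L, j], biotype_b = pairs[2L, j],
                     side = side, statistic = NA_real_, p_value = ft$p.value,
                     method = "fisher_exact", stringsAsFactors = FALSE)
        } else {
          ct <- suppressWarnings(stats::chisq.test(tab))
          data.frame(biotype_a = pairs[1L, j], biotype_b = pairs[2L, j],
                     side = side, statistic = unname(ct$statistic),
                     p_value = ct$p.value, method = "chi_squared",
                     stringsAsFactors = FALSE)
        }
      }))
    }))
    rownames(tests) <- NULL
  }
  list(fractions = fractions, tests = tests)
}
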