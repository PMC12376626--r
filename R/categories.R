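END_STATES <- c("none", "a_only", "b_only", "both")

#' Default 16-category map for two-factor end-binding states
#'
#' Each gene's 5' and 3' binding states (none / factor A only / factor B only /
#' both factors) form 16 pairs, numbered 1-16. With factor A = MYC and
#' factor B = MAX the scheme's defining cells are fixed:
#' 3 = 5'-MYC/3'-MYC, 4 = 5'-MYC/3'-MAX, 7 = 5'-MAX/3'-MAX, 9 = MYC/MAX at 5'
#' only, 10 = 5'-MYC/MAX with 3'-MAX, 10-12 all carry MYC/MAX at the 5' end,
#' 12 = MYC/MAX at both ends, 2/6/13 are TES-only categories, and 16 is the
#' fully unbound state. The remaining cells (1, 2, 5, 6, 8, 11, 13, 14, 15)
#' are not pinned down by those defining constraints; the completion below is a
#' package default, and any bijective map satisfying the constraints can be
#' supplied instead. Downstream code keys on the state pair, never on the
#' integer.
#'
#' @return data.frame with columns state_5p, state_3p (levels none, a_only,
#'   b_only, both) and category (1-16).
#' @export
default_category_map <- function() {
  df <- data.frame(
    state_5p = c("a_only", "none",   "a_only", "a_only",
                 "b_only", "none",   "b_only", "b_only",
                 "both",   "both",   "both",   "both",
                 "none",   "a_only", "b_only", "none"),
    state_3p = c("none",   "a_only", "a_only", "b_only",
                 "none",   "b_only", "b_only", "a_only",
                 "none",   "b_only", "a_only", "both",
                 "both",   "both",   "both",   "none"),
    category = 1:16,
    stringsAsFactors = FALSE)
  df
}

#' Validate a category map against the scheme's defining constraints
#'
#' Checks that the map is a bijection over the 16 state pairs and that every
#' constrained cell holds. Violations raise an error naming the violated
#' constraint.
#'
#' @param map data.frame as from [default_category_map()].
#' @return invisibly TRUE.
#' @export
validate_category_map <- function(map) {
  stopifnot(is.data.frame(map),
            all(c("state_5p", "state_3p", "category") %in% names(map)))
  if (nrow(map) != 16L ||
      anyDuplicated(paste(map$state_5p, map$state_3p)) ||
      anyDuplicated(map$category) ||
      !setequal(map$category, 1:16) ||
      !all(map$state_5p %in% END_STATES) || !all(map$state_3p %in% END_STATES))
    stop("category map must be a bijection between the 16 state pairs and 1:16")
  cell <- function(cat) map[map$category == cat, ]
  chk <- function(cat, s5, s3, label) {
    c0 <- cell(cat)
    if (!is.na(s5) && c0$state_5p != s5 || !is.na(s3) && c0$state_3p != s3)
      stop("category map violates constraint: ", label)
  }
  chk(3L, "a_only", "a_only", "category 3 must be 5'-A / 3'-A")
  chk(4L, "a_only", "b_only", "category 4 must be 5'-A / 3'-B")
  chk(7L, "b_only", "b_only", "category 7 must be 5'-B / 3'-B")
  chk(9L, "both", "none", "category 9 must be A/B at 5' ends only")
  chk(10L, "both", "b_only", "category 10 must be 5'-A/B with 3'-B")
  chk(12L, "both", "both", "category 12 must be A/B at both ends")
  chk(16L, "none", "none", "category 16 must be unbound at both ends")
  for (cat in c(10L, 11L, 12L))
    if (cell(cat)$state_5p != "both")
      stop("category map violates constraint: categories 10-12 must have both factors at the 5' end")
  for (cat in c(2L, 6L, 13L))
    if (cell(cat)$state_5p != "none" || cell(cat)$state_3p == "none")
      stop("category map violates constraint: categories 2, 6 and 13 must be TES-only binding")
  invisible(TRUE)
}

end_state <- function(has_a, has_b) {
  ifelse(has_a & has_b, "both",
         ifelse(has_a, "a_only", ifelse(has_b, "b_only", "none")))
}

#' Classify genes into the 16 end-binding categories
#'
#' Derives, for every gene in the annotation, the 5' and 3' binding states of
#' the two factors from presence/absence of end assignments (peak multiplicity
#' is deliberately ignored) and maps the state pair through the category map.
#'
#' @param assignments data.frame from [assign_peaks()] (typically with the
#'   ambiguity filter OFF, so that shared head-to-tail sites still count for
#'   both genes).
#' @param genes gene_models object; every gene receives a call.
#' @param factor_a,factor_b factor labels (defaults MYC and MAX; any pair
#'   works, e.g. MYCN or MXD-family members).
#' @param category_map bijective state-pair map, validated before use.
#' @param drop_ambiguous drop assignments flagged by [flag_ambiguous()] before
#'   deriving states (default FALSE).
#' @return data.frame gene_id, state_5p, state_3p, category. States are
#'   reported generically (none/a_only/b_only/both).
#' @export
classify_end_binding <- function(assignments, genes,
                                 factor_a = "MYC", factor_b = "MAX",
                                 category_map = default_category_map(),
                                 drop_ambiguous = FALSE) {
  validate_category_map(category_map)
  stopifnot(inherits(genes, "gene_models"))
  a <- assignments
  if (drop_ambiguous && nrow(a)) a <- a[!a$ambiguous, , drop = FALSE]
  gid <- genes$genes$gene_id
  has <- function(fac, kind) {
    gid %in% a$gene_id[a$factor == fac & a$end_kind == kind]
  }
  s5 <- end_state(has(factor_a, "TSS"), has(factor_b, "TSS"))
  s3 <- end_state(has(factor_a, "TES"), has(factor_b, "TES"))
  idx <- match(paste(s5, s3),
               paste(category_map$state_5p, category_map$state_3p))
  data.frame(gene_id = gid, state_5p = s5, state_3p = s3,
             category = category_map$category[idx],
             stringsAsFactors = FALSE)
}

#' Per-category gene counts and fractions
#'
#' @param calls data.frame from [classify_end_binding()].
#' @return data.frame category (1-16, all present), n, fraction; fractions sum
#'   to 1 over the gene universe.
#' @export
category_summary <- function(calls) {
  n <- vapply(1:16, function(k) sum(calls$category == k), integer(1))
  data.frame(category = 1:16, n = n, fraction = n / nrow(calls))
}
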