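#' Score the THYT1 signature for one sample
#'
#' THYT1 combines three alterations: Chr1q duplication, duplication of
#' the TERT locus on 5p, and TERT promoter mutation (C228T/C250T). The
#' occurrence of any one of them defines positivity. Missing flags are
#' distinct from FALSE: a sample with no positive flag and at least one
#' missing flag is indeterminate rather than negative.
#'
#' @param chr1q_dup,tert_dup,tert_mut Logical flags, `NA` = not
#'   assessed.
#' @return List with `status` ("positive", "negative" or
#'   "indeterminate") and `n_alterations` (count of TRUE flags).
#' @export
score_thyt1 <- function(chr1q_dup = NA, tert_dup = NA, tert_mut = NA) {
  flags <- c(chr1q_dup, tert_dup, tert_mut)
  n_alt <- sum(flags, na.rm = TRUE)
  status <- if (isTRUE(any(flags, na.rm = TRUE))) "positive"
            else if (!anyNA(flags)) "negative"
            else "indeterminate"
  list(status = status, n_alterations = n_alt)
}

#' Filter sequencing variants on read support
#'
#' A variant is retained when it is observed on both strands (when
#' required), in at least `min_reads` supporting reads, and in at least
#' `min_fraction` of the total reads at the site.
#'
#' @param records Data.frame with `supporting`, `total`, `forward`,
#'   `reverse` columns.
#' @param min_reads Minimum supporting reads (default 10).
#' @param min_fraction Minimum variant fraction (default 0.05).
#' @param require_both_strands Require support on both strands.
#' @return The retained rows of `records`.
#' @export
filter_variants <- function(records, min_reads = 10L, min_fraction = 0.05,
                            require_both_strands = TRUE) {
  stopifnot(all(c("supporting", "total") %in% names(records)))
  if (any(records$total == 0)) stop("record with zero total reads")
  if (any(records$supporting > records$total)) {
    stop("supporting reads exceed total reads")
  }
  keep <- records$supporting >= min_reads &
    records$supporting / records$total >= min_fraction
  if (require_both_strands) {
    keep <- keep & records$forward & records$reverse
  }
  records[keep, , drop = FALSE]
}

#' Classify microsatellite instability from a marker panel
#'
#' MSS when no marker is unstable; MSI-L when at least one but fewer
#' than `high_fraction` of markers are unstable; MSI-H when the
#' unstable fraction is greater than or equal to `high_fraction`
#' (default 30%).
#'
#' @param panel Logical stability vector (`TRUE` = unstable marker) or
#'   an integer count of unstable markers together with `n_markers`.
#' @param n_markers Panel size when `panel` is a count.
#' @param high_fraction MSI-H threshold on the unstable fraction.
#' @return `"MSS"`, `"MSI-L"` or `"MSI-H"`.
#' @export
classify_msi <- function(panel, n_markers = NULL, high_fraction = 0.30) {
  if (is.logical(panel)) {
    n <- length(panel); u <- sum(panel)
  } else {
    stopifnot(length(panel) == 1L, !is.null(n_markers))
    n <- n_markers; u <- panel
  }
  if (n < 1) stop("empty MSI panel")
  if (u < 0 || u > n) stop("unstable count outside 0..panel size")
  frac <- u / n
  if (u == 0) "MSS" else if (frac >= high_fraction) "MSI-H" else "MSI-L"
}

check_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(2L, 2L)))
  if (any(table < 0) || any(table != round(table))) {
    stop("2x2 table must hold non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("2x2 table has a zero margin")
  }
  invisible(TRUE)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p defined by the usual "probability at most that of the
#' observed table" rule over all tables with the same margins.
#'
#' @param table 2x2 integer matrix (rows = groups, columns =
#'   feature present/absent).
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  check_2x2(table)
  stats::fisher.test(table)$p.value
}

#' Pearson chi-square test on a 2x2 table
#'
#' @param table 2x2 integer matrix.
#' @param yates Apply the Yates continuity correction.
#' @return List with `statistic` and `p` (1 df).
#' @export
chi_square_2x2 <- function(table, yates = FALSE) {
  check_2x2(table)
  ht <- suppressWarnings(stats::chisq.test(table, correct = yates))
  list(statistic = unname(ht$statistic), p = unname(ht$p.value))
}

#' Contingency report for a set of binary features
#'
#' Builds the per-feature counts, percentages and Fisher p comparing
#' two groups, in the layout of a per-feature association table.
#'
#' @param flags Data.frame with a `group` column (two levels) and
#'   logical feature columns (NA allowed = not assessed).
#' @param features Feature column names (default: all logical columns).
#' @param case_level Group level treated as cases (first row).
#' @return Data.frame: feature, per-group n assessed / positive / %,
#'   Fisher p.
#' @export
contingency_report <- function(flags, features = NULL, case_level = "dm") {
  stopifnot("group" %in% names(flags))
  if (is.null(features)) {
    features <- names(flags)[vapply(flags, is.logical, TRUE)]
  }
  groups <- unique(flags$group)
  stopifnot(length(groups) == 2L, case_level %in% groups)
  other <- setdiff(groups, case_level)
  rows <- lapply(features, function(f) {
    x <- flags[[f]]
    ca <- x[flags$group == case_level]; co <- x[flags$group == other]
    ca <- ca[!is.na(ca)]; co <- co[!is.na(co)]
    tab <- matrix(c(sum(ca), sum(!ca), sum(co), sum(!co)), 2L, byrow = TRUE)
    p <- tryCatch(fisher_exact_2x2(tab), error = function(e) NA_real_)
    data.frame(feature = f,
               n_case = length(ca), pos_case = sum(ca),
               pct_case = 100 * mean(ca),
               n_control = length(co), pos_control = sum(co),
               pct_control = 100 * mean(co),
               fisher_p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
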