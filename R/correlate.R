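#' Spearman rank correlation coefficient
#'
#' The co-expression statistic of the workflow: Pearson correlation of
#' mid-ranks (ties receive their average rank). A constant vector has no
#' rank ordering, so correlation against it is undefined and raises an
#' error rather than returning 0 or NA.
#'
#' @param x,y numeric vectors of equal length, at least 3.
#' @return The correlation, in \[-1, 1\].
#' @examples
#' spearman_scc(1:6, c(2, 4, 6, 8, 10, 12))   #  1
#' spearman_scc(1:6, 6:1)                     # -1
#' @export
spearman_scc <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}

# Spearman correlations between rows of a and rows of b (genes x samples),
# computed as Pearson on row-wise mid-ranks. Constant rows give NA.
.spearman_rows <- function(a, b) {
  ra <- t(apply(a, 1L, rank))
  rb <- t(apply(b, 1L, rank))
  if (nrow(a) == 1L) ra <- matrix(ra, nrow = 1L, dimnames = dimnames(a))
  if (nrow(b) == 1L) rb <- matrix(rb, nrow = 1L, dimnames = dimnames(b))
  suppressWarnings(stats::cor(t(ra), t(rb)))
}

.require_ids <- function(ids, mat, what) {
  missing <- setdiff(ids, rownames(mat))
  if (length(missing))
    stop("id(s) absent from ", what, " matrix: ",
         paste(missing, collapse = ", "))
}

#' Correlation filter for predicted miRNA-target pairs
#'
#' Scores every interaction pair by the Spearman correlation between the
#' miRNA and its target across all samples (both conditions pooled) and
#' flags pairs that show the sponge-consistent anti-correlation, strictly
#' below `thresholds$scc_mirna_target_max` (default -0.7). Restricting
#' the pairs to differentially expressed genes is the caller's job
#' ([run_pipeline()] does it).
#'
#' @param pairs interaction data frame (`mirna_id`, `target_id`,
#'   `target_biotype`, ...).
#' @param mirna_expr,target_expr expression matrices with identical
#'   sample columns; all pair ids must be present.
#' @param thresholds a [threshold_config()].
#' @return `pairs` with columns `scc`, `n_samples` and `passed` appended.
#' @export
filter_mirna_targets <- function(pairs, mirna_expr, target_expr,
                                 thresholds = threshold_config()) {
  thresholds <- .as_thresholds(thresholds)
  .check_aligned_samples(mirna_expr, target_expr)
  out <- pairs
  if (!nrow(pairs)) {
    out$scc <- numeric(0); out$n_samples <- integer(0)
    out$passed <- logical(0)
    return(out)
  }
  .require_ids(pairs$mirna_id, mirna_expr, "miRNA expression")
  .require_ids(pairs$target_id, target_expr, "target expression")
  cc <- .spearman_rows(mirna_expr[unique(pairs$mirna_id), , drop = FALSE],
                       target_expr[unique(pairs$target_id), , drop = FALSE])
  out$scc <- cc[cbind(pairs$mirna_id, pairs$target_id)]
  if (anyNA(out$scc))
    warning("undefined correlation (constant expression) for ",
            sum(is.na(out$scc)), " pair(s); marked as not passed")
  out$n_samples <- ncol(mirna_expr)
  out$passed <- !is.na(out$scc) & out$scc < thresholds$scc_mirna_target_max
  rownames(out) <- NULL
  out
}

#' Co-expression screen of candidate lncRNA-mRNA sponge pairs
#'
#' Scores all pairs between differentially expressed lncRNAs and mRNAs
#' and flags those whose Spearman correlation across all samples is
#' strictly above `thresholds$scc_lnc_mrna_min` (default 0.9) -- the
#' positive co-expression expected of two transcripts competing for the
#' same miRNAs.
#'
#' @param del_ids,dem_ids differentially expressed lncRNA / mRNA ids.
#' @param lnc_expr,mrna_expr expression matrices with identical sample
#'   columns covering those ids.
#' @param thresholds a [threshold_config()].
#' @return Data frame `lncrna_id`, `mrna_id`, `scc`, `n_samples`,
#'   `passed`, one row per pair.
#' @export
filter_lnc_mrna <- function(del_ids, dem_ids, lnc_expr, mrna_expr,
                            thresholds = threshold_config()) {
  thresholds <- .as_thresholds(thresholds)
  .check_aligned_samples(lnc_expr, mrna_expr)
  if (!length(del_ids) || !length(dem_ids))
    return(data.frame(lncrna_id = character(0), mrna_id = character(0),
                      scc = numeric(0), n_samples = integer(0),
                      passed = logical(0)))
  .require_ids(del_ids, lnc_expr, "lncRNA expression")
  .require_ids(dem_ids, mrna_expr, "mRNA expression")
  cc <- .spearman_rows(lnc_expr[del_ids, , drop = FALSE],
                       mrna_expr[dem_ids, , drop = FALSE])
  out <- data.frame(
    lncrna_id = rep(del_ids, times = length(dem_ids)),
    mrna_id = rep(dem_ids, each = length(del_ids)),
    scc = as.vector(cc),
    n_samples = ncol(lnc_expr),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$scc))
    warning("undefined correlation (constant expression) for ",
            sum(is.na(out$scc)), " pair(s); marked as not passed")
  out$passed <- !is.na(out$scc) & out$scc > thresholds$scc_lnc_mrna_min
  out
}

.check_aligned_samples <- function(a, b) {
  if (is.null(colnames(a)) || is.null(colnames(b)) ||
      !identical(colnames(a), colnames(b)))
    stop("expression matrices must share identical sample columns")
  invisible(NULL)
}
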