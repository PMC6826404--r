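#' Assemble and test candidate ceRNA triples
#'
#' Third step of the ceRNA construction: for every co-expressed
#' lncRNA-mRNA pair (rows of `lnc_mrna` with `passed = TRUE`), count the
#' miRNAs shared between the lncRNA's and the mRNA's correlation-passed
#' target-miRNA sets and test whether that overlap is larger than chance
#' with [hypergeometric_p()]. The counts entering the test are
#' \describe{
#'   \item{n}{shared passed miRNAs of the pair,}
#'   \item{M}{passed target miRNAs of the lncRNA,}
#'   \item{N}{passed target miRNAs of the mRNA,}
#'   \item{U}{size of the miRNA universe.}
#' }
#' `U` defaults to the number of distinct miRNAs appearing in the
#' supplied miRNA-target records -- the differentially expressed miRNAs
#' that entered the analysis -- and can be overridden (e.g. with the full
#' annotated miRNA complement).
#'
#' One triple is emitted per (lncRNA, shared miRNA, mRNA) combination;
#' the p-value is a property of the pair and is replicated onto each of
#' its triples. A triple is `accepted` when the pair-level p is strictly
#' below `thresholds$cerna_p_max`; no multiple-testing correction is
#' applied to this p by default (`adjust = "none"`), matching the raw-p
#' gate of the original workflow, with `adjust = "BH"` available.
#'
#' @param mirna_lnc,mirna_mrna outputs of [filter_mirna_targets()] for
#'   lncRNA and mRNA targets respectively.
#' @param lnc_mrna output of [filter_lnc_mrna()].
#' @param thresholds a [threshold_config()].
#' @param universe optional integer overriding `U`.
#' @param adjust `"none"` (default) or `"BH"`; with `"BH"` the gate is
#'   applied to adjusted p-values.
#' @return Data frame with columns `lncrna_id`, `mirna_id`, `mrna_id`,
#'   `n`, `M`, `N`, `U`, `p_hyper`, `accepted`.
#' @export
assemble_triples <- function(mirna_lnc, mirna_mrna, lnc_mrna,
                             thresholds = threshold_config(),
                             universe = NULL,
                             adjust = c("none", "BH")) {
  thresholds <- .as_thresholds(thresholds)
  adjust <- match.arg(adjust)
  empty <- data.frame(lncrna_id = character(0), mirna_id = character(0),
                      mrna_id = character(0), n = integer(0), M = integer(0),
                      N = integer(0), U = integer(0), p_hyper = numeric(0),
                      accepted = logical(0))
  U <- universe %||%
    length(unique(c(mirna_lnc$mirna_id, mirna_mrna$mirna_id)))
  pairs <- lnc_mrna[lnc_mrna$passed, , drop = FALSE]
  ml <- mirna_lnc[mirna_lnc$passed, , drop = FALSE]
  mm <- mirna_mrna[mirna_mrna$passed, , drop = FALSE]
  if (!nrow(pairs) || !nrow(ml) || !nrow(mm)) {
    warning("no passed input pairs; empty triple set")
    return(empty)
  }
  mi_of_lnc <- split(ml$mirna_id, ml$target_id)
  mi_of_mrna <- split(mm$mirna_id, mm$target_id)

  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    lnc <- pairs$lncrna_id[i]; mrna <- pairs$mrna_id[i]
    a <- unique(mi_of_lnc[[lnc]] %||% character(0))
    b <- unique(mi_of_mrna[[mrna]] %||% character(0))
    shared <- intersect(a, b)
    if (!length(shared)) return(NULL)
    p <- hypergeometric_p(length(shared), length(a), length(b), U)
    data.frame(lncrna_id = lnc, mirna_id = sort(shared), mrna_id = mrna,
               n = length(shared), M = length(a), N = length(b), U = U,
               p_hyper = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    warning("no lncRNA-mRNA pair shares a passed miRNA; empty triple set")
    return(empty)
  }
  out <- do.call(rbind, rows)
  gate <- if (adjust == "BH") {
    # adjust once per pair, then replicate onto that pair's triples
    key <- paste(out$lncrna_id, out$mrna_id)
    first <- !duplicated(key)
    adj <- stats::p.adjust(out$p_hyper[first], method = "BH")
    adj[match(key, key[first])]
  } else out$p_hyper
  out$accepted <- gate < thresholds$cerna_p_max
  rownames(out) <- NULL
  out
}
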