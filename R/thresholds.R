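#' Analysis thresholds
#'
#' Bundles the cutoffs used along the ceRNA inference workflow. Defaults are
#' the values used in the chicken preadipocyte differentiation study:
#' differential expression at FDR < 0.05 and |log2FC| > 1; miRNA-target
#' anti-correlation at SCC < -0.7; lncRNA-mRNA co-expression at SCC > 0.9;
#' shared-miRNA hypergeometric test at p < 0.05; "highly expressed" miRNAs
#' at mean TPM > 4.5; over-representation at p < 0.05. All comparisons made
#' with these thresholds are strict inequalities.
#'
#' @param fdr_max maximum FDR for a gene to be called differentially
#'   expressed (exclusive bound).
#' @param abs_log2fc_min minimum |log2 fold change| (exclusive bound).
#' @param scc_mirna_target_max Spearman correlation below which a
#'   miRNA-target pair is retained (exclusive; negative).
#' @param scc_lnc_mrna_min Spearman correlation above which a lncRNA-mRNA
#'   pair is retained (exclusive).
#' @param cerna_p_max hypergeometric p-value bound for accepting a ceRNA
#'   pair (exclusive).
#' @param tpm_high mean TPM above which a miRNA counts as highly expressed
#'   (exclusive).
#' @param enrichment_p_max p-value bound for calling a gene set enriched
#'   (exclusive).
#'
#' @return A named list of class `"cerna_thresholds"`.
#' @examples
#' th <- threshold_config()
#' th$scc_lnc_mrna_min
#' @export
threshold_config <- function(fdr_max = 0.05,
                             abs_log2fc_min = 1,
                             scc_mirna_target_max = -0.7,
                             scc_lnc_mrna_min = 0.9,
                             cerna_p_max = 0.05,
                             tpm_high = 4.5,
                             enrichment_p_max = 0.05) {
  th <- list(
    fdr_max = fdr_max,
    abs_log2fc_min = abs_log2fc_min,
    scc_mirna_target_max = scc_mirna_target_max,
    scc_lnc_mrna_min = scc_lnc_mrna_min,
    cerna_p_max = cerna_p_max,
    tpm_high = tpm_high,
    enrichment_p_max = enrichment_p_max
  )
  for (nm in names(th)) {
    v <- th[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("threshold '", nm, "' must be a single finite number")
  }
  for (nm in c("scc_mirna_target_max", "scc_lnc_mrna_min"))
    if (abs(th[[nm]]) > 1)
      stop("threshold '", nm, "' must lie in [-1, 1], got ", th[[nm]])
  for (nm in c("fdr_max", "cerna_p_max", "enrichment_p_max"))
    if (th[[nm]] <= 0 || th[[nm]] > 1)
      stop("threshold '", nm, "' must lie in (0, 1], got ", th[[nm]])
  if (th$abs_log2fc_min < 0)
    stop("threshold 'abs_log2fc_min' must be non-negative")
  structure(th, class = "cerna_thresholds")
}

.as_thresholds <- function(x) {
  if (inherits(x, "cerna_thresholds")) return(x)
  if (is.null(x)) return(threshold_config())
  if (!is.list(x)) stop("thresholds must be a list or cerna_thresholds")
  unknown <- setdiff(names(x), names(formals(threshold_config)))
  if (length(unknown))
    stop("unknown threshold field(s): ", paste(unknown, collapse = ", "))
  do.call(threshold_config, x)
}
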