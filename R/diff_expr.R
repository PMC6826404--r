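#' Differential expression between two conditions
#'
#' Tests every gene of a normalized expression matrix for a difference
#' between the two sample groups and gates calls at the study thresholds
#' (strict FDR < `fdr_max` and |log2FC| > `abs_log2fc_min`). The fold
#' change is always `log2((mean_case + c) / (mean_ctrl + c))` on the
#' normalized scale with pseudocount `c` for stability at 3 replicates.
#'
#' Two p-value backends are available behind the same interface:
#' \describe{
#'   \item{`"moderated"`}{(default) moderated t-statistics from an
#'     empirical-Bayes linear model on `log2(expr + pseudocount)`
#'     (\code{limma}, intensity-trend variance prior). Variance
#'     information is shared across genes, which is what gives usable
#'     power at 3 replicates per group.}
#'   \item{`"welch"`}{per-gene Welch two-sample t-test on the same log2
#'     scale; assumption-light but severely underpowered at n = 3 once
#'     multiple testing is corrected (see the vignette), kept for
#'     sensitivity analyses.}
#' }
#' FDR is Benjamini-Hochberg within the supplied matrix; lncRNA, miRNA
#' and mRNA matrices are intended to be tested as three separate calls.
#'
#' @param expr normalized expression matrix (FPKM or TPM), genes x
#'   samples.
#' @param groups character/factor vector of group labels, either named by
#'   sample id or aligned to `colnames(expr)`; exactly two levels with at
#'   least two replicates each.
#' @param ref the reference (control) group label; defaults to the first
#'   level (first encountered label for character input).
#' @param method p-value backend, `"moderated"` or `"welch"`.
#' @param pseudocount added to normalized expression before log2.
#' @param thresholds a [threshold_config()]; gates `status`.
#' @return Data frame with one row per gene: `gene_id`, `mean_ctrl`,
#'   `mean_case`, `log2FC`, `p_value`, `fdr`, `status` (up/down/ns).
#' @examples
#' d <- generate_dataset(simulation_params(n_lncrna = 30, n_mirna = 10,
#'                                         n_mrna = 30,
#'                                         n_planted_triples = 2,
#'                                         n_planted_de = 5, seed = 2))
#' de <- test_differential(tpm(d$counts$mirna), d$groups)
#' table(de$status)
#' @export
test_differential <- function(expr, groups,
                              ref = NULL,
                              method = c("moderated", "welch"),
                              pseudocount = 1,
                              thresholds = threshold_config()) {
  method <- match.arg(method)
  thresholds <- .as_thresholds(thresholds)
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("'expr' must be a numeric matrix")
  groups <- .align_groups(groups, expr)
  lv <- if (is.factor(groups)) levels(groups) else unique(as.character(groups))
  groups <- as.character(groups)
  if (length(lv) != 2L)
    stop("exactly two groups required, found ", length(lv))
  if (any(table(groups) < 2L))
    stop("each group needs at least 2 replicates")
  ref <- ref %||% lv[1]
  if (!ref %in% lv) stop("reference group '", ref, "' not among labels")
  case <- setdiff(lv, ref)

  ctrl_cols <- groups == ref
  mean_ctrl <- rowMeans(expr[, ctrl_cols, drop = FALSE])
  mean_case <- rowMeans(expr[, !ctrl_cols, drop = FALSE])
  log2fc <- log2((mean_case + pseudocount) / (mean_ctrl + pseudocount))

  y <- log2(expr + pseudocount)
  p <- switch(method,
    moderated = {
      design <- stats::model.matrix(~ factor(groups, levels = c(ref, case)))
      fit <- limma::eBayes(limma::lmFit(y, design), trend = TRUE)
      fit$p.value[, 2]
    },
    welch = apply(y, 1, function(r) {
      a <- r[!ctrl_cols]; b <- r[ctrl_cols]
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        if (mean(a) == mean(b)) 1 else 0
      } else tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
    })
  )
  p <- pmin(pmax(unname(p), 0), 1)
  fdr <- stats::p.adjust(p, method = "BH")
  status <- ifelse(
    fdr < thresholds$fdr_max & log2fc > thresholds$abs_log2fc_min, "up",
    ifelse(fdr < thresholds$fdr_max & log2fc < -thresholds$abs_log2fc_min,
           "down", "ns"))
  data.frame(gene_id = rownames(expr),
             mean_ctrl = unname(mean_ctrl), mean_case = unname(mean_case),
             log2FC = unname(log2fc), p_value = p, fdr = fdr,
             status = status, stringsAsFactors = FALSE, row.names = NULL)
}

.align_groups <- function(groups, mat) {
  if (!is.null(names(groups))) {
    missing <- setdiff(colnames(mat), names(groups))
    if (length(missing))
      stop("no group label for sample(s): ", paste(missing, collapse = ", "))
    groups[colnames(mat)]
  } else {
    if (length(groups) != ncol(mat))
      stop("'groups' must have one label per sample column")
    groups
  }
}

#' Partition differential-expression calls
#'
#' Recomputes up/down calls from a result table at the supplied
#' thresholds (which may differ from those used at test time) and returns
#' the id sets.
#'
#' @param records result of [test_differential()].
#' @param thresholds a [threshold_config()].
#' @return List with character vectors `up`, `down` and `de`
#'   (= union, disjoint by construction).
#' @export
classify_de <- function(records, thresholds = threshold_config()) {
  thresholds <- .as_thresholds(thresholds)
  if (!nrow(records)) {
    warning("empty differential-expression table")
    return(list(up = character(0), down = character(0), de = character(0)))
  }
  sig <- records$fdr < thresholds$fdr_max
  up <- records$gene_id[sig & records$log2FC > thresholds$abs_log2fc_min]
  down <- records$gene_id[sig & records$log2FC < -thresholds$abs_log2fc_min]
  list(up = up, down = down, de = c(up, down))
}
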