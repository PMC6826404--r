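#' Gene-set over-representation analysis
#'
#' Upper-tail hypergeometric test of a query gene list against
#' user-supplied gene sets (e.g. pathway or ontology collections in GMT
#' format): for each set, the probability of observing at least the seen
#' overlap when `n_query` genes are drawn from a background of `N_bg`
#' containing `K` set members. The arithmetic is the same
#' [hypergeometric_p()] used by the shared-miRNA ceRNA test, called with
#' `(n = k, M = K, N = n_query, U = N_bg)`.
#'
#' Sets are intersected with the background before testing. A set is
#' called `significant` when its raw p-value is strictly below
#' `thresholds$enrichment_p_max` (default 0.05), the gate used by the
#' original workflow; the BH-adjusted `fdr` is reported alongside for
#' users who prefer a corrected gate.
#'
#' @param query character vector of gene ids; must be a subset of
#'   `background`.
#' @param gene_sets a data frame from [read_gmt()], or a named list of
#'   member id vectors.
#' @param background character vector of background gene ids (e.g. all
#'   genes tested for differential expression in the relevant biotype).
#' @param thresholds a [threshold_config()].
#' @return Data frame with one row per set: `set_id`, `name`, `k`, `K`,
#'   `n_query`, `N_bg`, `p_value`, `fdr`, `significant`.
#' @export
overrepresentation <- function(query, gene_sets, background,
                               thresholds = threshold_config()) {
  thresholds <- .as_thresholds(thresholds)
  query <- unique(query)
  background <- unique(background)
  outside <- setdiff(query, background)
  if (length(outside))
    stop("query gene(s) not in background: ",
         paste(outside, collapse = ", "))
  if (is.list(gene_sets) && !is.data.frame(gene_sets)) {
    if (is.null(names(gene_sets)))
      stop("'gene_sets' list must be named by set id")
    members <- unname(gene_sets)
    gene_sets <- data.frame(set_id = names(gene_sets),
                            name = names(gene_sets),
                            stringsAsFactors = FALSE)
    gene_sets$members <- I(members)
  }
  if (!is.data.frame(gene_sets) ||
      !all(c("set_id", "name", "members") %in% names(gene_sets)))
    stop("'gene_sets' must be a read_gmt() frame or a named list")
  N_bg <- length(background)
  n_query <- length(query)
  res <- lapply(seq_len(nrow(gene_sets)), function(i) {
    members <- intersect(unique(gene_sets$members[[i]]), background)
    k <- length(intersect(query, members))
    K <- length(members)
    data.frame(set_id = gene_sets$set_id[i], name = gene_sets$name[i],
               k = k, K = K, n_query = n_query, N_bg = N_bg,
               p_value = hypergeometric_p(k, K, n_query, N_bg),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < thresholds$enrichment_p_max
  rownames(out) <- NULL
  out
}
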