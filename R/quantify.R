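.check_count_matrix <- function(counts, what = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'", what, "' must be a numeric matrix (genes x samples)")
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      is.null(colnames(counts)))
    stop("'", what, "' must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids in '", what, "'")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in '", what, "'")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("'", what, "' must be non-negative and finite")
  if (any(counts != round(counts)))
    stop("'", what, "' must contain integer counts")
  invisible(counts)
}

.check_nonzero_columns <- function(counts) {
  zero <- colSums(counts) == 0
  if (any(zero))
    stop("all-zero sample column(s): ",
         paste(colnames(counts)[zero], collapse = ", "),
         " (library size undefined)")
  invisible(counts)
}

#' FPKM normalization
#'
#' Converts raw fragment counts to fragments per kilobase of transcript per
#' million mapped fragments: `FPKM = 1e9 * C / (N * L)`, where `C` is the
#' count for a gene in a sample, `N` the sample's total counts (column sum
#' of the supplied matrix), and `L` the annotated transcript length in
#' bases. Used for lncRNA and mRNA matrices; miRNA tag counts are
#' normalized length-free with [tpm()].
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns. Every column must have a nonzero total.
#' @param annotations data frame with columns `gene_id` and `length_bp`
#'   (positive integers); every row of `counts` must be annotated.
#' @return Numeric matrix of FPKM values with the same dimnames, carrying
#'   attribute `unit = "FPKM"`.
#' @examples
#' m <- matrix(c(100, 0), 2, 1,
#'             dimnames = list(c("g1", "g2"), "s1"))
#' m["g2", 1] <- 1e6 - 100
#' ann <- data.frame(gene_id = c("g1", "g2"), length_bp = c(1000, 1000))
#' fpkm(m, ann)["g1", 1]  # 100
#' @seealso [tpm()]
#' @export
fpkm <- function(counts, annotations) {
  .check_count_matrix(counts)
  .check_nonzero_columns(counts)
  if (!all(c("gene_id", "length_bp") %in% names(annotations)))
    stop("'annotations' needs columns gene_id and length_bp")
  len <- annotations$length_bp[match(rownames(counts), annotations$gene_id)]
  bad <- is.na(len) | len <= 0
  if (any(bad))
    stop("missing or non-positive length for gene(s): ",
         paste(rownames(counts)[bad], collapse = ", "))
  N <- colSums(counts)
  out <- 1e9 * sweep(counts / len, 2, N, "/")
  attr(out, "unit") <- "FPKM"
  out
}

#' TPM normalization for miRNA tag counts
#'
#' Tags per million: `TPM = C / (column total) * 1e6`. Each output column
#' sums to one million (to floating-point tolerance). Transcript length is
#' deliberately not involved: mature miRNA tags are of near-constant
#' length, so depth is the only nuisance scaled out.
#'
#' @param counts integer matrix of tag counts, genes x samples; every
#'   column must have a nonzero total.
#' @return Numeric matrix of TPM values with attribute `unit = "TPM"`.
#' @seealso [fpkm()]
#' @export
tpm <- function(counts) {
  .check_count_matrix(counts)
  .check_nonzero_columns(counts)
  out <- sweep(counts, 2, colSums(counts), "/") * 1e6
  attr(out, "unit") <- "TPM"
  out
}
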