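#' Crucial ceRNA interactions from chicken preadipocyte differentiation
#'
#' The twelve crucial lncRNA-miRNA-mRNA interactions reported for the
#' undifferentiated-vs-differentiated chicken preadipocyte contrast,
#' involving four miRNAs: three with literature support for a role in
#' adipocyte differentiation (gga-miR-128-1-5p, gga-miR-146a-3p,
#' gga-miR-135a-5p) and one selected for being highly connected and
#' highly expressed (gga-miR-6615-3p). Shipped as a small worked-example
#' network for [build_network()], [summarize_network()] and
#' [select_crucial()].
#'
#' @return Data frame with columns `lncrna_id`, `mirna_id`, `mrna_id`
#'   (12 rows).
#' @examples
#' tr <- chicken_crucial_triples()
#' summarize_network(build_network(tr))
#' @export
chicken_crucial_triples <- function() {
  path <- system.file("extdata", "chicken_crucial_cerna_triples.tsv",
                      package = "cernet", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname chicken_crucial_triples
#' @return `chicken_flagged_mirnas()`: the four miRNA ids defining the
#'   crucial interactions.
#' @export
chicken_flagged_mirnas <- function() {
  c("gga-miR-128-1-5p", "gga-miR-146a-3p", "gga-miR-135a-5p",
    "gga-miR-6615-3p")
}
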