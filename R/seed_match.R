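#' Minimal seed-match target prediction
#'
#' A deliberately simple stand-in for dedicated MRE-prediction tools so
#' that synthetic sequences can exercise the pipeline end to end: a
#' miRNA is predicted to target a transcript when the reverse complement
#' of its 7-mer seed (positions 2-8 of the mature miRNA) occurs anywhere
#' in the target sequence. No wobble pairing, no free-energy or context
#' scoring; multiple sites collapse to a single pair, since downstream
#' steps use interactions at pair level only.
#'
#' @param mirna_id id of the miRNA.
#' @param mirna_seq mature miRNA sequence, 5'->3', over A/C/G/U, length
#'   at least 8.
#' @param targets data frame with columns `id`, `biotype` (lncRNA or
#'   mRNA) and `seq` (transcript sequences over A/C/G/U).
#' @return Interaction data frame (`mirna_id`, `target_id`,
#'   `target_biotype`, `source = "seed_match"`), one row per target with
#'   at least one seed site, in input target order.
#' @examples
#' # seed of positions 2-8 is CGAUCGA; its reverse complement is UCGAUCG
#' seed_match_predict("mir-x", "ACGAUCGAUUU",
#'                    data.frame(id = "t1", biotype = "mRNA",
#'                               seq = "AAAUCGAUCGAAA"))
#' @export
seed_match_predict <- function(mirna_id, mirna_seq, targets) {
  .check_rna(mirna_seq, "mirna_seq")
  if (nchar(mirna_seq) < 8L)
    stop("'mirna_seq' must be at least 8 nt to carry a 7-mer seed")
  if (!all(c("id", "biotype", "seq") %in% names(targets)))
    stop("'targets' needs columns id, biotype, seq")
  bad_bt <- !targets$biotype %in% c("lncRNA", "mRNA")
  if (any(bad_bt))
    stop("invalid target biotype in row(s) ",
         paste(which(bad_bt), collapse = ", "))
  for (s in targets$seq) .check_rna(s, "target seq")
  seed <- substr(toupper(mirna_seq), 2L, 8L)
  site <- .rna_revcomp(seed)
  hit <- vapply(targets$seq,
                function(s) grepl(site, toupper(s), fixed = TRUE),
                logical(1), USE.NAMES = FALSE)
  data.frame(mirna_id = rep(mirna_id, sum(hit)),
             target_id = targets$id[hit],
             target_biotype = targets$biotype[hit],
             source = rep("seed_match", sum(hit)),
             stringsAsFactors = FALSE)
}

.check_rna <- function(s, what) {
  if (!is.character(s) || length(s) != 1L || is.na(s))
    stop("'", what, "' must be a single string")
  if (grepl("[^ACGUacgu]", s))
    stop("'", what, "' contains characters outside the RNA alphabet A/C/G/U")
  invisible(s)
}

.rna_revcomp <- function(s) {
  chartr("ACGU", "UGCA",
         paste(rev(strsplit(toupper(s), "")[[1]]), collapse = ""))
}
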