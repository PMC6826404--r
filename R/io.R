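.write_tsv <- function(df, path, row_names = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
}

#' Read / write a count matrix in the package TSV dialect
#'
#' Tab-delimited, UTF-8; first column `gene_id`, remaining columns one per
#' sample with the sample id in the header row.
#'
#' @param path file path.
#' @return `read_counts()`: an integer matrix with gene ids as rownames
#'   and sample ids as colnames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id")
    stop("first column of ", path, " must be 'gene_id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  .check_count_matrix(m)
  m
}

#' @rdname read_counts
#' @param counts integer matrix, genes x samples.
#' @export
write_counts <- function(counts, path) {
  .check_count_matrix(counts)
  df <- data.frame(gene_id = rownames(counts) %||% character(0), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
  invisible(path)
}

#' Read a sample-to-group map
#'
#' Two-column TSV (`sample_id`, `group`); exactly two distinct groups.
#'
#' @param path file path.
#' @return Named character vector mapping sample id to group label.
#' @export
read_samples <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("sample map needs columns sample_id and group")
  if (length(unique(df$group)) != 2L)
    stop("sample map must define exactly two groups, found ",
         length(unique(df$group)))
  setNames(df$group, df$sample_id)
}

#' Read gene annotations
#'
#' TSV with columns `gene_id`, `biotype` (lncRNA / miRNA / mRNA) and
#' `length_bp` (empty for miRNA).
#'
#' @param path file path.
#' @return Data frame with the three columns.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "biotype", "length_bp")
  if (!all(need %in% names(df)))
    stop("annotation file needs columns ", paste(need, collapse = ", "))
  bad <- !df$biotype %in% c("lncRNA", "miRNA", "mRNA")
  if (any(bad))
    stop("unknown biotype in annotation row(s) ",
         paste(which(bad), collapse = ", "))
  df$length_bp <- as.integer(df$length_bp)
  if (any(!is.na(df$length_bp) & df$length_bp <= 0))
    stop("annotation length_bp must be positive where present")
  df[need]
}

#' Read predicted miRNA-target interactions
#'
#' TSV with columns `mirna_id`, `target_id`, `target_biotype` (lncRNA or
#' mRNA) and optionally `source`. Stands in for merged output of MRE
#' prediction tools; duplicate (miRNA, target) pairs are dropped with a
#' warning, and rows with any other biotype are rejected.
#'
#' @param path file path.
#' @return Deduplicated data frame of interaction pairs.
#' @export
read_interactions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna_id", "target_id", "target_biotype")
  if (!all(need %in% names(df)))
    stop("interaction file needs columns ", paste(need, collapse = ", "))
  bad <- !df$target_biotype %in% c("lncRNA", "mRNA")
  if (any(bad))
    stop("invalid target_biotype in row(s) ",
         paste(which(bad), collapse = ", "),
         " of ", path, " (must be lncRNA or mRNA)")
  if (!"source" %in% names(df)) df$source <- rep("file", nrow(df))
  dup <- duplicated(df[c("mirna_id", "target_id")])
  if (any(dup)) {
    warning(sum(dup), " duplicate interaction pair(s) dropped")
    df <- df[!dup, ]
  }
  rownames(df) <- NULL
  df[c(need, "source")]
}

#' @rdname read_interactions
#' @param interactions data frame of interaction pairs.
#' @export
write_interactions <- function(interactions, path) {
  .write_tsv(interactions, path)
  invisible(path)
}

#' Write a simulated dataset to disk as plain-text fixtures
#'
#' Writes count matrices, the sample map, annotations, interactions and
#' the truth sidecar (JSON) into `out_dir`. The files round-trip
#' losslessly through [read_fixture()].
#'
#' @param dataset a `"cerna_dataset"` from [generate_dataset()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_fixture <- function(dataset, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  paths <- c(
    lncrna_counts = file.path(out_dir, "lncrna_counts.tsv"),
    mirna_counts = file.path(out_dir, "mirna_counts.tsv"),
    mrna_counts = file.path(out_dir, "mrna_counts.tsv"),
    samples = file.path(out_dir, "samples.tsv"),
    annotations = file.path(out_dir, "annotations.tsv"),
    interactions = file.path(out_dir, "interactions.tsv"),
    truth = file.path(out_dir, "truth.json")
  )
  write_counts(dataset$counts$lncrna, paths["lncrna_counts"])
  write_counts(dataset$counts$mirna, paths["mirna_counts"])
  write_counts(dataset$counts$mrna, paths["mrna_counts"])
  .write_tsv(data.frame(sample_id = names(dataset$groups),
                        group = unname(dataset$groups)), paths["samples"])
  .write_tsv(dataset$annotations, paths["annotations"])
  .write_tsv(dataset$interactions, paths["interactions"])
  jsonlite::write_json(dataset$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' @rdname write_fixture
#' @param dir directory previously written by [write_fixture()].
#' @return `read_fixture()`: the reconstructed `"cerna_dataset"`.
#' @export
read_fixture <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  truth$library_sizes <- lapply(truth$library_sizes, unlist)
  if (is.null(truth$planted_triples) || !length(truth$planted_triples))
    truth$planted_triples <- data.frame(lncrna_id = character(0),
                                        mirna_id = character(0),
                                        mrna_id = character(0))
  if (is.null(truth$planted_de) || !length(truth$planted_de))
    truth$planted_de <- data.frame(gene_id = character(0),
                                   direction = character(0))
  structure(list(
    counts = list(lncrna = read_counts(file.path(dir, "lncrna_counts.tsv")),
                  mirna = read_counts(file.path(dir, "mirna_counts.tsv")),
                  mrna = read_counts(file.path(dir, "mrna_counts.tsv"))),
    groups = read_samples(file.path(dir, "samples.tsv")),
    annotations = read_annotations(file.path(dir, "annotations.tsv")),
    interactions = read_interactions(file.path(dir, "interactions.tsv")),
    truth = truth
  ), class = "cerna_dataset")
}

#' Read gene sets in GMT format
#'
#' One set per line: set id, description, then member genes, all
#' tab-separated. Duplicate members within a set are dropped.
#'
#' @param path file path.
#' @return Data frame with columns `set_id`, `name`, and list-column
#'   `members`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3L
  if (any(short))
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(which(short), collapse = ", "))
  df <- data.frame(set_id = vapply(parts, `[[`, "", 1L),
                   name = vapply(parts, `[[`, "", 2L),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$set_id)) stop("duplicate set ids in ", path)
  df$members <- I(lapply(parts, function(x) unique(x[-(1:2)])))
  df
}
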