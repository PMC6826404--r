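#' Build the tripartite ceRNA network
#'
#' Turns accepted ceRNA triples into an undirected graph with two edge
#' classes, lncRNA-miRNA (`lnc_mi`) and miRNA-mRNA (`mi_mrna`); lncRNAs
#' and mRNAs are linked only through their shared miRNAs, never directly.
#' Edges are deduplicated, so a miRNA appearing in several triples with
#' the same partner contributes one edge, and node degree is counted on
#' that deduplicated edge set (NetworkAnalyzer semantics). The average
#' degree is `2 * |edges| / |nodes|`.
#'
#' @param triples data frame as from [assemble_triples()] (or any frame
#'   with `lncrna_id`, `mirna_id`, `mrna_id`); if an `accepted` column is
#'   present, only accepted rows are used unless `accepted_only = FALSE`.
#' @param accepted_only use only accepted triples (default TRUE).
#' @return An object of class `"cerna_network"`: list with `nodes`
#'   (data frame `id`, `biotype`, `degree`), `edges` (data frame `from`,
#'   `to`, `type`), `avg_degree`, and the originating `triples`.
#' @examples
#' tr <- data.frame(lncrna_id = "l1", mirna_id = "m1", mrna_id = "g1")
#' net <- build_network(tr)
#' net$avg_degree   # 2 edges, 3 nodes -> 4/3
#' @export
build_network <- function(triples, accepted_only = TRUE) {
  if (accepted_only && "accepted" %in% names(triples))
    triples <- triples[triples$accepted, , drop = FALSE]
  triples <- triples[!duplicated(triples[c("lncrna_id", "mirna_id", "mrna_id")]), ,
                     drop = FALSE]
  if (!nrow(triples)) {
    warning("no (accepted) triples; empty network")
    return(structure(list(
      nodes = data.frame(id = character(0), biotype = character(0),
                         degree = integer(0)),
      edges = data.frame(from = character(0), to = character(0),
                         type = character(0)),
      avg_degree = NaN, triples = triples), class = "cerna_network"))
  }
  edges <- unique(rbind(
    data.frame(from = triples$lncrna_id, to = triples$mirna_id,
               type = "lnc_mi", stringsAsFactors = FALSE),
    data.frame(from = triples$mirna_id, to = triples$mrna_id,
               type = "mi_mrna", stringsAsFactors = FALSE)
  ))
  edges <- edges[order(edges$type, edges$from, edges$to), ]
  rownames(edges) <- NULL
  nodes <- unique(rbind(
    data.frame(id = triples$lncrna_id, biotype = "lncRNA",
               stringsAsFactors = FALSE),
    data.frame(id = triples$mirna_id, biotype = "miRNA",
               stringsAsFactors = FALSE),
    data.frame(id = triples$mrna_id, biotype = "mRNA",
               stringsAsFactors = FALSE)
  ))
  nodes <- nodes[order(nodes$biotype, nodes$id), ]
  rownames(nodes) <- NULL
  deg <- table(c(edges$from, edges$to))
  nodes$degree <- as.integer(deg[nodes$id])
  rownames(triples) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 avg_degree = 2 * nrow(edges) / nrow(nodes),
                 triples = triples),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  s <- summarize_network(x)
  cat(sprintf(
    "cerna_network: %d triples | %d lncRNAs, %d miRNAs, %d mRNAs | %d edges | avg degree %.3g\n",
    s$n_triples, s$n_lncrna, s$n_mirna, s$n_mrna, s$n_edges, s$avg_degree))
  invisible(x)
}

#' Summarize a ceRNA network
#'
#' @param net a `"cerna_network"`.
#' @return Data frame (one row) with distinct counts per biotype, node,
#'   edge and triple counts, and the average degree.
#' @export
summarize_network <- function(net) {
  stopifnot(inherits(net, "cerna_network"))
  bt <- table(factor(net$nodes$biotype, c("lncRNA", "miRNA", "mRNA")))
  data.frame(n_lncrna = as.integer(bt["lncRNA"]),
             n_mirna = as.integer(bt["miRNA"]),
             n_mrna = as.integer(bt["mRNA"]),
             n_nodes = nrow(net$nodes),
             n_edges = nrow(net$edges),
             n_triples = nrow(net$triples),
             avg_degree = net$avg_degree,
             row.names = NULL)
}

#' Highly connected nodes
#'
#' Nodes whose degree strictly exceeds the network's average degree
#' (recomputed from the network at hand; the average is a property of
#' each network, not a fixed constant).
#'
#' @param net a `"cerna_network"`.
#' @return Character vector of hub node ids (sorted).
#' @export
identify_hubs <- function(net) {
  stopifnot(inherits(net, "cerna_network"))
  if (!nrow(net$nodes)) return(character(0))
  sort(net$nodes$id[net$nodes$degree > net$avg_degree])
}

#' Select crucial ceRNA interactions
#'
#' A triple is crucial when its miRNA is either literature-flagged
#' (`flagged_mirnas`) or automatically selected as simultaneously highly
#' connected (degree strictly above the network average) and highly
#' expressed (mean TPM across all samples strictly above
#' `thresholds$tpm_high`, default 4.5).
#'
#' @param net a `"cerna_network"`.
#' @param mirna_tpm TPM matrix covering the network's miRNAs.
#' @param flagged_mirnas character vector of miRNA ids flagged from the
#'   literature; ids absent from the network are dropped with a warning.
#' @param thresholds a [threshold_config()].
#' @return List with `flagged_mirnas`, `auto_mirnas` and
#'   `crucial_triples` (subset of `net$triples`).
#' @export
select_crucial <- function(net, mirna_tpm, flagged_mirnas = character(0),
                           thresholds = threshold_config()) {
  stopifnot(inherits(net, "cerna_network"))
  thresholds <- .as_thresholds(thresholds)
  mi_nodes <- net$nodes[net$nodes$biotype == "miRNA", , drop = FALSE]
  absent <- setdiff(flagged_mirnas, mi_nodes$id)
  if (length(absent)) {
    warning("flagged miRNA(s) not in network, ignored: ",
            paste(absent, collapse = ", "))
    flagged_mirnas <- setdiff(flagged_mirnas, absent)
  }
  auto <- character(0)
  if (nrow(mi_nodes)) {
    .require_ids(mi_nodes$id, mirna_tpm, "miRNA TPM")
    mean_tpm <- rowMeans(mirna_tpm[mi_nodes$id, , drop = FALSE])
    auto <- mi_nodes$id[mi_nodes$degree > net$avg_degree &
                          mean_tpm > thresholds$tpm_high]
  }
  keep <- union(flagged_mirnas, auto)
  list(flagged_mirnas = sort(flagged_mirnas),
       auto_mirnas = sort(auto),
       crucial_triples = net$triples[net$triples$mirna_id %in% keep, ,
                                     drop = FALSE])
}

#' Export / import a ceRNA network
#'
#' Writes the network as Cytoscape SIF (`source interaction target`, with
#' interaction `lnc_mi` or `mi_mrna`) plus node and edge TSV tables, in
#' deterministic lexicographic order so repeated exports are
#' byte-identical. [read_sif()] rebuilds nodes, edges and degrees from a
#' SIF file (triple provenance is not representable in SIF and comes back
#' empty).
#'
#' @param net a `"cerna_network"`.
#' @param out_dir output directory (created if needed).
#' @param formats any of `"sif"`, `"edges"`, `"nodes"`.
#' @return Invisibly, the written paths.
#' @export
export_network <- function(net, out_dir,
                           formats = c("sif", "edges", "nodes")) {
  stopifnot(inherits(net, "cerna_network"))
  bad <- setdiff(formats, c("sif", "edges", "nodes"))
  if (length(bad))
    stop("unknown export format(s): ", paste(bad, collapse = ", "))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  paths <- character(0)
  if ("sif" %in% formats) {
    p <- file.path(out_dir, "network.sif")
    writeLines(sprintf("%s\t%s\t%s", net$edges$from, net$edges$type,
                       net$edges$to), p)
    paths["sif"] <- p
  }
  if ("edges" %in% formats) {
    p <- file.path(out_dir, "edges.tsv")
    .write_tsv(net$edges, p)
    paths["edges"] <- p
  }
  if ("nodes" %in% formats) {
    p <- file.path(out_dir, "nodes.tsv")
    nodes <- net$nodes
    nodes$hub <- nodes$id %in% identify_hubs(net)
    .write_tsv(nodes, p)
    paths["nodes"] <- p
  }
  invisible(paths)
}

#' @rdname export_network
#' @param path a SIF file written by [export_network()].
#' @export
read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(build_network(data.frame(lncrna_id = character(0),
                                    mirna_id = character(0),
                                    mrna_id = character(0))))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("malformed SIF line(s): ",
         paste(which(lengths(parts) != 3L), collapse = ", "))
  edges <- data.frame(from = vapply(parts, `[[`, "", 1L),
                      type = vapply(parts, `[[`, "", 2L),
                      to = vapply(parts, `[[`, "", 3L),
                      stringsAsFactors = FALSE)
  bad <- !edges$type %in% c("lnc_mi", "mi_mrna")
  if (any(bad))
    stop("unknown interaction type(s): ",
         paste(unique(edges$type[bad]), collapse = ", "))
  edges <- unique(edges[, c("from", "to", "type")])
  edges <- edges[order(edges$type, edges$from, edges$to), ]
  rownames(edges) <- NULL
  nodes <- unique(rbind(
    data.frame(id = edges$from[edges$type == "lnc_mi"], biotype = "lncRNA"),
    data.frame(id = c(edges$to[edges$type == "lnc_mi"],
                      edges$from[edges$type == "mi_mrna"]),
               biotype = "miRNA"),
    data.frame(id = edges$to[edges$type == "mi_mrna"], biotype = "mRNA")
  ))
  nodes <- nodes[order(nodes$biotype, nodes$id), ]
  rownames(nodes) <- NULL
  deg <- table(c(edges$from, edges$to))
  nodes$degree <- as.integer(deg[nodes$id])
  structure(list(nodes = nodes, edges = edges,
                 avg_degree = 2 * nrow(edges) / nrow(nodes),
                 triples = data.frame(lncrna_id = character(0),
                                      mirna_id = character(0),
                                      mrna_id = character(0))),
            class = "cerna_network")
}
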