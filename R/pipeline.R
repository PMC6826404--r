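#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes an equivalent nested list), checks it, and
#' fills defaults. A configuration must provide exactly one input mode:
#' \describe{
#'   \item{`simulation`}{a list of [simulation_params()] fields, or an
#'     empty map for the defaults;}
#'   \item{`inputs`}{paths to `lncrna_counts`, `mirna_counts`,
#'     `mrna_counts`, `samples`, `annotations`, `interactions` files in
#'     the package TSV dialect.}
#' }
#' Optional keys: `thresholds` (fields of [threshold_config()]),
#' `flagged_mirnas` (character), `gene_sets` (GMT path, enables the
#' enrichment stage), `de_method` (`"moderated"` or `"welch"`), `seed`
#' (integer, default 1; also the default simulation seed), `out_dir`.
#' Unknown keys at either level are rejected with the offending key path.
#'
#' @param config path to a YAML file, or a list.
#' @return A validated list of class `"pipeline_config"`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || !length(config))
    stop("config must be a non-empty mapping")
  known <- c("simulation", "inputs", "thresholds", "flagged_mirnas",
             "gene_sets", "de_method", "seed", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  has_sim <- "simulation" %in% names(config)
  has_in <- "inputs" %in% names(config)
  if (has_sim == has_in)
    stop("config must provide exactly one of 'simulation' or 'inputs'")
  config$seed <- config$seed %||% 1L
  if (!is.numeric(config$seed) || config$seed != round(config$seed))
    stop("config key 'seed' must be an integer")
  config$seed <- as.integer(config$seed)
  if (has_sim) {
    sim <- config$simulation %||% list()
    unknown <- setdiff(names(sim), names(formals(simulation_params)))
    if (length(unknown))
      stop("unknown config key(s): ",
           paste(paste0("simulation.", unknown), collapse = ", "))
    if (is.null(sim$seed)) sim$seed <- config$seed
    config$simulation <- do.call(simulation_params, sim)
  } else {
    need <- c("lncrna_counts", "mirna_counts", "mrna_counts", "samples",
              "annotations", "interactions")
    missing <- setdiff(need, names(config$inputs))
    if (length(missing))
      stop("config 'inputs' missing key(s): ",
           paste(paste0("inputs.", missing), collapse = ", "))
    unknown <- setdiff(names(config$inputs), need)
    if (length(unknown))
      stop("unknown config key(s): ",
           paste(paste0("inputs.", unknown), collapse = ", "))
    for (k in need)
      if (!file.exists(config$inputs[[k]]))
        stop("config inputs.", k, ": file not found: ", config$inputs[[k]])
  }
  config$thresholds <- tryCatch(.as_thresholds(config$thresholds),
                                error = function(e)
                                  stop("config key 'thresholds': ",
                                       conditionMessage(e), call. = FALSE))
  config$flagged_mirnas <- as.character(config$flagged_mirnas %||% character(0))
  config$de_method <- match.arg(config$de_method %||% "moderated",
                                c("moderated", "welch"))
  if (!is.null(config$gene_sets) && !file.exists(config$gene_sets))
    stop("config key 'gene_sets': file not found: ", config$gene_sets)
  structure(config, class = "pipeline_config")
}

#' Run the full ceRNA inference pipeline
#'
#' Orchestrates input (simulation or file ingestion), FPKM/TPM
#' quantification, differential expression, correlation filtering, the
#' hypergeometric shared-miRNA test, network construction with hub and
#' crucial-interaction selection, and (when gene sets are configured)
#' over-representation analysis. Every stage writes its TSV outputs under
#' `out_dir`, and a `manifest.json` records the package version, seed,
#' thresholds and the MD5 of every written file; a rerun with the same
#' configuration is byte-identical.
#'
#' @param config a [validate_config()] result, a config list, or a YAML
#'   path.
#' @param out_dir output directory; overrides `config$out_dir`.
#' @return Invisibly, a list with all intermediate objects (`dataset`,
#'   `expr`, `de`, `de_sets`, `mirna_lnc`, `mirna_mrna`, `lnc_mrna`,
#'   `triples`, `network`, `summary`, `hubs`, `crucial`, `enrichment`,
#'   `manifest`).
#' @examples
#' \donttest{
#' cfg <- list(simulation = list(n_lncrna = 40, n_mirna = 20, n_mrna = 60,
#'                               n_planted_triples = 4, n_planted_de = 6),
#'             seed = 1)
#' res <- run_pipeline(cfg, out_dir = tempfile("cernet"))
#' res$summary
#' }
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("no output directory configured")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  th <- config$thresholds
  manifest_files <- list()
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  record <- function(stage_name, paths) {
    manifest_files[[stage_name]] <<- as.list(unname(
      vapply(paths, function(p) unname(tools::md5sum(p)), character(1))))
    names(manifest_files[[stage_name]]) <<- basename(unlist(paths))
  }

  # -- input ----------------------------------------------------------
  dataset <- stage("input", function() {
    if (!is.null(config$simulation)) {
      ds <- generate_dataset(config$simulation)
      write_fixture(ds, file.path(out_dir, "input"))
      ds
    } else {
      inp <- config$inputs
      structure(list(
        counts = list(lncrna = read_counts(inp$lncrna_counts),
                      mirna = read_counts(inp$mirna_counts),
                      mrna = read_counts(inp$mrna_counts)),
        groups = read_samples(inp$samples),
        annotations = read_annotations(inp$annotations),
        interactions = read_interactions(inp$interactions),
        truth = NULL), class = "cerna_dataset")
    }
  })
  if (!is.null(config$simulation))
    record("input", list.files(file.path(out_dir, "input"),
                               full.names = TRUE))

  # -- quantify -------------------------------------------------------
  expr <- stage("quantify", function() {
    ann <- dataset$annotations
    e <- list(lncrna = fpkm(dataset$counts$lncrna,
                            ann[ann$biotype == "lncRNA", ]),
              mirna = tpm(dataset$counts$mirna),
              mrna = fpkm(dataset$counts$mrna, ann[ann$biotype == "mRNA", ]))
    for (bt in names(e)) {
      unit <- attr(e[[bt]], "unit")
      df <- data.frame(gene_id = rownames(e[[bt]]), e[[bt]],
                       check.names = FALSE)
      .write_tsv(df, file.path(out_dir, sprintf("%s_%s.tsv", bt,
                                                tolower(unit))))
    }
    e
  })
  record("quantify", file.path(out_dir, c("lncrna_fpkm.tsv",
                                          "mirna_tpm.tsv",
                                          "mrna_fpkm.tsv")))

  # -- differential expression ---------------------------------------
  de <- stage("differential_expression", function() {
    lapply(expr, function(m)
      test_differential(m, dataset$groups, ref = "undifferentiated",
                        method = config$de_method, thresholds = th))
  })
  biotype_label <- c(lncrna = "lncRNA", mirna = "miRNA", mrna = "mRNA")
  for (bt in names(de)) {
    df <- de[[bt]]
    df$biotype <- biotype_label[[bt]]
    .write_tsv(df[c("gene_id", "biotype", "log2FC", "p_value", "fdr",
                    "status")],
               file.path(out_dir, sprintf("de_%s.tsv", bt)))
  }
  record("differential_expression",
         file.path(out_dir, sprintf("de_%s.tsv", names(de))))
  de_sets <- lapply(de, classify_de, thresholds = th)

  # -- correlation filters -------------------------------------------
  corr <- stage("correlate", function() {
    demi <- de_sets$mirna$de
    ia <- dataset$interactions
    ia_lnc <- ia[ia$target_biotype == "lncRNA" & ia$mirna_id %in% demi &
                   ia$target_id %in% de_sets$lncrna$de, , drop = FALSE]
    ia_mrna <- ia[ia$target_biotype == "mRNA" & ia$mirna_id %in% demi &
                    ia$target_id %in% de_sets$mrna$de, , drop = FALSE]
    list(
      mirna_lnc = filter_mirna_targets(ia_lnc, expr$mirna, expr$lncrna, th),
      mirna_mrna = filter_mirna_targets(ia_mrna, expr$mirna, expr$mrna, th),
      lnc_mrna = filter_lnc_mrna(de_sets$lncrna$de, de_sets$mrna$de,
                                 expr$lncrna, expr$mrna, th)
    )
  })
  .write_tsv(corr$mirna_lnc, file.path(out_dir, "scc_mirna_lncrna.tsv"))
  .write_tsv(corr$mirna_mrna, file.path(out_dir, "scc_mirna_mrna.tsv"))
  .write_tsv(corr$lnc_mrna, file.path(out_dir, "scc_lncrna_mrna.tsv"))
  record("correlate", file.path(out_dir, c("scc_mirna_lncrna.tsv",
                                           "scc_mirna_mrna.tsv",
                                           "scc_lncrna_mrna.tsv")))

  # -- ceRNA test -----------------------------------------------------
  triples <- stage("cerna", function() {
    suppressWarnings(assemble_triples(corr$mirna_lnc, corr$mirna_mrna,
                                      corr$lnc_mrna, th))
  })
  .write_tsv(triples, file.path(out_dir, "cerna_triples.tsv"))
  record("cerna", file.path(out_dir, "cerna_triples.tsv"))

  # -- network --------------------------------------------------------
  net <- stage("network", function()
    suppressWarnings(build_network(triples)))
  net_paths <- export_network(net, out_dir)
  summary_df <- summarize_network(net)
  .write_tsv(summary_df, file.path(out_dir, "network_summary.tsv"))
  hubs <- identify_hubs(net)
  writeLines(hubs, file.path(out_dir, "hubs.txt"))
  record("network", c(unname(net_paths),
                      file.path(out_dir, c("network_summary.tsv",
                                           "hubs.txt"))))

  # -- crucial interactions ------------------------------------------
  crucial <- stage("crucial", function()
    select_crucial(net, expr$mirna, config$flagged_mirnas, th))
  .write_tsv(crucial$crucial_triples,
             file.path(out_dir, "crucial_triples.tsv"))
  writeLines(sort(union(crucial$flagged_mirnas, crucial$auto_mirnas)),
             file.path(out_dir, "crucial_mirnas.txt"))
  record("crucial", file.path(out_dir, c("crucial_triples.tsv",
                                         "crucial_mirnas.txt")))

  # -- enrichment (optional) -----------------------------------------
  enrichment <- NULL
  if (!is.null(config$gene_sets)) {
    enrichment <- stage("enrichment", function() {
      sets <- read_gmt(config$gene_sets)
      query <- net$nodes$id[net$nodes$biotype == "mRNA"]
      background <- rownames(dataset$counts$mrna)
      overrepresentation(query, sets, background, th)
    })
    .write_tsv(enrichment, file.path(out_dir, "enrichment.tsv"))
    record("enrichment", file.path(out_dir, "enrichment.tsv"))
  }

  manifest <- list(
    package = "cernet",
    version = as.character(utils::packageVersion("cernet")),
    seed = config$seed,
    de_method = config$de_method,
    thresholds = unclass(th),
    flagged_mirnas = config$flagged_mirnas,
    stages = manifest_files
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(dataset = dataset, expr = expr, de = de,
                 de_sets = de_sets,
                 mirna_lnc = corr$mirna_lnc, mirna_mrna = corr$mirna_mrna,
                 lnc_mrna = corr$lnc_mrna, triples = triples,
                 network = net, summary = summary_df, hubs = hubs,
                 crucial = crucial, enrichment = enrichment,
                 manifest = manifest))
}
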