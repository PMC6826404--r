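#' Parameters for the two-condition ceRNA simulator
#'
#' Collects and validates the knobs of [generate_dataset()]. Defaults
#' emulate a two-condition preadipocyte differentiation contrast
#' (undifferentiated vs differentiated, three biological replicates each)
#' with a planted ceRNA signal strong enough to meet the operational
#' sponge definition used downstream (SCC filters at -0.7/0.9).
#'
#' @param n_lncrna,n_mirna,n_mrna number of genes per biotype.
#' @param n_samples_per_group biological replicates per condition.
#' @param n_planted_triples number of true ceRNA triples to plant; the
#'   three members of a triple are drawn without replacement, so it must
#'   not exceed `min(n_lncrna, n_mirna, n_mrna)`.
#' @param n_planted_de additional differentially expressed genes planted
#'   per biotype (beyond triple members), with random direction.
#' @param de_log2fc planted effect size in log2 units (> 0). Triple
#'   members move by this amount between conditions, the miRNA opposite
#'   to its lncRNA and mRNA partners.
#' @param nb_dispersion negative-binomial dispersion (> 0); counts are
#'   NB(mu, size = 1/dispersion).
#' @param baseline_mean typical baseline count per gene; per-gene baseline
#'   means are log-normal around this value (sdlog 0.5).
#' @param triple_coupling strength in (0, 1] of the shared per-sample
#'   latent state coupling the three members of a planted triple (Gaussian
#'   copula correlation; 1 = comonotone). See the package vignette for why
#'   the default is 1.
#' @param decoy_interactions_per_mirna decoy miRNA-target edges per miRNA,
#'   assigned to random non-triple targets; these are what the correlation
#'   filter must reject.
#' @param gene_length_range interval (bp) from which lncRNA and mRNA
#'   transcript lengths are drawn uniformly; miRNAs carry no length.
#' @param library_size_range interval of per-sample relative depth factors
#'   (multiplying all gene means in a sample); realized library sizes are
#'   recorded in the generated truth.
#' @param seed integer seed; identical parameters give byte-identical
#'   datasets.
#'
#' @return A validated list of class `"simulation_params"`.
#' @examples
#' p <- simulation_params(n_lncrna = 20, n_mirna = 10, n_mrna = 30,
#'                        n_planted_triples = 2, seed = 1)
#' @export
simulation_params <- function(n_lncrna = 200,
                              n_mirna = 100,
                              n_mrna = 500,
                              n_samples_per_group = 3,
                              n_planted_triples = 20,
                              n_planted_de = 30,
                              de_log2fc = 2,
                              nb_dispersion = 0.1,
                              baseline_mean = 200,
                              triple_coupling = 1,
                              decoy_interactions_per_mirna = 5,
                              gene_length_range = c(300, 3000),
                              library_size_range = c(0.85, 1.15),
                              seed = 1) {
  p <- as.list(environment())
  counts <- c("n_lncrna", "n_mirna", "n_mrna", "n_samples_per_group",
              "n_planted_triples", "n_planted_de",
              "decoy_interactions_per_mirna")
  for (nm in counts) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v != round(v))
      stop("parameter '", nm, "' must be a single non-negative integer")
    p[[nm]] <- as.integer(v)
  }
  if (p$n_samples_per_group < 2)
    stop("parameter 'n_samples_per_group' must be at least 2")
  if (p$n_planted_triples > min(p$n_lncrna, p$n_mirna, p$n_mrna))
    stop("parameter 'n_planted_triples' exceeds min(n_lncrna, n_mirna, n_mrna)")
  if (p$n_planted_de + p$n_planted_triples > min(p$n_lncrna, p$n_mirna, p$n_mrna))
    stop("parameter 'n_planted_de' leaves no room after planted triples")
  if (!is.numeric(p$de_log2fc) || p$de_log2fc <= 0)
    stop("parameter 'de_log2fc' must be > 0")
  if (!is.numeric(p$nb_dispersion) || p$nb_dispersion <= 0)
    stop("parameter 'nb_dispersion' must be > 0")
  if (!is.numeric(p$baseline_mean) || p$baseline_mean <= 0)
    stop("parameter 'baseline_mean' must be > 0")
  if (!is.numeric(p$triple_coupling) || p$triple_coupling <= 0 ||
      p$triple_coupling > 1)
    stop("parameter 'triple_coupling' must lie in (0, 1]")
  for (nm in c("gene_length_range", "library_size_range")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 2L || any(v <= 0) || v[1] > v[2])
      stop("parameter '", nm, "' must be a positive interval c(lo, hi)")
  }
  if (!is.numeric(p$seed) || length(p$seed) != 1L || p$seed != round(p$seed))
    stop("parameter 'seed' must be a single integer")
  p$seed <- as.integer(p$seed)
  structure(p, class = "simulation_params")
}

#' Simulate a two-condition dataset with planted ceRNA triples
#'
#' Generates negative-binomial count matrices for lncRNAs, miRNAs and
#' mRNAs over two conditions ("undifferentiated", "differentiated"),
#' plants differentially expressed genes and true ceRNA triples, and emits
#' a matching predicted-interaction list (planted edges plus decoys)
#' together with a truth record for validation.
#'
#' Planted differential expression moves a gene's group means apart by
#' `de_log2fc` log2 units (direction random per gene), split
#' symmetrically around the baseline so that library composition stays
#' balanced under total-count normalization.
#' For a planted triple, the lncRNA and mRNA move together and the miRNA
#' moves oppositely; on top of the group shift the three members share a
#' per-sample latent state through a Gaussian copula on the NB marginals
#' (strength `triple_coupling`), producing positive lncRNA-mRNA and
#' negative miRNA-target rank correlation across samples. Decoy
#' interactions connect random miRNAs to random non-triple targets and
#' carry no planted co-expression.
#'
#' @param params a [simulation_params()] object.
#' @return A list of class `"cerna_dataset"` with elements
#'   `counts` (list of integer matrices `lncrna`, `mirna`, `mrna`),
#'   `groups` (named character vector over samples),
#'   `annotations` (data frame `gene_id`, `biotype`, `length_bp`),
#'   `interactions` (data frame `mirna_id`, `target_id`, `target_biotype`,
#'   `source`), and `truth` (planted DE list, planted triples, realized
#'   library sizes, seed, params).
#' @examples
#' d <- generate_dataset(simulation_params(n_lncrna = 20, n_mirna = 10,
#'                                         n_mrna = 30,
#'                                         n_planted_triples = 2,
#'                                         n_planted_de = 3, seed = 7))
#' dim(d$counts$mrna)
#' d$truth$planted_triples
#' @export
generate_dataset <- function(params) {
  if (!inherits(params, "simulation_params"))
    params <- do.call(simulation_params, as.list(params))
  p <- params
  set.seed(p$seed)

  n_s <- 2L * p$n_samples_per_group
  samples <- c(sprintf("undiff_%d", seq_len(p$n_samples_per_group)),
               sprintf("diff_%d", seq_len(p$n_samples_per_group)))
  groups <- setNames(rep(c("undifferentiated", "differentiated"),
                         each = p$n_samples_per_group), samples)
  is_case <- groups == "differentiated"

  ids <- list(
    lncrna = sprintf("LNC%04d", seq_len(p$n_lncrna)),
    mirna  = sprintf("MIR%03d", seq_len(p$n_mirna)),
    mrna   = sprintf("MRNA%04d", seq_len(p$n_mrna))
  )

  # planted triples: disjoint members within each biotype
  tri <- lapply(ids, function(v) {
    if (p$n_planted_triples) sample(v, p$n_planted_triples) else character(0)
  })
  planted_triples <- data.frame(lncrna_id = tri$lncrna,
                                mirna_id = tri$mirna,
                                mrna_id = tri$mrna,
                                stringsAsFactors = FALSE)
  tri_dir <- if (p$n_planted_triples)
    sample(c(1, -1), p$n_planted_triples, replace = TRUE) else numeric(0)

  # extra planted DE genes, outside the triples
  extra <- lapply(names(ids), function(bt) {
    pool <- setdiff(ids[[bt]], tri[[bt]])
    if (p$n_planted_de) sample(pool, p$n_planted_de) else character(0)
  })
  names(extra) <- names(ids)

  de_dir <- list()  # gene -> +1/-1 (log2 shift direction in differentiated)
  for (k in seq_len(p$n_planted_triples)) {
    de_dir[[tri$lncrna[k]]] <- tri_dir[k]
    de_dir[[tri$mrna[k]]]   <- tri_dir[k]
    de_dir[[tri$mirna[k]]]  <- -tri_dir[k]
  }
  for (bt in names(ids)) for (g in extra[[bt]])
    de_dir[[g]] <- sample(c(1, -1), 1)

  depth <- stats::runif(n_s, p$library_size_range[1], p$library_size_range[2])

  simulate_matrix <- function(bt) {
    g <- ids[[bt]]
    base <- stats::rlnorm(length(g), log(p$baseline_mean), 0.5)
    names(base) <- g
    dirv <- vapply(g, function(x) de_dir[[x]] %||% 0, numeric(1))
    # group-mean matrix: baseline x DE shift x sample depth. The planted
    # effect is split symmetrically around the baseline (+/- de/2 per
    # group) so the between-group log2FC is de_log2fc while library
    # composition stays balanced - FPKM/TPM normalize by column totals,
    # and a one-sided shift would deflate every planted fold change.
    mu <- outer(base, rep(1, n_s)) *
      2^(outer(dirv, (as.numeric(is_case) - 0.5) * p$de_log2fc)) *
      rep(depth, each = length(g))
    m <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / p$nb_dispersion),
                nrow = length(g), ncol = n_s,
                dimnames = list(g, samples))
    list(mu = mu, m = m)
  }

  sim <- lapply(setNames(names(ids), names(ids)), simulate_matrix)
  counts <- lapply(sim, `[[`, "m")

  # overwrite planted-triple rows with copula-coupled NB draws
  rho <- p$triple_coupling
  for (k in seq_len(p$n_planted_triples)) {
    z_shared <- stats::rnorm(n_s)
    draw <- function(bt, gene, sign) {
      z <- sign * rho * z_shared +
        sqrt(1 - rho^2) * stats::rnorm(n_s)
      mu <- sim[[bt]]$mu[gene, ]
      stats::qnbinom(stats::pnorm(z), mu = mu, size = 1 / p$nb_dispersion)
    }
    counts$lncrna[tri$lncrna[k], ] <- draw("lncrna", tri$lncrna[k], +1)
    counts$mrna[tri$mrna[k], ]     <- draw("mrna", tri$mrna[k], +1)
    counts$mirna[tri$mirna[k], ]   <- draw("mirna", tri$mirna[k], -1)
  }
  counts <- lapply(counts, function(m) {
    storage.mode(m) <- "integer"
    m
  })

  annotations <- data.frame(
    gene_id = c(ids$lncrna, ids$mirna, ids$mrna),
    biotype = rep(c("lncRNA", "miRNA", "mRNA"),
                  c(p$n_lncrna, p$n_mirna, p$n_mrna)),
    length_bp = c(as.integer(round(stats::runif(p$n_lncrna,
                                                p$gene_length_range[1],
                                                p$gene_length_range[2]))),
                  rep(NA_integer_, p$n_mirna),
                  as.integer(round(stats::runif(p$n_mrna,
                                                p$gene_length_range[1],
                                                p$gene_length_range[2])))),
    stringsAsFactors = FALSE
  )

  planted_edges <- if (p$n_planted_triples) data.frame(
    mirna_id = rep(tri$mirna, 2L),
    target_id = c(tri$lncrna, tri$mrna),
    target_biotype = rep(c("lncRNA", "mRNA"), each = p$n_planted_triples),
    source = "planted",
    stringsAsFactors = FALSE
  ) else data.frame(mirna_id = character(0), target_id = character(0),
                    target_biotype = character(0), source = character(0))

  target_pool <- data.frame(
    target_id = c(setdiff(ids$lncrna, tri$lncrna),
                  setdiff(ids$mrna, tri$mrna)),
    target_biotype = rep(c("lncRNA", "mRNA"),
                         c(length(setdiff(ids$lncrna, tri$lncrna)),
                           length(setdiff(ids$mrna, tri$mrna)))),
    stringsAsFactors = FALSE
  )
  decoys <- if (p$decoy_interactions_per_mirna && nrow(target_pool)) {
    do.call(rbind, lapply(ids$mirna, function(mi) {
      j <- sample(nrow(target_pool),
                  min(p$decoy_interactions_per_mirna, nrow(target_pool)))
      data.frame(mirna_id = mi, target_id = target_pool$target_id[j],
                 target_biotype = target_pool$target_biotype[j],
                 source = "decoy", stringsAsFactors = FALSE)
    }))
  } else planted_edges[0, ]
  interactions <- rbind(planted_edges, decoys)
  interactions <- interactions[!duplicated(interactions[c("mirna_id", "target_id")]), ]
  rownames(interactions) <- NULL

  planted_de <- if (length(de_dir)) data.frame(
    gene_id = names(de_dir),
    direction = ifelse(unlist(de_dir) > 0, "up", "down"),
    stringsAsFactors = FALSE
  ) else data.frame(gene_id = character(0), direction = character(0))

  truth <- list(
    planted_de = planted_de,
    planted_triples = planted_triples,
    library_sizes = lapply(counts, function(m) {
      x <- colSums(m); storage.mode(x) <- "integer"; x
    }),
    seed = p$seed,
    params = unclass(p)
  )

  structure(list(counts = counts, groups = groups,
                 annotations = annotations, interactions = interactions,
                 truth = truth),
            class = "cerna_dataset")
}

#' @export
print.cerna_dataset <- function(x, ...) {
  cat("cerna_dataset:",
      nrow(x$counts$lncrna), "lncRNAs,",
      nrow(x$counts$mirna), "miRNAs,",
      nrow(x$counts$mrna), "mRNAs x", ncol(x$counts$lncrna), "samples\n")
  cat("  planted triples:", nrow(x$truth$planted_triples),
      "| interactions:", nrow(x$interactions),
      "| seed:", x$truth$seed, "\n")
  invisible(x)
}
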