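# Independent oracles, written against the definitions rather than the
# package code paths they check.

# Spearman via explicit mid-ranks and the raw Pearson sum formula.
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  a <- midrank(x); b <- midrank(y)
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  num / den
}

# Benjamini-Hochberg step-up, computed literally: q_i = p_(i) * m / i,
# then enforce monotonicity from the largest p down.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  if (m >= 2) for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Upper-tail hypergeometric by exhaustive enumeration of all C(U, N)
# draws: probability that at least n of the N drawn items fall in the
# M-item subset {1..M}.
oracle_hyper_enum <- function(n, M, N, U) {
  if (n == 0) return(1)
  if (N == 0) return(0)
  draws <- utils::combn(U, N)
  hits <- colSums(draws <= M)
  mean(hits >= n)
}

# Small, quick simulated dataset for structural tests.
small_params <- function(seed = 1, ...) {
  defaults <- list(n_lncrna = 40, n_mirna = 20, n_mrna = 60,
                   n_planted_triples = 4, n_planted_de = 6,
                   decoy_interactions_per_mirna = 3, seed = seed)
  do.call(simulation_params, utils::modifyList(defaults, list(...)))
}

triple_key <- function(df) paste(df$lncrna_id, df$mirna_id, df$mrna_id)
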