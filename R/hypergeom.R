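#' Upper-tail hypergeometric probability for shared-miRNA counts
#'
#' Computes the probability that a lncRNA and an mRNA share at least `n`
#' target miRNAs by chance, given that the lncRNA targets `M` miRNAs, the
#' mRNA targets `N` miRNAs, and the analysis universe holds `U` miRNAs:
#'
#' \deqn{p = 1 - \sum_{i=0}^{n-1} \binom{M}{i} \binom{U-M}{N-i} / \binom{U}{N}}
#'
#' i.e. the upper tail \eqn{P(X \ge n)} of a hypergeometric distribution
#' with `N` draws from a universe of `U` containing `M` successes. The sum
#' is evaluated directly over the upper tail in log space
#' (via [lchoose()]), which is stable for small p-values; `n = 0` returns
#' exactly 1. The same statistic doubles as the standard over-representation
#' test used by [overrepresentation()].
#'
#' @param n number of shared miRNAs (overlap), `0 <= n <= min(M, N)`.
#' @param M number of target miRNAs of the lncRNA (`M <= U`).
#' @param N number of target miRNAs of the mRNA (`N <= U`).
#' @param U number of miRNAs in the universe.
#' @return The upper-tail probability, a number in \[0, 1\]. Vectorized over
#'   its arguments (recycled to common length).
#' @examples
#' hypergeometric_p(2, 4, 5, 10)   # 186/252
#' hypergeometric_p(0, 4, 5, 10)   # empty sum -> 1
#' @export
hypergeometric_p <- function(n, M, N, U) {
  args <- list(n = n, M = M, N = N, U = U)
  len <- max(lengths(args))
  args <- lapply(args, rep_len, len)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0) ||
        any(v != round(v)))
      stop("'", nm, "' must contain non-negative integers")
  }
  n <- args$n; M <- args$M; N <- args$N; U <- args$U
  if (any(M > U)) stop("'M' must not exceed 'U'")
  if (any(N > U)) stop("'N' must not exceed 'U'")
  if (any(n > pmin(M, N))) stop("'n' must not exceed min(M, N)")
  vapply(seq_len(len), function(j) {
    if (n[j] == 0L) return(1)
    i <- seq.int(n[j], min(M[j], N[j]))
    lt <- lchoose(M[j], i) + lchoose(U[j] - M[j], N[j] - i) -
      lchoose(U[j], N[j])
    min(1, sum(exp(lt)))
  }, numeric(1))
}
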