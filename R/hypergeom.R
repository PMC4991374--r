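#' Validated parameter set for the hypergeometric overlap model
#'
#' Bundles the four quantities of the gene-set overlap model: a universe of
#' `N` genes, two sets of sizes `m` and `n` drawn from it, and an observed
#' overlap of `k` genes. The model asks how surprising an overlap of at
#' least `k` is when the `n`-set is drawn uniformly at random from the
#' universe containing a fixed `m`-set.
#'
#' @param N Universe size (number of genes in the genome; for *C. elegans*
#'   the conventional approximation is 20000).
#' @param m Size of gene set 1.
#' @param n Size of gene set 2.
#' @param k Observed overlap count.
#' @return An object of class `hypergeom_params`: a named list with fields
#'   `N`, `m`, `n`, `k`, all stored as doubles holding integer values.
#' @examples
#' hypergeom_params(N = 20000, m = 681, n = 109, k = 17)
#' @export
hypergeom_params <- function(N, m, n, k = 0) {
  for (nm in c("N", "m", "n", "k")) {
    v <- get(nm)
    if (length(v) != 1L || !is.numeric(v) || is.na(v) || v != round(v)) {
      stop("'", nm, "' must be a single non-negative integer", call. = FALSE)
    }
  }
  if (N < 1) stop("'N' must be positive", call. = FALSE)
  if (m < 0 || m > N) stop("'m' must satisfy 0 <= m <= N", call. = FALSE)
  if (n < 0 || n > N) stop("'n' must satisfy 0 <= n <= N", call. = FALSE)
  if (k < 0 || k > min(m, n)) {
    stop("'k' must satisfy 0 <= k <= min(m, n)", call. = FALSE)
  }
  structure(list(N = as.numeric(N), m = as.numeric(m),
                 n = as.numeric(n), k = as.numeric(k)),
            class = "hypergeom_params")
}

as_hg_params <- function(params, N, m, n, k) {
  if (!missing(params) && inherits(params, "hypergeom_params")) return(params)
  hypergeom_params(N = N, m = m, n = n, k = k)
}

#' Hypergeometric probability of an exact overlap count
#'
#' Probability that a random `n`-subset of an `N`-gene universe shares
#' exactly `i` genes with a fixed `m`-subset:
#' \deqn{P(X = i) = \frac{\binom{m}{i}\binom{N-m}{n-i}}{\binom{N}{n}}.}
#' The binomial coefficients are combined in log space (via [lchoose()],
#' i.e. log-gamma arithmetic), so the result is accurate at genome-scale
#' `N` where raw factorials overflow.
#'
#' @param i Overlap count, `0 <= i <= min(m, n)`.
#' @param params A [hypergeom_params()] object; alternatively supply
#'   `N`, `m`, `n` directly (its `k` field is ignored here).
#' @inheritParams hypergeom_params
#' @return The probability, 0 when the configuration is impossible
#'   (`n - i > N - m`).
#' @examples
#' hypergeom_pmf(2, N = 10, m = 4, n = 5)
#' @export
hypergeom_pmf <- function(i, params, N, m, n) {
  p <- as_hg_params(params, N, m, n, 0)
  if (length(i) != 1L || !is.numeric(i) || is.na(i) || i != round(i) ||
      i < 0 || i > min(p$m, p$n)) {
    stop("'i' must be an integer in [0, min(m, n)]", call. = FALSE)
  }
  if (p$n - i > p$N - p$m) return(0)
  exp(lchoose(p$m, i) + lchoose(p$N - p$m, p$n - i) - lchoose(p$N, p$n))
}

#' Upper-tail hypergeometric p-value for a gene-set overlap
#'
#' Probability of observing `k` or more shared genes,
#' \eqn{P(X \ge k) = 1 - \sum_{i=0}^{k-1} P(X = i)}, computed by direct
#' summation of the log-space pmf over the tail `i = k, ..., min(m, n)`
#' (numerically safer than the complement when the tail is tiny) and
#' clamped to `[0, 1]`. `k = 0` returns exactly 1.
#'
#' @param params A [hypergeom_params()] object carrying `(N, m, n, k)`;
#'   alternatively supply the four values directly.
#' @inheritParams hypergeom_params
#' @return The p-value in `[0, 1]`; always a true positive tail, never an
#'   exact zero (overlaps more extreme than possible return 0 only when
#'   `k > min(m, n)` is rejected upstream).
#' @examples
#' # dietary-restriction gene comparison: 4 of 48 among 109 targets
#' hypergeom_upper_tail(N = 20000, m = 48, n = 109, k = 4)
#' @export
hypergeom_upper_tail <- function(params, N, m, n, k) {
  p <- as_hg_params(params, N, m, n, k)
  if (p$k == 0) return(1)
  i <- seq(p$k, min(p$m, p$n))
  lp <- lchoose(p$m, i) + lchoose(p$N - p$m, p$n - i) - lchoose(p$N, p$n)
  min(1, max(0, sum(exp(lp))))
}

#' Expected overlap of two random gene sets
#'
#' Mean of the hypergeometric overlap distribution, `m * n / N`: the
#' overlap expected by chance between an `m`-set and an `n`-set drawn from
#' an `N`-gene universe. Symmetric in `m` and `n`.
#'
#' @inheritParams hypergeom_params
#' @return The expected count as a real number.
#' @examples
#' expected_overlap(m = 681, n = 109, N = 20000) # 3.71 genes by chance
#' @export
expected_overlap <- function(m, n, N) {
  if (length(N) != 1L || !is.numeric(N) || is.na(N) || N <= 0) {
    stop("'N' must be a positive number", call. = FALSE)
  }
  if (any(c(m, n) < 0) || m > N || n > N) {
    stop("'m' and 'n' must lie in [0, N]", call. = FALSE)
  }
  m * n / N
}
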