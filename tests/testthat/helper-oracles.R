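# Independent brute-force oracles used across the suite. Each is written
# from the definition, not from the implementation it checks.

# Exhaustive hypergeometric distribution: enumerate every n-subset of an
# N-universe whose first m elements are "marked" and tally the overlap.
# Returns P(X = i) for i = 0..min(m, n).
enum_overlap_dist <- function(N, m, n) {
  imax <- min(m, n)
  if (n == 0 || N == 0) {
    return(c(1, rep(0, imax)))
  }
  subs <- utils::combn(N, n)
  counts <- colSums(subs <= m)
  tab <- tabulate(counts + 1L, nbins = imax + 1L)
  tab / ncol(subs)
}

enum_upper_tail <- function(N, m, n, k) {
  pmf <- enum_overlap_dist(N, m, n)
  if (k <= 0) 1 else sum(pmf[seq(k + 1, length(pmf))])
}

# Brute-force KS statistic: max |F1 - F2| over a dense evaluation of both
# ECDFs at every pooled point (via the counting definition).
brute_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# Permutation p-value for the two-sample KS statistic.
perm_ks_p <- function(x, y, B = 10000) {
  obs <- brute_ks_D(x, y)
  pooled <- c(x, y)
  n1 <- length(x)
  hits <- 0
  for (b in seq_len(B)) {
    idx <- sample(length(pooled), n1)
    if (brute_ks_D(pooled[idx], pooled[-idx]) >= obs - 1e-12) hits <- hits + 1
  }
  hits / B
}

# Independently written IUPAC degeneracy table (standard nomenclature).
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Naive O(L * w) position-by-position scanner over the oracle table;
# sequence 'N' never matches.
naive_scan_positions <- function(seq, consensus) {
  s <- strsplit(seq, "")[[1]]
  m <- strsplit(consensus, "")[[1]]
  w <- length(m)
  out <- integer(0)
  if (w > length(s)) return(out)
  for (start in 1:(length(s) - w + 1)) {
    hit <- TRUE
    for (j in 1:w) {
      base <- s[start + j - 1]
      if (base == "N" || !(base %in% ORACLE_IUPAC[[m[j]]])) {
        hit <- FALSE
        break
      }
    }
    if (hit) out <- c(out, start)
  }
  out
}

# Brute-force coreness: for each K from 0 up, peel nodes of degree < K to
# fixpoint; a node's coreness is the largest K at which it survives.
brute_coreness <- function(g) {
  n <- igraph::vcount(g)
  core <- integer(n)
  if (n == 0) return(core)
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  maxd <- max(igraph::degree(g))
  for (K in 0:maxd) {
    alive <- rep(TRUE, n)
    repeat {
      deg <- vapply(seq_len(n), function(v) {
        if (alive[v]) sum(alive[adj[[v]]]) else NA_integer_
      }, integer(1))
      drop <- which(alive & deg < K)
      if (length(drop) == 0) break
      alive[drop] <- FALSE
    }
    core[alive] <- K
  }
  stats::setNames(core, igraph::V(g)$name)
}

# Random simple graph as an edge matrix over given node names.
random_edge_matrix <- function(nodes, p, seed) {
  set.seed(seed)
  n <- length(nodes)
  pairs <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p
  cbind(nodes[pairs[keep, 1]], nodes[pairs[keep, 2]])
}
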