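# Seeded generators emulating the study's three kinds of input — gene-list
# pairs with an exact planted overlap, promoter FASTA with motif words
# spiked at known offsets, and interaction networks with a planted
# high-degree, mutually interacting target subset — each with a recorded
# ground truth sufficient to verify every downstream claim. Seeds are
# mandatory arguments, never global state; identical arguments give
# byte-identical files.

write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Generate a gene-set pair with an exact planted overlap
#'
#' Synthesizes an `N`-identifier universe and two sets of sizes `m` and
#' `n` whose intersection has exactly `k` members, emulating the
#' published comparisons (e.g. a 681-gene longevity list against 109
#' direct targets with 17 shared genes).
#'
#' @param N,m,n,k Universe size, set sizes, planted overlap; requires
#'   `k <= min(m, n)` and `m + n - k <= N`.
#' @param seed Integer seed (mandatory).
#' @param dir If non-NULL, write `universe.txt`, `set1.txt`, `set2.txt`
#'   and `ground_truth.json` there.
#' @return List with `set1`, `set2` ([gene_set()]s), `universe`
#'   (character), `truth` (planted overlap ids and parameters), and
#'   `paths` when `dir` is given.
#' @export
gen_overlap_pair <- function(N, m, n, k, seed, dir = NULL) {
  p <- hypergeom_params(N, m, n, k) # validates the tuple
  if (m + n - k > N) {
    stop("infeasible: union m + n - k exceeds the universe N", call. = FALSE)
  }
  set.seed(seed)
  universe <- sprintf("g%06d", seq_len(N))
  perm <- sample(universe)
  shared <- perm[seq_len(k)]
  only1 <- perm[seq_len(m - k) + k]
  only2 <- perm[seq_len(n - k) + m]
  set1 <- gene_set(c(shared, only1), "set1")
  set2 <- gene_set(c(shared, only2), "set2")
  truth <- list(generator = "gen_overlap_pair", seed = seed,
                N = N, m = m, n = n, k = k, overlap_ids = sort(shared))
  out <- list(set1 = set1, set2 = set2, universe = universe, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(dir, c("universe.txt", "set1.txt", "set2.txt",
                              "ground_truth.json"))
    writeLines(universe, paths[1])
    write_gene_list(set1, paths[2])
    write_gene_list(set2, paths[3])
    write_ground_truth(truth, paths[4])
    out$paths <- stats::setNames(paths, c("universe", "set1", "set2", "truth"))
  }
  out
}

revcomp <- function(word) {
  chartr("ACGT", "TGCA",
         vapply(word, function(w) {
           paste(rev(strsplit(w, "")[[1]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}

# exact-word occurrence positions (A/C/G/T words only)
word_positions <- function(seq, word) scan_one(seq, word)

#' Generate promoter sequences with motif words spiked at known offsets
#'
#' Backgrounds are i.i.d. nucleotides at a configurable GC fraction
#' (default 0.5, i.e. equiprobable bases, for which the expected number
#' of chance hits of an exact `w`-mer per sequence is the closed form
#' `(L - w + 1) / 4^w`). Each requested spike overwrites the background
#' with an exact motif word at a 1-based offset. So that planted counts
#' are exact, a sequence's background is redrawn (up to `max_redraws`
#' times) until the finished sequence contains no occurrence of any
#' spiked word or its reverse complement beyond the planted ones.
#'
#' @param count Number of promoters.
#' @param length Sequence length in nucleotides (nominal 1 kb window).
#' @param gc_fraction Probability mass on G+C, split evenly.
#' @param spikes `NULL`, or a data frame with columns `gene_index`
#'   (1-based), `word` (exact A/C/G/T string), `offset` (1-based start),
#'   and optionally `motif` (label recorded in the ground truth). Spikes
#'   within one sequence must not overlap.
#' @param seed Integer seed (mandatory).
#' @param dir If non-NULL, write `promoters.fasta` and
#'   `ground_truth.json` there.
#' @param max_redraws Redraw budget per sequence before giving up with
#'   an error advising a longer sequence or fewer constraints.
#' @return List with `promoters` (a [promoter_set()]), `truth`, and
#'   `paths` when `dir` is given.
#' @export
gen_promoters <- function(count, length = 1000, gc_fraction = 0.5,
                          spikes = NULL, seed, dir = NULL,
                          max_redraws = 100) {
  stopifnot(count >= 0, length >= 1, gc_fraction >= 0, gc_fraction <= 1)
  genes <- sprintf("gene_%04d", seq_len(count))
  if (!is.null(spikes)) {
    spikes <- as.data.frame(spikes)
    stopifnot(all(c("gene_index", "word", "offset") %in% names(spikes)))
    if (is.null(spikes$motif)) spikes$motif <- spikes$word
    spikes$word <- toupper(spikes$word)
    if (any(grepl("[^ACGT]", spikes$word))) {
      stop("spiked words must be exact A/C/G/T strings", call. = FALSE)
    }
    if (any(spikes$gene_index < 1 | spikes$gene_index > count)) {
      stop("spike gene_index out of range", call. = FALSE)
    }
    if (any(spikes$offset < 1 |
            spikes$offset + nchar(spikes$word) - 1 > length)) {
      stop("spike does not fit within the sequence", call. = FALSE)
    }
    for (gi in unique(spikes$gene_index)) {
      s <- spikes[spikes$gene_index == gi, , drop = FALSE]
      if (nrow(s) > 1) {
        o <- order(s$offset)
        ends <- s$offset[o] + nchar(s$word[o]) - 1
        if (any(s$offset[o][-1] <= ends[-nrow(s)])) {
          stop("spikes overlap within gene index ", gi, call. = FALSE)
        }
      }
    }
    forbidden <- unique(c(spikes$word, revcomp(spikes$word)))
  } else {
    spikes <- data.frame(gene_index = integer(0), word = character(0),
                         offset = integer(0), motif = character(0),
                         stringsAsFactors = FALSE)
    forbidden <- character(0)
  }
  set.seed(seed)
  base_prob <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
                 G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seqs <- character(count)
  for (i in seq_len(count)) {
    sp <- spikes[spikes$gene_index == i, , drop = FALSE]
    planted <- Map(function(w, o) c(word = w, offset = o), sp$word, sp$offset)
    ok <- FALSE
    for (attempt in seq_len(max_redraws)) {
      s <- paste(sample(names(base_prob), length, replace = TRUE,
                        prob = base_prob), collapse = "")
      if (nrow(sp) > 0) {
        for (j in seq_len(nrow(sp))) {
          substr(s, sp$offset[j],
                 sp$offset[j] + nchar(sp$word[j]) - 1) <- sp$word[j]
        }
      }
      clean <- TRUE
      for (w in forbidden) {
        pos <- word_positions(s, w)
        want <- sp$offset[sp$word == w]
        if (!identical(sort(as.integer(pos)), sort(as.integer(want)))) {
          clean <- FALSE
          break
        }
      }
      if (clean) { ok <- TRUE; break }
    }
    if (!ok) {
      stop("could not draw a background free of accidental motif hits ",
           "after ", max_redraws, " attempts; use a longer sequence or ",
           "fewer constraints", call. = FALSE)
    }
    seqs[i] <- s
  }
  promoters <- promoter_set(genes, seqs, expected_length = length)
  truth <- list(generator = "gen_promoters", seed = seed, count = count,
                length = length, gc_fraction = gc_fraction,
                spikes = data.frame(gene = genes[spikes$gene_index],
                                    motif = spikes$motif,
                                    word = spikes$word,
                                    offset = spikes$offset,
                                    stringsAsFactors = FALSE))
  out <- list(promoters = promoters, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(dir, c("promoters.fasta", "ground_truth.json"))
    write_promoter_fasta(promoters, paths[1])
    write_ground_truth(truth, paths[2])
    out$paths <- stats::setNames(paths, c("fasta", "truth"))
  }
  out
}

#' Generate an interaction network with a planted hub target subset
#'
#' Samples an undirected simple graph from a Chung-Lu-style
#' expected-degree model: every node carries weight
#' `background_mean_degree`, target nodes carry it multiplied by
#' `degree_multiplier`, and each pair `(i, j)` is connected independently
#' with probability `w_i * w_j / sum(w)`. For target-target pairs the
#' connection odds are further scaled by `within_target_bias`, planting
#' the mutual-interaction signal. The result emulates the qualitative
#' finding pattern of the target-versus-rest topology comparison: with
#' `degree_multiplier > 1` targets are high-degree and central, and with
#' `within_target_bias > 1` they preferentially interact with each
#' other.
#'
#' @param n_nodes Total nodes; must exceed `target_count`.
#' @param background_mean_degree Expected degree of a background node.
#' @param target_count Number of planted target nodes (at least 2).
#' @param degree_multiplier Weight multiplier for target nodes.
#' @param within_target_bias Odds multiplier for target-target pairs.
#' @param seed Integer seed (mandatory).
#' @param dir If non-NULL, write `edges.tsv`, `nodes.txt`,
#'   `targets.txt`, `ground_truth.json` there.
#' @return List with `network` ([igraph::graph] including isolated
#'   nodes), `targets` ([gene_set()]), `truth`, and `paths` when `dir`
#'   is given.
#' @export
gen_planted_hub_network <- function(n_nodes, background_mean_degree,
                                    target_count, degree_multiplier = 1,
                                    within_target_bias = 1, seed,
                                    dir = NULL) {
  stopifnot(n_nodes > target_count, target_count >= 2,
            background_mean_degree > 0, degree_multiplier > 0,
            within_target_bias > 0)
  set.seed(seed)
  nodes <- sprintf("p%05d", seq_len(n_nodes))
  target_idx <- sort(sample(n_nodes, target_count))
  is_target <- seq_len(n_nodes) %in% target_idx
  w <- rep(background_mean_degree, n_nodes)
  w[is_target] <- w[is_target] * degree_multiplier
  S <- sum(w)
  if (max(w) >= n_nodes - 1 || max(w)^2 / S >= 1) {
    stop("infeasible expected degrees for this node count", call. = FALSE)
  }
  pair <- which(upper.tri(matrix(FALSE, n_nodes, n_nodes)), arr.ind = TRUE)
  i <- pair[, 1]; j <- pair[, 2]
  p <- w[i] * w[j] / S
  tt <- is_target[i] & is_target[j]
  p[tt] <- within_target_bias * p[tt] / (1 + (within_target_bias - 1) * p[tt])
  keep <- stats::runif(length(p)) < p
  em <- cbind(nodes[i[keep]], nodes[j[keep]])
  network <- interaction_network(em, nodes = nodes)
  targets <- gene_set(nodes[is_target], "planted_targets")
  truth <- list(generator = "gen_planted_hub_network", seed = seed,
                n_nodes = n_nodes,
                background_mean_degree = background_mean_degree,
                target_count = target_count,
                degree_multiplier = degree_multiplier,
                within_target_bias = within_target_bias,
                target_ids = nodes[is_target], n_edges = nrow(em))
  out <- list(network = network, targets = targets, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(dir, c("edges.tsv", "nodes.txt", "targets.txt",
                              "ground_truth.json"))
    write_edge_list(network, paths[1])
    writeLines(nodes, paths[2])
    write_gene_list(targets, paths[3])
    write_ground_truth(truth, paths[4])
    out$paths <- stats::setNames(paths,
                                 c("edges", "nodes", "targets", "truth"))
  }
  out
}
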