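#' Build an undirected simple interaction network
#'
#' Node identifiers are normalized as in [gene_set()] (trim + lower
#' case). Self-loops are dropped and duplicate edges (in either
#' orientation) collapsed, each with a message giving the count; the node
#' set is the union of edge endpoints plus any explicitly supplied
#' isolated nodes.
#'
#' @param edges Two-column character matrix or data frame of endpoint
#'   pairs (extra columns, e.g. an interaction-type annotation, are
#'   ignored: all measures here are type-blind).
#' @param nodes Optional character vector of additional (possibly
#'   isolated) node identifiers.
#' @return An undirected simple [igraph::graph] object.
#' @export
interaction_network <- function(edges, nodes = character(0)) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    em <- matrix(character(0), ncol = 2)
  } else {
    if (!is.matrix(edges) || ncol(edges) < 2) {
      stop("'edges' must have two endpoint columns", call. = FALSE)
    }
    em <- cbind(tolower(trimws(edges[, 1])), tolower(trimws(edges[, 2])))
  }
  # endpoints of dropped self-loops still count as (isolated) nodes
  nodes <- c(tolower(trimws(nodes)), as.vector(em))
  loops <- em[, 1] == em[, 2]
  if (any(loops)) {
    message("dropped ", sum(loops), " self-loop(s)")
    em <- em[!loops, , drop = FALSE]
  }
  key <- ifelse(em[, 1] < em[, 2],
                paste(em[, 1], em[, 2]), paste(em[, 2], em[, 1]))
  dup <- duplicated(key)
  if (any(dup)) {
    message("collapsed ", sum(dup), " duplicate edge(s)")
    em <- em[!dup, , drop = FALSE]
  }
  all_nodes <- sort(unique(c(as.vector(em), nodes)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = em[, 1], to = em[, 2], stringsAsFactors = FALSE),
    directed = FALSE, vertices = all_nodes)
  g
}

#' Read an interaction network from an edge-list file
#'
#' Whitespace/tab-delimited, two identifier columns per line (an optional
#' third interaction-type column is accepted and ignored); `#` comment
#' lines and blank lines are skipped. Cleaning (self-loop and duplicate
#' removal) is reported as in [interaction_network()]. An empty file is a
#' valid empty network.
#'
#' @param path File path.
#' @return An undirected simple [igraph::graph].
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge list not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(interaction_network(character(0)))
  toks <- strsplit(lines, "[ \t]+")
  ntok <- lengths(toks)
  bad <- which(ntok < 2 | ntok > 3)
  if (length(bad) > 0) {
    stop("edge list '", path, "' line ", lineno[bad[1]],
         ": expected 2 (or 3) fields, found ", ntok[bad[1]], call. = FALSE)
  }
  interaction_network(cbind(vapply(toks, `[`, character(1), 1),
                            vapply(toks, `[`, character(1), 2)))
}

#' Write a network as a two-column edge-list TSV
#'
#' Isolated nodes are preserved as `# node <id>` comment lines so the
#' file round-trips through [read_edge_list()] only up to isolated nodes;
#' generators therefore also emit the node list separately when isolated
#' nodes matter.
#'
#' @param network An [igraph::graph].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  em <- igraph::as_edgelist(network)
  writeLines(paste(em[, 1], em[, 2], sep = "\t"), path)
  invisible(path)
}

#' Node degree
#'
#' The number of distinct interaction partners of each node, `K_i`. The
#' handshake identity `sum(degrees) == 2 * ecount` always holds on a
#' simple graph.
#'
#' @param network An [igraph::graph].
#' @return Named integer vector over all nodes.
#' @export
degrees <- function(network) {
  igraph::degree(network, loops = FALSE)
}

#' K-core decomposition (coreness)
#'
#' The K-core of a graph is obtained by recursively removing all nodes
#' of degree less than K until every remaining node has degree at least
#' K; a node's coreness is the largest K for which it survives. The
#' result is independent of removal order. Coreness never exceeds
#' degree.
#'
#' @param network An [igraph::graph].
#' @return Named integer vector of coreness values.
#' @export
kcore_decomposition <- function(network) {
  igraph::coreness(network)
}

#' Target-neighbor ratio
#'
#' For each node, the fraction of its interaction partners that belong
#' to the target gene set: `|neighbors(v) ∩ targets| / K_v`. Undefined
#' (`NA`) for isolated nodes (`K_v = 0`), which are excluded from group
#' means downstream.
#'
#' @param network An [igraph::graph].
#' @param targets A [gene_set()] or character vector of identifiers
#'   (normalized as in [gene_set()]).
#' @return Named numeric vector in `[0, 1]`, `NA` where undefined.
#' @export
target_neighbor_ratio <- function(network, targets) {
  if (inherits(targets, "gene_set")) targets <- targets$members
  targets <- unique(tolower(trimws(targets)))
  deg <- degrees(network)
  in_targets <- igraph::V(network)$name %in% targets
  k_p <- vapply(igraph::adjacent_vertices(network, igraph::V(network)),
                function(nb) sum(in_targets[as.integer(nb)]), numeric(1))
  ratio <- ifelse(deg > 0, k_p / deg, NA_real_)
  names(ratio) <- igraph::V(network)$name
  ratio
}

#' Per-node topology table
#'
#' Degree, coreness and target-neighbor ratio for every node.
#'
#' @inheritParams target_neighbor_ratio
#' @return A `data.frame` with columns `node`, `degree`, `coreness`,
#'   `ratio` (`NA` ratio for isolated nodes).
#' @export
node_topology <- function(network, targets) {
  data.frame(node = igraph::V(network)$name,
             degree = as.integer(degrees(network)),
             coreness = as.integer(kcore_decomposition(network)),
             ratio = as.numeric(target_neighbor_ratio(network, targets)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare topology of a target set against the rest of the network
#'
#' Profiles three node-level features — degree, coreness, and
#' target-neighbor ratio — for the groups `all` (every node), `targets`
#' (target genes present in the network), and optionally
#' `targets_subgroup` (targets also in `subgroup`, e.g. the
#' lifespan-regulating subset). For each non-`all` group the features of
#' group members are compared with those of all other network nodes by
#' the two-sample KS test ([ks_two_sample()]). Group means use only
#' members present in the network; targets absent from the network are
#' counted and reported via a message, never imputed. Nodes with
#' undefined ratio (degree 0) are excluded from ratio means and ratio KS
#' samples. If a group's complement is empty the KS comparison is
#' skipped with a message and `NA` p-values.
#'
#' @inheritParams target_neighbor_ratio
#' @param subgroup Optional second [gene_set()]; the third summary row
#'   covers targets that are also in it.
#' @return A `data.frame` of class `group_topology` with one row per
#'   group: `group`, `n`, `mean_degree`, `mean_coreness`, `mean_ratio`,
#'   `ks_D_degree`, `ks_p_degree`, `ks_D_coreness`, `ks_p_coreness`,
#'   `ks_D_ratio`, `ks_p_ratio`.
#' @export
compare_groups <- function(network, targets, subgroup = NULL) {
  if (inherits(targets, "gene_set")) targets <- targets$members
  targets <- unique(tolower(trimws(targets)))
  topo <- node_topology(network, targets)
  in_net <- topo$node %in% targets
  if (!any(in_net)) stop("no target gene is present in the network",
                         call. = FALSE)
  absent <- sum(!targets %in% topo$node)
  if (absent > 0) {
    message(absent, " of ", length(targets),
            " target(s) absent from the network; excluded from summaries")
  }
  groups <- list(all = rep(TRUE, nrow(topo)), targets = in_net)
  if (!is.null(subgroup)) {
    if (inherits(subgroup, "gene_set")) subgroup <- subgroup$members
    subgroup <- unique(tolower(trimws(subgroup)))
    groups$targets_subgroup <- in_net & topo$node %in% subgroup
  }
  summarize <- function(label, sel) {
    feat <- function(x, sel) x[sel & !is.na(x)]
    row <- data.frame(
      group = label, n = sum(sel),
      mean_degree = mean(topo$degree[sel]),
      mean_coreness = mean(topo$coreness[sel]),
      mean_ratio = mean(topo$ratio[sel], na.rm = TRUE),
      ks_D_degree = NA_real_, ks_p_degree = NA_real_,
      ks_D_coreness = NA_real_, ks_p_coreness = NA_real_,
      ks_D_ratio = NA_real_, ks_p_ratio = NA_real_,
      stringsAsFactors = FALSE)
    if (label != "all") {
      other <- !sel
      if (!any(other) || !any(sel)) {
        message("group '", label,
                "': empty comparison group, KS test skipped")
      } else {
        for (f in c("degree", "coreness", "ratio")) {
          a <- feat(topo[[f]], sel)
          b <- feat(topo[[f]], other)
          if (length(a) > 0 && length(b) > 0) {
            ks <- ks_two_sample(a, b)
            row[[paste0("ks_D_", f)]] <- ks$D
            row[[paste0("ks_p_", f)]] <- ks$p_value
          }
        }
      }
    }
    row
  }
  out <- do.call(rbind, lapply(names(groups),
                               function(g) summarize(g, groups[[g]])))
  class(out) <- c("group_topology", "data.frame")
  out
}

#' Write per-node topology / group summary TSVs
#'
#' @param x A [node_topology()] or [compare_groups()] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
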