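test_that("edge-list parsing cleans loops/duplicates and keeps nodes", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "a\tb", "b\ta", "c\tc"), f)
  expect_message(expect_message(g <- read_edge_list(f), "self-loop"),
                 "duplicate")
  expect_setequal(igraph::V(g)$name, c("a", "b", "c"))
  expect_identical(igraph::ecount(g), 1)
  expect_identical(unname(degrees(g)["c"]), 0)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), f2)
  g2 <- read_edge_list(f2)
  expect_identical(igraph::vcount(g2), 0)

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "oops"), f3)
  expect_error(read_edge_list(f3), "line 2")

  # optional third (interaction-type) column is accepted and ignored
  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb\tphysical", "b\tc\tgenetic"), f4)
  expect_identical(igraph::ecount(read_edge_list(f4)), 2)

  # round-trip through the writer
  f5 <- withr::local_tempfile(fileext = ".tsv")
  net <- gen_planted_hub_network(60, 4, 10, 2, 1, seed = 67)
  write_edge_list(net$network, f5)
  back <- read_edge_list(f5)
  em <- function(g) {
    e <- igraph::as_edgelist(g)
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  expect_identical(em(back), em(net$network))
})

test_that("degrees satisfy the handshake identity and a naive count", {
  tri <- interaction_network(cbind(c("a", "b", "c"), c("b", "c", "a")))
  expect_identical(unname(degrees(tri)), rep(2, 3))

  nodes <- sprintf("v%03d", 1:200)
  em <- random_edge_matrix(nodes, 0.04, seed = 71)
  g <- interaction_network(em, nodes = nodes)
  d <- degrees(g)
  expect_identical(sum(d), 2 * igraph::ecount(g))
  naive <- stats::setNames(numeric(length(nodes)), nodes)
  for (r in seq_len(nrow(em))) {
    naive[em[r, 1]] <- naive[em[r, 1]] + 1
    naive[em[r, 2]] <- naive[em[r, 2]] + 1
  }
  expect_equal(d[nodes], naive)
})

test_that("coreness matches brute-force peeling and bounds", {
  tri <- interaction_network(cbind(c("a", "b", "c"), c("b", "c", "a")))
  expect_identical(unname(kcore_decomposition(tri)), rep(2, 3))

  star <- interaction_network(cbind("hub", paste0("leaf", 1:5)))
  expect_true(all(kcore_decomposition(star) == 1))

  set.seed(73)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    nodes <- sprintf("v%02d", 1:n)
    g <- interaction_network(random_edge_matrix(nodes, stats::runif(1, 0.05, 0.3),
                                                seed = 730 + rep),
                             nodes = nodes)
    core <- kcore_decomposition(g)
    oracle <- brute_coreness(g)
    expect_equal(unname(core[names(oracle)]), unname(as.numeric(oracle)))
    expect_true(all(core <= degrees(g)))
  }
})

test_that("coreness is invariant under node relabeling/processing order", {
  nodes <- sprintf("v%02d", 1:40)
  em <- random_edge_matrix(nodes, 0.15, seed = 79)
  base <- kcore_decomposition(interaction_network(em, nodes = nodes))
  set.seed(83)
  for (rep in 1:20) {
    perm <- sample(nrow(em))
    flip <- sample(c(TRUE, FALSE), nrow(em), replace = TRUE)
    em2 <- em[perm, , drop = FALSE]
    em2[flip, ] <- em2[flip, 2:1]
    core2 <- kcore_decomposition(interaction_network(em2, nodes = nodes))
    expect_identical(core2[names(base)], base)
  }
})

test_that("target-neighbor ratio matches a naive set-intersection oracle", {
  g <- interaction_network(cbind(c("x", "x", "x", "x", "y"),
                                 c("t1", "t2", "t3", "t4", "b1")),
                           nodes = "iso")
  r <- target_neighbor_ratio(g, c("t1", "t2", "t3", "t4"))
  expect_identical(unname(r["x"]), 1)
  expect_identical(unname(r["y"]), 0)
  expect_true(is.na(r["iso"]))

  nodes <- sprintf("v%03d", 1:100)
  g2 <- interaction_network(random_edge_matrix(nodes, 0.06, seed = 89),
                            nodes = nodes)
  set.seed(97)
  targets <- sample(nodes, 20)
  r2 <- target_neighbor_ratio(g2, targets)
  for (v in sample(nodes, 30)) {
    nb <- igraph::V(g2)$name[as.integer(igraph::neighbors(g2, v))]
    expected <- if (length(nb) == 0) NA_real_ else
      length(intersect(nb, targets)) / length(nb)
    expect_equal(unname(r2[v]), expected)
  }
  # targets = all nodes forces ratio 1 on every non-isolated node
  rall <- target_neighbor_ratio(g2, nodes)
  d <- degrees(g2)
  expect_true(all(rall[d > 0] == 1))
})

test_that("group comparison recovers a planted hub signal", {
  net <- gen_planted_hub_network(600, 6, 60, degree_multiplier = 3,
                                 within_target_bias = 2, seed = 101)
  s <- compare_groups(net$network, net$targets)
  expect_identical(s$group, c("all", "targets"))
  tgt <- s[s$group == "targets", ]
  all_row <- s[s$group == "all", ]
  expect_gt(tgt$mean_degree, all_row$mean_degree)
  expect_lt(tgt$ks_p_degree, 0.05)
  expect_gt(tgt$mean_ratio, all_row$mean_ratio)

  # subgroup (e.g. lifespan-regulating targets) adds a third summary
  sub <- gene_set(net$targets$members[1:15], "sub")
  s3 <- compare_groups(net$network, net$targets, subgroup = sub)
  expect_identical(nrow(s3), 3L)
  expect_identical(s3$group[3], "targets_subgroup")
  expect_identical(s3$n[3], 15L)
})

test_that("degenerate groupings are handled without fabricating tests", {
  tri <- interaction_network(cbind(c("a", "b", "c"), c("b", "c", "a")))
  # every node is a target: complement empty, KS skipped, means reported
  expect_message(s <- compare_groups(tri, c("a", "b", "c")), "skipped")
  expect_identical(s$mean_degree, c(2, 2))
  expect_true(is.na(s$ks_p_degree[2]))

  # vertex-transitive cycle: all degrees equal, KS D for degree is 0
  n <- 30
  cyc <- interaction_network(cbind(sprintf("c%02d", 1:n),
                                   sprintf("c%02d", c(2:n, 1))))
  s2 <- compare_groups(cyc, sprintf("c%02d", c(3, 9, 17)))
  expect_identical(s2$ks_D_degree[2], 0)

  expect_error(compare_groups(tri, c("zz")), "no target")

  # absent targets are reported, not imputed
  expect_message(compare_groups(tri, c("a", "zz")), "absent")
})

test_that("per-node topology table writes and holds invariants", {
  net <- gen_planted_hub_network(80, 4, 10, 2, 1, seed = 103)
  topo <- node_topology(net$network, net$targets)
  expect_true(all(topo$coreness <= topo$degree))
  ok <- !is.na(topo$ratio)
  expect_true(all(topo$ratio[ok] >= 0 & topo$ratio[ok] <= 1))
  expect_true(all(is.na(topo$ratio[topo$degree == 0])))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_topology_table(topo, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_identical(nrow(back), nrow(topo))
})
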