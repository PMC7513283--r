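# Network assembly, thresholding, the max-merge, topology metrics, and
# fragmentation sweeps.

test_that("assembly yields the complete graph and rejects missing pairs", {
  co <- data.frame(ps_a = "PS000001", ps_b = "PS000002", w = 1.3)
  net <- assemble(co, "CSN")
  expect_identical(nrow(net$edges), 1L)
  expect_length(net$nodes, 2L)

  set.seed(50)
  net50 <- random_network(50)
  expect_identical(nrow(net50$edges), 1225L)

  expect_error(assemble(net50$edges[-5, ], "CSN"), "incomplete")
  expect_error(assemble(rbind(net50$edges, net50$edges[1, ]), "CSN"), "duplicate")
})

test_that("thresholding is strict and drops isolated nodes", {
  tri <- assemble(data.frame(ps_a = c("A", "A", "B"), ps_b = c("B", "C", "C"),
                             w = c(0.5, 1.0, 1.5)), "NET")
  cut <- apply_threshold(tri, 1.0)
  expect_identical(nrow(cut$edges), 1L)       # only w = 1.5 survives w > 1.0
  expect_setequal(cut$nodes, c("B", "C"))
  expect_identical(nrow(tri$edges), 3L)       # original untouched

  noop <- apply_threshold(tri, 0.2)
  expect_identical(nrow(noop$edges), 3L)

  # nestedness: edge sets shrink monotonically along any threshold ladder
  set.seed(51)
  net <- random_network(50)
  key <- function(n) paste(n$edges$ps_a, n$edges$ps_b)
  prev <- key(net)
  for (t in sort(stats::runif(20))) {
    cur <- key(apply_threshold(net, t))
    expect_true(all(cur %in% prev))
    expect_identical(length(cur), sum(net$edges$w > t))  # brute filter oracle
    prev <- cur
  }
})

test_that("max-merge takes the strongest sub-ontology edge with BP>CC>MF ties", {
  ids <- c("A", "B", "C")
  mk <- function(w) assemble(data.frame(ps_a = c("A", "A", "B"),
                                        ps_b = c("B", "C", "C"), w = w), "X")
  same <- mk(c(1, 2, 3))
  merged <- merge_max(same, same, same)
  expect_true(all(merged$edges$provenance == "BSN-BP"))
  expect_equal(merged$edges$w, same$edges$w)

  m2 <- merge_max(mk(c(1, 1, 1)), mk(c(3, 1, 1)), mk(c(2, 1, 1)))
  ab <- m2$edges[m2$edges$ps_a == "A" & m2$edges$ps_b == "B", ]
  expect_identical(ab$w, 3)
  expect_identical(ab$provenance, "BSN-CC")

  # dominance and contribution-fraction recovery on a planted random triple
  set.seed(52)
  n <- 30
  pairs <- utils::combn(sprintf("PS%06d", 1:n), 2)
  base <- data.frame(ps_a = pairs[1, ], ps_b = pairs[2, ], stringsAsFactors = FALSE)
  winner <- sample(c("BSN-BP", "BSN-CC", "BSN-MF"), ncol(pairs), replace = TRUE,
                   prob = c(0.6, 0.3, 0.1))
  w_lo <- matrix(stats::runif(3 * ncol(pairs), 0, 1), ncol = 3,
                 dimnames = list(NULL, c("BSN-BP", "BSN-CC", "BSN-MF")))
  for (k in seq_len(ncol(pairs))) w_lo[k, winner[k]] <- stats::runif(1, 2, 3)
  nets <- lapply(colnames(w_lo), function(nm) {
    assemble(cbind(base, w = w_lo[, nm]), nm)
  })
  merged <- merge_max(nets[[1]], nets[[2]], nets[[3]])
  expect_identical(unname(merged$edges$provenance), unname(winner))
  contrib <- attr(merged, "contribution")
  expect_equal(sum(contrib), 1)
  expect_equal(unname(contrib),
               as.numeric(table(factor(winner, names(contrib)))) / length(winner))
  for (nm in colnames(w_lo)) {
    expect_true(all(merged$edges$w >= w_lo[, nm]))
  }
})

test_that("topology metrics match hand-computed small graphs and identities", {
  tri <- assemble(data.frame(ps_a = c("A", "A", "B"), ps_b = c("B", "C", "C"),
                             w = 1), "TRI")
  s <- topology_stats(tri)
  expect_equal(s$mean_k, 2)
  expect_equal(s$mean_C, 1)
  expect_equal(s$mean_l, 1)
  expect_equal(s$density, 1)
  expect_identical(s$n_components, 1L)

  path3 <- assemble(data.frame(ps_a = c("A", "A", "B"), ps_b = c("B", "C", "C"),
                               w = c(2, 2, 0.5)), "P3")
  s <- topology_stats(apply_threshold(path3, 1))  # path B - A - C
  expect_equal(s$mean_k, 4 / 3)
  expect_equal(s$mean_C, 0)
  expect_equal(s$mean_l, 4 / 3)
  expect_equal(s$density, 2 / 3)

  set.seed(53)
  for (rep in 1:5) {
    net <- apply_threshold(random_network(30), stats::runif(1, 0.3, 0.7))
    if (length(net$nodes) < 2) next
    s <- topology_stats(net)
    expect_equal(s$density, 2 * s$n_edges / (s$n_nodes * (s$n_nodes - 1)))
    expect_equal(s$mean_k, 2 * s$n_edges / s$n_nodes)
    expect_true(s$mean_C >= 0 && s$mean_C <= 1)
    expect_identical(s$n_nodes, length(net$nodes))
  }

  counts <- network_stats_from_counts(287, 5660)
  expect_equal(counts$mean_k, 2 * 5660 / 287)
  expect_equal(counts$density, 2 * 5660 / (287 * 286))
})

test_that("fragmentation curves are monotone and equal pointwise filtering", {
  set.seed(54)
  net <- random_network(50)
  expect_equal(fragmentation_curve(net, 0),
               data.frame(threshold = 0, node_fraction = 1, edge_fraction = 1))

  ts <- sort(stats::runif(20))
  fc <- fragmentation_curve(net, ts)
  expect_true(all(diff(fc$node_fraction) <= 0))
  expect_true(all(diff(fc$edge_fraction) <= 0))
  for (k in seq_along(ts)) {
    ft <- apply_threshold(net, ts[k])
    expect_equal(fc$node_fraction[k], length(ft$nodes) / 50)
    expect_equal(fc$edge_fraction[k], nrow(ft$edges) / 1225)
  }
  # all-equal weights: a step function
  flat <- assemble(data.frame(ps_a = c("A", "A", "B"), ps_b = c("B", "C", "C"),
                              w = 0.7), "FLAT")
  fc <- fragmentation_curve(flat, c(0, 0.69, 0.7, 0.71))
  expect_equal(fc$edge_fraction, c(1, 1, 0, 0))
  expect_equal(fc$node_fraction, c(1, 1, 0, 0))
})

test_that("the retention sweep finds the first threshold at or under target", {
  set.seed(55)
  net <- random_network(10)
  expect_equal(threshold_for_node_fraction(net, 1)$threshold, 0)

  res <- threshold_for_node_fraction(net, 0.2)
  expect_lte(res$fraction, 0.2)
  expect_identical(res$n_nodes, length(apply_threshold(net, res$threshold)$nodes))
  # every strictly smaller candidate threshold retains more than the target
  cands <- c(0, sort(unique(net$edges$w)))
  for (t in cands[cands < res$threshold]) {
    expect_gt(length(apply_threshold(net, t)$nodes) / 10, 0.2)
  }

  # hand-walked ladder: star weights 1..9 from a hub; cutting at w drops nodes
  star <- assemble(local({
    ids <- c("HUB", sprintf("N%02d", 1:9))
    pairs <- utils::combn(ids, 2)
    # hub edges carry weights 1..9, all leaf-leaf edges 0.01
    w <- rep(0.01, ncol(pairs))
    w[pairs[1, ] == "HUB" | pairs[2, ] == "HUB"] <- 1:9
    data.frame(ps_a = pairs[1, ], ps_b = pairs[2, ], w = w)
  }), "STAR")
  res <- threshold_for_node_fraction(star, 0.5)
  # thresholds 0.01,1,...: at t=5 the hub keeps spokes 6..9 -> 5 nodes = 50%
  expect_equal(res$threshold, 5)
  expect_equal(res$fraction, 0.5)
})

test_that("islands are components numbered by decreasing size", {
  net <- assemble(local({
    ids <- c("A", "B", "C", "D", "E")
    pairs <- utils::combn(ids, 2)
    w <- rep(0.1, ncol(pairs))
    keep2 <- function(a, b) pairs[1, ] == a & pairs[2, ] == b
    w[keep2("A", "B")] <- 3; w[keep2("B", "C")] <- 3; w[keep2("D", "E")] <- 3
    data.frame(ps_a = pairs[1, ], ps_b = pairs[2, ], w = w)
  }), "NET")
  isl <- islands(apply_threshold(net, 1))
  expect_identical(isl$island[isl$ps_id %in% c("A", "B", "C")], rep(1L, 3))
  expect_identical(isl$island[isl$ps_id %in% c("D", "E")], rep(2L, 2))
})

test_that("networks round-trip through edge-list TSV and GraphML export works", {
  set.seed(56)
  net <- random_network(12)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edgelist(net, path)
  back <- read_edgelist(path, net$name)
  expect_equal(back$edges$w, net$edges$w)
  expect_identical(back$nodes, net$nodes)

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 12)
  expect_equal(igraph::ecount(g), 66)
})
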