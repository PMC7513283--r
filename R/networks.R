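# Weighted similarity networks: assembly, thresholding, the max-merge of the
# GO sub-ontology networks, topology statistics, and fragmentation sweeps.

#' Assemble a complete weighted similarity network
#'
#' At threshold 0 the network is complete: every PS is linked to every other
#' PS (self-loops excluded), n(n-1)/2 edges for n nodes. Completeness is the
#' contract — a missing pair is an error. Self rows (from
#' `all_pair_coefficients(include_self = TRUE)`) are ignored.
#'
#' @param coefficients data.frame with columns `ps_a`, `ps_b`, `w` (and
#'   optionally `provenance`).
#' @param name network name, e.g. `"CSN"`, `"BSN-BP"`, `"BSN"`.
#' @return an object of class `similarity_network`.
#' @export
assemble <- function(coefficients, name) {
  e <- coefficients[coefficients$ps_a != coefficients$ps_b, , drop = FALSE]
  a <- pmin(e$ps_a, e$ps_b)
  b <- pmax(e$ps_a, e$ps_b)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate PS pairs in coefficient list")
  nodes <- sort(unique(c(a, b)))
  n <- length(nodes)
  if (nrow(e) != n * (n - 1) / 2) {
    stop(sprintf("incomplete coefficient set: %d pairs for %d nodes (need %d)",
                 nrow(e), n, n * (n - 1) / 2))
  }
  edges <- data.frame(ps_a = a, ps_b = b, w = e$w, stringsAsFactors = FALSE)
  if (!is.null(e$provenance)) edges$provenance <- e$provenance
  edges <- edges[order(edges$ps_a, edges$ps_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(name = name, nodes = nodes, edges = edges, threshold = 0),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("<similarity_network> %s: %d nodes, %d edges (threshold %g)\n",
              x$name, length(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Apply a similarity threshold
#'
#' Retains the edges with weight strictly greater than `w_min` (the loss of
#' all edges with w <= threshold); nodes left without any edge are removed.
#' The input network is unchanged.
#'
#' @param net a [assemble()]d network.
#' @param w_min threshold (>= 0).
#' @return a new `similarity_network` with `threshold = w_min`.
#' @export
apply_threshold <- function(net, w_min) {
  stopifnot(w_min >= 0)
  edges <- net$edges[net$edges$w > w_min, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(name = net$name,
                 nodes = sort(unique(c(edges$ps_a, edges$ps_b))),
                 edges = edges, threshold = w_min),
            class = "similarity_network")
}

#' Merge the three GO sub-ontology networks by maximum weight
#'
#' The general biological similarity network assigns to each PS pair the
#' highest coefficient among the BP, CC and MF networks. The winning
#' sub-ontology is recorded per edge (ties resolved BP > CC > MF), and the
#' share of edges each sub-ontology contributes is attached as the
#' `"contribution"` attribute.
#'
#' @param bp,cc,mf the three unthresholded sub-ontology networks.
#' @return a `similarity_network` named `"BSN"` with an edge `provenance`
#'   column.
#' @export
merge_max <- function(bp, cc, mf) {
  inputs <- list("BSN-BP" = bp, "BSN-CC" = cc, "BSN-MF" = mf)
  tabs <- lapply(names(inputs), function(nm) {
    e <- inputs[[nm]]$edges
    data.frame(key = paste(e$ps_a, e$ps_b, sep = "\r"), w = e$w,
               src = nm, stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, tabs)
  # stable order BP, CC, MF means ties keep the first (BP > CC > MF)
  best <- lapply(split(all, all$key), function(g) g[which.max(g$w), ])
  best <- do.call(rbind, best)
  pair <- do.call(rbind, strsplit(best$key, "\r", fixed = TRUE))
  edges <- data.frame(ps_a = pair[, 1], ps_b = pair[, 2], w = best$w,
                      provenance = best$src, stringsAsFactors = FALSE)
  edges <- edges[order(edges$ps_a, edges$ps_b), , drop = FALSE]
  rownames(edges) <- NULL
  net <- structure(list(name = "BSN",
                        nodes = sort(unique(c(edges$ps_a, edges$ps_b))),
                        edges = edges, threshold = 0),
                   class = "similarity_network")
  contrib <- table(factor(edges$provenance, levels = names(inputs))) / nrow(edges)
  attr(net, "contribution") <- c(contrib)
  net
}

.as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("ps_a", "ps_b")], directed = FALSE,
    vertices = data.frame(name = net$nodes))
  igraph::set_edge_attr(g, "weight", value = net$edges$w)
}

#' Unweighted topology statistics of a network
#'
#' Reports the standard network-analysis parameters on the (thresholded)
#' graph: node and edge counts, average connectivity <k> = 2E/n, average
#' local clustering coefficient <C> (C_i = 0 for nodes of degree < 2,
#' included in the mean), characteristic path length <l> averaged over
#' connected node pairs only, density = 2E/(n(n-1)), the number of connected
#' components, and the giant-component size.
#'
#' @param net a `similarity_network` with at least 2 nodes.
#' @return an object of class `network_stats`.
#' @export
topology_stats <- function(net) {
  if (length(net$nodes) < 2L) stop("network has fewer than 2 nodes")
  g <- .as_igraph(net)
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  ci <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  d <- igraph::distances(g, weights = NA)
  finite <- d[upper.tri(d)]
  finite <- finite[is.finite(finite)]
  comp <- igraph::components(g)
  structure(list(
    name = net$name, threshold = net$threshold,
    n_nodes = as.integer(n), n_edges = as.integer(e),
    mean_k = 2 * e / n,
    mean_C = mean(ci),
    mean_l = if (length(finite)) mean(finite) else NA_real_,
    density = 2 * e / (n * (n - 1)),
    n_components = as.integer(comp$no),
    gcc_size = as.integer(max(comp$csize))
  ), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf(
    "<network_stats> %s @ %g: n=%d E=%d <k>=%.3f <C>=%.3f <l>=%.3f density=%.3f components=%d (GCC %d)\n",
    x$name, x$threshold, x$n_nodes, x$n_edges, x$mean_k, x$mean_C, x$mean_l,
    x$density, x$n_components, x$gcc_size))
  invisible(x)
}

#' Analytic network statistics from node and edge counts
#'
#' The count-only identities of [topology_stats()]: average connectivity
#' `2E/n` and density `2E/(n(n-1))`. Useful for checking reported network
#' tables without the underlying graph.
#'
#' @param n_nodes,n_edges counts.
#' @return list with `mean_k` and `density`.
#' @export
network_stats_from_counts <- function(n_nodes, n_edges) {
  list(mean_k = 2 * n_edges / n_nodes,
       density = 2 * n_edges / (n_nodes * (n_nodes - 1)))
}

#' Percentage bookkeeping of a threshold step
#'
#' Percent of edges removed and percent of nodes lost between an unthresholded
#' and a thresholded network (or their counts).
#'
#' @param n0,e0 node and edge counts before thresholding.
#' @param n1,e1 node and edge counts after thresholding.
#' @return list with `pct_edges_removed` and `pct_nodes_lost` (0-100 scale).
#' @export
threshold_report <- function(n0, e0, n1, e1) {
  list(pct_edges_removed = 100 * (e0 - e1) / e0,
       pct_nodes_lost = 100 * (n0 - n1) / n0)
}

#' Node/edge retention as a function of the similarity threshold
#'
#' For each threshold, the fractions of the unthresholded network's nodes and
#' edges that survive strict-`>` filtering. Both series are non-increasing and
#' start at 1 for threshold 0.
#'
#' @param net an unthresholded `similarity_network`.
#' @param thresholds ascending numeric vector.
#' @return data.frame with columns `threshold`, `node_fraction`,
#'   `edge_fraction`.
#' @export
fragmentation_curve <- function(net, thresholds) {
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  n0 <- length(net$nodes)
  e0 <- nrow(net$edges)
  rows <- lapply(thresholds, function(t) {
    ft <- apply_threshold(net, t)
    c(t, length(ft$nodes) / n0, nrow(ft$edges) / e0)
  })
  m <- do.call(rbind, rows)
  data.frame(threshold = m[, 1], node_fraction = m[, 2], edge_fraction = m[, 3])
}

#' Smallest threshold retaining at most a target node fraction
#'
#' Walks the sorted distinct edge weights (plus 0) upward and returns the
#' first threshold at which the retained-node fraction drops to `target` or
#' below. A target of 1 returns threshold 0.
#'
#' @param net an unthresholded `similarity_network`.
#' @param target node fraction in (0, 1].
#' @return list with `threshold`, `fraction` (achieved node fraction), and
#'   `n_nodes` retained.
#' @export
threshold_for_node_fraction <- function(net, target) {
  stopifnot(target > 0, target <= 1)
  n0 <- length(net$nodes)
  for (t in c(0, sort(unique(net$edges$w)))) {
    ft <- apply_threshold(net, t)
    frac <- length(ft$nodes) / n0
    if (frac <= target) {
      return(list(threshold = t, fraction = frac, n_nodes = length(ft$nodes)))
    }
  }
  list(threshold = max(net$edges$w), fraction = 0, n_nodes = 0L) # unreachable
}

#' Islands of a thresholded network
#'
#' Islands are the connected components of the thresholded graph.
#'
#' @param net a `similarity_network`.
#' @return data.frame with columns `ps_id` and `island` (components numbered
#'   by decreasing size, ties by smallest member id).
#' @export
islands <- function(net) {
  g <- .as_igraph(net)
  comp <- igraph::components(g)
  member <- comp$membership
  first_id <- vapply(seq_len(comp$no),
                     function(i) min(names(member)[member == i]), character(1))
  rank <- order(-comp$csize, first_id)
  remap <- integer(comp$no)
  remap[rank] <- seq_len(comp$no)
  df <- data.frame(ps_id = names(member), island = remap[member],
                   stringsAsFactors = FALSE)
  df[order(df$island, df$ps_id), , drop = FALSE]
}

#' Write a network as a weighted edge-list TSV or GraphML
#'
#' Both are Cytoscape-importable; the edge list carries source, target,
#' weight and (for the merged biological network) provenance columns.
#'
#' @param net a `similarity_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(net, path) {
  e <- net$edges
  names(e)[names(e) == "ps_a"] <- "source"
  names(e)[names(e) == "ps_b"] <- "target"
  names(e)[names(e) == "w"] <- "weight"
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
write_graphml <- function(net, path) {
  g <- .as_igraph(net)
  if (!is.null(net$edges$provenance)) {
    g <- igraph::set_edge_attr(g, "provenance", value = net$edges$provenance)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read an edge-list TSV written by [write_edgelist()]
#'
#' @param path input path.
#' @param name network name.
#' @return a `similarity_network` (threshold 0 contract not enforced; use
#'   [assemble()] when completeness must hold).
#' @export
read_edgelist <- function(path, name) {
  e <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  edges <- data.frame(ps_a = pmin(e$source, e$target),
                      ps_b = pmax(e$source, e$target),
                      w = e$weight, stringsAsFactors = FALSE)
  if (!is.null(e$provenance)) edges$provenance <- e$provenance
  edges <- edges[order(edges$ps_a, edges$ps_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(name = name, nodes = sort(unique(c(edges$ps_a, edges$ps_b))),
                 edges = edges, threshold = 0),
            class = "similarity_network")
}
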