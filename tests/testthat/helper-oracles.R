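# Independent brute-force oracles and random-structure generators used across
# the suite. These re-derive expected values by enumeration, never through the
# package's own code paths.

# Random DAG: term i (topological order) gets 1-2 parents among earlier terms.
# Ids are a shuffled labeling so lexicographic order differs from topological.
random_dag <- function(n, namespace = "HPO") {
  ids <- sprintf("T:%04d", sample.int(9999, n))
  ord <- seq_len(n)
  terms <- vector("list", n)
  for (i in ord) {
    parents <- if (i == 1L) character(0) else {
      k <- min(i - 1L, sample(1:2, 1))
      ids[sample.int(i - 1L, k)]
    }
    terms[[i]] <- list(id = ids[i], name = paste0("term ", i), parents = parents)
  }
  ontology_dag(terms, namespace)
}

# Random annotation corpus over a DAG: each entity annotated with 1-4 terms.
random_annotations <- function(dag, n_entities) {
  live <- dag$ids[!dag$obsolete]
  ann <- lapply(seq_len(n_entities), function(i) {
    sample(live, sample(1:4, 1))
  })
  names(ann) <- paste0("E", seq_len(n_entities))
  ann
}

# Transitive closure by repeated parent expansion (no recursion, no cache).
brute_ancestors <- function(dag, t) {
  res <- t
  frontier <- t
  while (length(frontier)) {
    up <- unique(unlist(dag$parents[frontier], use.names = FALSE))
    up <- setdiff(up, res)
    res <- c(res, up)
    frontier <- up
  }
  res
}

# Exhaustive argmax over the ancestor intersection.
brute_mica <- function(dag, ic, t1, t2) {
  common <- intersect(brute_ancestors(dag, t1), brute_ancestors(dag, t2))
  vals <- ic$ic[common]
  sort(common[vals == max(vals)])[1]
}

# Exhaustive minimization of summed hop distance over the ancestor
# intersection; ties by higher IC then smallest id.
brute_cca <- function(dag, t1, t2, ic = NULL) {
  hops <- function(t) {
    d <- stats::setNames(0L, t)
    frontier <- t
    k <- 0L
    while (length(frontier)) {
      k <- k + 1L
      up <- setdiff(unique(unlist(dag$parents[frontier], use.names = FALSE)),
                    names(d))
      if (length(up)) d[up] <- k
      frontier <- up
    }
    d
  }
  d1 <- hops(t1)
  d2 <- hops(t2)
  common <- intersect(names(d1), names(d2))
  tot <- d1[common] + d2[common]
  best <- common[tot == min(tot)]
  if (length(best) > 1L && !is.null(ic)) {
    v <- ic$ic[best]
    best <- best[v == max(v)]
  }
  sort(best)[1]
}

# Naive O(m^3) average-linkage agglomeration on a distance matrix; returns the
# sequence of merge heights.
naive_average_linkage_heights <- function(D) {
  m <- nrow(D)
  clusters <- as.list(seq_len(m))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters[[length(clusters) + 1L]] <- merged
  }
  heights
}

# Adjusted Rand index from the pair-counting contingency form.
ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  sa <- sum(ch2(rowSums(tab)))
  sb <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  exp_idx <- sa * sb / n
  (sij - exp_idx) / ((sa + sb) / 2 - exp_idx)
}

# A complete random weighted network over n PS ids.
random_network <- function(n, name = "NET", wfun = stats::runif) {
  ids <- sprintf("PS%06d", seq_len(n))
  pairs <- utils::combn(ids, 2)
  co <- data.frame(ps_a = pairs[1, ], ps_b = pairs[2, ],
                   w = wfun(ncol(pairs)), stringsAsFactors = FALSE)
  assemble(co, name)
}
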