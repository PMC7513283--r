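# Hierarchical clustering of PS by their similarity profiles, and the
# clinical-versus-biological quadrant analysis.

#' Full symmetric PS-PS similarity matrix
#'
#' Assembles the m x m symmetric matrix M with M_ij the similarity coefficient
#' of PS i and PS j; the diagonal is each PS's self-coefficient (BMA of the
#' self-comparison matrix), so the coefficient table must include self rows
#' (`all_pair_coefficients(include_self = TRUE)`).
#'
#' @param coefficients data.frame with columns `ps_a`, `ps_b`, `w`, covering
#'   all pairs (including self pairs) of `ps_ids`.
#' @param ps_ids the PS to include, in the desired row order.
#' @return a named m x m numeric matrix.
#' @export
full_similarity_matrix <- function(coefficients, ps_ids) {
  m <- length(ps_ids)
  M <- matrix(NA_real_, m, m, dimnames = list(ps_ids, ps_ids))
  idx <- coefficients$ps_a %in% ps_ids & coefficients$ps_b %in% ps_ids
  e <- coefficients[idx, , drop = FALSE]
  M[cbind(e$ps_a, e$ps_b)] <- e$w
  M[cbind(e$ps_b, e$ps_a)] <- e$w
  if (anyNA(M)) {
    bad <- which(is.na(M), arr.ind = TRUE)[1, ]
    stop("missing coefficient for pair ", ps_ids[bad[1]], " / ", ps_ids[bad[2]])
  }
  M
}

#' Uncentered Pearson distance
#'
#' `1 - sum(x*y) / sqrt(sum(x^2) * sum(y^2))` — the cosine-type correlation
#' distance used for the hierarchical clustering of PS similarity profiles.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return a distance in `[0, 2]`.
#' @export
uncentered_pearson_distance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("vectors must have equal length >= 2")
  }
  nx <- sum(x^2)
  ny <- sum(y^2)
  if (nx == 0 || ny == 0) stop("zero-norm vector")
  1 - sum(x * y) / sqrt(nx * ny)
}

# Uncentered-Pearson distance matrix between the rows of M.
.uncentered_pearson_distmat <- function(M) {
  ss <- rowSums(M^2)
  if (any(ss == 0)) stop("zero-norm row(s): ", paste(rownames(M)[ss == 0], collapse = ", "))
  S <- M %*% t(M)
  D <- 1 - S / sqrt(outer(ss, ss))
  D[D < 0] <- 0 # numeric guard
  diag(D) <- 0
  D
}

#' Average-linkage clustering of PS similarity profiles
#'
#' Agglomerative (UPGMA) clustering of the rows of the full similarity matrix
#' under the uncentered Pearson distance, cut to exactly `k` clusters.
#'
#' @param M a symmetric matrix from [full_similarity_matrix()] (rows are the
#'   PS's similarity profiles).
#' @param k number of clusters (1 <= k <= nrow(M)).
#' @return an object of class `ps_clustering`: list with `assignment` (named
#'   integer), `hclust` (the merge tree), and `k`.
#' @export
average_linkage_cluster <- function(M, k) {
  stopifnot(k >= 1, k <= nrow(M))
  D <- .uncentered_pearson_distmat(M)
  if (k > 1L && all(D[upper.tri(D)] == 0)) {
    warning("all profiles identical; split is arbitrary (but deterministic)")
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  structure(list(assignment = stats::cutree(hc, k = k), hclust = hc, k = k),
            class = "ps_clustering")
}

#' @export
print.ps_clustering <- function(x, ...) {
  cat(sprintf("<ps_clustering> %d leaves in %d clusters (sizes: %s)\n",
              length(x$assignment), x$k,
              paste(sort(table(x$assignment), decreasing = TRUE), collapse = ", ")))
  invisible(x)
}

#' Export a clustering dendrogram as Newick text
#'
#' @param clustering a [average_linkage_cluster()] result.
#' @param path optional output path; when `NULL` the Newick string is
#'   returned.
#' @return the Newick string, invisibly when written to `path`.
#' @export
dendrogram_newick <- function(clustering, path = NULL) {
  phy <- ape::as.phylo(clustering$hclust)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Quadrant partition of PS pairs by clinical vs biological similarity
#'
#' Evaluated pairs are the intersection of the two coefficient tables' pairs.
#' With threshold T (default 2): quadrant II — both coefficients >= T;
#' III — biological >= T, clinical < T; IV — clinical >= T, biological < T;
#' I — both < T.
#'
#' @param clinical,biological data.frames with columns `ps_a`, `ps_b`, `w`
#'   (self pairs ignored).
#' @param threshold the high-similarity cutoff (on the coefficient scale).
#' @return an object of class `quadrant_summary`: `threshold`, `counts`
#'   (named I/II/III/IV), and `pairs` (one sorted data.frame per quadrant with
#'   both coefficients).
#' @export
quadrant_counts <- function(clinical, biological, threshold = 2) {
  keyify <- function(df) {
    df <- df[df$ps_a != df$ps_b, , drop = FALSE]
    setNames(df$w, paste(pmin(df$ps_a, df$ps_b), pmax(df$ps_a, df$ps_b), sep = "\r"))
  }
  cw <- keyify(clinical)
  bw <- keyify(biological)
  keys <- sort(intersect(names(cw), names(bw)))
  if (!length(keys)) stop("no PS pairs shared between the two coefficient tables")
  cv <- cw[keys]
  bv <- bw[keys]
  q <- ifelse(cv >= threshold & bv >= threshold, "II",
       ifelse(bv >= threshold, "III",
       ifelse(cv >= threshold, "IV", "I")))
  pair <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  df <- data.frame(ps_a = pair[, 1], ps_b = pair[, 2],
                   clinical = unname(cv), biological = unname(bv),
                   quadrant = q, stringsAsFactors = FALSE)
  counts <- vapply(c("I", "II", "III", "IV"), function(x) sum(q == x), integer(1))
  structure(list(threshold = threshold, counts = counts,
                 pairs = split(df[, 1:4], factor(df$quadrant, levels = c("I", "II", "III", "IV")))),
            class = "quadrant_summary")
}

#' @export
print.quadrant_summary <- function(x, ...) {
  cat(sprintf("<quadrant_summary> threshold %g: I=%d II=%d III=%d IV=%d (total %d pairs)\n",
              x$threshold, x$counts["I"], x$counts["II"], x$counts["III"],
              x$counts["IV"], sum(x$counts)))
  invisible(x)
}
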