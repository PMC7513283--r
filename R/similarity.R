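# PS-PS similarity: pairwise MICA-IC matrices and the best-match-average
# coefficient.

#' Pairwise MICA-IC matrix of two term profiles
#'
#' Entry (i, j) is the information content of the most informative common
#' ancestor of the i-th term of profile A and the j-th term of profile B.
#' Profiles sharing only the root yield an all-zero matrix.
#'
#' @param pa,pb term profiles (see [representative_profile()]) in the same
#'   namespace.
#' @param dag the namespace's [ontology_dag()].
#' @param ic a [compute_ic()] table for `dag`.
#' @return a |pa| x |pb| numeric matrix (nats).
#' @export
pairwise_ic_matrix <- function(pa, pb, dag, ic) {
  if (!identical(pa$namespace, pb$namespace)) {
    stop("namespace mismatch: ", pa$namespace, " vs ", pb$namespace)
  }
  .mica_ic_matrix(dag, ic, pa$terms, pb$terms)
}

#' Best-match-average similarity coefficient
#'
#' The average of all maximum similarities on each row and column of the
#' pairwise term-similarity matrix:
#' `w = (sum_i max_j m_ij + sum_j max_i m_ij) / (nrow + ncol)`.
#' The alternative reading — the mean of the row-wise average and the
#' column-wise average of the maxima — coincides for square matrices and is
#' available via `method = "two-mean"`.
#'
#' @param m a non-empty numeric matrix from [pairwise_ic_matrix()].
#' @param method `"rowcol-sum"` (default) or `"two-mean"`.
#' @return the coefficient w (non-negative, nats).
#' @export
best_match_average <- function(m, method = c("rowcol-sum", "two-mean")) {
  method <- match.arg(method)
  if (!length(m)) stop("empty similarity matrix")
  row_max <- apply(m, 1, max)
  col_max <- apply(m, 2, max)
  if (method == "rowcol-sum") {
    (sum(row_max) + sum(col_max)) / (nrow(m) + ncol(m))
  } else {
    (mean(row_max) + mean(col_max)) / 2
  }
}

#' Similarity coefficients for all PS pairs
#'
#' Computes the best-match-average coefficient for every unordered pair of
#' profiles (n(n-1)/2 coefficients for n profiles), optionally including each
#' PS's self-coefficient (the BMA of its self-comparison matrix, used as the
#' diagonal in clustering).
#'
#' @param profiles list of term profiles, all in the same namespace, one per
#'   PS.
#' @param dag,ic the namespace's DAG and IC table.
#' @param include_self also emit `ps_a == ps_b` rows.
#' @return a data.frame with columns `ps_a`, `ps_b`, `namespace`, `w`, ordered
#'   by sorted id pairs.
#' @export
all_pair_coefficients <- function(profiles, dag, ic, include_self = FALSE) {
  profiles <- profiles[!vapply(profiles, is.null, logical(1))]
  ids <- vapply(profiles, function(p) p$ps_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate ps_id in profiles: ", paste(ids[duplicated(ids)], collapse = ", "))
  }
  if (length(profiles) < 2L) stop("need at least two profiles")
  ns <- unique(vapply(profiles, function(p) p$namespace, character(1)))
  if (length(ns) != 1L) stop("profiles span multiple namespaces")
  ord <- order(ids)
  profiles <- profiles[ord]
  ids <- ids[ord]

  # one MICA-IC lookup over the unique terms of all profiles, indexed per pair
  uterms <- sort(unique(unlist(lapply(profiles, `[[`, "terms"), use.names = FALSE)))
  big <- .mica_ic_matrix(dag, ic, uterms, uterms)

  n <- length(profiles)
  res <- vector("list", n * (n - 1) / 2 + if (include_self) n else 0L)
  k <- 0L
  for (i in seq_len(n)) {
    ta <- profiles[[i]]$terms
    j0 <- if (include_self) i else i + 1L
    if (j0 > n) next
    for (j in j0:n) {
      tb <- profiles[[j]]$terms
      m <- big[ta, tb, drop = FALSE]
      k <- k + 1L
      res[[k]] <- list(ids[i], ids[j], best_match_average(m))
    }
  }
  res <- res[seq_len(k)]
  data.frame(
    ps_a = vapply(res, `[[`, character(1), 1),
    ps_b = vapply(res, `[[`, character(1), 2),
    namespace = ns,
    w = vapply(res, `[[`, numeric(1), 3),
    stringsAsFactors = FALSE
  )
}

#' Write / read a coefficient edge-list TSV
#'
#' The interchange format between the similarity and network stages
#' (Cytoscape-importable).
#'
#' @param coefficients a data.frame from [all_pair_coefficients()].
#' @param path file path.
#' @return `path` (writer) / the data.frame (reader).
#' @export
write_coefficients <- function(coefficients, path) {
  utils::write.table(coefficients, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "character", "numeric"))
}
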