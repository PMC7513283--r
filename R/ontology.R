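# Ontology DAGs, Resnik information content, and shared-ancestor queries.

#' Construct an ontology DAG
#'
#' Builds a rooted directed acyclic graph of ontology terms from parsed term
#' records. Terms are connected by `is_a` (parent) links only. The DAG must
#' have exactly one root (a non-obsolete term with no parents); obsolete terms
#' are retained for alt-id resolution but carry no parents and are excluded
#' from all ancestor queries.
#'
#' @param terms a list of term records, each a list with elements `id`,
#'   `name`, `parents` (character vector of parent ids), and optionally
#'   `obsolete` (logical) and `alt_ids` (character vector).
#' @param namespace ontology tag, one of `"HPO"`, `"GO-BP"`, `"GO-CC"`,
#'   `"GO-MF"`, `"DO"` (free-form tags are accepted for synthetic ontologies).
#' @return an object of class `ontology_dag` with precomputed ancestor sets.
#' @export
ontology_dag <- function(terms, namespace) {
  ids <- vapply(terms, function(t) t$id, character(1))
  if (any(!nzchar(ids))) stop("empty term id")
  if (anyDuplicated(ids)) {
    stop("duplicate term ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(terms) <- ids
  obsolete <- vapply(terms, function(t) isTRUE(t$obsolete), logical(1))
  parents <- lapply(terms, function(t) {
    if (isTRUE(t$obsolete)) character(0) else unique(as.character(t$parents))
  })
  labels <- vapply(terms, function(t) {
    if (is.null(t$name)) "" else as.character(t$name)[1]
  }, character(1))

  # alt_id -> primary id map
  alt <- character(0)
  for (t in terms) {
    if (length(t$alt_ids)) {
      a <- setNames(rep(t$id, length(t$alt_ids)), t$alt_ids)
      alt <- c(alt, a)
    }
  }
  if (anyDuplicated(names(alt))) alt <- alt[!duplicated(names(alt))]

  unresolved <- setdiff(unique(unlist(parents)), ids)
  if (length(unresolved)) {
    stop("parent ids not in ontology: ", paste(unresolved, collapse = ", "))
  }

  live <- ids[!obsolete]
  roots <- live[vapply(parents[live], length, integer(1)) == 0L]
  if (length(roots) == 0L) stop("no root term (missing root)")
  if (length(roots) > 1L) {
    stop("multiple roots found: ", paste(roots, collapse = ", "))
  }

  dag <- structure(
    list(ids = ids, labels = labels, parents = parents, obsolete = obsolete,
         alt = alt, namespace = namespace, root = roots),
    class = "ontology_dag"
  )
  dag$anc <- .compute_ancestor_closure(dag)
  dag
}

# Reflexive transitive closure over parent links for every non-obsolete term.
# Detects cycles (a term encountered while its own closure is being expanded).
.compute_ancestor_closure <- function(dag) {
  live <- dag$ids[!dag$obsolete]
  anc <- vector("list", length(live))
  names(anc) <- live
  state <- new.env(parent = emptyenv()) # 1 = in progress, 2 = done
  expand <- function(t, trail) {
    s <- state[[t]]
    if (identical(s, 2L)) return(anc[[t]])
    if (identical(s, 1L)) {
      stop("cycle detected involving terms: ",
           paste(c(trail[which(trail == t):length(trail)], t), collapse = " -> "))
    }
    state[[t]] <- 1L
    up <- dag$parents[[t]]
    res <- t
    for (p in up) res <- union(res, expand(p, c(trail, t)))
    anc[[t]] <<- res
    state[[t]] <- 2L
    res
  }
  for (t in live) expand(t, character(0))
  anc
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("<ontology_dag> namespace=%s terms=%d (obsolete %d) root=%s\n",
              x$namespace, length(x$ids), sum(x$obsolete), x$root))
  invisible(x)
}

# Resolve a (possibly alternate) id to its primary id; error if unknown.
resolve_id <- function(dag, t, allow_obsolete = FALSE) {
  if (!t %in% dag$ids) {
    if (t %in% names(dag$alt)) t <- unname(dag$alt[[t]]) else
      stop("unknown term id: ", t)
  }
  if (!allow_obsolete && dag$obsolete[[t]]) stop("term is obsolete: ", t)
  t
}

#' Ancestors of a term
#'
#' Reflexive transitive closure over `is_a` links: the result contains the
#' term itself and every term reachable through parent links, always including
#' the root. Alternate ids are resolved to their primary term first.
#'
#' @param dag an [ontology_dag()].
#' @param t a term id (primary or alternate).
#' @return character vector of ancestor term ids (including `t`).
#' @export
ancestors <- function(dag, t) {
  t <- resolve_id(dag, t)
  dag$anc[[t]]
}

#' Resnik information content from an annotation corpus
#'
#' Computes, for every non-obsolete term, the annotation-frequency information
#' content IC(t) = -ln p(t), where p(t) is the fraction of annotated entities
#' whose annotations fall on t or any of its descendants (equivalently, whose
#' upward-propagated annotation set contains t). The root covers every
#' annotated entity, so IC(root) = 0. Terms covering no entity are assigned
#' the maximum observed IC so that downstream similarity coefficients stay
#' finite.
#'
#' @param dag an [ontology_dag()].
#' @param annotations named list, entity id -> character vector of term ids.
#' @return an object of class `ic_table`: a list with `ic` (named numeric,
#'   nats) and `corpus_size` (number of annotated entities counted).
#' @export
compute_ic <- function(dag, annotations) {
  if (length(annotations) == 0L) stop("empty annotation corpus")
  live <- dag$ids[!dag$obsolete]
  counts <- setNames(integer(length(live)), live)
  n_used <- 0L
  for (terms in annotations) {
    kept <- character(0)
    for (t in terms) {
      if (t %in% names(dag$alt)) t <- unname(dag$alt[[t]])
      if (!t %in% dag$ids) {
        warning("annotation to unknown term dropped: ", t)
      } else if (dag$obsolete[[t]]) {
        warning("annotation to obsolete term dropped: ", t)
      } else {
        kept <- c(kept, t)
      }
    }
    if (!length(kept)) next
    n_used <- n_used + 1L
    cover <- unique(unlist(dag$anc[kept], use.names = FALSE))
    counts[cover] <- counts[cover] + 1L
  }
  if (n_used == 0L) stop("no usable annotations in corpus")
  ic <- setNames(rep(NA_real_, length(live)), live)
  seen <- counts > 0L
  ic[seen] <- -log(counts[seen] / n_used)
  max_ic <- max(ic[seen])
  ic[!seen] <- max_ic
  structure(list(ic = ic, corpus_size = n_used), class = "ic_table")
}

#' @export
print.ic_table <- function(x, ...) {
  cat(sprintf("<ic_table> %d terms, corpus of %d entities, max IC %.4f nats\n",
              length(x$ic), x$corpus_size, max(x$ic)))
  invisible(x)
}

#' Most informative common ancestor (MICA)
#'
#' Returns the shared ancestor of two terms with maximal information content.
#' The root is always a common ancestor, so a result always exists. Ties on IC
#' are broken by the lexicographically smallest term id, making runs
#' reproducible.
#'
#' @param dag an [ontology_dag()].
#' @param ic an [compute_ic()] table for `dag`.
#' @param t1,t2 term ids.
#' @return a single term id.
#' @export
mica <- function(dag, ic, t1, t2) {
  common <- intersect(ancestors(dag, t1), ancestors(dag, t2))
  vals <- ic$ic[common]
  best <- common[vals == max(vals)]
  sort(best)[1]
}

#' Closest common ancestor by hop distance
#'
#' Returns the common ancestor minimizing the summed upward hop distance from
#' the two terms. Ties are broken by higher IC (when an IC table is supplied),
#' then by the lexicographically smallest id.
#'
#' @param dag an [ontology_dag()].
#' @param t1,t2 term ids.
#' @param ic optional [compute_ic()] table used for tie-breaking.
#' @return a single term id.
#' @export
closest_common_ancestor <- function(dag, t1, t2, ic = NULL) {
  d1 <- .updistance(dag, resolve_id(dag, t1))
  d2 <- .updistance(dag, resolve_id(dag, t2))
  common <- intersect(names(d1), names(d2))
  tot <- d1[common] + d2[common]
  best <- common[tot == min(tot)]
  if (length(best) > 1L && !is.null(ic)) {
    v <- ic$ic[best]
    best <- best[v == max(v)]
  }
  sort(best)[1]
}

# Minimal hop distance from t to each of its ancestors (BFS upward).
.updistance <- function(dag, t) {
  dist <- setNames(0L, t)
  frontier <- t
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    up <- unique(unlist(dag$parents[frontier], use.names = FALSE))
    up <- setdiff(up, names(dist))
    if (length(up)) dist[up] <- d
    frontier <- up
  }
  dist
}

# IC(mica(a, b)) for all pairs of two term vectors; shared across the
# similarity module so repeated terms are looked up, not recomputed.
.mica_ic_matrix <- function(dag, ic, terms_a, terms_b) {
  ua <- unique(terms_a)
  ub <- unique(terms_b)
  m <- matrix(0, length(ua), length(ub), dimnames = list(ua, ub))
  for (i in seq_along(ua)) {
    anc_i <- dag$anc[[resolve_id(dag, ua[i])]]
    for (j in seq_along(ub)) {
      common <- intersect(anc_i, dag$anc[[resolve_id(dag, ub[j])]])
      m[i, j] <- max(ic$ic[common])
    }
  }
  m[terms_a, terms_b, drop = FALSE]
}
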