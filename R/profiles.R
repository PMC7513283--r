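# Intra-PS reduction: from the member diseases' annotations to M
# representative terms per ontology.

#' Representative term profile of a phenotypic series
#'
#' Reduces the annotations of a PS's member diseases to one representative
#' term per original annotation (M original terms in, M representative terms
#' out). For each original term t of each annotated member, the term is
#' compared against every other annotated member's term set: the shared term
#' is t itself when the other member also carries it, otherwise the closest
#' common ancestor with the other member's best-matching term. The resulting
#' per-term list of shared terms is sorted in ascending order of specificity
#' (IC), and the middle element (0-based index `floor(L/2)`, i.e. the more
#' specific of the two middles for even L) becomes t's representative. A PS
#' with a single annotated member keeps its terms unchanged.
#'
#' For clinical profiles the member annotation sets are the diseases' HPO
#' terms; for biological profiles each disease's set is the union of the GO
#' terms (in `dag`'s sub-ontology) of its gene products.
#'
#' @param ps a PS record (or PS id) from `corpus`.
#' @param corpus an [annotation_corpus()].
#' @param dag the [ontology_dag()] of the target namespace.
#' @param ic a [compute_ic()] table for `dag`.
#' @param source `"clinical"` (HPO) or `"biological"` (GO).
#' @return an object of class `term_profile` (`ps_id`, `namespace`, `terms`,
#'   `source`), or `NULL` when no member disease carries usable annotations
#'   in this namespace (the PS is then excluded from that network).
#' @export
representative_profile <- function(ps, corpus, dag, ic,
                                   source = c("clinical", "biological")) {
  source <- match.arg(source)
  if (is.character(ps)) ps <- corpus$series[[ps]]
  sets <- .member_term_sets(ps, corpus, dag, source)
  if (!length(sets)) return(NULL)

  if (length(sets) == 1L) {
    terms <- sets[[1]]
  } else {
    terms <- character(0)
    for (i in seq_along(sets)) {
      others <- sets[-i]
      for (t in sets[[i]]) {
        shared <- vapply(others, function(os) .shared_term(t, os, dag, ic),
                         character(1))
        icv <- ic$ic[shared]
        ord <- order(icv, shared)   # ascending specificity, ties by id
        shared <- shared[ord]
        terms <- c(terms, shared[floor(length(shared) / 2) + 1L])
      }
    }
  }
  structure(list(ps_id = ps$ps_id, namespace = dag$namespace,
                 terms = unname(terms), source = source),
            class = "term_profile")
}

# Per-member annotation sets in dag's namespace, alt-resolved, with unknown
# and obsolete terms dropped; members with empty sets are omitted.
.member_term_sets <- function(ps, corpus, dag, source) {
  sets <- list()
  for (d_id in ps$member_diseases) {
    d <- corpus$diseases[[d_id]]
    raw <- if (source == "clinical") {
      d$hpo_terms
    } else {
      unique(unlist(lapply(d$gene_products, function(s) {
        corpus$gene_products[[s]]$go_terms[[dag$namespace]]
      }), use.names = FALSE))
    }
    kept <- character(0)
    for (t in raw) {
      rt <- tryCatch(resolve_id(dag, t), error = function(e) NA_character_)
      if (!is.na(rt)) kept <- c(kept, rt)
    }
    if (length(kept)) sets[[d_id]] <- unique(kept)
  }
  sets
}

# Shared term of original term t against another member's term set: t itself
# if present; otherwise the closest common ancestor with the counterpart term
# that yields the most informative shared ancestor (ties by the counterpart's
# own IC, then by term id).
.shared_term <- function(t, other_set, dag, ic) {
  if (t %in% other_set) return(t)
  best_anc <- NA_character_
  best_key <- c(-Inf, -Inf)
  for (t2 in sort(other_set)) {
    a <- closest_common_ancestor(dag, t, t2, ic)
    key <- c(ic$ic[[a]], ic$ic[[t2]])
    if (key[1] > best_key[1] ||
        (key[1] == best_key[1] && key[2] > best_key[2])) {
      best_key <- key
      best_anc <- a
    }
  }
  best_anc
}

#' @export
print.term_profile <- function(x, ...) {
  cat(sprintf("<term_profile> %s [%s, %s]: %d terms\n",
              x$ps_id, x$namespace, x$source, length(x$terms)))
  invisible(x)
}
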