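# OBO 1.2/1.4 flat-file reading and writing (is_a edges only).

#' Parse an OBO flat file into an ontology DAG
#'
#' Reads `[Term]` stanzas (id, name, is_a, alt_id, is_obsolete, namespace) of
#' the hp.obo / go.obo / doid.obo dialects. Only `is_a` relationships are used;
#' `relationship:` tags (part_of, regulates, ...) are ignored. For GO, the
#' `namespace` argument selects which sub-ontology to keep; for HPO/DO all
#' terms are kept. Obsolete terms are retained but flagged, stripped of
#' parents, and excluded from ancestor queries. Alternate ids are mapped to
#' their primary term.
#'
#' @param path path to an OBO file (or a character vector of its lines).
#' @param namespace ontology tag: `"HPO"`, `"DO"`, `"GO-BP"`, `"GO-CC"`,
#'   `"GO-MF"`, or any tag for synthetic ontologies.
#' @return an [ontology_dag()].
#' @export
parse_obo <- function(path, namespace) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  go_ns <- c("GO-BP" = "biological_process",
             "GO-CC" = "cellular_component",
             "GO-MF" = "molecular_function")
  want_ns <- if (namespace %in% names(go_ns)) go_ns[[namespace]] else NULL

  terms <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function(cur) {
    if (is.null(cur) || is.null(cur$id)) return(NULL)
    if (!is.null(want_ns) && !is.null(cur$ns) && cur$ns != want_ns) return(NULL)
    cur
  }
  for (ln in lines) {
    ln <- sub("\\s*!.*$", "", ln)   # strip trailing comments
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[", ln)) {
      t <- flush(cur)
      if (!is.null(t)) terms[[length(terms) + 1L]] <- t
      cur <- if (ln == "[Term]") list(parents = character(0), alt_ids = character(0),
                                      obsolete = FALSE) else NULL
      in_term <- ln == "[Term]"
      next
    }
    if (!in_term || is.null(cur)) next
    kv <- regmatches(ln, regexpr(":", ln), invert = TRUE)[[1]]
    if (length(kv) != 2L) next
    key <- kv[1]
    val <- trimws(kv[2])
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "is_a") cur$parents <- c(cur$parents, val)
    else if (key == "alt_id") cur$alt_ids <- c(cur$alt_ids, val)
    else if (key == "namespace") cur$ns <- val
    else if (key == "is_obsolete" && val == "true") cur$obsolete <- TRUE
  }
  t <- flush(cur)
  if (!is.null(t)) terms[[length(terms) + 1L]] <- t
  if (!length(terms)) stop("no [Term] stanzas found")
  # drop parent links pointing outside the kept namespace (GO sub-ontology cuts)
  kept_ids <- vapply(terms, `[[`, character(1), "id")
  terms <- lapply(terms, function(t) {
    t$parents <- intersect(t$parents, kept_ids)
    t
  })
  ontology_dag(terms, namespace)
}

#' Write an ontology DAG as an OBO flat file
#'
#' Emits `[Term]` stanzas that [parse_obo()] reads back to an identical DAG.
#'
#' @param dag an [ontology_dag()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  go_ns <- c("GO-BP" = "biological_process",
             "GO-CC" = "cellular_component",
             "GO-MF" = "molecular_function")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (id in dag$ids) {
    writeLines("[Term]", con)
    writeLines(paste0("id: ", id), con)
    if (nzchar(dag$labels[[id]])) writeLines(paste0("name: ", dag$labels[[id]]), con)
    if (dag$namespace %in% names(go_ns)) {
      writeLines(paste0("namespace: ", go_ns[[dag$namespace]]), con)
    }
    alts <- names(dag$alt)[dag$alt == id]
    for (a in alts) writeLines(paste0("alt_id: ", a), con)
    for (p in dag$parents[[id]]) writeLines(paste0("is_a: ", p), con)
    if (dag$obsolete[[id]]) writeLines("is_obsolete: true", con)
    writeLines("", con)
  }
  invisible(path)
}
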