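# The PS -> disease -> gene-product corpus: container, parsers, writers.

#' Construct an annotation corpus
#'
#' The corpus ties together the three levels of the analysis: phenotypic
#' series (PS, groups of clinically similar diseases), member diseases with
#' their HPO phenotype and DO classification terms, and the diseases' causal
#' gene products with their GO annotations split by sub-ontology.
#'
#' @param diseases named list of disease records (`omim_id`, `label`,
#'   `hpo_terms`, `do_terms`, `gene_products`).
#' @param gene_products named list of gene-product records (`symbol`,
#'   `go_terms`: a list keyed by `"GO-BP"`, `"GO-CC"`, `"GO-MF"`).
#' @param series named list of PS records (`ps_id`, `label`,
#'   `member_diseases`, `do_class`).
#' @return an object of class `annotation_corpus`.
#' @export
annotation_corpus <- function(diseases, gene_products, series) {
  x <- structure(list(diseases = diseases, gene_products = gene_products,
                      series = series), class = "annotation_corpus")
  validate_corpus(x)
  x
}

#' Check referential integrity of a corpus
#'
#' Every disease referenced by a PS must exist, and every gene symbol
#' referenced by a disease must exist.
#'
#' @param corpus an [annotation_corpus()].
#' @return `corpus`, invisibly; errors on violation.
#' @export
validate_corpus <- function(corpus) {
  for (ps in corpus$series) {
    miss <- setdiff(ps$member_diseases, names(corpus$diseases))
    if (length(miss)) {
      stop("PS ", ps$ps_id, " references unknown diseases: ",
           paste(miss, collapse = ", "))
    }
    if (!length(ps$member_diseases)) stop("PS ", ps$ps_id, " has no member diseases")
  }
  for (d in corpus$diseases) {
    miss <- setdiff(d$gene_products, names(corpus$gene_products))
    if (length(miss)) {
      stop("disease ", d$omim_id, " references unknown gene products: ",
           paste(miss, collapse = ", "))
    }
  }
  invisible(corpus)
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat(sprintf("<annotation_corpus> %d PS, %d diseases, %d gene products\n",
              length(x$series), length(x$diseases), length(x$gene_products)))
  invisible(x)
}

.read_table_lines <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  lines[!grepl("^\\s*[#!]", lines) & nzchar(trimws(lines))]
}

#' Parse disease-phenotype annotations (phenotype_annotation.tab dialect)
#'
#' Reads the classic tab-delimited HPO disease-annotation layout (database,
#' disease id, disease name, qualifier, HPO term id, ...). Only OMIM-sourced
#' rows are kept; NOT-qualified rows and malformed rows are skipped and
#' counted.
#'
#' @param path file path (or character vector of lines).
#' @return named list, `"OMIM:<id>"` -> character vector of HPO term ids, with
#'   attributes `n_skipped` (malformed rows) and `n_non_omim`.
#' @export
parse_phenotype_annotations <- function(path) {
  rows <- .read_table_lines(path)
  if (!length(rows)) stop("no usable rows in phenotype annotation file")
  out <- list()
  n_skipped <- 0L
  n_non_omim <- 0L
  for (r in rows) {
    f <- strsplit(r, "\t", fixed = TRUE)[[1]]
    if (length(f) < 5L || !grepl("^HP:", f[5])) { n_skipped <- n_skipped + 1L; next }
    if (toupper(f[1]) != "OMIM") { n_non_omim <- n_non_omim + 1L; next }
    if (nzchar(f[4]) && grepl("NOT", f[4], fixed = TRUE)) next
    id <- paste0("OMIM:", sub("^OMIM:", "", f[2]))
    out[[id]] <- c(out[[id]], f[5])
  }
  if (!length(out)) stop("no usable OMIM annotation rows")
  out <- lapply(out, unique)
  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_non_omim") <- n_non_omim
  out
}

#' Parse a GAF 2.x gene-association file
#'
#' Splits annotations by GO aspect (P/F/C) into the `"GO-BP"` / `"GO-MF"` /
#' `"GO-CC"` namespaces. Rows whose qualifier contains `NOT` are dropped
#' (negation is not annotation). Evidence codes are kept by default; set
#' `exclude_evidence` to drop e.g. electronic (`"IEA"`) annotations.
#'
#' @param path file path (or character vector of lines).
#' @param exclude_evidence character vector of evidence codes to drop.
#' @return named list, gene symbol -> list of term-id vectors keyed by
#'   namespace.
#' @export
parse_gaf <- function(path, exclude_evidence = character(0)) {
  rows <- .read_table_lines(path)
  if (!length(rows)) stop("GAF file has no annotation rows")
  aspect_ns <- c(P = "GO-BP", F = "GO-MF", C = "GO-CC")
  out <- list()
  for (r in rows) {
    f <- strsplit(r, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L) next
    if (nzchar(f[4]) && grepl("NOT", f[4], fixed = TRUE)) next
    if (f[7] %in% exclude_evidence) next
    if (!f[9] %in% names(aspect_ns)) next
    sym <- f[3]
    ns <- aspect_ns[[f[9]]]
    out[[sym]][[ns]] <- c(out[[sym]][[ns]], f[5])
  }
  if (!length(out)) stop("GAF file has no usable annotation rows")
  lapply(out, function(g) lapply(g, unique))
}

# Extract "name, 123456" disease entries from an OMIM phenotype field.
.omim_phenotype_entries <- function(txt) {
  hits <- gregexpr("([^;]*?),\\s*(\\d{6})\\s*\\(\\d\\)", txt)[[1]]
  if (hits[1] == -1L) return(NULL)
  pieces <- regmatches(txt, gregexpr("([^;]*?),\\s*(\\d{6})\\s*\\(\\d\\)", txt))[[1]]
  lapply(pieces, function(p) {
    mim <- sub(".*,\\s*(\\d{6})\\s*\\(\\d\\).*", "\\1", p)
    lab <- trimws(sub(",\\s*\\d{6}\\s*\\(\\d\\).*", "", p))
    lab <- sub("^[\\[{?]+", "", lab)
    list(omim_id = paste0("OMIM:", mim), label = lab)
  })
}

#' Parse OMIM gene map, morbid map, and PS membership into a corpus skeleton
#'
#' Builds the PS -> disease -> gene chain. `genemap2` supplies, per gene, the
#' approved symbol and the disease MIM numbers in its Phenotypes column;
#' `morbidmap` supplies disease -> gene-symbol links; the PS membership table
#' (two tab-separated columns: PS id, disease MIM id; optional third column, a
#' PS label) supplies the series. Diseases without a mapped gene are retained
#' but have an empty gene set; PS whose diseases all fail to resolve are
#' dropped with a message. HPO/GO/DO annotations are attached separately.
#'
#' @param genemap path to a genemap2.txt-dialect file (may be `NULL`).
#' @param morbidmap path to a morbidmap.txt-dialect file (may be `NULL`).
#' @param ps_membership path to the PS membership table.
#' @return an [annotation_corpus()] skeleton (empty HPO/GO/DO term sets).
#' @export
parse_omim_maps <- function(genemap = NULL, morbidmap = NULL, ps_membership) {
  disease_genes <- list()   # omim disease id -> gene symbols
  disease_labels <- character(0)

  add_link <- function(omim_id, label, sym) {
    if (nzchar(sym)) {
      disease_genes[[omim_id]] <<- unique(c(disease_genes[[omim_id]], sym))
    } else if (is.null(disease_genes[[omim_id]])) {
      disease_genes[[omim_id]] <<- character(0)
    }
    if (is.na(disease_labels[omim_id]) || !nzchar(disease_labels[omim_id])) {
      disease_labels[omim_id] <<- label
    }
  }

  if (!is.null(genemap)) {
    for (r in .read_table_lines(genemap)) {
      f <- strsplit(r, "\t", fixed = TRUE)[[1]]
      if (length(f) < 13L) next
      sym <- trimws(f[9])
      if (!nzchar(sym)) sym <- trimws(strsplit(f[7], ",")[[1]][1])
      for (e in .omim_phenotype_entries(f[13])) add_link(e$omim_id, e$label, sym)
    }
  }
  if (!is.null(morbidmap)) {
    for (r in .read_table_lines(morbidmap)) {
      f <- strsplit(r, "\t", fixed = TRUE)[[1]]
      if (length(f) < 2L) next
      e <- .omim_phenotype_entries(f[1])
      if (is.null(e)) next
      sym <- trimws(strsplit(f[2], ",")[[1]][1])
      add_link(e[[1]]$omim_id, e[[1]]$label, sym)
    }
  }

  series <- list()
  for (r in .read_table_lines(ps_membership)) {
    f <- strsplit(r, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L) next
    ps_id <- f[1]
    omim_id <- paste0("OMIM:", sub("^OMIM:", "", f[2]))
    if (is.null(series[[ps_id]])) {
      series[[ps_id]] <- list(ps_id = ps_id,
                              label = if (length(f) >= 3L) f[3] else ps_id,
                              member_diseases = character(0), do_class = NA_character_)
    }
    series[[ps_id]]$member_diseases <-
      unique(c(series[[ps_id]]$member_diseases, omim_id))
    if (is.null(disease_genes[[omim_id]])) {
      # membership may name diseases absent from the maps; keep them gene-less
      disease_genes[[omim_id]] <- character(0)
      disease_labels[omim_id] <- omim_id
    }
  }
  if (!length(series)) stop("no PS found in membership file")

  diseases <- lapply(names(disease_genes), function(id) {
    list(omim_id = id,
         label = unname(disease_labels[id]),
         hpo_terms = character(0), do_terms = character(0),
         gene_products = disease_genes[[id]])
  })
  names(diseases) <- names(disease_genes)

  syms <- unique(unlist(disease_genes, use.names = FALSE))
  gene_products <- lapply(syms, function(s) list(symbol = s, go_terms = list()))
  names(gene_products) <- syms

  annotation_corpus(diseases, gene_products, series)
}

#' Attach HPO, GO and DO annotations to a corpus skeleton
#'
#' @param corpus an [annotation_corpus()].
#' @param hpo named list from [parse_phenotype_annotations()] (optional).
#' @param gaf named list from [parse_gaf()] (optional).
#' @param do_terms named list, disease id -> DO term ids (optional).
#' @return the updated corpus. Diseases with no HPO terms are reported: they
#'   are later excluded from clinical profiles.
#' @export
attach_annotations <- function(corpus, hpo = NULL, gaf = NULL, do_terms = NULL) {
  if (!is.null(hpo)) {
    for (id in names(corpus$diseases)) {
      if (!is.null(hpo[[id]])) corpus$diseases[[id]]$hpo_terms <- hpo[[id]]
    }
    n_bare <- sum(vapply(corpus$diseases, function(d) !length(d$hpo_terms), logical(1)))
    if (n_bare) message(n_bare, " diseases have no HPO annotations (excluded from clinical profiles)")
  }
  if (!is.null(do_terms)) {
    for (id in intersect(names(do_terms), names(corpus$diseases))) {
      corpus$diseases[[id]]$do_terms <- do_terms[[id]]
    }
  }
  if (!is.null(gaf)) {
    for (s in intersect(names(gaf), names(corpus$gene_products))) {
      corpus$gene_products[[s]]$go_terms <- gaf[[s]]
    }
  }
  validate_corpus(corpus)
  corpus
}

#' Top-level DO class of a phenotypic series
#'
#' Maps each member disease to the top-level DO categories covering its DO
#' terms (via DO ancestors) and returns the category annotating the plurality
#' of member diseases; ties are broken by lexicographically smallest category
#' id. By default the categories are the child terms of the DO root, with the
#' children of any category labeled "disease of anatomical entity" substituted
#' for it (the anatomical-system classes).
#'
#' @param ps a PS record from an [annotation_corpus()].
#' @param corpus the corpus holding the member diseases.
#' @param do_dag the DO [ontology_dag()].
#' @param categories optional character vector of category term ids.
#' @return a DO term id, or `NA_character_` if no member has a DO annotation.
#' @export
assign_do_class <- function(ps, corpus, do_dag, categories = NULL) {
  if (is.null(categories)) categories <- do_top_level_categories(do_dag)
  votes <- character(0)
  for (d_id in ps$member_diseases) {
    dts <- corpus$diseases[[d_id]]$do_terms
    if (!length(dts)) next
    anc <- unique(unlist(lapply(dts, function(t) {
      t <- tryCatch(resolve_id(do_dag, t), error = function(e) NA_character_)
      if (is.na(t)) character(0) else do_dag$anc[[t]]
    }), use.names = FALSE))
    votes <- c(votes, intersect(categories, anc))
  }
  if (!length(votes)) return(NA_character_)
  tab <- table(votes)
  winners <- names(tab)[tab == max(tab)]
  sort(winners)[1]
}

#' Default DO top-level categories
#'
#' Children of the DO root; any category whose label is
#' "disease of anatomical entity" is replaced by its own children.
#'
#' @param do_dag the DO [ontology_dag()].
#' @return character vector of category term ids.
#' @export
do_top_level_categories <- function(do_dag) {
  live <- do_dag$ids[!do_dag$obsolete]
  kids_of <- function(id) live[vapply(do_dag$parents[live],
                                      function(p) id %in% p, logical(1))]
  cats <- kids_of(do_dag$root)
  anat <- cats[tolower(do_dag$labels[cats]) == "disease of anatomical entity"]
  for (a in anat) cats <- c(setdiff(cats, a), kids_of(a))
  sort(cats)
}
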