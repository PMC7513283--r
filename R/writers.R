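# Fixture writers: emit the same flat-file dialects the corpus parsers read,
# so synthetic corpora round-trip through the I/O layer.

#' Write disease-phenotype annotations (phenotype_annotation.tab dialect)
#'
#' @param hpo named list, `"OMIM:<id>"` -> HPO term ids.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotype_annotations <- function(hpo, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(hpo)) {
    mim <- sub("^OMIM:", "", id)
    for (t in hpo[[id]]) {
      writeLines(paste("OMIM", mim, id, "", t, "", "", "", "", "", "", "", "",
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Write gene-product GO annotations as GAF 2.2
#'
#' @param gaf named list, gene symbol -> list of term-id vectors keyed by
#'   `"GO-BP"` / `"GO-CC"` / `"GO-MF"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(gaf, path) {
  ns_aspect <- c("GO-BP" = "P", "GO-MF" = "F", "GO-CC" = "C")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!gaf-version: 2.2", con)
  for (sym in names(gaf)) {
    for (ns in names(gaf[[sym]])) {
      for (t in gaf[[sym]][[ns]]) {
        f <- rep("", 17)
        f[1] <- "DB"; f[2] <- sym; f[3] <- sym; f[4] <- "involved_in"
        f[5] <- t; f[6] <- "REF"; f[7] <- "IDA"; f[9] <- ns_aspect[[ns]]
        f[12] <- "protein"; f[13] <- "taxon:9606"; f[14] <- "20200101"; f[15] <- "DB"
        writeLines(paste(f, collapse = "\t"), con)
      }
    }
  }
  invisible(path)
}

#' Write a PS membership table
#'
#' Two tab-separated columns (PS id, disease MIM id) plus a PS label column.
#'
#' @param corpus an [annotation_corpus()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ps_membership <- function(corpus, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ps in corpus$series) {
    for (d in ps$member_diseases) {
      writeLines(paste(ps$ps_id, sub("^OMIM:", "", d), ps$label, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Write a morbidmap.txt-dialect disease-gene table
#'
#' One row per disease-gene link: `"<label>, <MIM> (3)\t<symbol>\t<MIM>\t"`.
#' Diseases without gene products are emitted with an empty symbol field so
#' they survive the round trip as gene-less diseases.
#'
#' @param corpus an [annotation_corpus()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_morbidmap <- function(corpus, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# Phenotype\tGene Symbols\tMIM Number\tCyto Location", con)
  for (d in corpus$diseases) {
    mim <- sub("^OMIM:", "", d$omim_id)
    pheno <- paste0(d$label, ", ", mim, " (3)")
    syms <- if (length(d$gene_products)) d$gene_products else ""
    for (s in syms) {
      writeLines(paste(pheno, s, mim, "", sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Write a profile cache table
#'
#' TSV with columns ps_id, namespace, term_id, source; read back with
#' [read_profiles()].
#'
#' @param profiles a list of term profiles (see [representative_profile()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(ps_id = p$ps_id, namespace = p$namespace, term_id = p$terms,
               source = p$source, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a profile cache table written by [write_profiles()]
#'
#' @param path input path.
#' @return named list of term profiles.
#' @export
read_profiles <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$ps_id), function(g) {
    structure(list(ps_id = g$ps_id[1], namespace = g$namespace[1],
                   terms = g$term_id, source = g$source[1]),
              class = "term_profile")
  })
  out[order(names(out))]
}
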