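# End-to-end orchestration: profiles -> coefficients -> networks -> stats ->
# fragmentation -> islands/clusters -> quadrants, with TSV artifacts and a
# manifest.

#' Run configuration for the similarity-network pipeline
#'
#' @param analysis_threshold similarity threshold at which network topology is
#'   analyzed (default 1.0).
#' @param retention_target node fraction retained when isolating islands of
#'   highly similar PS (default 0.20).
#' @param quadrant_threshold high-similarity cutoff for the clinical-vs-
#'   biological quadrant partition (default 2.0).
#' @param k_clusters number of clusters cut from the average-linkage tree
#'   (default 8; capped at the number of clustered PS).
#' @return an object of class `run_config`.
#' @export
run_config <- function(analysis_threshold = 1.0, retention_target = 0.20,
                       quadrant_threshold = 2.0, k_clusters = 8L) {
  stopifnot(analysis_threshold >= 0, quadrant_threshold >= 0,
            retention_target > 0, retention_target <= 1, k_clusters >= 1)
  structure(list(analysis_threshold = analysis_threshold,
                 retention_target = retention_target,
                 quadrant_threshold = quadrant_threshold,
                 k_clusters = as.integer(k_clusters)),
            class = "run_config")
}

#' Run the full similarity-network pipeline
#'
#' Executes, in order: Resnik IC per namespace (diseases are the corpus for
#' HPO, gene products for each GO sub-ontology); representative term profiles
#' per PS and namespace; all-pair best-match-average coefficients (with self
#' coefficients for the clustering diagonal); network assembly (CSN, BSN-BP,
#' BSN-CC, BSN-MF, and the max-merged general BSN with per-sub-ontology
#' contribution fractions); topology statistics at the analysis threshold;
#' fragmentation curves; the retention threshold and island decomposition per
#' network; average-linkage clustering of the retained PS; and the
#' clinical-vs-biological quadrant summary. Every stage is a pure function of
#' the corpus, so reruns are bit-identical.
#'
#' @param corpus an [annotation_corpus()].
#' @param dags named list of [ontology_dag()]s: `HPO`, `GO-BP`, `GO-CC`,
#'   `GO-MF` (a `DO` entry, if present, drives PS class assignment).
#' @param config a [run_config()].
#' @param outdir optional directory; when given, every artifact is written as
#'   TSV/GraphML and a manifest is saved.
#' @return an object of class `ps_pipeline`: list with `profiles`,
#'   `coefficients`, `networks`, `stats`, `fragmentation`, `retention`,
#'   `islands`, `clusters`, `quadrants`, `do_classes`, `manifest`.
#' @export
run_pipeline <- function(corpus, dags, config = run_config(), outdir = NULL) {
  ann_ns <- c("HPO", "GO-BP", "GO-CC", "GO-MF")
  missing_ns <- setdiff(ann_ns, names(dags))
  if (length(missing_ns)) stop("missing ontologies: ", paste(missing_ns, collapse = ", "))
  manifest <- list()
  log_stage <- function(stage, artifact, n) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, artifact = artifact, n = n, stringsAsFactors = FALSE)
    message(sprintf("[%s] %s: %d", stage, artifact, n))
  }

  # stage 1: information content per namespace
  ics <- list()
  for (ns in ann_ns) {
    ann <- if (ns == "HPO") {
      lapply(corpus$diseases, `[[`, "hpo_terms")
    } else {
      lapply(corpus$gene_products, function(g) g$go_terms[[ns]])
    }
    ann <- ann[vapply(ann, length, integer(1)) > 0]
    if (!length(ann)) stop("stage ic: no annotations in namespace ", ns)
    ics[[ns]] <- compute_ic(dags[[ns]], ann)
    log_stage("ic", ns, ics[[ns]]$corpus_size)
  }

  # stage 2: representative profiles
  profiles <- list()
  for (ns in ann_ns) {
    src <- if (ns == "HPO") "clinical" else "biological"
    pr <- lapply(corpus$series, function(ps) {
      representative_profile(ps, corpus, dags[[ns]], ics[[ns]], source = src)
    })
    pr <- pr[!vapply(pr, is.null, logical(1))]
    if (length(pr) < 2L) stop("stage profiles: fewer than 2 PS have ", ns, " profiles")
    profiles[[ns]] <- pr
    log_stage("profiles", ns, length(pr))
  }

  # stage 3: coefficients (self pairs included for the clustering diagonal)
  coefficients <- list()
  for (ns in ann_ns) {
    coefficients[[ns]] <- all_pair_coefficients(profiles[[ns]], dags[[ns]],
                                                ics[[ns]], include_self = TRUE)
    log_stage("coefficients", ns, nrow(coefficients[[ns]]))
  }

  # stage 4: networks
  networks <- list(
    CSN      = assemble(coefficients[["HPO"]], "CSN"),
    "BSN-BP" = assemble(coefficients[["GO-BP"]], "BSN-BP"),
    "BSN-CC" = assemble(coefficients[["GO-CC"]], "BSN-CC"),
    "BSN-MF" = assemble(coefficients[["GO-MF"]], "BSN-MF")
  )
  networks$BSN <- merge_max(networks[["BSN-BP"]], networks[["BSN-CC"]],
                            networks[["BSN-MF"]])
  for (nm in names(networks)) log_stage("networks", nm, nrow(networks[[nm]]$edges))

  # stage 5: topology statistics at the analysis threshold (a network that
  # empties out at the threshold yields NULL stats rather than aborting)
  stats_tbl <- lapply(networks, function(net) {
    ft <- apply_threshold(net, config$analysis_threshold)
    if (length(ft$nodes) < 2L) return(NULL)
    topology_stats(ft)
  })
  log_stage("stats", paste0("threshold ", config$analysis_threshold),
            length(stats_tbl))

  # stage 6: fragmentation curves over the observed weight range
  fragmentation <- lapply(networks, function(net) {
    ws <- sort(unique(net$edges$w))
    grid <- if (length(ws) > 40L) ws[unique(round(seq(1, length(ws), length.out = 40L)))] else ws
    fragmentation_curve(net, c(0, grid))
  })
  log_stage("fragmentation", "curves", length(fragmentation))

  # stage 7: retention thresholds and islands
  retention <- lapply(networks, threshold_for_node_fraction,
                      target = config$retention_target)
  island_tbl <- lapply(names(networks), function(nm) {
    islands(apply_threshold(networks[[nm]], retention[[nm]]$threshold))
  })
  names(island_tbl) <- names(networks)
  for (nm in names(networks)) log_stage("islands", nm, max(0L, island_tbl[[nm]]$island))

  # stage 8: clustering of the retained PS by their full similarity profiles
  clusters <- list()
  for (nm in c("CSN", "BSN")) {
    coeff <- if (nm == "CSN") coefficients[["HPO"]] else .bsn_coefficients_with_self(
      networks$BSN, coefficients, profiles, dags, ics)
    kept <- unique(island_tbl[[nm]]$ps_id)
    if (length(kept) >= 2L) {
      M <- full_similarity_matrix(coeff, sort(kept))
      k <- min(config$k_clusters, nrow(M))
      clusters[[nm]] <- average_linkage_cluster(M, k)
      log_stage("clusters", nm, k)
    }
  }

  # stage 9: quadrant analysis (CSN vs general BSN)
  quadrants <- quadrant_counts(networks$CSN$edges, networks$BSN$edges,
                               threshold = config$quadrant_threshold)
  log_stage("quadrants", "pairs", sum(quadrants$counts))

  # DO classes, when a DO ontology is supplied
  do_classes <- NULL
  if (!is.null(dags$DO)) {
    do_classes <- vapply(corpus$series, assign_do_class, character(1),
                         corpus = corpus, do_dag = dags$DO)
    log_stage("do_classes", "PS", sum(!is.na(do_classes)))
  }

  manifest <- do.call(rbind, manifest)
  out <- structure(list(profiles = profiles, coefficients = coefficients,
                        networks = networks, stats = stats_tbl,
                        fragmentation = fragmentation, retention = retention,
                        islands = island_tbl, clusters = clusters,
                        quadrants = quadrants, do_classes = do_classes,
                        config = config, manifest = manifest),
                   class = "ps_pipeline")
  if (!is.null(outdir)) .write_artifacts(out, outdir)
  out
}

# The general BSN's coefficient table including self rows (max of the three
# sub-ontology self coefficients), for the clustering diagonal.
.bsn_coefficients_with_self <- function(bsn, coefficients, profiles, dags, ics) {
  selfs <- lapply(c("GO-BP", "GO-CC", "GO-MF"), function(ns) {
    co <- coefficients[[ns]]
    co[co$ps_a == co$ps_b, c("ps_a", "ps_b", "w")]
  })
  all_self <- do.call(rbind, selfs)
  best <- vapply(split(all_self$w, all_self$ps_a), max, numeric(1))
  rbind(bsn$edges[, c("ps_a", "ps_b", "w")],
        data.frame(ps_a = names(best), ps_b = names(best), w = unname(best),
                   stringsAsFactors = FALSE))
}

.write_artifacts <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  for (ns in names(out$profiles)) {
    write_profiles(out$profiles[[ns]], p(paste0("profiles_", ns, ".tsv")))
    write_coefficients(out$coefficients[[ns]], p(paste0("coefficients_", ns, ".tsv")))
  }
  for (nm in names(out$networks)) {
    write_edgelist(out$networks[[nm]], p(paste0("network_", nm, ".tsv")))
    write_graphml(out$networks[[nm]], p(paste0("network_", nm, ".graphml")))
    utils::write.table(out$fragmentation[[nm]], p(paste0("fragmentation_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$islands[[nm]], p(paste0("islands_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  stats_df <- do.call(rbind, lapply(Filter(Negate(is.null), out$stats), function(s) {
    data.frame(network = s$name, threshold = s$threshold, n_nodes = s$n_nodes,
               n_edges = s$n_edges, mean_k = s$mean_k, mean_C = s$mean_C,
               mean_l = s$mean_l, density = s$density,
               n_components = s$n_components, gcc_size = s$gcc_size)
  }))
  utils::write.table(stats_df, p("network_stats.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (nm in names(out$clusters)) {
    a <- out$clusters[[nm]]$assignment
    utils::write.table(data.frame(ps_id = names(a), cluster = unname(a)),
                       p(paste0("clusters_", nm, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    dendrogram_newick(out$clusters[[nm]], p(paste0("dendrogram_", nm, ".nwk")))
  }
  qp <- do.call(rbind, lapply(names(out$quadrants$pairs), function(q) {
    df <- out$quadrants$pairs[[q]]
    if (nrow(df)) cbind(df, quadrant = q) else NULL
  }))
  utils::write.table(qp, p("quadrants.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(out$manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(outdir)
}

#' @export
print.ps_pipeline <- function(x, ...) {
  cat("<ps_pipeline>\n")
  cat(sprintf("  networks: %s\n", paste(names(x$networks), collapse = ", ")))
  for (nm in names(x$networks)) {
    s <- x$stats[[nm]]
    if (is.null(s)) {
      cat(sprintf("  %-7s n=%d E=%d @0 | empty at analysis threshold\n",
                  nm, length(x$networks[[nm]]$nodes), nrow(x$networks[[nm]]$edges)))
    } else {
      cat(sprintf("  %-7s n=%d E=%d @0 | n=%d E=%d <k>=%.2f <C>=%.3f density=%.3f @%g\n",
                  nm, length(x$networks[[nm]]$nodes), nrow(x$networks[[nm]]$edges),
                  s$n_nodes, s$n_edges, s$mean_k, s$mean_C, s$density, s$threshold))
    }
  }
  print(x$quadrants)
  invisible(x)
}
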