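# Synthetic ontologies and PS cohorts with planted ground truth, so every
# pipeline stage is testable without database downloads.

#' Configuration for a synthetic PS cohort
#'
#' Defines the shape of the generated ontologies and corpus and the planted
#' similarity structure. PS in the same planted group draw their annotations
#' from a shared, leaf-biased term pool, so within-group pairs carry high
#' best-match-average coefficients; between-group pool overlap and
#' per-annotation noise dilute the signal in a controlled way.
#'
#' @param seed integer RNG seed.
#' @param n_ps number of phenotypic series.
#' @param diseases_per_ps integer range (min, max) of member diseases per PS.
#' @param genes_per_disease integer range of causal genes per disease.
#' @param terms_per_entity integer range of annotations per disease (HPO) and
#'   per gene (each GO sub-ontology).
#' @param dag_depth,branching shape of the complete-tree ontologies; leaves
#'   (the most specific, highest-IC terms) carry the annotations.
#' @param n_planted_groups number of planted PS groups.
#' @param group_modes per group, which similarity is planted: `"both"`,
#'   `"clinical"`, `"biological"`, or `"neither"` (recycled to
#'   `n_planted_groups`); modes map to the expected quadrants II/IV/III/I of
#'   the within-group pairs.
#' @param within_group_term_overlap probability that an annotation is drawn
#'   from the group pool (vs a uniform random leaf); must exceed
#'   `between_group_term_overlap`.
#' @param between_group_term_overlap fraction of each group pool shared with
#'   the other groups.
#' @param annotation_noise per-annotation probability of resampling a
#'   uniformly random leaf.
#' @param pool_size leaves per group term pool.
#' @param dominant_namespace GO sub-ontology that carries the planted
#'   biological signal (and therefore wins the max-merge for within-group
#'   pairs).
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_ps = 24L,
                             diseases_per_ps = c(2L, 3L),
                             genes_per_disease = c(1L, 2L),
                             terms_per_entity = c(4L, 7L),
                             dag_depth = 5L, branching = 3L,
                             n_planted_groups = 6L,
                             group_modes = "both",
                             within_group_term_overlap = 0.95,
                             between_group_term_overlap = 0,
                             annotation_noise = 0,
                             pool_size = 6L,
                             dominant_namespace = "GO-BP") {
  stopifnot(n_ps >= 2, n_planted_groups >= 1, n_planted_groups <= n_ps,
            within_group_term_overlap >= 0, within_group_term_overlap <= 1,
            between_group_term_overlap >= 0, between_group_term_overlap <= 1,
            annotation_noise >= 0, annotation_noise <= 1,
            dag_depth >= 2, branching >= 2,
            dominant_namespace %in% c("GO-BP", "GO-CC", "GO-MF"))
  if (within_group_term_overlap <= between_group_term_overlap) {
    stop("within_group_term_overlap must exceed between_group_term_overlap")
  }
  pool_depth <- max(1L, dag_depth - 2L)
  n_subtrees <- branching^pool_depth
  leaves_per_subtree <- branching^(dag_depth - pool_depth)
  n_shared <- round(between_group_term_overlap * pool_size)
  if (n_planted_groups + (n_shared > 0) > n_subtrees ||
      pool_size - n_shared > leaves_per_subtree ||
      n_shared > leaves_per_subtree) {
    stop("infeasible overlap constraints: group pools do not fit the ontology")
  }
  structure(list(seed = as.integer(seed), n_ps = as.integer(n_ps),
                 diseases_per_ps = diseases_per_ps,
                 genes_per_disease = genes_per_disease,
                 terms_per_entity = terms_per_entity,
                 dag_depth = dag_depth, branching = branching,
                 n_planted_groups = as.integer(n_planted_groups),
                 group_modes = rep_len(group_modes, n_planted_groups),
                 within_group_term_overlap = within_group_term_overlap,
                 between_group_term_overlap = between_group_term_overlap,
                 annotation_noise = annotation_noise,
                 pool_size = as.integer(pool_size),
                 pool_depth = pool_depth,
                 dominant_namespace = dominant_namespace),
            class = "synthetic_config")
}

#' Generate a complete-tree ontology DAG
#'
#' @param prefix accession prefix (e.g. `"HP"`).
#' @param namespace ontology tag.
#' @param depth,branching tree shape; the root is level 0.
#' @return an [ontology_dag()]; its leaves are in attribute `"leaves"`.
#' @export
make_tree_ontology <- function(prefix, namespace, depth, branching) {
  n <- (branching^(depth + 1) - 1) / (branching - 1)
  ids <- sprintf("%s:%07d", prefix, seq_len(n) - 1L)
  terms <- vector("list", n)
  for (i in seq_len(n)) {
    parent <- if (i == 1L) character(0) else ids[(i - 2L) %/% branching + 1L]
    terms[[i]] <- list(id = ids[i], name = paste0(prefix, " term ", i - 1L),
                       parents = parent)
  }
  dag <- ontology_dag(terms, namespace)
  attr(dag, "leaves") <- ids[(n - branching^depth + 1L):n]
  dag
}

#' The three-PS schematic fixture
#'
#' Two five-term ontologies (an HPO-like and a GO-BP-like tree: terms 2 and 3
#' are children of 4; terms 1 and 4 are children of the root 0) and a corpus
#' of three single-disease PS labeled A, B, C, annotated so that A and B share
#' term 1, A and C share terms whose most informative common ancestor is 4,
#' and B and C share only the root.
#'
#' @return list with elements `hpo`, `go` (the two [ontology_dag()]s) and
#'   `corpus` (an [annotation_corpus()]).
#' @export
make_figure1_fixture <- function() {
  five_term <- function(prefix, namespace) {
    ids <- sprintf("%s:%07d", prefix, 0:4)
    ontology_dag(list(
      list(id = ids[1], name = "term 0 (root)", parents = character(0)),
      list(id = ids[2], name = "term 1", parents = ids[1]),
      list(id = ids[3], name = "term 2", parents = ids[5]),
      list(id = ids[4], name = "term 3", parents = ids[5]),
      list(id = ids[5], name = "term 4", parents = ids[1])
    ), namespace)
  }
  hpo <- five_term("HP", "HPO")
  go <- five_term("GO", "GO-BP")
  hp <- function(k) sprintf("HP:%07d", k)
  gt <- function(k) sprintf("GO:%07d", k)

  diseases <- list(
    "OMIM:100001" = list(omim_id = "OMIM:100001", label = "disease A1",
                         hpo_terms = c(hp(1), hp(2)), do_terms = character(0),
                         gene_products = "GENEA"),
    "OMIM:100002" = list(omim_id = "OMIM:100002", label = "disease B1",
                         hpo_terms = hp(1), do_terms = character(0),
                         gene_products = "GENEB"),
    "OMIM:100003" = list(omim_id = "OMIM:100003", label = "disease C1",
                         hpo_terms = hp(3), do_terms = character(0),
                         gene_products = "GENEC")
  )
  gene_products <- list(
    GENEA = list(symbol = "GENEA", go_terms = list("GO-BP" = c(gt(1), gt(2)))),
    GENEB = list(symbol = "GENEB", go_terms = list("GO-BP" = gt(1))),
    GENEC = list(symbol = "GENEC", go_terms = list("GO-BP" = gt(3)))
  )
  series <- list(
    PS000001 = list(ps_id = "PS000001", label = "A",
                    member_diseases = "OMIM:100001", do_class = NA_character_),
    PS000002 = list(ps_id = "PS000002", label = "B",
                    member_diseases = "OMIM:100002", do_class = NA_character_),
    PS000003 = list(ps_id = "PS000003", label = "C",
                    member_diseases = "OMIM:100003", do_class = NA_character_)
  )
  list(hpo = hpo, go = go,
       corpus = annotation_corpus(diseases, gene_products, series))
}

#' Simulate a PS cohort with planted group structure
#'
#' Generates one HPO-like and three GO-like tree ontologies plus a small DO
#' classification tree, then a corpus of PS whose member diseases (and their
#' genes) draw annotations from group term pools according to the group's
#' mode: `"both"` plants clinical and biological similarity, `"clinical"` /
#' `"biological"` plant only one of them (private per-PS pools carry the
#' other), `"neither"` plants none. The planted biological signal lives in
#' `config$dominant_namespace`; the other GO sub-ontologies draw from private
#' pools, so the dominant one wins the max-merge for within-group pairs.
#'
#' @param config a [synthetic_config()].
#' @return list with `corpus`, `dags` (named: HPO, GO-BP, GO-CC, GO-MF, DO),
#'   and `truth`: `ps_group` (named integer), `group_modes`,
#'   `expected_quadrant` (data.frame per PS pair), `dominant_namespace`, and
#'   `do_class` (named, per PS).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  dags <- list(
    "HPO"   = make_tree_ontology("HP", "HPO", config$dag_depth, config$branching),
    "GO-BP" = make_tree_ontology("GB", "GO-BP", config$dag_depth, config$branching),
    "GO-CC" = make_tree_ontology("GC", "GO-CC", config$dag_depth, config$branching),
    "GO-MF" = make_tree_ontology("GM", "GO-MF", config$dag_depth, config$branching)
  )
  # DO: a root with eight top-level category children
  do_ids <- sprintf("DOID:%07d", 0:8)
  do_terms <- c(list(list(id = do_ids[1], name = "disease", parents = character(0))),
                lapply(2:9, function(i) list(id = do_ids[i],
                                             name = paste0("disease class ", i - 1L),
                                             parents = do_ids[1])))
  dags$DO <- ontology_dag(do_terms, "DO")

  ng <- config$n_planted_groups
  modes <- config$group_modes
  ps_ids <- sprintf("PS%06d", seq_len(config$n_ps))
  ps_group <- setNames(rep(seq_len(ng), length.out = config$n_ps), ps_ids)

  # Group pools are leaf sets localized under distinct subtrees (annotations
  # of related diseases cluster in ontology branches), with a shared slice
  # drawn from one further subtree to give the planted between-group overlap.
  subtree_leaves <- function(dag, node) {
    leaves <- attr(dag, "leaves")
    leaves[vapply(leaves, function(l) node %in% dag$anc[[l]], logical(1))]
  }
  make_pools <- function(dag) {
    b <- config$branching
    L <- config$pool_depth
    first <- (b^L - 1L) %/% (b - 1L) + 1L
    roots <- sample(dag$ids[first:(first + b^L - 1L)])
    n_shared <- round(config$between_group_term_overlap * config$pool_size)
    shared <- if (n_shared > 0) {
      sample(subtree_leaves(dag, roots[ng + 1L]), n_shared)
    } else character(0)
    lapply(seq_len(ng), function(g) {
      c(shared, sample(subtree_leaves(dag, roots[g]),
                       config$pool_size - n_shared))
    })
  }
  ann_ns <- c("HPO", "GO-BP", "GO-CC", "GO-MF")
  pools <- lapply(dags[ann_ns], make_pools)

  rng_range <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)
  draw_terms <- function(dag, pool, n, planted) {
    leaves <- attr(dag, "leaves")
    out <- character(n)
    for (i in seq_len(n)) {
      from_pool <- planted && stats::runif(1) < config$within_group_term_overlap
      out[i] <- if (from_pool) sample(pool, 1L) else sample(leaves, 1L)
      if (config$annotation_noise > 0 && stats::runif(1) < config$annotation_noise) {
        out[i] <- sample(leaves, 1L)
      }
    }
    unique(out)
  }

  diseases <- list()
  gene_products <- list()
  series <- list()
  gene_counter <- 0L
  dis_counter <- 0L
  truth_do <- setNames(character(config$n_ps), ps_ids)

  for (p in seq_len(config$n_ps)) {
    g <- ps_group[[p]]
    mode <- modes[[g]]
    clin_planted <- mode %in% c("both", "clinical")
    bio_planted <- mode %in% c("both", "biological")
    # private per-PS pools carry the non-planted side so members stay coherent
    priv <- lapply(dags[ann_ns], function(d) sample(attr(d, "leaves"), config$pool_size))
    do_cat <- do_ids[1 + (g - 1L) %% 8L + 1L]
    truth_do[p] <- do_cat

    n_dis <- rng_range(config$diseases_per_ps)
    members <- character(n_dis)
    for (d in seq_len(n_dis)) {
      dis_counter <- dis_counter + 1L
      d_id <- sprintf("OMIM:%06d", 100000L + dis_counter)
      members[d] <- d_id
      hpo_pool <- if (clin_planted) pools$HPO[[g]] else priv$HPO
      hpo_terms <- draw_terms(dags$HPO, hpo_pool, rng_range(config$terms_per_entity),
                              TRUE)
      n_genes <- rng_range(config$genes_per_disease)
      gsyms <- character(n_genes)
      for (k in seq_len(n_genes)) {
        gene_counter <- gene_counter + 1L
        sym <- sprintf("GENE%05d", gene_counter)
        gsyms[k] <- sym
        go_terms <- list()
        for (ns in c("GO-BP", "GO-CC", "GO-MF")) {
          planted_here <- bio_planted && ns == config$dominant_namespace
          pool <- if (planted_here) pools[[ns]][[g]] else priv[[ns]]
          go_terms[[ns]] <- draw_terms(dags[[ns]], pool,
                                       rng_range(config$terms_per_entity), TRUE)
        }
        gene_products[[sym]] <- list(symbol = sym, go_terms = go_terms)
      }
      diseases[[d_id]] <- list(omim_id = d_id, label = paste0("disease ", d_id),
                               hpo_terms = hpo_terms, do_terms = do_cat,
                               gene_products = gsyms)
    }
    series[[ps_ids[p]]] <- list(ps_id = ps_ids[p],
                                label = paste0("series ", p, " (group ", g, ")"),
                                member_diseases = members,
                                do_class = NA_character_)
  }

  corpus <- annotation_corpus(diseases, gene_products, series)

  mode_quadrant <- c(both = "II", clinical = "IV", biological = "III",
                     neither = "I")
  pairs <- utils::combn(ps_ids, 2)
  same <- ps_group[pairs[1, ]] == ps_group[pairs[2, ]]
  eq <- ifelse(same, mode_quadrant[modes[ps_group[pairs[1, ]]]], "I")
  expected_quadrant <- data.frame(ps_a = pairs[1, ], ps_b = pairs[2, ],
                                  quadrant = unname(eq),
                                  same_group = same, stringsAsFactors = FALSE)

  list(corpus = corpus, dags = dags,
       truth = list(ps_group = ps_group, group_modes = modes,
                    expected_quadrant = expected_quadrant,
                    dominant_namespace = config$dominant_namespace,
                    do_class = truth_do),
       config = config)
}
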