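# Corpus parsers, writers, referential integrity, and DO classification.

test_that("phenotype annotations aggregate per disease and count skipped rows", {
  expect_error(parse_phenotype_annotations(character(0)), "no usable rows")

  rows <- c("OMIM\t100001\tDisease X\t\tHP:0000001\t\t\t\t\t\t\t\t",
            "OMIM\t100001\tDisease X\t\tHP:0000002\t\t\t\t\t\t\t\t")
  ann <- parse_phenotype_annotations(rows)
  expect_setequal(ann[["OMIM:100001"]], c("HP:0000001", "HP:0000002"))

  # 100-row fixture: 90 valid, 10 malformed (missing term column)
  good <- sprintf("OMIM\t%06d\tD\t\tHP:%07d", 100000 + 1:90, 1:90)
  bad <- sprintf("OMIM\t%06d\tD", 200000 + 1:10)
  mixed <- sample(c(good, bad))
  ann <- parse_phenotype_annotations(mixed)
  expect_length(ann, 90L)
  expect_identical(attr(ann, "n_skipped"), 10L)

  # non-OMIM sources are skipped with a counter
  ann <- parse_phenotype_annotations(c(good[1], "ORPHA\t55\tD\t\tHP:0000001"))
  expect_length(ann, 1L)
  expect_identical(attr(ann, "n_non_omim"), 1L)
})

test_that("GAF rows route by aspect and NOT qualifiers are dropped", {
  gaf_row <- function(sym, term, aspect, qual = "involved_in") {
    f <- rep("", 17)
    f[2] <- sym; f[3] <- sym; f[4] <- qual; f[5] <- term; f[7] <- "IDA"; f[9] <- aspect
    paste(f, collapse = "\t")
  }
  expect_error(parse_gaf("!gaf-version: 2.2"), "no annotation rows")
  out <- parse_gaf(c("!gaf-version: 2.2",
                     gaf_row("G1", "GO:0000001", "P"),
                     gaf_row("G1", "GO:0000002", "C"),
                     gaf_row("G1", "GO:0000003", "P", qual = "NOT|involved_in")))
  expect_setequal(names(out$G1), c("GO-BP", "GO-CC"))
  expect_identical(out$G1[["GO-BP"]], "GO:0000001")

  # evidence filtering is opt-in
  lines <- c(gaf_row("G2", "GO:0000004", "F"))
  lines_iea <- sub("IDA", "IEA", lines)
  expect_error(parse_gaf(lines_iea, exclude_evidence = "IEA"), "no usable")
})

test_that("synthetic GAF and phenotype tables round-trip exactly", {
  cfg <- synthetic_config(seed = 11, n_ps = 8, n_planted_groups = 2)
  sim <- simulate_cohort(cfg)
  corpus <- sim$corpus

  tab <- withr::local_tempfile(fileext = ".tab")
  hpo <- lapply(corpus$diseases, `[[`, "hpo_terms")
  write_phenotype_annotations(hpo, tab)
  back <- parse_phenotype_annotations(tab)
  expect_setequal(names(back), names(hpo))
  for (d in names(hpo)) expect_setequal(back[[d]], hpo[[d]])

  gaf_path <- withr::local_tempfile(fileext = ".gaf")
  gaf <- lapply(corpus$gene_products, `[[`, "go_terms")
  write_gaf(gaf, gaf_path)
  gback <- parse_gaf(gaf_path)
  expect_setequal(names(gback), names(gaf))
  for (s in names(gaf)) {
    for (ns in names(gaf[[s]])) expect_setequal(gback[[s]][[ns]], gaf[[s]][[ns]])
  }
})

test_that("OMIM maps and PS membership build the PS-disease-gene chain", {
  morbid <- c("# header",
              "Some disease, 100001 (3)\tGENE1, G1ALT\t600001\t1p32",
              "Other disease, 100002 (3)\tGENE2\t600002\t2q11")
  members <- c("PS000100\t100001\tSeries one",
               "PS000100\t100002\tSeries one",
               "PS000200\t100002\tSeries two")  # shared disease: allowed
  corpus <- parse_omim_maps(morbidmap = morbid, ps_membership = members)
  expect_setequal(names(corpus$series), c("PS000100", "PS000200"))
  expect_setequal(corpus$series$PS000100$member_diseases,
                  c("OMIM:100001", "OMIM:100002"))
  expect_identical(corpus$series$PS000200$member_diseases, "OMIM:100002")
  expect_identical(corpus$diseases[["OMIM:100001"]]$gene_products, "GENE1")

  # genemap2 phenotype column is an alternative disease-gene source
  gm <- paste(c("1", "1", "2", "p", "p", "600003", "GENE3, ALT", "name", "GENE3",
                "111", "ENSG", "", "Third disease, 100003 (3), Autosomal recessive"),
              collapse = "\t")
  corpus2 <- parse_omim_maps(genemap = gm, morbidmap = NULL,
                             ps_membership = "PS000300\t100003")
  expect_identical(corpus2$diseases[["OMIM:100003"]]$gene_products, "GENE3")

  # membership rows naming unmapped diseases keep them, gene-less
  corpus3 <- parse_omim_maps(morbidmap = morbid,
                             ps_membership = c(members, "PS000300\t100009"))
  expect_length(corpus3$diseases[["OMIM:100009"]]$gene_products, 0L)
})

test_that("a synthetic corpus round-trips through the OMIM-dialect writers", {
  cfg <- synthetic_config(seed = 12, n_ps = 10, n_planted_groups = 2)
  sim <- simulate_cohort(cfg)
  corpus <- sim$corpus
  mm <- withr::local_tempfile(fileext = ".txt")
  ps <- withr::local_tempfile(fileext = ".txt")
  write_morbidmap(corpus, mm)
  write_ps_membership(corpus, ps)
  back <- parse_omim_maps(morbidmap = mm, ps_membership = ps)
  expect_setequal(names(back$series), names(corpus$series))
  for (id in names(corpus$series)) {
    expect_setequal(back$series[[id]]$member_diseases,
                    corpus$series[[id]]$member_diseases)
  }
  for (d in names(corpus$diseases)) {
    expect_setequal(back$diseases[[d]]$gene_products,
                    corpus$diseases[[d]]$gene_products)
  }
})

test_that("corpus referential integrity is enforced", {
  fx <- make_figure1_fixture()
  broken <- fx$corpus
  broken$series$PS000001$member_diseases <- c("OMIM:100001", "OMIM:999999")
  expect_error(validate_corpus(broken), "unknown diseases")
  broken2 <- fx$corpus
  broken2$diseases[["OMIM:100001"]]$gene_products <- "NOGENE"
  expect_error(validate_corpus(broken2), "unknown gene products")
})

test_that("DO class assignment takes the plurality with lexicographic ties", {
  do_dag <- ontology_dag(list(
    list(id = "DOID:4", name = "disease", parents = character(0)),
    list(id = "DOID:1", name = "syndrome", parents = "DOID:4"),
    list(id = "DOID:2", name = "disease of anatomical entity", parents = "DOID:4"),
    list(id = "DOID:21", name = "cardiovascular system disease", parents = "DOID:2"),
    list(id = "DOID:22", name = "nervous system disease", parents = "DOID:2"),
    list(id = "DOID:211", name = "heart disease", parents = "DOID:21")
  ), "DO")
  cats <- do_top_level_categories(do_dag)
  expect_setequal(cats, c("DOID:1", "DOID:21", "DOID:22"))

  mk_corpus <- function(do_per_disease) {
    n <- length(do_per_disease)
    ids <- sprintf("OMIM:%06d", 100000 + seq_len(n))
    diseases <- lapply(seq_len(n), function(i) {
      list(omim_id = ids[i], label = ids[i], hpo_terms = character(0),
           do_terms = do_per_disease[[i]], gene_products = character(0))
    })
    names(diseases) <- ids
    series <- list(PS1 = list(ps_id = "PS1", label = "PS1",
                              member_diseases = ids, do_class = NA_character_))
    annotation_corpus(diseases, list(), series)
  }

  unan <- mk_corpus(list("DOID:1", "DOID:1", "DOID:1"))
  expect_identical(assign_do_class(unan$series$PS1, unan, do_dag), "DOID:1")

  plur <- mk_corpus(list("DOID:211", "DOID:21", "DOID:22"))
  expect_identical(assign_do_class(plur$series$PS1, plur, do_dag), "DOID:21")

  none <- mk_corpus(list(character(0), character(0)))
  expect_identical(assign_do_class(none$series$PS1, none, do_dag), NA_character_)

  # planted classes in the synthetic cohort are recovered
  cfg <- synthetic_config(seed = 13, n_ps = 8, n_planted_groups = 4)
  sim <- simulate_cohort(cfg)
  got <- vapply(sim$corpus$series, assign_do_class, character(1),
                corpus = sim$corpus, do_dag = sim$dags$DO)
  expect_identical(unname(got[names(sim$truth$do_class)]),
                   unname(sim$truth$do_class))
})
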