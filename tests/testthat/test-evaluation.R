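test_that("reference annotations join on both concepts with set semantics", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "pmid\tconcept_type\tconcept_label",
    "1\tdisease\tAlzheimer's Disease",
    "1\tgene\tAPOE",
    "2\tdisease\tAlzheimer's Disease",
    "3\tgene\tAPOE",
    "4\tgene\tAPOE",
    "4\tdisease\tAlzheimer's Disease",
    "4\tgene\tAPOE"
  ), tsv)
  ref <- load_reference_annotations(tsv, "APOE", "Alzheimer's Disease")
  expect_identical(ref$pmids, c("1", "4"))

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("pmid\tconcept_type\tconcept_label", empty)
  expect_equal(length(load_reference_annotations(empty, "a", "b")$pmids), 0L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pmid\tlabel", "1\tx"), bad)
  expect_error(load_reference_annotations(bad, "a", "b"), "concept_type")
})

test_that("pipeline annotation sets come from the dementia-type profile", {
  gen <- generate_corpus(random_corpus_spec(120, seed = 61))
  reg <- default_demo_registry()
  summaries <- lapply(seq_len(nrow(reg)), function(i) {
    extract_gene_summary(filter_nd(build_gspp(gen$corpus, reg[i, ])), reg)
  })
  truth <- truth_gene_summary(gen$truth, "APOE")$categories$dementia_type
  row <- which(truth$subcategory == "Alzheimer's Disease")
  expected <- if (length(row) > 0) truth$pmids[[row]] else character(0)
  got <- pipeline_annotation_set(summaries, "APOE", "Alzheimer's Disease")
  expect_identical(got$pmids, expected)
  # unknown dementia type -> empty set, not an error
  expect_equal(length(pipeline_annotation_set(summaries, "APOE",
                                              "Nonexistent")$pmids), 0L)
  expect_error(pipeline_annotation_set(summaries, "NOGENE", "x"), "NOGENE")
})

test_that("overlap reports satisfy exact set arithmetic", {
  rep1 <- compare_annotation_sets(c("1", "2", "3"), c("2", "3", "4"))
  expect_equal(rep1$n_ours, 3L)
  expect_equal(rep1$n_reference, 3L)
  expect_equal(rep1$n_overlap, 2L)
  expect_identical(rep1$reference_only_pmids, "4")

  same <- compare_annotation_sets(c("7", "8"), c("8", "7"))
  expect_equal(same$n_overlap, same$n_ours)

  # duplication and ordering do not matter
  shuffled <- compare_annotation_sets(c("3", "1", "2", "2"),
                                      c("4", "3", "2", "4"))
  expect_equal(shuffled$n_overlap, rep1$n_overlap)
})

test_that("overlap equals brute-force intersection on random sets", {
  set.seed(71)
  for (i in 1:200) {
    ours <- as.character(sample(1:60, sample(0:25, 1)))
    ref <- as.character(sample(1:60, sample(0:25, 1)))
    rep <- compare_annotation_sets(ours, ref)
    brute <- sum(vapply(unique(ours), function(p) p %in% ref, logical(1)))
    expect_equal(rep$n_overlap, brute)
    expect_lte(rep$n_overlap, min(rep$n_ours, rep$n_reference))
    # swapping arguments transposes the roles, preserving the overlap
    swapped <- compare_annotation_sets(ref, ours)
    expect_equal(swapped$n_overlap, rep$n_overlap)
    expect_equal(swapped$n_ours, rep$n_reference)
  }
})

test_that("overlap JSON reports fractions to four decimals", {
  rep <- compare_annotation_sets(as.character(1:3), as.character(2:8))
  path <- withr::local_tempfile(fileext = ".json")
  write_overlap_json(rep, path)
  obj <- jsonlite::read_json(path)
  expect_equal(obj$n_overlap, 2L)
  expect_equal(obj$overlap_fraction_of_ours, round(2 / 3, 4))
  gl <- glance(rep)
  expect_equal(gl$n_overlap, 2L)
  expect_equal(nrow(tidy(rep)), 5L)
})
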