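# A small ND-filtered fixture profile with known content.
make_nd_profile <- function() {
  x <- corpus(
    pmid = c("11", "12", "13", "14"),
    title = c(
      "APOE in Alzheimer's disease",
      "APOE and the hippocampus in Alzheimer's disease",
      "APOE, hippocampus and thalamus in Parkinson's disease",
      "TREM2 modulates APOE signaling in Alzheimer's disease"
    ),
    abstract = c(
      "Oxidative stress was measured.",
      "Tau deposition was quantified in 5xFAD mice.",
      "No keywords here.",
      "Microglia were imaged in the hippocampus."
    ),
    year = c(2004L, 2004L, 2010L, 0L),
    journal = rep("J Test", 4)
  )
  filter_nd(build_gspp(x, demo_gene_apoe()))
}

test_that("year trend partitions records with valid years", {
  prof <- make_nd_profile()
  trend <- extract_year_trend(prof)
  expect_identical(trend$subcategory, c("2004", "2010"))
  expect_identical(trend$count, c(2L, 1L))
  expect_identical(trend$pmids[[1]], c("11", "12"))
  # year-0 sentinel records are excluded; counts partition the rest
  expect_equal(sum(trend$count), sum(prof$year > 0))
  # empty profile -> empty trend
  empty <- filter_nd(build_gspp(corpus(), demo_gene_apoe()))
  expect_equal(nrow(extract_year_trend(empty)), 0L)
})

test_that("extraction requires the ND filter to have been applied", {
  prof <- build_gspp(make_demo_corpus(), demo_gene_apoe())
  expect_error(extract_year_trend(prof), "nd_filtered")
})

test_that("term categories count each record once per subcategory", {
  prof <- make_nd_profile()
  br <- extract_term_category(prof, default_brain_region_vocabulary())
  expect_identical(br$category, rep("brain_region", 2))
  # record 13 mentions both regions and contributes one pmid to each
  expect_identical(br$pmids[[which(br$subcategory == "Hippocampus")]],
                   c("12", "13", "14"))
  expect_identical(br$pmids[[which(br$subcategory == "Thalamus")]], "13")
  # zero-hit vocabulary entries are absent
  expect_false("Amygdala" %in% br$subcategory)

  dem <- extract_term_category(prof, default_dementia_vocabulary())
  expect_identical(
    dem$pmids[[which(dem$subcategory == "Parkinson's Disease")]], "13")
  expect_true(all(unlist(dem$pmids) %in% prof$pmid))

  kw <- extract_term_category(prof, default_keyword_vocabulary())
  expect_identical(kw$pmids[[which(kw$subcategory == "tau deposition")]],
                   "12")
  mm <- extract_term_category(prof, default_mouse_model_vocabulary())
  expect_identical(mm$subcategory, "5xFAD")
})

test_that("co-occurring genes are POS-gated and exclude the focal gene", {
  prof <- make_nd_profile()
  reg <- default_demo_registry()
  co <- extract_cooccurring_genes(prof, reg)
  expect_identical(co$subcategory, "TREM2")
  expect_identical(co$pmids[[1]], "14")
  expect_false("APOE" %in% co$subcategory)
})

test_that("gated co-occurrence counts never exceed ungated; ungated is symmetric", {
  gen <- generate_corpus(random_corpus_spec(150, seed = 51))
  reg <- default_demo_registry()
  count_of <- function(summaries, a, b) {
    s <- summaries[[match(a, reg$symbol)]]$categories$cooccurring_gene
    i <- which(s$subcategory == b)
    if (length(i) == 0L) 0L else s$count[[i]]
  }
  summarize_all <- function(gating) {
    lapply(seq_len(nrow(reg)), function(i) {
      prof <- filter_nd(build_gspp(gen$corpus, reg[i, ]))
      extract_gene_summary(prof, reg, pos_gating = gating)
    })
  }
  gated <- summarize_all(TRUE)
  ungated <- summarize_all(FALSE)
  for (a in reg$symbol) {
    for (b in setdiff(reg$symbol, a)) {
      expect_identical(count_of(ungated, a, b), count_of(ungated, b, a))
      expect_lte(count_of(gated, a, b), count_of(ungated, a, b))
    }
  }
})

test_that("pruning drops summaries empty in all three content categories", {
  gen <- generate_corpus(random_corpus_spec(80, seed = 52))
  reg <- default_demo_registry()
  summaries <- lapply(seq_len(nrow(reg)), function(i) {
    extract_gene_summary(filter_nd(build_gspp(gen$corpus, reg[i, ])), reg)
  })
  # blank the content categories of the first summary but keep its trend
  s0 <- summaries[[1]]
  for (cc in c("brain_region", "mouse_model", "keyword")) {
    s0$categories[[cc]] <- s0$categories[[cc]][0, ]
  }
  expect_true(nrow(s0$categories$year_trend) > 0)
  pruned <- suppressMessages(prune_profiles(c(list(s0), summaries[-1])))
  expect_false(any(vapply(pruned, identical, logical(1), s0)))
  # pruning twice == pruning once
  expect_identical(suppressMessages(prune_profiles(pruned)), pruned)
  # a summary with at least one region hit is kept
  with_region <- summaries[vapply(summaries, function(s)
    nrow(s$categories$brain_region) > 0, logical(1))]
  expect_identical(suppressMessages(prune_profiles(with_region)),
                   with_region)
  expect_message(prune_profiles(list(s0)), "pruned=1")
})

test_that("summarize_corpus reports six category rows with both totals", {
  gen <- generate_corpus(random_corpus_spec(100, seed = 53))
  reg <- default_demo_registry()
  summaries <- lapply(seq_len(nrow(reg)), function(i) {
    extract_gene_summary(filter_nd(build_gspp(gen$corpus, reg[i, ])), reg)
  })
  tab <- summarize_corpus(summaries)
  expect_equal(nrow(tab), 6L)
  expect_identical(tab$category[1], "year_trend")
  expect_true(all(tab$n_publications <= tab$n_attributions))
  # distinct-pmid total never exceeds the corpus size
  expect_true(all(tab$n_publications <= nrow(gen$corpus)))
  # empty input -> all-zero rows
  zero <- summarize_corpus(list())
  expect_equal(nrow(zero), 6L)
  expect_true(all(zero$n_subcategories == 0))

  # the table matches generator truth
  truth_summaries <- lapply(reg$symbol, function(sym)
    truth_gene_summary(gen$truth, sym))
  expect_equal(tab, summarize_corpus(truth_summaries))
})

test_that("gene summary JSON write -> read -> write is byte-identical", {
  gen <- generate_corpus(random_corpus_spec(60, seed = 54))
  reg <- default_demo_registry()
  s <- extract_gene_summary(filter_nd(build_gspp(gen$corpus, reg[1, ])), reg)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_gene_summary_json(s, p1)
  s2 <- read_gene_summary_json(p1)
  write_gene_summary_json(s2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_identical(s2$gene, s$gene)
  expect_equal(tidy(s2), tidy(s))
})

test_that("tidy and glance expose summaries as tibbles", {
  prof <- make_nd_profile()
  s <- extract_gene_summary(prof, default_demo_registry())
  td <- tidy(s)
  expect_true(all(c("gene", "category", "subcategory", "count", "pmids")
                  %in% names(td)))
  expect_true(all(td$gene == "APOE"))
  expect_true(all(td$count == lengths(td$pmids)))
  gl <- glance(s)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n_records, nrow(prof))
})

test_that("plot helpers return ggplot objects", {
  prof <- make_nd_profile()
  s <- extract_gene_summary(prof, default_demo_registry())
  expect_s3_class(plot_year_trend(s), "ggplot")
  expect_s3_class(plot_category_counts(s, "brain_region"), "ggplot")
  expect_s3_class(ggplot2::autoplot(s), "ggplot")
})
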