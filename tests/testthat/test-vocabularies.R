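test_that("default vocabularies have the documented shape", {
  dem <- default_dementia_vocabulary()
  expect_equal(length(unique(dem$canonical)), 7L)
  alz <- dem$variant[dem$canonical == "Alzheimer's Disease"]
  expect_true(any(vapply(alz, identical, logical(1), "alzheimer")))

  br <- default_brain_region_vocabulary()
  expect_equal(length(unique(br$canonical)), 13L)
  expect_identical(sort(unique(br$canonical))[1], "Amygdala")
  expect_identical(br$variant[br$canonical == "Basal ganglia"][[1]],
                   c("basal", "ganglia"))

  kw <- default_keyword_vocabulary()
  expect_equal(length(unique(kw$canonical)), 32L)
  expect_identical(kw$variant[kw$canonical == "tau deposition"][[1]],
                   c("tau", "deposition"))

  mm <- default_mouse_model_vocabulary()
  expect_equal(length(unique(mm$canonical)), 11L)
  expect_identical(mm$variant[mm$canonical == "3xTg-AD"][[1]],
                   c("3xtg", "ad"))
})

test_that("vocabulary variants are self-consistent with tokenize", {
  for (vocab in default_vocabularies()) {
    for (i in seq_len(nrow(vocab))) {
      v <- vocab$variant[[i]]
      expect_identical(tokenize(paste(v, collapse = " ")), v)
      expect_true(match_term(tokenize(vocab$canonical[[i]]), list(v),
                             mode = "prefix"),
                  info = vocab$canonical[[i]])
    }
  }
})

test_that("vocabulary construction rejects degenerate variants", {
  expect_error(term_vocabulary("keyword", list(ok = "tau", bad = "...")),
               "bad")
  expect_error(term_vocabulary("keyword", list(empty = character(0))),
               "empty")
})

test_that("load_term_vocabulary reads YAML and JSON configs", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("alpha term: alpha term", "beta: [beta, betas]"), yml)
  v <- load_term_vocabulary(yml, "keyword")
  expect_equal(length(unique(v$canonical)), 2L)
  expect_equal(sum(v$canonical == "beta"), 2L)

  js <- withr::local_tempfile(fileext = ".json")
  writeLines('{"gamma": ["gamma ray"]}', js)
  v2 <- load_term_vocabulary(js, "brain_region")
  expect_identical(v2$variant[[1]], c("gamma", "ray"))
})

test_that("gene registries parse gene_info TSVs with the sentinel and stoplist", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_registry_fixture(path)
  reg <- load_gene_registry(path)
  expect_identical(reg$symbol, c("APOE", "TREM2", "MAPT"))
  expect_identical(reg$aliases[[1]], c("AD2", "LPG", "APO-E"))
  expect_identical(reg$aliases[[2]], character(0))
  # "TAU" passes (not a common word, 3 chars); "MTBT1" passes
  expect_identical(reg$aliases[[3]], c("TAU", "MTBT1"))

  # stoplist drops short and common-word aliases
  reg2 <- gene_registry("APOE", list(c("AD", "LPG", "WAS", "apoe")))
  expect_identical(reg2$aliases[[1]], "LPG")
  reg3 <- gene_registry("APOE", list(c("AD", "LPG")), apply_stoplist = FALSE)
  expect_identical(reg3$aliases[[1]], c("AD", "LPG"))

  # header-only file -> empty registry; missing columns -> schema error
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("#tax_id\tGeneID\tSymbol\tSynonyms", empty)
  expect_equal(nrow(load_gene_registry(empty)), 0L)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb\tc", "1\t2\t3"), bad)
  expect_error(load_gene_registry(bad), "Symbol")
})

test_that("registry load preserves row order deterministically", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_registry_fixture(path)
  expect_identical(load_gene_registry(path), load_gene_registry(path))
})

test_that("gene surface forms tokenize multiword aliases as n-grams", {
  forms <- gene_surface_forms(list(symbol = "PSEN1",
                                   aliases = "presenilin 1"))
  expect_identical(forms[[1]], "psen1")
  expect_identical(forms[[2]], c("presenilin", "1"))
  # case-insensitive dedup keeps each distinct form once
  forms2 <- gene_surface_forms(list(symbol = "APOE",
                                    aliases = c("Apoe", "LPG")))
  expect_equal(length(forms2), 2L)
})
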