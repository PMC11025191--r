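test_that("PubMed XML parsing extracts records, abstracts and year fallbacks", {
  path <- withr::local_tempfile(fileext = ".xml")
  write_pubmed_fixture(path)
  x <- read_pubmed_xml(path)
  expect_equal(nrow(x), 3L)
  expect_identical(x$pmid, c("11111", "22222", "33333"))
  # AbstractText blocks concatenate in document order with single spaces
  expect_identical(x$abstract[1], "First block. Second block.")
  # a record may lack an abstract entirely
  expect_identical(x$abstract[2], "")
  # MedlineDate fallback takes the leading four digits
  expect_identical(x$year, c(2004L, 2004L, 2019L))
  expect_identical(x$journal[1], "J Alpha")
})

test_that("empty PubmedArticleSet gives an empty corpus", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines("<PubmedArticleSet></PubmedArticleSet>", path)
  expect_equal(nrow(read_pubmed_xml(path)), 0L)
})

test_that("malformed XML raises a parse error; missing PMID skips with warning", {
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<PubmedArticleSet><unclosed>", bad)
  expect_error(read_pubmed_xml(bad), "malformed")

  nopmid <- withr::local_tempfile(fileext = ".xml")
  writeLines('<PubmedArticleSet><PubmedArticle><MedlineCitation>
    <Article><ArticleTitle>No id</ArticleTitle></Article>
    </MedlineCitation></PubmedArticle></PubmedArticleSet>', nopmid)
  expect_warning(x <- read_pubmed_xml(nopmid), "PMID")
  expect_equal(nrow(x), 0L)
})

test_that("record tables round-trip and enforce the schema", {
  x <- make_demo_corpus()

  csv <- withr::local_tempfile(fileext = ".csv")
  write_gspp_csv(x, csv)
  expect_identical(readLines(csv)[1], "pmid,year,title,abstract,journal")
  back <- read_records_table(csv)
  expect_equal(back, x)

  js <- withr::local_tempfile(fileext = ".json")
  write_records_json(x, js)
  expect_equal(read_records_table(js), x)

  # header-only CSV -> zero records
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("pmid,title,abstract,year,journal", empty)
  expect_equal(nrow(read_records_table(empty)), 0L)

  # missing column -> schema error naming it
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pmid,title,year", "1,A,2000"), bad)
  expect_error(read_records_table(bad), "abstract")

  # duplicate pmid -> validation error naming the pmid
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pmid,title,abstract,year,journal",
               "123,A,,2000,J", "123,B,,2001,J"), dup)
  expect_error(read_records_table(dup), "123")
})

test_that("GSPP CSV write -> read -> write is byte-identical", {
  x <- make_demo_corpus()
  x$abstract[2] <- "Line one.\nLine two, with a comma and \"quotes\"."
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_gspp_csv(x, p1)
  write_gspp_csv(read_records_table(p1), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("gene queries list each distinct surface form exactly once", {
  expect_identical(build_gene_query(list(symbol = "APOE",
                                         aliases = character(0))),
                   "APOE[Title/Abstract]")
  expect_identical(
    build_gene_query(list(symbol = "APOE", aliases = c("AD2", "LPG"))),
    "APOE[Title/Abstract] OR AD2[Title/Abstract] OR LPG[Title/Abstract]")
  # duplicate of the symbol (any case) collapses
  expect_identical(
    build_gene_query(list(symbol = "APOE", aliases = c("apoe", "LPG"))),
    "APOE[Title/Abstract] OR LPG[Title/Abstract]")
})

test_that("corpus validation rejects bad years and empty fields", {
  expect_error(corpus(pmid = "1", title = "", abstract = "", year = 2000L,
                      journal = ""), "title")
  expect_error(corpus(pmid = "1", title = "T", abstract = "", year = 1750L,
                      journal = ""), "year")
  # the year-0 sentinel is allowed (missing-date records stay in the corpus)
  expect_equal(nrow(corpus(pmid = "1", title = "T", abstract = "",
                           year = 0L, journal = "")), 1L)
})
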