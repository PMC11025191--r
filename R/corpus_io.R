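# Reading and writing publication records.
# A corpus is a tibble with one row per publication and columns
#   pmid (character, unique), title, abstract, year (integer), journal.
# Supported dialects: PubMed XML (PubmedArticleSet), flat CSV/JSON record
# tables, and the per-gene GSPP CSV (fixed column order).

.corpus_cols <- c("pmid", "title", "abstract", "year", "journal")
.gspp_cols <- c("pmid", "year", "title", "abstract", "journal")

#' Construct and validate a corpus tibble
#'
#' @param pmid,title,abstract,year,journal Parallel vectors of record fields.
#' @return A validated corpus tibble.
#' @export
#' @examples
#' corpus(pmid = "101", title = "APOE in Alzheimer's disease",
#'        abstract = "", year = 2004L, journal = "J Neurosci")
corpus <- function(pmid = character(0), title = character(0),
                   abstract = character(0), year = integer(0),
                   journal = character(0)) {
  out <- tibble::tibble(
    pmid = as.character(pmid),
    title = as.character(title),
    abstract = dplyr::coalesce(as.character(abstract), ""),
    year = as.integer(year),
    journal = dplyr::coalesce(as.character(journal), "")
  )
  validate_corpus(out)
}

#' Validate corpus invariants
#'
#' Checks presence of the five record columns, non-empty unique PMIDs,
#' non-empty titles, and publication years in `[1800, current year + 1]`
#' (with `0` allowed as the missing-year sentinel; such records are excluded
#' from trend extraction but kept everywhere else).
#'
#' @param x A data frame of publication records.
#' @return `x` as a tibble, invisibly validated.
#' @export
validate_corpus <- function(x) {
  missing <- setdiff(.corpus_cols, names(x))
  if (length(missing) > 0L) {
    stop("corpus schema error: missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- tibble::as_tibble(x)[, .corpus_cols]
  if (any(is.na(x$pmid) | !nzchar(x$pmid))) {
    stop("corpus validation error: empty pmid", call. = FALSE)
  }
  dup <- x$pmid[duplicated(x$pmid)]
  if (length(dup) > 0L) {
    stop("corpus validation error: duplicate pmid: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(x$title) | !nzchar(x$title))) {
    stop("corpus validation error: empty title (pmid ",
         x$pmid[which(is.na(x$title) | !nzchar(x$title))[1]], ")",
         call. = FALSE)
  }
  yr_max <- as.integer(format(Sys.Date(), "%Y")) + 1L
  bad <- !is.na(x$year) & x$year != 0L & (x$year < 1800L | x$year > yr_max)
  if (any(bad)) {
    stop("corpus validation error: year out of range for pmid ",
         x$pmid[which(bad)[1]], call. = FALSE)
  }
  x$year[is.na(x$year)] <- 0L
  x$abstract[is.na(x$abstract)] <- ""
  x$journal[is.na(x$journal)] <- ""
  x
}

.medline_year <- function(article) {
  y <- xml2::xml_text(xml2::xml_find_first(
    article, ".//Journal/JournalIssue/PubDate/Year"))
  if (!is.na(y) && nzchar(y)) return(as.integer(y))
  md <- xml2::xml_text(xml2::xml_find_first(
    article, ".//Journal/JournalIssue/PubDate/MedlineDate"))
  if (!is.na(md)) {
    m <- stringr::str_extract(md, "^\\d{4}")
    if (!is.na(m)) return(as.integer(m))
  }
  0L
}

#' Read a PubMed XML file into a corpus
#'
#' Parses a `PubmedArticleSet` document: one record per `PubmedArticle`. The
#' abstract is the concatenation of all `AbstractText` blocks in document
#' order, separated by single spaces (structured-abstract labels are not
#' re-inserted). The year comes from `PubDate/Year`, falling back to the
#' leading four digits of `MedlineDate`, then to the `0` sentinel. Articles
#' without a PMID are skipped with a warning.
#'
#' @param path Path to a PubMed XML file.
#' @return A corpus tibble.
#' @export
read_pubmed_xml <- function(path) {
  stopifnot(file.exists(path))
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) {
      stop("malformed PubMed XML in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  articles <- xml2::xml_find_all(doc, "//PubmedArticle")
  if (length(articles) == 0L) return(corpus())
  recs <- purrr::map(articles, function(a) {
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//MedlineCitation/PMID"))
    if (is.na(pmid) || !nzchar(pmid)) {
      warning("skipping PubmedArticle without PMID", call. = FALSE)
      return(NULL)
    }
    abst <- xml2::xml_text(xml2::xml_find_all(a, ".//Abstract/AbstractText"))
    list(
      pmid = pmid,
      title = xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle")),
      abstract = paste(abst, collapse = " "),
      year = .medline_year(a),
      journal = xml2::xml_text(xml2::xml_find_first(a, ".//Journal/Title"))
    )
  })
  recs <- purrr::compact(recs)
  if (length(recs) == 0L) return(corpus())
  corpus(
    pmid = purrr::map_chr(recs, "pmid"),
    title = purrr::map_chr(recs, "title"),
    abstract = purrr::map_chr(recs, "abstract"),
    year = purrr::map_int(recs, "year"),
    journal = purrr::map_chr(recs, function(r) r$journal %||% "")
  )
}

#' Read a flat record table (CSV or JSON) into a corpus
#'
#' The table must provide the keys `pmid`, `title`, `abstract`, `year`,
#' `journal` (any column order). Missing columns raise a schema error naming
#' them; duplicate PMIDs raise a validation error naming the PMID.
#'
#' @param path Path to the file.
#' @param dialect `"csv"` or `"json"`; defaults from the file extension.
#' @return A corpus tibble.
#' @export
read_records_table <- function(path, dialect = c("auto", "csv", "json")) {
  stopifnot(file.exists(path))
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  tbl <- if (dialect == "json") {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (length(x) == 0L) {
      tibble::tibble(pmid = character(0), title = character(0),
                     abstract = character(0), year = integer(0),
                     journal = character(0))
    } else {
      tibble::as_tibble(x)
    }
  } else {
    readr::read_csv(path, col_types = readr::cols(.default = "c"),
                    progress = FALSE, show_col_types = FALSE)
  }
  missing <- setdiff(.corpus_cols, names(tbl))
  if (length(missing) > 0L) {
    stop("record table schema error: missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  corpus(pmid = tbl$pmid, title = tbl$title, abstract = tbl$abstract,
         year = tbl$year, journal = tbl$journal)
}

#' Write a corpus as a flat JSON record table
#'
#' @param x A corpus tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records_json <- function(x, path) {
  x <- validate_corpus(x)
  jsonlite::write_json(x, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a gene publication profile (or any corpus) as a GSPP CSV
#'
#' One row per publication, fixed column order
#' `pmid,year,title,abstract,journal`, UTF-8, RFC 4180 quoting with embedded
#' newlines preserved inside quotes. Round-trips through
#' [read_records_table()].
#'
#' @param profile A GSPP (see [build_gspp()]) or corpus tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gspp_csv <- function(profile, path) {
  x <- validate_corpus(profile)[, .gspp_cols]
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Build a PubMed-style query string for a gene
#'
#' Disjunction of the official symbol and each alias, each restricted to
#' title/abstract fields, deterministic order (symbol first, aliases in
#' registry order), surface forms case-insensitively de-duplicated.
#'
#' @param gene A one-row registry slice or `list(symbol =, aliases =)`.
#' @return Query string, e.g.
#'   `"APOE[Title/Abstract] OR AD2[Title/Abstract]"`.
#' @export
#' @examples
#' build_gene_query(list(symbol = "APOE", aliases = c("AD2", "LPG")))
build_gene_query <- function(gene) {
  g <- as_gene_entry(gene)
  stopifnot(nzchar(g$symbol))
  forms <- c(g$symbol, g$aliases)
  forms <- forms[nzchar(forms)]
  forms <- forms[!duplicated(stringr::str_to_lower(forms))]
  paste0(forms, "[Title/Abstract]", collapse = " OR ")
}
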