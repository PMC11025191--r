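# Per-gene information extraction: the six category profiles, gene summaries,
# post-extraction pruning and the corpus-level summary table.
#
# A category profile is a tibble with one row per observed sub-category:
#   category    : one of year_trend, dementia_type, brain_region,
#                 mouse_model, keyword, cooccurring_gene
#   subcategory : 4-digit year string / canonical vocabulary name /
#                 co-occurring official gene symbol
#   count       : number of distinct publications attributed (== length(pmids))
#   pmids       : list-column of PMIDs, sorted ascending numerically
# Sub-categories with zero publications are absent by construction.

.summary_categories <- c("year_trend", "dementia_type", "brain_region",
                         "mouse_model", "keyword", "cooccurring_gene")

# Sort pmids ascending numerically (digit strings; alphabetical fallback for
# equal numeric keys keeps the sort total).
sort_pmids <- function(pmids) {
  pmids <- unique(pmids)
  pmids[order(suppressWarnings(as.numeric(pmids)), pmids)]
}

empty_category_profile <- function(category) {
  tibble::tibble(category = character(0), subcategory = character(0),
                 count = integer(0), pmids = list())
}

# Assemble a category profile from a named list: subcategory -> pmid vector.
category_profile <- function(category, hits) {
  hits <- hits[lengths(hits) > 0L]
  if (length(hits) == 0L) return(empty_category_profile(category))
  keys <- names(hits)
  ord <- order(keys)
  tibble::tibble(
    category = category,
    subcategory = keys[ord],
    count = unname(vapply(hits[ord], function(p) length(unique(p)),
                          integer(1))),
    pmids = unname(lapply(hits[ord], sort_pmids))
  )
}

.assert_nd <- function(profile) {
  if (!is_nd_filtered(profile)) {
    stop("extraction requires an nd_filtered profile; apply filter_nd() first",
         call. = FALSE)
  }
  invisible(profile)
}

#' Extract the yearly publication trend of a profile
#'
#' Stratifies the profile's publications by year: one sub-category per
#' distinct publication year, with the PMIDs and total count for that year.
#' Records carrying the missing-year sentinel (`year == 0`) are excluded, so
#' counts partition exactly the records with a valid year.
#'
#' @param profile An ND-filtered GSPP (see [filter_nd()]).
#' @return A category profile tibble (`category == "year_trend"`,
#'   sub-categories are 4-digit year strings).
#' @export
extract_year_trend <- function(profile) {
  .assert_nd(profile)
  keep <- !is.na(profile$year) & profile$year > 0L
  hits <- split(profile$pmid[keep], sprintf("%04d", profile$year[keep]))
  category_profile("year_trend", hits)
}

#' Extract a term-vocabulary category from a profile
#'
#' For each canonical vocabulary entry, collects the PMIDs of the records
#' whose title+abstract token stream matches one of its variants. A record
#' counts at most once per sub-category regardless of mention count, and may
#' appear under several sub-categories. Dementia types use prefix matching
#' (simplified stems); brain regions, mouse models and keywords use exact
#' token matching.
#'
#' @param profile An ND-filtered GSPP.
#' @param vocab A term-vocabulary tibble (see [term_vocabulary()]).
#' @param mode `"exact"` or `"prefix"`; defaults to `"prefix"` for the
#'   dementia category and `"exact"` otherwise.
#' @param .tokens Optional precomputed token list named by pmid.
#' @return A category profile tibble; the category name is
#'   `"dementia_type"` for dementia vocabularies, else the vocabulary
#'   category.
#' @export
extract_term_category <- function(profile, vocab, mode = NULL,
                                  .tokens = NULL) {
  .assert_nd(profile)
  validate_vocabulary(vocab)
  vcat <- vocab$category[[1]] %||% "keyword"
  mode <- mode %||% (if (identical(vcat, "dementia")) "prefix" else "exact")
  mode <- match.arg(mode, c("exact", "prefix"))
  out_cat <- if (identical(vcat, "dementia")) "dementia_type" else vcat
  if (nrow(profile) == 0L) return(empty_category_profile(out_cat))
  toks <- .align_tokens(.tokens, profile) %||% corpus_token_list(profile)
  by_canon <- split(vocab$variant, vocab$canonical)
  hits <- lapply(by_canon, function(variants) {
    profile$pmid[vapply(seq_len(nrow(profile)),
                        function(i) match_term(toks[[i]], variants, mode),
                        logical(1))]
  })
  category_profile(out_cat, hits)
}

#' Extract POS-gated co-occurring genes from a profile
#'
#' For each record, the title and abstract are part-of-speech tagged and
#' gated to nominal/adjectival tokens (see [pos_gate()]); every registry
#' gene's surface forms are then matched against the gated token stream.
#' PMIDs are aggregated per co-occurring official symbol; the focal gene
#' itself is excluded.
#'
#' @param profile An ND-filtered GSPP.
#' @param registry Gene registry tibble (see [gene_registry()]).
#' @param pos_gating Apply the POS gate (default `TRUE`). With gating
#'   disabled, matching runs on the plain [tokenize()] stream, which makes
#'   co-occurrence counts symmetric across gene pairs.
#' @param allowed_tags Tags admitted by the gate.
#' @param .tokens Optional precomputed *gated* (or plain, if
#'   `pos_gating = FALSE`) token list named by pmid.
#' @return A category profile tibble (`category == "cooccurring_gene"`,
#'   sub-categories are official symbols).
#' @export
extract_cooccurring_genes <- function(profile, registry, pos_gating = TRUE,
                                      allowed_tags = default_pos_tags(),
                                      .tokens = NULL) {
  .assert_nd(profile)
  stopifnot(is.data.frame(registry),
            all(c("symbol", "aliases") %in% names(registry)))
  focal <- gspp_gene(profile)$symbol
  if (nrow(profile) == 0L) return(empty_category_profile("cooccurring_gene"))
  toks <- .align_tokens(.tokens, profile) %||% {
    txt <- paste(profile$title, profile$abstract)
    fn <- if (pos_gating) {
      function(t) pos_gate(t, allowed_tags)
    } else {
      tokenize
    }
    stats::setNames(lapply(txt, fn), profile$pmid)
  }
  others <- registry[registry$symbol != focal, , drop = FALSE]
  hits <- stats::setNames(lapply(seq_len(nrow(others)), function(i) {
    forms <- gene_surface_forms(others[i, ])
    profile$pmid[vapply(
      seq_len(nrow(profile)),
      function(j) match_term(toks[[j]], forms, "exact"),
      logical(1))]
  }), others$symbol)
  category_profile("cooccurring_gene", hits)
}

#' Extract the full six-category summary for one gene
#'
#' Runs all six extractors over an ND-filtered profile: yearly trend,
#' dementia types (prefix matching), brain regions, mouse models, keywords
#' (exact matching) and POS-gated co-occurring genes.
#'
#' @param profile An ND-filtered GSPP.
#' @param registry Gene registry for co-occurrence extraction.
#' @param vocabularies Named list with elements `dementia`, `brain_region`,
#'   `mouse_model`, `keyword` (defaults to [default_vocabularies()]).
#' @param pos_gating,allowed_tags Passed to [extract_cooccurring_genes()].
#' @param .gated_tokens Optional precomputed POS-gated token list named by
#'   pmid, shared across genes built from the same corpus.
#' @return A `gene_summary` object: list with `gene` (symbol), `n_records`,
#'   and `categories` (named list of six category profile tibbles).
#' @export
extract_gene_summary <- function(profile, registry,
                                 vocabularies = default_vocabularies(),
                                 pos_gating = TRUE,
                                 allowed_tags = default_pos_tags(),
                                 .gated_tokens = NULL) {
  .assert_nd(profile)
  stopifnot(all(c("dementia", "brain_region", "mouse_model", "keyword") %in%
                  names(vocabularies)))
  toks <- corpus_token_list(profile)
  cats <- list(
    year_trend = extract_year_trend(profile),
    dementia_type = extract_term_category(profile, vocabularies$dementia,
                                          .tokens = toks),
    brain_region = extract_term_category(profile, vocabularies$brain_region,
                                         .tokens = toks),
    mouse_model = extract_term_category(profile, vocabularies$mouse_model,
                                        .tokens = toks),
    keyword = extract_term_category(profile, vocabularies$keyword,
                                    .tokens = toks),
    cooccurring_gene = extract_cooccurring_genes(
      profile, registry, pos_gating = pos_gating,
      allowed_tags = allowed_tags, .tokens = .gated_tokens)
  )
  structure(
    list(gene = gspp_gene(profile)$symbol, n_records = nrow(profile),
         categories = cats),
    class = "gene_summary"
  )
}

#' @export
print.gene_summary <- function(x, ...) {
  cat("Gene summary:", x$gene, "(", x$n_records, "ND publications )\n")
  for (cat_name in .summary_categories) {
    prof <- x$categories[[cat_name]]
    cat("  ", format(cat_name, width = 17), nrow(prof), "sub-categories\n")
  }
  invisible(x)
}

#' Prune gene summaries with no content-category hits
#'
#' Drops summaries whose brain-region, mouse-model AND keyword profiles are
#' all empty (the three content categories); all other summaries pass through
#' unchanged. The number dropped is reported as a message. Pruning is
#' idempotent.
#'
#' @param summaries List of `gene_summary` objects.
#' @return The retained summaries, same order.
#' @export
prune_profiles <- function(summaries) {
  keep <- vapply(summaries, function(s) {
    any(vapply(c("brain_region", "mouse_model", "keyword"),
               function(cc) nrow(s$categories[[cc]]) > 0L, logical(1)))
  }, logical(1))
  message("pruned=", sum(!keep), " retained=", sum(keep))
  summaries[keep]
}

#' Summarize a set of gene summaries, one row per information category
#'
#' For each of the six categories, reports the number of distinct
#' sub-categories observed across all genes, the number of distinct
#' publications (PMIDs de-duplicated across genes and sub-categories), and
#' the raw attribution sum (each gene x sub-category count added up, so a
#' publication attributed to several genes or sub-categories is counted each
#' time). Both publication readings are exposed because corpus-level totals
#' are ambiguous between them.
#'
#' @param summaries List of `gene_summary` objects.
#' @return Tibble with columns `category`, `n_subcategories`,
#'   `n_publications`, `n_attributions`, always six rows.
#' @export
summarize_corpus <- function(summaries) {
  rows <- lapply(.summary_categories, function(cat_name) {
    profs <- lapply(summaries, function(s) s$categories[[cat_name]])
    subs <- unique(unlist(lapply(profs, function(p) p$subcategory),
                          use.names = FALSE))
    pmids <- unique(unlist(lapply(profs, function(p)
      unlist(p$pmids, use.names = FALSE)), use.names = FALSE))
    tibble::tibble(
      category = cat_name,
      n_subcategories = length(subs),
      n_publications = length(pmids),
      n_attributions = sum(vapply(profs, function(p) sum(p$count),
                                  integer(1)))
    )
  })
  dplyr::bind_rows(rows)
}

# --- Serialization ----------------------------------------------------------
# GeneSummary JSON mirrors a two-attribute-per-category design: for every
# sub-category a count and the PMID list. The writer is canonical (fixed
# category order, sorted sub-categories and PMIDs, 2-space pretty printing)
# so write -> read -> write is byte-identical.

#' Write a gene summary as canonical JSON
#'
#' Schema: `{"gene": symbol, "n_records": n, "categories": {name:
#' {subcategory: {"count": n, "pmids": [...]}}}}`. Categories appear in fixed
#' order, sub-categories sorted by key, PMIDs sorted ascending numerically;
#' the output is deterministic and round-trips byte-identically through
#' [read_gene_summary_json()].
#'
#' @param summary A `gene_summary` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "gene_summary"))
  cats <- lapply(.summary_categories, function(cat_name) {
    prof <- summary$categories[[cat_name]]
    ord <- order(prof$subcategory)
    entries <- lapply(ord, function(i) list(
      count = jsonlite::unbox(as.integer(prof$count[[i]])),
      pmids = as.character(sort_pmids(prof$pmids[[i]]))
    ))
    stats::setNames(entries, prof$subcategory[ord])
  })
  obj <- list(
    gene = jsonlite::unbox(summary$gene),
    n_records = jsonlite::unbox(as.integer(summary$n_records)),
    categories = stats::setNames(cats, .summary_categories)
  )
  json <- jsonlite::toJSON(obj, pretty = 2, digits = NA)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read a gene summary from JSON
#'
#' @param path Path written by [write_gene_summary_json()].
#' @return A `gene_summary` object.
#' @export
read_gene_summary_json <- function(path) {
  stopifnot(file.exists(path))
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cats <- lapply(.summary_categories, function(cat_name) {
    entries <- obj$categories[[cat_name]] %||% list()
    hits <- lapply(entries, function(e)
      as.character(unlist(e$pmids, use.names = FALSE)))
    category_profile(cat_name, hits)
  })
  structure(
    list(gene = obj$gene[[1]], n_records = as.integer(obj$n_records[[1]]),
         categories = stats::setNames(cats, .summary_categories)),
    class = "gene_summary"
  )
}
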