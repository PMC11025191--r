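# Deterministic synthetic corpora with planted, known concept mentions.
# Every pipeline stage can be checked against an exact truth oracle derived
# from the planting plan alone (never by re-running the matchers): a record
# belongs to gene G's ND profile iff G and some dementia type were planted in
# it, and each category count is the size of the corresponding intersection
# of planted index sets.

# Carrier phrase pools. Every word is screened at generation time against all
# active vocabulary variant tokens (prefix-aware) and gene surface forms, so
# planted phrases are the only source of concept mentions.
.carrier_prefixes <- c(
  "We examined", "This work considered", "Findings concerning",
  "Observations regarding", "New evidence about", "A survey of"
)
.carrier_suffixes <- c(
  "in a longitudinal cohort.", "across the enrollment sample.",
  "under the reported protocol.", "at the baseline visit.",
  "throughout the followup period.", "within the survey panel."
)
.filler_words_default <- c(
  "cohort", "baseline", "protocol", "outcome", "enrollment", "criterion",
  "interval", "longitudinal", "survey", "archive", "catalog", "index",
  "appendix", "procedure", "design", "panel", "battery", "domain", "score",
  "scale", "module", "segment", "window", "phase", "stage", "cycle",
  "period", "duration", "sampling", "questionnaire", "followup", "visit",
  "record", "ledger", "roster", "quota", "margin", "bracket", "tier"
)
.journal_pool <- c("J Synth Neurosci", "Ann Mock Med", "Simulated Brain Res",
                   "Arch Test Biol")

#' Default filler vocabulary for synthetic corpora
#' @return Character vector of neutral words.
#' @export
default_filler_words <- function() .filler_words_default

#' Describe one planted concept
#'
#' @param type `"gene"`, `"dementia"`, `"brain_region"`, `"mouse_model"` or
#'   `"keyword"`.
#' @param concept Canonical name: an official gene symbol or a vocabulary
#'   canonical entry.
#' @param records Integer vector of 1-based record indices that must mention
#'   the concept.
#' @param surface Surface form inserted into the text; defaults to `concept`.
#'   For genes it may be an alias surface form.
#' @return One planting-plan row (tibble).
#' @export
plant_concept <- function(type, concept, records, surface = NULL) {
  type <- match.arg(type, c("gene", "dementia", "brain_region",
                            "mouse_model", "keyword"))
  stopifnot(is.character(concept), length(concept) == 1L, nzchar(concept))
  tibble::tibble(type = type, concept = concept,
                 surface = surface %||% concept,
                 records = list(sort(unique(as.integer(records)))))
}

#' Specify a synthetic corpus
#'
#' @param n_records Number of publication records.
#' @param plan Planting plan: rows from [plant_concept()] bound together.
#'   Indices are 1-based and must lie in `[1, n_records]`.
#' @param year_range Inclusive integer pair for publication years.
#' @param seed Integer seed; identical specs generate byte-identical corpora.
#' @param filler Filler vocabulary (screened against the active vocabularies
#'   at generation time).
#' @return A `corpus_spec` object.
#' @export
corpus_spec <- function(n_records, plan, year_range = c(1995L, 2023L),
                        seed = 1L, filler = default_filler_words()) {
  stopifnot(is.numeric(n_records), n_records >= 0L,
            is.data.frame(plan) || is.null(plan),
            length(year_range) == 2L, year_range[1] <= year_range[2])
  plan <- plan %||% plant_concept("gene", "NONE", integer(0))[0, ]
  idx <- unlist(plan$records, use.names = FALSE)
  if (length(idx) > 0L && (min(idx) < 1L || max(idx) > n_records)) {
    stop("corpus_spec validation error: planted record indices must lie in ",
         "[1, n_records]", call. = FALSE)
  }
  structure(list(n_records = as.integer(n_records), plan = plan,
                 year_range = as.integer(year_range), seed = as.integer(seed),
                 filler = filler),
            class = "corpus_spec")
}

# All (token, prefix?) screening pairs implied by vocabularies + registry.
.screening_tokens <- function(registry, vocabularies) {
  vocab_tokens <- lapply(names(vocabularies), function(nm) {
    toks <- unlist(vocabularies[[nm]]$variant, use.names = FALSE)
    tibble::tibble(token = toks, prefix = identical(nm, "dementia"))
  })
  gene_tokens <- tibble::tibble(
    token = unlist(lapply(seq_len(nrow(registry)), function(i)
      unlist(gene_surface_forms(registry[i, ]), use.names = FALSE)),
      use.names = FALSE),
    prefix = FALSE
  )
  dplyr::distinct(dplyr::bind_rows(c(vocab_tokens, list(gene_tokens))))
}

.collides <- function(word, screen) {
  any(screen$token == word) ||
    any(screen$prefix & startsWith(word, screen$token))
}

# Error if any filler/carrier token could fire a concept matcher.
.screen_neutral_words <- function(words, screen, what) {
  toks <- unique(unlist(lapply(words, tokenize), use.names = FALSE))
  bad <- toks[vapply(toks, .collides, logical(1), screen = screen)]
  if (length(bad) > 0L) {
    stop("synthetic corpus ", what, " collides with an active vocabulary: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# Error if one planted surface embeds a different concept's variant n-gram.
.screen_cross_concepts <- function(plan, registry, vocabularies) {
  variant_sets <- list()
  for (nm in names(vocabularies)) {
    v <- vocabularies[[nm]]
    for (i in seq_len(nrow(v))) {
      key <- paste0(nm, ":", v$canonical[[i]])
      variant_sets[[key]] <- c(variant_sets[[key]] %||% list(),
                               list(v$variant[[i]]))
    }
  }
  for (i in seq_len(nrow(registry))) {
    variant_sets[[paste0("gene:", registry$symbol[[i]])]] <-
      gene_surface_forms(registry[i, ])
  }
  key_of <- function(type, concept) {
    paste0(if (type == "dementia") "dementia" else type, ":", concept)
  }
  for (i in seq_len(nrow(plan))) {
    toks <- tokenize(plan$surface[[i]])
    own <- key_of(plan$type[[i]], plan$concept[[i]])
    for (key in names(variant_sets)) {
      if (key == own) next
      mode <- if (startsWith(key, "dementia:")) "prefix" else "exact"
      if (match_term(toks, variant_sets[[key]], mode)) {
        stop("planted surface '", plan$surface[[i]], "' (", own,
             ") embeds a variant of ", key, call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Generate a synthetic corpus with exact planted truth
#'
#' Each record's title and abstract are built from neutral filler sentences
#' plus one grammatical carrier sentence per planted concept ("We examined
#' {surface} in a longitudinal cohort."), so the POS gate sees planted gene
#' symbols in nominal contexts. Filler and carrier words are validated
#' against every active vocabulary and gene surface form, and planted
#' surfaces are checked for cross-concept containment; a collision is an
#' error, never silent. Identical specs (including the seed) produce
#' byte-identical corpora.
#'
#' @param spec A [corpus_spec()].
#' @param registry Gene registry whose genes are being planted/screened.
#' @param vocabularies Named list of the four term vocabularies.
#' @return List with `corpus` (a corpus tibble) and `truth` (a
#'   `corpus_truth` object; see [truth_gene_summary()]).
#' @export
generate_corpus <- function(spec, registry = default_demo_registry(),
                            vocabularies = default_vocabularies()) {
  stopifnot(inherits(spec, "corpus_spec"))
  screen <- .screening_tokens(registry, vocabularies)
  .screen_neutral_words(spec$filler, screen, "filler word")
  .screen_neutral_words(c(.carrier_prefixes, .carrier_suffixes), screen,
                        "carrier phrase")
  .screen_cross_concepts(spec$plan, registry, vocabularies)
  n <- spec$n_records
  if (n == 0L) {
    return(list(corpus = corpus(),
                truth = new_corpus_truth(spec, character(0), integer(0))))
  }
  planted_by_record <- vector("list", n)
  for (i in seq_len(nrow(spec$plan))) {
    for (r in spec$plan$records[[i]]) {
      planted_by_record[[r]] <- c(planted_by_record[[r]], i)
    }
  }
  withr::with_seed(spec$seed, {
    years <- sample(seq(spec$year_range[1], spec$year_range[2]), n,
                    replace = TRUE)
    journals <- sample(.journal_pool, n, replace = TRUE)
    filler_sentence <- function() {
      w <- sample(spec$filler, sample(4:8, 1L), replace = TRUE)
      paste0(paste(c(stringr::str_to_title(w[1]), w[-1]), collapse = " "), ".")
    }
    carrier_sentence <- function(surface) {
      paste(sample(.carrier_prefixes, 1L), surface,
            sample(.carrier_suffixes, 1L))
    }
    titles <- character(n)
    abstracts <- character(n)
    for (r in seq_len(n)) {
      plan_rows <- planted_by_record[[r]]
      sentences <- vapply(plan_rows, function(i)
        carrier_sentence(spec$plan$surface[[i]]), character(1))
      titles[r] <- if (length(sentences) > 0L) sentences[[1]] else
        filler_sentence()
      body <- c(if (length(sentences) > 1L) sentences[-1],
                replicate(sample(1:3, 1L), filler_sentence()))
      abstracts[r] <- paste(body, collapse = " ")
    }
  })
  pmids <- sprintf("%d", 1000000L + seq_len(n))
  out <- corpus(pmid = pmids, title = titles, abstract = abstracts,
                year = years, journal = journals)
  list(corpus = out, truth = new_corpus_truth(spec, pmids, years))
}

new_corpus_truth <- function(spec, pmids, years) {
  plan <- spec$plan
  idx_of <- function(type) which(plan$type == type)
  concept_records <- function(rows) {
    stats::setNames(lapply(rows, function(i) plan$records[[i]]),
                    plan$concept[rows])
  }
  # a concept planted under several surfaces: union its index sets
  merge_named <- function(lst) {
    if (length(lst) == 0L) return(list())
    lapply(split(lst, names(lst)), function(parts)
      sort(unique(unlist(parts, use.names = FALSE))))
  }
  by_type <- lapply(c(gene = "gene", dementia = "dementia",
                      brain_region = "brain_region",
                      mouse_model = "mouse_model", keyword = "keyword"),
                    function(tp) merge_named(concept_records(idx_of(tp))))
  structure(list(spec = spec, pmids = pmids, years = years,
                 concept_records = by_type,
                 nd_records = sort(unique(unlist(by_type$dementia,
                                                 use.names = FALSE)))),
            class = "corpus_truth")
}

#' Expected ND-profile record indices for a gene, from the plan alone
#' @param truth A `corpus_truth`.
#' @param symbol Official gene symbol.
#' @param nd_filtered Intersect with dementia-planted records (default).
#' @return Sorted integer vector of 1-based record indices.
#' @export
truth_gene_records <- function(truth, symbol, nd_filtered = TRUE) {
  g <- truth$concept_records$gene[[symbol]] %||% integer(0)
  if (nd_filtered) intersect(g, truth$nd_records) else g
}

#' Expected gene summary derived from the planting plan
#'
#' Computes, purely by index-set arithmetic on the planting plan (no text
#' matching), the category profiles the pipeline must recover for one gene:
#' year trend over the gene's ND records, planted dementia/region/strain/
#' keyword counts, and co-occurring genes from joint plantings.
#'
#' @param truth A `corpus_truth` from [generate_corpus()].
#' @param symbol Official gene symbol.
#' @return A `gene_summary` object with the six expected category profiles.
#' @export
truth_gene_summary <- function(truth, symbol) {
  recs <- truth_gene_records(truth, symbol)
  pm <- function(idx) truth$pmids[idx]
  term_cat <- function(out_name, type) {
    hits <- lapply(truth$concept_records[[type]],
                   function(idx) pm(intersect(recs, idx)))
    category_profile(out_name, hits)
  }
  year_hits <- split(pm(recs),
                     sprintf("%04d", truth$years[recs]))
  co_hits <- lapply(truth$concept_records$gene, function(idx)
    pm(intersect(recs, idx)))
  co_hits[[symbol]] <- NULL
  cats <- list(
    year_trend = category_profile("year_trend", year_hits),
    dementia_type = term_cat("dementia_type", "dementia"),
    brain_region = term_cat("brain_region", "brain_region"),
    mouse_model = term_cat("mouse_model", "mouse_model"),
    keyword = term_cat("keyword", "keyword"),
    cooccurring_gene = category_profile("cooccurring_gene", co_hits)
  )
  structure(list(gene = symbol, n_records = length(recs), categories = cats),
            class = "gene_summary")
}

#' Draw a randomized corpus specification
#'
#' Randomly plants genes (with occasional alias surfaces), dementia types,
#' brain regions, mouse strains and keywords at controlled per-document
#' rates. These defaults emulate an ND-focused abstract collection: most
#' records carry a dementia mention, a third carry a brain region, strains
#' are rarer, and a sizeable minority of records co-mention two or more
#' genes.
#'
#' @param n_records Number of records.
#' @param seed Integer seed.
#' @param registry,vocabularies Active gene registry and vocabularies.
#' @param p_nd Probability a record mentions at least one dementia type.
#' @param p_second_gene Probability a record carries a second gene.
#' @param p_region,p_strain,p_keyword Per-record planting probabilities.
#' @return A `corpus_spec`.
#' @export
random_corpus_spec <- function(n_records, seed,
                               registry = default_demo_registry(),
                               vocabularies = default_vocabularies(),
                               p_nd = 0.85, p_second_gene = 0.35,
                               p_region = 0.35, p_strain = 0.15,
                               p_keyword = 0.45) {
  withr::with_seed(as.integer(seed), {
    symbols <- registry$symbol
    pick <- function(pool) pool[sample.int(length(pool), 1L)]
    plan_env <- new.env(parent = emptyenv())
    add <- function(type, concept, r, surface = NULL) {
      key <- paste0(type, "\r", concept, "\r", surface %||% concept)
      assign(key, c(get0(key, envir = plan_env) %||% integer(0), r),
             envir = plan_env)
    }
    for (r in seq_len(n_records)) {
      g1 <- pick(symbols)
      row <- registry[registry$symbol == g1, ]
      aliases <- row$aliases[[1]]
      surface <- if (length(aliases) > 0L && stats::runif(1) < 0.2)
        aliases[[1]] else g1
      add("gene", g1, r, surface)
      if (stats::runif(1) < p_second_gene) {
        g2 <- pick(setdiff(symbols, g1))
        add("gene", g2, r)
      }
      if (stats::runif(1) < p_nd) {
        add("dementia", pick(unique(vocabularies$dementia$canonical)), r)
      }
      if (stats::runif(1) < p_region) {
        add("brain_region", pick(unique(vocabularies$brain_region$canonical)), r)
      }
      if (stats::runif(1) < p_strain) {
        add("mouse_model", pick(unique(vocabularies$mouse_model$canonical)), r)
      }
      n_kw <- stats::rbinom(1L, 2L, p_keyword / 2)
      if (n_kw > 0L) {
        for (kw in sample(unique(vocabularies$keyword$canonical), n_kw)) {
          add("keyword", kw, r)
        }
      }
    }
    keys <- sort(ls(plan_env))
    plan <- dplyr::bind_rows(lapply(keys, function(key) {
      parts <- stringr::str_split_1(key, "\r")
      plant_concept(parts[1], parts[2], get(key, envir = plan_env),
                    surface = parts[3])
    }))
    corpus_spec(n_records, plan, seed = as.integer(seed))
  })
}

#' Run the full pipeline on a synthetic corpus and compare against truth
#'
#' Generates the corpus, builds the GSPP for every registry gene, applies the
#' disease-of-focus filter, extracts all six categories and compares each
#' category profile with the plan-derived truth oracle, exactly.
#'
#' @param spec A [corpus_spec()].
#' @param registry,vocabularies Active registry and vocabularies.
#' @param pos_gating Gate co-occurrence extraction (default `TRUE`).
#' @return List with `comparison` (tibble: `gene`, `category`, `match`),
#'   `all_match` (logical), `summaries` (pipeline output) and `truth`.
#' @export
run_end_to_end <- function(spec, registry = default_demo_registry(),
                           vocabularies = default_vocabularies(),
                           pos_gating = TRUE) {
  gen <- generate_corpus(spec, registry, vocabularies)
  toks <- corpus_token_list(gen$corpus)
  txt <- paste(gen$corpus$title, gen$corpus$abstract)
  gated <- if (pos_gating) {
    stats::setNames(lapply(txt, pos_gate), gen$corpus$pmid)
  } else {
    toks
  }
  summaries <- lapply(seq_len(nrow(registry)), function(i) {
    prof <- build_gspp(gen$corpus, registry[i, ], .tokens = toks)
    prof <- filter_nd(prof, vocabularies$dementia, .tokens = toks)
    extract_gene_summary(prof, registry, vocabularies,
                         pos_gating = pos_gating, .gated_tokens = gated)
  })
  rows <- purrr::map2(summaries, registry$symbol, function(s, sym) {
    expected <- truth_gene_summary(gen$truth, sym)
    tibble::tibble(
      gene = sym,
      category = .summary_categories,
      match = vapply(.summary_categories, function(cc)
        isTRUE(all.equal(
          as.data.frame(s$categories[[cc]]),
          as.data.frame(expected$categories[[cc]]),
          check.attributes = FALSE)),
        logical(1))
    )
  })
  comparison <- dplyr::bind_rows(rows)
  list(comparison = comparison, all_match = all(comparison$match),
       summaries = summaries, truth = gen$truth)
}
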