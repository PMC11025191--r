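# Controlled vocabularies: the gene registry and the four term categories
# (dementia types, brain regions, mouse-model strains, expert keywords).
# A vocabulary is a tidy tibble with one row per (canonical name, variant):
#   category  : "dementia", "brain_region", "mouse_model" or "keyword"
#   canonical : the sub-category label reported in extraction output
#   variant   : list-column of normalized token vectors (see tokenize())

.vocab_categories <- c("dementia", "brain_region", "mouse_model", "keyword")

#' Construct a term vocabulary from canonical names and variant strings
#'
#' Each variant string is normalized with [tokenize()]; a variant that
#' normalizes to zero tokens is a configuration error. Every canonical entry
#' must have at least one variant.
#'
#' @param category One of `"dementia"`, `"brain_region"`, `"mouse_model"`,
#'   `"keyword"`.
#' @param entries Named list: canonical name -> character vector of variant
#'   strings (a bare string is treated as one variant).
#' @return A tibble with columns `category`, `canonical`, `variant`
#'   (list-column of token vectors).
#' @export
#' @examples
#' term_vocabulary("brain_region", list(Hippocampus = "hippocampus"))
term_vocabulary <- function(category, entries) {
  category <- match.arg(category, .vocab_categories)
  stopifnot(is.list(entries), length(entries) > 0L,
            !is.null(names(entries)), all(nzchar(names(entries))))
  rows <- purrr::imap(entries, function(variants, canonical) {
    variants <- as.character(variants)
    if (length(variants) == 0L) {
      stop("vocabulary entry '", canonical, "' has no variants", call. = FALSE)
    }
    toks <- lapply(variants, tokenize)
    empty <- lengths(toks) == 0L
    if (any(empty)) {
      stop("vocabulary entry '", canonical, "' has a variant that normalizes ",
           "to no tokens: '", variants[empty][[1]], "'", call. = FALSE)
    }
    tibble::tibble(category = category, canonical = canonical, variant = toks)
  })
  out <- dplyr::bind_rows(rows)
  validate_vocabulary(out)
  out
}

validate_vocabulary <- function(vocab) {
  stopifnot(is.data.frame(vocab),
            all(c("category", "canonical", "variant") %in% names(vocab)))
  toks <- unlist(vocab$variant, use.names = FALSE)
  bad <- stringr::str_detect(toks, "[\\s[:punct:]]")
  if (any(bad)) {
    stop("vocabulary variant token contains whitespace/punctuation: '",
         toks[bad][[1]], "'", call. = FALSE)
  }
  invisible(vocab)
}

#' Default dementia-type vocabulary
#'
#' The seven major dementia types used as the disease-of-focus filter, each
#' carried by its simplified-stem variant so that, in prefix matching,
#' "alzheimer" covers "Alzheimer's", "alzheimers", etc.
#'
#' @return A term-vocabulary tibble with 7 canonical entries.
#' @export
#' @examples
#' default_dementia_vocabulary()
default_dementia_vocabulary <- function() {
  term_vocabulary("dementia", list(
    "Alzheimer's Disease"     = "alzheimer",
    "Parkinson's Disease"     = "parkinson",
    "Huntington's Disease"    = "huntington",
    "Frontotemporal Dementia" = "frontotemporal dementia",
    "Lewy Body Dementia"      = "lewy body",
    "Vascular Dementia"       = "vascular dementia",
    "Mixed Dementia"          = "mixed dementia"
  ))
}

#' Default brain-region vocabulary
#'
#' The thirteen brain regions commonly studied in neurodegenerative disease,
#' in alphabetical order; multiword regions are multi-token variants matched
#' as contiguous n-grams.
#'
#' @return A term-vocabulary tibble with 13 canonical entries.
#' @export
#' @examples
#' default_brain_region_vocabulary()
default_brain_region_vocabulary <- function() {
  regions <- c(
    "Amygdala", "Basal ganglia", "Brain stem", "Cerebellum",
    "Cingulate gyrus", "Corpus callosum", "Hippocampus", "Hypothalamus",
    "Neocortex", "Pituitary gland", "Prefrontal cortex", "Spinal cord",
    "Thalamus"
  )
  term_vocabulary("brain_region",
                  stats::setNames(as.list(stringr::str_to_lower(regions)),
                                  regions))
}

#' Load a term vocabulary from a YAML or JSON config file
#'
#' The config maps canonical names to a variant string or list of variant
#' strings. Variants are normalized with [tokenize()]; an entry whose variant
#' normalizes to nothing is rejected with an error naming the entry.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @param category Vocabulary category (see [term_vocabulary()]).
#' @return A term-vocabulary tibble.
#' @export
load_term_vocabulary <- function(path, category) {
  stopifnot(file.exists(path))
  entries <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  term_vocabulary(category, entries)
}

#' Default expert-keyword vocabulary (synthetic snapshot)
#'
#' Loads the 32-entry keyword config shipped with the package
#' (`inst/extdata/keywords.synthetic.yaml`): a synthetic snapshot of
#' expert-curated AD-research keywords covering major disease processes
#' (tau deposition, innate immune response, lipid metabolism, oxidative
#' stress, ...). Treated as configuration, not constants: supply your own
#' file through [load_term_vocabulary()] to replace it.
#'
#' @return A term-vocabulary tibble with 32 canonical entries.
#' @export
default_keyword_vocabulary <- function() {
  load_term_vocabulary(
    system.file("extdata", "keywords.synthetic.yaml", package = "pubprofiles",
                mustWork = TRUE),
    "keyword"
  )
}

#' Default mouse-model strain vocabulary (synthetic snapshot)
#'
#' Loads the shipped strain-name config
#' (`inst/extdata/mouse_models.synthetic.yaml`), a synthetic snapshot of
#' eleven named Alzheimer's-disease mouse-model strains. Strain names are the
#' primary identifiers and are matched as token n-grams after normalization
#' ("3xTg-AD" matches as `c("3xtg", "ad")`).
#'
#' @return A term-vocabulary tibble with 11 canonical entries.
#' @export
default_mouse_model_vocabulary <- function() {
  load_term_vocabulary(
    system.file("extdata", "mouse_models.synthetic.yaml",
                package = "pubprofiles", mustWork = TRUE),
    "mouse_model"
  )
}

#' All four default term vocabularies
#'
#' @return Named list of term-vocabulary tibbles: `dementia`, `brain_region`,
#'   `mouse_model`, `keyword`.
#' @export
default_vocabularies <- function() {
  list(
    dementia     = default_dementia_vocabulary(),
    brain_region = default_brain_region_vocabulary(),
    mouse_model  = default_mouse_model_vocabulary(),
    keyword      = default_keyword_vocabulary()
  )
}

# --- Gene registry ----------------------------------------------------------

# Common English words that collide with gene symbols/aliases under
# lowercased token matching; aliases equal to these are dropped by the
# default stoplist (the official symbol itself is always retained).
.common_word_stoplist <- c(
  "a", "ad", "all", "an", "and", "arc", "arms", "art", "at", "bad", "bar",
  "base", "bed", "best", "bid", "can", "cat", "cell", "chip", "clock",
  "cope", "damage", "digit", "fact", "fast", "fat", "fate", "fig", "fix",
  "flame", "for", "gas", "gel", "goat", "great", "grip", "hip", "hit",
  "ice", "if", "impact", "in", "is", "it", "kit", "large", "light", "lot",
  "map", "mark", "mass", "max", "men", "met", "mice", "minor", "miss",
  "nodal", "not", "of", "on", "or", "out", "pale", "pan", "pigs", "pink",
  "pit", "rain", "red", "rest", "rev", "set", "sharp", "she", "shot",
  "spring", "star", "stop", "tan", "the", "tip", "to", "top", "trap",
  "turn", "up", "via", "was", "wars", "web", "will", "yes"
)

#' Common-word stoplist for ambiguous gene aliases
#'
#' @return Character vector of lowercase words excluded from alias matching
#'   by default.
#' @export
default_gene_stoplist <- function() .common_word_stoplist

.filter_aliases <- function(symbol, aliases, stoplist) {
  aliases <- aliases[nzchar(aliases)]
  # case-insensitive dedup and removal of the symbol itself
  aliases <- aliases[!duplicated(stringr::str_to_lower(aliases))]
  aliases <- aliases[stringr::str_to_lower(aliases) !=
                       stringr::str_to_lower(symbol)]
  if (!is.null(stoplist)) {
    low <- stringr::str_to_lower(aliases)
    aliases <- aliases[nchar(aliases) > 2L & !(low %in% stoplist)]
  }
  aliases
}

#' Build a gene registry tibble
#'
#' @param symbol Character vector of official (HUGO-style) gene symbols.
#' @param aliases List of character vectors of alias surface forms (or a
#'   single character vector when `length(symbol) == 1`).
#' @param apply_stoplist Drop aliases that are two characters or fewer, or
#'   that equal a common English word (see [default_gene_stoplist()]).
#'   Official symbols are never dropped.
#' @param stoplist Lowercase words treated as ambiguous.
#' @return Tibble with columns `symbol` and `aliases` (list-column).
#' @export
#' @examples
#' gene_registry("APOE", list(c("AD2", "LPG")))
gene_registry <- function(symbol, aliases = NULL, apply_stoplist = TRUE,
                          stoplist = default_gene_stoplist()) {
  stopifnot(is.character(symbol), all(nzchar(symbol)), !anyDuplicated(symbol))
  if (is.null(aliases)) aliases <- rep(list(character(0)), length(symbol))
  if (is.character(aliases) && length(symbol) == 1L) aliases <- list(aliases)
  stopifnot(length(aliases) == length(symbol))
  sl <- if (apply_stoplist) stoplist else NULL
  tibble::tibble(
    symbol = symbol,
    aliases = purrr::map2(symbol, aliases,
                          function(s, a) .filter_aliases(s, as.character(a), sl))
  )
}

#' Load a gene registry from a gene_info-style TSV
#'
#' Accepts either the NCBI `gene_info` layout (columns named `Symbol` and
#' `Synonyms`, a leading `#` on the header tolerated) or a bare two-column
#' `symbol<TAB>synonyms` file. Synonyms are pipe-separated; `"-"` denotes no
#' synonyms. Row order is preserved.
#'
#' @inheritParams gene_registry
#' @param path Path to the TSV file.
#' @return Tibble with columns `symbol` and `aliases` (list-column).
#' @export
load_gene_registry <- function(path, apply_stoplist = TRUE,
                               stoplist = default_gene_stoplist()) {
  stopifnot(file.exists(path))
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  names(tbl) <- sub("^#", "", names(tbl))
  low <- stringr::str_to_lower(names(tbl))
  sym_col <- which(low == "symbol")
  syn_col <- which(low == "synonyms")
  if (length(sym_col) == 0L || length(syn_col) == 0L) {
    if (ncol(tbl) == 2L) {
      sym_col <- 1L
      syn_col <- 2L
    } else {
      missing <- c("Symbol", "Synonyms")[c(length(sym_col) == 0L,
                                           length(syn_col) == 0L)]
      stop("gene registry schema error: missing columns: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  if (nrow(tbl) == 0L) {
    return(tibble::tibble(symbol = character(0), aliases = list()))
  }
  syn <- tbl[[syn_col[[1]]]]
  aliases <- lapply(syn, function(s) {
    if (is.na(s) || s == "-" || !nzchar(s)) character(0)
    else stringr::str_split_1(s, stringr::fixed("|"))
  })
  gene_registry(tbl[[sym_col[[1]]]], aliases,
                apply_stoplist = apply_stoplist, stoplist = stoplist)
}

#' Normalized surface forms of a gene for token matching
#'
#' Tokenizes the official symbol and each retained alias into variant token
#' sequences (multi-token aliases are matched as n-grams), case-insensitively
#' de-duplicated, symbol first.
#'
#' @param gene A one-row slice of a gene registry, or a list with `symbol`
#'   and `aliases`.
#' @return List of character token vectors.
#' @export
gene_surface_forms <- function(gene) {
  g <- as_gene_entry(gene)
  forms <- c(list(tokenize(g$symbol)), lapply(g$aliases, tokenize))
  forms <- forms[lengths(forms) > 0L]
  forms[!duplicated(vapply(forms, paste, character(1), collapse = " "))]
}

# Coerce a registry row / list into list(symbol=, aliases=).
as_gene_entry <- function(gene) {
  if (is.data.frame(gene)) {
    stopifnot(nrow(gene) == 1L, all(c("symbol", "aliases") %in% names(gene)))
    return(list(symbol = gene$symbol[[1]],
                aliases = as.character(gene$aliases[[1]])))
  }
  stopifnot(is.list(gene), !is.null(gene$symbol))
  list(symbol = gene$symbol,
       aliases = as.character(gene$aliases %||% character(0)))
}

#' Demonstration gene registry
#'
#' A small built-in registry of ten well-studied neurodegeneration genes,
#' used by examples, the synthetic-corpus generator and the command-line
#' `simulate` workflow. Alias surface forms are chosen to be unambiguous
#' under token matching.
#'
#' @return Tibble with columns `symbol` and `aliases`.
#' @export
default_demo_registry <- function() {
  gene_registry(
    symbol = c("APOE", "TREM2", "MAPT", "PSEN1", "SNCA",
               "BIN1", "CLU", "PICALM", "GRN", "CD33"),
    aliases = list(
      c("apolipoprotein E"), character(0), character(0),
      c("presenilin 1"), c("alphasynuclein"),
      character(0), c("APOJ"), character(0), c("progranulin"), character(0)
    )
  )
}
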