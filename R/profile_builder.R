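# Gene-specific publication profiles (GSPPs).
# A GSPP is a corpus tibble restricted to the publications whose title or
# abstract contains the gene's official symbol or a retained alias as a
# normalized token n-gram, carrying the gene identity and an nd_filtered
# provenance flag as attributes.

new_gspp <- function(records, gene, nd_filtered) {
  out <- tibble::as_tibble(records)
  class(out) <- c("gspp", class(tibble::tibble()))
  attr(out, "gene") <- gene
  attr(out, "nd_filtered") <- isTRUE(nd_filtered)
  out
}

#' Gene identity of a profile
#' @param profile A GSPP.
#' @return `list(symbol =, aliases =)`.
#' @export
gspp_gene <- function(profile) attr(profile, "gene", exact = TRUE)

#' Has the disease-of-focus filter been applied?
#' @param profile A GSPP.
#' @return Logical scalar.
#' @export
is_nd_filtered <- function(profile) isTRUE(attr(profile, "nd_filtered"))

#' @export
print.gspp <- function(x, ...) {
  g <- gspp_gene(x)
  cat("Gene-specific publication profile: ", g$symbol,
      " (", nrow(x), " records, nd_filtered = ", is_nd_filtered(x), ")\n",
      sep = "")
  NextMethod()
}

# One token vector per record: tokenize(title + " " + abstract). The single
# separator space keeps an occurrence in either field matchable without
# creating spurious n-grams (titles end in safe punctuation-stripped tokens).
corpus_token_list <- function(x) {
  txt <- paste(x$title, x$abstract)
  stats::setNames(lapply(txt, tokenize), x$pmid)
}

# Reorder a pmid-named precomputed token list to a corpus slice; one
# vectorized match() instead of per-record name lookups.
.align_tokens <- function(.tokens, x) {
  if (is.null(.tokens)) return(NULL)
  idx <- match(x$pmid, names(.tokens))
  if (anyNA(idx)) {
    stop(".tokens must cover every pmid in the corpus", call. = FALSE)
  }
  .tokens[idx]
}

#' Build a gene-specific publication profile from a corpus
#'
#' Keeps exactly the records whose concatenated title and abstract token
#' stream contains the gene's symbol or a retained alias as a contiguous
#' n-gram (exact token match on normalized tokens). The result carries
#' `nd_filtered = FALSE`; apply [filter_nd()] next.
#'
#' @param x A corpus tibble.
#' @param gene A one-row gene-registry slice or `list(symbol =, aliases =)`.
#'   Aliases are matched as given: apply the ambiguity stoplist at registry
#'   load time (see [load_gene_registry()]).
#' @param .tokens Optional precomputed token list named by pmid (one
#'   [tokenize()] result of `title + " " + abstract` per record), to avoid
#'   re-tokenizing a corpus shared across genes.
#' @return A `gspp` object (corpus tibble + gene attributes).
#' @export
#' @examples
#' x <- corpus(pmid = c("1", "2"),
#'             title = c("APOE and Alzheimer's disease", "Unrelated work"),
#'             abstract = c("", ""), year = c(2004L, 2005L),
#'             journal = c("", ""))
#' build_gspp(x, list(symbol = "APOE", aliases = character(0)))
build_gspp <- function(x, gene, .tokens = NULL) {
  x <- validate_corpus(x)
  g <- as_gene_entry(gene)
  forms <- gene_surface_forms(g)
  stopifnot(length(forms) >= 1L)
  toks <- .align_tokens(.tokens, x) %||% corpus_token_list(x)
  keep <- vapply(seq_len(nrow(x)),
                 function(i) match_term(toks[[i]], forms, "exact"),
                 logical(1))
  new_gspp(x[keep, , drop = FALSE], g, nd_filtered = FALSE)
}

#' Apply the neurodegenerative disease-of-focus filter to a profile
#'
#' Keeps the records whose title or abstract matches at least one dementia
#' vocabulary entry (prefix matching by default, so the simplified stem
#' "alzheimer" covers its inflections). Record order is preserved and the
#' profile is flagged `nd_filtered = TRUE`. Applying the filter to an
#' already-filtered profile is a precondition error; idempotence holds at the
#' record-set level (re-evaluating the predicate on the output is a no-op).
#'
#' @param profile A GSPP with `nd_filtered = FALSE`.
#' @param vocab Dementia term vocabulary.
#' @param mode Matching mode, `"prefix"` (default) or `"exact"`.
#' @param .tokens Optional precomputed token list named by pmid.
#' @return The filtered `gspp`.
#' @export
filter_nd <- function(profile, vocab = default_dementia_vocabulary(),
                      mode = c("prefix", "exact"), .tokens = NULL) {
  mode <- match.arg(mode)
  if (is_nd_filtered(profile)) {
    stop("profile is already nd_filtered; the disease filter is applied once",
         call. = FALSE)
  }
  g <- gspp_gene(profile)
  validate_vocabulary(vocab)
  toks <- .align_tokens(.tokens, profile) %||% corpus_token_list(profile)
  keep <- vapply(seq_len(nrow(profile)),
                 function(i) match_term(toks[[i]], vocab$variant, mode),
                 logical(1))
  new_gspp(profile[keep, , drop = FALSE], g, nd_filtered = TRUE)
}
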