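# Tokenization, normalization, multiword term matching and POS gating.
# These primitives back every filter and extractor in the package, so their
# behaviour is deliberately simple and fully specified:
#   * a token is a maximal run of letters/digits, lowercased; punctuation
#     (including hyphens and dashes) splits tokens
#   * term matching is contiguous n-gram matching over normalized tokens
#   * POS gating keeps only tokens whose Penn Treebank tag is in an allowed
#     set before gene-symbol matching

#' Split free text into sentences
#'
#' Lightweight rule-based sentence segmentation: splits after `.`, `!` or `?`
#' followed by whitespace. Abbreviation handling is intentionally minimal;
#' downstream matching operates on the concatenated token stream, so sentence
#' boundaries only matter for part-of-speech tagging context.
#'
#' @param text Character scalar (may be empty or `NA`).
#' @return Character vector of sentences (zero-length for empty input).
#' @export
#' @examples
#' split_sentences("APOE is a risk factor. TREM2 modulates microglia.")
split_sentences <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(text)) return(character(0))
  out <- stringr::str_split_1(text, "(?<=[.!?])\\s+")
  out[nzchar(stringr::str_trim(out))]
}

#' Tokenize free text into normalized word tokens
#'
#' Sentences are segmented, word tokens extracted, punctuation removed and the
#' survivors lowercased. A token is a maximal run of letters or digits, so
#' hyphens and dashes split ("blood-brain" becomes `c("blood", "brain")`)
#' while alphanumeric compounds stay intact ("apoe4" is one token). Greek
#' letters and digits are retained inside tokens. The function is total:
#' empty or `NA` input yields `character(0)`.
#'
#' @param text Character scalar.
#' @return Character vector of normalized tokens.
#' @export
#' @examples
#' tokenize("Alzheimer's disease (AD).")
#' tokenize("blood-brain barrier")
tokenize <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(text)) return(character(0))
  toks <- stringr::str_extract_all(stringr::str_to_lower(text), "[\\p{L}\\p{N}]+")[[1]]
  toks[nzchar(toks)]
}

#' Test whether any term variant occurs in a token sequence
#'
#' A variant is an ordered vector of normalized tokens; it matches when it
#' occurs as a contiguous n-gram in `tokens`. In `"prefix"` mode each variant
#' token matches any token that begins with it, which is how simplified
#' disease stems work ("alzheimer" matches "alzheimers"). Exact mode is
#' strictly stronger than prefix mode.
#'
#' @param tokens Character vector of normalized tokens (e.g. from
#'   [tokenize()]).
#' @param variants List of character vectors, each a variant token sequence.
#' @param mode `"exact"` or `"prefix"`.
#' @return Logical scalar.
#' @export
#' @examples
#' match_term(tokenize("severe basal ganglia lesions"),
#'            list(c("basal", "ganglia")), mode = "exact")
#' match_term(tokenize("Alzheimer's disease"), list("alzheimer"), mode = "prefix")
match_term <- function(tokens, variants, mode = c("exact", "prefix")) {
  mode <- match.arg(mode)
  stopifnot(length(variants) >= 1L)
  n <- length(tokens)
  if (n == 0L) return(FALSE)
  for (v in variants) {
    k <- length(v)
    if (k == 0L || k > n) next
    starts <- if (mode == "exact") which(tokens == v[[1L]]) else which(startsWith(tokens, v[[1L]]))
    starts <- starts[starts <= n - k + 1L]
    if (k == 1L) {
      if (length(starts) > 0L) return(TRUE)
      next
    }
    for (i in starts) {
      win <- tokens[i:(i + k - 1L)]
      hit <- if (mode == "exact") all(win == v) else all(startsWith(win, v))
      if (hit) return(TRUE)
    }
  }
  FALSE
}

# --- Part-of-speech tagging -------------------------------------------------
# A lexicon-plus-rules tagger over the Penn Treebank tag set. Closed-class
# words and common (scientific) verbs come from small lexicons; everything
# else is tagged by suffix and capitalization rules with NN as the default.
# The tagger exists to gate gene-mention candidates to nominal/adjectival
# contexts, so its design goal is high recall on noun-like tokens (gene
# symbols tag NNP via the digit/upper-case rules), not treebank accuracy.

.closed_class <- local({
  lex <- c(
    the = "DT", a = "DT", an = "DT", this = "DT", that = "DT", these = "DT",
    those = "DT", each = "DT", every = "DT", some = "DT", any = "DT",
    no = "DT", all = "DT", both = "DT", another = "DT",
    of = "IN", `in` = "IN", on = "IN", at = "IN", by = "IN", `for` = "IN",
    with = "IN", from = "IN", into = "IN", through = "IN", during = "IN",
    between = "IN", among = "IN", within = "IN", across = "IN",
    after = "IN", before = "IN", under = "IN", over = "IN", against = "IN",
    about = "IN", via = "IN", per = "IN", than = "IN", as = "IN",
    without = "IN", upon = "IN", toward = "IN", towards = "IN",
    to = "TO",
    and = "CC", or = "CC", but = "CC", nor = "CC", yet = "CC", plus = "CC",
    `if` = "IN", `while` = "IN", although = "IN", because = "IN",
    when = "WRB", where = "WRB", how = "WRB", why = "WRB", whereas = "IN",
    which = "WDT", who = "WP", whose = "WP$", what = "WP",
    it = "PRP", its = "PRP$", we = "PRP", our = "PRP$", they = "PRP",
    their = "PRP$", he = "PRP", she = "PRP", his = "PRP$", her = "PRP$",
    them = "PRP", us = "PRP", i = "PRP", you = "PRP", your = "PRP$",
    can = "MD", could = "MD", may = "MD", might = "MD", must = "MD",
    shall = "MD", should = "MD", will = "MD", would = "MD",
    there = "EX", not = "RB", also = "RB", however = "RB", thus = "RB",
    therefore = "RB", moreover = "RB", furthermore = "RB", often = "RB",
    always = "RB", never = "RB", here = "RB", then = "RB", well = "RB",
    more = "RBR", most = "RBS", less = "RBR", least = "RBS", very = "RB",
    be = "VB", been = "VBN", being = "VBG", am = "VBP", is = "VBZ",
    are = "VBP", was = "VBD", were = "VBD"
  )
  lex
})

.verb_bases <- c(
  "have", "do", "show", "suggest", "indicate", "demonstrate", "reveal",
  "report", "find", "identify", "investigate", "examine", "analyze",
  "assess", "evaluate", "observe", "associate", "correlate", "regulate",
  "modulate", "mediate", "induce", "inhibit", "promote", "impair",
  "contribute", "remain", "involve", "include", "perform", "conduct",
  "compare", "confirm", "require", "affect", "alter", "cause", "occur",
  "develop", "exhibit", "display", "highlight", "underlie", "attenuate",
  "exacerbate", "enhance", "disrupt"
)

.verb_forms <- local({
  out <- character(0)
  add <- function(w, tag) out[w] <<- tag
  for (b in .verb_bases) {
    add(b, "VB")
    last <- substring(b, nchar(b))
    add(if (last == "e") paste0(b, "s") else if (last %in% c("s", "x", "h"))
      paste0(b, "es") else paste0(b, "s"), "VBZ")
    add(if (last == "e") paste0(b, "d") else paste0(b, "ed"), "VBD")
    add(if (last == "e") paste0(substring(b, 1, nchar(b) - 1), "ing") else
      paste0(b, "ing"), "VBG")
  }
  add("has", "VBZ"); add("had", "VBD"); add("having", "VBG")
  add("does", "VBZ"); add("did", "VBD"); add("done", "VBN")
  add("found", "VBD"); add("shown", "VBN"); add("given", "VBN")
  out
})

.lexicon <- c(.closed_class, .verb_forms[setdiff(names(.verb_forms),
                                                 names(.closed_class))])

# Vectorized rule cascade over one token vector; lexicon first, then suffix
# and capitalization rules, NN as the default.
.tag_words <- function(surf) {
  low <- stringr::str_to_lower(surf)
  tag <- unname(.lexicon[low])
  open <- is.na(tag)
  nc <- nchar(low)
  apply_rule <- function(cond, t) {
    sel <- open & cond
    tag[sel] <<- t
    open[sel] <<- FALSE
  }
  apply_rule(endsWith(low, "ly") & nc > 3L, "RB")
  apply_rule(grepl("[0-9]", surf), "NNP")
  apply_rule(grepl("^[A-Z]{2,}", surf), "NNP")
  apply_rule(endsWith(low, "ing") & nc > 4L, "VBG")
  apply_rule(endsWith(low, "ed") & nc > 3L, "VBN")
  apply_rule(grepl("^[A-Z]", surf), "NNP")
  apply_rule(grepl("(al|ic|ous|ive|able|ible|ary|ory)$", low) & nc > 4L, "JJ")
  apply_rule(endsWith(low, "s") & !grepl("(ss|us|is)$", low) & nc > 3L, "NNS")
  tag[open] <- "NN"
  tag
}

#' Part-of-speech tag a text
#'
#' Tags the un-normalized word-token stream (surface forms, case preserved)
#' with Penn Treebank tags using closed-class and verb lexicons plus suffix
#' and capitalization rules. Unknown tokens default to `NN`; tokens with
#' digits or in upper case tag `NNP`, which is the behaviour gene symbols
#' rely on.
#'
#' @param text Character scalar.
#' @return A tibble with columns `token` (surface form) and `tag`.
#' @export
#' @examples
#' pos_tag("TREM2 modulates microglia in the hippocampus.")
pos_tag <- function(text) {
  sents <- split_sentences(text)
  if (length(sents) == 0L) {
    return(tibble::tibble(token = character(0), tag = character(0)))
  }
  surf <- unlist(stringr::str_extract_all(
    sents, "[\\p{L}\\p{N}][\\p{L}\\p{N}'’/\\-]*"
  ), use.names = FALSE)
  if (length(surf) == 0L) {
    return(tibble::tibble(token = character(0), tag = character(0)))
  }
  tibble::tibble(token = surf, tag = .tag_words(surf))
}

#' Default POS tags admitted by the gene-mention gate
#'
#' Nominal tags plus adjectives: `NN`, `NNS`, `NNP`, `NNPS`, `JJ`. Gene
#' symbols tag as proper or common nouns, occasionally as adjectives inside
#' noun compounds, so this closed set keeps gene-symbol candidates while
#' discarding verbs, function words and adverbs.
#'
#' @return Character vector of Penn Treebank tags.
#' @export
default_pos_tags <- function() c("NN", "NNS", "NNP", "NNPS", "JJ")

#' POS-gate a text down to normalized nominal/adjectival tokens
#'
#' Tags the raw token stream, keeps tokens whose tag is in `allowed_tags`,
#' then normalizes the survivors exactly as [tokenize()] does. The result is
#' always a sub-multiset of `tokenize(text)`.
#'
#' @param text Character scalar.
#' @param allowed_tags Non-empty character vector of Penn Treebank tags.
#' @return Character vector of normalized tokens.
#' @export
#' @examples
#' pos_gate("TREM2 modulates microglia.")
pos_gate <- function(text, allowed_tags = default_pos_tags()) {
  stopifnot(length(allowed_tags) >= 1L)
  tagged <- pos_tag(text)
  keep <- tagged$token[tagged$tag %in% allowed_tags]
  if (length(keep) == 0L) return(character(0))
  out <- unlist(stringr::str_extract_all(stringr::str_to_lower(keep),
                                         "[\\p{L}\\p{N}]+"),
                use.names = FALSE)
  out[nzchar(out)]
}
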