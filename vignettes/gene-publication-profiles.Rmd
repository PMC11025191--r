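---
title: "Mining gene-specific neurodegeneration publication profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining gene-specific neurodegeneration publication profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pubprofiles)
```

## The procedure

`pubprofiles` implements a dictionary-based text-mining pipeline over
publication records (PMID, title, abstract, year, journal):

1. **Profile construction.** For each gene in a registry, the
   gene-specific publication profile (GSPP) keeps exactly the records whose
   title-plus-abstract token stream contains the official symbol or a
   retained alias as a contiguous token n-gram. Title and abstract are
   concatenated with a single separator because a mention in either field
   counts; matching is never per-sentence.
2. **Disease-of-focus filtering.** A profile record survives if it matches
   at least one of seven dementia types, each represented by a simplified
   stem matched in prefix mode (`"alzheimer"` fires on "Alzheimer's",
   "alzheimers", ...). Profiles that empty out here are retained; pruning
   happens only after extraction.
3. **Extraction.** Six category profiles per gene: yearly trend, dementia
   types, brain regions, mouse-model strains, expert keywords, and
   co-occurring genes. Every category reports, per sub-category, a
   publication count and the sorted PMID list; a record counts at most once
   per sub-category and may appear under several.
4. **Pruning and summary.** Gene summaries with no hits in any of the three
   content categories (brain region, mouse model, keyword) are removed;
   the corpus summary reports sub-category and publication totals per
   category.
5. **Evaluation.** The pipeline's (gene, dementia-type) PMID set can be
   compared with any reference annotation file by exact set intersection.

The pipeline proper is deterministic; all randomness is confined to the
synthetic-corpus generator and controlled by explicit seeds.

## The token model

All filters and extractors share one normalization: text is segmented into
sentences, word-tokenized, punctuation removed, and lowercased. A token is a
maximal run of letters or digits, so hyphens and slashes split
("blood-brain" → `blood`, `brain`; "APP/PS1" → `app`, `ps1`) while
alphanumeric compounds survive intact (`apoe4`, `5xfad`). Greek letters are
retained. Since matching operates on the concatenated token stream, sentence
boundaries only influence part-of-speech tagging.

Term matching is contiguous n-gram matching over these tokens, in two
modes:

* **exact** — every variant token equals the corresponding text token; used
  for gene symbols/aliases, brain regions, strains and keywords.
* **prefix** — each variant token matches any text token that begins with
  it; used for dementia stems. Exact matching is strictly stronger, which
  the test suite asserts as a property.

Whether disease matching should be exact or stem-prefix is genuinely open;
prefix mode is the more faithful reading of "simplified names" and is the
default, with exact mode available through the `mode` argument.

## POS gating for co-occurring genes

Gene symbols are short and collide with ordinary words, so co-occurrence
extraction first tags the raw token stream and keeps only tokens tagged
`NN`, `NNS`, `NNP`, `NNPS` or `JJ` before symbol matching. The tag set is
deliberately closed to nominals plus adjectives (gene symbols tag as proper
or common nouns, occasionally as adjectives in noun compounds) and is
configurable via `allowed_tags`.

The tagger is a lexicon-plus-rules tagger over the Penn Treebank tag set: a
closed-class lexicon (determiners, prepositions, pronouns, modals,
be/have/do forms), a small lexicon of common scientific verbs with generated
inflections, then suffix and capitalization rules with `NN` as the default.
Tokens containing digits or starting with two capitals tag `NNP`, which is
the rule gene symbols rely on. The design goal is high recall on noun-like
tokens rather than treebank accuracy: over-keeping a noun costs nothing
(filler nouns are not gene symbols), while over-removing a gene mention
would lose a co-occurrence.

One inherent caveat of gating: removing tokens can make previously
non-adjacent tokens adjacent, so a multi-token alias could in principle
match across a gated-out gap. Single-token symbols are unaffected; multi-
token aliases are rare and the ambiguity stoplist already removes the
riskiest surface forms.

## Vocabularies as configuration

The dementia (7 types) and brain-region (13 regions) vocabularies are fixed
domain knowledge and constructed in code. The keyword vocabulary (32
entries) and the mouse-model strain list (11 strains) are **configuration**:
the package ships synthetic snapshots
(`inst/extdata/keywords.synthetic.yaml`,
`inst/extdata/mouse_models.synthetic.yaml`) that users replace with their
own curated lists through `load_term_vocabulary()`. Every variant is
normalized with the package tokenizer at load time, so vocabulary files and
matching can never disagree about tokenization — a self-consistency the
tests assert for all shipped vocabularies.

Gene aliases equal to common English words, or of two characters or fewer
(e.g. the alias "AD"), are excluded from matching by default: under
lowercased token matching they would over-match catastrophically. The
stoplist applies to aliases only — the official symbol is always retained as
the gene's primary key — and can be disabled (`apply_stoplist = FALSE`) or
replaced.

## Numerical and representational choices

* **Missing years.** A record with no recoverable publication year keeps
  the sentinel `year = 0`: it stays in every category except the yearly
  trend. Losing a record from all categories over a missing date would be
  worse than excluding it from one.
* **PMID ordering.** PMID lists are stored sorted ascending numerically;
  sub-categories sort alphabetically (years as 4-digit strings). This makes
  every serialization canonical: GSPP CSV and gene-summary JSON round-trip
  write → read → write byte-identically, which the acceptance tests check.
* **Corpus totals.** "Total publications per category" is ambiguous when a
  publication is attributed to several genes: `summarize_corpus()` reports
  both readings, `n_publications` (distinct PMIDs across genes) and
  `n_attributions` (raw sum of counts).
* **Dementia extraction aggregates all years**; a per-year breakdown can be
  derived from the year-trend PMIDs when needed.
* **Degenerate inputs.** Empty corpora, empty profiles and header-only
  tables flow through every stage as empty tibbles; zero-hit sub-categories
  are absent rather than zero-count rows.

## The synthetic-corpus generator

`generate_corpus()` turns a planting plan — per concept, the exact set of
record indices that must mention it — into records whose titles and
abstracts are neutral filler sentences plus one grammatical carrier sentence
per planted concept ("We examined {surface} in a longitudinal cohort."), so
the POS gate sees gene symbols in nominal contexts. Three screens make the
plan an *exact* truth oracle rather than an approximate one:

* filler and carrier words are validated against every active vocabulary
  token (prefix-aware for dementia stems) and every gene surface form;
* planted surfaces are checked for cross-concept containment (a surface may
  not embed another concept's variant n-gram);
* a collision is an error, never a silent approximation.

`truth_gene_summary()` then derives expected category profiles purely by
index-set arithmetic on the plan — no text matching — and
`run_end_to_end()` compares pipeline output against that truth exactly.
`random_corpus_spec()` draws randomized plans at rates meant to emulate an
ND-focused abstract collection: 85% of records carry a dementia mention,
about a third a brain region, 15% a strain, and a third of records
co-mention a second gene. These rates are fixed study conditions for the
test suite, not tuning knobs.

What the generator does **not** emulate: real abstract language (filler is
not English prose), ambiguous or polysemous gene mentions, full-name-only
mentions ("apolipoprotein E" without the symbol), typographical variation
beyond tokenization, or PubMed's growth dynamics. Passing the planted-count
tests therefore demonstrates that the *mechanics* of filtering and
extraction are exact, not that dictionary matching resolves the linguistic
ambiguity of real abstracts — on real text, precision and recall are bounded
by the dictionaries themselves.

## Problem sizes used by the tests

The acceptance suite runs 50 randomized corpora of 50–1,000 records each
for planted-count recovery, 200-record corpora for the brute-force filter
oracle and symmetry checks, and 1,000 random set pairs for overlap
arithmetic; `scripts/acceptance.R` uses 25 corpora of 50–600 records. These
sizes exercise every code path (multi-gene records, empty profiles, alias
surfaces, all four vocabularies) while keeping a full run to a few minutes
on one CPU.

## Known limitations

* Dictionary matching cannot disambiguate gene symbols from identical
  acronyms beyond the stoplist; no supervised NER is attempted.
* Matching is title/abstract only, by design; full-text mentions are
  invisible, which depresses overlap against full-text-based reference
  annotation sources.
* The rule tagger is approximate outside nominal contexts; the gate's tag
  set errs toward recall.
* No ontology expansion: a concept absent from the vocabulary is absent
  from the results.
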