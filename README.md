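# pubprofiles

Gene-centric literature mining for neurodegenerative disease (ND)
publications.

Researchers in the Alzheimer's disease (AD) field face an ever-growing body
of publications. `pubprofiles` builds, for each gene of interest, a
**gene-specific publication profile (GSPP)** — the set of publications whose
title or abstract mentions the gene's official symbol or an alias — then
filters each profile to the dementias of focus and extracts six categories
of per-gene information:

1. **Yearly publication trend** — PMIDs and counts stratified by year.
2. **Dementia types** — occurrences of the seven major dementia types
   (Alzheimer's, Parkinson's, Huntington's, frontotemporal, Lewy body,
   vascular, mixed), matched through simplified-stem variants
   ("alzheimer" covers "Alzheimer's", "alzheimers", ...).
3. **Brain regions** — the thirteen regions commonly studied in ND, from
   Amygdala to Thalamus, matched as token n-grams.
4. **Mouse models** — named AD mouse-model strains (5xFAD, 3xTg-AD, ...).
5. **Expert keywords** — a 32-entry configurable keyword vocabulary of AD
   disease processes (tau deposition, lipid metabolism, oxidative stress,
   ...).
6. **Co-occurring genes** — other registry genes mentioned in the same
   publications, with candidate tokens gated to nominal/adjectival
   part-of-speech tags (`NN`, `NNS`, `NNP`, `NNPS`, `JJ`) before symbol
   matching.

All matching operates on a shared token model: title and abstract are
segmented, tokenized, punctuation-stripped and lowercased; a vocabulary
variant matches when its token sequence occurs as a contiguous n-gram
(optionally by token prefix, for disease stems). Profiles that end up empty
in all three content categories (brain region, mouse model, keyword) are
pruned, and corpus-level tables report sub-category and publication totals
per category. An evaluation module compares the pipeline's
(gene, dementia-type) PMID sets against reference annotation files by exact
set intersection. A deterministic synthetic-corpus generator plants known
gene/disease/region/strain/keyword mentions so that every stage can be
verified against an exact truth oracle.

## Worked example

```r
library(pubprofiles)

x <- corpus(
  pmid = c("101", "102", "103"),
  title = c("APOE and Alzheimer's disease progression",
            "TREM2 modulates APOE signaling in Alzheimer's disease",
            "Cerebellar circuits in healthy aging"),
  abstract = c("We measured hippocampus volume and oxidative stress.",
               "Microglia were imaged in 5xFAD mice.",
               "No disease terms appear here."),
  year = c(2004L, 2010L, 2010L), journal = rep("J Example", 3))

registry <- default_demo_registry()
profile <- build_gspp(x, registry[registry$symbol == "APOE", ]) |> filter_nd()
profile$pmid
#> [1] "101" "102"

s <- extract_gene_summary(profile, registry)
tidy(s)
#> # A tibble: 8 × 5
#>   gene  category         subcategory         count pmids
#>   <chr> <chr>            <chr>               <int> <list>
#> 1 APOE  year_trend       2004                    1 <chr [1]>
#> 2 APOE  year_trend       2010                    1 <chr [1]>
#> 3 APOE  dementia_type    Alzheimer's Disease     2 <chr [2]>
#> 4 APOE  brain_region     Hippocampus             1 <chr [1]>
#> 5 APOE  mouse_model      5xFAD                   1 <chr [1]>
#> 6 APOE  keyword          microglia               1 <chr [1]>
#> 7 APOE  keyword          oxidative stress        1 <chr [1]>
#> 8 APOE  cooccurring_gene TREM2                   1 <chr [1]>
```

Record 103 is dropped by the gene filter (no APOE token) and would in any
case fail the disease-of-focus filter. Both ND records mention Alzheimer's
disease, so the `dementia_type` entry lists two PMIDs; record 101
contributes the Hippocampus and oxidative-stress hits, record 102 the 5xFAD
strain, the microglia keyword and the TREM2 co-occurrence (TREM2 survives
the POS gate because gene symbols tag as proper nouns).

Corpus-level reporting across many genes:

```r
summarize_corpus(list(s))
#> # A tibble: 6 × 4
#>   category         n_subcategories n_publications n_attributions
#>   <chr>                      <int>          <int>          <int>
#> 1 year_trend                     2              2              2
#> 2 dementia_type                  1              2              2
#> ...
```

`n_publications` counts distinct PMIDs per category across genes;
`n_attributions` is the raw sum of per-gene sub-category counts (a
publication attributed to several genes or sub-categories counts each
time). `plot_year_trend()`, `plot_category_counts()` and `autoplot()` give
portal-style ggplot views; `write_gene_summary_json()` /
`write_gspp_csv()` serialize results deterministically.

A command-line workflow (`simulate`, `build-profiles`, `filter`, `extract`,
`summarize`, `compare`) is available through `run_command()` and the
launcher script in `inst/cli/pubprofiles.R`.

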