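Package: pubprofiles
Title: Gene-Centric Literature Mining for Neurodegenerative Disease Publications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds gene-specific publication profiles (GSPPs) from
    PubMed-style records, filters them to neurodegenerative-disease
    publications with token-level dictionary rules, and extracts six
    categories of information per gene: yearly publication trend, dementia
    types, brain regions, mouse-model strains, expert keywords, and
    part-of-speech-gated co-occurring genes. Includes controlled-vocabulary
    management, profile pruning and corpus summaries, annotation-overlap
    evaluation against reference annotation sets, and a deterministic
    synthetic-corpus generator with exact planted-mention truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
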