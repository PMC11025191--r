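# Fixture builders shared across test files. All fixtures are generated in
# code; nothing is read from disk except what the tests themselves write.

# A tiny handmade corpus with known gene/disease/region content.
make_demo_corpus <- function() {
  corpus(
    pmid = c("101", "102", "103", "104", "105"),
    title = c(
      "APOE and Alzheimer's disease progression",
      "TREM2 modulates APOE signaling in Alzheimer's disease",
      "Cerebellar circuits in healthy aging",
      "APOE in Parkinson's disease and the hippocampus",
      "Apolipoprotein biology of lipoproteins"
    ),
    abstract = c(
      "We studied hippocampus volume and oxidative stress in carriers.",
      "Microglia respond to amyloid beta. The thalamus was unaffected.",
      "No disease terms appear in this record about motor learning.",
      "Vascular dementia was excluded. Mitochondria were profiled.",
      "This record mentions apolipoprotein E only as a full name phrase."
    ),
    year = c(2004L, 2010L, 2010L, 2004L, 1999L),
    journal = rep("J Test", 5)
  )
}

demo_gene_apoe <- function() list(symbol = "APOE", aliases = character(0))

write_pubmed_fixture <- function(path) {
  xml <- '<?xml version="1.0" encoding="UTF-8"?>
<PubmedArticleSet>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>11111</PMID>
      <Article>
        <Journal>
          <JournalIssue><PubDate><Year>2004</Year></PubDate></JournalIssue>
          <Title>J Alpha</Title>
        </Journal>
        <ArticleTitle>APOE genotype and dementia risk</ArticleTitle>
        <Abstract>
          <AbstractText Label="BACKGROUND">First block.</AbstractText>
          <AbstractText Label="METHODS">Second block.</AbstractText>
        </Abstract>
      </Article>
    </MedlineCitation>
  </PubmedArticle>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>22222</PMID>
      <Article>
        <Journal>
          <JournalIssue><PubDate><MedlineDate>2004 Jan-Feb</MedlineDate></PubDate></JournalIssue>
          <Title>J Beta</Title>
        </Journal>
        <ArticleTitle>A title without an abstract</ArticleTitle>
      </Article>
    </MedlineCitation>
  </PubmedArticle>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>33333</PMID>
      <Article>
        <Journal>
          <JournalIssue><PubDate><Year>2019</Year></PubDate></JournalIssue>
          <Title>J Gamma</Title>
        </Journal>
        <ArticleTitle>Third article</ArticleTitle>
        <Abstract><AbstractText>Single block.</AbstractText></Abstract>
      </Article>
    </MedlineCitation>
  </PubmedArticle>
</PubmedArticleSet>'
  writeLines(xml, path)
  path
}

write_registry_fixture <- function(path) {
  writeLines(c(
    "#tax_id\tGeneID\tSymbol\tSynonyms",
    "9606\t348\tAPOE\tAD2|LPG|APO-E",
    "9606\t54209\tTREM2\t-",
    "9606\t4137\tMAPT\tTAU|MTBT1"
  ), path)
  path
}

# Filter an nd-unfiltered profile's record set by brute force: paste the
# normalized tokens into a single space-joined string and test term presence
# with anchored regular expressions (an independent mechanism from the
# package's n-gram window scan).
naive_has_term <- function(text, variant_tokens, prefix = FALSE) {
  hay <- paste(tokenize(text), collapse = " ")
  pat <- if (prefix) {
    paste0("(^| )", paste(paste0(variant_tokens, "[^ ]*"), collapse = " "),
           "( |$)")
  } else {
    paste0("(^| )", paste(variant_tokens, collapse = " "), "( |$)")
  }
  grepl(pat, hay)
}

naive_gene_filter <- function(x, forms) {
  vapply(seq_len(nrow(x)), function(i) {
    any(vapply(forms, function(f)
      naive_has_term(paste(x$title[i], x$abstract[i]), f), logical(1)))
  }, logical(1))
}

naive_nd_filter <- function(x, vocab) {
  vapply(seq_len(nrow(x)), function(i) {
    any(vapply(vocab$variant, function(v)
      naive_has_term(paste(x$title[i], x$abstract[i]), v, prefix = TRUE),
      logical(1)))
  }, logical(1))
}
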