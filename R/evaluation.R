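# Annotation-overlap evaluation: compare the pipeline's (gene, dementia-type)
# publication annotations against a reference annotation source by exact
# PMID set intersection.

#' Construct an annotation set
#'
#' A labelled set of PMIDs annotated with a fixed concept pair. Duplicates
#' collapse (set semantics) and PMIDs are stored sorted.
#'
#' @param label Source name (e.g. `"pipeline"`, `"reference"`).
#' @param pmids Character vector of PMIDs.
#' @return An `annotation_set` object.
#' @export
annotation_set <- function(label, pmids) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  structure(list(label = label, pmids = sort_pmids(as.character(pmids))),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("Annotation set '", x$label, "': ", length(x$pmids), " PMIDs\n",
      sep = "")
  invisible(x)
}

#' Load reference annotations carrying two concepts
#'
#' Reads a three-column TSV (`pmid`, `concept_type`, `concept_label`) and
#' returns the PMIDs annotated with *both* requested concept labels.
#' Duplicate rows collapse under set semantics.
#'
#' @param path Path to the TSV file.
#' @param concept_a,concept_b Concept labels that must both be present for a
#'   PMID to qualify (matched against `concept_label`).
#' @param label Label for the resulting set (defaults to the file name).
#' @return An `annotation_set`.
#' @export
load_reference_annotations <- function(path, concept_a, concept_b,
                                       label = basename(path)) {
  stopifnot(file.exists(path))
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  required <- c("pmid", "concept_type", "concept_label")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0L) {
    stop("reference annotation schema error: missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  with_a <- unique(tbl$pmid[tbl$concept_label == concept_a])
  with_b <- unique(tbl$pmid[tbl$concept_label == concept_b])
  annotation_set(label, intersect(with_a, with_b))
}

#' Extract the pipeline's annotation set for a (gene, dementia type) pair
#'
#' Looks up the gene's `dementia_type` category profile in a list of gene
#' summaries and returns the PMIDs recorded under the requested dementia
#' type. An unknown gene is an error; an unmatched dementia type yields an
#' empty set (a valid outcome).
#'
#' @param summaries List of `gene_summary` objects.
#' @param gene Official gene symbol.
#' @param dementia_type Canonical dementia-type name (e.g.
#'   `"Alzheimer's Disease"`).
#' @return An `annotation_set` labelled `"pipeline"`.
#' @export
pipeline_annotation_set <- function(summaries, gene, dementia_type) {
  symbols <- vapply(summaries, function(s) s$gene, character(1))
  idx <- match(gene, symbols)
  if (is.na(idx)) {
    stop("unknown gene '", gene, "' in summaries", call. = FALSE)
  }
  prof <- summaries[[idx]]$categories$dementia_type
  row <- which(prof$subcategory == dementia_type)
  pmids <- if (length(row) == 0L) character(0) else prof$pmids[[row[[1]]]]
  annotation_set("pipeline", pmids)
}

#' Compare two annotation sets by exact intersection
#'
#' Computes set sizes, the overlap count, and the overlap fraction relative
#' to each side. The PMIDs present only in the reference are kept on the
#' report for manual audit. The report is invariant to input ordering and
#' duplication, and swapping the arguments transposes the `ours`/`reference`
#' roles while preserving the overlap.
#'
#' @param ours,reference `annotation_set` objects (or character vectors of
#'   PMIDs).
#' @return An `overlap_report`: list with `n_ours`, `n_reference`,
#'   `n_overlap`, `overlap_fraction_of_ours`,
#'   `overlap_fraction_of_reference`, `reference_only_pmids`.
#' @export
#' @examples
#' compare_annotation_sets(annotation_set("pipeline", c("1", "2", "3")),
#'                         annotation_set("reference", c("2", "3", "4")))
compare_annotation_sets <- function(ours, reference) {
  if (!inherits(ours, "annotation_set")) ours <- annotation_set("ours", ours)
  if (!inherits(reference, "annotation_set")) {
    reference <- annotation_set("reference", reference)
  }
  both <- intersect(ours$pmids, reference$pmids)
  n_ours <- length(ours$pmids)
  n_reference <- length(reference$pmids)
  n_overlap <- length(both)
  structure(list(
    n_ours = n_ours,
    n_reference = n_reference,
    n_overlap = n_overlap,
    overlap_fraction_of_ours = if (n_ours > 0L) n_overlap / n_ours else 0,
    overlap_fraction_of_reference =
      if (n_reference > 0L) n_overlap / n_reference else 0,
    reference_only_pmids = sort_pmids(setdiff(reference$pmids, ours$pmids))
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Annotation overlap: ours=", x$n_ours, " reference=", x$n_reference,
      " overlap=", x$n_overlap,
      " (", sprintf("%.4f", x$overlap_fraction_of_ours), " of ours, ",
      sprintf("%.4f", x$overlap_fraction_of_reference), " of reference)\n",
      sep = "")
  invisible(x)
}

#' Write an overlap report as JSON
#'
#' Counts are written raw; fractions are reported to four decimal places.
#'
#' @param report An `overlap_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_overlap_json <- function(report, path) {
  stopifnot(inherits(report, "overlap_report"))
  obj <- list(
    n_ours = jsonlite::unbox(report$n_ours),
    n_reference = jsonlite::unbox(report$n_reference),
    n_overlap = jsonlite::unbox(report$n_overlap),
    overlap_fraction_of_ours =
      jsonlite::unbox(round(report$overlap_fraction_of_ours, 4)),
    overlap_fraction_of_reference =
      jsonlite::unbox(round(report$overlap_fraction_of_reference, 4)),
    reference_only_pmids = as.character(report$reference_only_pmids)
  )
  writeLines(jsonlite::toJSON(obj, pretty = 2, digits = NA), path,
             useBytes = TRUE)
  invisible(path)
}
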