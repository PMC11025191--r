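# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a gene summary into one long tibble
#'
#' @param x A `gene_summary`.
#' @param ... Unused.
#' @return Tibble with columns `gene`, `category`, `subcategory`, `count`,
#'   `pmids` (list-column), one row per observed sub-category.
#' @export
tidy.gene_summary <- function(x, ...) {
  dplyr::bind_rows(x$categories) |>
    dplyr::mutate(gene = x$gene, .before = 1L)
}

#' One-row overview of a gene summary
#'
#' @param x A `gene_summary`.
#' @param ... Unused.
#' @return One-row tibble: `gene`, `n_records`, and the number of observed
#'   sub-categories in each of the six categories.
#' @export
glance.gene_summary <- function(x, ...) {
  counts <- lapply(x$categories, nrow)
  tibble::tibble(gene = x$gene, n_records = x$n_records,
                 !!!stats::setNames(counts, paste0("n_", names(counts))))
}

#' Tidy an overlap report
#'
#' @param x An `overlap_report`.
#' @param ... Unused.
#' @return Tibble with one row per quantity (`metric`, `value`).
#' @export
tidy.overlap_report <- function(x, ...) {
  tibble::tibble(
    metric = c("n_ours", "n_reference", "n_overlap",
               "overlap_fraction_of_ours", "overlap_fraction_of_reference"),
    value = c(x$n_ours, x$n_reference, x$n_overlap,
              x$overlap_fraction_of_ours, x$overlap_fraction_of_reference)
  )
}

#' One-row overview of an overlap report
#'
#' @param x An `overlap_report`.
#' @param ... Unused.
#' @return One-row tibble of the report counts and fractions.
#' @export
glance.overlap_report <- function(x, ...) {
  tibble::tibble(
    n_ours = x$n_ours, n_reference = x$n_reference, n_overlap = x$n_overlap,
    overlap_fraction_of_ours = x$overlap_fraction_of_ours,
    overlap_fraction_of_reference = x$overlap_fraction_of_reference
  )
}
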