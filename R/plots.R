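# ggplot2 views of gene summaries, mirroring the portal-style displays:
# a yearly trend bar chart and horizontal count bars per category.

#' Plot the yearly publication trend of a gene summary
#'
#' @param summary A `gene_summary` object.
#' @return A ggplot object (column chart of publications per year).
#' @export
plot_year_trend <- function(summary) {
  stopifnot(inherits(summary, "gene_summary"))
  prof <- summary$categories$year_trend
  dat <- tibble::tibble(year = as.integer(prof$subcategory),
                        count = prof$count)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$year, y = .data$count)) +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::labs(
      title = paste0(summary$gene, ": ND publications per year"),
      x = "Publication year", y = "Publications"
    ) +
    ggplot2::theme_minimal()
}

#' Plot sub-category publication counts for one information category
#'
#' Horizontal bars sorted by count, the portal-style view used for dementia
#' types, brain regions, mouse models, keywords and co-occurring genes.
#'
#' @param summary A `gene_summary` object.
#' @param category One of `"dementia_type"`, `"brain_region"`,
#'   `"mouse_model"`, `"keyword"`, `"cooccurring_gene"`.
#' @param top_n Show at most this many sub-categories (by count).
#' @return A ggplot object.
#' @export
plot_category_counts <- function(summary, category = "keyword", top_n = 20L) {
  stopifnot(inherits(summary, "gene_summary"))
  category <- match.arg(category, setdiff(.summary_categories, "year_trend"))
  prof <- summary$categories[[category]]
  dat <- dplyr::slice_max(
    tibble::tibble(subcategory = prof$subcategory, count = prof$count),
    order_by = .data$count, n = top_n, with_ties = FALSE
  )
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$count,
    y = stats::reorder(.data$subcategory, .data$count)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      title = paste0(summary$gene, ": ", gsub("_", " ", category)),
      x = "Publications", y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Autoplot a gene summary
#'
#' @param object A `gene_summary`.
#' @param category Category to display; `"year_trend"` (default) dispatches
#'   to [plot_year_trend()], anything else to [plot_category_counts()].
#' @param ... Passed to [plot_category_counts()].
#' @return A ggplot object.
#' @export
autoplot.gene_summary <- function(object, category = "year_trend", ...) {
  if (identical(category, "year_trend")) {
    plot_year_trend(object)
  } else {
    plot_category_counts(object, category = category, ...)
  }
}
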