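# ggplot2 views of the main result types.

#' Unit-length composition per genomic context
#'
#' Bar chart of the percentage of each unit-length class (mono..hexa) within
#' the exon, intron and intergenic compartments, the usual first figure of a
#' genome SSR survey.
#'
#' @param records classified SSR tibble.
#' @return a ggplot object.
#' @export
plot_unit_length_distribution <- function(records) {
  members <- expand_members(records)
  if (!"context" %in% names(members)) {
    abort("records must carry a context column")
  }
  d <- members |>
    count(context, unit_length) |>
    group_by(context) |>
    mutate(pct = 100 * n / sum(n)) |>
    ungroup() |>
    mutate(unit_class = factor(UNIT_CLASS_NAMES[unit_length],
                               levels = UNIT_CLASS_NAMES))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$unit_class, y = .data$pct,
                                  fill = .data$context)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "repeat unit class", y = "% of SSRs in context",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn bin_by_repeat_count plot a repeat-count bin table as grouped
#'   bars per unit class and compartment.
#' @param object a `repeat_bin_table`.
#' @param ... unused.
#' @export
autoplot.repeat_bin_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin, y = .data$n,
                                       fill = .data$context)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$unit_class), scales = "free_y") +
    ggplot2::labs(x = "number of repeats", y = "SSR count", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' SNP-link counts per compartment
#'
#' Side-by-side counts of flanking regions and linked SNP occurrences in the
#' genic and intergenic compartments.
#'
#' @param links output of [link_snps()] with a `context` column.
#' @return a ggplot object.
#' @export
plot_snp_links <- function(links) {
  if (!"context" %in% names(links)) abort("links must carry a context column")
  comp <- ifelse(links$context == "intergenic", "intergenic", "genic")
  d <- bind_rows(
    tibble(compartment = comp, what = "flanking regions with SNP",
           n = as.integer(links$n_snps > 0)),
    tibble(compartment = comp, what = "linked SNPs", n = links$n_snps)
  ) |>
    group_by(.data$compartment, .data$what) |>
    summarise(n = sum(n), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$compartment, y = .data$n,
                                  fill = .data$what)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "count", fill = NULL) +
    ggplot2::theme_minimal()
}
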