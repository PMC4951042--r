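# broom-style accessors for the summary objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname summarize_mining
#' @param x a `mining_summary`.
#' @param ... unused.
#' @export
tidy.mining_summary <- function(x, ...) {
  tibble(
    item = c("Total number of scaffolds examined",
             "Total size of examined sequences (bp)",
             "Total number of identified SSRs",
             "Number of SSR containing sequences",
             "Number of sequences containing more than one SSR",
             "Number of SSRs present in compound formation",
             "Frequency (SSRs per Mb)"),
    value = c(x$n_sequences_examined, x$total_bp, x$n_ssrs,
              x$n_ssr_containing_sequences,
              x$n_sequences_with_more_than_one_ssr,
              x$n_ssrs_in_compound_formation, x$freq_per_mb)
  )
}

#' @rdname summarize_mining
#' @export
glance.mining_summary <- function(x, ...) {
  as_tibble(x[c("n_sequences_examined", "total_bp", "n_ssrs",
                "n_ssr_containing_sequences",
                "n_sequences_with_more_than_one_ssr",
                "n_ssrs_in_compound_formation", "freq_per_mb")])
}

#' @rdname context_summary
#' @param x a `context_summary`.
#' @param ... unused.
#' @export
tidy.context_summary <- function(x, ...) x$compartments

#' @rdname context_summary
#' @export
glance.context_summary <- function(x, ...) {
  tibble(
    n_exon = x$counts[["exon"]], n_intron = x$counts[["intron"]],
    n_intergenic = x$counts[["intergenic"]],
    genic_bp = x$genic_bp, intergenic_bp = x$intergenic_bp,
    total_bp = x$total_bp
  )
}

#' @rdname snp_summary
#' @param x a `snp_link_summary`.
#' @param ... unused.
#' @export
glance.snp_link_summary <- function(x, ...) {
  as_tibble(x[c("n_regions_total", "n_regions_with_snp",
                "pct_regions_with_snp", "n_snps_linked",
                "mean_snps_per_linked_region")])
}

#' @rdname ispcr_summary
#' @param x an `ispcr_summary`.
#' @param ... unused.
#' @export
glance.ispcr_summary <- function(x, ...) {
  as_tibble(x[c("n_primers_tested", "n_primers_with_hits",
                "n_amplimers_total", "total_amplimer_bp",
                "mean_amplimers_per_hitting_primer")])
}

#' @rdname ispcr_summary
#' @export
tidy.ispcr_summary <- function(x, ...) x$amplimers
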