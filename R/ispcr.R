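# In silico PCR with primersearch-style semantics: exhaustive primer-site
# scanning under a percent-mismatch budget (Hamming distance, no indels) and
# enumeration of the products any plus/minus site combination would amplify.

#' Find primer binding sites on a template
#'
#' All positions on both strands where the primer matches with Hamming
#' distance at most `floor(mismatch_pct/100 * primer length)`. No indels; an
#' N on the template never matches. The 5' position reported is the leftmost
#' template base of a plus-strand site and the rightmost template base of a
#' minus-strand site.
#'
#' @param template a single sequence (character scalar, optionally named) or
#'   one element of a genome vector.
#' @param primer ACGT primer, length >= 10.
#' @param mismatch_pct allowed mismatch percentage, 0-50.
#' @param template_id id used in the output (defaults to the template's name).
#' @return tibble `template_id`, `strand`, `start_5prime`, `n_mismatches`,
#'   sorted by footprint position.
#' @export
find_primer_sites <- function(template, primer, mismatch_pct = 0,
                              template_id = NULL) {
  stopifnot(length(template) == 1, is.character(primer), length(primer) == 1)
  primer <- toupper(primer)
  if (nchar(primer) < 10) abort("primer length must be >= 10")
  if (grepl("[^ACGT]", primer)) abort("primer must contain only A, C, G, T")
  if (mismatch_pct < 0 || mismatch_pct > 50) {
    abort("mismatch_pct must be in [0, 50]")
  }
  template_id <- template_id %||% names(template) %||% "template"
  template <- toupper(unname(template))
  if (nchar(primer) > nchar(template)) {
    return(tibble(template_id = character(), strand = character(),
                  start_5prime = integer(), n_mismatches = integer()))
  }
  max_mm <- floor(mismatch_pct / 100 * nchar(primer))
  subject <- Biostrings::DNAString(template)
  scan_one <- function(pat, strand) {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                     max.mismatch = max_mm,
                                     with.indels = FALSE, fixed = TRUE)
    if (length(hits) == 0) return(NULL)
    frag <- as.character(hits)
    mm <- vapply(frag, function(f) hamming(f, pat), integer(1),
                 USE.NAMES = FALSE)
    tibble(
      template_id = template_id, strand = strand,
      start_5prime = if (strand == "+") IRanges::start(hits)
                     else IRanges::end(hits),
      n_mismatches = mm,
      fp_start = IRanges::start(hits), fp_end = IRanges::end(hits)
    )
  }
  out <- bind_rows(scan_one(primer, "+"), scan_one(revcomp(primer), "-"))
  if (nrow(out) == 0) {
    return(tibble(template_id = character(), strand = character(),
                  start_5prime = integer(), n_mismatches = integer()))
  }
  out <- out[order(out$fp_start, out$strand), ]
  out$fp_start <- NULL; out$fp_end <- NULL
  out
}

hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Predict PCR amplimers on a template
#'
#' Pairs every plus-strand site of one primer with every minus-strand site of
#' the other primer downstream of it, in both role orientations (forward
#' binding plus with reverse binding minus, and the swap), keeping products
#' whose outer 5'-to-5' span is at most `max_amplimer` and whose primer
#' footprints do not overlap. Duplicate products found under both role
#' assignments are reported once.
#'
#' @param template single template sequence (optionally named).
#' @param forward,reverse the primer pair (ACGT).
#' @param mismatch_pct allowed mismatch percentage per primer.
#' @param max_amplimer maximal product length (default 5000).
#' @param template_id id used in the output.
#' @return tibble `template_id`, `start`, `end` (outer 1-based inclusive
#'   coordinates), `length`, `mm_fwd`, `mm_rev`, sorted by position.
#' @export
predict_amplimers <- function(template, forward, reverse, mismatch_pct = 0,
                              max_amplimer = 5000, template_id = NULL) {
  template_id <- template_id %||% names(template) %||% "template"
  len_f <- nchar(forward); len_r <- nchar(reverse)
  sites_f <- find_primer_sites(template, forward, mismatch_pct, template_id)
  sites_r <- find_primer_sites(template, reverse, mismatch_pct, template_id)
  combine <- function(plus, minus, len_plus, len_minus, swap) {
    p <- plus[plus$strand == "+", , drop = FALSE]
    m <- minus[minus$strand == "-", , drop = FALSE]
    if (nrow(p) == 0 || nrow(m) == 0) return(NULL)
    grid <- tidyr::expand_grid(pi = seq_len(nrow(p)), mi = seq_len(nrow(m)))
    start <- p$start_5prime[grid$pi]
    end <- m$start_5prime[grid$mi]
    len <- end - start + 1L
    keep <- len >= len_plus + len_minus & len <= max_amplimer
    if (!any(keep)) return(NULL)
    tibble(
      template_id = template_id,
      start = start[keep], end = end[keep], length = len[keep],
      mm_fwd = if (swap) m$n_mismatches[grid$mi][keep]
               else p$n_mismatches[grid$pi][keep],
      mm_rev = if (swap) p$n_mismatches[grid$pi][keep]
               else m$n_mismatches[grid$mi][keep]
    )
  }
  out <- bind_rows(
    combine(sites_f, sites_r, len_f, len_r, swap = FALSE),
    combine(sites_r, sites_f, len_r, len_f, swap = TRUE)
  )
  if (nrow(out) == 0) {
    return(tibble(template_id = character(), start = integer(),
                  end = integer(), length = integer(),
                  mm_fwd = integer(), mm_rev = integer()))
  }
  out <- out[!duplicated(out[c("start", "end")]), , drop = FALSE]
  out[order(out$start, out$end), ]
}

#' In silico PCR of a primer panel against a genome set
#'
#' Runs [predict_amplimers()] for every pair of the panel against every
#' template and accumulates the validation counters: primers tested, primers
#' with at least one amplimer ("hits"), total amplimers, total amplified
#' bases, and the mean amplimers per hitting primer (truncated to 2 decimals,
#' the convention of the published 2.37-alleles-per-primer figure).
#'
#' @param panel tibble with `primer_name`, `forward_seq`, `reverse_seq`.
#' @param genome genome (named character vector or DNAStringSet).
#' @param mismatch_pct allowed mismatch percentage per primer.
#' @param max_amplimer maximal product length.
#' @return object of class `ispcr_summary`; the per-amplimer table is kept in
#'   `$amplimers` for per-assembly allele-length comparisons.
#' @export
ispcr_summary <- function(panel, genome, mismatch_pct = 0,
                          max_amplimer = 5000) {
  if (nrow(panel) == 0) abort("empty primer panel")
  genome <- as_genome(genome)
  amps <- list()
  for (i in seq_len(nrow(panel))) {
    for (sc in names(genome)) {
      a <- predict_amplimers(genome[[sc]], panel$forward_seq[[i]],
                             panel$reverse_seq[[i]], mismatch_pct,
                             max_amplimer, template_id = sc)
      if (nrow(a) > 0) {
        a$primer_name <- panel$primer_name[[i]]
        amps[[length(amps) + 1L]] <- a
      }
    }
  }
  amps <- if (length(amps) == 0) {
    tibble(template_id = character(), start = integer(), end = integer(),
           length = integer(), mm_fwd = integer(), mm_rev = integer(),
           primer_name = character())
  } else bind_rows(amps)
  with_hits <- length(unique(amps$primer_name))
  structure(list(
    n_primers_tested = nrow(panel),
    n_primers_with_hits = with_hits,
    n_amplimers_total = nrow(amps),
    total_amplimer_bp = sum(amps$length),
    mean_amplimers_per_hitting_primer = if (with_hits > 0)
      truncate_decimal(nrow(amps) / with_hits, 2) else 0,
    amplimers = amps
  ), class = "ispcr_summary")
}

#' @export
print.ispcr_summary <- function(x, ...) {
  cat("in silico PCR summary\n")
  cat(sprintf("  primers tested:       %d\n", x$n_primers_tested))
  cat(sprintf("  primers with hits:    %d\n", x$n_primers_with_hits))
  cat(sprintf("  amplimers:            %d (%.0f bp total)\n",
              x$n_amplimers_total, x$total_amplimer_bp))
  cat(sprintf("  amplimers per hitting primer: %.2f\n",
              x$mean_amplimers_per_hitting_primer))
  invisible(x)
}
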