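# Attach known SNPs to the primer-bounded flanking regions of designed pairs
# and summarise SNP/flank statistics genome-wide.

#' Link SNPs to primer flanking regions
#'
#' The flanking region of a pair is its amplicon minus the repeat motif
#' interval (two sub-intervals between each primer-bounded amplicon edge and
#' the repeat). Every SNP whose position falls inside the amplicon and --
#' unless `include_motif` -- outside the motif interval is linked; a SNP may
#' link to several overlapping amplicons. Positions are 1-based on the
#' scaffold.
#'
#' @param pairs designed pairs (with `primer_name`, `scaffold_id`,
#'   `amp_start`, `amp_end`, `ssr_start`, `ssr_end`).
#' @param snps SNP tibble from [read_snp_table()].
#' @param include_motif also link SNPs inside the repeat motif itself.
#' @return tibble with one row per pair: `primer_name`, `scaffold_id`,
#'   `flanks` (list-column of up to two `start`/`end` intervals), `snps`
#'   (list-column of sorted positions), `n_snps`, and the pair's `context`
#'   when present.
#' @export
link_snps <- function(pairs, snps, include_motif = FALSE) {
  if (!"primer_name" %in% names(pairs)) {
    abort("pairs must carry primer_name (see assign_primer_names())")
  }
  out <- pairs[intersect(c("primer_name", "scaffold_id", "context"),
                         names(pairs))]
  out$flanks <- purrr::pmap(
    pairs[c("amp_start", "amp_end", "ssr_start", "ssr_end")],
    function(amp_start, amp_end, ssr_start, ssr_end) {
      if (include_motif) return(tibble(start = amp_start, end = amp_end))
      f <- tibble(start = c(amp_start, ssr_end + 1L),
                  end = c(ssr_start - 1L, amp_end))
      f[f$end >= f$start, , drop = FALSE]
    })
  out$snps <- vector("list", nrow(pairs))
  for (sc in unique(pairs$scaffold_id)) {
    pi <- which(pairs$scaffold_id == sc)
    sp <- sort(snps$position[snps$scaffold_id == sc])
    if (length(sp) == 0) {
      out$snps[pi] <- list(integer(0))
      next
    }
    pts <- IRanges::IRanges(sp, width = 1L)
    amp <- IRanges::IRanges(pairs$amp_start[pi], pairs$amp_end[pi])
    hits <- IRanges::findOverlaps(pts, amp)
    for (j in seq_along(pi)) {
      pos <- sp[S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == j]]
      if (!include_motif) {
        pos <- pos[pos < pairs$ssr_start[pi[j]] | pos > pairs$ssr_end[pi[j]]]
      }
      out$snps[[pi[j]]] <- unique(pos)
    }
  }
  out$n_snps <- lengths(out$snps)
  as_tibble(out)
}

#' Summary of SNP-flank linkage
#'
#' Region-level statistics over the flanking regions of all designed pairs:
#' how many regions carry at least one SNP, the percentage of regions with a
#' SNP, the number of linked SNP occurrences, and the mean SNPs per linked
#' region, split by genic/intergenic context when available. Printed
#' percentage and mean are truncated to 2 decimals (the convention of the
#' published 75.55 percent / 2.97 per region figures).
#'
#' @param links output of [link_snps()].
#' @param n_pairs_total the number of pairs the links were computed from
#'   (defaults to `nrow(links)`).
#' @return object of class `snp_link_summary`.
#' @export
snp_summary <- function(links, n_pairs_total = nrow(links)) {
  if (n_pairs_total < nrow(links)) {
    abort("n_pairs_total smaller than the number of linked regions")
  }
  one <- function(l, n_total) {
    with_snp <- sum(l$n_snps > 0)
    linked <- sum(l$n_snps)
    list(
      n_regions_total = n_total,
      n_regions_with_snp = with_snp,
      pct_regions_with_snp = if (n_total > 0)
        truncate_decimal(100 * with_snp / n_total, 2) else 0,
      n_snps_linked = linked,
      mean_snps_per_linked_region = if (with_snp > 0)
        truncate_decimal(linked / with_snp, 2) else 0,
      mean_snps_per_linked_region_raw = if (with_snp > 0)
        linked / with_snp else 0
    )
  }
  res <- one(links, n_pairs_total)
  if ("context" %in% names(links)) {
    genic <- links[links$context %in% c("exon", "intron"), , drop = FALSE]
    inter <- links[links$context == "intergenic", , drop = FALSE]
    res$genic <- one(genic, nrow(genic))
    res$intergenic <- one(inter, nrow(inter))
  }
  structure(res, class = "snp_link_summary")
}

#' @export
print.snp_link_summary <- function(x, ...) {
  cat("SNP / flanking-region summary\n")
  cat(sprintf("  regions: %d, with SNP: %d (%.2f%%)\n",
              x$n_regions_total, x$n_regions_with_snp,
              x$pct_regions_with_snp))
  cat(sprintf("  SNP occurrences linked: %d (mean %.2f per linked region)\n",
              x$n_snps_linked, x$mean_snps_per_linked_region))
  invisible(x)
}

#' Serialise SNP links as TSV
#' @param links output of [link_snps()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snp_links <- function(links, path) {
  out <- tibble(
    primer_name = links$primer_name,
    n_snps = links$n_snps,
    snp_positions = vapply(links$snps, function(p) {
      paste(p, collapse = ";")
    }, character(1))
  )
  readr::write_tsv(out, path)
  invisible(path)
}
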