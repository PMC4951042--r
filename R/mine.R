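# Perfect-microsatellite mining, compound merging, motif canonicalisation and
# the genome-level mining summary. This is the core scanner of the toolkit.

#' Mining thresholds
#'
#' Per-unit-length minimum repeat counts and the compound-merging interruption
#' distance. The defaults are the classical genome-survey criteria: at least
#' 10 repeats for mononucleotides, 6 for dinucleotides, 5 for tri- through
#' hexanucleotides, and at most 100 bp between two repeats reported as one
#' compound microsatellite.
#'
#' @param min_repeats named numeric vector mapping unit length (`"1"`..`"6"`)
#'   to the minimum repeat count; all minima must be at least 2.
#' @param max_interruption maximal number of bases between two repeats merged
#'   into a compound locus.
#' @return an object of class `ssr_thresholds`.
#' @export
#' @examples
#' ssr_thresholds()
ssr_thresholds <- function(min_repeats = c(`1` = 10, `2` = 6, `3` = 5,
                                           `4` = 5, `5` = 5, `6` = 5),
                           max_interruption = 100) {
  min_repeats <- min_repeats[as.character(1:6)]
  if (anyNA(min_repeats)) abort("min_repeats must cover unit lengths 1..6")
  if (any(min_repeats < 2)) abort("all minimum repeat counts must be >= 2")
  if (max_interruption < 0) abort("max_interruption must be >= 0")
  structure(list(min_repeats = as.integer(min_repeats),
                 max_interruption = as.integer(max_interruption)),
            class = "ssr_thresholds")
}

#' Find perfect microsatellites
#'
#' Scans every scaffold on the forward strand for maximal perfect tandem
#' repeats of primitive units of length 1-6 meeting the per-unit-length
#' minimum repeat counts. Only complete unit repetitions are counted (a
#' trailing partial unit is excluded from the record span); runs are broken by
#' any non-ACGT base; an interval reportable with unit length k is not
#' re-reported with a non-primitive unit of length 2k or 3k. Overlapping runs
#' with different primitive units are all reported. Output is sorted by
#' scaffold, start, then unit length.
#'
#' @param genome named character vector of sequences (or DNAStringSet); see
#'   [as_genome()].
#' @param thresholds an [ssr_thresholds()] object.
#' @return SSR tibble: `scaffold_id`, `start`, `end` (1-based inclusive),
#'   `unit` (literal first unit of the run), `unit_length`, `repeat_count`,
#'   `kind = "perfect"`, `n_members = 1`, `members` (NULL).
#' @export
#' @examples
#' find_perfect_ssrs(c(s1 = "GGAAAAAAAAAACC"))
find_perfect_ssrs <- function(genome, thresholds = ssr_thresholds()) {
  genome <- as_genome(genome)
  stopifnot(inherits(thresholds, "ssr_thresholds"))
  res <- purrr::imap(genome, function(seq, id) scan_scaffold(seq, id, thresholds))
  out <- bind_rows(res)
  if (nrow(out) == 0) return(empty_ssr_tbl())
  out <- out[order(match(out$scaffold_id, names(genome)), out$start,
                   out$unit_length), ]
  out$kind <- "perfect"
  out$n_members <- 1L
  out$members <- vector("list", nrow(out))
  as_tibble(out)
}

# vectorised lag-k run scan of one scaffold
scan_scaffold <- function(seq, id, thresholds) {
  n <- nchar(seq)
  if (n == 0) return(NULL)
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  ok <- x %in% c("A", "C", "G", "T")
  min_rep <- thresholds$min_repeats
  acc <- list()
  for (k in 1:6) {
    if (n < k * min_rep[k]) next
    idx <- seq_len(n - k)
    eq <- (x[idx] == x[idx + k]) & ok[idx]
    r <- rle(eq)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    sel <- which(r$values & r$lengths >= (min_rep[k] - 1L) * k)
    if (length(sel) == 0) next
    starts <- run_start[sel]
    m <- r$lengths[sel] %/% k + 1L
    keep <- m >= min_rep[k]
    if (!any(keep)) next
    starts <- starts[keep]; m <- m[keep]
    units <- substr(rep(seq, length(starts)), starts, starts + k - 1L)
    prim <- is_primitive_unit(units)
    if (!any(prim)) next
    acc[[length(acc) + 1L]] <- tibble(
      scaffold_id = id,
      start = as.integer(starts[prim]),
      end = as.integer(starts[prim] + k * m[prim] - 1L),
      unit = units[prim],
      unit_length = as.integer(k),
      repeat_count = as.integer(m[prim])
    )
  }
  if (length(acc) == 0) NULL else bind_rows(acc)
}

#' Merge nearby repeats into compound microsatellites
#'
#' Collapses maximal chains of perfect repeats on the same scaffold whose
#' inter-record gap (`next start - previous end - 1`) is at most
#' `max_interruption` into single compound records. Chaining is greedy
#' left-to-right; because the gap relation is evaluated pairwise on adjacent
#' records, greedy chains are the maximal chains. Isolated records pass
#' through unchanged.
#'
#' @param records perfect SSR tibble, sorted by start within each scaffold.
#' @param max_interruption maximal interruption in bases (default 100).
#' @return SSR tibble where compound rows have `kind = "compound"`, `unit` the
#'   slash-joined member units, `n_members` the chain length and `members` the
#'   member records.
#' @export
merge_compound <- function(records, max_interruption = 100) {
  if (nrow(records) == 0) return(empty_ssr_tbl())
  if (!all(records$kind == "perfect")) abort("merge_compound() expects perfect records")
  parts <- split(records,
                 factor(records$scaffold_id, levels = unique(records$scaffold_id)))
  member_cols <- c("scaffold_id", "start", "end", "unit", "unit_length",
                   "repeat_count", "kind")
  out <- lapply(parts, function(d) {
    if (is.unsorted(d$start)) abort("records must be sorted by start")
    gap <- d$start[-1] - d$end[-nrow(d)] - 1L
    chain <- cumsum(c(0L, as.integer(gap > max_interruption)))
    rows <- lapply(split(seq_len(nrow(d)), chain), function(ix) {
      g <- d[ix, , drop = FALSE]
      if (nrow(g) == 1) return(g)
      tibble(
        scaffold_id = g$scaffold_id[[1]],
        start = min(g$start), end = max(g$end),
        unit = paste(g$unit, collapse = "/"),
        unit_length = NA_integer_, repeat_count = NA_integer_,
        kind = "compound", n_members = nrow(g),
        members = list(g[member_cols])
      )
    })
    bind_rows(rows)
  })
  out <- bind_rows(out)
  out <- out[order(match(out$scaffold_id, unique(records$scaffold_id)), out$start), ]
  as_tibble(out[names(empty_ssr_tbl())])
}

#' Canonical form of a repeat unit
#'
#' Lexicographically smallest rotation of the unit; with `collapse_strand`,
#' smallest over the rotations of the unit and of its reverse complement, so
#' that a motif family (e.g. AG/GA/CT/TC) maps to a single representative.
#'
#' @param unit character vector of primitive units (length 1-6).
#' @param collapse_strand collapse the unit with its reverse complement.
#' @return character vector of canonical units.
#' @export
#' @examples
#' normalize_motif("TA", collapse_strand = FALSE)  # "AT"
#' normalize_motif("GGC")                          # "CCG"
normalize_motif <- function(unit, collapse_strand = TRUE) {
  if (!all(is_primitive_unit(unit))) {
    abort("normalize_motif() requires primitive units")
  }
  vapply(unit, function(u) {
    cands <- rotations_of(u)
    if (collapse_strand) cands <- c(cands, rotations_of(revcomp(u)))
    min(cands)
  }, character(1), USE.NAMES = FALSE)
}

rotations_of <- function(u) {
  k <- nchar(u)
  vapply(seq_len(k), function(i) {
    paste0(substr(u, i, k), substr(u, 1, i - 1))
  }, character(1))
}

#' Genome-level mining summary
#'
#' Counters over the mined record set, matching the layout of a standard
#' genome SSR survey table. A compound record contributes its member count to
#' the SSR total, i.e. the total counts constituent repeats, not compound
#' wrappers.
#'
#' @param records SSR tibble (perfect and/or compound records).
#' @param genome the genome the records were mined from.
#' @return object of class `mining_summary` with fields
#'   `n_sequences_examined`, `total_bp`, `n_ssrs`,
#'   `n_ssr_containing_sequences`, `n_sequences_with_more_than_one_ssr`,
#'   `n_ssrs_in_compound_formation`, `freq_per_mb` (truncated to 2 decimals)
#'   and `freq_per_mb_raw`.
#' @export
summarize_mining <- function(records, genome) {
  genome <- as_genome(genome)
  if (nrow(records) > 0 && !all(records$scaffold_id %in% names(genome))) {
    abort("records refer to scaffolds absent from the genome")
  }
  weights <- if (nrow(records) == 0) integer(0) else
    ifelse(records$kind == "compound", records$n_members, 1L)
  n_ssrs <- sum(weights)
  per_scaffold <- if (nrow(records) == 0) integer(0) else
    tapply(weights, records$scaffold_id, sum)
  total_bp <- sum(nchar(genome))
  structure(list(
    n_sequences_examined = length(genome),
    total_bp = total_bp,
    n_ssrs = as.integer(n_ssrs),
    n_ssr_containing_sequences = length(per_scaffold),
    n_sequences_with_more_than_one_ssr = sum(per_scaffold > 1),
    n_ssrs_in_compound_formation =
      as.integer(sum(weights[records$kind == "compound"])),
    freq_per_mb = freq_per_mb(n_ssrs, total_bp, digits = 2),
    freq_per_mb_raw = freq_per_mb(n_ssrs, total_bp, raw = TRUE)
  ), class = "mining_summary")
}

#' @export
print.mining_summary <- function(x, ...) {
  cat("SSR mining summary\n")
  cat(sprintf("  sequences examined:            %d\n", x$n_sequences_examined))
  cat(sprintf("  total size (bp):               %.0f\n", x$total_bp))
  cat(sprintf("  identified SSRs:               %d\n", x$n_ssrs))
  cat(sprintf("  SSR-containing sequences:      %d\n", x$n_ssr_containing_sequences))
  cat(sprintf("  sequences with >1 SSR:         %d\n",
              x$n_sequences_with_more_than_one_ssr))
  cat(sprintf("  SSRs in compound formation:    %d\n",
              x$n_ssrs_in_compound_formation))
  cat(sprintf("  frequency (SSRs/Mb):           %.2f\n", x$freq_per_mb))
  invisible(x)
}

#' Write a MISA-style record table
#'
#' Emits the familiar per-repeat TSV (`ID`, `SSR nr`, `SSR type`, `SSR`,
#' `size`, `start`, `end`) for cross-checking against other miners: `p1`-`p6`
#' for perfect records by unit length, `c` for compound records.
#'
#' @param records SSR tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_misa_table <- function(records, path) {
  nr <- stats::ave(seq_len(nrow(records)), records$scaffold_id,
                   FUN = seq_along)
  ssr_repr <- ifelse(
    records$kind == "compound",
    vapply(records$members, function(m) {
      paste(sprintf("(%s)%d", m$unit, m$repeat_count), collapse = "*")
    }, character(1)),
    sprintf("(%s)%d", records$unit, records$repeat_count)
  )
  out <- tibble(
    ID = records$scaffold_id,
    `SSR nr` = as.integer(nr),
    `SSR type` = ifelse(records$kind == "compound", "c",
                        paste0("p", records$unit_length)),
    SSR = ssr_repr,
    size = records$end - records$start + 1L,
    start = records$start,
    end = records$end
  )
  readr::write_tsv(out, path)
  invisible(path)
}
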