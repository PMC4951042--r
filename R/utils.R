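# Small shared helpers: sequence manipulation, rounding conventions, genome coercion.

IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

UNIT_CLASS_NAMES <- c("mono", "di", "tri", "tetra", "penta", "hexa")

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`; accepts upper-case ACGTN.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAC"))
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# truncate toward zero at `digits` decimals; the reporting convention used for
# all printed per-Mb frequencies, percentages and means (matches how published
# summary tables were derived, e.g. 347.558 -> 347.5).
truncate_decimal <- function(x, digits = 2) {
  trunc(x * 10^digits) / 10^digits
}

#' Per-megabase frequency
#'
#' Frequency of `n` events over `bp` bases, expressed per Mb. The printed
#' value is truncated toward zero at `digits` decimals, the convention under
#' which genome-scale SSR surveys report per-Mb densities (e.g. 42,061 loci
#' over 121,018,751 bp prints as 347.5 per Mb).
#'
#' @param n event count.
#' @param bp bases surveyed.
#' @param digits decimals kept in the printed value.
#' @param raw if `TRUE` return the full-precision ratio instead.
#' @return numeric frequency per Mb.
#' @export
#' @examples
#' freq_per_mb(42061, 121018751, digits = 1)
freq_per_mb <- function(n, bp, digits = 2, raw = FALSE) {
  if (any(bp <= 0 & n > 0)) {
    abort("freq_per_mb(): zero-length compartment with a positive count")
  }
  f <- ifelse(bp > 0, n / (bp / 1e6), 0)
  if (raw) f else truncate_decimal(f, digits)
}

# TRUE when a unit of length 1-6 is primitive (not a repetition of a shorter
# unit, so "AT" yes, "ATAT" no). Vectorised.
is_primitive_unit <- function(unit) {
  len <- nchar(unit)
  out <- rep(TRUE, length(unit))
  for (k in unique(len)) {
    idx <- which(len == k)
    divs <- seq_len(k - 1)
    divs <- divs[k %% divs == 0]
    for (d in divs) {
      rep_version <- strrep(substr(unit[idx], 1, d), k / d)
      out[idx] <- out[idx] & (unit[idx] != rep_version)
    }
  }
  out
}

#' Coerce a genome to a named character vector
#'
#' Accepts a named character vector, a [Biostrings::DNAStringSet], or a single
#' unnamed sequence (named `"seq1"`). Sequences are upper-cased; scaffold ids
#' must be unique.
#'
#' @param genome genome in any accepted representation.
#' @return named character vector of upper-case sequences.
#' @export
as_genome <- function(genome) {
  if (methods::is(genome, "XStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (!is.character(genome)) {
    abort("genome must be a named character vector or a DNAStringSet")
  }
  if (is.null(names(genome))) {
    if (length(genome) == 1L) names(genome) <- "seq1"
    else abort("multi-sequence genomes must be named")
  }
  if (anyDuplicated(names(genome))) {
    abort("duplicate scaffold ids in genome")
  }
  setNames(toupper(genome), names(genome))
}

# empty SSR tibble with the canonical column set
empty_ssr_tbl <- function() {
  tibble(
    scaffold_id = character(), start = integer(), end = integer(),
    unit = character(), unit_length = integer(), repeat_count = integer(),
    kind = character(), n_members = integer(), members = list()
  )
}

# expand compound records into their perfect members; perfect rows pass through
expand_members <- function(records) {
  if (nrow(records) == 0) return(records)
  if (!"kind" %in% names(records) || all(records$kind == "perfect")) {
    return(records)
  }
  keep_context <- "context" %in% names(records)
  rows <- purrr::pmap(records, function(...) {
    r <- list(...)
    if (identical(r$kind, "compound")) {
      m <- r$members
      if (keep_context && !is.null(m)) m$context <- r$context
      m
    } else {
      out <- tibble(
        scaffold_id = r$scaffold_id, start = r$start, end = r$end,
        unit = r$unit, unit_length = r$unit_length,
        repeat_count = r$repeat_count, kind = "perfect"
      )
      if (keep_context) out$context <- r$context
      out
    }
  })
  bind_rows(rows)
}
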