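# Genetic-code analyses of trinucleotide repeat units: the primitive tri-motif
# space and single-substitution convertibility of sense codons to stops.

STOP_CODONS <- c("TAA", "TAG", "TGA")

AMINO_ACID_NAMES <- c(
  A = "Alanine", R = "Arginine", N = "Asparagine", D = "Aspartic acid",
  C = "Cysteine", Q = "Glutamine", E = "Glutamic acid", G = "Glycine",
  H = "Histidine", I = "Isoleucine", L = "Leucine", K = "Lysine",
  M = "Methionine", F = "Phenylalanine", P = "Proline", S = "Serine",
  T = "Threonine", W = "Tryptophan", Y = "Tyrosine", V = "Valine"
)

#' Enumerate the trinucleotide repeat-motif space
#'
#' All 3-base sequences over ACGT whose unit is primitive, i.e. the 64 codons
#' minus the four homopolymers (AAA, CCC, GGG, TTT) that reduce to
#' mononucleotide repeats -- the 60 distinct trinucleotide repeat unit
#' sequences observable in a genome scan. Lexicographic order.
#'
#' @return character vector of 60 units.
#' @export
enumerate_tri_motifs <- function() {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  sort(all3[is_primitive_unit(all3)])
}

#' Stop codons reachable by one substitution
#'
#' The subset of \{TAA, TAG, TGA\} at Hamming distance exactly 1 from a sense
#' codon -- the single-base substitutions that would truncate translation if
#' they hit a trinucleotide repeat lying in an exon.
#'
#' @param codon a sense codon (ACGT, length 3) under the standard genetic
#'   code.
#' @return character vector (possibly empty) of reachable stop codons.
#' @export
#' @examples
#' stop_convertible("CGA")  # "TGA"
#' stop_convertible("ATG")  # none
stop_convertible <- function(codon) {
  stopifnot(length(codon) == 1)
  codon <- toupper(codon)
  if (nchar(codon) != 3 || grepl("[^ACGT]", codon)) {
    abort("codon must be a 3-base ACGT sequence")
  }
  if (codon %in% STOP_CODONS) abort("input is itself a stop codon")
  STOP_CODONS[vapply(STOP_CODONS, function(s) hamming(codon, s) == 1L,
                     logical(1))]
}

#' Survey exon trinucleotide repeats for stop convertibility
#'
#' One report per distinct literal repeat unit (evaluated as a codon in its
#' literal frame) with a non-empty set of reachable stop codons, sorted by
#' amino acid then codon. With `rotations = TRUE` the unit's two rotations
#' are additionally evaluated as codons.
#'
#' @param records SSR tibble of exon-context trinucleotide repeats (rows with
#'   other unit lengths or contexts are ignored).
#' @param rotations also evaluate the two rotations of each unit.
#' @return tibble `amino_acid`, `codon`, `stops` (list-column of reachable
#'   stop codons).
#' @export
survey_exon_tri_stops <- function(records, rotations = FALSE) {
  members <- expand_members(records)
  if (nrow(members) > 0) {
    keep <- members$unit_length == 3L
    if ("context" %in% names(members)) keep <- keep & members$context == "exon"
    members <- members[keep, , drop = FALSE]
  }
  units <- unique(members$unit)
  if (rotations) units <- unique(unlist(lapply(units, rotations_of)))
  units <- setdiff(units, STOP_CODONS)
  if (length(units) == 0) {
    return(tibble(amino_acid = character(), codon = character(),
                  stops = list()))
  }
  aa <- Biostrings::GENETIC_CODE[units]
  stops <- lapply(units, stop_convertible)
  out <- tibble(
    amino_acid = unname(AMINO_ACID_NAMES[aa]),
    codon = units, stops = stops
  )
  out <- out[lengths(out$stops) > 0, , drop = FALSE]
  out[order(out$amino_acid, out$codon), ]
}

#' Write a stop-convertibility report
#'
#' Flat TSV with one row per (amino acid, repeat sequence, stop codon).
#'
#' @param report output of [survey_exon_tri_stops()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stop_report <- function(report, path) {
  flat <- tidyr::unnest(
    tibble(amino_acid = report$amino_acid, repeat_sequence = report$codon,
           stop_codon = report$stops),
    "stop_codon")
  readr::write_tsv(flat, path)
  invisible(path)
}
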