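# Genomic-context classification of repeats (exon / intron / intergenic) and
# the compartment-level tables: per-Mb frequencies, repeat-count bins, and
# motif presence sets.

#' Classify repeats by genomic context
#'
#' Assigns each record `exon`, `intron` or `intergenic`. Under the default
#' `"start"` rule a record is placed by its start coordinate: intergenic if
#' the start lies in no gene span, exon if it lies in an exon interval of the
#' covering gene, intron otherwise. A repeat straddling an exon/intron
#' boundary therefore follows its start. The alternative `"majority"` rule
#' assigns the compartment with the largest base overlap (ties resolved
#' exon > intron > intergenic). Overlapping genes: the first gene in
#' (scaffold, start) order wins.
#'
#' @param records SSR tibble.
#' @param genes gene-model tibble from [read_gene_annotation()] (may be empty).
#' @param rule `"start"` (default) or `"majority"`.
#' @return `records` with a `context` column.
#' @export
classify_context <- function(records, genes, rule = c("start", "majority")) {
  rule <- match.arg(rule)
  records$context <- rep("intergenic", nrow(records))
  if (nrow(records) == 0 || is.null(genes) || nrow(genes) == 0) return(records)
  genes <- genes[order(genes$scaffold_id, genes$start), ]
  for (sc in unique(records$scaffold_id)) {
    ri <- which(records$scaffold_id == sc)
    g <- genes[genes$scaffold_id == sc, , drop = FALSE]
    if (nrow(g) == 0) next
    gene_rng <- IRanges::IRanges(g$start, g$end)
    if (rule == "start") {
      pts <- IRanges::IRanges(records$start[ri], width = 1L)
      hit <- IRanges::findOverlaps(pts, gene_rng, select = "first")
      for (j in seq_along(ri)) {
        if (is.na(hit[j])) next
        ex <- g$exons[[hit[j]]]
        in_exon <- any(records$start[ri[j]] >= ex$start &
                       records$start[ri[j]] <= ex$end)
        records$context[ri[j]] <- if (in_exon) "exon" else "intron"
      }
    } else {
      exon_rng <- IRanges::reduce(IRanges::IRanges(
        unlist(lapply(g$exons, `[[`, "start")),
        unlist(lapply(g$exons, `[[`, "end"))))
      genic_rng <- IRanges::reduce(gene_rng)
      for (j in seq_along(ri)) {
        r <- IRanges::IRanges(records$start[ri[j]], records$end[ri[j]])
        w <- IRanges::width(r)
        exon_bp <- sum(IRanges::width(IRanges::intersect(r, exon_rng)))
        genic_bp <- sum(IRanges::width(IRanges::intersect(r, genic_rng)))
        intron_bp <- genic_bp - exon_bp
        inter_bp <- w - genic_bp
        best <- which.max(c(exon_bp, intron_bp, inter_bp))
        records$context[ri[j]] <- c("exon", "intron", "intergenic")[best]
      }
    }
  }
  records
}

# union of gene spans per scaffold, in bp
genic_bp_of <- function(genes) {
  if (is.null(genes) || nrow(genes) == 0) return(0)
  sum(vapply(split(genes, genes$scaffold_id), function(g) {
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(g$start, g$end))))
  }, numeric(1)))
}

#' Compartment summary of classified repeats
#'
#' Counts and per-Mb frequencies for the genic (exon + intron) and intergenic
#' compartments, plus the unit-length composition of each context. Genic bp is
#' the union of gene spans; intergenic bp is the remainder of the genome.
#' A compound record counts its members.
#'
#' @param records classified SSR tibble (see [classify_context()]).
#' @param genes gene-model tibble.
#' @param genome the genome the records were mined from.
#' @return object of class `context_summary`: `counts` (per-context member
#'   counts), `compartments` (tibble with `compartment`, `n`, `bp`,
#'   `freq_per_mb` truncated to 1 decimal, `freq_per_mb_raw`), and
#'   `unit_length_pct` (percentage of each unit-length class within each
#'   context, 1 decimal).
#' @export
context_summary <- function(records, genes, genome) {
  genome <- as_genome(genome)
  if (nrow(records) > 0 && !"context" %in% names(records)) {
    abort("records must be classified first (classify_context())")
  }
  members <- expand_members(records)
  total_bp <- sum(nchar(genome))
  genic_bp <- genic_bp_of(genes)
  intergenic_bp <- total_bp - genic_bp
  counts <- c(exon = 0L, intron = 0L, intergenic = 0L)
  if (nrow(members) > 0) {
    tab <- table(factor(members$context, levels = names(counts)))
    counts[] <- as.integer(tab)
  }
  n_genic <- counts[["exon"]] + counts[["intron"]]
  n_inter <- counts[["intergenic"]]
  compartments <- tibble(
    compartment = c("genic", "intergenic", "total"),
    n = c(n_genic, n_inter, n_genic + n_inter),
    bp = c(genic_bp, intergenic_bp, total_bp),
    freq_per_mb = c(freq_per_mb(n_genic, genic_bp, digits = 1),
                    freq_per_mb(n_inter, intergenic_bp, digits = 1),
                    freq_per_mb(n_genic + n_inter, total_bp, digits = 2)),
    freq_per_mb_raw = c(freq_per_mb(n_genic, genic_bp, raw = TRUE),
                        freq_per_mb(n_inter, intergenic_bp, raw = TRUE),
                        freq_per_mb(n_genic + n_inter, total_bp, raw = TRUE))
  )
  ulp <- if (nrow(members) == 0) {
    tibble(context = character(), unit_length = integer(),
           n = integer(), pct = numeric())
  } else {
    members |>
      count(context, unit_length) |>
      group_by(context) |>
      mutate(pct = round(100 * n / sum(n), 1)) |>
      ungroup()
  }
  structure(list(counts = counts, compartments = compartments,
                 unit_length_pct = ulp,
                 genic_bp = genic_bp, intergenic_bp = intergenic_bp,
                 total_bp = total_bp),
            class = "context_summary")
}

#' @export
print.context_summary <- function(x, ...) {
  cat("SSR context summary\n")
  cat(sprintf("  exon %d / intron %d / intergenic %d\n",
              x$counts[["exon"]], x$counts[["intron"]],
              x$counts[["intergenic"]]))
  print(x$compartments)
  invisible(x)
}

# bin edges by table kind; the triplet table collapses the long tail
REPEAT_BIN_EDGES <- list(
  non_triplet = c(5, 10, 16, 21, 26, 31, 36, 46, 56, 71, 101, 151, 201, 351),
  triplet = c(5, 10, 16, 21, 26, 31, 36, 46, 56, 71, 101, 251)
)

#' Repeat-count bin table
#'
#' Cross-tabulates perfect repeats (compound members counted individually) by
#' repeat-count bin, unit class and genic/intergenic context, in the layout of
#' the classical survey tables: non-triplet (mono, di, tetra, penta) or
#' triplet (tri, hexa) repeat types, bins 5-9, 10-15, ..., ending at 201-350
#' (non-triplet) or 101-250 (triplet). Records whose repeat count exceeds the
#' last bin edge are dropped and counted in the `n_dropped` attribute.
#'
#' @param records classified SSR tibble.
#' @param table_kind `"non_triplet"` or `"triplet"`.
#' @return tibble with columns `bin`, `unit_class`, `context`
#'   (genic/intergenic) and `n`, complete over all cells; attributes
#'   `table_kind`, `n_dropped`.
#' @export
bin_by_repeat_count <- function(records, table_kind = c("non_triplet", "triplet")) {
  table_kind <- match.arg(table_kind)
  members <- expand_members(records)
  if (nrow(members) > 0 && !"context" %in% names(members)) {
    abort("records must carry a context column")
  }
  lens <- if (table_kind == "non_triplet") c(1L, 2L, 4L, 5L) else c(3L, 6L)
  classes <- UNIT_CLASS_NAMES[lens]
  edges <- REPEAT_BIN_EDGES[[table_kind]]
  labels <- paste0(edges[-length(edges)], "-", edges[-1] - 1)
  members <- members[members$unit_length %in% lens, , drop = FALSE]
  too_big <- members$repeat_count >= edges[length(edges)]
  n_dropped <- sum(too_big)
  if (n_dropped > 0) {
    inform(sprintf("bin_by_repeat_count: dropped %d record(s) beyond the last bin",
                   n_dropped))
  }
  members <- members[!too_big, , drop = FALSE]
  grid <- tidyr::expand_grid(bin = factor(labels, levels = labels),
                             unit_class = factor(classes, levels = classes),
                             context = factor(c("genic", "intergenic")))
  if (nrow(members) == 0) {
    out <- grid
    out$n <- 0L
  } else {
    members$bin <- cut(members$repeat_count, breaks = edges, right = FALSE,
                       labels = labels)
    members$unit_class <- factor(UNIT_CLASS_NAMES[members$unit_length],
                                 levels = classes)
    members$context2 <- factor(
      ifelse(members$context == "intergenic", "intergenic", "genic"))
    tab <- members |>
      count(bin, unit_class, context = context2) |>
      mutate(bin = factor(bin, levels = labels))
    out <- left_join(grid, tab, by = c("bin", "unit_class", "context"))
    out$n <- ifelse(is.na(out$n), 0L, out$n)
  }
  out <- as_tibble(out)
  attr(out, "table_kind") <- table_kind
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("repeat_bin_table", class(out))
  out
}

#' Motif presence sets across compartments
#'
#' For the requested unit-length classes, partitions the observed normalised
#' motifs into those seen only in the genic compartment, only in the
#' intergenic compartment, and in both (the comparison underlying
#' genic-vs-intergenic motif family figures).
#'
#' @param records classified SSR tibble.
#' @param unit_lengths integer vector of unit lengths to include (default
#'   4:6, the tetra/penta/hexa comparison).
#' @param collapse_strand normalise motifs over both strands (default TRUE).
#' @return list of class `motif_presence_sets` with sorted character vectors
#'   `genic_only`, `intergenic_only`, `shared`.
#' @export
motif_presence_sets <- function(records, unit_lengths = 4:6,
                                collapse_strand = TRUE) {
  members <- expand_members(records)
  members <- members[members$unit_length %in% unit_lengths, , drop = FALSE]
  if (nrow(members) > 0 && !"context" %in% names(members)) {
    abort("records must carry a context column")
  }
  motifs <- if (nrow(members) == 0) character(0) else
    normalize_motif(members$unit, collapse_strand = collapse_strand)
  genic <- unique(motifs[members$context %in% c("exon", "intron")])
  inter <- unique(motifs[members$context == "intergenic"])
  structure(list(
    genic_only = sort(setdiff(genic, inter)),
    intergenic_only = sort(setdiff(inter, genic)),
    shared = sort(intersect(genic, inter))
  ), class = "motif_presence_sets")
}

#' @export
print.motif_presence_sets <- function(x, ...) {
  cat(sprintf("motif presence: %d genic-only, %d intergenic-only, %d shared\n",
              length(x$genic_only), length(x$intergenic_only),
              length(x$shared)))
  invisible(x)
}
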