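# Orchestration: mine -> merge -> classify -> design -> link SNPs ->
# (optional) in silico PCR -> marker database and summary reports.

#' Build marker-database rows from designed pairs and SNP links
#'
#' Joins the designed pairs, their SNP links and the gene annotation into the
#' fixed marker-database layout. Repeat coordinates are re-expressed within
#' the amplicon (1-based from the amplicon 5' end); `annealing_temperature`
#' is the mean primer Tm rounded to 1 decimal; `gc_percent` carries both
#' primers as `fwd;rev`; gene fields are empty for intergenic markers.
#'
#' @param pairs named designed pairs (see [assign_primer_names()]).
#' @param links SNP links from [link_snps()], or NULL for no SNP column data.
#' @param genes gene-model tibble, or NULL.
#' @return marker database tibble in the fixed column order.
#' @export
build_marker_database <- function(pairs, links = NULL, genes = NULL) {
  n <- nrow(pairs)
  unit_len <- nchar(pairs$ssr_unit)
  repeat_type <- ifelse(pairs$ssr_kind == "compound", "compound",
                        UNIT_CLASS_NAMES[pmin(unit_len, 6L)])
  snp_positions <- rep(list(integer(0)), n)
  if (!is.null(links) && nrow(links) > 0) {
    m <- match(pairs$primer_name, links$primer_name)
    snp_positions[!is.na(m)] <- links$snps[m[!is.na(m)]]
  }
  gene_product <- rep("", n); gene_start <- rep(NA_integer_, n)
  gene_end <- rep(NA_integer_, n)
  if (!is.null(genes) && nrow(genes) > 0) {
    for (i in which(pairs$context %in% c("exon", "intron"))) {
      g <- genes[genes$scaffold_id == pairs$scaffold_id[[i]] &
                 genes$start <= pairs$ssr_start[[i]] &
                 genes$end >= pairs$ssr_start[[i]], , drop = FALSE]
      if (nrow(g) > 0) {
        gene_product[i] <- g$product[[1]]
        gene_start[i] <- g$start[[1]]
        gene_end[i] <- g$end[[1]]
      }
    }
  }
  tibble(
    primer_name = pairs$primer_name,
    repeat_type = repeat_type,
    repeat_sequence = pairs$ssr_unit,
    repeat_size = pairs$ssr_end - pairs$ssr_start + 1L,
    repeat_start = pairs$ssr_start - pairs$amp_start + 1L,
    repeat_end = pairs$ssr_end - pairs$amp_start + 1L,
    forward_seq = pairs$forward_seq,
    reverse_seq = pairs$reverse_seq,
    annealing_temperature = round((pairs$fwd_tm + pairs$rev_tm) / 2, 1),
    gc_percent = sprintf("%.1f;%.1f", pairs$fwd_gc, pairs$rev_gc),
    product_size = pairs$product_size,
    scaffold_id = pairs$scaffold_id,
    gene_product = gene_product,
    gene_start = gene_start,
    gene_end = gene_end,
    snp_positions = snp_positions
  )
}

#' Run the full marker-development pipeline
#'
#' Mines perfect repeats, merges compounds, classifies contexts, designs and
#' names primer pairs, links SNPs, optionally validates the panel by in
#' silico PCR against its own genome, and (when `out_dir` is given) writes
#' the marker database, the summary tables and a JSON run manifest.
#' Re-running with identical inputs reproduces identical outputs.
#'
#' @param genome genome (named character vector, DNAStringSet, or a FASTA
#'   path).
#' @param genes gene-model tibble, an annotation path, or NULL.
#' @param snps SNP tibble, a VCF/TSV path, or NULL.
#' @param out_dir optional output directory.
#' @param thresholds [ssr_thresholds()].
#' @param params [design_params()].
#' @param context_rule boundary rule for [classify_context()].
#' @param include_motif_snps link SNPs inside the repeat motif too.
#' @param run_ispcr validate the designed panel by in silico PCR at
#'   `mismatch_pct`.
#' @param mismatch_pct mismatch budget for the validation step.
#' @param annotation_dialect,snp_dialect dialects used when `genes`/`snps`
#'   are paths.
#' @return list of class `ssr_pipeline_run` with the mined records, pairs,
#'   links, database, summaries and manifest.
#' @export
run_pipeline <- function(genome, genes = NULL, snps = NULL, out_dir = NULL,
                         thresholds = ssr_thresholds(),
                         params = design_params(),
                         context_rule = "start",
                         include_motif_snps = FALSE,
                         run_ispcr = FALSE, mismatch_pct = 0,
                         annotation_dialect = "tsv", snp_dialect = "vcf") {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- read_genome_fasta(genome)
  }
  genome <- as_genome(genome)
  if (is.character(genes)) genes <- read_gene_annotation(genes, annotation_dialect)
  if (is.character(snps)) snps <- read_snp_table(snps, snp_dialect)

  perfect <- find_perfect_ssrs(genome, thresholds)
  records <- merge_compound(perfect, thresholds$max_interruption)
  records <- classify_context(records, genes, rule = context_rule)

  mining <- summarize_mining(records, genome)
  contexts <- context_summary(records, genes, genome)
  bins_nt <- bin_by_repeat_count(records, "non_triplet")
  bins_t <- bin_by_repeat_count(records, "triplet")

  pairs <- design_primers(records, genome, params)
  pairs <- assign_primer_names(pairs)
  coverage <- coverage_summary(pairs, genome, genes)

  links <- NULL; snp_sum <- NULL
  if (!is.null(snps) && nrow(pairs) > 0) {
    links <- link_snps(pairs, snps, include_motif = include_motif_snps)
    snp_sum <- snp_summary(links, n_pairs_total = nrow(pairs))
  }

  ispcr <- NULL
  if (run_ispcr && nrow(pairs) > 0) {
    ispcr <- ispcr_summary(pairs, genome, mismatch_pct = mismatch_pct)
  }

  db <- build_marker_database(pairs, links, genes)

  manifest <- list(
    tool = "ssrmarkers",
    version = as.character(utils::packageVersion("ssrmarkers")),
    config_hash = rlang::hash(list(thresholds = unclass(thresholds),
                                   params = unclass(params),
                                   context_rule = context_rule,
                                   include_motif_snps = include_motif_snps,
                                   run_ispcr = run_ispcr,
                                   mismatch_pct = mismatch_pct)),
    input_checksums = list(
      genome = rlang::hash(genome),
      genes = rlang::hash(genes),
      snps = rlang::hash(snps)
    ),
    counters = list(
      n_sequences = length(genome),
      total_bp = unname(sum(nchar(genome))),
      n_ssrs = mining$n_ssrs,
      n_ssrs_in_compound_formation = mining$n_ssrs_in_compound_formation,
      n_exon = unname(contexts$counts[["exon"]]),
      n_intron = unname(contexts$counts[["intron"]]),
      n_intergenic = unname(contexts$counts[["intergenic"]]),
      n_primer_pairs = nrow(pairs),
      amplified_bp = coverage$amplified_bp[coverage$compartment == "total"],
      n_regions_with_snp = if (is.null(snp_sum)) 0L else
        snp_sum$n_regions_with_snp,
      n_snps_linked = if (is.null(snp_sum)) 0L else snp_sum$n_snps_linked,
      n_amplimers = if (is.null(ispcr)) 0L else ispcr$n_amplimers_total
    )
  )

  run <- structure(list(
    records = records, mining = mining, contexts = contexts,
    bins_non_triplet = bins_nt, bins_triplet = bins_t,
    pairs = pairs, coverage = coverage, links = links,
    snp_summary = snp_sum, ispcr = ispcr, database = db,
    manifest = manifest
  ), class = "ssr_pipeline_run")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_primer_database(db, file.path(out_dir, "marker_database.tsv"))
    readr::write_tsv(tidy(mining), file.path(out_dir, "mining_summary.tsv"))
    readr::write_tsv(contexts$compartments,
                     file.path(out_dir, "context_summary.tsv"))
    readr::write_tsv(bins_nt, file.path(out_dir, "bins_non_triplet.tsv"))
    readr::write_tsv(bins_t, file.path(out_dir, "bins_triplet.tsv"))
    if (!is.null(links)) {
      write_snp_links(links, file.path(out_dir, "snp_links.tsv"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run
}

#' @export
print.ssr_pipeline_run <- function(x, ...) {
  cat("SSR marker pipeline run\n")
  c <- x$manifest$counters
  cat(sprintf("  %d SSRs on %d sequence(s) (%.0f bp)\n",
              c$n_ssrs, c$n_sequences, c$total_bp))
  cat(sprintf("  exon/intron/intergenic: %d/%d/%d\n",
              c$n_exon, c$n_intron, c$n_intergenic))
  cat(sprintf("  primer pairs designed: %d; SNP occurrences linked: %d\n",
              c$n_primer_pairs, c$n_snps_linked))
  invisible(x)
}
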