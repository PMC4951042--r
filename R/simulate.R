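# Synthetic genomes with planted microsatellites, gene models and SNPs.
# Every planted feature is recorded in a truth table, and the background is
# screened so that mining recovers exactly the planted repeats -- which makes
# the whole pipeline testable offline with known answers.

#' Build a simulation specification
#'
#' Describes the synthetic genome: how many scaffolds, which repeats to plant
#' (unit, repeat count, genomic context), the SNP rate, and the background
#' base composition. Planted repeats are laid out in independent locus blocks
#' -- `left_pad` clean bases, the repeat, `right_pad` clean bases -- joined by
#' `separator` clean bases, so consecutive plants can never merge into an
#' unrequested compound (`separator` must exceed `max_interruption`). A
#' compound locus is requested explicitly via the `gap_after` column of
#' `ssr_plants`: a non-NA gap (at most `max_interruption`) places the next
#' plant in the same block at that distance.
#'
#' Defaults state a small but realistic world: background GC 39 percent and a
#' SNP rate of 0.009 per bp, matching the base composition and the
#' 3.5M-SNPs-over-381-Mb density of a date-palm draft assembly; pads of 450 bp
#' leave a full primer search window on each side of every plant.
#'
#' @param ssr_plants tibble with columns `unit`, `repeat_count`, `context`
#'   (`exon`, `intron` or `intergenic`) and optionally `gap_after`.
#' @param n_scaffolds number of scaffolds plants are distributed over
#'   (round-robin).
#' @param snp_rate per-bp probability of planting a SNP.
#' @param gc_background background GC fraction.
#' @param seed integer seed; same seed, same genome, byte for byte.
#' @param left_pad,right_pad clean flank length around each plant (bases).
#' @param separator clean bases between locus blocks.
#' @param exon_pad exon length at each end of an intron-context gene.
#' @param thresholds [ssr_thresholds()] used to screen the background.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(ssr_plants = default_ssr_plants(),
                            n_scaffolds = 4L,
                            snp_rate = 0.009,
                            gc_background = 0.39,
                            seed = 1L,
                            left_pad = 450L, right_pad = 450L,
                            separator = 150L, exon_pad = 60L,
                            thresholds = ssr_thresholds()) {
  stopifnot(nrow(ssr_plants) > 0, n_scaffolds >= 1,
            snp_rate >= 0, snp_rate < 1,
            gc_background > 0, gc_background < 1)
  if (!"gap_after" %in% names(ssr_plants)) {
    ssr_plants$gap_after <- NA_integer_
  }
  if (!all(ssr_plants$context %in% c("exon", "intron", "intergenic"))) {
    abort("plant context must be exon, intron or intergenic")
  }
  if (!all(is_primitive_unit(ssr_plants$unit))) {
    abort("planted units must be primitive")
  }
  min_rep <- thresholds$min_repeats[nchar(ssr_plants$unit)]
  if (any(ssr_plants$repeat_count < min_rep)) {
    abort("planted repeat counts must meet the mining thresholds")
  }
  if (any(!is.na(ssr_plants$gap_after) &
          ssr_plants$gap_after > thresholds$max_interruption)) {
    abort("gap_after must not exceed max_interruption")
  }
  if (separator <= thresholds$max_interruption) {
    abort("separator must exceed max_interruption")
  }
  structure(list(
    ssr_plants = ssr_plants, n_scaffolds = as.integer(n_scaffolds),
    snp_rate = snp_rate, gc_background = gc_background,
    seed = as.integer(seed), left_pad = as.integer(left_pad),
    right_pad = as.integer(right_pad), separator = as.integer(separator),
    exon_pad = as.integer(exon_pad), thresholds = thresholds
  ), class = "simulation_spec")
}

#' Default planted-repeat table
#'
#' A deterministic mixture over unit lengths and contexts: motifs cycle
#' through a fixed pool (mono through hexa), contexts cycle
#' intergenic/intron/intergenic/exon (so roughly half intergenic, a quarter
#' intronic, a quarter exonic), exon plants are always trinucleotide units
#' (coding regions tolerate triplet repeats), and repeat counts cycle from
#' the mining threshold upwards.
#'
#' @param n number of plants.
#' @return tibble with `unit`, `repeat_count`, `context`.
#' @export
default_ssr_plants <- function(n = 24L) {
  pool <- c("A", "T", "AG", "AT", "CT", "AAG", "ATC", "CCG", "AAT",
            "AAAT", "ACGT", "AAAAT", "AAGTCC")
  tri_pool <- c("AAG", "ATC", "CCG", "AGA", "CGA", "TAC", "AAT", "CAG")
  contexts <- rep(c("intergenic", "intron", "intergenic", "exon"),
                  length.out = n)
  unit <- character(n); j_pool <- 0L; j_tri <- 0L
  for (i in seq_len(n)) {
    if (contexts[i] == "exon") {
      j_tri <- j_tri %% length(tri_pool) + 1L
      unit[i] <- tri_pool[j_tri]
    } else {
      j_pool <- j_pool %% length(pool) + 1L
      unit[i] <- pool[j_pool]
    }
  }
  thr <- ssr_thresholds()$min_repeats
  extra <- rep(0:3, length.out = n)
  tibble(unit = unit,
         repeat_count = as.integer(thr[nchar(unit)] + extra),
         context = contexts)
}

BASES <- c("A", "C", "G", "T")

# i.i.d. background segment free of threshold-meeting repeats, with forbidden
# first/last characters so it can never phase-extend an adjacent plant
clean_segment <- function(len, gc, thresholds, forbid_first = NULL,
                          forbid_last = NULL, max_tries = 200L) {
  if (len == 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  for (try in seq_len(max_tries)) {
    x <- sample(BASES, len, replace = TRUE, prob = p)
    if (!is.null(forbid_first) && x[1] %in% forbid_first) {
      x[1] <- sample(setdiff(BASES, forbid_first), 1)
    }
    if (!is.null(forbid_last) && x[len] %in% forbid_last) {
      x[len] <- sample(setdiff(BASES, forbid_last), 1)
    }
    s <- paste(x, collapse = "")
    if (nrow(find_perfect_ssrs(c(seg = s), thresholds)) == 0) return(s)
  }
  abort("could not sample a clean background segment")
}

#' Simulate a genome with planted repeats, genes and SNPs
#'
#' Realises a [simulation_spec()]: plants are distributed round-robin over
#' scaffolds and embedded in screened background (no incidental repeat meets
#' the thresholds, and block boundaries cannot extend a plant), gene models
#' are created around exon/intron-context plants (an exon-context gene is a
#' single exon spanning its block; an intron-context gene carries an
#' `exon_pad` exon at each block end with the plant in the intron between),
#' and SNPs are dropped uniformly at rate `snp_rate` with the reference
#' allele read from the genome. Each assembled scaffold is verified by
#' re-mining: the mined record set must equal the planted one, otherwise the
#' scaffold is resampled.
#'
#' @param spec a [simulation_spec()].
#' @param dir optional directory; when given, writes `genome.fasta`,
#'   `genes.tsv`, `snps.vcf` and `truth_ssrs.tsv` there.
#' @return list of class `simulated_genome`: `genome` (named character
#'   vector), `genes`, `snps`, `truth` (list with `ssrs`, `genes`, `snps`),
#'   `spec`, and `paths` when `dir` was given.
#' @export
simulate_genome <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  plants <- spec$ssr_plants
  # group plants into blocks: a non-NA gap_after keeps the next plant in the
  # same block (an explicitly requested compound locus)
  block_id <- cumsum(c(1L, ifelse(is.na(plants$gap_after[-nrow(plants)]),
                                  1L, 0L)))
  plants$block <- block_id
  blocks <- split(plants, plants$block)
  scaffold_of_block <- rep_len(seq_len(spec$n_scaffolds), length(blocks))

  genome <- character(spec$n_scaffolds)
  names(genome) <- sprintf("scf%02d", seq_len(spec$n_scaffolds))
  truth_ssrs <- list(); truth_genes <- list()
  gene_no <- 0L

  for (sc in seq_len(spec$n_scaffolds)) {
    my_blocks <- blocks[scaffold_of_block == sc]
    for (attempt in 1:25) {
      built <- build_scaffold(my_blocks, spec, names(genome)[sc],
                              gene_start_no = gene_no)
      mined <- find_perfect_ssrs(setNames(built$seq, names(genome)[sc]),
                                 spec$thresholds)
      want <- built$ssrs[c("start", "end", "unit")]
      got <- mined[c("start", "end", "unit")]
      if (nrow(got) == nrow(want) && all(got == want)) break
      if (attempt == 25) abort("simulation failed to converge on a clean scaffold")
    }
    genome[sc] <- built$seq
    truth_ssrs[[sc]] <- built$ssrs
    truth_genes[[sc]] <- built$genes
    gene_no <- gene_no + nrow(built$genes)
  }

  truth_ssrs <- bind_rows(truth_ssrs)
  truth_genes <- bind_rows(truth_genes)

  # SNPs: i.i.d. per position
  snps <- list()
  for (sc in names(genome)) {
    n <- nchar(genome[[sc]])
    pos <- which(stats::runif(n) < spec$snp_rate)
    if (length(pos) == 0) next
    ref <- substring(genome[[sc]], pos, pos)
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1),
                  character(1), USE.NAMES = FALSE)
    snps[[sc]] <- tibble(scaffold_id = sc, position = pos, ref = ref,
                         alt = alt)
  }
  snps <- if (length(snps) == 0) {
    tibble(scaffold_id = character(), position = integer(),
           ref = character(), alt = character())
  } else bind_rows(snps)

  out <- structure(list(
    genome = genome,
    genes = truth_genes,
    snps = snps,
    truth = list(ssrs = truth_ssrs, genes = truth_genes, snps = snps),
    spec = spec
  ), class = "simulated_genome")

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      genome = file.path(dir, "genome.fasta"),
      genes = file.path(dir, "genes.tsv"),
      snps = file.path(dir, "snps.vcf"),
      truth_ssrs = file.path(dir, "truth_ssrs.tsv")
    )
    write_genome_fasta(genome, paths$genome)
    write_gene_annotation_tsv(truth_genes, paths$genes)
    write_snp_vcf(snps, paths$snps)
    readr::write_tsv(truth_ssrs, paths$truth_ssrs)
    out$paths <- paths
  }
  out
}

# assemble one scaffold from its blocks; returns seq, planted ssrs, genes
build_scaffold <- function(my_blocks, spec, scaffold_id, gene_start_no) {
  thr <- spec$thresholds
  gc <- spec$gc_background
  pieces <- character(0)
  pos <- 0L                     # length assembled so far
  ssrs <- list(); genes <- list()
  gene_no <- gene_start_no
  for (b in my_blocks) {
    block_start <- pos + 1L
    # left pad: must not phase-extend the first plant leftwards
    u1 <- b$unit[[1]]
    pad <- clean_segment(spec$left_pad, gc, thr,
                         forbid_last = substr(u1, nchar(u1), nchar(u1)))
    pieces <- c(pieces, pad); pos <- pos + nchar(pad)
    for (i in seq_len(nrow(b))) {
      u <- b$unit[[i]]; m <- b$repeat_count[[i]]
      run <- strrep(u, m)
      ssrs[[length(ssrs) + 1L]] <- tibble(
        scaffold_id = scaffold_id, start = pos + 1L,
        end = pos + nchar(run), unit = u, unit_length = nchar(u),
        repeat_count = m, context = b$context[[1]],
        block = b$block[[1]]
      )
      pieces <- c(pieces, run); pos <- pos + nchar(run)
      gap <- b$gap_after[[i]]
      if (i < nrow(b)) {
        u_next <- b$unit[[i + 1]]
        g <- clean_segment(gap, gc, thr,
                           forbid_first = substr(u, 1, 1),
                           forbid_last = substr(u_next, nchar(u_next),
                                                nchar(u_next)))
        pieces <- c(pieces, g); pos <- pos + nchar(g)
      }
    }
    u_last <- b$unit[[nrow(b)]]
    pad <- clean_segment(spec$right_pad, gc, thr,
                         forbid_first = substr(u_last, 1, 1))
    pieces <- c(pieces, pad); pos <- pos + nchar(pad)
    block_end <- pos
    ctx <- b$context[[1]]
    if (ctx != "intergenic") {
      gene_no <- gene_no + 1L
      exons <- if (ctx == "exon") {
        tibble(start = block_start, end = block_end)
      } else {
        tibble(start = c(block_start, block_end - spec$exon_pad + 1L),
               end = c(block_start + spec$exon_pad - 1L, block_end))
      }
      genes[[length(genes) + 1L]] <- tibble(
        gene_id = sprintf("gene%04d", gene_no),
        scaffold_id = scaffold_id,
        start = block_start, end = block_end,
        product = sprintf("hypothetical protein %04d", gene_no),
        exons = list(exons)
      )
    }
    sep <- clean_segment(spec$separator, gc, thr)
    pieces <- c(pieces, sep); pos <- pos + nchar(sep)
  }
  list(
    seq = paste(pieces, collapse = ""),
    ssrs = if (length(ssrs)) bind_rows(ssrs) else
      tibble(scaffold_id = character(), start = integer(), end = integer(),
             unit = character(), unit_length = integer(),
             repeat_count = integer(), context = character(),
             block = integer()),
    genes = if (length(genes)) bind_rows(genes) else
      tibble(gene_id = character(), scaffold_id = character(),
             start = integer(), end = integer(), product = character(),
             exons = list())
  )
}

#' Write gene models in the simple TSV dialect
#'
#' Columns `gene_id`, `scaffold_id`, `start`, `end`, `exons`
#' (semicolon-joined `start-end` intervals) and `product`; the dialect read
#' back by `read_gene_annotation(dialect = "tsv")`.
#'
#' @param genes gene-model tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation_tsv <- function(genes, path) {
  out <- tibble(
    gene_id = genes$gene_id, scaffold_id = genes$scaffold_id,
    start = genes$start, end = genes$end,
    exons = vapply(genes$exons, function(e) {
      paste(sprintf("%d-%d", e$start, e$end), collapse = ";")
    }, character(1)),
    product = genes$product
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Compare mined repeats against the planted truth
#'
#' A mined record matches a planted one when scaffold, start and end are
#' identical and the units agree up to rotation. Compound records are
#' expanded to their members before matching.
#'
#' @param mined SSR tibble from the miner.
#' @param truth planted-truth SSR tibble (e.g. `sim$truth$ssrs`).
#' @return list with `precision`, `recall`, `n_exact`.
#' @export
truth_compare <- function(mined, truth) {
  mined <- expand_members(mined)
  key <- function(d) paste(d$scaffold_id, d$start, d$end,
                           normalize_motif(d$unit, collapse_strand = FALSE))
  mk <- if (nrow(mined) > 0) key(mined) else character(0)
  tk <- if (nrow(truth) > 0) key(truth) else character(0)
  n_exact <- length(intersect(unique(mk), unique(tk)))
  list(
    precision = if (length(mk) > 0) sum(mk %in% tk) / length(mk) else 0,
    recall = if (length(tk) > 0) sum(tk %in% mk) / length(tk) else 0,
    n_exact = n_exact
  )
}
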