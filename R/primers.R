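# Flanking-primer design around mined repeats: candidate enumeration under
# length / Tm / GC constraints, separable penalty minimisation, context-based
# naming, and amplified-genome coverage.

#' Primer design parameters
#'
#' The design criteria: optimum primer length 20 bp, optimum melting
#' temperature 55 degrees C, optimum GC 50 percent, product size 100-500 bp.
#' Acceptable ranges and the candidate search window are tunable.
#'
#' @param primer_opt_len optimum primer length (bases).
#' @param primer_len_range acceptable primer length range.
#' @param tm_opt optimum melting temperature (deg C).
#' @param tm_range acceptable Tm range.
#' @param gc_opt optimum GC content (percent).
#' @param gc_range acceptable GC range.
#' @param product_range acceptable PCR product size range (bases).
#' @param search_flank bases scanned on each side of the repeat for primer
#'   candidates.
#' @param w_len,w_tm,w_gc penalty weights for deviations from the optima.
#' @param salt_mM,primer_nM Tm model conditions (monovalent salt, total
#'   oligo concentration).
#' @return object of class `design_params`.
#' @export
design_params <- function(primer_opt_len = 20L,
                          primer_len_range = c(18L, 27L),
                          tm_opt = 55, tm_range = c(50, 60),
                          gc_opt = 50, gc_range = c(20, 80),
                          product_range = c(100L, 500L),
                          search_flank = 400L,
                          w_len = 1, w_tm = 1, w_gc = 1,
                          salt_mM = 50, primer_nM = 50) {
  stopifnot(
    primer_opt_len >= primer_len_range[1], primer_opt_len <= primer_len_range[2],
    tm_opt >= tm_range[1], tm_opt <= tm_range[2],
    gc_opt >= gc_range[1], gc_opt <= gc_range[2],
    product_range[1] > 0, product_range[2] >= product_range[1],
    search_flank > 0
  )
  structure(as.list(environment()), class = "design_params")
}

#' GC content of DNA sequences
#'
#' @param seq character vector of non-empty ACGT sequences.
#' @return numeric vector, percent G+C.
#' @export
#' @examples
#' gc_content("ATGC")
gc_content <- function(seq) {
  if (any(!nzchar(seq)) || anyNA(seq)) abort("gc_content(): empty sequence")
  if (any(grepl("[^ACGT]", seq))) {
    abort("gc_content(): sequences must contain only A, C, G, T")
  }
  100 * (nchar(gsub("[AT]", "", seq))) / nchar(seq)
}

# SantaLucia (1998) unified nearest-neighbour parameters.
# dH in kcal/mol, dS in cal/(mol K); rows indexed by dinucleotide.
NN_DH <- c(AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
           CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
           GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
           TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9)
NN_DS <- c(AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
           CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
           GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
           TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2)

#' Melting temperature of an oligonucleotide
#'
#' Nearest-neighbour duplex Tm under the unified SantaLucia (1998)
#' parameters, with duplex-initiation terms for the terminal base pairs, the
#' entropic salt correction 0.368 (N-1) ln\[Na+\], and the CT/4 concentration
#' factor for non-self-complementary duplexes. `method = "wallace"` gives the
#' simple 2(A+T)+4(G+C) rule for cross-checks.
#'
#' @param seq character vector of ACGT sequences, length >= 8 for the
#'   nearest-neighbour model.
#' @param salt_mM monovalent cation concentration (mM).
#' @param primer_nM total oligo concentration (nM).
#' @param method `"santalucia"` (default) or `"wallace"`.
#' @return numeric vector of Tm in degrees C.
#' @export
#' @examples
#' melting_temperature("ATGCATGCATGCATGCATGC")
melting_temperature <- function(seq, salt_mM = 50, primer_nM = 50,
                                method = c("santalucia", "wallace")) {
  method <- match.arg(method)
  if (any(!nzchar(seq)) || anyNA(seq)) abort("melting_temperature(): empty sequence")
  if (any(grepl("[^ACGT]", seq))) {
    abort("melting_temperature(): sequences must contain only A, C, G, T")
  }
  if (method == "wallace") {
    at <- nchar(gsub("[GC]", "", seq))
    gc <- nchar(seq) - at
    return(2 * at + 4 * gc)
  }
  if (any(nchar(seq) < 8)) {
    abort("melting_temperature(): nearest-neighbour model needs length >= 8")
  }
  R <- 1.9872           # cal/(mol K)
  ct <- primer_nM * 1e-9
  na <- salt_mM * 1e-3
  vapply(seq, function(s) {
    n <- nchar(s)
    dinucs <- substring(s, 1:(n - 1), 2:n)
    dh <- sum(NN_DH[dinucs])
    ds <- sum(NN_DS[dinucs])
    ends <- c(substr(s, 1, 1), substr(s, n, n))
    for (e in ends) {
      if (e %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
      else                    { dh <- dh + 2.3; ds <- ds + 4.1 }
    }
    ds <- ds + 0.368 * (n - 1) * log(na)
    1000 * dh / (ds + R * log(ct / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

# TRUE when the sequence contains a self-complementary stretch of >= k bases
# (an 8-mer whose reverse complement also occurs in the sequence): a cheap
# hairpin/self-dimer guard in place of full duplex thermodynamics.
has_selfcomp_run <- function(seq, k = 8L) {
  n <- nchar(seq)
  if (n < k) return(FALSE)
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  any(revcomp(kmers) %in% kmers)
}

# for every start position s of a window, the smallest end e such that
# [s, e] contains some k-mer together with its reverse complement
# (Inf when none); one pass over the window's k-mers
selfcomp_reach <- function(w, k = 8L) {
  n <- nchar(w)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  kmers <- substring(w, 1:m, k:n)
  rw <- revcomp(w)
  # revcomp of the k-mer at i is the rw substring covering the same bases
  rc <- substring(rw, n - (1:m) - k + 2L, n - (1:m) + 1L)
  by_kmer <- split(seq_len(m), kmers)
  hi <- rep(Inf, m)
  for (i in seq_len(m)) {
    js <- by_kmer[[rc[i]]]
    if (!is.null(js)) {
      js <- js[js >= i]
      if (length(js)) hi[i] <- js[1] + k - 1L
    }
  }
  rev(cummin(rev(hi)))
}

# enumerate one side's primer candidates inside [win_start, win_end]
# (footprint fully inside the window); returns a tibble or NULL.
# Tm/GC for all (start, length) combinations come from cumulative
# nearest-neighbour sums over the window, so each candidate costs O(1);
# the arithmetic is the same as melting_temperature().
enumerate_candidates <- function(seq, win_start, win_end, params) {
  win_len <- win_end - win_start + 1L
  if (win_len < params$primer_len_range[1]) return(NULL)
  w <- substr(seq, win_start, win_end)
  chars <- strsplit(w, "", fixed = TRUE)[[1]]
  code <- match(chars, c("A", "C", "G", "T"))
  n_bad <- cumsum(is.na(code))
  n_gc <- cumsum(!is.na(code) & code %in% c(2L, 3L))
  di <- (code[-win_len] - 1L) * 4L + code[-1L]
  di_ok <- !is.na(di)
  dh_cum <- c(0, cumsum(ifelse(di_ok, NN_DH[di], 0)))
  ds_cum <- c(0, cumsum(ifelse(di_ok, NN_DS[di], 0)))
  lens <- params$primer_len_range[1]:params$primer_len_range[2]
  cand <- list()
  for (len in lens) {
    if (win_len < len) next
    s <- 1:(win_len - len + 1L)
    e <- s + len - 1L
    ok <- (n_bad[e] - c(0, n_bad)[s]) == 0
    if (!any(ok)) next
    s <- s[ok]; e <- e[ok]
    gc <- 100 * (n_gc[e] - c(0, n_gc)[s]) / len
    dh <- dh_cum[e] - dh_cum[s]
    ds <- ds_cum[e] - ds_cum[s]
    term_gc_first <- code[s] %in% c(2L, 3L)
    term_gc_last <- code[e] %in% c(2L, 3L)
    dh <- dh + ifelse(term_gc_first, 0.1, 2.3) + ifelse(term_gc_last, 0.1, 2.3)
    ds <- ds + ifelse(term_gc_first, -2.8, 4.1) + ifelse(term_gc_last, -2.8, 4.1)
    ds <- ds + 0.368 * (len - 1) * log(params$salt_mM * 1e-3)
    tm <- 1000 * dh / (ds + 1.9872 * log(params$primer_nM * 1e-9 / 4)) - 273.15
    keep <- gc >= params$gc_range[1] & gc <= params$gc_range[2] &
      tm >= params$tm_range[1] & tm <= params$tm_range[2]
    if (!any(keep)) next
    cand[[length(cand) + 1L]] <- tibble(
      start = win_start + s[keep] - 1L, len = len,
      gc = gc[keep], tm = tm[keep]
    )
  }
  if (length(cand) == 0) return(NULL)
  cand <- bind_rows(cand)
  # self-complementarity guard, window-level: M[s] is the smallest end e such
  # that [s, e] encloses an 8-mer and its reverse complement; a candidate is
  # rejected iff M[rel start] <= rel end (equivalent to has_selfcomp_run()).
  M <- selfcomp_reach(w)
  rel_s <- cand$start - win_start + 1L
  rel_e <- rel_s + cand$len - 1L
  hit <- rel_s <= length(M) & M[pmin(rel_s, length(M))] <= rel_e
  cand <- cand[!hit, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  cand$seq <- substring(seq, cand$start, cand$start + cand$len - 1)
  cand$penalty <- params$w_len * abs(cand$len - params$primer_opt_len) +
    params$w_tm * abs(cand$tm - params$tm_opt) +
    params$w_gc * abs(cand$gc - params$gc_opt)
  cand
}

#' Design the best flanking primer pair for one repeat
#'
#' Enumerates every candidate forward primer fully left of the repeat (within
#' `search_flank`, length/Tm/GC in range, no ambiguous base, no
#' self-complementary run of 8+) and every reverse candidate symmetrically on
#' the right, scores each feasible pair by
#' `w_len (|lenF-opt| + |lenR-opt|) + w_tm (|TmF-55| + |TmR-55|) +
#' w_gc (|GCF-50| + |GCR-50|)`, discards pairs whose product size falls
#' outside `product_range`, and returns the minimum-penalty pair. Ties are
#' broken by smaller product, then leftmost forward start, then shorter
#' primers. The reverse primer is reported 5'->3' on the minus strand.
#'
#' @param ssr one-row SSR tibble (or a list with `scaffold_id`, `start`,
#'   `end`).
#' @param genome genome containing the repeat's scaffold.
#' @param params a [design_params()] object.
#' @return one-row tibble describing the pair, or `NULL` when no candidate
#'   pair satisfies the constraints.
#' @export
design_primer_pair <- function(ssr, genome, params = design_params()) {
  genome <- as_genome(genome)
  if (!ssr$scaffold_id[[1]] %in% names(genome)) {
    abort(paste0("scaffold not in genome: ", ssr$scaffold_id[[1]]))
  }
  seq <- genome[[ssr$scaffold_id[[1]]]]
  n <- nchar(seq)
  s <- ssr$start[[1]]; e <- ssr$end[[1]]
  fwd <- enumerate_candidates(seq, max(1L, s - params$search_flank),
                              s - 1L, params)
  if (is.null(fwd)) return(NULL)
  rev <- enumerate_candidates(seq, e + 1L,
                              min(n, e + params$search_flank), params)
  if (is.null(rev)) return(NULL)
  rev$end3 <- rev$start + rev$len - 1L  # rightmost template base = amplicon end
  best <- best_pair(fwd, rev, params$product_range)
  if (is.null(best)) return(NULL)
  f <- fwd[best$fi, ]; r <- rev[best$ri, ]
  tibble(
    scaffold_id = ssr$scaffold_id[[1]],
    ssr_start = s, ssr_end = e,
    ssr_unit = if ("unit" %in% names(ssr)) ssr$unit[[1]] else NA_character_,
    ssr_kind = if ("kind" %in% names(ssr)) ssr$kind[[1]] else "perfect",
    forward_seq = f$seq, reverse_seq = revcomp(r$seq),
    fwd_tm = f$tm, rev_tm = r$tm, fwd_gc = f$gc, rev_gc = r$gc,
    fwd_len = f$len, rev_len = r$len,
    amp_start = f$start, amp_end = r$end3,
    product_size = r$end3 - f$start + 1L,
    penalty = f$penalty + r$penalty
  )
}

# minimum-penalty (forward, reverse) pair under the product-size window.
# Separable penalty => sliding-window minimum over forward candidates as the
# reverse 3' end advances; ties resolved smaller product, then leftmost
# forward start, then shorter forward, then shorter reverse.
best_pair <- function(fwd, rev, product_range) {
  f_ord <- order(fwd$start)
  fs <- fwd$start[f_ord]; fp <- fwd$penalty[f_ord]
  r_ord <- order(rev$end3)
  re <- rev$end3[r_ord]; rp <- rev$penalty[r_ord]
  lo_p <- product_range[1]; hi_p <- product_range[2]
  eps <- 1e-9
  best <- Inf
  # pass 1: find the minimum total penalty with a monotonic-deque window min;
  # window of forward indices for reverse j: fs in [re[j]-hi_p+1, re[j]-lo_p+1]
  dq <- integer(length(fs)); head <- 1L; tail <- 0L; add <- 1L
  for (j in seq_along(re)) {
    wmin <- re[j] - hi_p + 1L; wmax <- re[j] - lo_p + 1L
    while (add <= length(fs) && fs[add] <= wmax) {
      while (tail >= head && fp[dq[tail]] >= fp[add]) tail <- tail - 1L
      tail <- tail + 1L; dq[tail] <- add; add <- add + 1L
    }
    while (tail >= head && fs[dq[head]] < wmin) head <- head + 1L
    if (tail >= head) {
      tot <- rp[j] + fp[dq[head]]
      if (tot < best) best <- tot
    }
  }
  if (!is.finite(best)) return(NULL)
  # pass 2: collect all pairs achieving the minimum, apply tie-breaks
  cand_r <- which(rp <= best - min(fp) + eps)
  winners <- NULL
  for (j in cand_r) {
    wmin <- re[j] - hi_p + 1L; wmax <- re[j] - lo_p + 1L
    fi <- which(fs >= wmin & fs <= wmax & fp <= best - rp[j] + eps)
    if (length(fi) == 0) next
    winners <- bind_rows(winners, tibble(
      fi = f_ord[fi], ri = r_ord[j],
      product = re[j] - fs[fi] + 1L,
      fstart = fs[fi]
    ))
  }
  if (is.null(winners) || nrow(winners) == 0) return(NULL)
  winners$flen <- fwd$len[winners$fi]
  winners$rlen <- rev$len[winners$ri]
  winners <- winners[order(winners$product, winners$fstart,
                           winners$flen, winners$rlen), ]
  list(fi = winners$fi[[1]], ri = winners$ri[[1]])
}

#' Design primer pairs for a set of repeats
#'
#' Applies [design_primer_pair()] to every record; repeats for which no pair
#' satisfies the constraints are dropped (the designed/total shortfall is the
#' expected behaviour on real genomes). Compound repeats are targeted over
#' their full span. The input `context` column, when present, is carried
#' through.
#'
#' @param records SSR tibble.
#' @param genome genome the records were mined from.
#' @param params a [design_params()] object.
#' @return tibble of designed pairs, one row per successful repeat.
#' @export
design_primers <- function(records, genome, params = design_params()) {
  genome <- as_genome(genome)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    p <- design_primer_pair(records[i, ], genome, params)
    if (!is.null(p) && "context" %in% names(records)) {
      p$context <- records$context[[i]]
    }
    p
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(
      scaffold_id = character(), ssr_start = integer(), ssr_end = integer(),
      ssr_unit = character(), ssr_kind = character(),
      forward_seq = character(), reverse_seq = character(),
      fwd_tm = numeric(), rev_tm = numeric(), fwd_gc = numeric(),
      rev_gc = numeric(), fwd_len = integer(), rev_len = integer(),
      amp_start = integer(), amp_end = integer(), product_size = integer(),
      penalty = numeric(), context = character()
    )
  }
  out
}

#' Name primer pairs by genic context
#'
#' Genic pairs (repeat in an exon or intron) are numbered `Pd_G_SSR1..n` and
#' intergenic pairs `Pd_IG_SSR1..m`, each series independently, in (scaffold,
#' repeat start) order, so the naming is independent of input order.
#'
#' @param pairs designed pairs with a `context` column.
#' @param prefix_genic,prefix_intergenic name prefixes.
#' @return `pairs` sorted by (scaffold, start) with a `primer_name` column.
#' @export
assign_primer_names <- function(pairs, prefix_genic = "Pd_G_SSR",
                                prefix_intergenic = "Pd_IG_SSR") {
  if (nrow(pairs) == 0) {
    pairs$primer_name <- character(0)
    return(pairs)
  }
  if (!"context" %in% names(pairs)) abort("pairs must carry a context column")
  pairs <- pairs[order(pairs$scaffold_id, pairs$ssr_start, pairs$ssr_end), ]
  genic <- pairs$context %in% c("exon", "intron")
  pairs$primer_name <- NA_character_
  pairs$primer_name[genic] <- paste0(prefix_genic, seq_len(sum(genic)))
  pairs$primer_name[!genic] <- paste0(prefix_intergenic, seq_len(sum(!genic)))
  pairs
}

#' Genome coverage of the designed amplicons
#'
#' Total bases covered by the amplified products after merging overlapping
#' amplicon intervals per scaffold, with fractions of the total genome and,
#' when gene models are supplied, of the genic and intergenic compartments
#' (per-compartment coverage uses the pairs of that compartment).
#'
#' @param pairs designed pairs.
#' @param genome the source genome.
#' @param genes optional gene-model tibble for compartment figures.
#' @return tibble with `compartment`, `n_pairs`, `amplified_bp`,
#'   `compartment_bp`, `fraction`.
#' @export
coverage_summary <- function(pairs, genome, genes = NULL) {
  genome <- as_genome(genome)
  total_bp <- sum(nchar(genome))
  merged_bp <- function(p) {
    if (nrow(p) == 0) return(0)
    sum(vapply(split(p, p$scaffold_id), function(d) {
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(d$amp_start, d$amp_end))))
    }, numeric(1)))
  }
  out <- tibble(
    compartment = "total", n_pairs = nrow(pairs),
    amplified_bp = merged_bp(pairs), compartment_bp = total_bp
  )
  if (!is.null(genes) && "context" %in% names(pairs)) {
    genic_bp <- genic_bp_of(genes)
    g <- pairs[pairs$context %in% c("exon", "intron"), , drop = FALSE]
    i <- pairs[pairs$context == "intergenic", , drop = FALSE]
    out <- bind_rows(out,
      tibble(compartment = "genic", n_pairs = nrow(g),
             amplified_bp = merged_bp(g), compartment_bp = genic_bp),
      tibble(compartment = "intergenic", n_pairs = nrow(i),
             amplified_bp = merged_bp(i),
             compartment_bp = total_bp - genic_bp))
  }
  out$fraction <- ifelse(out$compartment_bp > 0,
                         out$amplified_bp / out$compartment_bp, 0)
  out
}
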