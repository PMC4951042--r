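# Independent oracles used across the suite. Each re-derives the expected
# behaviour by direct enumeration, deliberately avoiding the package's
# vectorised implementations.

ORACLE_BASES <- c("A", "C", "G", "T")

random_seq <- function(n, seed, n_prob = 0, gc = 0.5) {
  set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  x <- sample(ORACLE_BASES, n, replace = TRUE, prob = p)
  if (n_prob > 0) {
    idx <- which(runif(n) < n_prob)
    x[idx] <- "N"
  }
  paste(x, collapse = "")
}

# primitivity by explicit divisor check
oracle_primitive <- function(unit) {
  k <- nchar(unit)
  for (d in seq_len(k - 1)) {
    if (k %% d != 0) next
    if (strrep(substr(unit, 1, d), k / d) == unit) return(FALSE)
  }
  TRUE
}

# brute-force perfect-SSR scanner: tests every (position, unit length) pair,
# counts complete unit repetitions to the right, reports left-maximal runs
oracle_find_ssrs <- function(seq, thresholds = ssr_thresholds()) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(x)
  valid <- x %in% ORACLE_BASES
  rows <- list()
  for (k in 1:6) {
    min_rep <- thresholds$min_repeats[k]
    last_start <- n - k * min_rep + 1
    if (last_start < 1) next
    for (i in seq_len(last_start)) {
      if (!valid[i] || x[i] != x[i + k]) next          # needs >= 2 repeats
      if (any(!valid[i:(i + k - 1)])) next
      # left maximality: the run must not continue one base to the left
      if (i > 1 && valid[i - 1] && x[i - 1] == x[i + k - 1]) next
      unit <- substr(seq, i, i + k - 1)
      if (!oracle_primitive(unit)) next
      m <- 1
      repeat {
        nxt_start <- i + m * k
        if (nxt_start + k - 1 > n) break
        if (substr(seq, nxt_start, nxt_start + k - 1) != unit) break
        m <- m + 1
      }
      if (m >= min_rep) {
        rows[[length(rows) + 1]] <- data.frame(
          start = i, end = i + k * m - 1, unit = unit,
          unit_length = k, repeat_count = m, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(), end = integer(), unit = character(),
                      unit_length = integer(), repeat_count = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$unit_length), , drop = FALSE]
}

# greedy left-to-right chaining oracle for compound merging: returns, for
# sorted records of one scaffold, the chain id of each record
oracle_chain_ids <- function(starts, ends, max_interruption) {
  chain <- integer(length(starts))
  if (length(starts) == 0) return(chain)
  chain[1] <- 1L
  for (i in seq_along(starts)[-1]) {
    gap <- starts[i] - ends[i - 1] - 1
    chain[i] <- if (gap <= max_interruption) chain[i - 1] else chain[i - 1] + 1L
  }
  chain
}

# naive sliding-window primer-site oracle on both strands; N never matches
oracle_primer_sites <- function(template, primer, mismatch_pct) {
  tmpl <- strsplit(template, "", fixed = TRUE)[[1]]
  n <- length(tmpl)
  plen <- nchar(primer)
  max_mm <- floor(mismatch_pct / 100 * plen)
  scan <- function(pat, strand) {
    p <- strsplit(pat, "", fixed = TRUE)[[1]]
    hits <- list()
    for (s in seq_len(n - plen + 1)) {
      frag <- tmpl[s:(s + plen - 1)]
      mm <- sum(frag != p | !(frag %in% ORACLE_BASES))
      if (mm <= max_mm) {
        hits[[length(hits) + 1]] <- data.frame(
          strand = strand,
          start_5prime = if (strand == "+") s else s + plen - 1,
          n_mismatches = mm, fp = s, stringsAsFactors = FALSE
        )
      }
    }
    if (length(hits)) do.call(rbind, hits) else NULL
  }
  rc <- paste(rev(chartr("ACGTN", "TGCAN", strsplit(primer, "",
    fixed = TRUE)[[1]])), collapse = "")
  out <- rbind(scan(primer, "+"), scan(rc, "-"))
  if (is.null(out)) {
    return(data.frame(strand = character(), start_5prime = integer(),
                      n_mismatches = integer(), stringsAsFactors = FALSE))
  }
  out <- out[order(out$fp, out$strand), , drop = FALSE]
  out$fp <- NULL
  rownames(out) <- NULL
  out
}

# shared 200-plant simulation for the planted-truth and round-trip checks,
# built once per test run
acceptance_simulation <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_genome(
        simulation_spec(default_ssr_plants(200), n_scaffolds = 8, seed = 11))
    }
    cache
  }
})

# quadratic all-pairs SNP containment oracle
oracle_link_snps <- function(pairs, snps, include_motif = FALSE) {
  lapply(seq_len(nrow(pairs)), function(i) {
    sel <- snps$scaffold_id == pairs$scaffold_id[i] &
      snps$position >= pairs$amp_start[i] &
      snps$position <= pairs$amp_end[i]
    if (!include_motif) {
      sel <- sel & (snps$position < pairs$ssr_start[i] |
                    snps$position > pairs$ssr_end[i])
    }
    sort(unique(snps$position[sel]))
  })
}

# independent self-complementarity check used by the primer-design oracle
oracle_selfcomp <- function(seq, k = 8) {
  n <- nchar(seq)
  if (n < k) return(FALSE)
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  rcs <- vapply(kmers, function(s) {
    paste(rev(chartr("ACGT", "TGCA", strsplit(s, "", fixed = TRUE)[[1]])),
          collapse = "")
  }, character(1))
  any(rcs %in% kmers)
}

# exhaustive primer-pair enumeration oracle: every (forward, reverse)
# candidate combination, scored per the design criteria
oracle_best_pair <- function(seq, ssr_start, ssr_end, params) {
  cand_side <- function(win_lo, win_hi) {
    out <- list()
    for (len in params$primer_len_range[1]:params$primer_len_range[2]) {
      if (win_hi - win_lo + 1 < len) next
      for (s in win_lo:(win_hi - len + 1)) {
        sq <- substr(seq, s, s + len - 1)
        if (grepl("[^ACGT]", sq)) next
        gc <- gc_content(sq)
        if (gc < params$gc_range[1] || gc > params$gc_range[2]) next
        tm <- melting_temperature(sq, params$salt_mM, params$primer_nM)
        if (tm < params$tm_range[1] || tm > params$tm_range[2]) next
        if (oracle_selfcomp(sq)) next
        out[[length(out) + 1]] <- data.frame(
          start = s, len = len, gc = gc, tm = tm,
          penalty = params$w_len * abs(len - params$primer_opt_len) +
            params$w_tm * abs(tm - params$tm_opt) +
            params$w_gc * abs(gc - params$gc_opt),
          stringsAsFactors = FALSE
        )
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  n <- nchar(seq)
  fwd <- cand_side(max(1, ssr_start - params$search_flank), ssr_start - 1)
  rev <- cand_side(ssr_end + 1, min(n, ssr_end + params$search_flank))
  if (is.null(fwd) || is.null(rev)) return(NULL)
  best <- NULL
  for (i in seq_len(nrow(fwd))) {
    for (j in seq_len(nrow(rev))) {
      prod <- (rev$start[j] + rev$len[j] - 1) - fwd$start[i] + 1
      if (prod < params$product_range[1] || prod > params$product_range[2]) next
      cand <- list(penalty = fwd$penalty[i] + rev$penalty[j],
                   product = prod, fstart = fwd$start[i],
                   flen = fwd$len[i], rlen = rev$len[j],
                   fi = i, rj = j)
      if (is.null(best)) { best <- cand; next }
      d <- cand$penalty - best$penalty
      better <- d < -1e-9 ||
        (abs(d) <= 1e-9 && (cand$product < best$product ||
          (cand$product == best$product && (cand$fstart < best$fstart ||
            (cand$fstart == best$fstart && (cand$flen < best$flen ||
              (cand$flen == best$flen && cand$rlen < best$rlen)))))))
      if (better) best <- cand
    }
  }
  best
}
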