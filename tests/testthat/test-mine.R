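# The perfect-SSR scanner, compound merging, motif canonicalisation and the
# mining summary, checked against brute-force oracles and planted truth.

norm_records <- function(d) {
  data.frame(start = as.integer(d$start), end = as.integer(d$end),
             unit = as.character(d$unit),
             unit_length = as.integer(d$unit_length),
             repeat_count = as.integer(d$repeat_count),
             row.names = NULL, stringsAsFactors = FALSE)
}

test_that("threshold boundaries behave as specified", {
  expect_equal(norm_records(find_perfect_ssrs(c(s = "GGAAAAAAAAAACC"))),
               data.frame(start = 3L, end = 12L, unit = "A",
                          unit_length = 1L, repeat_count = 10L,
                          stringsAsFactors = FALSE))
  # (AC)x5 below the dinucleotide threshold of 6
  expect_equal(nrow(find_perfect_ssrs(c(s = "ACACACACAC"))), 0)
  expect_equal(norm_records(find_perfect_ssrs(c(s = "TGAGAGAGAGAGAC"))),
               data.frame(start = 2L, end = 13L, unit = "GA",
                          unit_length = 2L, repeat_count = 6L,
                          stringsAsFactors = FALSE))
  expect_equal(nrow(find_perfect_ssrs(c(s = ""))), 0)
})

test_that("the scanner equals the brute-force oracle on random sequences", {
  for (seed in 1:6) {
    s <- random_seq(3000, seed = seed,
                    n_prob = if (seed %% 2 == 0) 0.01 else 0)
    # salt with repeats so there is something to find
    s <- paste0(s, strrep("AT", 8), random_seq(500, seed + 100),
                strrep("AAG", 6), strrep("A", 12), random_seq(300, seed + 200))
    got <- find_perfect_ssrs(c(x = s))
    want <- oracle_find_ssrs(s)
    expect_equal(norm_records(got), norm_records(want), info = paste("seed", seed))
  }
})

test_that("reported runs are maximal and N-free", {
  s <- paste0(random_seq(2000, 42), strrep("CT", 10), "N",
              strrep("CT", 7), random_seq(200, 43))
  rec <- find_perfect_ssrs(c(x = s))
  expect_gte(nrow(rec), 2)
  for (i in seq_len(nrow(rec))) {
    k <- rec$unit_length[i]
    expect_false(grepl("[^ACGT]", substr(s, rec$start[i], rec$end[i])))
    # extending by one full unit on either side must leave the sequence or
    # mismatch (record spans are whole unit multiples, so units align)
    if (rec$start[i] - k >= 1) {
      expect_false(substr(s, rec$start[i] - k, rec$start[i] - 1) == rec$unit[i])
    }
    if (rec$end[i] + k <= nchar(s)) {
      expect_false(substr(s, rec$end[i] + 1, rec$end[i] + k) == rec$unit[i])
    }
  }
  expect_equal(norm_records(rec), norm_records(oracle_find_ssrs(s)))
})

test_that("raising a threshold only removes records (monotonicity)", {
  s <- paste0(strrep("A", 12), random_seq(800, 7), strrep("AG", 9),
              random_seq(400, 8), strrep("AAT", 7))
  base <- find_perfect_ssrs(c(x = s))
  stricter <- ssr_thresholds(min_repeats = c(`1` = 12, `2` = 8, `3` = 6,
                                             `4` = 5, `5` = 5, `6` = 5))
  sub <- find_perfect_ssrs(c(x = s), stricter)
  key <- function(d) paste(d$start, d$end, d$unit)
  expect_true(all(key(sub) %in% key(base)))
  expect_lte(nrow(sub), nrow(base))
})

test_that("compound merging follows the interruption rule", {
  rec <- find_perfect_ssrs(c(x = paste0(
    strrep("AT", 6),            # 1-12
    "GCTCGTC",                  # gap of 7 clean bases
    strrep("AGA", 5)            # 20-34
  )))
  merged <- merge_compound(rec, max_interruption = 100)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$kind, "compound")
  expect_equal(merged$n_members, 2L)
  expect_equal(merged$start, 1L)
  expect_equal(merged$end, 34L)
})

test_that("a gap of exactly max_interruption + 1 keeps records separate", {
  rec <- tibble::tibble(
    scaffold_id = "s", start = c(1L, 114L), end = c(12L, 128L),
    unit = c("AT", "AGA"), unit_length = c(2L, 3L),
    repeat_count = c(6L, 5L), kind = "perfect", n_members = 1L,
    members = list(NULL, NULL)
  )
  # gap = 114 - 12 - 1 = 101
  merged <- merge_compound(rec, max_interruption = 100)
  expect_equal(merged$kind, c("perfect", "perfect"))
  merged2 <- merge_compound(rec, max_interruption = 101)
  expect_equal(merged2$kind, "compound")
})

test_that("chains agree with the greedy oracle and conserve member counts", {
  set.seed(99)
  for (trial in 1:10) {
    n <- sample(3:12, 1)
    starts <- sort(sample.int(5000, n))
    ends <- starts + sample(10:40, n, replace = TRUE)
    starts[-1] <- pmax(starts[-1], ends[-n] + 1)  # keep sorted, non-nested
    ends <- starts + sample(10:40, n, replace = TRUE)
    rec <- tibble::tibble(
      scaffold_id = "s", start = as.integer(starts), end = as.integer(ends),
      unit = "AT", unit_length = 2L, repeat_count = 6L,
      kind = "perfect", n_members = 1L, members = replicate(n, NULL)
    )
    rec <- rec[order(rec$start), ]
    merged <- merge_compound(rec, max_interruption = 100)
    want <- oracle_chain_ids(rec$start, rec$end, 100)
    expect_equal(nrow(merged), max(want))
    # count conservation
    expect_equal(sum(ifelse(merged$kind == "compound", merged$n_members, 1L)),
                 n)
    sizes <- as.integer(table(want))
    expect_equal(sort(ifelse(merged$kind == "compound", merged$n_members, 1L)),
                 sort(sizes))
  }
  expect_error(merge_compound(tibble::tibble(
    scaffold_id = "s", start = c(50L, 1L), end = c(60L, 12L), unit = "A",
    unit_length = 1L, repeat_count = 10L, kind = "perfect", n_members = 1L,
    members = list(NULL, NULL))), "sorted")
})

test_that("motif normalisation picks the smallest rotation (and strand)", {
  expect_equal(normalize_motif("TA", collapse_strand = FALSE), "AT")
  expect_equal(normalize_motif("A"), "A")
  # brute force over all 6 candidates {GGC,GCG,CGG,GCC,CCG,CGC}
  expect_equal(normalize_motif("GGC", collapse_strand = TRUE), "CCG")
  expect_error(normalize_motif("ATAT"), "primitive")
  # property: result is invariant under rotation and (collapsed) revcomp
  set.seed(5)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    u <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
    if (!oracle_primitive(u)) next
    rots <- vapply(seq_len(k), function(j) {
      paste0(substr(u, j, k), substr(u, 1, j - 1))
    }, character(1))
    expect_length(unique(normalize_motif(rots, collapse_strand = FALSE)), 1)
    expect_equal(normalize_motif(u), normalize_motif(revcomp(u)))
  }
})

test_that("mining summary counts members and truncates the frequency", {
  g <- c(a = paste0(strrep("A", 12), random_seq(100, 11), strrep("AG", 7)),
         b = random_seq(200, 12), c = paste0(random_seq(50, 13), strrep("AAT", 6)))
  rec <- merge_compound(find_perfect_ssrs(g))
  s <- summarize_mining(rec, g)
  expect_equal(s$n_sequences_examined, 3)
  expect_equal(s$total_bp, sum(nchar(g)))
  expect_equal(s$n_ssrs, sum(ifelse(rec$kind == "compound", rec$n_members, 1L)))
  expect_gte(s$n_ssrs, 3)
  expect_equal(s$freq_per_mb, trunc(s$n_ssrs / (s$total_bp / 1e6) * 100) / 100)
  # empty set
  s0 <- summarize_mining(find_perfect_ssrs(c(x = "ACGT")), c(x = "ACGT"))
  expect_equal(s0$n_ssrs, 0)
  expect_equal(s0$freq_per_mb, 0)
  # tidiers
  expect_equal(nrow(tidy(s)), 7)
  expect_equal(glance(s)$n_ssrs, s$n_ssrs)
})
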