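# In silico PCR: site finding vs a sliding-window oracle, amplimer
# enumeration, mismatch budgets and the panel summary.

test_that("verbatim and reverse-complement sites are found", {
  primer <- "ACGTACGTTAGCCGATCGAT"
  tmpl <- paste0(random_seq(60, 1), primer, random_seq(60, 2))
  hits <- find_primer_sites(tmpl, primer, 0)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "+")
  expect_equal(hits$start_5prime, 61L)
  expect_equal(hits$n_mismatches, 0L)

  tmpl2 <- paste0(random_seq(40, 3), revcomp(primer), random_seq(40, 4))
  hits2 <- find_primer_sites(tmpl2, primer, 0)
  expect_equal(nrow(hits2), 1)
  expect_equal(hits2$strand, "-")
  # 5' of a minus-strand site is the rightmost template base of the footprint
  expect_equal(hits2$start_5prime, 40L + nchar(primer))

  # primer longer than template
  expect_equal(nrow(find_primer_sites("ACGTACGTAAA", strrep("ACGT", 5), 0)), 0)
})

test_that("site finding equals the naive sliding-window oracle", {
  for (seed in 1:4) {
    tmpl <- random_seq(5000, seed, n_prob = 0.005)
    primer <- random_seq(20, seed + 50)
    for (pct in c(0, 10, 20)) {
      got <- find_primer_sites(tmpl, primer, pct)
      want <- oracle_primer_sites(tmpl, primer, pct)
      expect_equal(nrow(got), nrow(want), info = paste(seed, pct))
      if (nrow(got) > 0) {
        expect_equal(got$strand, want$strand)
        expect_equal(got$start_5prime, want$start_5prime)
        expect_equal(got$n_mismatches, want$n_mismatches)
      }
    }
  }
})

test_that("a constructed locus yields exactly one amplimer of known length", {
  fwd <- "ACGGATTCAGGCATAACGTT"
  rev <- "TGACCTTGAGACCTTGACAC"
  tmpl <- paste0(random_seq(50, 7), fwd, random_seq(160, 8),
                 revcomp(rev), random_seq(50, 9))
  amps <- predict_amplimers(tmpl, fwd, rev, 0)
  expect_equal(nrow(amps), 1)
  expect_equal(amps$length, nchar(fwd) + 160L + nchar(rev))
  expect_equal(amps$start, 51L)

  # one mismatch in the forward site: invisible at 0%, tolerated at 10%
  tmpl_mm <- tmpl
  substr(tmpl_mm, 55, 55) <- if (substr(tmpl, 55, 55) == "A") "C" else "A"
  expect_equal(nrow(predict_amplimers(tmpl_mm, fwd, rev, 0)), 0)
  amps10 <- predict_amplimers(tmpl_mm, fwd, rev, 10)  # floor(0.10*20) = 2
  expect_equal(nrow(amps10), 1)
  expect_equal(amps10$mm_fwd, 1L)
})

test_that("multiple upstream sites give one amplimer each", {
  fwd <- "ACGGATTCAGGCATAACGTT"
  rev <- "TGACCTTGAGACCTTGACAC"
  tmpl <- paste0(random_seq(30, 10), fwd, random_seq(90, 11), fwd,
                 random_seq(100, 12), revcomp(rev), random_seq(30, 13))
  amps <- predict_amplimers(tmpl, fwd, rev, 0)
  expect_equal(nrow(amps), 2)
  # both end at the same reverse 5' end; lengths differ by the site offset
  expect_equal(length(unique(amps$end)), 1)
  expect_equal(diff(sort(amps$start)), 90L + nchar(fwd))
})

test_that("role swap symmetry and mismatch monotonicity hold", {
  for (seed in 20:22) {
    fwd <- random_seq(18, seed)
    rev <- random_seq(19, seed + 5)
    tmpl <- paste0(random_seq(300, seed + 10), fwd, random_seq(120, seed + 20),
                   revcomp(rev), random_seq(300, seed + 30))
    a1 <- predict_amplimers(tmpl, fwd, rev, 10)
    a2 <- predict_amplimers(tmpl, rev, fwd, 10)
    expect_equal(a1[c("start", "end", "length")], a2[c("start", "end", "length")])
    a0 <- predict_amplimers(tmpl, fwd, rev, 0)
    key <- function(a) paste(a$start, a$end)
    expect_true(all(key(a0) %in% key(a1)))
  }
})

test_that("panel summary counts hits, amplimers and mean alleles", {
  fwd <- "ACGGATTCAGGCATAACGTT"; rev <- "TGACCTTGAGACCTTGACAC"
  g <- c(t1 = paste0(random_seq(40, 31), fwd, random_seq(150, 32),
                     revcomp(rev), random_seq(40, 33)),
         t2 = paste0(random_seq(40, 34), fwd, random_seq(200, 35),
                     revcomp(rev), random_seq(40, 36)))
  panel <- tibble::tibble(
    primer_name = c("P1", "P2"),
    forward_seq = c(fwd, "GGCCGGTTAACCGGTTAACC"),
    reverse_seq = c(rev, "TTGGCCAATTGGCCAATTGG")
  )
  s <- ispcr_summary(panel, g)
  expect_equal(s$n_primers_tested, 2)
  expect_equal(s$n_primers_with_hits, 1)   # P2 binds nowhere
  expect_equal(s$n_amplimers_total, 2)     # one product per template
  expect_equal(s$mean_amplimers_per_hitting_primer, 2)
  expect_equal(s$total_amplimer_bp, sum(s$amplimers$length))
  expect_error(ispcr_summary(panel[0, ], g), "empty")
})

test_that("designed pairs re-find their locus at 0% (cross-module)", {
  spec <- simulation_spec(default_ssr_plants(8), n_scaffolds = 2, seed = 23)
  sim <- simulate_genome(spec)
  rec <- classify_context(find_perfect_ssrs(sim$genome), sim$genes)
  pairs <- assign_primer_names(design_primers(rec, sim$genome))
  expect_gt(nrow(pairs), 0)
  for (i in seq_len(nrow(pairs))) {
    amps <- predict_amplimers(sim$genome[[pairs$scaffold_id[i]]],
                              pairs$forward_seq[i], pairs$reverse_seq[i], 0,
                              template_id = pairs$scaffold_id[i])
    expect_true(any(amps$length == pairs$product_size[i] &
                    amps$start == pairs$amp_start[i]))
  }
})
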