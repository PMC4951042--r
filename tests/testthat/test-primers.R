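# GC, melting temperature, pair design (vs exhaustive oracle), naming and
# amplicon coverage.

test_that("gc_content computes percent G+C and rejects bad input", {
  expect_equal(gc_content("ATGC"), 50)
  expect_equal(gc_content("GGGG"), 100)
  expect_equal(gc_content(c("AT", "GC")), c(0, 100))
  expect_error(gc_content(""), "empty")
  expect_error(gc_content("ACGN"), "only A, C, G, T")
})

test_that("nearest-neighbour Tm matches the frozen thermodynamics oracle", {
  # reference value computed once with an independent nearest-neighbour
  # implementation (unified parameters, 50 mM Na+, 50 nM total strands,
  # 0.368 (N-1) ln[Na+] salt term): 55.4979 degrees C
  expect_equal(melting_temperature("ATGCATGCATGCATGCATGC"), 55.4979,
               tolerance = 0.01)
  # duplex symmetry
  for (seed in 1:5) {
    s <- random_seq(20, seed)
    expect_equal(melting_temperature(s), melting_temperature(revcomp(s)),
                 tolerance = 1e-9)
  }
  # GC monotonicity at fixed length (oracle values 71.78 vs 24.19)
  expect_gt(melting_temperature(paste0(strrep("G", 10), strrep("C", 10))),
            melting_temperature(strrep("AT", 10)))
  expect_equal(melting_temperature(paste0(strrep("G", 10), strrep("C", 10))),
               71.78, tolerance = 0.02)
  # Wallace rule
  expect_equal(melting_temperature("ACGTACGTAC", method = "wallace"),
               2 * 5 + 4 * 5)
  expect_error(melting_temperature("ACGTACG"), "length >= 8")
})

test_that("a clean simulated locus yields a constraint-satisfying pair", {
  spec <- simulation_spec(
    tibble::tibble(unit = "AGA", repeat_count = 6L, context = "intergenic"),
    n_scaffolds = 1, snp_rate = 0, gc_background = 0.5, seed = 42,
    left_pad = 150L, right_pad = 150L
  )
  sim <- simulate_genome(spec)
  ssr <- sim$truth$ssrs[1, ]
  pair <- design_primer_pair(ssr, sim$genome)
  expect_false(is.null(pair))
  expect_gte(pair$product_size, 100)
  expect_lte(pair$product_size, 500)
  expect_lt(pair$amp_start, ssr$start)
  expect_gt(pair$amp_end, ssr$end)
  # primer sequences equal the genome text at the amplicon edges
  g <- sim$genome[[1]]
  expect_equal(pair$forward_seq,
               substr(g, pair$amp_start, pair$amp_start + pair$fwd_len - 1))
  expect_equal(pair$reverse_seq,
               revcomp(substr(g, pair$amp_end - pair$rev_len + 1, pair$amp_end)))
  expect_true(all(c(pair$fwd_tm, pair$rev_tm) >= 50 &
                  c(pair$fwd_tm, pair$rev_tm) <= 60))
  expect_true(all(c(pair$fwd_gc, pair$rev_gc) >= 20 &
                  c(pair$fwd_gc, pair$rev_gc) <= 80))
})

test_that("infeasible geometry returns NULL", {
  # a left flank shorter than the minimum primer length admits no forward
  # candidate at all
  seq <- paste0(random_seq(14, 3), strrep("AG", 8), random_seq(400, 4))
  ssr <- tibble::tibble(scaffold_id = "s1", start = 15L, end = 30L)
  expect_null(design_primer_pair(ssr, c(s1 = seq)))
  # and a scaffold too short on the right for any product in range
  seq2 <- paste0(random_seq(200, 5), strrep("AG", 8), random_seq(20, 6))
  ssr2 <- tibble::tibble(scaffold_id = "s1", start = 201L, end = 216L)
  expect_null(design_primer_pair(ssr2, c(s1 = seq2)))
})

test_that("the designed pair equals the exhaustive-enumeration oracle", {
  params <- design_params(search_flank = 120L)  # keeps the oracle affordable
  for (seed in c(2, 9)) {
    spec <- simulation_spec(
      tibble::tibble(unit = c("AT", "AAG"), repeat_count = c(7L, 5L),
                     context = "intergenic"),
      n_scaffolds = 1, snp_rate = 0, gc_background = 0.5, seed = seed,
      left_pad = 130L, right_pad = 130L
    )
    sim <- simulate_genome(spec)
    for (i in seq_len(nrow(sim$truth$ssrs))) {
      ssr <- sim$truth$ssrs[i, ]
      got <- design_primer_pair(ssr, sim$genome, params)
      want <- oracle_best_pair(sim$genome[[1]], ssr$start, ssr$end, params)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_false(is.null(got))
        expect_equal(got$penalty, want$penalty, tolerance = 1e-6)
        expect_equal(got$amp_start, want$fstart)
        expect_equal(got$product_size, want$product)
        expect_equal(got$fwd_len, want$flen)
        expect_equal(got$rev_len, want$rlen)
      }
    }
  }
})

test_that("naming is per-series, ordered, and input-order independent", {
  pairs <- tibble::tibble(
    scaffold_id = c("s1", "s1", "s2"),
    ssr_start = c(500L, 100L, 50L), ssr_end = c(520L, 120L, 70L),
    context = c("intron", "intergenic", "exon")
  )
  named <- assign_primer_names(pairs)
  expect_equal(named$primer_name[named$ssr_start == 100], "Pd_IG_SSR1")
  expect_equal(named$primer_name[named$ssr_start == 500], "Pd_G_SSR1")
  expect_equal(named$primer_name[named$ssr_start == 50], "Pd_G_SSR2")
  shuffled <- assign_primer_names(pairs[c(3, 1, 2), ])
  expect_equal(named[order(named$primer_name), ],
               shuffled[order(shuffled$primer_name), ])
  empty <- assign_primer_names(pairs[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("coverage merges overlapping amplicons before counting", {
  g <- c(s1 = random_seq(2000, 1), s2 = random_seq(1000, 2))
  pairs <- tibble::tibble(
    scaffold_id = c("s1", "s1", "s2"),
    amp_start = c(101L, 101L, 1L), amp_end = c(300L, 300L, 200L)
  )
  cov <- coverage_summary(pairs, g)
  expect_equal(cov$amplified_bp, 400)  # duplicate counted once
  expect_equal(cov$fraction, 400 / 3000)

  # random-interval fuzz vs a manual sweep union
  set.seed(12)
  starts <- sample.int(1900, 50)
  fuzz <- tibble::tibble(scaffold_id = "s1", amp_start = as.integer(starts),
                         amp_end = as.integer(starts + sample(50:200, 50,
                                                              replace = TRUE)))
  fuzz$amp_end <- pmin(fuzz$amp_end, 2000L)
  covered <- rep(FALSE, 2000)
  for (i in seq_len(nrow(fuzz))) {
    covered[fuzz$amp_start[i]:fuzz$amp_end[i]] <- TRUE
  }
  expect_equal(coverage_summary(fuzz, g["s1"])$amplified_bp, sum(covered))
})
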