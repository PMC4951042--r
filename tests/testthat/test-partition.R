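# Context classification and the compartment tables.

toy_genes <- function() {
  tibble::tibble(
    gene_id = "g1", scaffold_id = "s1", start = 100L, end = 500L,
    product = "kinase",
    exons = list(tibble::tibble(start = c(100L, 300L), end = c(200L, 500L)))
  )
}

toy_rec <- function(start, end, unit = "AT", scaffold = "s1") {
  tibble::tibble(
    scaffold_id = scaffold, start = as.integer(start), end = as.integer(end),
    unit = unit, unit_length = nchar(unit), repeat_count = 6L,
    kind = "perfect", n_members = 1L, members = list(NULL)
  )
}

test_that("context assignment follows the start rule", {
  genes <- toy_genes()
  expect_equal(classify_context(toy_rec(150, 170), genes)$context, "exon")
  expect_equal(classify_context(toy_rec(600, 620), genes)$context, "intergenic")
  expect_equal(classify_context(toy_rec(250, 280), genes)$context, "intron")
  # straddles the exon/intron boundary: start wins
  expect_equal(classify_context(toy_rec(195, 230), genes)$context, "exon")
  # majority rule flips the same record to intron (6 exon bp vs 30 intron bp)
  expect_equal(classify_context(toy_rec(195, 230), genes,
                                rule = "majority")$context, "intron")
  # no genes at all
  expect_equal(classify_context(toy_rec(150, 170), genes[0, ])$context,
               "intergenic")
})

test_that("context counts are conserved on arbitrary inputs", {
  set.seed(21)
  genes <- toy_genes()
  starts <- sample.int(1000, 60)
  rec <- dplyr::bind_rows(lapply(starts, function(s) toy_rec(s, s + 11)))
  cl <- classify_context(rec, genes)
  expect_equal(sum(table(cl$context)), nrow(rec))
  expect_true(all(cl$context[cl$start > 500 | cl$start < 100] == "intergenic"))
})

test_that("compartment summary recovers planted per-context counts", {
  spec <- simulation_spec(default_ssr_plants(16), n_scaffolds = 2, seed = 5)
  sim <- simulate_genome(spec)
  rec <- classify_context(find_perfect_ssrs(sim$genome), sim$genes)
  expect_equal(rec$context, sim$truth$ssrs$context)
  cs <- context_summary(rec, sim$genes, sim$genome)
  truth_tab <- table(factor(sim$truth$ssrs$context,
                            c("exon", "intron", "intergenic")))
  expect_equal(unname(cs$counts), as.integer(truth_tab))
  # frequency identity: counts reconstruct from freq * Mb within rounding
  comp <- cs$compartments
  recon <- comp$freq_per_mb_raw[comp$compartment != "total"] *
    comp$bp[comp$compartment != "total"] / 1e6
  expect_equal(sum(recon), comp$n[comp$compartment == "total"], tolerance = 1e-9)
  expect_equal(cs$genic_bp + cs$intergenic_bp, sum(nchar(sim$genome)))
})

test_that("repeat-count bins match a brute-force histogram", {
  set.seed(77)
  n <- 1000
  lens <- sample(c(1L, 2L, 3L, 4L, 5L, 6L), n, replace = TRUE)
  counts <- as.integer(pmax(5, rpois(n, 12)))
  counts[lens == 1] <- pmax(counts[lens == 1], 10L)
  rec <- tibble::tibble(
    scaffold_id = "s1", start = seq_len(n) * 500L,
    end = seq_len(n) * 500L + lens * counts - 1L,
    unit = vapply(lens, function(k) strrep("A", k), character(1)),  # unit text unused here
    unit_length = lens, repeat_count = counts, kind = "perfect",
    n_members = 1L, members = replicate(n, NULL),
    context = sample(c("exon", "intron", "intergenic"), n, replace = TRUE)
  )
  tab <- bin_by_repeat_count(rec, "non_triplet")
  edges <- c(5, 10, 16, 21, 26, 31, 36, 46, 56, 71, 101, 151, 201, 351)
  labels <- paste0(edges[-length(edges)], "-", edges[-1] - 1)
  for (ul in c(1L, 2L, 4L, 5L)) {
    for (ctx in c("genic", "intergenic")) {
      sel <- rec$unit_length == ul & rec$repeat_count < 351 &
        (if (ctx == "genic") rec$context != "intergenic"
         else rec$context == "intergenic")
      want <- table(cut(rec$repeat_count[sel], edges, right = FALSE,
                        labels = labels))
      cls <- c("mono", "di", "tri", "tetra", "penta", "hexa")[ul]
      got <- tab$n[tab$unit_class == cls & tab$context == ctx]
      expect_equal(got, as.integer(want))
    }
  }
  # column sums conserve the records below the last edge
  expect_equal(sum(tab$n),
               sum(rec$unit_length %in% c(1, 2, 4, 5) & rec$repeat_count < 351))
})

test_that("single records land in the documented cells", {
  r1 <- toy_rec(600, 611, unit = "A")
  r1$unit_length <- 1L; r1$repeat_count <- 12L; r1$context <- "intron"
  t1 <- bin_by_repeat_count(r1, "non_triplet")
  expect_equal(t1$n[t1$bin == "10-15" & t1$unit_class == "mono" &
                    t1$context == "genic"], 1L)
  expect_equal(sum(t1$n), 1L)

  r2 <- toy_rec(600, 620, unit = "AAG")
  r2$unit_length <- 3L; r2$repeat_count <- 7L; r2$context <- "intergenic"
  t2 <- bin_by_repeat_count(r2, "triplet")
  expect_equal(t2$n[t2$bin == "5-9" & t2$unit_class == "tri" &
                    t2$context == "intergenic"], 1L)
  expect_equal(sum(t2$n), 1L)
})

test_that("motif presence sets partition observed motifs", {
  rec <- dplyr::bind_rows(
    toy_rec(600, 620, unit = "ACGT"), toy_rec(700, 720, unit = "ACGT"),
    toy_rec(800, 820, unit = "AACG")
  )
  rec$unit_length <- 4L
  rec$context <- c("intron", "intergenic", "exon")
  sets <- motif_presence_sets(rec, unit_lengths = 4)
  expect_equal(sets$shared, normalize_motif("ACGT"))
  expect_equal(sets$genic_only, normalize_motif("AACG"))
  expect_equal(sets$intergenic_only, character(0))
  # pairwise disjoint, union covers everything
  expect_length(intersect(sets$shared, sets$genic_only), 0)

  rec$context <- c("intron", "intron", "intron")
  sets2 <- motif_presence_sets(rec, unit_lengths = 4)
  expect_equal(sets2$shared, character(0))

  # planted overlap: k motifs shared by construction
  recs <- dplyr::bind_rows(
    toy_rec(100, 120, "AAAC"), toy_rec(200, 220, "AAAC"),
    toy_rec(300, 320, "AAAG"), toy_rec(400, 420, "AAAG"),
    toy_rec(500, 520, "AATC"), toy_rec(600, 620, "AGGG")
  )
  recs$unit_length <- 4L
  recs$context <- c("exon", "intergenic", "intron", "intergenic",
                    "exon", "intergenic")
  s3 <- motif_presence_sets(recs, unit_lengths = 4)
  expect_length(s3$shared, 2)
  expect_length(s3$genic_only, 1)
  expect_length(s3$intergenic_only, 1)
})
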