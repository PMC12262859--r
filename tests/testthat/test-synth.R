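test_that("generated references are reproducible and arm arithmetic holds", {
  g1 <- generate_reference(c(a = 1e5, b = 1e5), seed = 7)
  g2 <- generate_reference(c(a = 1e5, b = 1e5), seed = 7)
  expect_identical(g1$sequences, g2$sequences)

  g3 <- generate_reference(c(a = 1e5, b = 1e5), seed = 8)
  expect_false(identical(g1$sequences, g3$sequences))

  ga <- generate_reference(c(a = 1e5), arm_fraction = 0.4, seed = 1)
  expect_equal(ga$arm_table[arm == "p", .(start, end)],
               data.table(start = 0L, end = 40000L))
  expect_equal(ga$arm_table[arm == "q", .(start, end)],
               data.table(start = 40000L, end = 100000L))

  ## mouse-like 21 acrocentric chromosomes -> 21 q arms
  mm <- generate_reference(setNames(rep(2000, 21), paste0("chr", 1:21)),
                           arm_fraction = 0, seed = 2)
  expect_equal(nrow(mm$arm_table), 21L)
  expect_true(all(mm$arm_table$arm == "q"))

  expect_error(generate_reference(c(a = 1000), seed = 1), "2000")
  expect_error(generate_reference(c(a = 1e5)), "seed")
})

test_that("FASTA round trip preserves sequences", {
  g <- generate_reference(c(chrA = 5000, chrB = 3000), seed = 3)
  fa <- tempfile(fileext = ".fa")
  write_genome_fasta(g, fa)
  g2 <- read_genome_fasta(fa)
  expect_identical(g2$sequences, g$sequences)
  unlink(fa)
})

test_that("sampled lengths respect support, mode and the comb", {
  prof <- host_cfdna_profile()
  x <- sample_fragment_lengths(prof, 1e5, seed = 42)
  expect_true(all(x >= prof$support[1] & x <= prof$support[2]))
  expect_identical(histogram_mode(size_histogram(x)), 167L)

  ## symmetric kernel, no comb: pmf peaks exactly at the mode and the
  ## empirical argmax converges to it
  sym <- size_profile(mode = 150, comb_depth = 0, sd_below = 12,
                      sd_above = 12, dinucleosome_weight = 0)
  pmf <- length_pmf(sym)
  expect_identical(pmf[which.max(prob), length_bp], 150L)
  y <- sample_fragment_lengths(sym, 1e6, seed = 1)
  expect_lte(abs(histogram_mode(size_histogram(y)) - 150L), 1L)

  ## identical seeds give identical draws
  expect_identical(sample_fragment_lengths(prof, 1000, seed = 5),
                   sample_fragment_lengths(prof, 1000, seed = 5))

  expect_error(sample_fragment_lengths(prof, 0), ">= 1")
  expect_error(size_profile(support = c(100, 100)), "support")
  expect_error(size_profile(mode = 40, support = c(50, 500)), "mode")
})

test_that("tumor profile is short-fragment enriched relative to control", {
  tum <- sample_fragment_lengths(ctdna_profile(), 1e5, seed = 9)
  ctl <- sample_fragment_lengths(host_cfdna_profile(), 1e5, seed = 9)
  expect_gt(compute_s2l(tum)$ratio, compute_s2l(ctl)$ratio)
  expect_identical(histogram_mode(size_histogram(tum)), 143L)
})

test_that("fsd effects strictly enrich the targeted length range", {
  prof <- host_cfdna_profile()
  ef <- list(fsd_effect("host_cfdna", "cell_line", "X", c(220, 309), 2.0))
  base <- sample_fragment_lengths(prof, 1e5, seed = 10)
  enr <- sample_fragment_lengths(prof, 1e5, seed = 10, effects = ef)
  in_range <- function(v) mean(v >= 220 & v <= 309)
  expect_gt(in_range(enr), in_range(base))
  ## pmf-level check: enrichment is exact at the distribution level
  p0 <- length_pmf(prof)
  p1 <- length_pmf(prof, ef)
  r0 <- p0[length_bp >= 220 & length_bp <= 309, sum(prob)]
  r1 <- p1[length_bp >= 220 & length_bp <= 309, sum(prob)]
  expect_equal(r1, 2 * r0 / (1 + r0), tolerance = 1e-12)
})

test_that("cohort generation books mixtures, truth and verdicts correctly", {
  genomes <- small_test_genomes()
  design <- small_test_design()
  co <- generate_cohort(design, genomes$host, genomes$graft, seed = 77)

  expect_equal(nrow(co$sample_sheet), 15L)
  expect_equal(sum(co$sample_sheet$type == "cdx"), 12L)
  expect_equal(sum(co$sample_sheet$type == "control"), 3L)

  ## per-sample graft share matches the drawn fraction within binomial error
  mix <- co$fragments[, .(graft = sum(species == "graft"), n = .N),
                      by = sample_id]
  mix <- merge(mix, co$sample_sheet, by = "sample_id")
  for (i in seq_len(nrow(mix))) {
    f <- mix$ctdna_fraction[i]
    sd3 <- 3 * sqrt(mix$n[i] * f * (1 - f))
    expect_lte(abs(mix$graft[i] - mix$n[i] * f), max(sd3, 1))
  }
  expect_true(all(mix[type == "control", graft] == 0))

  ## support bounds and determinism
  expect_true(all(co$fragments$length_bp >= 50 &
                    co$fragments$length_bp <= 500))
  co2 <- generate_cohort(design, genomes$host, genomes$graft, seed = 77)
  expect_identical(co$fragments, co2$fragments)
  expect_identical(co$verdicts, co2$verdicts)

  ## one verdict per (read, method)
  expect_equal(anyDuplicated(co$verdicts, by = c("read_id", "method")), 0L)
})

test_that("noiseless classifiers reproduce the truth labels", {
  genomes <- small_test_genomes()
  design <- small_test_design(
    classifier_rates = list(A = c(fnr = 0, fpr = 0),
                            B = c(fnr = 0, fpr = 0)))
  co <- generate_cohort(design, genomes$host, genomes$graft, seed = 5)
  v <- merge(co$verdicts, co$fragments[, .(read_id, species)],
             by = "read_id")
  expect_true(all(v[species == "graft", call] == "human"))
  expect_true(all(v[species == "host", call] == "mouse"))
  expect_equal(nrow(co$control_human_alignments), 0L)
})

test_that("copy-number weights scale placement density as expected", {
  genomes <- small_test_genomes()
  graft <- genomes$graft
  ## double one region's weight; count midpoints per bin
  w <- data.table(cell_line = "A549", chrom = "gchr1",
                  start = 0L, end = 50000L, weight = 2)
  design <- small_test_design(
    ctdna_fraction_range = c(0.49, 0.51),
    fragments_per_sample = 50000L,
    replicates_per_group = 1L, controls = 0L)
  co <- generate_cohort(design, genomes$host, graft, seed = 13,
                        cna_profiles = rbind(
                          w, copy(w)[, cell_line := "M97H"]))
  grid <- bin_grid(graft, 50000)
  gf <- co$fragments[species == "graft" & sample_id == "A549_pancreas_1"]
  cnt <- bin_counts(gf, grid)
  boosted <- cnt[chrom == "gchr1" & start == 0, count]
  others <- cnt[!(chrom == "gchr1" & start == 0), count]
  expected <- 2 * mean(others)
  expect_lt(abs(boosted - expected), 3 * sqrt(expected))
})
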