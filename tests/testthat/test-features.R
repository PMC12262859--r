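test_that("S2L ratio uses inclusive bounds and errors on empty long class", {
  expect_equal(compute_s2l(c(rep(100, 10), rep(180, 5)))$ratio, 2)
  ## boundary lengths 80/160 are short, 161/200 long
  expect_equal(compute_s2l(c(80, 160, 161, 200))$ratio, 1)
  expect_equal(compute_s2l(c(79, 201, 161))$ratio, 0)
  expect_error(compute_s2l(c(100, 150)), "undefined")
  ## strict monotonicity in added short fragments
  base <- c(rep(120, 10), rep(180, 10))
  expect_gt(compute_s2l(c(base, 90))$ratio, compute_s2l(base)$ratio)
})

test_that("size histogram mode and tie-breaking", {
  expect_identical(histogram_mode(size_histogram(c(167, 167, 150))), 167L)
  expect_identical(
    histogram_mode(size_histogram(rep(c(150, 167), each = 3))), 150L)
  expect_error(size_histogram(numeric(0)), "empty")
  h <- size_histogram(c(100, 100, 102))
  expect_equal(h[length_bp == 101, count], 0L)
  expect_equal(sum(h$fraction), 1)
})

test_that("periodicity estimation recovers comb spacings", {
  comb10 <- rep(seq(97, 157, by = 10), times = 20)
  expect_equal(estimate_periodicity(size_histogram(comb10)), 10)
  comb7 <- rep(seq(95, 158, by = 7), times = 20)
  expect_equal(estimate_periodicity(size_histogram(comb7)), 7)
  expect_error(estimate_periodicity(size_histogram(rep(120, 5))),
               "undefined period")
  ## generator truth recovery at depth
  x <- sample_fragment_lengths(host_cfdna_profile(), 1e6, seed = 31)
  expect_lt(abs(estimate_periodicity(size_histogram(x)) - 10), 1)
})

test_that("motif spectra follow the stated end/breakpoint conventions", {
  ## homopolymer reference: EDM mass splits A-motif / T-motif
  gA <- toy_genome(c(c1 = strrep("A", 100)))
  fr <- toy_fragments("c1", c(10, 30), c(40, 70))
  sp <- compute_motif_spectrum(fr, gA, "EDM")
  expect_equal(nrow(sp), 4096L)
  expect_equal(sp[motif == "AAAAAA", frequency], 0.5)
  expect_equal(sp[motif == "TTTTTT", frequency], 0.5)
  expect_equal(sum(sp$frequency), 1, tolerance = 1e-9)

  ## hand-checkable periodic reference, fragment [6, 14)
  g <- toy_genome(c(c1 = "ACGTACGTACGTACGTACGT"))
  f1 <- toy_fragments("c1", 6, 14)
  edm <- compute_motif_spectrum(f1, g, "EDM")
  ## upstream ref[6,12) = GTACGT; downstream revcomp(ref[8,14)) =
  ## revcomp(ACGTAC) = GTACGT
  expect_equal(edm[motif == "GTACGT", frequency], 1)
  bpm <- compute_motif_spectrum(f1, g, "BPM")
  ## upstream ref[3,9) = TACGTA; downstream revcomp(ref[11,17)) =
  ## revcomp(TACGTA) = TACGTA
  expect_equal(bpm[motif == "TACGTA", frequency], 1)

  ## BPM windows running off-chromosome are skipped and logged
  f2 <- toy_fragments("c1", c(1, 6), c(19, 14))
  bpm2 <- compute_motif_spectrum(f2, g, "BPM")
  expect_equal(attr(bpm2, "n_skipped"), 2L)
  expect_equal(attr(bpm2, "n_counted"), 2L)
})

test_that("motif counts equal a brute-force per-fragment recount", {
  g <- generate_reference(c(m1 = 5000, m2 = 4000), seed = 17)
  set.seed(18)
  n <- 300L
  chrom <- sample(c("m1", "m2"), n, TRUE)
  start <- sample.int(3500L, n)
  fr <- toy_fragments(chrom, start, start + sample(60:400, n, TRUE))
  for (flavor in c("EDM", "BPM")) {
    got <- compute_motif_spectrum(fr, g, flavor)
    want <- brute_motifs(fr, g, flavor)
    tab <- table(factor(want, levels = all_6mers()))
    expect_equal(got$count, as.integer(tab), ignore_attr = TRUE)
    expect_equal(sum(got$frequency), 1, tolerance = 1e-9)
  }
})

test_that("N-containing motifs are excluded from the denominator", {
  g <- toy_genome(c(c1 = paste0(strrep("A", 20), "N", strrep("A", 30))))
  fr <- toy_fragments("c1", c(18, 2), c(40, 10))  # first upstream spans N
  sp <- compute_motif_spectrum(fr, g, "EDM")
  expect_equal(attr(sp, "n_counted"), 3L)
  expect_equal(sum(sp$frequency), 1, tolerance = 1e-9)
})

test_that("spectra are invariant on a reverse-complement-symmetric genome", {
  seqs <- c(c1 = "ACGTTGCAACGTACGTTGCA")
  g <- toy_genome(seqs)
  grc <- toy_genome(c(c1 = brute_revcomp(seqs[["c1"]])))
  L <- nchar(seqs[["c1"]])
  fr <- toy_fragments("c1", c(2, 7), c(12, 15))
  ## mirrored fragments on the reverse-complemented genome
  fr_rc <- toy_fragments("c1", L - c(12, 15), L - c(2, 7))
  for (flavor in c("EDM", "BPM")) {
    a <- compute_motif_spectrum(fr, g, flavor)
    b <- compute_motif_spectrum(fr_rc, grc, flavor)
    expect_equal(a$frequency, b$frequency)
  }
})

test_that("FSD dimensions match the arm conventions", {
  expect_equal(length(mouse_arms()), 21L)
  expect_equal(length(fsd_feature_names(mouse_arms())), 1407L)
  expect_equal(length(human_arms()), 40L)
  expect_equal(length(fsd_feature_names(human_arms())), 2680L)
  expect_equal(length(human_arms(exclude_xp = FALSE)), 41L)
  expect_equal(nrow(fsd_bins()), 67L)
  expect_error(fsd_bins(65, 400, 5), "whole number")
})

test_that("FSD fractions normalise per arm with inclusive 5 bp bins", {
  at <- data.table(chrom = c("c1", "c1"), arm = c("p", "q"),
                   start = c(0L, 500L), end = c(500L, 1000L))
  ## single fragment of length 67 on the p arm
  f <- toy_fragments("c1", 10, 77)
  fsd <- compute_fsd(f, at)
  expect_equal(nrow(fsd), 134L)
  expect_equal(fsd[arm == "c1p" & bin_start == 65, fraction], 1)
  expect_equal(fsd[arm == "c1p", sum(fraction)], 1)
  expect_equal(attr(fsd, "empty_arms"), "c1q")

  ## boundary lengths: 64 excluded, 65/399 included, 400 excluded
  f2 <- toy_fragments("c1", c(0, 0, 0, 600), c(64, 65, 399, 1000))
  fsd2 <- compute_fsd(f2, at)
  expect_equal(fsd2[arm == "c1p" & bin_start == 65, fraction], 0.5)
  expect_equal(fsd2[arm == "c1p" & bin_start == 395, fraction], 0.5)
  expect_equal(fsd2[arm == "c1q", sum(fraction)], 0)

  ## arm assignment by start position
  f3 <- toy_fragments("c1", 499, 599)  # starts on p, crosses into q
  fsd3 <- compute_fsd(f3, at)
  expect_equal(fsd3[arm == "c1p" & bin_start == 100, fraction], 1)
})

test_that("FSD is order-invariant and pooling-consistent", {
  g <- small_test_genomes()$host
  set.seed(8)
  n <- 2000L
  f <- toy_fragments(sample(names(g$seqlengths), n, TRUE),
                     sample.int(1e5, n), integer(n))
  f[, end := start + sample(65:399, n, TRUE)]
  f[, length_bp := end - start]
  a <- compute_fsd(f, g)
  b <- compute_fsd(f[sample.int(n)], g)
  expect_equal(a, b, ignore_attr = TRUE)

  ## computing on pooled fragments equals count-weighted per-arm average
  f[, sample_id := rep(c("r1", "r2"), length.out = n)]
  pooled <- compute_fsd(f, g)
  p1 <- compute_fsd(f[sample_id == "r1"], g)
  p2 <- compute_fsd(f[sample_id == "r2"], g)
  w1 <- f[sample_id == "r1", .N, by = .(arm = paste0(chrom, "q"))]
  for (an in unique(pooled$arm)) {
    n1 <- nrow(f[sample_id == "r1" & paste0(chrom, "q") == an])
    n2 <- nrow(f[sample_id == "r2" & paste0(chrom, "q") == an])
    mix <- (p1[arm == an, fraction] * n1 + p2[arm == an, fraction] * n2) /
      (n1 + n2)
    expect_equal(pooled[arm == an, fraction], mix, tolerance = 1e-12)
  }
})
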