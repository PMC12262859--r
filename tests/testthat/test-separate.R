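test_that("blacklist support rule: two samples or two methods", {
  reg <- function(s, m, start, end)
    data.table(chrom = "c1", start = start, end = end,
               sample_id = s, method = m)
  ## two distinct samples, one method -> blacklisted
  bl <- build_blacklist(rbind(reg("s1", "A", 100L, 200L),
                              reg("s2", "A", 150L, 250L)))
  expect_equal(bl, data.table(chrom = "c1", start = 150L, end = 200L),
               ignore_attr = TRUE)
  ## one sample, two methods -> blacklisted
  bl2 <- build_blacklist(rbind(reg("s1", "A", 100L, 200L),
                               reg("s1", "B", 100L, 200L)))
  expect_equal(bl2, data.table(chrom = "c1", start = 100L, end = 200L),
               ignore_attr = TRUE)
  ## single source -> empty
  bl3 <- build_blacklist(reg("s1", "A", 100L, 200L))
  expect_equal(nrow(bl3), 0L)
  ## unknown chromosome rejected by name
  g <- toy_genome(c(c1 = "ACGTACGTAC"))
  expect_error(build_blacklist(reg("s1", "A", 1L, 2L)[, chrom := "cX"],
                               genome = g), "cX")
})

test_that("blacklist equals a per-base brute-force counter on random toys", {
  chrom_len <- c(t1 = 100000L)
  for (seed in 1:4) {
    set.seed(seed)
    n <- 40L
    start <- sample.int(99000L, n) - 1L
    regions <- data.table(chrom = "t1", start = start,
                          end = start + sample(200:1500, n, replace = TRUE),
                          sample_id = sample(paste0("s", 1:3), n, TRUE),
                          method = sample(c("A", "B"), n, TRUE))
    got <- build_blacklist(regions)
    want <- brute_blacklist(regions, chrom_len)
    expect_equal(as.data.frame(got), as.data.frame(want),
                 ignore_attr = TRUE)
  }
})

test_that("human-call merging is a union over methods", {
  v <- data.table(read_id = c(1L, 2L, 2L, 3L, 3L, 4L),
                  method = c("A", "A", "B", "A", "B", "B"),
                  call = c("human", "human", "human", "mouse", "mouse",
                           "both"))
  expect_setequal(merge_human_calls(v), c(1L, 2L))
  ## conflicting duplicate verdicts error
  bad <- rbind(v, data.table(read_id = 1L, method = "A", call = "mouse"))
  expect_error(merge_human_calls(bad), "conflicting")
  ## consistent duplicates are tolerated
  dup <- rbind(v, v[1])
  expect_setequal(merge_human_calls(dup), c(1L, 2L))
})

test_that("alignment filter applies MAPQ >= 30 and any-overlap removal", {
  reads <- toy_fragments("c1", c(0, 100, 200, 300), c(60, 160, 260, 360),
                         mapq = c(29L, 30L, 60L, 60L))
  bl <- structure(data.table(chrom = "c1", start = 259L, end = 400L),
                  class = c("blacklist", "data.table", "data.frame"))
  kept <- filter_alignments(reads, bl, 30L)
  ## mapq 29 dropped; 1 bp overlap (260 > 259) dropped; [300,360) dropped
  expect_equal(kept$start, 100L)
  ## empty blacklist: only the MAPQ rule
  kept2 <- filter_alignments(reads, NULL, 30L)
  expect_equal(kept2$start, c(100L, 200L, 300L))
  ## monotonicity: a larger blacklist never retains more
  bl_big <- structure(data.table(chrom = "c1", start = 0L, end = 400L),
                      class = class(bl))
  expect_lte(nrow(filter_alignments(reads, bl_big, 30L)), nrow(kept))
})

test_that("fragment inference takes the outer span and length bounds", {
  rp <- data.table(
    read_id = c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 6L, 6L),
    mate = c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L, 1L, 2L),
    chrom = c("c1", "c1", "c1", "c1", "c1", "c1", "c1", "c1", "c1",
              "c1", "c2"),
    start = c(1000L, 1100L, 0L, 20L, 5000L, 5951L, 0L, 500L, 0L, 0L, 0L),
    end = c(1080L, 1167L, 49L, 49L, 5100L, 6000L, 600L, 1001L, 100L,
            100L, 100L),
    mapq = 60L)
  fr <- infer_fragments(rp)
  ## pair 1: outer span 1000-1167 -> 167 bp
  expect_equal(fr[read_id == 1L, end - start], 167L)
  ## 49 bp dropped, exactly 1000 bp kept, 1001 bp dropped
  expect_false(2L %in% fr$read_id)
  expect_false(4L %in% fr$read_id)
  expect_true(3L %in% fr$read_id)
  expect_equal(attr(fr, "n_orphan"), 1L)       # read 5
  expect_equal(attr(fr, "n_discordant"), 1L)   # read 6
})

test_that("fragment inference boundary lengths 49/50/1000/1001", {
  mk <- function(id, len) data.table(
    read_id = id, mate = 1:2, chrom = "c1",
    start = c(0L, max(0L, len - 10L)), end = c(min(10L, len), len),
    mapq = 60L)
  rp <- rbind(mk(1L, 49L), mk(2L, 50L), mk(3L, 1000L), mk(4L, 1001L))
  fr <- infer_fragments(rp)
  expect_setequal(fr$read_id, c(2L, 3L))
  expect_equal(attr(fr, "n_out_of_range"), 2L)
})

test_that("round trip fragments -> read pairs -> fragments is lossless", {
  set.seed(3)
  f <- toy_fragments("c1", start = sample.int(1e4, 50),
                     end = integer(50))
  f[, end := start + sample(60:400, 50, replace = TRUE)]
  f[, length_bp := end - start]
  rp <- fragments_to_read_pairs(f)
  fr <- infer_fragments(rp)
  setorder(fr, read_id)
  expect_equal(fr[, .(read_id, chrom, start, end)],
               f[, .(read_id, chrom, start, end)], ignore_attr = TRUE)
})

test_that("pooling is additive and grouping yields four representatives", {
  sheet <- CJ(cell_line = c("A", "B"), site = c("x", "y"), rep = 1:3)
  sheet[, sample_id := paste(cell_line, site, rep, sep = "_")]
  frags <- rbindlist(lapply(sheet$sample_id, function(s)
    toy_fragments("c1", 1:10, 61:70, sample_id = s)))
  pooled <- pool_replicates(frags, sheet)
  expect_equal(length(unique(pooled$group)), 4L)
  expect_equal(nrow(pooled), nrow(frags))
  expect_equal(pooled[, .N, by = group]$N, rep(30L, 4L))
  ## single sample pools to itself
  one <- pool_replicates(frags[sample_id == "A_x_1"], sheet)
  expect_equal(nrow(one), 10L)
})

test_that("downsampling is exact, distinct and seeded", {
  f <- toy_fragments("c1", 0:999, 100:1099)
  d <- downsample_fragments(f, 100L, seed = 1)
  expect_equal(nrow(d), 100L)
  expect_equal(anyDuplicated(d$read_id), 0L)
  expect_identical(d, downsample_fragments(f, 100L, seed = 1))
  expect_warning(all_f <- downsample_fragments(f, 10000L, seed = 1),
                 "exceeds")
  expect_equal(nrow(all_f), 1000L)
  expect_error(downsample_fragments(f, 0L), ">= 1")
})

test_that("noiseless separation recovers the truth set exactly", {
  genomes <- small_test_genomes()
  design <- small_test_design(
    classifier_rates = list(A = c(fnr = 0, fpr = 0),
                            B = c(fnr = 0, fpr = 0)))
  co <- generate_cohort(design, genomes$host, genomes$graft, seed = 21)
  human_ids <- merge_human_calls(co$verdicts)
  bl <- build_blacklist(co$control_human_alignments)
  iso <- isolate_ctdna(co$graft_realignments, human_ids, bl,
                       min_mapq = 30L, min_len = 50L, max_len = 1000L)
  ## oracle: truth graft fragments passing the stated filters
  truth <- co$fragments[species == "graft" & mapq >= 30 &
                          length_bp >= 50 & length_bp <= 1000]
  expect_setequal(iso$read_id, truth$read_id)
  expect_identical(
    iso[order(read_id), .(chrom, start, end)],
    truth[order(read_id), .(chrom, start, end)])
})
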