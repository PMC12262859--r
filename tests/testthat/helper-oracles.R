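## Shared fixtures and independent brute-force oracles.

library(data.table)

## Tiny deterministic genome from an explicit sequence string.
toy_genome <- function(seqs, arm_table = NULL, species = "toy") {
  if (is.null(arm_table))
    arm_table <- data.table(chrom = names(seqs), arm = "q", start = 0L,
                            end = nchar(seqs))
  genome_model(species, seqs, arm_table)
}

## Fragment table from parallel vectors.
toy_fragments <- function(chrom, start, end, mapq = 60L,
                          sample_id = "s1", read_id = NULL) {
  n <- max(length(chrom), length(start), length(end))
  data.table(sample_id = rep_len(sample_id, n),
             read_id = if (is.null(read_id)) seq_len(n) else read_id,
             chrom = rep_len(chrom, n), start = as.integer(start),
             end = as.integer(end),
             length_bp = as.integer(end) - as.integer(start),
             mapq = rep_len(as.integer(mapq), n))
}

## Brute-force folded AUC by explicit pair enumeration.
brute_auc <- function(values, labels) {
  lv <- unique(labels)
  a <- values[labels == lv[1]]
  b <- values[labels == lv[2]]
  wins <- 0
  for (x in a) for (y in b) wins <- wins + (x > y) + 0.5 * (x == y)
  auc <- wins / (length(a) * length(b))
  max(auc, 1 - auc)
}

## Brute-force per-base blacklist support counter on a small genome.
## regions: data.table(chrom, start, end, sample_id, method) already
## merged or not (per-base counting makes merging irrelevant).
brute_blacklist <- function(regions, chrom_len,
                            min_samples = 2L, min_methods = 2L) {
  out <- list()
  for (cn in names(chrom_len)) {
    L <- chrom_len[[cn]]
    rs <- regions[chrom == cn]
    nsam <- nmet <- integer(L)
    srcs <- split(rs, by = c("sample_id", "method"))
    srcs <- srcs[vapply(srcs, nrow, integer(1)) > 0L]
    covs <- lapply(srcs, function(src) {
      cov <- logical(L)
      for (i in seq_len(nrow(src)))
        cov[(src$start[i] + 1L):src$end[i]] <- TRUE
      cov
    })
    sams <- vapply(srcs, function(s) s$sample_id[1], character(1))
    mets <- vapply(srcs, function(s) s$method[1], character(1))
    for (p in seq_len(L)) {
      hit <- vapply(covs, function(cv) cv[p], logical(1))
      nsam[p] <- length(unique(sams[hit]))
      nmet[p] <- length(unique(mets[hit]))
    }
    black <- nsam >= min_samples | nmet >= min_methods
    if (any(black)) {
      r <- rle(black)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- which(r$values)
      out[[cn]] <- data.table(chrom = cn, start = starts[keep] - 1L,
                              end = ends[keep])
    }
  }
  if (length(out) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer()))
  rbindlist(out)
}

## Minimal reverse complement for the motif oracle.
brute_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## Brute-force motif recount: loop over fragments with substr.
brute_motifs <- function(fragments, genome, flavor) {
  res <- character(0)
  for (i in seq_len(nrow(fragments))) {
    cn <- fragments$chrom[i]
    s <- fragments$start[i]
    e <- fragments$end[i]
    seq_c <- genome$sequences[[cn]]
    L <- nchar(seq_c)
    if (flavor == "EDM") {
      if (s + 6L <= L) res <- c(res, substr(seq_c, s + 1L, s + 6L))
      if (e - 6L >= 0L) res <- c(res, brute_revcomp(substr(seq_c, e - 5L, e)))
    } else {
      if (s - 3L >= 0L && s + 3L <= L)
        res <- c(res, substr(seq_c, s - 2L, s + 3L))
      if (e - 3L >= 0L && e + 3L <= L)
        res <- c(res, brute_revcomp(substr(seq_c, e - 2L, e + 3L)))
    }
  }
  res[!grepl("N", res)]
}

## Small cohort settings reused across tests (fast but non-trivial).
small_test_genomes <- function(seed = 424242) {
  list(host = generate_reference(setNames(rep(2e5, 3), paste0("hchr", 1:3)),
                                 0, "host", seed = seed),
       graft = generate_reference(setNames(rep(2e5, 2), paste0("gchr", 1:2)),
                                  0.4, "graft", seed = seed + 1L))
}

small_test_design <- function(...) {
  args <- utils::modifyList(list(fragments_per_sample = 6000L), list(...))
  do.call(cohort_design, args)
}
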