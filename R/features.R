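## Fragmentomics features: S2L ratio, size histogram and periodicity,
## 6-mer end / breakpoint motif spectra, per-arm fragment size vectors.

.frag_lengths <- function(fragments) {
  if (is.numeric(fragments)) return(as.integer(fragments))
  f <- as.data.table(fragments)
  if ("length_bp" %in% names(f)) return(f$length_bp)
  f$end - f$start
}

#' Short-to-long fragment ratio (S2L)
#'
#' Ratio of the number of short fragments (80-160 bp) to long fragments
#' (161-200 bp), both ranges inclusive. A higher S2L indicates enrichment
#' of sub-mononucleosomal fragments, a hallmark of tumor-derived cfDNA.
#'
#' @param fragments Fragment table (with `length_bp` or `start`/`end`) or a
#'   numeric vector of lengths.
#' @param short_range,long_range Inclusive bp ranges for the two classes.
#' @return List of class `s2l_ratio`: `short_count`, `long_count`, `ratio`.
#' @examples
#' compute_s2l(c(rep(100, 10), rep(180, 5)))$ratio  # 2
#' @export
compute_s2l <- function(fragments, short_range = c(80L, 160L),
                        long_range = c(161L, 200L)) {
  len <- .frag_lengths(fragments)
  short_count <- sum(len >= short_range[1] & len <= short_range[2])
  long_count <- sum(len >= long_range[1] & len <= long_range[2])
  if (long_count == 0L)
    stop("undefined S2L ratio: no fragments in the long range ",
         long_range[1], "-", long_range[2], " bp")
  structure(list(short_count = short_count, long_count = long_count,
                 ratio = short_count / long_count),
            class = "s2l_ratio")
}

#' Integer fragment-length histogram
#'
#' Counts fragments at every integer length of the observed range and
#' reports the modal length (smallest length on ties).
#'
#' @param fragments Fragment table or numeric length vector.
#' @return `data.table` of class `size_histogram` with columns `length_bp`,
#'   `count`, `fraction`; the mode is in `attr(, "mode")` (also via
#'   [histogram_mode()]).
#' @export
size_histogram <- function(fragments) {
  len <- .frag_lengths(fragments)
  if (length(len) == 0L) stop("empty input: no fragments")
  rng <- range(len)
  grid <- rng[1]:rng[2]
  counts <- tabulate(len - rng[1] + 1L, nbins = length(grid))
  h <- data.table(length_bp = grid, count = counts,
                  fraction = counts / sum(counts))
  setattr(h, "mode", grid[which.max(counts)])
  setattr(h, "class", c("size_histogram", class(h)))
  h
}

#' @rdname size_histogram
#' @param histogram A `size_histogram`.
#' @export
histogram_mode <- function(histogram) attr(histogram, "mode")

#' Estimate the sub-mononucleosomal ladder period
#'
#' Smooths the length histogram with a centred moving average and returns
#' the mean spacing between successive local maxima inside the search
#' window (default 90-160 bp, below the mononucleosomal peak).
#'
#' @param histogram A [size_histogram()] result.
#' @param search_range Inclusive bp window searched for local maxima.
#' @param smooth_window Moving-average window in bp (odd, default 3).
#' @return Estimated period in bp.
#' @examples
#' len <- rep(c(97, 107, 117, 127, 137, 147, 157), times = 20)
#' estimate_periodicity(size_histogram(len))  # 10
#' @export
estimate_periodicity <- function(histogram, search_range = c(90L, 160L),
                                 smooth_window = 3L) {
  stopifnot(inherits(histogram, "size_histogram"))
  if (nrow(histogram) < max(smooth_window, 3L))
    stop("undefined period: fewer than 2 local maxima in the search range")
  sm <- as.numeric(stats::filter(histogram$count,
                                 rep(1 / smooth_window, smooth_window),
                                 sides = 2))
  x <- histogram$length_bp
  ## local maxima with plateau centring: a flat run higher than both
  ## flanks counts once, at its centre
  n <- length(sm)
  peak_idx <- integer(0)
  i <- 2L
  while (i < n) {
    if (is.na(sm[i])) { i <- i + 1L; next }
    j <- i
    while (j < n && !is.na(sm[j + 1L]) && sm[j + 1L] == sm[i]) j <- j + 1L
    left <- sm[i - 1L]
    right <- if (j < n) sm[j + 1L] else NA_real_
    if (!is.na(left) && !is.na(right) && sm[i] > left && sm[i] > right)
      peak_idx <- c(peak_idx, as.integer(round((i + j) / 2)))
    i <- max(j, i + 1L)
  }
  peaks <- x[peak_idx]
  peaks <- peaks[peaks >= search_range[1] & peaks <= search_range[2]]
  if (length(peaks) < 2L)
    stop("undefined period: fewer than 2 local maxima in the search range")
  mean(diff(peaks))
}

#' All 4,096 DNA 6-mers
#' @return Character vector of the 4^6 motifs over A/C/G/T, sorted.
#' @export
all_6mers <- function() {
  b <- c("A", "C", "G", "T")
  g <- do.call(CJ, rep(list(b), 6L))
  sort(g[, do.call(paste0, .SD)])
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' 6-mer end / breakpoint motif spectrum
#'
#' Each fragment contributes one motif per end, read 5' to 3' into the
#' fragment (the downstream-end motif is reverse-complemented):
#' \describe{
#'   \item{EDM (end motif)}{the first 6 reference bases inside each end:
#'     upstream `ref[start, start+6)`; downstream
#'     `revcomp(ref[end-6, end))`.}
#'   \item{BPM (breakpoint motif)}{6 bases spanning each break, 3 outside
#'     plus 3 inside: upstream `ref[start-3, start+3)`; downstream
#'     `revcomp(ref[end-3, end+3))`.}
#' }
#' Ends whose motif window runs off the chromosome are skipped (counted in
#' `attr(, "n_skipped")`); motifs containing N are excluded from both the
#' counts and the denominator.
#'
#' @param fragments Fragment table with `chrom, start, end` on `genome`.
#' @param genome A [genome_model].
#' @param flavor `"EDM"` or `"BPM"`.
#' @return `data.table` of class `motif_spectrum` with all 4,096 rows
#'   (`motif`, `count`, `frequency`); frequencies sum to 1 when any motif
#'   was counted.
#' @export
compute_motif_spectrum <- function(fragments, genome,
                                   flavor = c("EDM", "BPM")) {
  flavor <- match.arg(flavor)
  f <- as.data.table(fragments)
  stopifnot(inherits(genome, "genome_model"))
  unknown <- setdiff(unique(f$chrom), names(genome$sequences))
  if (length(unknown)) stop("fragments on unknown chromosome: ", unknown[1])

  n_skipped <- 0L
  motifs <- vector("list", 2L * length(unique(f$chrom)))
  k <- 0L
  for (cn in unique(f$chrom)) {
    seq_c <- genome$sequences[[cn]]
    L <- genome$seqlengths[[cn]]
    fc <- f[chrom == cn]
    if (flavor == "EDM") {
      up_s <- fc$start + 1L;  up_e <- fc$start + 6L
      dn_s <- fc$end - 5L;    dn_e <- fc$end
    } else {
      up_s <- fc$start - 2L;  up_e <- fc$start + 3L
      dn_s <- fc$end - 2L;    dn_e <- fc$end + 3L
    }
    ok_up <- up_s >= 1L & up_e <= L
    ok_dn <- dn_s >= 1L & dn_e <= L
    n_skipped <- n_skipped + sum(!ok_up) + sum(!ok_dn)
    k <- k + 1L
    motifs[[k]] <- substring(seq_c, up_s[ok_up], up_e[ok_up])
    k <- k + 1L
    motifs[[k]] <- .revcomp(substring(seq_c, dn_s[ok_dn], dn_e[ok_dn]))
  }
  all_m <- unlist(motifs[seq_len(k)], use.names = FALSE)
  all_m <- all_m[!grepl("N", all_m, fixed = TRUE)]

  levels <- all_6mers()
  counts <- tabulate(factor(all_m, levels = levels), nbins = length(levels))
  total <- sum(counts)
  out <- data.table(motif = levels, count = counts,
                    frequency = if (total > 0) counts / total else 0)
  setattr(out, "flavor", flavor)
  setattr(out, "n_counted", total)
  setattr(out, "n_skipped", n_skipped)
  setattr(out, "class", c("motif_spectrum", class(out)))
  out
}

#' FSD bin definitions
#'
#' 5-bp fragment-length bins with inclusive bounds from 65 to 399 bp
#' (67 bins: 65-69, 70-74, ..., 395-399).
#'
#' @param min_bp,max_bp,step Bin range and width.
#' @return `data.table` with `bin_start`, `bin_end`.
#' @export
fsd_bins <- function(min_bp = 65L, max_bp = 399L, step = 5L) {
  if ((max_bp - min_bp + 1L) %% step != 0L)
    stop("invalid spec: bin range ", min_bp, "-", max_bp,
         " is not a whole number of ", step, " bp bins")
  starts <- seq(min_bp, max_bp, by = step)
  data.table(bin_start = as.integer(starts),
             bin_end = as.integer(starts + step - 1L))
}

#' Names of the FSD feature space for a given arm list
#' @param arms Character vector of arm names (see [mouse_arms()]).
#' @param bins Bin table from [fsd_bins()].
#' @return Character vector of length `67 * length(arms)`, e.g.
#'   `"chr1q_65_69"`.
#' @export
fsd_feature_names <- function(arms, bins = fsd_bins()) {
  as.vector(t(outer(arms, paste0(bins$bin_start, "_", bins$bin_end),
                    paste, sep = "_")))
}

#' Per-arm fragment size distribution (FSD) vector
#'
#' For every chromosome arm, the fraction of fragments whose length falls
#' in each 5-bp bin from 65 to 399 bp. Fragments are assigned to the arm
#' containing their start position; fragments with length outside the bin
#' range are excluded; fractions are normalised within each arm. Arms with
#' no in-range fragment yield zero rows and are flagged.
#'
#' @param fragments Fragment table with `chrom, start` and `length_bp`
#'   (or `end`).
#' @param arm_table Arm table (`chrom, arm, start, end`) or a
#'   [genome_model].
#' @param bins Bin table from [fsd_bins()].
#' @return `data.table` of class `fsd_vector` over the full
#'   `arm x bin` grid: `arm, bin_start, bin_end, fraction`; empty arms are
#'   listed in `attr(, "empty_arms")`.
#' @export
compute_fsd <- function(fragments, arm_table, bins = fsd_bins()) {
  if (inherits(arm_table, "genome_model")) arm_table <- arm_table$arm_table
  at <- as.data.table(arm_table)
  at[, arm_name := paste0(chrom, arm)]
  f <- as.data.table(fragments)
  if (!"length_bp" %in% names(f)) f <- copy(f)[, length_bp := end - start]

  ## assign arm by start position (0-based, half-open arm intervals)
  pts <- .as_granges(data.table(chrom = f$chrom, start = f$start,
                                end = f$start + 1L))
  armsgr <- .as_granges(at)
  hits <- GenomicRanges::findOverlaps(pts, armsgr, select = "first")
  if (anyNA(hits))
    stop("some fragments are not assignable to any arm")
  f[, arm := at$arm_name[hits]]

  f <- f[length_bp >= bins$bin_start[1] &
           length_bp <= bins$bin_end[nrow(bins)]]
  grid <- CJ(arm = at$arm_name, bin_i = seq_len(nrow(bins)))
  if (nrow(f) > 0L) {
    f[, bin_i := findInterval(length_bp, bins$bin_start)]
    cnt <- f[, .N, by = .(arm, bin_i)]
    grid <- merge(grid, cnt, by = c("arm", "bin_i"), all.x = TRUE)
  } else grid[, N := NA_integer_]
  grid[is.na(N), N := 0L]
  grid[, fraction := {tot <- sum(N); if (tot > 0) N / tot else 0}, by = arm]
  out <- data.table(arm = grid$arm,
                    bin_start = bins$bin_start[grid$bin_i],
                    bin_end = bins$bin_end[grid$bin_i],
                    fraction = grid$fraction)
  setorder(out, arm, bin_start)
  empty <- out[, .(tot = sum(fraction)), by = arm][tot == 0, arm]
  setattr(out, "empty_arms", empty)
  setattr(out, "class", c("fsd_vector", class(out)))
  out
}

#' Flatten an FSD table into a named feature vector
#' @param fsd A [compute_fsd()] result.
#' @return Named numeric vector (`arm_binstart_binend` names).
#' @export
fsd_as_vector <- function(fsd) {
  setNames(fsd$fraction, paste(fsd$arm, fsd$bin_start, fsd$bin_end,
                               sep = "_"))
}
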