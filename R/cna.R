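## Copy-number feature matrix: fixed-width bins, midpoint counts,
## depth-normalised log2 ratios, and PCA.

#' Tile a genome into fixed-width bins
#'
#' Bins are half-open `[start, end)` intervals tiled per chromosome (the
#' final bin of a chromosome may be shorter). Bins overlapping any
#' excluded region are masked: they are carried with counts but never
#' appear as feature-matrix columns.
#'
#' @param genome A [genome_model] (its `excluded_regions` are masked) or a
#'   named vector of chromosome lengths.
#' @param bin_width Bin width in bp (default 1 Mb).
#' @param exclude Optional extra `chrom, start, end` table to mask.
#' @return `data.table` of class `bin_grid`: `bin_id, chrom, start, end,
#'   masked`.
#' @export
bin_grid <- function(genome, bin_width = 1e6, exclude = NULL) {
  if (inherits(genome, "genome_model")) {
    seqlengths <- genome$seqlengths
    excl <- genome$excluded_regions
  } else {
    seqlengths <- genome
    excl <- NULL
  }
  if (!is.null(exclude))
    excl <- rbind(excl, as.data.table(exclude)[, .(chrom, start, end)],
                  fill = TRUE)
  grid <- rbindlist(lapply(names(seqlengths), function(cn) {
    L <- seqlengths[[cn]]
    starts <- seq(0L, L - 1L, by = as.integer(bin_width))
    data.table(chrom = cn, start = as.integer(starts),
               end = as.integer(pmin(starts + bin_width, L)))
  }))
  grid[, bin_id := paste0(chrom, ":", start, "-", end)]
  grid[, masked := FALSE]
  if (!is.null(excl) && nrow(excl) > 0L) {
    hits <- GenomicRanges::findOverlaps(.as_granges(grid),
                                        .as_granges(as.data.table(excl)))
    grid[unique(S4Vectors::queryHits(hits)), masked := TRUE]
  }
  setcolorder(grid, c("bin_id", "chrom", "start", "end", "masked"))
  setattr(grid, "class", c("bin_grid", class(grid)))
  grid
}

#' Count fragments per bin by midpoint
#'
#' A fragment belongs to the bin containing its midpoint
#' `(start + end) %/% 2`; a midpoint on a bin boundary goes to the
#' higher (right) bin, following the half-open convention.
#'
#' @param fragments Fragment table with `chrom, start, end`.
#' @param grid A [bin_grid()].
#' @return `data.table` `bin_id, chrom, start, end, masked, count` in grid
#'   order.
#' @export
bin_counts <- function(fragments, grid) {
  f <- as.data.table(fragments)
  out <- copy(as.data.table(grid))
  out[, count := 0L]
  if (nrow(f) > 0L) {
    f <- copy(f)[, mid := (start + end) %/% 2L]
    for (cn in unique(f$chrom)) {
      g <- grid[chrom == cn]
      if (nrow(g) == 0L) next
      mids <- f[chrom == cn, mid]
      idx <- findInterval(mids, g$start)
      ok <- idx >= 1L
      ok[ok] <- mids[ok] < g$end[idx[ok]]
      tab <- tabulate(idx[ok], nbins = nrow(g))
      out[chrom == cn, count := count + tab]
    }
  }
  out[]
}

#' Depth-normalised log2 copy-ratio matrix
#'
#' Each sample's unmasked bin counts are scaled to a common total, a
#' pseudocount is added, and the log2 ratio against an expected per-bin
#' value is taken. The expected value is the mean of the depth-normalised
#' control samples when `reference_counts` is given, otherwise each
#' sample's own median normalised bin count.
#'
#' @param sample_counts Named list (or samples x bins matrix, columns =
#'   `bin_id`) of [bin_counts()] results / count vectors.
#' @param grid The shared [bin_grid()].
#' @param reference_counts Optional list/matrix of control sample counts.
#' @param pseudocount Added to both numerator and denominator
#'   (default 0.5).
#' @param target_total Common total the unmasked counts are scaled to.
#' @return Matrix of class `cna_matrix` (samples x unmasked bins) of
#'   finite log2 ratios.
#' @export
log2_ratio_matrix <- function(sample_counts, grid, reference_counts = NULL,
                              pseudocount = 0.5, target_total = 1e6) {
  to_mat <- function(x) {
    if (is.matrix(x)) return(x)
    rows <- lapply(x, function(b) {
      if (is.data.frame(b)) setNames(as.data.table(b)$count,
                                     as.data.table(b)$bin_id)
      else b
    })
    do.call(rbind, rows)
  }
  m <- to_mat(sample_counts)
  unmasked <- grid$bin_id[!grid$masked]
  m <- m[, unmasked, drop = FALSE]
  totals <- rowSums(m)
  if (any(totals == 0)) stop("zero total count for sample ",
                             rownames(m)[which(totals == 0)[1]])
  norm <- m / totals * target_total

  if (!is.null(reference_counts)) {
    r <- to_mat(reference_counts)[, unmasked, drop = FALSE]
    rt <- rowSums(r)
    if (any(rt == 0)) stop("zero total count in reference sample")
    expected <- colMeans(r / rt * target_total)
    lr <- log2(sweep(norm + pseudocount, 2L, expected + pseudocount, "/"))
  } else {
    med <- apply(norm, 1L, stats::median)
    lr <- log2((norm + pseudocount) / (med + pseudocount))
  }
  structure(lr, class = c("cna_matrix", class(lr)))
}

.pca <- function(m) {
  if (nrow(m) < 2L) stop("PCA needs >= 2 samples")
  if (all(apply(m, 2L, function(x) isTRUE(all.equal(stats::var(x), 0)))))
    stop("degenerate input: constant matrix")
  p <- prcomp(m, center = TRUE, scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2) * 100
  list(scores = p$x, variance_explained = ve, rotation = p$rotation)
}

#' PCA of a copy-number (or any feature) matrix
#'
#' Columns are centred; variance-explained percentages sum to 100 over
#' the returned components.
#'
#' @param matrix Samples x features numeric matrix.
#' @return List with `scores` (samples x PCs), `variance_explained`
#'   (percentages), `rotation`.
#' @export
cna_pca <- function(matrix) {
  .pca(unclass(matrix))
}
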