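## Plain-text interchange: BED6 fragments, TSV tables.

#' Write fragments as BED6
#'
#' Columns: chrom, start, end, name (read id), score (MAPQ), strand.
#' Coordinates are written as stored (0-based half-open), matching BED.
#'
#' @param fragments Fragment table with `chrom, start, end` and optionally
#'   `read_id`, `mapq`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fragments_bed <- function(fragments, path) {
  f <- as.data.table(fragments)
  bed <- data.table(
    chrom = f$chrom, start = f$start, end = f$end,
    name = if ("read_id" %in% names(f)) as.character(f$read_id) else ".",
    score = if ("mapq" %in% names(f)) f$mapq else 0L,
    strand = "+")
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED file into a fragment table
#' @param path BED3+ file (tab-separated, no header).
#' @return `data.table` with `chrom, start, end` and, when present,
#'   `read_id`, `mapq`, `strand`, `length_bp`.
#' @export
read_fragments_bed <- function(path) {
  bed <- fread(path, header = FALSE, sep = "\t")
  nm <- c("chrom", "start", "end", "read_id", "mapq", "strand")
  setnames(bed, nm[seq_len(min(ncol(bed), 6L))])
  bed[, length_bp := end - start]
  bed[]
}

#' Write a table as TSV
#' @param x A data.frame / data.table.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tsv <- function(x, path) {
  fwrite(as.data.table(x), path, sep = "\t")
  invisible(path)
}

#' Split fragments into 150 bp paired read alignments
#'
#' Emulates the interval footprint of paired-end sequencing: mate 1 covers
#' the first `read_len` bases of the fragment, mate 2 the last `read_len`
#' (both truncated to the fragment for short inserts). Useful for
#' exercising [infer_fragments()] round-trips.
#'
#' @param fragments Fragment table with `read_id, chrom, start, end` and
#'   optionally `mapq, sample_id`.
#' @param read_len Read length in bp.
#' @return Alignment table with a `mate` column.
#' @export
fragments_to_read_pairs <- function(fragments, read_len = 150L) {
  f <- as.data.table(fragments)
  m1 <- f[, .(read_id, mate = 1L, chrom, start,
              end = pmin(start + read_len, end))]
  m2 <- f[, .(read_id, mate = 2L, chrom,
              start = pmax(end - read_len, start), end)]
  out <- rbind(m1, m2)
  for (cc in intersect(c("mapq", "sample_id"), names(f)))
    out[, (cc) := rep(f[[cc]], 2L)]
  setorder(out, read_id, mate)
  out[]
}
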