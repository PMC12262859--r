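## ctDNA isolation: control-derived blacklists, classifier-call merging,
## alignment filters, fragment inference, pooling and down-sampling.

.as_granges <- function(dt, seqlengths = NULL) {
  GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end),
    seqlengths = seqlengths)
}

.granges_to_dt <- function(gr) {
  data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

#' Build a blacklist from control human-prone alignments
#'
#' Control samples contain no graft DNA, so any of their reads that align
#' to the graft genome mark regions of cross-species homology or mapping
#' artifact. Per (sample, method), overlapping alignments are first merged
#' into regions; a genomic position is then blacklisted iff it is covered
#' by regions from at least two distinct samples OR at least two distinct
#' methods. The output is a merged, non-overlapping interval set.
#'
#' @param control_alignments `data.table` with columns `chrom, start, end,
#'   sample_id, method` (0-based half-open intervals on the graft genome).
#' @param genome Optional [genome_model]; when given, unknown chromosomes
#'   are rejected by name.
#' @param min_samples,min_methods Support thresholds (defaults 2 and 2).
#' @return `data.table` of class `blacklist` with columns
#'   `chrom, start, end`, sorted and merged.
#' @export
build_blacklist <- function(control_alignments, genome = NULL,
                            min_samples = 2L, min_methods = 2L) {
  aln <- as.data.table(control_alignments)
  req <- c("chrom", "start", "end", "sample_id", "method")
  if (!all(req %in% names(aln)))
    stop("control_alignments needs columns ", paste(req, collapse = ", "))
  if (!is.null(genome)) {
    unknown <- setdiff(unique(aln$chrom), names(genome$seqlengths))
    if (length(unknown))
      stop("unknown chromosome in input: ", unknown[1])
  }
  empty <- structure(data.table(chrom = character(), start = integer(),
                                end = integer()),
                     class = c("blacklist", "data.table", "data.frame"))
  if (nrow(aln) == 0L) return(empty)

  ## merge alignments into regions per (sample, method)
  regions <- aln[, .granges_to_dt(GenomicRanges::reduce(.as_granges(.SD))),
                 by = .(sample_id, method)]
  gr <- .as_granges(regions)

  ## disjoint pieces; count distinct supporting samples and methods
  dj <- GenomicRanges::disjoin(gr)
  hits <- GenomicRanges::findOverlaps(dj, gr)
  sup <- data.table(piece = S4Vectors::queryHits(hits),
                    sample_id = regions$sample_id[S4Vectors::subjectHits(hits)],
                    method = regions$method[S4Vectors::subjectHits(hits)])
  keep <- sup[, .(ok = uniqueN(sample_id) >= min_samples |
                    uniqueN(method) >= min_methods), by = piece][ok == TRUE]
  if (nrow(keep) == 0L) return(empty)
  out <- .granges_to_dt(GenomicRanges::reduce(dj[keep$piece]))
  setkey(out, chrom, start)
  structure(out, class = c("blacklist", "data.table", "data.frame"))
}

#' Merge human calls from two classifiers
#'
#' Returns the union of read ids called `"human"` by any method. Ambiguous
#' calls (`"both"`, `"neither"`) do not count as human. Conflicting
#' duplicate verdicts for the same (read, method) are an error.
#'
#' @param verdicts `data.table` with columns `read_id, method, call`.
#' @return Vector of unique read ids called human by at least one method.
#' @export
merge_human_calls <- function(verdicts) {
  v <- as.data.table(verdicts)
  if (!all(c("read_id", "method", "call") %in% names(v)))
    stop("verdicts needs columns read_id, method, call")
  ## duplicate (read, method) pairs are rare: only group when they exist
  dup_pair <- duplicated(v, by = c("read_id", "method"))
  if (any(dup_pair)) {
    keys <- unique(v[dup_pair, .(read_id, method)])
    dd <- v[keys, on = c("read_id", "method")]
    conf <- dd[, .(n_call = uniqueN(call)), by = .(read_id, method)]
    if (any(conf$n_call > 1L))
      stop("conflicting duplicate verdicts for read ",
           conf[n_call > 1L, read_id][1])
  }
  unique(v[call == "human", read_id])
}

#' Filter alignments by mapping quality and blacklist overlap
#'
#' Retains alignments with `mapq >= min_mapq` whose interval does not
#' overlap any blacklisted interval by even a single base.
#'
#' @param reads `data.table` with `chrom, start, end, mapq` (plus any
#'   carried columns).
#' @param blacklist A [build_blacklist()] result (or any
#'   `chrom, start, end` table); `NULL`/empty applies only the MAPQ rule.
#' @param min_mapq Minimum mapping quality (default 30).
#' @return The retained rows.
#' @export
filter_alignments <- function(reads, blacklist = NULL, min_mapq = 30L) {
  r <- as.data.table(reads)
  keep <- r$mapq >= min_mapq
  if (!is.null(blacklist) && nrow(blacklist) > 0L && any(keep)) {
    hits <- GenomicRanges::findOverlaps(.as_granges(r),
                                        .as_granges(as.data.table(blacklist)))
    keep[unique(S4Vectors::queryHits(hits))] <- FALSE
  }
  r[keep]
}

#' Infer fragments from paired read alignments
#'
#' A fragment is the outer span of a properly paired alignment (leftmost
#' start to rightmost end). Pairs on different chromosomes and orphan
#' reads are skipped (counted in the `skipped` attribute); fragments with
#' length outside `[min_len, max_len]` are dropped.
#'
#' @param read_pairs `data.table` with `read_id, mate` (1/2), `chrom,
#'   start, end` and optionally `mapq, sample_id`.
#' @param min_len,max_len Retained fragment length range in bp (inclusive,
#'   defaults 50 and 1000).
#' @return Fragment `data.table` (`read_id, chrom, start, end, length_bp`,
#'   plus `mapq` = min of the mates and any `sample_id`), with attributes
#'   `n_orphan`, `n_discordant`, `n_out_of_range`.
#' @export
infer_fragments <- function(read_pairs, min_len = 50L, max_len = 1000L) {
  rp <- as.data.table(read_pairs)
  stopifnot(all(c("read_id", "mate", "chrom", "start", "end") %in% names(rp)))
  cnt <- rp[, .N, by = read_id]
  orphan <- cnt[N != 2L, read_id]
  rp <- rp[!read_id %in% orphan]
  has_mapq <- "mapq" %in% names(rp)
  has_sample <- "sample_id" %in% names(rp)
  frag <- rp[, .(chrom_n = uniqueN(chrom), chrom = chrom[1L],
                 start = min(start), end = max(end),
                 mapq = if (has_mapq) min(mapq) else NA_integer_,
                 sample_id = if (has_sample) sample_id[1L] else NA_character_),
             by = read_id]
  n_disc <- sum(frag$chrom_n > 1L)
  frag <- frag[chrom_n == 1L][, chrom_n := NULL]
  frag[, length_bp := end - start]
  n_oor <- sum(frag$length_bp < min_len | frag$length_bp > max_len)
  frag <- frag[length_bp >= min_len & length_bp <= max_len]
  setattr(frag, "n_orphan", length(orphan))
  setattr(frag, "n_discordant", n_disc)
  setattr(frag, "n_out_of_range", n_oor)
  frag[]
}

#' Filter fragments by length
#'
#' @param fragments Fragment table with a `length_bp` (or `start`/`end`)
#'   column.
#' @param min_len,max_len Inclusive length bounds in bp.
#' @return Retained rows.
#' @export
filter_fragment_lengths <- function(fragments, min_len = 50L,
                                    max_len = 1000L) {
  f <- as.data.table(fragments)
  if (!"length_bp" %in% names(f)) f[, length_bp := end - start]
  f[length_bp >= min_len & length_bp <= max_len]
}

#' Pool replicate samples into representative samples
#'
#' Multiset union of per-sample fragment sets, keyed by a grouping of the
#' sample sheet (default cell line x site, yielding the four representative
#' samples of a 2 x 2 CDX design).
#'
#' @param fragments Fragment table with a `sample_id` column.
#' @param sample_sheet Table with `sample_id` and the grouping columns.
#' @param group_by Character vector of sheet columns to pool by.
#' @return Fragment table with an added `group` column.
#' @export
pool_replicates <- function(fragments, sample_sheet,
                            group_by = c("cell_line", "site")) {
  f <- as.data.table(fragments)
  sheet <- as.data.table(sample_sheet)
  stopifnot(all(group_by %in% names(sheet)))
  m <- merge(f, sheet[, c("sample_id", group_by), with = FALSE],
             by = "sample_id")
  m[, group := do.call(paste, c(.SD, sep = "_")), .SDcols = group_by]
  m[, (group_by) := NULL]
  m[]
}

#' Down-sample fragments without replacement
#'
#' Draws exactly `min(target_count, available)` fragments uniformly without
#' replacement; a target above the available count returns everything with
#' a warning.
#'
#' @param fragments Fragment table.
#' @param target_count Number of fragments to keep (>= 1).
#' @param seed Optional integer seed.
#' @return The sampled rows.
#' @export
downsample_fragments <- function(fragments, target_count, seed = NULL) {
  if (target_count < 1) stop("target_count must be >= 1")
  f <- as.data.table(fragments)
  if (!is.null(seed)) set.seed(seed)
  if (target_count > nrow(f)) {
    warning("target_count (", target_count, ") exceeds available (",
            nrow(f), "); returning all fragments")
    return(f)
  }
  f[sample.int(nrow(f), target_count)]
}

#' Isolate ctDNA fragments from a candidate re-alignment set
#'
#' Applies the isolation chain to graft-genome re-alignments of reads
#' called human by either classifier: MAPQ filter, blacklist-overlap
#' removal, and fragment length bounds.
#'
#' @param realignments `data.table` of graft-genome alignments
#'   (`sample_id, read_id, chrom, start, end, mapq`).
#' @param human_read_ids Read ids called human (from
#'   [merge_human_calls()]).
#' @param blacklist A blacklist or `NULL`.
#' @param min_mapq,min_len,max_len Filter thresholds.
#' @return Isolated ctDNA fragment table with a `length_bp` column and a
#'   `counts` attribute recording the per-stage retention.
#' @export
isolate_ctdna <- function(realignments, human_read_ids, blacklist = NULL,
                          min_mapq = 30L, min_len = 50L, max_len = 1000L) {
  cand <- as.data.table(realignments)[read_id %in% human_read_ids]
  n0 <- nrow(cand)
  filt <- filter_alignments(cand, blacklist, min_mapq)
  n1 <- nrow(filt)
  out <- filter_fragment_lengths(filt, min_len, max_len)
  setattr(out, "counts",
          c(candidates = n0, after_mapq_blacklist = n1, retained = nrow(out)))
  out[]
}
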