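## Synthetic reference genomes and chromosome-arm conventions.

#' Construct a genome model
#'
#' A `genome_model` bundles per-chromosome sequence, an arm table and an
#' excluded-region list. Coordinates are 0-based half-open throughout.
#'
#' @param species_tag Single label, e.g. `"host"` or `"graft"`.
#' @param sequences Named character vector of chromosome sequences
#'   (A/C/G/T/N only).
#' @param arm_table `data.table` with columns `chrom`, `arm` (`"p"`/`"q"`),
#'   `start`, `end`. Arms must be disjoint and within chromosome bounds.
#' @param excluded_regions Optional `data.table` with `chrom`, `start`, `end`
#'   marking assembly gaps / excludable-region analogues.
#'
#' @return An object of class `genome_model` with elements `species_tag`,
#'   `sequences`, `seqlengths`, `arm_table`, `excluded_regions`.
#' @export
genome_model <- function(species_tag, sequences, arm_table,
                         excluded_regions = NULL) {
  stopifnot(is.character(species_tag), length(species_tag) == 1L)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must be uniquely named by chromosome")
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("sequences may contain only A/C/G/T/N: ", names(sequences)[bad][1])
  seqlengths <- setNames(nchar(sequences), names(sequences))

  arm_table <- as.data.table(arm_table)
  req <- c("chrom", "arm", "start", "end")
  if (!all(req %in% names(arm_table)))
    stop("arm_table needs columns chrom, arm, start, end")
  if (!all(arm_table$chrom %in% names(sequences)))
    stop("arm_table names unknown chromosome: ",
         setdiff(arm_table$chrom, names(sequences))[1])
  if (any(arm_table$start < 0) ||
      any(arm_table$end > seqlengths[arm_table$chrom]))
    stop("arm intervals must lie within chromosome bounds")
  setkey(arm_table, chrom, start)
  ov <- arm_table[, any(start[-1L] < head(end, -1L)), by = chrom]$V1
  if (any(ov)) stop("arm intervals overlap within a chromosome")

  if (is.null(excluded_regions))
    excluded_regions <- data.table(chrom = character(), start = integer(),
                                   end = integer())
  excluded_regions <- as.data.table(excluded_regions)

  structure(list(species_tag = species_tag,
                 sequences = sequences,
                 seqlengths = seqlengths,
                 arm_table = arm_table,
                 excluded_regions = excluded_regions),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model '%s': %d chromosomes, %.2f Mb, %d arms\n",
              x$species_tag, length(x$sequences),
              sum(x$seqlengths) / 1e6, nrow(x$arm_table)))
  invisible(x)
}

#' Generate a reproducible synthetic reference genome
#'
#' Draws i.i.d. bases at a given GC content for each chromosome and derives
#' an arm table from per-chromosome arm fractions. An arm fraction of 0
#' yields a single q arm spanning the chromosome (the acrocentric mouse
#' convention); a fraction f in (0, 1) yields p = \[0, f*L) and
#' q = \[f*L, L).
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (>= 2 kb).
#' @param arm_fraction Single numeric in \[0, 1) or a vector recycled over
#'   chromosomes: fraction of each chromosome assigned to the p arm.
#' @param species_tag Label stored in the model.
#' @param gc GC content of the simulated sequence.
#' @param seed Integer seed; required so references are reproducible.
#' @param fasta Optional path; when given, the sequences are written as FASTA.
#'
#' @return A [genome_model].
#' @examples
#' g <- generate_reference(c(chr1 = 1e5, chr2 = 1e5), arm_fraction = 0.4,
#'                         seed = 7)
#' g$arm_table
#' @export
generate_reference <- function(chrom_lengths, arm_fraction = 0,
                               species_tag = "synthetic", gc = 0.42,
                               seed, fasta = NULL) {
  if (missing(seed)) stop("seed is required")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  if (any(chrom_lengths < 2000))
    stop("invalid spec: chromosome lengths must be >= 2000 bp")
  if (any(arm_fraction < 0 | arm_fraction >= 1))
    stop("invalid spec: arm_fraction must be in [0, 1)")
  arm_fraction <- rep_len(arm_fraction, length(chrom_lengths))

  base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  set.seed(seed)
  sequences <- vapply(chrom_lengths, function(L) {
    paste(sample(names(base_prob), L, replace = TRUE, prob = base_prob),
          collapse = "")
  }, character(1L))

  arms <- rbindlist(lapply(seq_along(chrom_lengths), function(i) {
    L <- as.integer(chrom_lengths[i])
    f <- arm_fraction[i]
    nm <- names(chrom_lengths)[i]
    if (f == 0) {
      data.table(chrom = nm, arm = "q", start = 0L, end = L)
    } else {
      cut <- as.integer(round(f * L))
      data.table(chrom = nm, arm = c("p", "q"),
                 start = c(0L, cut), end = c(cut, L))
    }
  }))

  g <- genome_model(species_tag, sequences, arms)
  if (!is.null(fasta)) write_genome_fasta(g, fasta)
  g
}

#' Write a genome model as FASTA
#' @param genome A [genome_model].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  dna <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(dna, filepath = path)
  invisible(path)
}

#' Read a FASTA file into a genome model
#'
#' The arm table defaults to one q arm per chromosome unless supplied.
#' @param path FASTA file.
#' @param species_tag Label for the model.
#' @param arm_table Optional arm table; default one q arm per chromosome.
#' @return A [genome_model].
#' @export
read_genome_fasta <- function(path, species_tag = "imported",
                              arm_table = NULL) {
  dna <- Biostrings::readDNAStringSet(path)
  seqs <- setNames(as.character(dna), sub("\\s.*$", "", names(dna)))
  if (is.null(arm_table))
    arm_table <- data.table(chrom = names(seqs), arm = "q", start = 0L,
                            end = nchar(seqs))
  genome_model(species_tag, seqs, arm_table)
}

#' Conventional chromosome-arm lists for FSD features
#'
#' `mouse_arms()` returns the q arms of the 19 mouse autosomes plus chrX and
#' chrY (21 arms; mouse chromosomes are acrocentric so only q arms carry
#' fragment-size features). `human_arms()` returns both arms of the human
#' autosomes plus chrX, excluding the short arms of the acrocentric
#' chromosomes 13, 14, 15, 21 and 22 and chrY entirely; with
#' `exclude_xp = TRUE` (default) chrXp is also excluded, giving 40 arms.
#'
#' @param exclude_xp Drop chrXp from the human list (default `TRUE`).
#' @return Character vector of arm names such as `"chr1q"`.
#' @export
mouse_arms <- function() {
  paste0("chr", c(1:19, "X", "Y"), "q")
}

#' @rdname mouse_arms
#' @export
human_arms <- function(exclude_xp = TRUE) {
  chroms <- c(1:22, "X")
  arms <- as.vector(t(outer(paste0("chr", chroms), c("p", "q"), paste0)))
  drop <- paste0("chr", c(13, 14, 15, 21, 22), "p")
  if (exclude_xp) drop <- c(drop, "chrXp")
  setdiff(arms, drop)
}
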