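## Synthetic CDX cohorts: two-species fragment populations, copy-number
## weighted placement, and imperfect species-classifier verdicts.

#' Declare a fragment-size enrichment effect
#'
#' Group-specific fragment-size distribution (FSD) effects multiply the
#' length pmf of the targeted stream over a bp range for samples at the
#' given factor level (e.g. enrich 220-309 bp host cfDNA in one cell line).
#'
#' @param target `"host_cfdna"` or `"ctdna"`: which stream is affected.
#' @param factor `"cell_line"` or `"site"`: which design factor drives it.
#' @param level Factor level (e.g. a cell line name) receiving the effect.
#' @param range Length-2 bp range (inclusive) that is enriched.
#' @param multiplier Enrichment multiplier (> 0).
#' @return A list of class `fsd_effect`.
#' @export
fsd_effect <- function(target = c("host_cfdna", "ctdna"),
                       factor = c("cell_line", "site"),
                       level, range, multiplier) {
  target <- match.arg(target)
  factor <- match.arg(factor)
  stopifnot(length(range) == 2L, range[1] <= range[2], multiplier > 0)
  structure(list(target = target, factor = factor, level = level,
                 range = as.integer(range), multiplier = multiplier),
            class = "fsd_effect")
}

default_fsd_effects <- function(cell_lines = c("A549", "M97H"),
                                sites = c("pancreas", "rectum")) {
  list(
    fsd_effect("host_cfdna", "cell_line", cell_lines[2], c(220, 309), 2.0),
    fsd_effect("host_cfdna", "cell_line", cell_lines[1], c(150, 174), 1.3),
    fsd_effect("ctdna", "site", sites[1], c(120, 129), 2.0),
    fsd_effect("ctdna", "site", sites[2], c(185, 214), 2.0)
  )
}

#' Cohort design for a synthetic CDX study
#'
#' Describes the factorial design of a xenograft plasma study: two tumor
#' cell lines crossed with two implantation sites, each with replicate
#' animals, plus host-only controls. Defaults mirror a 12-model CDX study
#' (2 cell lines x 2 sites x 3 replicates) with 3 controls and per-sample
#' tumor fractions spanning 0.21\% to 18.96\%.
#'
#' @param cell_lines,sites Two labels each.
#' @param replicates_per_group Animals per (cell line, site) group.
#' @param controls Number of host-only control samples.
#' @param ctdna_fraction_range Range the per-sample ctDNA fraction is drawn
#'   from (uniformly), as proportions in (0, 1).
#' @param fragments_per_sample Total fragments simulated per sample.
#' @param fsd_effects List of [fsd_effect()]s; defaults place cell-line
#'   effects on host cfDNA and site effects on ctDNA.
#' @param host_profile,graft_profile Size profiles for the two streams.
#' @param classifier_rates Named list (one per method, default methods
#'   `"A"` and `"B"`) of `c(fnr=, fpr=)`: per-read probabilities that a
#'   graft read is missed (fnr) or a host read is called human (fpr).
#' @param low_mapq_rate Fraction of genuine alignments drawn with MAPQ < 30.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(cell_lines = c("A549", "M97H"),
                          sites = c("pancreas", "rectum"),
                          replicates_per_group = 3L,
                          controls = 3L,
                          ctdna_fraction_range = c(0.0021, 0.1896),
                          fragments_per_sample = 150000L,
                          fsd_effects = default_fsd_effects(cell_lines, sites),
                          host_profile = host_cfdna_profile(),
                          graft_profile = ctdna_profile(),
                          classifier_rates = list(
                            A = c(fnr = 0.05, fpr = 0.010),
                            B = c(fnr = 0.10, fpr = 0.005)),
                          low_mapq_rate = 0.05) {
  stopifnot(length(cell_lines) == 2L, length(sites) == 2L)
  if (replicates_per_group < 1L)
    stop("invalid spec: replicates_per_group must be >= 1")
  if (controls < 0L) stop("invalid spec: controls must be >= 0")
  fr <- ctdna_fraction_range
  if (length(fr) != 2L || any(fr <= 0) || any(fr >= 1) || fr[1] > fr[2])
    stop("invalid spec: ctdna_fraction_range must be within (0, 1)")
  for (ef in fsd_effects) {
    prof <- if (ef$target == "host_cfdna") host_profile else graft_profile
    if (ef$range[1] < prof$support[1] || ef$range[2] > prof$support[2])
      stop("invalid spec: fsd_effect range outside profile support")
  }
  structure(list(cell_lines = cell_lines, sites = sites,
                 replicates_per_group = as.integer(replicates_per_group),
                 controls = as.integer(controls),
                 ctdna_fraction_range = fr,
                 fragments_per_sample = as.integer(fragments_per_sample),
                 fsd_effects = fsd_effects,
                 host_profile = host_profile,
                 graft_profile = graft_profile,
                 classifier_rates = classifier_rates,
                 low_mapq_rate = low_mapq_rate),
            class = "cohort_design")
}

## Segment table for weighted placement: chromosome intervals with
## per-interval placement weight (default 1, overridden by `weights`).
placement_segments <- function(genome, weights = NULL) {
  segs <- rbindlist(lapply(names(genome$seqlengths), function(cn) {
    L <- genome$seqlengths[[cn]]
    b <- c(0L, L)
    if (!is.null(weights)) {
      w <- weights[chrom == cn]
      b <- sort(unique(c(b, w$start, w$end)))
      b <- b[b >= 0 & b <= L]
    }
    dt <- data.table(chrom = cn, start = head(b, -1L), end = tail(b, -1L),
                     weight = 1)
    if (!is.null(weights)) {
      w <- weights[chrom == cn]
      for (i in seq_len(nrow(w)))
        dt[start >= w$start[i] & end <= w$end[i], weight := w$weight[i]]
    }
    dt
  }))
  segs[, width := end - start]
  segs[width > 0]
}

## Place fragments of given lengths: segment sampled by width*weight,
## start uniform within the segment, end clamped to the chromosome.
place_fragments <- function(genome, lengths, weights = NULL) {
  segs <- placement_segments(genome, weights)
  n <- length(lengths)
  idx <- sample.int(nrow(segs), n, replace = TRUE,
                    prob = segs$width * segs$weight)
  start <- as.integer(floor(segs$start[idx] + runif(n) * segs$width[idx]))
  chrom <- segs$chrom[idx]
  L <- genome$seqlengths[chrom]
  over <- start + lengths > L
  start[over] <- as.integer(L[over] - lengths[over])
  start[start < 0L] <- 0L
  data.table(chrom = chrom, start = start,
             end = start + as.integer(lengths))
}

#' Default copy-number profiles for the graft genome
#'
#' Gives each cell line a distinct large-scale gain (weight 1.6 on the
#' first half of one chromosome) and loss (weight 0.5 on half of another),
#' chosen deterministically from the chromosome order so the two cell
#' lines are separable from binned coverage alone.
#'
#' @param graft_genome A [genome_model] for the graft (human-like) genome.
#' @param cell_lines Two cell-line labels.
#' @return `data.table` with columns `cell_line, chrom, start, end, weight`.
#' @export
default_cna_profiles <- function(graft_genome,
                                 cell_lines = c("A549", "M97H")) {
  cn <- names(graft_genome$seqlengths)
  if (length(cn) < 2L) stop("graft genome needs >= 2 chromosomes")
  L <- graft_genome$seqlengths
  pick <- function(i) cn[((i - 1L) %% length(cn)) + 1L]
  rbindlist(lapply(seq_along(cell_lines), function(k) {
    gain <- pick(k)
    loss <- pick(k + 1L)
    data.table(cell_line = cell_lines[k],
               chrom = c(gain, loss),
               start = c(0L, as.integer(L[[loss]] %/% 2L)),
               end = c(as.integer(L[[gain]] %/% 2L), L[[loss]]),
               weight = c(1.6, 0.5))
  }))
}

## Per-read classifier verdicts for one method.
classifier_calls <- function(species, fnr, fpr) {
  n <- length(species)
  u <- runif(n)
  ifelse(species == "graft",
         ifelse(u < fnr, "mouse", "human"),
         ifelse(u < fpr, "human", "mouse"))
}

#' Generate a synthetic CDX cohort
#'
#' Simulates a full xenograft plasma study: host-only control samples and
#' CDX samples mixing host cfDNA with graft ctDNA at a per-sample tumor
#' fraction drawn from the design range. Every fragment carries its true
#' species; two imperfect species classifiers emit per-read verdicts;
#' graft placement is modulated by per-region copy-number weights; host
#' reads mistaken for human ("human-prone" reads) receive graft-genome
#' placements concentrated in shared homology regions, which is what makes
#' a control-derived blacklist effective.
#'
#' @param design A [cohort_design].
#' @param host_genome,graft_genome [genome_model]s for the two species.
#' @param seed Integer seed; all randomness is derived from it.
#' @param cna_profiles Optional per-cell-line placement weights
#'   (`data.table`: `cell_line, chrom, start, end, weight`); default
#'   [default_cna_profiles()].
#' @param n_homology Number of shared homology regions on the graft genome.
#' @param homology_width Width (bp) of each homology region.
#'
#' @return A list of class `cdx_cohort` with elements:
#' \describe{
#'   \item{fragments}{truth table: `sample_id, read_id, species, chrom,
#'     start, end, length_bp, mapq` (coordinates on the species' own
#'     genome).}
#'   \item{sample_sheet}{`sample_id, type, cell_line, site, ctdna_fraction`.}
#'   \item{verdicts}{long table `read_id, method, call`.}
#'   \item{graft_realignments}{graft-genome alignments of every read called
#'     human by at least one method (the re-alignment step's output).}
#'   \item{control_human_alignments}{graft-genome intervals of control
#'     human-prone reads, per (sample, method): blacklist input.}
#'   \item{homology_regions}{truth for the homology regions.}
#' }
#' @export
generate_cohort <- function(design, host_genome, graft_genome, seed,
                            cna_profiles = NULL, n_homology = 3L,
                            homology_width = 10000L) {
  stopifnot(inherits(design, "cohort_design"),
            inherits(host_genome, "genome_model"),
            inherits(graft_genome, "genome_model"))
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  if (is.null(cna_profiles))
    cna_profiles <- default_cna_profiles(graft_genome, design$cell_lines)

  ## sample sheet
  cdx <- CJ(cell_line = design$cell_lines, site = design$sites,
            rep = seq_len(design$replicates_per_group))
  cdx[, sample_id := paste(cell_line, site, rep, sep = "_")]
  cdx[, type := "cdx"]
  ctrl <- data.table(cell_line = NA_character_, site = NA_character_,
                     rep = seq_len(design$controls))
  ctrl[, sample_id := paste0("CTRL", rep)]
  ctrl[, type := "control"]
  sheet <- rbind(ctrl, cdx)[, .(sample_id, type, cell_line, site)]
  fr <- design$ctdna_fraction_range
  sheet[, ctdna_fraction := ifelse(type == "cdx",
                                   runif(.N, fr[1], fr[2]), 0)]

  ## shared homology regions on the graft genome
  glen <- graft_genome$seqlengths
  hchrom <- sample(names(glen), n_homology, replace = TRUE,
                   prob = as.numeric(glen))
  hstart <- as.integer(floor(runif(n_homology) *
                               (glen[hchrom] - homology_width)))
  homology <- data.table(chrom = hchrom, start = hstart,
                         end = hstart + as.integer(homology_width))

  draw_mapq <- function(n, low_rate) {
    low <- runif(n) < low_rate
    ifelse(low, sample.int(30L, n, replace = TRUE) - 1L,
           sample(30:60, n, replace = TRUE))
  }

  host_effects_for <- function(cl, st) {
    Filter(function(ef) ef$target == "host_cfdna" &&
             ((ef$factor == "cell_line" && identical(ef$level, cl)) ||
              (ef$factor == "site" && identical(ef$level, st))),
           design$fsd_effects)
  }
  graft_effects_for <- function(cl, st) {
    Filter(function(ef) ef$target == "ctdna" &&
             ((ef$factor == "cell_line" && identical(ef$level, cl)) ||
              (ef$factor == "site" && identical(ef$level, st))),
           design$fsd_effects)
  }

  frag_list <- vector("list", nrow(sheet))
  next_id <- 1L
  for (i in seq_len(nrow(sheet))) {
    sm <- sheet[i]
    n_tot <- design$fragments_per_sample
    n_graft <- if (sm$type == "cdx")
      rbinom(1L, n_tot, sm$ctdna_fraction) else 0L
    n_host <- n_tot - n_graft

    hpmf <- length_pmf(design$host_profile,
                       host_effects_for(sm$cell_line, sm$site))
    hl <- sample(hpmf$length_bp, n_host, replace = TRUE, prob = hpmf$prob)
    hpos <- place_fragments(host_genome, hl)
    host_dt <- data.table(sample_id = sm$sample_id, species = "host",
                          chrom = hpos$chrom, start = hpos$start,
                          end = hpos$end, length_bp = as.integer(hl))
    if (n_graft > 0L) {
      gpmf <- length_pmf(design$graft_profile,
                         graft_effects_for(sm$cell_line, sm$site))
      gl <- sample(gpmf$length_bp, n_graft, replace = TRUE, prob = gpmf$prob)
      gw <- cna_profiles[cell_line == sm$cell_line,
                         .(chrom, start, end, weight)]
      gpos <- place_fragments(graft_genome, gl, weights = gw)
      graft_dt <- data.table(sample_id = sm$sample_id, species = "graft",
                             chrom = gpos$chrom, start = gpos$start,
                             end = gpos$end, length_bp = as.integer(gl))
      dt <- rbind(host_dt, graft_dt)
    } else dt <- host_dt
    dt[, mapq := draw_mapq(.N, design$low_mapq_rate)]
    dt[, read_id := next_id + seq_len(.N) - 1L]
    next_id <- next_id + nrow(dt)
    frag_list[[i]] <- dt
  }
  fragments <- rbindlist(frag_list)
  setcolorder(fragments, c("sample_id", "read_id", "species", "chrom",
                           "start", "end", "length_bp", "mapq"))

  ## classifier verdicts, one per (read, method)
  methods <- names(design$classifier_rates)
  verdicts <- rbindlist(lapply(methods, function(m) {
    r <- design$classifier_rates[[m]]
    data.table(read_id = fragments$read_id, method = m,
               call = classifier_calls(fragments$species,
                                       r[["fnr"]], r[["fpr"]]))
  }))

  ## graft-genome placements for host reads called human by >= 1 method
  called_human <- unique(verdicts[call == "human", read_id])
  fp_hosts <- fragments[species == "host" & read_id %in% called_human]
  if (nrow(fp_hosts) > 0L) {
    in_hom <- runif(nrow(fp_hosts)) < 0.7
    hidx <- sample.int(nrow(homology), nrow(fp_hosts), replace = TRUE)
    hom_start <- as.integer(floor(homology$start[hidx] +
                                    runif(nrow(fp_hosts)) *
                                    (homology_width - fp_hosts$length_bp)))
    unif <- place_fragments(graft_genome, fp_hosts$length_bp)
    fp_realn <- data.table(
      sample_id = fp_hosts$sample_id, read_id = fp_hosts$read_id,
      chrom = ifelse(in_hom, homology$chrom[hidx], unif$chrom),
      start = ifelse(in_hom, hom_start, unif$start))
    fp_realn[, end := start + fp_hosts$length_bp]
    fp_realn[, mapq := ifelse(runif(.N) < 0.5,
                              sample.int(30L, .N, replace = TRUE) - 1L,
                              sample(30:60, .N, replace = TRUE))]
  } else {
    fp_realn <- data.table(sample_id = character(), read_id = integer(),
                           chrom = character(), start = integer(),
                           end = integer(), mapq = integer())
  }
  true_graft <- fragments[species == "graft" & read_id %in% called_human,
                          .(sample_id, read_id, chrom, start, end, mapq)]
  graft_realignments <- rbind(true_graft, fp_realn)

  ## blacklist input: control human-prone intervals per (sample, method)
  ctrl_ids <- sheet[type == "control", sample_id]
  ctrl_fp <- merge(fp_realn[sample_id %in% ctrl_ids],
                   verdicts[call == "human"], by = "read_id")
  control_human_alignments <- ctrl_fp[, .(chrom, start, end, sample_id,
                                          method)]

  structure(list(fragments = fragments, sample_sheet = sheet,
                 verdicts = verdicts,
                 graft_realignments = graft_realignments,
                 control_human_alignments = control_human_alignments,
                 homology_regions = homology,
                 cna_profiles = cna_profiles,
                 design = design, seed = seed),
            class = "cdx_cohort")
}

#' @export
print.cdx_cohort <- function(x, ...) {
  cat(sprintf("cdx_cohort: %d samples (%d CDX, %d controls), %d fragments\n",
              nrow(x$sample_sheet), sum(x$sample_sheet$type == "cdx"),
              sum(x$sample_sheet$type == "control"), nrow(x$fragments)))
  invisible(x)
}
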