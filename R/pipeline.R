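## End-to-end orchestration: config validation, the simulate -> separate ->
## features -> cna -> stats pipeline, and the run manifest.

#' Default run configuration
#'
#' Nested list of every tunable in the synthetic study: genome sizes,
#' cohort design, filter thresholds (MAPQ 30, fragment length 50-1000 bp),
#' feature definitions (S2L ranges, FSD bins 65-399 step 5), CNA binning
#' and the AUC/permutation settings.
#'
#' @return Named nested list understood by [validate_config()] and
#'   [run_study()].
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = NULL,
    genomes = list(
      host = list(n_chrom = 4L, chrom_length = 2e6, arm_fraction = 0,
                  gc = 0.42),
      graft = list(n_chrom = 3L, chrom_length = 2e6, arm_fraction = 0.4,
                   gc = 0.41)),
    profiles = list(
      host = list(mode = 167, period = 10, comb_depth = 0.7,
                  short_boost = 1, dinucleosome_weight = 0.04,
                  support = c(50L, 500L), sd_below = 25, sd_above = 15),
      graft = list(mode = 143, period = 7, comb_depth = 0.5,
                   short_boost = 1.6, dinucleosome_weight = 0.02,
                   support = c(50L, 500L), sd_below = 16, sd_above = 12)),
    design = list(
      cell_lines = c("A549", "M97H"),
      sites = c("pancreas", "rectum"),
      replicates_per_group = 3L,
      controls = 3L,
      ctdna_fraction_range = c(0.0021, 0.1896),
      fragments_per_sample = 150000L,
      fsd_effects = NULL,  # NULL = default cell-line/site effects
      classifier_rates = list(A = c(fnr = 0.05, fpr = 0.010),
                              B = c(fnr = 0.10, fpr = 0.005)),
      low_mapq_rate = 0.05),
    filters = list(min_mapq = 30L, min_len = 50L, max_len = 1000L,
                   downsample_host = NULL),
    features = list(fsd_min = 65L, fsd_max = 399L, fsd_step = 5L,
                    s2l_short = c(80L, 160L), s2l_long = c(161L, 200L),
                    motifs = TRUE),
    cna = list(bin_width = 2e5, pseudocount = 0.5),
    stats = list(auc_informative = 0.9, auc_permutation = 0.8,
                 n_perm = 1000L)
  )
}

.check_known_keys <- function(cfg, defaults, path = "") {
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config key: ", paste0(path, unknown[1]))
  for (k in names(cfg)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(cfg[[k]]))
      .check_known_keys(cfg[[k]], defaults[[k]], paste0(path, k, "$"))
  }
  invisible(TRUE)
}

#' Validate and normalise a run configuration
#'
#' Fills defaults, rejects unknown keys, and checks cross-field
#' consistency: fragment length bounds must be ordered, the FSD bin range
#' must tile exactly into bins (65-399 in steps of 5 does; an end of 400
#' does not), and the S2L ranges must lie within the retained fragment
#' length range.
#'
#' @param config Partial configuration list (possibly empty) or a YAML
#'   file path.
#' @return The completed configuration.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  defaults <- default_config()
  .check_known_keys(config, defaults)
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)

  fl <- cfg$filters
  if (fl$min_len >= fl$max_len)
    stop("contradictory config: filters$min_len (", fl$min_len,
         ") must be below filters$max_len (", fl$max_len, ")")
  ft <- cfg$features
  if ((ft$fsd_max - ft$fsd_min + 1L) %% ft$fsd_step != 0L)
    stop("contradictory config: features$fsd_min..features$fsd_max (",
         ft$fsd_min, "-", ft$fsd_max, ") is not a whole number of ",
         ft$fsd_step, " bp bins")
  for (r in c("s2l_short", "s2l_long")) {
    if (ft[[r]][1] < fl$min_len || ft[[r]][2] > fl$max_len)
      stop("contradictory config: features$", r,
           " lies outside filters$min_len..filters$max_len")
  }
  st <- cfg$stats
  if (st$n_perm < 1L) stop("contradictory config: stats$n_perm must be >= 1")
  for (thr in c("auc_informative", "auc_permutation"))
    if (st[[thr]] <= 0.5 || st[[thr]] > 1)
      stop("contradictory config: stats$", thr, " must be in (0.5, 1]")
  cfg
}

.build_design <- function(cfg) {
  d <- cfg$design
  hp <- do.call(size_profile, cfg$profiles$host)
  gp <- do.call(size_profile, cfg$profiles$graft)
  effects <- if (is.null(d$fsd_effects)) {
    default_fsd_effects(d$cell_lines, d$sites)
  } else {
    lapply(d$fsd_effects, function(ef)
      if (inherits(ef, "fsd_effect")) ef else do.call(fsd_effect, ef))
  }
  rates <- lapply(d$classifier_rates, function(r) {
    r <- unlist(r)
    c(fnr = unname(r[["fnr"]]), fpr = unname(r[["fpr"]]))
  })
  cohort_design(cell_lines = d$cell_lines, sites = d$sites,
                replicates_per_group = d$replicates_per_group,
                controls = d$controls,
                ctdna_fraction_range = d$ctdna_fraction_range,
                fragments_per_sample = d$fragments_per_sample,
                fsd_effects = effects,
                host_profile = hp, graft_profile = gp,
                classifier_rates = rates,
                low_mapq_rate = d$low_mapq_rate)
}

.fsd_matrix <- function(fragments, arm_table, bins, sample_ids) {
  rows <- lapply(sample_ids, function(s) {
    fsd_as_vector(compute_fsd(fragments[sample_id == s], arm_table, bins))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- sample_ids
  m
}

.motif_matrix <- function(fragments, genome, flavor, sample_ids) {
  rows <- lapply(sample_ids, function(s) {
    sp <- compute_motif_spectrum(fragments[sample_id == s], genome, flavor)
    setNames(sp$frequency, sp$motif)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- sample_ids
  m
}

#' Run the full synthetic CDX study
#'
#' Orchestrates simulate -> separate -> features -> cna -> stats: builds
#' the two reference genomes and the cohort, isolates the ctDNA stream
#' (classifier-call merge, blacklist, MAPQ and length filters) and the
#' host cfDNA stream, computes per-sample FSD (and optionally motif)
#' matrices, the CNA log2-ratio matrix with PCA, and the four permutation
#' contrasts (host cfDNA and ctDNA, each grouped by cell line and by
#' site), plus informative-marker counts at the reporting threshold.
#' Fully deterministic for a fixed config seed.
#'
#' @param config Configuration list or YAML path; see [default_config()].
#' @param genomes Optional pre-built list `list(host =, graft =)` of
#'   [genome_model]s, reused across runs to skip sequence simulation.
#' @return List of class `xenofrag_study`: `config`, `genomes`, `cohort`,
#'   `blacklist`, `streams` (host / ctdna fragment tables), `features`,
#'   `cna`, `stats` (permutation results and the informative-count
#'   table), `manifest`.
#' @export
run_study <- function(config = list(), genomes = NULL) {
  cfg <- validate_config(config)
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 12L)

  ## --- simulate -----------------------------------------------------
  if (is.null(genomes)) {
    gh <- cfg$genomes$host
    gg <- cfg$genomes$graft
    host <- generate_reference(
      setNames(rep(gh$chrom_length, gh$n_chrom),
               paste0("hchr", seq_len(gh$n_chrom))),
      arm_fraction = gh$arm_fraction, species_tag = "host", gc = gh$gc,
      seed = seeds[1])
    graft <- generate_reference(
      setNames(rep(gg$chrom_length, gg$n_chrom),
               paste0("gchr", seq_len(gg$n_chrom))),
      arm_fraction = gg$arm_fraction, species_tag = "graft", gc = gg$gc,
      seed = seeds[2])
    genomes <- list(host = host, graft = graft)
  }
  design <- .build_design(cfg)
  cohort <- generate_cohort(design, genomes$host, genomes$graft,
                            seed = seeds[3])
  sheet <- cohort$sample_sheet
  cdx_ids <- sheet[type == "cdx", sample_id]

  ## --- separate -----------------------------------------------------
  blacklist <- build_blacklist(cohort$control_human_alignments,
                               genome = genomes$graft)
  human_ids <- merge_human_calls(cohort$verdicts)
  fl <- cfg$filters
  ctdna <- isolate_ctdna(cohort$graft_realignments, human_ids, blacklist,
                         min_mapq = fl$min_mapq, min_len = fl$min_len,
                         max_len = fl$max_len)
  ctdna_counts <- attr(ctdna, "counts")

  host_raw <- cohort$fragments[species == "host" & !read_id %in% human_ids]
  n_host0 <- nrow(host_raw)
  host_mq <- filter_alignments(host_raw, NULL, fl$min_mapq)
  host_stream <- filter_fragment_lengths(host_mq, fl$min_len, fl$max_len)
  if (!is.null(fl$downsample_host)) {
    host_stream <- host_stream[
      , downsample_fragments(.SD, fl$downsample_host, seed = seeds[4]),
      by = sample_id]
  }

  ## --- features -----------------------------------------------------
  bins <- fsd_bins(cfg$features$fsd_min, cfg$features$fsd_max,
                   cfg$features$fsd_step)
  host_ids <- sheet$sample_id
  fsd_host <- .fsd_matrix(host_stream, genomes$host, bins, host_ids)
  fsd_ctdna <- .fsd_matrix(ctdna, genomes$graft, bins, cdx_ids)

  s2l_of <- function(frags, ids) {
    vapply(ids, function(s) {
      tryCatch(compute_s2l(frags[sample_id == s],
                           cfg$features$s2l_short,
                           cfg$features$s2l_long)$ratio,
               error = function(e) NA_real_)
    }, numeric(1L))
  }
  s2l <- list(host = s2l_of(host_stream, host_ids),
              ctdna = s2l_of(ctdna, cdx_ids))

  pooled_ctdna <- pool_replicates(ctdna[sample_id %in% cdx_ids], sheet)
  pooled_hist <- lapply(split(pooled_ctdna, pooled_ctdna$group),
                        size_histogram)

  features <- list(fsd = list(host = fsd_host, ctdna = fsd_ctdna),
                   s2l = s2l, pooled_ctdna_histograms = pooled_hist)
  if (isTRUE(cfg$features$motifs)) {
    features$edm <- list(
      host = .motif_matrix(host_stream, genomes$host, "EDM", host_ids),
      ctdna = .motif_matrix(ctdna, genomes$graft, "EDM", cdx_ids))
    features$bpm <- list(
      host = .motif_matrix(host_stream, genomes$host, "BPM", host_ids),
      ctdna = .motif_matrix(ctdna, genomes$graft, "BPM", cdx_ids))
  }

  ## --- cna ----------------------------------------------------------
  grid <- bin_grid(genomes$graft, cfg$cna$bin_width)
  counts_list <- lapply(setNames(cdx_ids, cdx_ids), function(s)
    bin_counts(ctdna[sample_id == s], grid))
  nonzero <- vapply(counts_list, function(b) sum(b$count) > 0, logical(1L))
  cna <- NULL
  if (sum(nonzero) >= 2L) {
    lr <- log2_ratio_matrix(counts_list[nonzero], grid,
                            pseudocount = cfg$cna$pseudocount)
    cna <- list(grid = grid, counts = counts_list, log2 = lr,
                pca = cna_pca(lr))
  }

  ## --- stats --------------------------------------------------------
  labels_for <- function(factor_name)
    setNames(sheet[type == "cdx"][[factor_name]], cdx_ids)
  perm <- list()
  k <- 0L
  for (stream in c("host", "ctdna")) {
    mat <- features$fsd[[stream]][cdx_ids, , drop = FALSE]
    for (fac in c("cell_line", "site")) {
      k <- k + 1L
      perm[[paste(stream, fac, sep = "_")]] <-
        permutation_test(mat, labels_for(fac),
                         n_perm = cfg$stats$n_perm,
                         threshold = cfg$stats$auc_permutation,
                         seed = seeds[4L + k])
    }
  }

  feature_sets <- list(FSD = features$fsd)
  if (isTRUE(cfg$features$motifs))
    feature_sets <- c(feature_sets,
                      list(EDM = features$edm, BPM = features$bpm))
  informative <- rbindlist(lapply(names(feature_sets), function(fn) {
    rbindlist(lapply(c("host", "ctdna"), function(stream) {
      mat <- feature_sets[[fn]][[stream]][cdx_ids, , drop = FALSE]
      rbindlist(lapply(c("cell_line", "site"), function(fac) {
        ci <- count_informative(mat, labels_for(fac),
                                cfg$stats$auc_informative)
        data.table(stream = stream, factor = fac, feature = fn,
                   n_features = ncol(mat), informative = ci$count)
      }))
    }))
  }))

  manifest <- list(
    seeds = seeds,
    thresholds = cfg$filters,
    fragment_counts = data.table(
      stage = c("generated", "host_candidates", "host_after_mapq",
                "host_retained", "ctdna_candidates",
                "ctdna_after_mapq_blacklist", "ctdna_retained"),
      count = c(nrow(cohort$fragments), n_host0, nrow(host_mq),
                nrow(host_stream), ctdna_counts[["candidates"]],
                ctdna_counts[["after_mapq_blacklist"]],
                ctdna_counts[["retained"]])))

  res <- structure(list(config = cfg, genomes = genomes, cohort = cohort,
                        blacklist = blacklist,
                        streams = list(host = host_stream, ctdna = ctdna),
                        features = features, cna = cna,
                        stats = list(permutation = perm,
                                     informative = informative),
                        manifest = manifest),
                   class = "xenofrag_study")
  if (!is.null(cfg$output_dir)) write_study(res, cfg$output_dir)
  res
}

#' Write the main result tables of a study to a directory
#' @param study A [run_study()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(study$cohort$sample_sheet, file.path(dir, "sample_sheet.tsv"))
  write_tsv(study$manifest$fragment_counts,
            file.path(dir, "fragment_counts.tsv"))
  write_tsv(study$stats$informative, file.path(dir, "informative.tsv"))
  perm <- rbindlist(lapply(names(study$stats$permutation), function(nm) {
    p <- study$stats$permutation[[nm]]
    data.table(contrast = nm, observed = p$observed_informative,
               p_value = p$p_value, null_q95 = p$null_q95)
  }))
  write_tsv(perm, file.path(dir, "permutation.tsv"))
  if (nrow(study$blacklist) > 0L)
    fwrite(study$blacklist, file.path(dir, "blacklist.bed"), sep = "\t",
           col.names = FALSE)
  for (stream in names(study$streams))
    write_fragments_bed(study$streams[[stream]],
                        file.path(dir, paste0(stream, "_fragments.bed")))
  for (stream in names(study$features$fsd)) {
    m <- study$features$fsd[[stream]]
    dt <- data.table(sample_id = rownames(m), as.data.table(m))
    write_tsv(dt, file.path(dir, paste0("fsd_", stream, ".tsv")))
  }
  if (!is.null(study$cna))
    write_tsv(data.table(sample_id = rownames(study$cna$log2),
                         as.data.table(unclass(study$cna$log2))),
              file.path(dir, "cna_log2.tsv"))
  invisible(dir)
}

#' @export
print.xenofrag_study <- function(x, ...) {
  cat("xenofrag_study\n")
  print(x$manifest$fragment_counts)
  cat("\npermutation contrasts (FSD):\n")
  for (nm in names(x$stats$permutation)) {
    p <- x$stats$permutation[[nm]]
    cat(sprintf("  %-18s observed %4d  p = %.3f\n", nm,
                p$observed_informative, p$p_value))
  }
  invisible(x)
}
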