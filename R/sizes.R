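## Fragment length models: nucleosomal size profiles and sampling.

#' Fragment size profile
#'
#' Parametric model of a cfDNA fragment length distribution. The base
#' distribution is a skewed discrete unimodal kernel around `mode`
#' (Gaussian with separate widths below and above the mode) plus a
#' di-nucleosome bump centred at `2 * mode`. Below the mode the kernel is
#' multiplied by a cosine comb of the given `period` (the ~10 bp nuclease
#' ladder) and by a smooth sub-mononucleosomal enrichment factor that ramps
#' from 1 near the mode up to `short_boost` in the short tail, then the
#' whole mass function is renormalised.
#'
#' @param mode Modal fragment length in bp.
#' @param period Ladder period in bp below the mode.
#' @param comb_depth Relative amplitude of the cosine comb, in \[0, 1\].
#' @param short_boost Multiplier (>= 0) for the sub-mononucleosomal tail;
#'   1 leaves the tail untouched. The factor ramps in logistically around
#'   `mode - 35` bp with a 10 bp scale so neither the modal peak nor the
#'   first ladder tooth below it is moved.
#' @param dinucleosome_weight Probability mass of the di-nucleosome bump
#'   (Gaussian at `2 * mode`, sd 30 bp).
#' @param support Length-2 integer vector `[min, max]` of attainable lengths.
#' @param sd_below,sd_above Kernel widths (bp) below/above the mode. Equal
#'   values give a symmetric kernel.
#'
#' @return An object of class `size_profile`.
#' @seealso [host_cfdna_profile()], [ctdna_profile()],
#'   [sample_fragment_lengths()]
#' @export
size_profile <- function(mode = 167, period = 10, comb_depth = 0.7,
                         short_boost = 1, dinucleosome_weight = 0.04,
                         support = c(50L, 500L), sd_below = 25,
                         sd_above = 15) {
  if (length(support) != 2L || support[1] >= support[2])
    stop("invalid spec: empty or inverted support")
  if (mode < support[1] || mode > support[2])
    stop("invalid spec: mode must lie within support")
  if (period <= 0) stop("invalid spec: period must be > 0")
  if (comb_depth < 0 || comb_depth > 1)
    stop("invalid spec: comb_depth must be in [0, 1]")
  if (short_boost < 0 || dinucleosome_weight < 0 || dinucleosome_weight > 1)
    stop("invalid spec: weights must be >= 0 (dinucleosome_weight <= 1)")
  structure(list(mode = mode, period = period, comb_depth = comb_depth,
                 short_boost = short_boost,
                 dinucleosome_weight = dinucleosome_weight,
                 support = as.integer(support),
                 sd_below = sd_below, sd_above = sd_above),
            class = "size_profile")
}

#' Default size profiles for host cfDNA and tumor-derived ctDNA
#'
#' `host_cfdna_profile()` models normal plasma cfDNA: mode 167 bp with a
#' deep ~10 bp sub-mononucleosomal ladder. `ctdna_profile()` models
#' tumor-derived ctDNA: shorter mode (143 bp), shorter ladder period
#' (7 bp) and an enriched short-fragment tail.
#'
#' @param ... Overrides passed to [size_profile()].
#' @return A `size_profile`.
#' @export
host_cfdna_profile <- function(...) {
  args <- utils::modifyList(
    list(mode = 167, period = 10, comb_depth = 0.7, short_boost = 1,
         dinucleosome_weight = 0.04, support = c(50L, 500L),
         sd_below = 25, sd_above = 15),
    list(...))
  do.call(size_profile, args)
}

#' @rdname host_cfdna_profile
#' @export
ctdna_profile <- function(...) {
  args <- utils::modifyList(
    list(mode = 143, period = 7, comb_depth = 0.5, short_boost = 1.6,
         dinucleosome_weight = 0.02, support = c(50L, 500L),
         sd_below = 16, sd_above = 12),
    list(...))
  do.call(size_profile, args)
}

#' Discrete probability mass function of a size profile
#'
#' @param profile A [size_profile].
#' @param effects Optional list of [fsd_effect()]-style range enrichments,
#'   each with elements `range` (length-2, bp, inclusive) and `multiplier`;
#'   the pmf is multiplied by `multiplier` over `range` and renormalised.
#' @return `data.table` with columns `length_bp` and `prob` over the support.
#' @export
length_pmf <- function(profile, effects = NULL) {
  stopifnot(inherits(profile, "size_profile"))
  s <- profile$support[1]:profile$support[2]
  sdv <- ifelse(s < profile$mode, profile$sd_below, profile$sd_above)
  kern <- exp(-0.5 * ((s - profile$mode) / sdv)^2)
  comb <- ifelse(s <= profile$mode,
                 1 + profile$comb_depth *
                   cos(2 * pi * (profile$mode - s) / profile$period),
                 1)
  boost <- 1 + (profile$short_boost - 1) *
    stats::plogis((profile$mode - 35 - s) / 10)
  mono <- kern * comb * boost
  mono <- mono / sum(mono)
  di <- exp(-0.5 * ((s - 2 * profile$mode) / 30)^2)
  w <- if (sum(di) > 0) profile$dinucleosome_weight else 0
  if (w > 0) di <- di / sum(di)
  prob <- (1 - w) * mono + w * di

  if (!is.null(effects)) {
    for (ef in effects) {
      idx <- s >= ef$range[1] & s <= ef$range[2]
      if (!any(idx))
        stop("invalid spec: effect range outside profile support")
      prob[idx] <- prob[idx] * ef$multiplier
    }
    prob <- prob / sum(prob)
  }
  data.table(length_bp = s, prob = prob)
}

#' Sample fragment lengths from a size profile
#'
#' @param profile A [size_profile].
#' @param n Number of lengths to draw (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @param effects Optional enrichment effects, see [length_pmf()].
#' @return Integer vector of `n` fragment lengths within the support.
#' @examples
#' x <- sample_fragment_lengths(host_cfdna_profile(), 1e4, seed = 1)
#' table(x)[which.max(table(x))]  # modal length
#' @export
sample_fragment_lengths <- function(profile, n, seed = NULL, effects = NULL) {
  if (n < 1) stop("n must be >= 1")
  pmf <- length_pmf(profile, effects = effects)
  if (!is.null(seed)) set.seed(seed)
  sample(pmf$length_bp, n, replace = TRUE, prob = pmf$prob)
}
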