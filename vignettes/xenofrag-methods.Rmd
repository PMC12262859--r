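---
title: "Dissecting cfDNA and ctDNA fragmentomics with synthetic xenograft cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting cfDNA and ctDNA fragmentomics with synthetic xenograft cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenofrag)
library(data.table)
```

## The problem

Plasma cell-free DNA (cfDNA) is a mixture: in a tumor-bearing organism most
fragments come from non-tumor (largely hematopoietic) cells, with a minority
of circulating tumor DNA (ctDNA). Fragmentation itself is informative —
fragment length, the nucleotide motifs at fragment ends and breakpoints, and
the per-region coverage all carry signal about the cells and nucleases that
produced the fragments. The difficulty is that tumor-associated changes in a
patient's cfDNA could come from the ctDNA itself, from altered non-tumor
cfDNA, or both, and in a plain plasma sample these two streams cannot be
separated.

A cell line-derived xenograft (CDX) design breaks this degeneracy: a human
tumor cell line grows in a mouse, so every sequenced fragment is either
mouse (host cfDNA) or human (graft ctDNA) and can, in principle, be
assigned to its species by alignment-based classification. `xenofrag`
implements this dissection as a fully synthetic, testable pipeline:

1. **simulate** a two-species cohort with known truth,
2. **separate** the ctDNA stream using classifier verdicts, a
   control-derived blacklist, and quality filters,
3. compute **fragmentomics features** (S2L, size histograms and
   periodicity, end/breakpoint motif spectra, per-arm fragment size
   distributions),
4. build the binned **copy-number** log2-ratio matrix, and
5. run the **marker statistics** (per-marker AUC, informative-marker
   counts, balanced-label permutation nulls, rank-sum/t tests with BH
   correction, clustering/PCA).

Because the generator knows the truth, every downstream claim of the
pipeline is checkable against it.

## The fragment length model

A `size_profile` describes one stream's length distribution on an integer
bp grid over `support` (default 50–500 bp):

* a skewed unimodal kernel centred on `mode` — Gaussian with width
  `sd_below` under the mode and `sd_above` above it, reflecting the sharp
  drop above the mononucleosomal peak;
* a cosine comb for lengths at or below the mode,
  `1 + comb_depth * cos(2 * pi * (mode - l) / period)`, producing the
  nuclease ladder of sub-peaks spaced `period` bp apart;
* a smooth sub-mononucleosomal enrichment that ramps logistically from 1
  near `mode - 35` bp up to `short_boost` deep in the short tail, so that
  boosting short fragments moves neither the mode nor the first ladder
  tooth;
* a di-nucleosome bump: a Gaussian at `2 * mode` (sd 30 bp) carrying
  `dinucleosome_weight` of the total mass.

The product is renormalised into a pmf; sampling is plain multinomial
draws. The defaults encode the two canonical streams:

| profile | mode | period | comb_depth | short_boost | sd_below/above |
|---|---|---|---|---|---|
| `host_cfdna_profile()` | 167 bp | 10 bp | 0.7 | 1.0 | 25 / 15 |
| `ctdna_profile()` | 143 bp | 7 bp | 0.5 | 1.6 | 16 / 12 |

The modal lengths and ladder periods are the field's standard values for
plasma cfDNA and tumor-derived ctDNA; the kernel widths, comb depth and
boost were fixed once, during design, so that (i) the sampled mode is
stable at the stated value for 10^5 fragments — the competing candidate is
always the first ladder tooth one period below the mode, so the peak must
exceed it by clearly more than counting noise — and (ii) the ladder
survives histogram smoothing and is recovered by the period estimator at
10^6 fragments. Only the peak position, period and short-fragment
enrichment are treated as biology; the functional family is an explicit
modelling choice, since fragment data constrain the peak structure but not
a distribution family. The mechanism that sets the shorter ctDNA
periodicity is not modelled; `period` is an exposed parameter, not a
mechanistic claim.

```{r lengths}
x <- sample_fragment_lengths(host_cfdna_profile(), 1e5, seed = 1)
histogram_mode(size_histogram(x))
estimate_periodicity(size_histogram(
  sample_fragment_lengths(host_cfdna_profile(), 1e6, seed = 1)))
```

## The synthetic cohort

`cohort_design()` declares a 2 cell-line x 2 site factorial with 3
replicate animals per cell (12 CDX samples) and 3 host-only controls. Per
CDX sample, the tumor fraction is drawn uniformly from 0.21%–18.96%; only
the range of observed tumor fractions is a published anchor, and the
uniform law is the maximum-entropy choice on a bounded interval. The graft
fragment count is binomial in that fraction.

Group-specific biology enters through `fsd_effect()`s, which multiply a
stream's length pmf over a bp range for samples at one factor level. The
defaults place **cell-line** effects on the **host cfDNA** stream
(220–309 bp enriched x2.0 for one line; 150–174 bp x1.3 for the other)
and **site** effects on the **ctDNA** stream (120–129 bp x2.0 for one
site; 185–214 bp x2.0 for the other). This crossed placement is the
study's key structural hypothesis — the host response tracks the tumor
cell line while ctDNA fragmentation tracks the implantation niche — and
makes the "matched factor significant, mismatched factor null" contrast a
well-posed recovery target.

Two scale choices matter and are deliberate:

* **Depth.** Real plasma studies of this kind sequence on the order of
  10^8 fragments per sample; the default synthetic design uses
  1.5 x 10^5 fragments on Mb-scale genomes so that a full cohort
  simulates in seconds and a 20-cohort recovery experiment runs in a few
  minutes on one CPU.
* **Effect sizes.** The multipliers above are larger than the subtle
  shifts seen in real data, compensating for the ~500-fold depth
  reduction: they were chosen once so that per-arm FSD counting noise at
  the lowest tumor fractions stays small relative to the planted shifts,
  and were not revisited afterwards. What the recovery test demonstrates
  is therefore the *logic* of the dissection (the right factor is
  detected on the right stream, and only there), not sensitivity at
  clinical effect sizes.

Placement is uniform within chromosomes, modulated by per-region
copy-number weights for graft fragments (`default_cna_profiles()` gives
each cell line a distinct gain and loss), which is what the CNA module
later recovers. Mapping quality is drawn with a configurable low-MAPQ
contamination rate (default 5% below 30).

Classifier behaviour is modelled phenomenologically: per read and per
method, a graft read is missed with probability `fnr` and a host read is
called human with probability `fpr` (defaults 5%/1% for method A,
10%/0.5% for method B — one more sensitive, one more specific).
Misclassified host reads receive graft-genome placements concentrated
(70%) in a small set of shared homology regions; this is the mechanism
that makes a control-derived blacklist effective, mirroring how real
cross-species mapping artifacts cluster in conserved sequence.

## ctDNA isolation

The separation module is deliberately rule-for-rule simple:

* **Blacklist.** Per (control sample, method), human-aligned intervals
  are merged; a position is blacklisted iff covered by >= 2 distinct
  samples or >= 2 distinct methods. Support is evaluated per base (via
  interval disjoint pieces) and the result re-merged: the input "regions"
  of different sources need not align in extent, so any region-level rule
  would be ambiguous. The implementation is tested against a literal
  per-base counting oracle.
* **Call merge.** A read is a ctDNA candidate if either classifier calls
  it human; ambiguous calls (`both`/`neither`) are conservatively not
  treated as human. Conflicting duplicate verdicts are an error, not a
  silent pick.
* **Filters.** MAPQ >= 30; any overlap (>= 1 bp) with a blacklisted
  interval removes an alignment — the strictest reading of "not falling
  within" a blacklisted region; fragment length must lie in 50–1000 bp
  inclusive.
* **Fragments.** From paired alignments, the fragment is the outer span
  of the two mates; orphans and cross-chromosome pairs are skipped and
  counted, never silently dropped.
* **Pooling / down-sampling.** Replicates pool by multiset union (the
  2 x 2 design yields four representative samples); down-sampling is
  uniform without replacement, and a target above the available count
  returns everything with a warning so that small synthetic runs stay
  usable.

With error-free classifiers the isolated ctDNA set equals, exactly, the
truth-labelled graft fragments that pass those same filters — the suite
asserts set equality, not a statistical resemblance.

## Fragmentomics features

* **S2L**: count of 80–160 bp fragments over count of 161–200 bp
  fragments, inclusive bounds; a zero long-count is an explicit error.
* **Size histogram**: integer-length counts; mode = argmax, smallest
  length on ties.
* **Periodicity**: centred moving average (window 3 bp) of the counts,
  then the mean spacing of successive strict local maxima inside a search
  window (default 90–160 bp, below the mononucleosomal peak). A
  local-maxima estimator is one of several defensible definitions of
  "periodicity"; it is used consistently for both streams.
* **Motif spectra** over all 4,096 6-mers, both fragment ends counted,
  read 5'→3' into the fragment so the downstream-end motif is
  reverse-complemented. EDM takes the 6 reference bases just inside each
  end; BPM takes 3 outside + 3 inside, spanning the break. Windows
  running off a chromosome are skipped with a logged count; motifs
  containing N are excluded from the denominator. The orientation
  convention is fixed and documented precisely so that hand-computed
  oracles are well-defined; the tests include a literal per-fragment
  recount.
* **FSD**: per chromosome arm, the fraction of fragments (assigned by
  start position; boundary-spanning fragments are not split) in each of
  the 67 inclusive 5-bp bins from 65 to 399 bp, normalised within arm.
  The two published arm conventions are provided: `mouse_arms()` (21
  acrocentric q arms; 1,407 features) and `human_arms()` (40 arms; 2,680
  features). For the human list, excluding the five acrocentric short
  arms and chrY leaves 41 arms (2,747 features); the published feature
  count corresponds to 40 arms, so the default additionally excludes
  chrXp — a configurable reading (`human_arms(exclude_xp = FALSE)`), not
  an assertion about intent.

## Copy-number matrix

Fragments are assigned to fixed-width bins (default 1 Mb; boundary
midpoints go to the right bin) by midpoint; bins overlapping excluded
regions are masked and never become matrix columns. Each sample's
unmasked counts are scaled to a common total, and
`log2((count + 0.5) / (expected + 0.5))` is taken against either the mean
of depth-normalised controls or, absent controls, the sample's own median
bin — the pseudocount guarantees finite values and the normalisation makes
the matrix exactly depth-invariant. Segmentation, GC correction and
tumor-fraction estimation are out of scope; on composition-controlled
synthetic genomes GC correction would be a no-op, but the hook (an
exclusion mask plus externally corrected counts) is the natural extension
point.

## Marker statistics

The per-marker AUC is computed from midranks as
`(R1 - n1(n1+1)/2) / (n1 n2)` — the Mann–Whitney statistic over all
cross-group pairs with ties counted half — and **folded** to
`max(A, 1 - A)`. Folding reports the better of the two orientations —
effectively the auto-direction convention of standard ROC software, whose
median-based heuristic agrees except in rare tie-dominated cases — and
makes the permutation null symmetric under label exchange; the suite
cross-checks against `pROC` (best of both fixed directions) on random
instances.

The permutation test shuffles the balanced labels uniformly (sampling
with replacement across iterations, not exhaustively), recomputes every
marker's folded AUC per iteration, and counts markers above the
informative threshold. Two thresholds coexist on purpose: 0.8 inside the
permutation null and 0.9 for reported informative counts; the asymmetry
is preserved as published rather than reconciled. The p-value is
`#(null >= observed) / n_perm` — it may legitimately be 0 — with an
optional `(count+1)/(n_perm+1)` estimator off by default; the one-sided
95% band is the empirical 95% quantile of the null counts. Under an
exchangeable null the p-value is approximately uniform, which the suite
checks across 200 null cohorts.

Two-group comparisons use the rank-sum test, exact when `n1 * n2 <= 400`
and tie-free, else the normal approximation with continuity correction,
with the Hodges–Lehmann interval for the shift; note that an exact
two-sided 3v3 rank-sum test cannot give p below 0.1, so small-sample
p-values reported below that level by other software necessarily come
from an approximation — both modes are exposed and neither is privileged.
Degenerate zero-variance inputs are flagged, not raised. BH adjustment
delegates to the standard step-up implementation.

## Orchestration and reproducibility

`run_study()` chains the five stages from a single validated config
(unknown keys rejected; contradictions — inverted length bounds, a bin
range that does not tile, S2L windows outside the retained lengths —
are named errors). One master seed deterministically derives all stage
seeds, so identical configs give byte-identical results; the manifest
records per-stage fragment counts, which are checked to be non-increasing
along each filter chain.

Problem sizes used by the shipped tests and reproduction script: modes
are checked on 10^5 sampled lengths and periodicity on 10^6; the factor
recovery experiment runs 20 cohorts of 15 samples x 1.5 x 10^5 fragments
on a 14 Mb genome pair; oracle equivalences run on 100 kb toy genomes and
up to 100 random marker instances. These sizes make the whole suite
feasible on a laptop-class single CPU while keeping every check
statistically meaningful at the planted effect sizes.

## What passing tests do and do not show

The generator reproduces the *statistical skeleton* assumed by the
analysis: bimodal species mixture, nucleosomal size ladders,
group-specific FSD shifts, copy-number-weighted coverage, clustered
cross-species mapping artifacts, imperfect classifiers. It does not model
GC and mappability bias, sequence-dependent nuclease preference (motif
spectra here reflect reference composition only — so motif features carry
no planted group signal and act as negative controls in the informative
count table), UMI-level duplication, library chemistry, or real homology
structure between genomes. Consequently, green tests certify the
correctness of the rules and statistics and the internal consistency of
the pipeline on data satisfying its assumptions — they do not certify
sensitivity or specificity on real plasma sequencing, where the
unmodelled biases dominate the error budget.
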