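---
title: "Methods: morphological profiling and MOA enrichment in moascreen"
author: "moascreen maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphological profiling and MOA enrichment in moascreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moascreen)
```

## The problem

High-content screens of cancer/fibroblast co-cultures image every well of a
384-well plate in three fluorescence channels — CK8/18 marking epithelial
cancer cells, vimentin marking fibroblasts, and Hoechst marking all nuclei —
after treatment with a compound library at several concentrations. The
scientific question this package addresses is whether the *morphological
profiles* of the treated cancer-cell population are consistent within a
mechanism-of-action (MOA) class: if compounds sharing a target produce
similar phenotypes, a well's profile should correlate most strongly with
wells treated by same-MOA compounds, and a rank-based enrichment statistic
over those correlations should be significant more often than chance.

`moascreen` implements the full analysis path — image preparation,
single-cell extraction, well-level profiling, and the permutation-based MOA
enrichment statistic — together with a synthetic-data generator that
emulates the screen, so every stage is tested end to end without any raw
image download.

## Pipeline stages and their conventions

### Field-of-view geometry

Each well is acquired as four overlapping camera tiles (2 x 2, 5% overlap
in the emulated design). `merge_fovs()` stacks tiles horizontally in pairs
and then vertically; the merged side is `2 * tile - overlap`. In every
overlap band the pixels of the top-/left-most tile are kept and the
trailing tile's duplicated band is cropped. Because the synthetic
`split_into_fovs()` copies overlap pixels from the parent image rather
than re-rendering them, split followed by merge is *bit-identical* — the
suite asserts this for overlaps 0–10 px. Real microscopes do not guarantee
identical overlap pixels; sub-pixel registration and blending are out of
scope, and `overlap_px` is an explicit parameter because the tile size of
the original acquisition is not derivable from the merged image size alone.

### Illumination correction

Uneven excitation and vignetting are corrected retrospectively:
`estimate_illumination()` averages many well images per channel, smooths
the mean image with a Gaussian kernel at a large spatial scale (default
sigma = 1/4 of the image side, large enough that individual cells do not
imprint), rescales to mean 1, and `apply_illumination()` divides it out.
Smoothing uses an explicit replicate (edge-extension) boundary: a circular
FFT boundary would wrap intensity across edges and visibly distort the
recovered field precisely where vignetting matters most. The kernel is
capped at the image size. The profile is floored at a tiny positive value
so division is always defined; after rescaling its mean is 1 to within
1e-6 and its minimum is strictly positive.

### Percentile intensity normalization

Before feature extraction each channel is rescaled so that its 99th
percentile maps to 255, then clipped to [0, 255]: the brightest ~1% of
pixels saturate and the remaining dynamic range is standardized across
wells and channels. Percentiles use linear interpolation between order
statistics (R's type-7 quantile); the tests pin this convention against a
direct sort-based computation. An all-zero channel has a zero percentile;
rather than divide by zero, the channel is returned as zeros with a
warning.

### Single-cell extraction

Cancer-cell objects arrive as an integer label mask (produced upstream by
a segmentation tool; the package never segments). `regions_from_mask()`
computes centroid, area, bounding box, crack-length perimeter (pixel edges
between region and complement; a single pixel has perimeter 4), and
eccentricity from the second-central-moment ellipse (0 = circle, near 1 =
line). A per-axis variance of 1/12 — the variance of a unit pixel — is
added to the moments so that a one-pixel-wide bar has eccentricity
strictly below 1, keeping the statistic inside [0, 1).

`crop_cells()` centres a `box x box` window on the floored centroid
(half-open span `[r - box %/% 2, r - box %/% 2 + box)`, 0-based); cells
whose window leaves the image are excluded and counted, so
`crops + excluded = labels`. In masked mode all pixels outside the target
label are zeroed in all three channels, isolating one cell per crop; the
conventional sizes are 50 px unmasked and 90 px masked.

`handcrafted_features()` yields a compact 23-dimensional descriptor (area,
perimeter, eccentricity, solidity, extent, and six intensity statistics
per channel over the labelled pixels). Solidity rasterises the convex hull
of pixel centres back onto the grid so it never exceeds 1; degenerate
collinear regions get solidity 1 by convention. `embed_features()` defines
the extractor contract for learned embeddings — any function from a crop
to a fixed-length vector — and ships a seeded mock (random projection of
pooled channel statistics) so the pipeline around an embedding can be
tested without network weights.

### Well profiles and robust normalization

Single-cell features are mean-aggregated per well (`aggregate_well()`);
wells with zero imaged cells are flagged missing rather than zero-filled
and take no part in control statistics or enrichment. Profiles are then
normalized per plate against the negative controls:

    normalized = (value - median(DMSO wells)) / MAD(DMSO wells)

The MAD is the raw median absolute deviation — no 1.4826 consistency
factor — matching the plain formula; the factor is available behind
`mad_scale = TRUE`. A feature whose control MAD is zero on a plate carries
no robust scale there; the default policy drops it on that plate (values
set `NA`, warned, and excluded from later correlations), with an optional
epsilon floor (`mad_epsilon`) for pipelines that prefer to keep it. The
choice between dropping and flooring is a documented convention, not an
estimate.

After normalization the negative-control median is zero per plate and
feature. With the usual twelve controls the median is the mean of two
order statistics, so "zero" holds to double precision (~1e-15) rather
than bit-exactly; with an odd number of controls it is bit-exact. The
tests assert a 1e-12 bound.

### Plate quality

`zprime()` implements the standard separation factor
`Z' = 1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|`, with per-well
cancer-cell count as the default readout — the cytotoxic positive control
(BzCl) kills most cells, so counts separate the arms. Plates with Z' > 0.5
pass. Z' is affine-invariant and at most 1; equal arm means return `-Inf`
with a warning.

## The MOA enrichment statistic

For a treated query well, all treated wells (controls excluded by default)
are ranked by the correlation of their normalized profiles with the
query's — Pearson by default, Spearman by flag; the metric is a parameter
because no single choice is canonical. The sort is stable and descending
with ties broken by well key, and the query well itself (self-correlation
exactly 1) is fixed at rank 1.

A running sum walks down the ranking with unweighted Kolmogorov–Smirnov
increments: `+1/N_hit` at wells sharing the query's MOA and `-1/N_miss`
otherwise. The increments sum to zero, so the curve always ends at 0; the
enrichment score *es* is the maximum of the running sum and lies in
[0, 1]. The score depends only on the *order* of labels, not on the
correlation magnitudes — a property the suite asserts under monotone
transforms. Choosing the unweighted scheme makes *es* scale-free; a
sign-only specification of the increments leaves the magnitudes open, and
the classic unweighted choice is the least-assumption one.

Significance: the MOA labels at ranks 2..N are shuffled uniformly
(rank 1 — the query itself — stays fixed), *es* is recomputed for each of
`n_perm = 1000` shuffles, and

    p = #( es_perm > es_obs ) / n_perm

with *strictly greater* counting and no add-one smoothing, so p = 0 is
attainable; a conservative `(k+1)/(B+1)` variant sits behind a flag. No
multiple-testing correction is applied across wells or MOAs. A query
whose MOA has fewer than two eligible wells (or no non-member) is flagged
not-computable. In the leave-compound-out variant every other well of the
query's compound (its sibling concentrations) is removed from the ranked
list before scoring, so a compound cannot enrich by matching itself.

Per co-culture and MOA, `percent_enriched` is
`100 * n(p < alpha) / n(total computable queries)`.

### Numerical exactness of ties

The running sum is computed on an exact integer scale — `+N_miss` per hit,
`-N_hit` per miss, divided by `N_hit * N_miss` once at the end. This
matters: with fractional increments, floating-point accumulation makes
mathematically equal scores differ in the last bit, and the
strictly-greater tie comparison then flips unpredictably between the
Monte-Carlo sampler and exhaustive enumeration (errors up to 0.36 in p
were observed before the integer scheme was adopted). With integer
arithmetic, ties are exact and the sampler agrees with full enumeration
to sampling error.

### Seeding

All randomness flows from one master seed. Stage seeds and per-query
permutation seeds are derived deterministically from `(seed, key)` string
hashes, so results are identical regardless of scan order or subsetting,
and the whole pipeline is byte-reproducible (asserted in the tests).

## The synthetic screen

The generator defines the conditions under which the statistics are
exercised:

* **Layout** — 384-well plates with 12 DMSO and 12 BzCl control wells
  (the usual QC design), every compound at 5 concentrations exactly once,
  positions seeded-random. The default pipeline scale is 2 plates x 44
  annotated wells (4 compounds x 5 concentrations + 24 controls) at ~50
  cells per well — a desk-scale screen that runs in seconds.
* **Effects** — each MOA class gets one direction in feature space, drawn
  once and scaled to a chosen L2 norm, multiplied by a non-negative
  concentration curve that rises with dose (default
  `0.1, 0.3, 0.6, 0.85, 1`), reflecting that low doses induce subtle or
  no morphological change. Per-plate feature offsets (sd 0.25) motivate
  the per-plate normalization; per-cell noise is unit Gaussian. DMSO
  wells receive zero effect by construction.
* **Cell counts** — healthy wells draw ~50 cells with 10% CV (controlled
  seeding); positive-control wells retain 5% of that, which is what makes
  the cell-count Z' informative. The real screen's count and intensity
  distributions are uncharacterized, so these are conventions chosen for
  realism, not estimates.
* **Images** — cells are ellipses of controlled area, eccentricity and
  orientation (fibroblasts elongated, cancer cells rounder), painted into
  the three channels with per-cell brightness jitter, a smooth
  multiplicative illumination field, and Gaussian noise. Ground-truth
  cancer masks come for free. The renderer is deliberately simple: no
  photorealism, no spectral bleed-through, no cell–cell signalling.

Because the generator is simple, passing tests demonstrate the *statistical
and geometric contracts* of the pipeline — calibration, recovery,
exactness — not performance on real microscopy, where segmentation error,
focus drift and staining variation add failure modes the simulator does
not model.

## Calibration and recovery experiments

Two seeded simulations anchor the statistical claims; both are run by the
test suite and recomputed from scratch by `scripts/acceptance.R`.

* **Type-I calibration.** A null screen (zero effect everywhere) with 6
  plates x 35 compounds x 7 MOA classes gives 1050 treated query wells;
  with 1000 permutations per query, the fraction flagged enriched at
  alpha = 0.05 is asserted to lie in [0.03, 0.07]. Note that the
  empirical rate varies between screen realizations by more than the
  binomial standard error suggests, because all queries share one profile
  matrix: across independent screens we observe rates roughly between
  0.03 and 0.08. The test fixes the screen seed; the acceptance script
  reports the rate for whatever seed it is given.
* **MOA recovery.** Ten MOA classes — the number of selected classes in
  the emulated study design — with one class given a shared shift of 3
  cell-level noise sd at the top three concentrations. The shifted class
  must exceed 60% enrichment (it typically reaches 100%), while the nine
  null classes stay far below it — the tests bound their mean at 12% and
  each class at 30%, and across screen realizations the mean lands
  roughly between 5% and 11%.

A caveat the recovery experiment exposes: the running-sum statistic is
anti-conservative for *null* MOAs when hit fractions are large. With only
4 MOA classes (25% hit fraction each) the strongly shifted wells form one
tight correlation cluster that occupies a contiguous block of every
ranking, and null-MOA enrichment rises to ~20% — the same
inter-correlation anti-conservatism known from gene-set enrichment
analysis. With the 10-class design, hit fractions are 10% and the null
classes sit at ~5%. Interpreting percent-enriched for screens with few,
large MOA classes therefore requires caution; the statistic is best
behaved when each class is a small fraction of the ranked list.

## Limitations

* The pipeline analyzes the cancer population only; fibroblast channels
  contribute context to crops but no fibroblast-level features.
* Segmentation and learned embeddings are contracts, not implementations:
  masks are inputs, and the mock extractor stands in for a CNN.
* The merge convention (keep top-/left-most tile) is exact for synthetic
  tiles but is not a stitching algorithm for real, imperfectly-registered
  acquisitions.
* Permutation p-values are uncorrected across wells and MOAs, exactly as
  specified for the summary statistic they feed; consumers who need
  family-wise control should apply it downstream.
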