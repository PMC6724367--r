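---
title: "Quantifying Wolbachia titer: counting conventions, absolute qPCR, and subsampling power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Wolbachia titer: counting conventions, absolute qPCR, and subsampling power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wolbtiter)
```

## The measurement problem

*Wolbachia* is a maternally transmitted intracellular bacterium whose
per-cell abundance ("titer") in the host germline determines how reliably it
reaches the next generation. Titer is measured two ways in this package:

* **Cytology** — DNA-stained confocal z-stacks in which each bacterial
  nucleoid appears as a bright, sub-resolution punctum; titer is the punctum
  count per cell or cyst.
* **Absolute qPCR** — copy number of a single-copy bacterial gene (*wsp*)
  inferred from threshold cycles against a plasmid standard curve; titer is
  copies per reaction, back-extrapolated to copies per fly.

Both pipelines end in the same statistical machinery: a test-selection
decision tree for two-group comparisons, and an empirical subsampling power
analysis that asks how many samples would have sufficed.

## Counting conventions

`quantify_stack_3d()` is the computational analog of manual scoring: after
thresholding, 3D connected components (26-connectivity by default) are
counted, so a punctum visible in several adjacent focal planes is counted
once. It suits small samples — single germline stem cells (GSCs) and early
cysts — where every plane is examined.

Large stage-10 egg chambers are too dense for full scoring, so
`quantify_stage10_cyst()` implements the semi-automated convention: locate
the widest focal plane (`find_z_center()`, the Z-center of the roughly
football-shaped chamber), count particles per plane (8-connectivity,
ImageJ-style Analyze Particles) from that plane through half the Z-depth,
and double the sum, assuming Z-symmetry.

Per-plane counting scores a plane-straddling punctum twice.
`estimate_plane_redundancy()` quantifies this: among particles in the second
plane of each adjacent plane pair, the fraction whose signal overlaps a
particle in the first plane by at least 2 pixels. A 1-pixel overlap is
ignored — two pixels of shared support are required before two detections
are called the same bacterium. Redundancy is *reported*, not subtracted, by
default (`redundancy_correct = TRUE` applies `total * (1 - fraction)`),
because the published stage-10 convention doubles raw counts without a
stated correction.

### Thresholding and noise

The threshold policy is always explicit and recorded in the result
(`threshold_used`): `"otsu"` (histogram-based, good when foreground and
background form distinct modes), `"percentile"`, or `"fixed"`. Two practical
notes, both visible in the test suite:

* Otsu's method fails on *sparse* spot images — when puncta occupy well
  under 1% of voxels the histogram is effectively unimodal and the threshold
  lands inside the background noise. For such stacks use a fixed threshold
  placed between the background level and the punctum amplitude.
* For noisy acquisitions, `smooth_stack()` (plane-wise Gaussian blur,
  sigma 0.8 px by default) before thresholding suppresses uncorrelated
  sensor noise far more than it dims multi-pixel puncta. With noise at 20%
  of punctum amplitude, smoothing plus a fixed threshold at
  background + 0.3 x amplitude and a 3-voxel size filter recovers synthetic
  ground truth to within 2%.

The size filter (`min_size_px`/`min_size_vox`, default 2) removes
single-pixel detections. Masks are *exclusion* masks — the programmatic
stand-in for manually erasing follicle cells and extraneous host signal —
and are honored both in threshold computation and in counting; adding a mask
can never increase a count.

Indices are 1-based `(z, y, x)` with plane 1 the top of the acquisition;
Z-spacing metadata defaults to 1.5 um.

## The synthetic stack generator

`make_stack()` renders what the counting conventions assume: isotropic
Gaussian puncta (sigma = radius/2) of amplitude 1000 over background 100,
optional large dim host-nucleus blobs, and additive Gaussian noise, with
every placed object reported as ground truth. It makes no attempt at optical
realism — no PSF anisotropy, photobleaching, or depth attenuation — so
passing tests certify the *counting machinery*, not robustness to microscope
pathology. Placement is rejection sampling under a minimum pairwise center
distance; an impossible request fails loudly with a capacity error rather
than silently packing fewer objects.

`z_profile = "planar"` confines each punctum to one focal plane (nucleoids
are small relative to a 1.5-um z-step), with a `straddle_fraction` rendered
on two adjacent planes to emulate plane-straddling signal — the knob behind
the redundancy tests. `make_stage10_stack()` places planar puncta in
mirrored pairs around a central plane, with no punctum on the center plane
and a placement rule (lateral separation, or at least two planes apart in
z), so both 3D counting and half-depth doubling recover the exact truth on
noise-free renders.

## Absolute qPCR

`fit_standard_curve()` fits `Ct = intercept + slope * log10(copies)` to a
plasmid dilution series (at least 3 points over at least 2 decades) and
derives the amplification efficiency `E = 10^(-1/slope) - 1`; perfect
doubling gives slope -3.3219 and E = 100%. Fits outside E in [0.9, 1.1] or
with R^2 below 0.98 warn. `ct_to_copies()` inverts the curve; the
no-amplification sentinel is an *empty Ct* (`NA`), never "Ct 40", and
converts to 0 copies — negatives are not assigned fabricated copy numbers.
`summarize_sample()` aggregates technical replicates by the median of
per-replicate copies (robust to a single bad well; `"mean"` available), and
`classify_infection()` calls a sample infected if any replicate amplifies
below a configurable cycle cutoff.

`relative_ratio()` computes the conventional *wsp/rpl32* ratio, provided
precisely so its failure mode can be demonstrated: host nurse cells
endoreplicate, so the reference gene's copy number is not constant — a
1.7-fold rise in host copies at constant bacterial load drops the "relative
titer" by 1/1.7 while absolute *wsp* counts are unchanged. A zero reference
estimate is an error, never a silent infinity.
`extrapolate_source_copies()` scales reaction copies to copies per fly from
template/extract volumes, dilution factor, and flies per homogenate
(default 5). The synthetic plate model inverts the same log-linear equation
with Gaussian Ct noise, so curve fitting on noise-free plates is exact to
machine precision — a round-trip identity the tests assert.

## Test selection and the randomization t-test

`select_test()` implements the decision tree: Shapiro-Wilk per group and
Levene's test (mean-centered, the classic SPSS-style form; median centering
available) at a diagnostic alpha of 0.05. Both groups normal and
variance-homogeneous: Student's t; normal but heterogeneous: Welch's t;
non-normal and homogeneous: Mann-Whitney U; non-normal and heterogeneous:
a bootstrap randomization t-test. The diagnostic alpha is a package choice —
the tree's source specifies the tests but not the alpha. Note the
selected test is a deterministic function of the computed diagnostics, so on
random data the *canonical* test for a scenario is the modal, not the
guaranteed, selection — Shapiro-Wilk false-rejects about 5% of truly normal
groups.

Mann-Whitney p-values are exact when the combined sample size is at most 20
with no ties, otherwise the normal approximation with tie and continuity
correction. `kruskal_wallis()` (tie-corrected H, chi-square on k-1 df)
covers the three-stage developmental comparisons; identical values across
groups give H = 0, p = 1 rather than an error.

`randomization_t_test()` concretizes "randomization-based t-test with
bootstrapping", which the source methods leave unspecified: the observed
statistic is Welch's t; the null is built by centering both groups to the
pooled mean and resampling each group with replacement; the p-value is
`(1 + #{|t*| >= |t_obs|}) / (1 + reps)`, a valid, slightly conservative
Monte-Carlo p-value. Resamples with zero variance in both groups count as
exceedances (conservative). A label-permutation null is available via
`method = "permutation"`. On normal data the bootstrap p converges to the
Welch p (the tests assert agreement within 0.02 at 100,000 replicates).

## Subsampling power

`power_at_n()` draws `n` values *with replacement, independently from each
dataset*, tests the pair two-tailed, and repeats (default 10,000 iterations,
alpha 0.01 two-tailed); `power_curve()` sweeps n = 2..35 with an independent
seeded stream per n. Degenerate subsamples (zero variance in both groups)
count as non-significant: they carry no evidence, and aborting would bias
the proportion.

Three test policies are offered because the original procedure's dispatch
granularity is not recoverable: `auto_once` (default — one test selected
from the full datasets, restricted to the t-variants and Mann-Whitney, with
a randomization-test selection mapped to Welch's t for cost),
`auto_per_iteration` (Shapiro/Levene re-run on every subsample pair — the
reading "significance assessed in accordance with the normality of the data
being analyzed" applied per draw), and `fixed`. The germline power
reproductions in `scripts/acceptance.R` use `auto_per_iteration`; the
package default stays `auto_once`, which matches analyses whose figure
legends list a single test per comparison.

Two structural facts worth knowing when reading curves: Mann-Whitney on
subsamples of n = 2 (or 3) *cannot* reach p < 0.01 — its exact two-sided
p-value is bounded below 0.01 at those sizes — so rank-based curves
legitimately start at zero; and null self-comparison curves are calibrated
(proportion ~ alpha at every n) for the t path, while the rank path is
conservative at small n for the same discreteness reason. The calibration
check in the test suite resamples from a 1,000-value normal source: with
small sources, the t-test's size at n of 2-4 inherits the realized sample's
kurtosis and wanders by tens of percent for reasons unrelated to the
procedure.

`min_n_for_power()` reports the first n whose proportion reaches a target —
the "how few samples would have sufficed" readout.

## Synthetic supplementary tables

The original per-ovariole and per-well measurement tables are distributed
only as spreadsheet supplements that this package does not ship. The
`synthetic_*` generators therefore construct stand-in datasets that carry
the published summary statistics by construction:

* sample medians are matched exactly by multiplicative rescale
  (61.5 / 1140 / 22500 nucleoids for GSC / stage 4 / stage 10 on control
  food; 79 vs 55, 1180 vs 1260, and 22900 vs 8240 for un-enriched vs
  yeast-enriched; cluster per-cell 58.9; rifampicin at 29% of carrier);
* printed test statistics are matched by a deterministic root-solve on a
  median-preserving spread transform (Welch p = 0.878 for cluster vs single
  GSC, Welch p = 0.017 for the GSC diet effect) or by exact construction
  (regression R^2 = 0.854 with Student p = 0.896 for manual vs
  semi-automated recounts; cross-stage R^2 of 0.108 / 0.159 / 0.084 via
  Gram-Schmidt on the sample vectors);
* everything else is a package choice made once: titer dispersions are
  lognormal with log-sd 0.4-0.45 at stages 4 and 10 (broad overlap at
  stage 4, clear separation with substantial spread at stage 10) and
  near-normal spread at the GSC stage where the spread is pinned by the
  printed p-value; 2-4 cells per GSC cluster; qPCR Ct noise 0.15 cycles.

Quantities *not* calibrated — subsampling power proportions, the
Kruskal-Wallis stage comparison, the minimum informative stage-10 sample
size, the quantified rifampicin ratio after qPCR noise — emerge from these
constructions when the pipeline runs, which is what makes the reproduction
informative. What stand-ins cannot do is validate the package against the
original raw measurements: value-level features of the real data (integer
counts, outliers, acquisition-order structure) are not represented, and the
per-fly extrapolation to tens of millions of bacteria cannot be checked at
all because the dilution factors behind it are not published.

## Problem sizes and numerical choices

The shipped checks use synthetic stacks up to 21 x 240 x 240 voxels with up
to 500 puncta, 10,000 subsample iterations per sample size, 100,000
bootstrap replicates for the convergence check, and 6 stand-in realizations
averaged for power reproductions — sizes chosen so the whole suite exercises
every code path in minutes on one core while keeping Monte-Carlo error well
inside the asserted tolerances. Ties in `find_z_center()` break toward the
lower plane index (recorded); regressions report the later stage on the
earlier stage (R^2 is orientation-invariant); percent-of-control uses
medians, matching the published 36% figure.

## Known limitations

* No follicle-cell or stage segmentation: masks and staging come from the
  user, as in the original manual workflow.
* Diffraction-limited doublets closer than the threshold footprint merge;
  the generator's strict-separation fixtures deliberately avoid this regime,
  so exact-recovery results say nothing about clumped bacteria.
* One standard curve per plate per gene; no DeltaDeltaCt, no multiplexing,
  no spike-in recovery correction (spike-in columns pass through untouched).
* The rank-sum inner loop of the power procedure uses the normal
  approximation whenever ties are present, which for heavily tied count data
  at moderate n is slightly conservative.
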