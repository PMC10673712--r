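---
title: "Detecting homologous recombination deficiency from shallow WGS copy-number profiles"
author: "swgsHRD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting homologous recombination deficiency from shallow WGS copy-number profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swgsHRD)
```

## The problem and the model

Tumors with homologous recombination deficiency (HRD) repair double-strand
breaks through error-prone alternative pathways and accumulate a
characteristic genome-wide pattern of large copy-number scars. Counting
those scars is a practical HRD biomarker: it requires only shallow
whole-genome sequencing (~1X), which is cheap, FFPE-compatible and easy to
decentralize.

`swgsHRD` implements the full decision engine on top of a bin-level
normalized copy-number ratio profile (~50 kb bins, ratio 1.0 at the sample
median ploidy):

1. **Quality attribution.** Tumor content (4 ordinal categories),
   intrinsic sequencing noise (3), and FFPE artifact load (4) are measured
   and integrated into *good* / *fair* / *low*.
2. **Segmentation and noise reduction.** Per-arm circular binary
   segmentation (CBS), a small-segment filter, and merge passes that
   remove both sub-threshold level differences and segments explained by
   the FFPE panel-of-normals noise profile.
3. **Profile characterization.** Genome complexity from clustered
   copy-number levels, four binary nonHRD-associated attributes (CCNE1
   amplification, ERBB2 amplification, focal-amplification phenotype,
   CDK12-type tandem-duplication phenotype), the LGA counts, and five
   ancillary LGA indexes.
4. **Stepwise diagnostics.** The LGA-score with penalties and a bonus,
   clear-cut calls outside the 18–22 margin band, evidence-based
   resolution of borderline cases, and quality-restricted rules.

A **large genomic alteration (LGA)** is a copy-number break between two
adjacent same-arm segments whose sizes, rounded half-up to the integer
megabase, are both at least 10 Mb ("more than 9 Mb" after rounding), and
whose level difference reaches a threshold. Two thresholds exist: *soft*
(0.10 ratio units, the permissive call suited to complex genomes) and
*stringent* (0.20, the restrictive call suited to simple genomes). Breaks
across centromeres never count; bins straddling a centromere are assigned
to no arm and excluded.

The **LGA-score** is

> score = LGA − PENALTY + BONUS, floored at 0,

with PENALTY = 0/5/8 for none/one/more-than-one binary attribute and
BONUS = 5 for a "simple" genome (two most abundant CN levels covering more
than 70% of the genome) and 0 otherwise. The decision threshold is 20 with
a ±2 margin: scores below 18 are clear-cut nonHRD, above 22 clear-cut HRD.
Borderline scores (18–22) are shifted to 19 (nonHRD) or 21 (HRD) by
majority vote over evidence items: the penalty (zero favors HRD), the
complexity class (simple favors HRD, complex+ favors nonHRD), and each
ancillary index against its configured floor. An exact tie resolves
conservatively to 19. The legacy v1 cutoffs (sensitive 15 / specific 20)
are reported for reference but never drive a decision.

Quality shapes the rules: good-quality samples use the conservative
soft/stringent pairing (nonHRD requires even the permissive soft score
below 18; HRD requires even the restrictive stringent score above 22);
noisy samples are fixed to the stringent threshold and low-tumor-content
samples to the soft one; fair-quality samples receive clear-cut calls only
(borderline → non-determined); low-quality samples receive only clear-cut
nonHRD when the total breakpoint count is small (default cap 40).

Because CBS has a stochastic component (its permutation tests), the LGA
count is reported with a confidence interval over 20 reruns with distinct
sub-seeds (`seed + i`). Both the min–max range and the 2.5/97.5 percentiles
are reported; min–max is the default interval. A CI spanning a decision
bound attaches a warning but never overrides the point-run decision.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `binSize` | 50 kb | bin grid of the input profile |
| `softDelta` / `stringentDelta` | 0.10 / 0.20 | LGA level-difference thresholds (ratio units) |
| `minSegmentMb` | 3 Mb | small-segment dissolution floor |
| `mergeDelta` | 0.10 / 0.15 / 0.20 | level-merge threshold for good/fair/low quality |
| `ffpeCorrMergeThreshold` | 0.5 | FFPE-correlation cutoff for artifact merges |
| `alpha`, `nPerm` | 0.01, 100 | CBS split significance and permutations |
| `nReruns` | 20 | segmentation reruns behind the LGA confidence interval |
| `threshold`, `margin` | 20, 2 | LGA-score decision threshold and clear-cut margin |
| `penaltyOne`/`penaltyMany`, `bonusSimple` | 5/8, 5 | score adjustments |
| `ampThreshold` | 2.0 | ratio level calling an amplification (~2× median ploidy) |
| `tdMinGains` | 8 | interstitial 1–10 Mb gains defining the TD phenotype |
| `extraLargeFlankMb`, `telomereWindowMb` | 30, 1 | ancillary index definitions |
| `lowQualityBreakpointCap` | 40 | breakpoint cap for low-quality nonHRD |

The published description fixes the score constants (threshold, margin,
penalties, bonus, borderline shifts, the 70% complexity rule, the
"more-than-two-arms" focal rule and the 1–10 Mb TD gain window) but leaves
several numeric cut points to its supplementary material: the quality
category thresholds, the soft/stringent deltas, the per-quality merge
thresholds, the "extra-large"/"telomeric" definitions, the ancillary-index
floors and the low-quality breakpoint cap. Those are package defaults,
calibrated once on the simulator (e.g. tumor fractions of ≥0.4 / ≥0.25 /
≥0.15 map to content categories 1–3; a clean one-copy step at 50% purity
passes the stringent delta) and exposed in `qualityThresholds()`,
`segmentationParams()` and `classifierConfig()`. They are stand-ins with
the published *structure*, not reproductions of unpublished values.

## Segmentation internals and numerical choices

* The CBS scan maximizes the circular split statistic
  `U(i,j) = |S_j - S_i - k/n S_n| * sqrt(n / (k(n-k)))` over all arcs with
  `k ≤ n/2` (the complement arc is redundant), which is exactly the
  least-squares-optimal binary circular split. Significance is
  `U / sigma` with a robust noise scale `sigma = mad(diff(x)) / sqrt(2)`.
* Permutation tests only run in the ambiguous zone: statistics below the
  null-maximum expectation `sqrt(2 log N)` (N = number of arcs) are
  rejected outright, and Bonferroni-significant ones accepted outright.
  This keeps clear decisions deterministic — so noise-free profiles
  segment exactly and their rerun CI has width 0 — while preserving the
  stochastic component where it genuinely matters.
* With `sigma = 0` (noise-free input) any real level change splits
  deterministically; segmentation is then exact, which the tests exploit
  as an oracle property.
* Small-segment dissolution absorbs a sub-floor segment into the
  nearer-level neighbor *at the neighbor's level* (the spike is treated as
  noise, not averaged in), then coalesces equal-level adjacencies,
  smallest segment first, to a fixpoint. Ties go to the left neighbor.
* Level merges are applied smallest-difference-first; ties by genomic
  position. An FFPE merge requires both a high correlation between the
  candidate segment's deviations and the expected FFPE deviation *and*
  that the level difference disappears once the expected deviation is
  subtracted — correlation alone is shift-invariant and would also fire on
  genuine copy-number offsets.
* Segment sizes are rounded half-up (`floor(x + 0.5)`), so a 9.5 Mb flank
  rounds to 10 and supports an LGA while 9.49 does not. R's banker's
  rounding is deliberately not used.
* The FFPE-noise quality axis correlates residuals of a *coarse*
  pre-segmentation (single CBS pass, then segments under 15 Mb dissolved)
  with the panel profile; the dissolution keeps wave-scale artifacts in
  the residual track instead of letting the pre-segmentation absorb them.
* The tumor-content proxy inverts the dilution model on the recurrent
  spacing of clustered segment levels (`purity = ploidy × spacing`,
  capped at 1). A flat genome has no spacing information: category 4 with
  a warning, which routes the sample into the low-quality rules — a flat
  diploid profile is still called nonHRD there because its soft score and
  breakpoint count are tiny.

## What the simulator emulates — and what it does not

`simulateTumorProfile()` generates bin-level profiles with known ground
truth: per-arm planted copy-number breaks with both flanks ≥ 12 Mb
(guaranteeing unambiguous LGA truth), small 3–9 Mb events, CCNE1/ERBB2
amplicons (copy number 10 over a ~4 Mb window), focal amplifications,
1–10 Mb tandem-duplication gains, purity dilution
(`ratio = tf · cn / ploidy + (1 − tf)`), a smooth FFPE wave (three
sinusoids with 5–30 Mb periods per chromosome plus sparse spikes, shared
across profiles via `waveSeed`) and Gaussian bin noise (a
negative-binomial read-count option approximates ~20 reads per 50 kb bin
at 1X). Planted copy levels follow multiplicative steps of ×0.5 / ×1.5 /
×2 on the current copy number — integer copy changes from a diploid base —
so observed step heights span the soft and stringent thresholds across the
purity range.

The simulator does **not** emulate mappability or replication-timing
waves, allele-specific signal, subclonal heterogeneity, or read-level
artifacts; its FFPE wave is a stand-in shape, since no quantitative FFPE
noise spectrum is published. Passing the recovery suites therefore
demonstrates that the *decision engine* is faithful and robust in the
declared noise model, not that any particular clinical sensitivity is
guaranteed on real FFPE libraries.

## Validation suites and problem sizes

The test suite and `scripts/acceptance.R` recompute, from scratch:

* the concordance statistics of the three transcribed 3×3 tables
  (agreements, failure rates, Cohen's kappa with the non-contributive
  outcome as a genuine third category — the reading that reproduces the
  printed kappas; the 2×2 variant is also reported);
* the exact score-logic truth table over all penalty × complexity ×
  raw-LGA combinations (0–45) under good quality;
* the LGA flank-rounding boundary and the stringent ≤ soft ordering over
  200 simulated profiles (three-chromosome toy genome at 250 kb bins in
  the tests; hg19 at 250 kb in the acceptance script — the ordering is
  resolution-independent);
* CBS against an exhaustive least-squares oracle on 100 noise-free arms of
  ≤ 60 bins with ≤ 3 breaks;
* end-to-end recovery on 200 simulated hg19 profiles at 50 kb bins
  (tumor fraction uniform on [0.4, 1], noise sd uniform on [0.05, 0.2],
  planted LGA 0–6 for nonHRD-like and 28–40 for HRD-like genomes), with
  20-rerun confidence intervals checked for bracketing on five noisy
  profiles and zero width on two noise-free ones. The CI subset is kept
  small because each interval costs 20 full segmentations.

Independent oracles never share code with the implementation: the
least-squares oracle enumerates breakpoints from prefix sums, kappa is
cross-checked against `e1071::classAgreement`, and the intrinsic-noise
metric is checked against the closed form
`sqrt(2) Φ⁻¹(0.75) σ` of the median absolute difference of Gaussian noise.

## Known limitations

* Absolute purity/ploidy are not estimated; only the ordinal content
  category the decision rules need.
* The quality thresholds and ancillary floors are calibrated stand-ins
  (see above) — on real data they should be re-fitted against an annotated
  cohort before clinical use.
* X is retained and Y excluded from scoring (the reference application is
  ovarian carcinoma); both choices are configurable through a custom build
  table.
* Cohort-level clinical quantities (clear-cut rates on a trial population,
  survival benefit by HRD status) require patient-level data and are out
  of scope; the concordance module consumes published contingency tables
  only.
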