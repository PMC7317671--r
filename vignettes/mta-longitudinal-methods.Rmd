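---
title: "Models and methods behind mtalong"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mtalong}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtalong)
library(dplyr)
```

# The problem

Radiologists grade medial temporal lobe atrophy on Scheltens' MTA scale: an
integer 0 (no atrophy) to 4 (end-stage) per hemisphere, judged from the
hippocampus, choroid fissure and inferior lateral ventricle (ILV) on a
single coronal slice. Automated tools produce the same quantity either as a
continuous rating or indirectly as hippocampal (HC) and ILV volumes.
`mtalong` implements the longitudinal analysis of such data in non-demented
memory-clinic patients (subjective cognitive decline, SCD, or mild
cognitive impairment, MCI), stratified by CSF biomarkers: amyloid
positivity A+ if the A&beta;42/40 ratio falls strictly below 0.10, tau
positivity T+ if p-tau exceeds 72 pg/ml. Equality maps to the normal side
because the cut-offs are strict inequalities; both cut-offs are
configurable. The A-T+ combination is admitted but flagged with a warning,
as it is rarely observed in this population.

The package answers four questions:

1. How well do raters agree, and how do ratings track volumes?
   (`weighted_kappa()`, `independent_spearman()`)
2. How fast does each biomarker group progress?
   (`subject_slopes()`, `group_rate_summary()`)
3. How much volume change does it take before a discrete rating moves?
   (`compute_deltas()`, `kde_by_delta_class()`, `crossover_threshold()`)
4. What do those rates imply in years?
   (`full_score_time()`, `threshold_crossing_time()`)

# Per-subject annual change

Each subject's trajectory for each measure is reduced to an ordinary
least-squares slope against age at scan — the average annual change. The
closed form `sum((x - mean(x)) (y - mean(y))) / sum((x - mean(x))^2)` is
used directly; no mixed-effects or spline models are fitted (the linearity
assumption over six years is a deliberate scope decision, and its
limitation is inherited by everything downstream). Group differences in
slopes are tested with a tie-corrected Kruskal–Wallis H. The chi-square
approximation (df = groups − 1) serves all realistic sizes; when ten or
fewer subjects enter a comparison the p-value is computed exactly by
enumerating all assignments of the observed slopes to the group sizes, so
that tiny fixtures are testable without relying on an approximation that is
poor there. The number of comparisons `m` for the Bonferroni flag is an
input (default 66), not recomputed from the table layout.

A discrete bounded rating observed at four fixed visits can only realise a
handful of slopes. `enumerate_discrete_slopes()` makes that explicit: with
visits at 0/2/4/6 years, a rating that steps up once by one point admits
exactly the slopes {0, 0.15, 0.2}. This is the resolution limit of
rating-based atrophy rates and the reason rate estimation from integer
ratings in short follow-ups is unreliable.

# Agreement

Cohen's weighted kappa uses disagreement weights `|i − j|/4` (linear,
default), `((i − j)/4)^2` (quadratic) or 0/1 (unweighted); the weighting is
reported alongside every kappa because the qualitative Landis–Koch bands
are conventionally applied to either. Continuous automated ratings are
rounded half-away-from-zero and clipped to [0, 4] before entering kappa;
they enter rank correlations as-is. Because repeated scans of one subject
are not independent, cross-measure Spearman correlations use exactly one
visit per subject — the baseline visit by default (deterministic), or one
uniform-random visit per subject under a seed.

# Rating sensitivity: crossover thresholds

For a rater, every follow-up image is paired with its subject's baseline:
rating change &Delta;MTA and volume changes &Delta;HC, &Delta;ILV (mm^3 and
percent of baseline; percent thresholds are computed by running the same
procedure on the percent variable, never by rescaling the mm^3 threshold).
Hemispheres are pooled by default. Pairs whose rating decreased are
excluded (and counted): the class structure is &Delta;MTA = 0, +1, +2-or-more,
with classes under five pairs pooled into a single "increased" class.

Within each class a Gaussian kernel density is estimated with a
Scott's-rule bandwidth (`sd * n^(-1/5)`), all classes evaluated on one
shared 512-point grid spanning the pooled data plus three maximal
bandwidths. The crossover threshold compares the prior-weighted densities
`g0 = p0 f0` and `g+ = sum(pk fk)` (posterior-probability crossing; an
unweighted curve-crossing mode is also provided, and the two can differ
materially when the class priors are unbalanced — both are reported when in
doubt). The threshold is the inner end of the maximal run of `g+ > g0`
anchored at the directional grid edge — more negative for losses (HC), more
positive for growth (ILV) — linearly interpolated between bracketing grid
points. Anchoring at the edge rather than scanning outward from the grid
midrange matters in practice: skewed volume-change extremes displace the
midrange far from the data bulk, and a midrange-origin scan can
spuriously cap the threshold there. If `g+` never dominates out to the
edge an explicit no-crossover result is returned, not an error.

One caveat found while validating: higher rater noise widens the
&Delta;MTA = 0 density (as expected) but does *not* necessarily push the
prior-weighted crossover further out — noise also inflates the
increased-rating prior, which scales `g+` up and pulls the crossing inward.
The property suite therefore asserts the widening and that the threshold
responds to noise, not a direction.

# Progression times

Two clocks are implemented. From continuous ratings: a group advancing at
`r` scale units/year needs `1/r` years for a full point (non-positive rates
give `Inf`). From thresholds: a group losing HC volume at `v` mm^3/year
reaches a crossover threshold `T` after `|T|/|v|` years. For the bundled
published inputs (`reference_rates()`, `reference_thresholds()`), left and
right hemisphere rates are averaged arithmetically before division, and the
two radiologists' thresholds likewise; this averaging convention reproduces
the published times within rounding and is documented as assumed. Under the
latent-uniform assumption (an integer rating k reflects a continuous score
uniform on [k, k+1), so the group mean is k + 0.5) the first clock should
read roughly twice the second; `reconciliation_ratio()` reports the actual
ratio, which exceeds 2 for the bundled inputs.

```{r conversion}
conversion_summary()
```

# The synthetic cohort generator

No patient data ship with the package; `generate_cohort()` draws cohorts
with the statistical structure the analysis assumes so every stage is
testable. Defaults are the study conditions of the motivating cohort and
are not tuned per analysis:

* **Composition.** 93 subjects in A-T- / A+T- / A+T+ groups of 54/18/21,
  SCD:MCI 42:12, 8:10, 11:10; baseline age normal(70.1, 5.4) truncated to
  [60, 80] years; four scans at 0/2/4/6 years.
* **Latent trait.** Each hemisphere carries a continuous latent MTA score
  `m(t) = m0 + r t`. Baselines and rates are normal per group — baseline
  means/SDs 1.26/0.57, 1.40/0.68, 1.24/0.61 and rate means/SDs 0.04/0.04,
  0.075/0.05, 0.12/0.08 units/year, taken from the automated-rater group
  summaries — with left/right correlated at 0.8 via a shared subject
  component, and baselines truncated to [0, 4].
* **Raters.** The automated rater returns `clip(m + noise, 0, 4)` with
  noise SD 0.15. Each human rater applies an additive bias (default
  −0.05 and −0.70: one rater systematically more conservative), adds noise
  (SD 0.3), rounds half-away-from-zero and clips. The rounding rule is
  stated because half-integer latents occur with zero noise. The human
  noise SD is a calibration choice (nothing in the study quantifies it);
  0.3 keeps re-rated trajectories rarely lower at follow-up, the
  qualitative behaviour reported for the radiologists.
* **Volumes.** HC is linear in the latent trait (4700 − 820·m + noise,
  SD 150 mm^3); ILV is exponential (150·exp(1.28·m) + noise, SD 60 mm^3,
  floored at 1) because the volume–rating relationship is convex — the ILV
  change per rating step grows with the score. Link coefficients were
  chosen once so that implied group baseline volumes and annual changes sit
  in the published ranges (820 mm^3 per MTA unit is the average ratio of
  published HC-loss to rating rates).
* **CSF, QC, cognition.** CSF values are group-conditional normals centred
  on the published group means, rejection-sampled to respect the cut-offs.
  Each image fails QC independently with probability 33/372. MMSE and ADAS
  delayed word recall are linear in time with group-specific random
  baselines and rates (MMSE rounded and clipped to 0–30). The
  dementia-diagnosis flag is a threshold (2.5) on the mean latent trait —
  an arbitrary convenience, not a hazard model.

What the generator does **not** emulate: scanner and protocol effects,
non-linear trajectories, informative QC failure, correlated rater errors,
attrition, and any image content. Passing tests therefore demonstrate the
pipeline's statistical correctness under its own assumptions, not
performance on real images.

# Numerical conventions and degenerate inputs

* Missing cells are explicit `NA`s; each analysis drops what it cannot use
  and counts it (no imputation anywhere).
* Hemispheres are a keyed dimension and never averaged implicitly; each
  function documents its handling (slopes and kappas per hemisphere;
  delta pairs pooled by default).
* Perfect agreement returns kappa 1 even when degenerate marginals make
  the chance-corrected formula 0/0.
* Duplicate observations, non-increasing ages and out-of-range ratings are
  load errors naming the offending row; rating 4.5 cannot enter a
  discrete rater's column.
* Slope deduplication in `enumerate_discrete_slopes()` uses a 1e-12
  tolerance; crossover interpolation is linear between grid points.
* Output tables are written at six significant digits; in-memory results
  keep full precision. Identical configuration and seed give byte-identical
  outputs.

# Problem sizes used in the shipped checks

The test-suite and acceptance script sizes were chosen once as a
compromise between statistical resolution and a desk-scale run: the
analytic crossover recovery uses 1e5 draws (tolerance 0.05 on a threshold
of magnitude ~1.5); parameter recovery and group-separation checks use the
study composition scaled by 20 (1,860 subjects), the separation check
repeated over 100 seeds; everything else runs at study scale or below.

# Known limitations

* Linear trajectories only; accelerating atrophy biases the progression
  times optimistically far from baseline.
* The crossover estimate inherits KDE boundary bias and the bandwidth
  rule; with heavily unbalanced classes the prior-weighted crossing is
  sensitive to the class priors.
* The published headline thresholds (−238/−235 mm^3) and group rates are
  reproducible only as *inputs* here (`reference_rates()`): recomputing
  them requires the study's images and raters.
* `m = 66` comparisons is taken at face value as configuration, because
  the comparison inventory behind it is not itemised anywhere.
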