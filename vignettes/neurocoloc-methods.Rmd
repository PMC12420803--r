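---
title: "Methods: local synchronization, surrogate-based co-localization, and the synthetic validation study"
author: "neurocoloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: local synchronization, surrogate-based co-localization, and the synthetic validation study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neurocoloc)
```

This vignette documents the statistical models the package implements, the
parameters that matter, the numerical conventions chosen where the
literature is silent, and exactly what the synthetic validation study does
and does not demonstrate.

# Local synchronization (LCOR)

For a voxel $v$ with time series $x_v$, the local correlation is the
Gaussian-distance-weighted average of its temporal Pearson correlations with
the other analysis-mask voxels in its neighbourhood:

$$\mathrm{LCOR}(v) \;=\;
\frac{\sum_{u \neq v} w(d_{vu})\, \mathrm{cor}(x_v, x_u)}
     {\sum_{u \neq v} w(d_{vu})},
\qquad w(d) = \exp\!\left(-\frac{d^2}{2\sigma^2}\right),$$

with $d_{vu}$ the Euclidean distance in mm and
$\sigma = \mathrm{FWHM}/2.3548$.

Parameters (see `lcorParams()`):

* **kernelFwhmMm** (default 25 mm) — the spatial scale of "local". This is
  the standard kernel for the measure; at typical acquisition resolutions it
  averages correlations over a neighbourhood of a few hundred voxels.
* **truncationRadiusMm** (default 2×FWHM) — beyond this radius Gaussian
  weights are below $10^{-5}$ of the peak; truncation bounds the
  computation with negligible bias.
* **smoothFwhmMm** (default 6 mm) — Gaussian smoothing applied to the LCOR
  *map*, not the time series. Smoothing is mask-aware: the map is convolved
  with non-finite voxels zeroed and renormalized by the smoothed
  finite-voxel indicator, so values near mask edges are unbiased rather
  than shrunk toward zero.
* **includeSelf** (default `FALSE`) — the centre voxel's self-correlation
  of 1 is excluded from its own average; including it would add a constant
  inflation term. The flag exists for sensitivity analyses.
* Kernel weights are normalized over the analysis mask (not the full
  grid): a voxel's LCOR is the weighted mean over the neighbours that
  actually enter the analysis.

Confound regression (`regressConfounds()`) replaces every voxel series by
its least-squares residual against an intercept plus the supplied
regressors (tissue mean signals, motion parameters); collinear columns are
dropped with a warning. The pipeline order is confound regression → LCOR →
map smoothing, with robustness switches (drop initial volumes, no
smoothing, no tissue-mean regression) exposed in `studyConfig()`.

Zero-variance voxels cannot carry a correlation and propagate as `NA`;
regions that end up with no finite voxel propagate as `NA` through
`parcellate()` and are removed pairwise before any correlation
(pairwise-deletion convention for partially covered regions).

# Voxel-wise group inference

`fitVoxelwiseGlm()` fits an ordinary least-squares model per voxel with the
contrast t-statistic $t = c^\top\hat\beta / \sqrt{\hat\sigma^2\, c^\top
(X^\top X)^{-1} c}$ and $df = n - \mathrm{rank}(X)$. The standard design
(`buildDesign()`) contains intercept, group, centred age/IQ/motion, a sex
indicator and dummy-coded site fixed effects; site is also the permutation
stratum.

`permutationInference()` uses Freedman–Lane residual permutation: the
nuisance-only model is fitted, its residuals are permuted within site
strata, added back to the nuisance fit, and the full-model t-map is
recomputed. Max-|t| and max-|TFCE| across the map form the family-wise
null distributions, with $p = (1 + \#\{\max_{perm} \ge observed\}) /
(n_{perm} + 1)$. When fewer distinct within-strata permutations exist than
requested, they are enumerated exhaustively and the p-value becomes the
exact rank over all permutations including the identity. The significance
masks require **both** criteria — voxel-FWE p < α **and** TFCE-FWE p < α —
reading the combined threshold as an intersection; this is the stricter of
the two possible readings and is flagged as a sensitivity choice.

TFCE uses $\mathrm{TFCE}(v) = \sum_h e(v,h)^E\, h^H\, \mathrm{d}h$ with the
common defaults $E = 0.5$, $H = 2$, 26-connectivity, and
$\mathrm{d}h = \max|t|/100$. Numerical conventions: the sum is evaluated at
the *midpoint* height of each threshold slab (midpoint quadrature converges
to the continuous form as $\mathrm{d}h \to 0$ and is accurate to well under
1% at 100 steps, where right-endpoint evaluation carries a 1.5% bias); the
negative tail is obtained by transforming the negated map identically and is
returned with negative sign. Scaling behaviour: multiplying the map by
$\lambda$ with $\mathrm{d}h$ rescaled proportionally multiplies TFCE by
$\lambda^{H+1}$ (one factor $\lambda^H$ from the heights, one $\lambda$ from
the step), preserving the voxel ordering.

# Co-localization statistics

`partialSpearman()` ranks both maps and the gray-matter covariate (average
ranks for ties, pairwise deletion of missing regions), residualizes the two
rank vectors on `[1, rank(gm)]` and correlates the residuals. The covariate
is partialled from *both* vectors (symmetric partial correlation). If the
covariate explains a vector completely — residual norm below $10^{-10}$ of
the rank scale — the partial correlation is 0 by convention; a variable
that is constant after ranking is an error.

## Surrogate maps

The permutation null must preserve the template's spatial autocorrelation;
otherwise smooth maps produce far too many small p-values. Because the
atlas includes subcortical regions, spin-style spherical rotations do not
apply, so the package uses variogram matching at the region level:

1. permute the template values across regions;
2. smooth the permutation across regions with a distance-decaying kernel
   (candidate families: exponential $e^{-d/\delta}$ and Gaussian
   $e^{-d^2/2\delta^2}$, bandwidths at quantiles of the inter-centroid
   distances);
3. mix smoothed and unsmoothed permutations with weight $\lambda$;
4. rank-remap the result onto the original value multiset, so every
   surrogate is an exact rearrangement of the template's values.

$(\delta, \lambda)$ are selected once per template by least-squares match
of the binned semivariogram $\gamma(h) = \tfrac12\,\mathrm{mean}\,(z_i -
z_j)^2$ (equal-count bins, pairs up to the 75th distance percentile)
over pilot permutations, evaluated after rank-remapping. The achieved mean
absolute relative variogram deviation is recorded in the `SurrogateSet`.
The two-sided permutation p compares $|\rho_{obs}|$ with the surrogate
$|\rho|$ distribution (absolute-value comparison rather than doubling a
one-sided tail).

Reporting conventions: Fisher $z = \mathrm{atanh}(\rho)$ with $|\rho| = 1$
clipped at $1 - 10^{-15}$ (with a warning) to keep z finite; the 95% CI is
$\tanh(z \pm 1.96/\sqrt{n-3})$; the *reported* df is $n - 2$, the
correlation-test convention used in region-level co-localization reporting
(a 119-region atlas prints df 117, the canonical 16-template profile prints
df 14).

## Exploration, replication, meta-combination

`explorationReplication()` encodes the two-cohort protocol: templates with
uncorrected two-sided p < α in the exploration cohort are flagged; only
flagged templates are tested in the replication cohort (replication =
p < α with the same sign); per flagged template the two cohort p-values are
combined by Fisher's method and Benjamini–Hochberg adjusted across the
flagged set. The final selection requires replication *and* adjusted
combined p < α.

# Pharmacological and individual-level analyses

Δ-scores are drug-minus-placebo subject means of LCOR within a significance
mask; `deltaTest()` performs the one-sided one-sample t-test (df = n − 1)
with a one-sided 90% CI open toward the hypothesised tail and Cohen's
$d = |\bar\Delta| / s_\Delta$. Note this standard definition implies
$|t| = d\sqrt{n}$; published pairs that violate the identity cannot be
reproduced by any sample and the package makes no attempt to
reverse-engineer alternative d formulas.

Individual z-maps standardize each case subject's region values against the
control group mean and SD (n − 1 denominator), computed on region means —
consistent with a region-level workflow. Subject co-localization strengths
are Fisher-z partial Spearman correlations of the z-map with a template;
symptom correlations are Pearson with df = n − 2, reported raw and
BH-adjusted.

# The synthetic validation study

The generator (`synthesizeStudy()`, `makeAtlas()`, `makeTemplateMaps()`,
`makeCohort()`, `makeDrugSessions()`, `makeClinicalScores()`) emulates the
*structure* of a two-cohort case-control study with a pharmacological arm:

* **Atlas** — contiguous regions grown from random seeds inside an
  ellipsoidal mask (6-connected growth, random tie-breaking under the
  seed); region centroids are exact voxel-mean mm coordinates.
* **Templates** — Gaussian random fields sampled at region centroids
  (squared-exponential covariance, length scale `smoothnessMm`, default
  18 mm ≈ a third of the synthetic brain extent), min-max rescaled to
  [0, 100]; a smooth gray-matter probability map in [0.25, 0.95] is drawn
  alongside. With 16 maps the canonical receptor/transporter names attach.
* **Signal model** — within region $r$ every voxel series is
  $x_v = w\,g_r + (1-w)\,\varepsilon_v$: a shared low-pass-filtered
  regional signal plus i.i.d. voxel noise. The mixing weight
  $w \in [0.05, 0.95]$ is the ground-truth synchronization dial (true LCOR
  is monotone in $w$; verified Spearman > 0.95 at 200 timepoints). Weights
  combine a 0.5 baseline, subject offsets (SD 0.04), region jitter
  (SD 0.02) and zero-mean Gaussian site offsets (SD 0.03).
* **Effect injection** — case subjects shift $w_r$ by `effectSize` times
  the standardized template $(T_r - \bar T)/s_T$, making the effect size
  unit-free. The magnitude is a free parameter of the generator: published
  case-control studies do not state effect magnitudes in LCOR units, so the
  validation suite uses −0.12 (a weight shift of about ±0.24 in the
  template's extreme regions) against voxel noise SD 1 — large enough that
  a 20-per-group study should recover it, which is what the recovery tests
  then verify.
* **Covariates** — age lognormal (median 16 y), sex Bernoulli with mild
  group imbalance, IQ normal (108, 15), motion folded-normal around
  0.9 mm/deg, site uniform. These emulate the usual covariate table
  without copying any study's values.
* **Drug sessions** — per subject, three runs (two drugs + placebo) share
  the subject's baseline weights; each drug shifts $w$ inside its own
  voxel mask (the "decrease" mask sits in the top quartile of the effect
  template, the "increase" mask in the top quartile of a second template,
  overlap removed), so the two drugs have distinct neurochemical
  geographies.
* **Clinical scores** — `coupling · standardized(strength) +
  √(1−coupling²) · noise`, affinely mapped to plausible symptom-scale
  ranges (total 0–30, three subscores) and rounded to integer points;
  `strength` is each case subject's true rank-correlation between their
  weight deviation and the effect template.

**What passing tests show** — that the statistics are implemented correctly
(oracle equivalence at $10^{-10}$), that the surrogate permutation test is
calibrated on smooth null maps where naive permutation is demonstrably
anticonservative, that family-wise error is controlled under the global
null, and that a template-shaped effect of documented size is recovered
through the full two-cohort protocol with the correct sign while null
studies stay empty.

**What they do not show** — the generator has no scanner physics, no head
motion time-courses, no physiological noise, no spatial normalization
error, no realistic inter-site protocol differences, and its templates are
idealized Gaussian fields rather than real tracer distributions. Passing
on synthetic data therefore validates the *machinery*, not any empirical
claim about real cohorts.

## Problem sizes used by the validation suite

Chosen as the smallest sizes at which each property is statistically
identifiable: calibration uses 40 regions, 500 surrogates and 500
replicates; effect recovery uses a 12×12×12 grid at 4 mm, 20 subjects per
group, 30 timepoints, 16 templates and 200 surrogates over 50 effect and 50
null replicates; family-wise-error control uses 200 replicates of 100
permutations; the end-to-end determinism check runs the full study twice at
a reduced configuration and compares output bytes.

# Known limitations

* Surrogate generation fits one $(\delta, \lambda)$ per template; maps
  whose autocorrelation is strongly anisotropic or scale-mixed are matched
  only in the aggregate variogram sense (the achieved fit error is always
  recorded).
* Site enters as fixed effects and permutation strata; no mixed-effects
  site model is offered.
* The voxel-FWE ∧ TFCE-FWE intersection criterion is conservative; the
  alternative (TFCE within the voxel-FWE mask) is not implemented.
* Exhaustive permutation enumeration is used automatically only when the
  distinct-permutation count is below the requested number.
* Parcellation supports region means only; no voxel-level (unparcellated)
  co-localization is provided, and no surface or CIFTI formats.
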