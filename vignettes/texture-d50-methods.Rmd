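---
title: "Methods: D50 progression modelling and voxel-wise texture inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: D50 progression modelling and voxel-wise texture inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(texd50)
```

`texd50` analyses cross-sectional ALS imaging cohorts pseudo-longitudinally:
each patient is placed on their own disease timeline by the D50 progression
model, and voxel-wise texture maps of T1-weighted MRI are related to the
resulting accumulation and aggressiveness descriptors. This vignette is the
package's own account of the methods, their assumptions, the numerical
choices made where the design was genuinely open, and their limits.

## The D50 progression model

ALSFRS-R scores (integers 0–48, 48 = full function) are modelled as a
sigmoidal decline from full health,

$$F(t) = \frac{48}{1 + \exp\left((t - D_{50})/d_x\right)},$$

with $t$ in months since symptom onset. $D_{50}$ (months) is the time at
which half of motor function is lost and quantifies disease
*aggressiveness*; $d_x$ (months) is the decline time constant. Disease
*accumulation* is $rD_{50} = t/(2 D_{50})$, which equals 0.5 at $t = D_{50}$
by construction, and stratifies the course into Phase I ($rD_{50} < 0.25$),
Phase II ($0.25 \le rD_{50} < 0.50$) and Phases III/IV ($\ge 0.50$);
aggressiveness is dichotomised at $D_{50} = 30$ months (LA above, HA at or
below). Any monotone reparameterisation of the sigmoid is observationally
equivalent for $D_{50}$ and $rD_{50}$, so the minimal two-parameter form
above is used.

Two conventions deserve note because published renderings differ on them:
the phase intervals are half-open with the boundary belonging to the later
phase (0.25 is Phase II, 0.50 is Phase III/IV), and the aggressiveness
boundary $D_{50} = 30$ is classed HA by default; `classify_aggressiveness()`
exposes the boundary membership as an argument rather than resolving the
ambiguity silently.

### Fitting

`fit_d50()` uses bounded nonlinear least squares
(`minpack.lm`, Levenberg–Marquardt) with box constraints
$D_{50} \in [0.5, 500]$, $d_x \in [0.1, 100]$ months — wide enough to cover
any clinically plausible course while keeping the flat tails of the
likelihood away from the optimiser. Because short series from slowly
progressing patients are nearly flat, the fit is multi-started from three
$D_{50}$ initialisations: the last observed time, twice the last observed
time, and the time at which the score crosses 24 by linear interpolation.
A virtual full-health anchor observation $(t=0, F=48)$ is prepended by
default (weight 1, skipped when a real $t=0$ visit exists, disabled with
`anchor = FALSE`): the model describes a transition *from full health*, and
the anchor identifies fits from as few as two real visits. Non-convergence
is never silent — the best-found parameters are returned with
`converged = FALSE`, falling back to a coarse profile search if every
optimiser start fails.

Two properties pin down correctness and are tested against a dense
grid-search oracle: time-scale equivariance (multiplying all visit times by
$k$ scales $\hat D_{50}$ and $\hat d_x$ by exactly $k$) and RSS optimality
(the optimiser never loses to a 0.1-month grid over both parameters).

## Voxel-wise GLCM autocorrelation on three orthogonal planes

Texture is computed per voxel from grey-level co-occurrence matrices:

- **Quantisation.** Global min–max linear binning over the analysis mask
  into $N_g = 8$ levels: $\ell = \min(\lfloor (v - v_{\min})/(v_{\max} -
  v_{\min}) \cdot N_g \rfloor + 1, N_g)$. A constant volume maps to level 1
  (any single level is equivalent; 1 gives the minimal feature value).
  Global (not per-window) quantisation keeps the map comparable across
  voxels and presumes globally intensity-standardised inputs, which the
  upstream preprocessing of real T1 pipelines provides; per-window
  quantisation is available behind `per_window = TRUE`.
- **Co-occurrence.** For each masked voxel, one GLCM per orthogonal grid
  plane (axial x–y, coronal x–z, sagittal y–z), accumulating all four
  in-plane directions (0°, 45°, 90°, 135°) at distance 1 between voxel pairs
  that both lie inside the $(2r+1)^2$ in-plane window ($r = 1$) and inside
  the mask. Pairs are counted in both orientations, so the matrix is
  symmetric and the direction set is invariant under axis mirroring.
- **Feature.** Haralick autocorrelation
  $\sum_i \sum_j i\, j\, p(i,j)$, bounded in $[1, N_g^2]$; the stored map
  value is the mean over the planes with at least one valid pair. Voxels
  with no valid pair in any plane carry a missing marker and are excluded
  from the GLM mask. No smoothing is applied to the map (kernel 0).

Because the binning is min–max based, maps are exactly invariant under
positive affine rescaling of the input intensities. The compiled
implementation is verified voxel-for-voxel (to 1e-10) against an exhaustive
pair-enumeration oracle on random masked volumes.

## Voxel-wise general linear models

`build_design()` encodes the effect of interest plus the nuisance set used
throughout: sex and onset site as 0/1 indicators, age mean-centred, and the
*congruent* progression parameter mean-centred ($D_{50}$ when analysing
$rD_{50}$ or phases; $rD_{50}$ when analysing $D_{50}$ or aggressiveness) —
so accumulation effects are corrected for aggressiveness and vice versa.
Group contrasts use two group-indicator columns without an intercept and
contrast $(1, -1, 0, \dots)$; regressions use an intercept plus a
mean-centred effect column. Comparisons against healthy controls use age and
sex only. For the onset contrast the nuisance set is sex and age: onset is
the effect itself, and the congruent-parameter rule concerns the
$D_{50}$/$rD_{50}$ analyses. Patients beyond Phase II are dropped from the
phase contrast (with a warning): later phases are too sparse in the kind of
cohort modelled here for a group of their own, and mixing them into Phase II
would blur the accumulation ordering.

Per voxel, ordinary least squares gives
$t = c^\top\hat\beta / \sqrt{\hat\sigma^2\, c^\top (X^\top X)^{-1} c}$ with
$df = n - p$ over the intersection mask of all subjects' defined voxels.
Voxels with zero residual variance are marked $\pm\infty$ (sign of the
estimated effect) rather than dropped. Thresholding is one-sided
($t > t_{1-p}$, default $p = 5\times 10^{-4}$), matching directional
contrast practice; both directions of every contrast are always evaluated,
and absence of supra-threshold voxels is emitted as an empty cluster table,
not omitted. Clusters are connected components at 18-connectivity by
default (6 and 26 available) retained at extent $\ge 10$ voxels; the
comparator is configurable because reports phrase the rule both as "10
voxels" and "> 10 voxels". Ties in the table ordering are broken by peak t,
then by lexicographic peak index, so outputs are bit-stable.

No correction beyond the uncorrected voxel threshold plus extent rule is
applied, mirroring common practice for this analysis; the cluster tables
should accordingly be read as descriptive localisation, not FWE-controlled
inference.

## The cohort report

`summarize_cohort()` gates every continuous variable through Shapiro–Wilk
($\alpha = 0.05$): normal variables print mean ± SD, skewed ones median ±
IQR (as the width $Q_3 - Q_1$), each with the total range; categorical
variables print counts with percentages rounded half-up to one decimal
(half-up, not banker's, to match clinical-table convention).
`compare_groups()` applies the same gate to choose between the pooled
two-sample t-test and the Mann–Whitney U test, and uses the χ² test without
continuity correction for categorical tables — the convention under which
small 2×2 clinical tables reproduce commonly reported p values; the
correction is available via `correct = TRUE`.

## What the synthetic data emulate — and what they do not

`simulate_cohort()` reproduces the *marginal* clinical structure of a
representative ALS clinic cohort: true $D_{50}$ log-normal, parameterised by
a median of 30.23 months with the spread matched numerically to an IQR of
22.53 (positivity and right skew are the essential features); $d_x$
log-normal with median 6 months (a decline spanning roughly two years around
$D_{50}$, typical of observed courses); accumulation at scan drawn from a
Beta distribution with mean 0.28 and sd 0.13, truncated to [0.05, 0.70],
which places roughly 42%/55% of patients in Phases I/II; age, sex and onset
marginals matching the cohort frequencies (63.08 ± 15.36 years truncated to
the observed range, 59.5% male, 29.3% bulbar). Visits start just before the
scan and follow a jittered 3-month schedule for 5 visits; scores are
$\mathrm{round}(\mathrm{clip}(F(t) + \varepsilon, 0, 48))$ with
$\varepsilon \sim N(0, 2^2)$. The generator makes no attempt to model
correlations between covariates (e.g. bulbar onset and sex), informative
visit censoring, or sub-score structure.

`simulate_phantoms()` builds each subject as spatially smoothed Gaussian
noise inside an ellipsoidal mask, with the smoothing FWHM (in voxels) raised
to a group-specific value inside a spherical ROI. Group differences are
injected as differences in *spatial autocorrelation* — the image property
the GLCM autocorrelation feature provably responds to — not as
mean-intensity shifts, which global min–max quantisation would largely
absorb. Every smoothed field is rank-standardised to uniform marginals (a
probability integral transform) before composition. This emulates the
global intensity standardisation that real T1 pipelines apply upstream, and
it matters numerically: without it the per-subject sample extremes set the
quantisation bin edges, and their sampling jitter injects a common
intensity-scale noise component into every voxel of the texture map, making
the voxel-wise null markedly conservative and inflating between-subject
variance. Phantoms contain no anatomy, no bias fields, no registration
error and no partial-volume structure; passing phantom tests therefore
demonstrates the statistical machinery, not robustness to real-data
artefacts.

All randomness flows from a single seed through a documented splitting
scheme (`sample.int` sub-seeds per stage and per subject), so any stage can
be regenerated independently and pipelines re-run bit-identically;
`run_pipeline()` records seeds, the config and per-file MD5 digests in a run
manifest.

## Numerical choices and degenerate inputs

- Phase boundaries honour half-open intervals exactly (`cut(..., right =
  FALSE)`); negative $rD_{50}$ or non-positive $D_{50}$ are rejected, never
  coerced.
- Constant-intensity volumes quantise to level 1; single-voxel masks yield
  an all-missing texture map rather than an error.
- $\hat\sigma^2 = 0$ voxels carry signed infinities; contrast vectors of
  zeros give $t = 0$.
- The t cut-off is computed from the t distribution at the map's residual
  df, never hard-coded; p thresholds outside (0, 0.5] are rejected.
- Percentage rounding is half-away-from-zero with a $10^{-9}$ guard against
  binary representation of exact halves.
- Gaussian smoothing uses a separable kernel truncated at $3\sigma$ with
  mirror boundaries; $\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$.

## Problem sizes used in the test suite

The suites validate each stage at sizes chosen to keep oracles exhaustive
and simulations informative: texture oracles on random volumes up to
$9^3$ with random masks; GLM oracles at $n = 20$ subjects on $6^3$ grids;
null calibration on $32^3$ phantoms with 20 + 20 subjects pooled over
replicates to about $2\times10^6$ voxel-tests (both one-sided directions of
the contrast are counted, as the pipeline always evaluates both); parameter
recovery on 200 simulated five-visit series.

## Known limitations

- **Per-voxel texture values are noisy.** With radius 1, a voxel's GLCM
  pools only ~20 pairs per plane, and when the underlying field is smooth
  those pairs are heavily correlated. The between-subject standard deviation
  of a single voxel's autocorrelation is consequently of the same order as
  the largest group effect a smoothing-strength difference can produce.
  At 20 + 20 subjects and the voxel threshold $p < 5\times10^{-4}$, the
  end-to-end phantom effect (ROI FWHM 2.0 vs 0.5) does not reach the t
  cut-off voxel-wise, and the pipeline does not recover the ROI as a
  supra-threshold cluster; the acceptance script reports the measured Dice
  success count honestly. Detecting smoothing-scale texture differences
  voxel-wise at such strict thresholds needs substantially larger cohorts
  (or regional averaging of the maps, which is out of scope here).
- **Extreme-tail calibration is approximate.** Texture values are means of
  few effectively-independent pair products, so their finite-sample t
  statistics have slightly heavy tails at $p = 5\times10^{-4}$; the
  end-to-end null supra-threshold fraction runs a few percent above nominal
  (the acceptance script reports the measured fraction and its ratio to
  nominal). Replicate-level hit counts are also mildly overdispersed
  relative to binomial because voxel tests within one map share subjects.
- The D50 fit assumes the decline is sigmoidal in the total score; plateaus,
  transient improvements and sub-score heterogeneity are not modelled.
- Cluster tables are uncorrected for multiplicity beyond the extent rule; a
  permutation-based family-wise option is a natural extension but is not
  part of this version.
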