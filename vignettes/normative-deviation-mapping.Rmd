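---
title: "Normative deviation mapping: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative deviation mapping: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Group-average contrasts blur over the fact that two patients with the
same diagnosis can deviate from typical brain anatomy in entirely
different places. Normative modeling replaces the group average with a
growth-chart logic: regress each regional measure on age (and scanner)
in a reference population, then express every individual as a deviation
Z-score per region. "Extreme" deviations (Z > 2 or Z < −2, strictly) are
then mapped per region and per person, and group questions are asked of
those maps — which regions are extreme in how many patients, do patients
carry more extremes than controls, do extremes track a clinical trait.

`normdev` implements that pipeline for wide subjects-by-ROIs tables of
cortical thickness, cortical surface area and subcortical volume, on a
Destrieux-style dictionary of 148 + 148 + 31 = 327 regions by default.
The dictionary is fully configurable: region counts near but not equal
to 327 appear in the literature depending on which structures are
included, and nothing in the code assumes a particular atlas.

# The normative model

## Warped Bayesian linear regression

Per ROI, the observed measure $y$ is mapped through a sinh-arcsinh
(SHASH) warp

$$\phi(y) = \sinh\!\big(\delta \cdot \mathrm{asinh}((y - c)/d) - \epsilon\big)$$

and modeled as Gaussian in warped space, $\phi(y)\,|\,x \sim
N(w^\top\psi(x), \beta^{-1})$, with an isotropic Gaussian prior
$w \sim N(0, \alpha^{-1} I)$. $\epsilon$ controls skew, $\delta$
tailweight; $\epsilon = 0, \delta = 1$ (with $c = 0, d = 1$) is the
identity, so the Gaussian model is nested and is the optimizer's
starting neighborhood. The fit maximizes the marginal likelihood
including the Jacobian $\sum_i \log \phi'(y_i)$, with the weight
posterior closed-form given the warp.

Numerical choices, all of which matter for reproducibility:

* **Parameterization and bounds.** The optimizer works on
  $(\epsilon, \log\delta, \log\alpha, \log\beta)$ with L-BFGS-B bounds
  $\epsilon \in [-3, 3]$, $\log\delta \in [-2.3, 2.3]$,
  $\log\alpha \in [-20, 20]$, $\log\beta \in [-30, 40]$. The affine
  pre-warp location and scale are fixed at the training median and
  standard deviation of $y$; freeing them adds no fit quality in our
  experiments (the optimizer drifts to a bound) while costing stability.
* **Restarts.** Three seeded starts (identity-neighborhood plus two
  jittered); best objective wins; relative convergence tolerance
  `factr = 1e7` (about 2e-9); non-convergence of all starts is an error
  carrying the optimizer trace.
* **Basis.** Intercept + cubic B-spline in age with 5 interior knots at
  training-age quantiles + one-hot fixed effects for training sites
  (first site as reference). A raw linear age column is off by default
  because the spline span already contains it — switching it on
  produces the rank-deficiency error, intentionally, naming the
  collinear column. Degree, knot count and site encoding are
  configurable through `basis_spec()`.
* **Predictive variance.** $\sigma_{pred}^2 = \beta^{-1} +
  \psi(x)^\top\Sigma_w\psi(x)$ includes the weight-posterior term, so
  scores far from the bulk of training ages shrink toward zero rather
  than exploding.
* **Extrapolation.** Ages outside the training range are scored (spline
  extrapolation) with a warning counting the affected subjects; a
  hard refusal would make single out-of-range participants — which real
  cohorts contain — unscorable.

## Site transfer

Models are trained on reference sites; clinical data usually comes from
scanners the reference never saw. `adapt_to_site()` estimates, per
(ROI, new site), the mean $\mu_s$ and spread $\rho_s$ of calibration
controls' standardized residuals $(\phi(y) - w^\top\psi(x)) /
\sigma_{pred}$, and downstream scores become $Z = (r - \mu_s)/\rho_s$.
Only the residual moments are adjusted; the weight posterior is not
refit. This is the committed transfer contract: it is cheap, needs only
a modest control sample per site (minimum 10, configurable; the default
synthetic calibration pool has 998 controls across the transfer sites),
and handles both additive offsets and scale inflation. Training sites
use the null adaptation $(\mu_s, \rho_s) = (0, 1)$; scoring an unseen,
uncalibrated site is an error that names the fix.

## Model persistence

`save_models()` writes one JSON file per (modality, ROI) with a
versioned schema. Doubles are serialized as 17-significant-digit
strings — the shortest representation that uniquely determines an IEEE
double — so a save/load round-trip reproduces Z-scores bit-identically.

# Deviation summaries

* Thresholds are strict (`Z > 2`, `Z < -2`); a score exactly at the
  threshold is not extreme.
* Per-ROI group frequencies are reported as exact percentages plus a
  one-decimal label (the convention of the field's tables: 5 of 38 is
  "13.2"), with tier flags at the 5 / 7.5 / 10% frequency levels used
  for map displays.
* Group mean rates average each subject's percentage of flagged regions
  (per modality and sign). A pooled variant (flags over group cells) is
  available behind `pooled = TRUE`; the two differ only through subject
  weighting and coincide here because every subject has every region.
  The per-subject average is the default because it is the statistic a
  per-individual burden account implies.
* Per-subject burden counts aggregate across all supplied modalities;
  `has_any` flags at least one extreme of either sign.
* Top-k listings break ties deterministically by (percentage desc,
  count desc, ROI name asc), so reruns and platforms agree.

# Inference

* **Matching.** 1:1 propensity matching of each diagnostic group to
  healthy controls on age and site: logistic model of case membership,
  greedy nearest-neighbour without replacement on the linear predictor,
  cases processed in descending propensity order. Under complete
  separation the distance falls back to standardized covariates with a
  warning. Balance (standardized mean differences before/after) is part
  of the result object. Implemented directly on `stats::glm` — the
  procedure is small and fully specified, and owning it keeps the
  dependency footprint at base R.
* **Permutation GLM.** Freedman–Lane: regress the outcome on the
  nuisance columns, permute the nuisance residuals, refit the full
  model, recompute the contrast t. Outcome and design are demeaned
  (PALM-style); the projected-out intercept costs one residual degree
  of freedom, which makes the contrast t equal the classic two-sample t
  when there are no covariates. Monte-Carlo p-values use the
  $(1 + \#\{|t^*| \ge |t|\})/(1 + n_{perm})$ convention; `exact = TRUE`
  enumerates all permutations (n ≤ 8) and returns the exact proportion.
  Nuisance covariates are standardized — the contrast t is invariant to
  column scaling and ICV in mm³ would otherwise dominate the
  conditioning.
* **Contrast family.** The default group-contrast table holds four
  clinically motivated pairings (each diagnostic group vs HC, plus
  violent vs non-violent patients), each in both one-sided directions —
  eight contrasts, mirroring permutation toolkits' paired $C$ / $-C$
  convention, which with 332 regions yields the familiar
  2,656-test family (2,616 at the default 327-region dictionary). Any
  user-supplied contrast table is accepted; a single `permutation_glm()`
  call defaults to two-sided.
* **Multiplicity.** Benjamini–Hochberg FDR over the pooled family at
  three nested tiers: ROIs within (modality, contrast); ROIs ×
  contrasts within modality; everything. BH is the default because the
  tiered map legends this package mirrors are FDR-based; a
  max-statistic Westfall–Young familywise alternative is available and
  uses permutation streams aligned across the family (one stream per
  (modality, contrast), shared by all ROIs). Corrected p-values are
  clamped to be monotone across tiers: a larger family is never
  reported as more favorable.
* **Burden tests** are one-sided by design (patients hypothesized to
  carry *more* negative and *fewer* positive extremes than controls),
  by label permutation on the group mean difference; degenerate inputs
  (all counts equal) return p = 1 with a warning.
* **Trait association** (PCL-R total, 0–40) runs per ROI on the
  violence groups, with age, psychosis status and — for area and
  volume — ICV as nuisance covariates; subjects without the trait (or
  without ICV, for those modalities) are excluded with a message, and
  fewer than 10 usable subjects is a refusal.

# The synthetic cohort generator

The generator exists so that every stage is testable with known ground
truth; no real data of this kind is shareable. Per subject and ROI:

$$y = f_{roi}(age) + o_{site}\,\sigma_{roi} + s_{site}\,\sigma_{roi}\,
S^{-1}(\eta;\epsilon,\delta) + b_{roi}\,\widetilde{icv} \;[+\; \text{effects}]$$

with $\eta \sim N(0,1)$ and $S^{-1}$ the inverse SHASH map.

* **Trajectories** $f_{roi}$ are cubic polynomials in scaled age,
  drawn once per ROI from modality-appropriate ranges (thickness
  ~2.2–3.0 mm declining with age; area and volume proportional to a
  per-ROI base scale), deterministically from the spec seed.
* **Sites**: four training sites and two transfer sites by default,
  with per-site offsets expressed in residual-σ units (one number that
  is coherent across modalities with different physical units — the
  package's resolution of specifying offsets "in measurement units"
  across three unit systems) and multiplicative residual scales.
* **Noise shape.** Residuals follow the inverse-SHASH law so the
  normative warp family matches the generator. That statement needs a
  caveat the package owns honestly: the warped-response likelihood can
  only Gaussianize residual skew exactly when the warp's affine
  location tracks the normative mean, and a global $(c, d)$ cannot
  track an age trend expressed in measurement space. Strong residual
  skew under a strong age trend therefore leaves a small irreducible
  tail miscalibration no optimizer setting can remove (we verified that
  freeing $c, d$ merely drifts to a bound). The defaults
  ($\epsilon = 0.10$, $\delta = 1.05$) were chosen once to keep the
  generator inside the family's approximation capacity — visibly
  skewed and heteroskedastic, yet with held-out tail rates
  statistically compatible with the Gaussian 2.3% target, as the
  acceptance script measures. A `contamination` switch injects
  wide-Gaussian outliers for deliberate misspecification experiments.
* **ICV coupling** for area/volume uses a fixed generative coefficient
  derived from the model-implied pre-coupling spread, so that the
  value–ICV correlation matches the requested loading (default 0.4) in
  a cohort spanning the default age range — and, importantly, so the
  same law generates reference and clinical tables. (An earlier
  per-table empirical scaling subtly changed the generative law between
  tables and mis-calibrated transfer; the fixed coefficient is the
  correct construction.)
* **Effects** are sparse and group-specific: per (group, modality,
  ROI), a signed shift in residual-σ units carried by a
  Bernoulli(prevalence) subset — encoding the premise that only a
  fraction of patients carries any given deviation — plus an optional
  `trait_link` coupling the ROI residual to the simulated PCL-R total
  (Normal(20, 8) clipped to 0–40, violence groups only, mean-centred so
  group means are untouched).
* **RNG discipline.** Every draw derives from the spec seed through a
  named per-purpose stream, so toggling effects does not perturb noise
  realizations, and identical spec + seed gives byte-identical files.
* **Defaults mirror the study design**: group sizes 38 / 138 / 20 /
  196, a 998-control calibration pool, all-male cohorts
  (`female_fraction = 0`, adjustable), group age ranges matching the
  demographics table.

What the generator does **not** emulate — and hence what passing tests
do not certify about real data: inter-regional correlation (ROIs are
conditionally independent given age, site and ICV), sex effects,
longitudinal structure, medication and substance-use confounds, scanner
drift within site, motion/QC artifacts, and any real atlas geometry.

# Statistical conventions in the test suite

Calibration checks pool the Z matrix across the fitted ROI set (10
ROIs). This is deliberate: with site-adaptation moments estimated from
200 calibration controls, the mean of a *single* ROI's held-out Z
carries sampling noise of about $\sqrt{1/200 + 1/5000} \approx 0.07$,
so a ±0.05 window on one ROI would fail a correctly implemented model
half the time. The pooled mean is the quantity for which the ±0.05
window is a meaningful test.

Problem sizes were chosen as the smallest that keep the Monte-Carlo
intervals informative: reference pools of 500–2,000; 5,000 held-out
controls for calibration and coverage; 500 null datasets × 500
permutations for error control; 20 seeded replicates for recovery
checks. Our own power analysis of the trait-association ranking check
is worth recording: at the simulated link of 0.05 Z-units per PCL-R
point and n = 58 trait carriers, the trait regressor's expected |t| is
about 2.9, essentially the same as the expected maximum null |t| across
25 regions, so the trait ROI wins the minimum-p ranking in only roughly
70–80% of replicates — a power ceiling of the design, not an
implementation defect; the corresponding acceptance check reports the
observed rate honestly.

# Known limitations

* The transfer step adjusts residual moments only; a site whose age
  trend *shape* differs from the reference population is out of scope.
* The warp family's tail flexibility is shared across ages (one
  $\epsilon, \delta$ per ROI); age-varying skew is not modeled.
* BH across a pooled tier treats all tests as exchangeable; spatially
  informed procedures (TFCE and relatives) are out of scope.
* Reported Cohen's d follows $d = t\sqrt{1/n_1 + 1/n_2}$; published
  (t, d) pairs computed under other conventions will not be reproduced
  exactly.
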