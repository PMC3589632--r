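---
title: "Methods: population PK of a 7-day continuous infusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population PK of a 7-day continuous infusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(civipk)
```

This vignette is the package's own account of its science: the model it
fits, the approximations and numerical choices it makes, what its
synthetic-data generator does and does not emulate, and where genuinely
open design questions were settled by a documented choice.

## Structural model and units

Sepantronium is given as a constant-rate intravenous infusion over 168 h
(4.8 mg/m²/day scaled by body surface area), repeated every 21 days. A
one-compartment model parameterised by clearance CL (L/h) and volume V (L)
is used throughout; `predict_conc()` evaluates the closed-form solution of
`dC/dt = R(t)/V − (CL/V)·C` for arbitrary piecewise-constant infusion
histories with additive superposition. A two-compartment alternative is
deliberately out of scope: with sampling concentrated during the infusion
plateau and only two post-stop samples per patient, distributional phases
are not identifiable, and the one-compartment model is the tool for the
question the analysis asks (individual exposure during infusion).

Units are fixed package-wide — time h, amount mg, volume L, concentration
ng/mL — and the mg/L → ng/mL conversion (×1000) happens only at the
prediction boundary. Query times exactly at an infusion stop use the
during-infusion branch (left-continuous convention); the two branches agree
there analytically, so this is a tie-break, not a model choice.

## Statistical model

* Inter-individual variability: one exponential random effect on CL,
  `CLᵢ = TVCLᵢ·exp(ηᵢ)`, `η ~ N(0, ω²)`. V carries no random effect: the
  sparse post-infusion sampling cannot separate variability in V from
  variability in CL, and attempting it destabilises the fit.
* Residual error: proportional, `C_obs = C_pred(1 + ε)`, `ε ~ N(0, σ²)`,
  with two magnitudes. Patients whose pooled during-infusion samples
  contain an IQR-rule outlier keep all their data but move to a separate,
  larger σ² — modelling the unexplained concentration spikes instead of
  deleting them.
* Covariate model on CL: multiplicative power terms for continuous
  covariates, `(X/X_ref)^θ`, and ratio factors for indicators, `θ^Z`.
  The CLCR and ALT reference values are pinned to 79.22 mL/min and
  19.0 U/L so that fitted exponents are directly comparable with the
  published final model; other continuous candidates use the dataset
  median.

Observations below the LLOQ (0.05 ng/mL) or missing are excluded from the
likelihood (no LLOQ/2 imputation, no M3-style censored likelihood) but kept
in the tables for audit.

## Estimation: FOCE-I as a per-patient Laplace approximation

`foce_ofv()` returns −2× an approximate log marginal likelihood. For each
patient the one-dimensional conditional objective in η (data term plus
prior) is minimised by a safeguarded Newton iteration (numerical
derivatives, step clamped to ±2, backtracking, step tolerance 1e−10), and
the marginal likelihood is approximated by Laplace's method at that mode.
The residual variance is evaluated at the conditional prediction — the
"interaction" in FOCE-I — so the variance depends on η. Additive constants
follow the extended least-squares convention and are held fixed: OFV
*differences* between nested models are likelihood-ratio statistics, and no
claim of numerical equality with any particular NONMEM build is made. With
ω² = 0 the code switches to the exact pooled Gaussian −2 log-likelihood.

Two numerical details matter in practice:

* The curvature entering the Laplace term is computed with a larger step
  (1e−3) than the Newton derivatives (1e−4). A second difference of a
  quantity of order 10³ at step 1e−5 carries ~1e−3 of cancellation noise,
  which is enough to make quasi-Newton outer optimisers report false
  convergence; the larger step removes the noise while its O(h²)
  truncation error stays far below the approximation error of Laplace
  itself.
* With a proportional error model the conditional mode is *not* exactly at
  the prior mean even when a patient's data equal the population
  prediction: the log-variance term contributes a gradient of order σ².
  This O(σ²) offset is a property of the estimator with interaction, not a
  bug; the tests check the η = 0 limit in the small-σ regime.

The outer problem is solved by `nlminb()` on a transformed scale: log for
CL, V, ω² and both σ²; log for ratio coefficients; raw for power
exponents; all bounded to ±30 to keep overflow excursions recoverable
(non-finite predictions yield an infinite OFV rather than an error).
Because `nlminb`'s gradient test is conservative on numerically
differentiated objectives, a fit that ends with "false convergence" is
restarted once from its own optimum and declared converged only if the
restart cannot improve the objective by more than 1e−3. Standard errors
come from the inverse numerical Hessian of the OFV at the optimum
(covariance = 2·H⁻¹), reported as CV% of each estimate via the delta
method; the outlier-group σ² is estimated only when the dataset actually
contains outlier-group observations.

Weighted residuals are the classic population WRES: per patient,
`Cov = diag(σ²·PRED²) + ω²·G·Gᵀ` from the first-order linearisation at
η = 0, and `WRES = Cov^(−1/2)(DV − PRED)`. Conditional-weighted variants
are a different dialect and are not computed.

## Outlier rule

Q1 and Q3 are computed over all during-infusion, quantifiable
concentrations pooled across patients and cycles, with linear interpolation
between order statistics (`stats::quantile` type 7) — the most widespread
quartile estimator, and the pooling that matches a single global threshold
for the whole analysis set. "Above"/"below" are strict inequalities, so a
degenerate all-equal dataset produces no flags. Both choices are
configurable (`type`, `pooled`), as is the grouping granularity: by default
the error group is assigned per *patient* (all samples of a flagged patient
share the larger σ²); a per-observation mode exists but is off by default.
Whether the original analysis pooled quartiles across cycles is not
documented; pooling across cycles is this package's declared reading and a
per-cycle variant was deliberately not added.

## Covariate selection

Screening regresses the base-model post-hoc η on each continuous covariate
(two-sample t-test or one-way ANOVA for categoricals) at a default
α = 0.1 — the screening threshold of the original analysis is not stated,
so this is a package default, chosen permissive because screening exists
only to cut the forward-addition workload. Forward addition adds the
candidate block with the largest significant OFV drop (χ² with df = block
size at α = 0.05), initialising each trial fit from the current optimum
with the new coefficients at their null values — which also guarantees the
nested-model monotonicity the tests assert. Backward elimination removes
the block whose exclusion costs least whenever that cost is not significant
at α = 0.01. Cancer type (HRPC and MM indicators against the NSCLC
reference) always enters and leaves as one 2-df block. Ties on
significance are broken by larger ΔOFV, then by candidate order, making
selection deterministic given the dataset.

## Bootstrap validation

`bootstrap_pk()` resamples whole patients with replacement to the original
count and refits, starting each replicate at the point estimates (speed and
stability; a replicate is "failed" if the optimizer does not confirm
convergence). By default resampling is stratified by study so that both
cancer-type indicator columns are non-degenerate in every replicate — the
original text does not say whether it stratified, so the literal
unstratified mode is available too. 95% CIs are the 2.5th/97.5th
percentiles of converged replicates, same type-7 interpolation as
everywhere else. All replicate index sets are drawn up front from the seed,
so resampling is bit-reproducible regardless of how individual fits behave.

## Exposure

`compute_css()` implements `Css = dose/(CL·duration)·1000` with the
individual post-hoc CL and the total amount infused over one 168-h cycle
("individual actual dose" is read as that cycle total, BSA × 4.8 × 7).
`renal_effect_summary()` propagates a CLCR change through the power term:
CL ratio `(CLCR/ref)^θ`, Css ratio its reciprocal. At CLCR = 40 mL/min
versus the 79.22 reference with θ = 0.425 this gives the −25% CL / +34%
Css effect that motivates dose attention in renal impairment.

## The virtual-study generator

`simulate_study()` reproduces the design the analysis assumes so every
stage is testable without clinical data: 33/34/29 patients across NSCLC /
HRPC / MM, all-male HRPC, one 168-h infusion cycle with four
during-infusion samples (24, 72, 120 h and immediately before stop) plus
one draw in each of the 0.5–4 h and 6–24 h post-stop windows (~6 samples
per patient, matching the reported average; the two post-stop samples are
what identifies V). Covariates are drawn from truncated marginals matched
to the reported demographics — normal for age, weight and height,
log-normal for serum creatinine, ALT, AST and α₁-AGP (their reported means
exceed their medians) — with body surface area derived from height and
weight by the DuBois formula and CLCR by Cockcroft–Gault, which induces
realistic age–weight–renal-function correlation rather than sampling CLCR
independently. Generating parameters default to the published final model.

The contamination mechanism is **synthetic fiction**: the original analysis
found no cause for its concentration spikes, so the generator invents one
with the same footprint — ~11/96 patients receive multiplicative spikes
(uniform 5–50×) in 1–2 during-infusion samples, and those patients' noise
uses the outlier-group σ², which defaults to CV 100% because the published
outlier-group residual estimate is printed on an ambiguous scale and is
therefore treated as configurable rather than asserted. Consequences the
tests acknowledge: a handful of unspiked samples from high-noise or
genuinely low-clearance patients can legitimately cross the global IQR
limit, so spike recovery is checked as "every spike ≥5× the high limit is
flagged, and at most a few flags are not injected spikes", not as exact
set equality.

What the generator does *not* emulate: dropout, inter-occasion
variability, assay error beyond proportional noise, BLQ-rich designs (the
simulated regimen rarely censors), correlated covariate pathology beyond
the DuBois/Cockcroft–Gault structure, or multi-cycle sampling by default
(the per-cycle times beyond cycle 1 were never printed; `n_cycles` is a
knob, and superposition across cycles is tested against an ODE oracle).
Passing tests therefore demonstrate that the estimation machinery is
correct and calibrated under its own assumptions — not that those
assumptions fit any particular clinical dataset.

## Problem sizes and reproducibility

The test suite runs every stochastic check at sizes chosen to make its
statistical assertions meaningful while keeping the suite quick: the
recovery and diagnostic checks use the full 96-patient design (single fits
take well under a second with the compiled kernel), type-I calibration of
the selection LRT uses 200 replicates of a 40-patient design, and bootstrap
coverage uses 10 meta-replicates of 50-replicate bootstraps on a 25-patient
design. The pipeline (`run_full_analysis()`) derives per-stage seeds from
one master seed, writes only text intermediates (CSV/JSON), and is a pure
function of its configuration; users drive everything from R — the
functions and this vignette are the interface, with
`scripts/acceptance.R` as a thin shell entry point for end-to-end
recomputation.

## Known limitations

* The Laplace/FOCE-I objective is an approximation; its gap to exact
  quadrature is bounded in the tests (≤0.5 OFV units on small instances)
  but grows with ω² and very sparse per-patient data.
* Percentile bootstrap CIs undercover modestly at small cohort sizes;
  BCa or bootstrap-t intervals are out of scope.
* No covariates on V, no full covariance matrix for random effects, no
  SAEM or Bayesian estimation, no censored-likelihood BLQ handling.
* The outlier-group σ² is only weakly identified when few patients are
  flagged; its CV% is accordingly large.
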