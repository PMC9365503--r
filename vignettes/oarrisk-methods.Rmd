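---
title: "Methods: radiobiological risk models for breast-radiotherapy comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiobiological risk models for breast-radiotherapy comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oarrisk)
```

`oarrisk` compares breast-radiotherapy technique combinations on late
normal-tissue endpoints: lung complication probability, secondary-cancer
risk of the lungs and contralateral breast, and cardiac excess relative
risk. This vignette explains each model, the parameters that matter, what
the synthetic cohorts do and do not emulate, and the numerical and design
choices behind the implementation.

## Dose model and biologically weighted summation

A treatment course is a `fractionation(n, d)` (n fractions of d Gy); an
organ's exposure in one course is a `dose_distribution`: a vector of voxel
doses with a uniform voxel volume. Voxel vectors of different courses of the
same patient are assumed pre-aligned (an input contract — no registration is
attempted, and no DICOM parsing is in scope).

Courses with different fractionation are compared via the linear-quadratic
biologically effective dose, `BED = n·d·(1 + d/(α/β))`. `sum_courses()`
converts each voxel's per-course dose to BED under *proportional
fractionation* — every voxel is treated in all n fractions of its course, so
its local dose per fraction is its total dose divided by n — sums BEDs
across courses, and reports the total as EQD2 (the isoeffective total dose
in 2-Gy fractions). Throughout, α/β = 3 Gy (late-responding tissue), and no
protracted-irradiation correction is applied because the brachytherapy boost
is high-dose-rate.

Two summation scales coexist deliberately:

* **EQD2 sum** — used for NTCP and the in-field secondary-cancer model. The
  choice to feed biologically accumulated ("BED2") rather than physical
  summed DVHs into the LKB model is a reading of how mixed-fractionation
  plans are most consistently compared, not a unique convention; the
  `physical = TRUE` flag of `sum_courses()` exposes the alternative.
* **Physical sum** — used for the reported dose metrics (Dmean, V20 Gy,
  D1%), for the out-of-field linear no-threshold risk (its slope is fit to
  absorbed dose), and for the cardiac model (whose 7.4%/Gy slope is an
  epidemiological fit to mean physical heart dose).

## DVHs and their metrics

`dvh_from_distribution()` bins voxels into contiguous half-open bins
`[kw, (k+1)w)` of width w = 0.1 Gy by default — fine enough that binning
error in EUD and NTCP is far below model differences at clinical doses. The
representative dose of an occupied bin is the *mean of its voxels* rather
than the bin midpoint: this conserves the organ mean dose exactly, and an
all-zero distribution correctly yields zero dose, zero EUD and zero
secondary-cancer risk instead of a spurious half-bin-width dose. Empty bins
(kept, so bins stay contiguous) use the midpoint; their volume is zero, so
they contribute nothing.

`V_x` interpolates linearly inside bins of the cumulative curve; `D_y%` (the
minimum dose received by the hottest y% of the volume) inverts that curve.
For point-mass DVHs built directly from `(dose, volume)` pairs — used in
tests and textbook examples — both metrics fall back to step-function
conventions.

## LKB normal-tissue complication probability

`EUD = (Σᵢ vᵢ·Dᵢ^(1/n))ⁿ` reduces a DVH to the uniform dose of equal
complication risk; `NTCP = Φ((EUD − D50)/(m·D50))`. The three parameters per
endpoint: `n` (1 = parallel organ, EUD is then exactly the mean dose;
toward 0 = serial, EUD approaches the maximum dose), `m` (probit slope,
dimensionless), `D50` (Gy; 50% complication at a uniform whole-organ dose —
the model's anchor identity, `NTCP(D50) = 0.5` exactly).

Numerical choices: Φ is evaluated in closed form through the standard-normal
CDF, not by quadrature of the defining integral (mathematically identical,
exact and fast; the test suite cross-checks against numerical quadrature).
The generalised mean is computed with a log-sum-exp rearrangement so the
serial limit (n of order 10⁻³) does not overflow `D^(1/n)`; zero-dose bins
are skipped — their contribution is exactly zero, avoiding `0^(1/n)` edge
cases.

The bundled registry (YAML, user-extensible via `lkb_registry(path)`) holds
the two lung endpoints: symptomatic pneumonitis (1.000, 0.35, 37.6 Gy) —
applied to both the ipsilateral and the whole lung, as no separate
whole-lung fit is distinguished — and radiation pneumonitis grade ≥ 2
(0.990, 0.37, 30.8 Gy).

## Secondary-cancer excess absolute risk

Both regimes share the age modifier
`μ = exp(γe·(age_x − 30) + γa·ln(age_a/70))`, normalised to 1 at exposure
age 30 / attained age 70, and the organ-specific initial slope δ in
(10,000 PY·Gy)⁻¹.

**Out-of-field (linear no-threshold):** `EAR = δ·D·μ` with D the mean organ
dose — appropriate below roughly 20% of the prescription isodose, where
treatment-planning dose calculation is unreliable and measured (TLD) doses
are the better input. When a measured mean dose is supplied to
`patient_risk_profile()`, it overrides the distribution mean for these
organs.

**In-field (mechanistic):** `EAR = δ·μ·Σᵢ vᵢ·RED(Dᵢ)`. The risk-equivalent
dose

`RED = e^(−α′D)/(α′R) · [1 − 2R + R²e^(+α′D) − (1−R)²·e^(−α′DR/(1−R))]`

models cell killing and inter-fraction repopulation/repair with capacity
R ∈ [0, 1]. The sign of the `R²` term's exponential is chosen positive: that
is the form whose low-dose limit is `RED → D`, i.e. consistent with the
linear no-threshold behaviour the model must reduce to (typeset versions of
the formula sometimes render this sign ambiguously; the negative variant
breaks the limit). Boundary forms are substituted analytically within
ε = 10⁻⁶ of the ends — `D·e^(−α′D)` (bell/cell-kill) at R → 0 and
`(1 − e^(−α′D))/α′` (plateau) at R → 1 — and `RED(0)` is forced to exact
zero rather than floating-point residue. `RED(D) ≤ D` holds on the whole
parameter range.

`α′ = α + β·(d_T/D_T)·D` carries the fraction-size dependence; β is derived
as α/(α/β) with α/β = 3 Gy since only α is tabulated. For a biologically
summed plan the per-course products accumulate as `α′D = α·Σ BED_course`,
which for an EQD2-scaled DVH collapses to a local fraction dose of exactly
2 Gy, i.e. `α′ = α·(1 + 2/(α/β))`; `ear_full(x, "eqd2", ...)` selects this
pathway. This choice is self-consistent with the linear-quadratic framework
and reduces exactly to the single-course rule.

Routing (configurable, `organ_routing()`): ipsilateral lung → in-field full
model on the summed DVH; contralateral lung and breast → out-of-field LNT
on the mean dose; the heart gets the cardiac ERR rather than an EAR. The
penumbra region (20–80% isodose) has no operationally separate treatment:
its voxels simply enter the in-field DVH.

## Cardiac excess relative risk

`ERR = 0.074 Gy⁻¹ · D_mean`, linear and threshold-free;
`cumulative = baseline·(1 + ERR)` with clamping at certainty, and
`err_from_risks()` as its inverse (e.g. a 1.6% baseline and 2.0% cumulative
risk back-calculate to ERR = 25%). Latency/time-since-exposure structure is
not modelled.

## TLD aggregation and the photoneutron estimate

`mean_organ_dose()` averages the background readings once, subtracts that
mean from each chip (so per-chip net values remain reportable), floors
negative nets at zero with a warning, scales by the number of fractions and
averages. `outlier_excluded_mean()` recomputes after dropping flagged chips
— both with- and without-outlier results are first-class outputs, since
whether an in-field chip should enter downstream risk estimates is a
judgement call. mSv and mGy are treated as numerically equal only inside the
deliberately order-of-magnitude photoneutron chain
(`neutron_estimate()`: 18-MV dose share → neutron coefficient → IMRT
monitor-unit factor → linac emission ratio).

## The synthetic cohort generator

No clinical dose data ship with the package; `generate_cohorts()` produces
a study-shaped dataset so every downstream stage is testable. Defaults
emulate four scenarios — 3D-CRT + sequential boost (25×2 + 5×2 Gy),
3D-CRT + brachytherapy (25×2 + 2×6 Gy), IMRT + brachytherapy (25×2 +
2×6 Gy), IMRT + SiB (28×1.8 Gy, boost integrated) — with cohort sizes
10/10/8/10 (38 patients; the 3D-CRT + brachytherapy cohort is smaller
because that technique was being phased out in the emulated setting).

Per organ and patient, a target summed mean dose is drawn from the
scenario's configured Normal distribution (means and SDs transcribed from
published per-scenario cohort statistics into
`inst/extdata/scenario_calibration.yaml` — calibration targets are data,
not code). The voxel vector is then an exchangeable three-component
mixture: in-field voxels uniform within ±5% of the prescription, penumbra
voxels uniform between 20% and 80% of it, and an out-of-field exponential
tail truncated at 20% of the prescription (with its rate solved
numerically so the truncated mean is exact). The in-field weight is solved
so the expected mean equals the target; organs routed out-of-field are pure
truncated-exponential. Brachytherapy boosts contribute only a small
exponential tail to the organs at risk (steep source falloff); the
sequential teletherapy boost re-uses the mixture at its own prescription.
Default 5,000 voxels per organ — EUD/NTCP binning error is negligible at
that size and a 38-patient study generates in under a second.

Sub-seeds are derived deterministically per (scenario, patient, organ) from
the base seed, so cohorts are extensible without reshuffling and identical
(seed, config) yields an identical dataset (the manifest carries a content
hash). TLD sessions draw five chip readings per organ around the configured
per-fraction dose plus ambient background with multiplicative log-normal
noise of unit mean (CV 10%), three background readings, and optionally one
injected "barely in-field" outlier chip.

**What passing tests show — and what they do not.** The generator is
calibrated at DVH level to per-scenario mean doses; it reproduces mean-dose
statistics, scenario orderings, determinism, and the algebraic structure
every model consumes. It does *not* reproduce the spatial or shape detail
of clinical tangential-field DVHs: the synthetic ipsilateral lung carries
less mid-dose volume than real plans, so in-field EAR levels sit below
clinically reported ranges even though out-of-field EARs, NTCPs and ERRs
land in realistic ranges. Synthetic-cohort results validate the pipeline's
correctness, not clinical dose-planning conclusions. Patient-anatomy and
measurement variability are reported as separate sources (per-patient
spread from the dose model; per-chip spread from the TLD noise), since
their combination in published summary SDs is not uniquely decomposable.

## Cohort comparison and reporting

`compare_groups()` gates on Shapiro–Wilk normality at α = 0.05 per group
(standard and appropriate at the small n of such studies): both normal →
Welch two-sample t-test; otherwise → two-sided Mann–Whitney U with normal
approximation and tie/continuity correction. The unpaired Mann–Whitney form
is used because scenario cohorts are independent groups. Constant groups
(where normality cannot be assessed) fall back to Mann–Whitney with a
warning. Under a simulated normal null the gated procedure's type-I error
stays at the nominal 5% (checked at 2,000 replicates in the test suite).

Raw pairwise p-values are reported without multiplicity correction,
matching common practice in planning-study reports; a Holm-adjusted column
is additionally emitted and labelled as an extension. `pooled_mean()`
combines scenario means into technique- or boost-level averages weighted by
cohort size — identical to the mean of the concatenated per-patient values
when those exist. Report cells are formatted "mean ± SD (min – max)" with
one decimal for doses, percentages and ERR and integers for EAR per 10,000
person-years; boxplot summaries use quartiles with whiskers at 1.5×IQR and
explicit outlier lists.

## Problem sizes and tolerances

The test suite runs 38-patient default studies, a 200-patient single-
scenario recovery check (3-standard-error criterion on the configured mean
dose), 60-patient-per-scenario cohorts for the ordering property, and 2,000
null replicates for the type-I-error calibration — about half a minute in
total on one core. Exact identities (probit anchor, EQD2 round trip, LNT
worked examples) are asserted at 10⁻⁹–10⁻¹² relative tolerance; frozen
high-precision evaluations (EUD at n = 0.99, RED at mid-dose, age
modifiers) at 10⁻⁵–10⁻⁷; Monte-Carlo checks at 3 SE.

## Known limitations

* No DICOM-RT, registration, or dose-calculation functionality: inputs are
  voxel vectors or DVHs in the package's plain-text formats.
* The EQD2-vs-physical split described above is a modelling choice where
  conventions genuinely differ; both pathways are exposed.
* Alternative NTCP formalisms (relative seriality, logistic) and
  site-specific secondary-cancer parameter fitting are out of scope.
* The cardiac model carries no latency structure; EAR→ERR conversion is
  provided only as the single back-calculation utility.
* Synthetic cohorts are DVH-realistic in their means, not shape-realistic;
  see the generator section.
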