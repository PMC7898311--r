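---
title: "Methods: population generation, PBPK disposition and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population generation, PBPK disposition and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it computes, which
assumptions the computations rest on, and where design choices were
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Virtual renal-impairment populations

### Generative model

A renal category (mild, moderate, severe) is described by a
`population_params` object holding, per sex: an age range, a quadratic
height–age polynomial (cm), an exponential weight–height relation, age-banded
serum-creatinine means and CVs (µmol/L), hematocrit and α1-acid glycoprotein
(AGP) means and CVs, serum-albumin (HSA) age coefficients, and one shared
kidney-volume regression. A subject is sampled covariate by covariate in
that order; kidney function follows from Cockcroft–Gault creatinine
clearance normalized to 1.73 m² body surface area (DuBois), and the subject
is accepted only when the normalized GFR lies in the category band
(60–89 / 30–59 / 15–29 mL/min/1.73 m²).

Assumptions worth making explicit:

* **Ages are uniform** over the per-sex range by default. The empirical age
  histograms of the source cohorts are not available in usable form, so the
  generator does not attempt to reproduce their shape; a user-supplied
  empirical distribution can be plugged into `sample_age()`. Uniform ages
  are the single largest approximation in the population model and are the
  reason the cohort-mean tolerances for stochastic quantities are set at
  5–10% rather than at sampling error.
* **Positive-valued covariates are lognormal**, parameterized by arithmetic
  mean `m` and CV `v`: `sdlog = sqrt(log(1+v²))`,
  `meanlog = log(m) − sdlog²/2`. This guarantees positivity and reproduces
  the arithmetic moments exactly; it is also the convention of commercial
  population simulators, which makes the printed (mean, CV%) tables directly
  usable.
* **Weight inherits its variability through height**: the height residual
  (SD defaulting to the observed per-sex, per-category height SD, e.g.
  5.58 cm for mild males) is the only stochastic term in the
  height→weight chain. An optional lognormal weight residual exists but is
  off by default, since the observed weight SDs are largely explained by
  the height spread through the exponential relation.

### Two interpretation decisions

Two rows of the source parameter table cannot be used as printed and were
given defined, documented interpretations:

* **Weight–height.** The printed form `BH = e^(a + b·BW)` returns
  ~21 cm heights at 70 kg, so it is algebraically unusable. It is read here
  as `BW = exp(a + b·BH_cm)`. Under that reading the relation reproduces
  the observed sex-specific mean weights to about 1% (asserted in the test
  suite), which is strong evidence the printed equation simply has its
  variables transposed.
* **Kidney volume.** The coefficients ("baseline, BW, BH") come without
  units or functional form. The adopted linear form
  `V(mL) = baseline + β_BW·BW(kg) + β_BH·BH(m)` gives ~240 mL (both
  kidneys) for a mild-category adult and ~119 mL for a severe one —
  physiologically plausible magnitudes with the expected monotone decline
  across categories, which is what the downstream model needs (the kidney
  compartment volume). Any other dimensional reading produces implausible
  volumes.

Similarly, the **HSA age relation** ships only as three coefficients. The
form used is `HSA = C0 + C1·Age + C2·(Age/10)²` (g/L): with the printed
negative `C2` values a plain `Age²` term drives albumin negative within the
adult age range, while the decade-scaled quadratic stays in the
physiological 35–50 g/L window. The form is configurable and the
coefficients are echoed into every subject record's provenance so a
different convention can be substituted without ambiguity.

### Band enforcement and its bias

GFR-band containment is enforced by rejection: creatinine is redrawn up to
100 times, after which age (and the covariates derived from it) is also
resampled. This guarantees 100% containment while leaving the covariate
marginals as close as possible to their targets. It is not free of
distortion: truncating the Cockcroft–Gault output truncates the creatinine
distribution conditionally, and because the lognormal is right-skewed the
upper tail loses more mass than the lower. The effect is visible in the
moderate category, whose band is narrow relative to its ~23% creatinine
CVs: the accepted-cohort mean creatinine sits systematically a few percent
below the unconditional band mean. The acceptance tolerances for cohort
means (5/7/10% for mild/moderate/severe) absorb this; the alternative —
sampling creatinine from the truncated conditional directly — would hide
the inconsistency between the printed bands and the printed GFR limits
rather than surface it.

### Reproducibility

Each subject draws from an RNG substream seeded by the i-th draw of a
master stream, so subject *i* is identical whether generated alone, in a
cohort of 40 or of 4,000 (asserted byte-identically in the tests). All
trial-level randomness funnels through one integer seed.

### The derived mild-impairment reference population

`derive_caucasian_mild()` implements the standard construction of a mild
renal-impairment reference from a healthy template: all serum-creatinine
band means ×1.5 (the ratio of the healthy to the mild lower GFR cutoff,
90/60), everything else untouched, with a provenance flag that warns on
accidental double application. The bundled healthy Chinese and Caucasian
templates are synthetic placeholders (clearly marked in the files): the
healthy models of commercial simulators are proprietary, so these files
define plausible magnitudes and are meant to be replaced by users who have
validated healthy parameter sets. Their `gfr_band` is null so the derived
model remains samplable.

## 2. Drug disposition

### Partition coefficients and Vss

`predict_kp()` implements two published tissue-composition methods.
Poulin–Theil: partitioning into tissue neutral lipid and water with an
octanol surrogate (vegetable-oil surrogate and no tissue-binding correction
in adipose), corrected by the unbound-fraction ratio with the conventional
`fu_t = 1/(1 + 0.5(1−fu)/fu)`. Rodgers–Rowland: Henderson–Hasselbalch
ionization at plasma pH 7.4 / cell-water pH 7.0 / erythrocyte pH 7.22;
acidic-phospholipid binding for moderate-to-strong bases (association
constant back-calculated from the blood:plasma ratio and hematocrit);
albumin (acids, weak bases, zwitterions) or lipoprotein (neutrals) binding
extrapolated from plasma. Zwitterions with a basic pKa ≥ 7 take the
acidic-phospholipid branch with the full polyprotic ionization factors;
otherwise the acid branch is used. The two methods intentionally differ in
referencing (unbound plasma vs plasma water) and in the adipose surrogate,
which is why the cross-method agreement test uses a hydrophilic neutral
compound.

The bundled tissue-composition CSV is a literature-informed approximation
of the standard adult composition tables used by these methods; it is plain
text and user-replaceable. The four drug fixtures (ceftazidime, cefodizime,
vancomycin, cefuroxime) are likewise literature-informed approximations —
the original model-input tables are not publicly available — and every file
carries a provenance block saying so.

`Vss = (V_plasma + Σ_t Kp_t·V_t)/BW` is linear in the Kp vector, so the
uniform **Kp scalar** that reconciles predicted with observed Vss has the
closed form `(Vss_obs − Vp/BW)/(Vss_pred − Vp/BW)`; the fixtures ship with
scalars prefitted on the reference adult (reproducible via
`fit_kp_scalar()`), and the round-trip is asserted to 1e−6.

### Subject scaling

* Unbound fraction: single-binding-protein scaling
  `fu_s = 1/(1 + ((1−fu)/fu)·P_s/P_ref)` with reference HSA 45 g/L and AGP
  0.75 g/L; monotone, bounded in (0,1].
* Renal clearance: `CLr_s = CLr_ref · GFR_s/GFR_ref` with `GFR_ref`
  defaulting to 120 mL/min/1.73 m² (typical healthy adult; configurable per
  drug since reference conventions differ between sources). The non-renal
  route is left unchanged — CKD effects on hepatic elimination are out of
  scope and this is a stated limitation, not an oversight.
* Organ volumes scale with body weight, cardiac output (6.0 L/min
  reference) with BSA; flow fractions are renormalized to sum exactly to
  cardiac output. The kidney compartment volume is overridden by the
  population model's regression value.

## 3. The ODE model and its numerics

Fourteen compartments (twelve perfusion-limited tissues including a lumped
"rest", plus venous and arterial blood); gut and spleen drain through the
liver. The state is blood-referenced amount; plasma concentration is
`C_venous/B:P` on output.

**Elimination convention.** Renal elimination is drawn from the kidney
compartment and non-renal from the liver, each at its venous-equilibrium
outflow concentration. Drawing at rate `CL·C_out` directly would make the
observable dose/AUC smaller than the assigned `CL` by the organ-extraction
factor `1/(1 + CL_b/Q)` — about 10–15% for these drugs — while the input
clearances are themselves *defined* as dose/AUC from clinical studies. Each
systemic blood clearance is therefore converted to an organ-intrinsic value
`CLint_b = Q·CL_b/(Q − CL_b)` (well-stirred relation), which makes the
simulated dose/AUC_inf equal the assigned systemic clearance exactly for a
linear model; the test suite asserts the identity to 0.5%. The conversion
requires `CL_b < Q`; the model refuses drugs whose blood clearance
approaches the eliminating organ's blood flow, which is the correct
behaviour for a perfusion-limited structure.

**Integration.** `deSolve::lsoda` with rtol 1e−8 / atol 1e−10, integrated
piecewise between dose boundaries: every infusion start/stop and bolus time
restarts the solver, so discontinuities never cross a solver step. Boluses
increment the venous amount; infusions are constant-rate segment inputs.
Mass balance — dose in minus (amount in body + cumulative eliminations) —
is evaluated at every output point and its maximum relative error attached
to the profile; the suite requires < 1e−6 (observed values are near machine
precision). Output is on a 0.05 h grid by default. Negative states below
−1e−8 trigger a warning and are clipped to zero on output only.

## 4. Trials, NCA and evaluation

`run_trial()` reproduces the virtual-study design (default 10 trials × 10
subjects, equivalent by construction to 100 × 1 because subjects are drawn
from per-subject streams before grouping). NCA uses the linear-up/log-down
trapezoid (exact on mono-exponential decays), λz by unweighted log-linear
regression over trailing windows of ≥ 3 post-peak points chosen by best
adjusted R² (capped at 20 points so dense grids stay linear-time; a fixed
window is available), `AUC_inf = AUC_last + Clast/λz`, `CL = dose/AUC_inf`,
`CLr = Ae_renal/AUC_inf` with the cumulative renal amount taken at the end
of the simulated horizon — the documented convention is to simulate ≥ 7
half-lives when `CLr` matters. Profiles whose terminal slope cannot be
estimated are flagged (`lambda_z = NA`) rather than extrapolated.

The default sampling schedule (0, 0.25, 0.5, 1, 2, 4, 6, 8, 12, 24 h) is a
typical rich IV schedule for short-half-life antibacterials; study-specific
schedules should be passed explicitly, as should infusion durations
(default 0.5 h) — the original studies' designs are not published in usable
form.

Evaluation: fold-error windows are inclusive at 0.5/2 and 0.8/1.25 and
log-symmetric; MAPE is the plain arithmetic form
`(1/n)Σ|pred−obs|·100/obs`. `compare_models()` sorts population models by
MAPE. The repository ships a synthetic "observed" PK table generated by the
simulator plus lognormal CV-20% noise (`make_fixtures()`), so the
evaluation path is testable with no external data; the file header marks it
as synthetic.

## 5. Problem sizes and what the tests do (and do not) show

The acceptance computations use the internal-validation scale: 4,000
subjects per category for cohort means (seconds of compute), deterministic
single evaluations for the demographic equations, and reference-subject
simulations of 48–240 h for the PK identities. Unit and property tests use
cohorts of 40–2,000 and trials of up to 2 × 3 subjects, sizes chosen so the
whole suite runs in well under a minute while keeping Monte-Carlo standard
errors far below the asserted tolerances.

Passing tests show that the generator reproduces the *summary statistics*
of the observed CKD cohorts under the stated distributional assumptions,
and that the simulator obeys the structural identities of linear PK. They
do not show that the synthetic cohorts match real patients in joint
covariate structure (age–creatinine correlation within bands, comorbidity,
anthropometric skew), nor that the drug fixtures equal any study's actual
inputs, nor that predictions match clinical concentrations — that last
comparison requires user-supplied observed tables via the evaluation
module.

## 6. Known limitations

* Renal elimination is a single GFR-proportional lumped clearance: active
  secretion (cefuroxime, ~28%) and tubular reabsorption (vancomycin, ~25%)
  are carried only as metadata notes, so drugs with large transporter
  contributions will be predicted with bias.
* Non-renal clearance is CKD-invariant by design.
* Renal blood flow is not reduced with disease severity (only kidney
  volume and clearance are); this affects distribution negligibly at these
  extraction ratios but is not physiological.
* Healthy reference populations are synthetic placeholders.
* The tissue-composition table and drug fixtures are approximations; all
  are plain text and replaceable without touching code.
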