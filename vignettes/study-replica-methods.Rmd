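---
title: "Models and design choices behind the MetSyn study replica"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices behind the MetSyn study replica}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models
behind each stage, the tunable parameters and why their defaults are
what they are, what the synthetic-data generator does and does not
emulate, and the choices made where the design was genuinely open. It
states no empirical result that the test suite or `scripts/acceptance.R`
do not themselves compute.

## 1. The study design being replicated

The pipeline replicates a cross-sectional analysis of treatment-naive
men with metabolic syndrome in which three measurement domains are
combined:

* an untargeted plasma metabolomics panel (917 annotated metabolites,
  relative abundances);
* hyperinsulinemic euglycemic clamp measurements — the glucose disposal
  rate Rd as the gold-standard index of peripheral insulin resistance,
  and, in a subset, stable-isotope glycerol kinetics quantifying
  insulin's suppression of lipolysis;
* the Framingham 10-year general cardiovascular risk score.

The analysis surfaces are: a Mann–Whitney screen of metabolites between
insulin-resistant (Rd < 37.3 μmol·kg⁻¹·min⁻¹) and non-resistant men; a
Spearman screen of metabolites against the risk score; a nested
cross-validated boosted-tree classifier of high vs low risk, on all
metabolites and again on its top-20 features; the intersection of those
top features with the univariate correlates; and correlation analyses of
metabolites and clinical parameters against the lipolysis suppression
index. Because no machine-readable cohort is deposited with such
studies, every stage here runs against a synthetic cohort whose ground
truth is known, which turns each analysis into a recoverable-parameter
experiment.

## 2. One-pool clamp kinetics and the Steele estimators

### Forward model

The simulator (`gen_clamp()`) uses a single well-mixed pool: tracee
amount per kg body weight distributed in volume $V$ (L/kg), endogenous
appearance $Ra(t)$ and tracer infusion $F$ entering, and first-order,
non-discriminating disposal with rate constant $k$ fixed by basal
equilibrium, $k = (Ra_b + F)/(V C_b)$. With $E$ the tracer mole
fraction, the tracer leaves in proportion to $E$, giving

$$\dot Q_{tr} = F - E \cdot k\,Q_{tot}, \qquad
  \dot Q_{ee} = Ra(t) - k\,Q_{ee}.$$

Insulin (start $t = 0$) suppresses appearance mono-exponentially with
half-time $t_{1/2}$ toward a plateau $(1 - s/100)\,Ra_b$, where $s$ is
the subject's true percent suppression. These linear equations are
solved in closed form (no integrator error); a test cross-checks the
closed form against `deSolve::lsoda` and verifies tracer mass balance by
finite differences.

The real physiology is multi-compartment; one pool is chosen because it
is the idealization the Steele estimator assumes, which makes recovery
tests exact in the noise-free limit — a deliberate estimator-aligned
simulator. What passing recovery tests show is that the estimator and
windowing logic are correct, not that the Steele model is adequate for
any particular tissue.

### Estimators

At isotopic steady state, tracer dilution gives $Ra = F/E - F$; the
subtraction removes the tracer's own contribution to turnover, as is
conventional for primed-continuous protocols (`correct_tracer = FALSE`
exposes the uncorrected $F/E$). The non-steady form applied to each
consecutive sample pair is

$$Ra = \frac{\bar F - p V \bar C\,(E_2-E_1)/(t_2-t_1)}{\bar E} - \bar F,
\qquad Rd = Ra - p V\,\frac{C_2-C_1}{t_2-t_1},$$

which reduces exactly to the steady form when $C$ and $E$ are constant,
and is exact for the one-pool model when $p = 1$. The pool fraction
$p$ (default 0.65) and distribution volume (0.22 L/kg glucose,
0.23 L/kg glycerol) follow the conventional clamp literature; they are
explicit, configurable `steele_params()` because published studies
rarely print them. Negative estimates from noisy data are flagged with a
warning, never clipped: silent clipping hides data problems.

### Suppression and windowing

`estimate_suppression()` takes the basal Ra from steady-state dilution
over the pre-insulin samples (t ≤ 0, after ≥ 2 h of tracer
equilibration) and the clamp Ra as the mean of non-steady estimates over
the final 30 minutes of the insulin phase, then reports
$100\,(Ra_b - Ra_c)/Ra_b$. Because the terminal window sits on the
plateau, the result is insensitive to the (uncertain) $pV$ product.

Two protocol defaults deserve note. The suppression half-time defaults
to 30 min — the simplest transient that genuinely exercises the
non-steady estimator. The simulated insulin phase runs 240 min with
samples spanning basal, 2 h and 4 h, and is labelled `step1` throughout:
clamp studies of this design use a second insulin step, but its rate is
typically unpublished and nothing downstream consumes it, so the
generator does not invent one. With a 240-min phase the residual
transient in the terminal window is below 1% of the basal-to-plateau
drop, so noise-free recovery errors stay well under one percentage
point; a 120-min phase with a 30-min half-time would leave a ~6%
residual and systematically underestimate suppression.

Glycerol protocol free parameters (no published values exist for
concentration or enrichment levels): basal appearance median
2.5 μmol·kg⁻¹·min⁻¹ (log-normal, σ_log 0.25 across subjects), basal
plasma glycerol median 80 μmol/L, tracer infusion 0.1 μmol·kg⁻¹·min⁻¹ —
typical magnitudes for glycerol turnover in obese men, giving basal
enrichments near 4%. Measurement noise is multiplicative log-normal
with CV 5% on concentration and enrichment.

## 3. Framingham risk

The sex-specific 2008 general-CVD Cox model (lipid-based variant) is
used: risk $= 100\,(1 - S_0^{\exp(LP - \overline{LP})})$, with $LP$
linear in ln(age), ln(total cholesterol), ln(HDL), ln(SBP) (separate
coefficients when on antihypertensive treatment), smoking and diabetes.
The lipid-based rather than BMI-based variant is chosen because lipids
are among the pipeline's inputs. Coefficients are transcribed into
`inst/extdata/framingham_general_cvd_2008.json` rather than hard-coded,
and the test suite reproduces the reference publication's worked example
(a 61-year-old female smoker, TC 180 mg/dL, HDL 47 mg/dL, untreated SBP
124 mmHg, no diabetes → 10.48%) to 0.1 percentage point before any
cohort is scored; a 1000-case perturbation suite checks the sign of
every covariate's effect. Both sexes are implemented although the
emulated cohort is all-male. Lipids are accepted in mmol/L (converted
internally at 38.67 mg/dL per mmol/L) or mg/dL. Cohorts are
dichotomized at 12%, at-or-above counting as high risk; the cutoff is a
configuration constant, not optimized.

## 4. Metabolite preprocessing

Two operations, applied in a fixed, test-pinned order:

1. **Median rescaling** — each metabolite's non-missing values are
   divided by their median, making every non-missing column median
   exactly 1 (tolerance 1e-12 in tests).
2. **Half-minimum imputation** — each missing cell becomes 50% of its
   metabolite's minimum observed value across samples, the conventional
   surrogate for values below the detection limit.

Normalize-then-impute is adopted because the narrative convention in
metabolomics methods sections lists normalization first; the two orders
differ (the imputed value is half the minimum of the *rescaled* column),
so a regression test pins the choice. Medians are taken over non-missing
values only — missing cells have no defined abundance — and "minimum
observed value" is read column-wise, not globally. Batch correction,
log transformation and QC-sample handling are out of scope.

## 5. Univariate screening

Mann–Whitney U (exact distribution for small untied samples,
tie-corrected normal approximation otherwise — `stats::wilcox.test`
semantics, which an exhaustive-enumeration oracle verifies for all
n+m ≤ 12 in the tests), Spearman rank correlation with average ranks for
ties, and Benjamini–Hochberg step-up q-values (Benjamini–Yekutieli
behind a flag; BH is what "FDR correction" conventionally means). All
tests are two-sided with direction reported separately. The
multiplicity family is deliberately the caller's choice: the screens
accept any metabolite subset, because family choice is analytically
consequential — a metabolite can be significant within a 451-member
lipid family and not within the full 917-member panel, and
`lipolysis_analysis()` computes both to make that dependence visible.
Clinical parameters vs suppression form their own 8-test family.

HOMA-IR is glucose [mmol/L] × insulin [μU/mL] / 22.5 with
6.945 pmol/L per μU/mL; studies report HOMA-IR values without printing
the formula, so the standard literature definition is adopted.

## 6. The nested cross-validation harness

Per iteration *i* (seeded `base_seed + i`): two fresh standard-normal
sanity columns are appended; a stratified 80/20 train/test split is
drawn; hyperparameters are chosen by stratified 5-fold cross-validation
on the training split, maximizing held-out AUC (rank-based, tie-aware),
with ties resolved in grid order; the winner is refit on the full
training split; test AUC and gain-based importances are recorded.
Aggregation is the mean importance over iterations plus each feature's
selection frequency (how often it entered a per-iteration top-k among
features with positive gain). The final ranking orders by mean
importance, then frequency, then feature id — deterministic by
construction, and a test compares it against an independent sort.
Hyperparameter selection never touches the test split; a test corrupts
the test rows after the fact and asserts the chosen configuration is
unchanged.

The learner is gradient-boosted trees (xgboost) behind a small contract
(fit / predict-probability / importance). The default grid is depth
{2, 3, 4} × learning rate {0.05, 0.1, 0.3} × rounds {50, 100, 200} ×
subsample {0.8, 1.0}. Simulation studies in the tests and acceptance
script use `cv_reduced_grid()` (depth {2, 3}, rate 0.3, 30 rounds,
subsample 0.8) with 16-level histograms: at n ≈ 132 samples the reduced
settings reach essentially the same test AUC while keeping hundreds of
thousands of fits affordable, and coarse histograms lose nothing when a
training fold holds ~105 distinct values per feature. Everything runs
single-threaded so that results are bit-reproducible; the whole result
object (per-iteration AUCs included) is identical across repeated calls.

The sanity probes guard interpretation: if random columns reach the
top-k importance in more than 5% of iterations, reported importances
should not be trusted, and `sanity_report()` warns. Under pure noise the
probes are exchangeable with real features, so their top-k rate is just
k·n_sanity/(p + n_sanity) — that regime is tested too.

The across-iteration standard deviation accompanies the mean AUC
(mean ± sd is the reporting convention). Note that outer test splits
overlap across iterations, so the sd understates independent-sample
variability; it is a descriptive spread, not a standard error.

## 7. The synthetic cohort generator

`sim_config()` fixes the study conditions; the same config is
bit-reproducible. Defaults: 132 male subjects, 917 metabolites, an IR
fraction of 92/132, 14 planted IR-effect metabolites at a 1-SD log-scale
shift, 33 planted risk correlates at latent correlation 0.4, true
suppression centred at 68.1%.

**Clinical records.** Covariates are drawn from independent scaled
distributions whose medians and spreads match the published baseline
characteristics of such cohorts (median BMI 33.9 kg/m², glucose
5.72 mmol/L, total cholesterol 5.0 mmol/L, …); no attempt is made to
reproduce the real covariance structure, which is unpublished. Two
deliberate dependencies are built in: fasting insulin is drawn
conditionally on IR status (medians 123 vs 69 pmol/L), and the measured
Rd is drawn consistently with the label (so `classify_ir()` reproduces
the truth exactly — the label *is* the Rd dichotomy, as in the study
design). Being treatment-naive, diabetes and BP-treatment flags default
to 0; smoking to 25%. Sex is fixed male by default; female generation is
allowed but off.

**True suppression** is centred at the configured value with a built-in
negative dependence on log fasting insulin (8 percentage points per SD,
residual SD 6, clipped to [0, 100]): hyperinsulinemic subjects suppress
lipolysis less. This plants the HOMA-IR/insulin vs Ra-supp association
the lipolysis analysis must recover, while leaving lipids, BMI and age
unassociated — matching the null side of that analysis.

**Metabolites.** Log-normal per metabolite (meanlog ~ N(2, 1), sdlog ~
U(0.3, 0.8)). IR effects shift log abundance by `ir_effect_size` log-SDs
in IR subjects; risk correlates share a latent correlation with the
subject's standardized Framingham linear predictor, so the planted
association survives the nonlinear risk transform in rank-based
screens. The two planted index sets are disjoint by validation —
enabling the end-to-end check that the IR hit set and the risk hit set
barely intersect, the study's central negative finding. Annotations are
synthetic Metabolon-style two-level labels with roughly half the panel
in the lipid superfamily.

**Missingness** is purely left-censored: a cell can only be missing if
its latent value lies below its metabolite's detection limit (the 10%
column quantile by default), each such cell censored with probability
0.5 (~5% of cells overall). A test regenerates the latent matrix and
verifies every missing cell sat below its limit.

**What the generator does not emulate** — and therefore what passing
tests do *not* establish about real data: inter-metabolite correlation
(real panels are strongly blocked by pathway), batch and run-day
effects, the 236 unannotated metabolites, heavy-tailed or
mixture-distributed abundances, covariate-dependent censoring, and any
real biological coupling between metabolites and fluxes. Recovery rates
and AUCs on the synthetic cohort characterize the pipeline's
statistical machinery under its stated assumptions, not expected
performance on a new cohort; with planted 1-SD effects the classifier
separates groups more cleanly than real metabolome–risk associations
do.

## 8. Numerical choices and degenerate inputs

* Closed-form kinetics guard the $k = \lambda$ resonance by nudging
  $\lambda$ by 1e-8 relatively.
* Truncated clinical draws use rejection sampling (deterministic given
  the seed); true suppression is clipped, not redrawn, at [0, 100].
* An n = 0 cohort is an empty result, not an error; an all-missing or
  zero-median metabolite is an error naming the metabolite; a constant
  vector makes Spearman's rho undefined and is flagged rather than
  raised; single-class labels, missing cells at screening time, and
  classes smaller than the inner fold count are errors.
* Stage seeds derive from one master seed (`run_study(seed =)`), so the
  whole report — summary JSON included — is byte-identical across
  reruns.

## 9. Problem sizes used by the checks

The test suite and acceptance script size their simulations as follows,
as the package's own choices: full study conditions (n = 132, 917
metabolites, 100 CV iterations) for the planted-recovery and acceptance
runs, with 10 replicate cohorts for the recovery medians; 500 replicate
132 × 200 null tables for FDR calibration; 500 exhaustive-enumeration
cases and 1000 brute-force BH vectors for the oracle equivalences; 100
noisy clamp replicates for suppression error; reduced grids and 16-level
histograms throughout the simulation studies, as discussed in §6.

## 10. Known limitations

* The Steele constants used by real studies are rarely printed; if a
  cohort's fluxes were computed with different $p$, $V$ or windowing,
  absolute Ra values will differ even though suppression percentages
  are largely insensitive.
* The Mann–Whitney normal approximation (with ties) and the exact small-
  sample path can disagree near n + m ≈ 50 at the fourth decimal; the
  suite pins the exact path only where enumeration is feasible.
* The harness's AUC sd is across overlapping outer splits (§6).
* The generator's independence assumptions make BH's independence
  regime the operative one; under strong positive dependence BH remains
  valid but the calibration test's tight band would not transfer.
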