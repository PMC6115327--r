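---
title: "Evaluating temperature-dependent solubility QSPR models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating temperature-dependent solubility QSPR models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdsolqspr)
```

## The model and its assumptions

Temperature-dependent intrinsic solubility is modelled through the van't
Hoff relationship: if the standard enthalpy of solution ΔH⁰_sol of a
material is approximately constant over the temperature range of interest,

$$\log_{10} S = \frac{-\Delta H^{0}_{sol}}{\ln(10)\,R\,T} + c,$$

so log solubility is linear in $1/T$ with slope proportional to
$-\Delta H^{0}_{sol}$ ($R$ = 8.3145×10⁻³ kJ mol⁻¹ K⁻¹; all energies are
kept in kJ/mol internally, with kcal/mol converted at the boundary,
1 kcal = 4.184 kJ). `fit_vant_hoff()` is unweighted ordinary least squares
of log10 S on 1/T — no weighting scheme is assumed — and reports the line's
r² alongside the derived enthalpy so the "how well does the linear
relationship hold" question is answerable per material as a distribution
(`vant_hoff_by_material()`), without a hard-coded acceptance cut-off.

Solid-state energetics enter through
$\Delta H_{sub} = -E_{latt} - 2RT$ (evaluated at a constant 298 K unless
stated otherwise), and the fusion relations
$T_m = \Delta H_{fus}/\Delta S_{fus}$ and
$\Delta H_{fus} = \Delta H_{sub} + \Delta H_{cond}$. Jointly these imply
that lattice energy and melting point should be negatively correlated,
which motivates both the generator's correlated MP/LE columns and the
diagnostic `correlate_lattice_melting()`, whose one-tail p value is the
lower-tail probability, under the zero-correlation null, of a correlation
as negative as observed (t distribution, n − 2 degrees of freedom).

## Why two cross-validation protocols

Instances are `[material]_[temperature]` pairs, so a material measured at
several temperatures contributes several rows whose endpoints lie on one
van't Hoff line. Vanilla repeated stratified K-fold assignment (CV=v,
`make_vanilla_folds()`) treats rows as exchangeable and will place
same-material rows in corresponding training and test sets; a flexible
learner can then predict held-out rows by recognising the material rather
than by generalizing. The remove-temperature protocol (CV=rt,
`make_rt_folds()`) truncates IDs to the material key, keeps one row per
material with the arithmetic-mean endpoint, stratifies *that* table, and
lets every original row inherit its material's fold — materials can never
straddle folds (`verify_fold_plan()` asserts this exhaustively). CV=rt is a
pseudo-cross-validation: its estimate answers "how well do we predict new
materials", which is the deployment-relevant question.

Stratification for a continuous endpoint is rank-block assignment: sort by
endpoint (random tie-break), cut the ranked list into consecutive blocks of
K, deal each block's members to distinct folds at random; a final partial
block of size m is dealt to folds 1..m after shuffling. The mechanism is a
design choice — sorting rather than binning — made for simplicity and
reproducibility; fold endpoint means stay within one global SD of the
global mean for n ≥ 5K. One master seed drives everything; repetition r
uses a seed derived from it, so plans are reproducible and repetitions
independent.

## Learners and their conventions

Random forest regression (`ranger`) is built once per seed — five seeds by
default — with each tree grown on a 63.2% without-replacement sample of the
training rows; every reported statistic and importance is the arithmetic
mean across seeds. Tree count defaults to 500; tree-level hyperparameters
stay at library defaults. Multiple linear regression is ordinary least
squares; rank-deficient designs (collinear descriptors, or more descriptors
than rows, which the experiment matrix legitimately produces) are solved by
the SVD pseudo-inverse — the minimum-norm least-squares solution — and
flagged rather than refused, since heavily over-parameterised linear fits
are themselves a finding (extreme overfitting), not an error.

Descriptors are range-scaled to [0, 1] inside each fold using training
ranges only; test values are not clipped, and a descriptor constant on the
training rows maps to 0 everywhere so column counts stay comparable across
folds (the alternative, dropping the column, would make importance vectors
unalignable). Missing descriptor values are rejected at load rather than
imputed.

Importance is extracted from a final model built on the entire dataset:
absolute slope magnitudes for MLR (meaningful because descriptors are
scaled), and permutation importance for random forests — the mean increase
in MSE over 10 permutations of a column, averaged over the five seed
models. Computing it on the full data matches the final-model convention;
held-out-fold importance would estimate a different (also legitimate)
quantity.

## The statistics

Validation metrics are RMSE and R² = 1 − MSE/Var, with Var the *population*
variance of the test-fold endpoints; R² can be negative, and with a
zero-variance test fold it is undefined (reported `NA`, RMSE still valid).
Ranking enforces the comparison rules: mean RMSE for models sharing a
dataset and folds, mean R² across datasets or fold schemes (RMSE is not
comparable when the endpoint range differs) — `rank_models()` raises an
error when asked to violate this.

The paired significance analysis compares results differing in exactly one
factor across five key scenarios (lattice energy in/out, melting point
in/out, crystal- vs conformer-derived 3D descriptors, feature selection
on/off, CV=v vs CV=rt), pairing RMSE components for the first four and R²
for the protocol scenario, whose folds necessarily differ. The test is a
two-sided paired t test on per-(repetition, fold, seed) differences with
Holm adjustment within each scenario family and a 0.05 threshold on the
adjusted p values; both choices are explicit and configurable. The p values
are *approximate*: cross-validation components are dependent, which a t
test ignores, so significance tends to be overstated — the output carries
this caveat, and the calibration driver verifies that under an independent
null the raw type-I error is nominal and the Holm family-wise rate stays
below 5%.

## What the generator emulates — and what it does not

`simulate_qspr_dataset()` draws, per material: ΔH⁰_sol ~ N(20, 15²) kJ/mol
and intercept ~ N(−4, 2²) (realistic spreads for diverse organics);
temperatures on a jittered uniform grid over 278–323 K (the span of
practical aqueous measurements; jitter ±2 K so both interpolation and
extrapolation occur); endpoint noise 0.1 log10 units by default (typical
inter-laboratory solubility disagreement; set to 0.05 in the recovery
study). Descriptors are standard normal; a unit-variance signal built from
the informative ones (linear, plus an optional standardized quadratic term
weighted by `nonlinear_weight` so that forests can outperform linear
models when the link is curved) is mixed into each material parameter with
weight `beta_scale` (default 0.8, i.e. descriptors explain ~64% of
parameter variance — materials are predictable but not trivially so).
Melting point and lattice energy are generated with a target Pearson
correlation (default −0.3, matching the weak negative correlations expected
from the fusion relations); the realized correlation converges to the
target as the number of materials grows. Benchmark-shaped configurations
(`benchmark_shape_config()`) reproduce the six study datasets' instance
counts and endpoint kinds exactly.

The generator is a statistical emulation only: descriptors have no
chemical semantics, the descriptor–endpoint link is homoscedastic
Gaussian, and there are no polymorphs, measurement-method effects, or
curated-literature error structure. Passing tests therefore demonstrate
that the *machinery* behaves as specified under the assumed data structure,
not that any particular chemical dataset will show a given R².

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: constant scaled columns map to 0;
equal-endpoint stratification reduces to a balanced random partition;
identical paired vectors give p = 1; fusion-term completion iterates to a
fixed point and reports violations beyond 10⁻⁶ kJ/mol on over-determined
inputs. Seeds: every stochastic entry point takes a seed and restores the
caller's RNG state.

The shipped studies use sizes chosen to make each effect measurable while
keeping a full run in minutes on one core: 20 replicates of 60 materials ×
5 temperatures for the protocol comparison (the leakage gap is ~0.8 R²
units, so 20 replicates is ample); 100 random draws for fold-integrity
checks; 1000 replicates for significance calibration; 300 materials for
the lattice-energy surrogate. Forests inside the replicated studies use
100–200 trees: the leakage and surrogate effects do not depend on forest
size, and the across-seed variance criterion is tested separately at 500
trees.

Two quantitative limits are worth stating because they follow from the
model, not from implementation. First, van't Hoff enthalpy recovery is
limited by the short 1/T lever arm: over 278–323 K,
$\sqrt{\sum (x - \bar x)^2} \approx 3.5\times10^{-4}$ for a 5-point grid,
so 0.05 log-unit noise propagates to an enthalpy SD of ~2.7 kJ/mol and an
expected MAE near 2 kJ/mol — sub-kJ/mol recovery from such data is not
achievable at this noise level, and the recovery test asserts agreement
with this propagated-error prediction. Second, random forests attenuate
high-dimensional linear signals even without noise (R² ≈ 0.78 with 8
informative descriptors at n = 300), so the surrogate study that asks
"does the pipeline recover a descriptor-determined lattice energy" uses a
low-dimensional noiseless link (2 informative descriptors), isolating the
pipeline from that separate, well-known forest behaviour.

## Known limitations

ΔH⁰_sol is assumed temperature-independent (no curvature in the van't Hoff
plot). The feature-selection stage is a pluggable interface with a simple
correlation filter as default, not a reimplementation of any particular
published algorithm. The paired t test ignores fold dependence by design,
mirroring the approximate framing it is labelled with. The experiment
matrix supports, but does not require, user-supplied real QSPR tables in
the documented CSV + sidecar-YAML format; all shipped results are
computed on synthetic data.
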