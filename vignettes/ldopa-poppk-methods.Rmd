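---
title: "Population pharmacokinetics of L-DOPA brain disposition in the unilateral rotenone rat: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of L-DOPA brain disposition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldopapk)
```

## The scientific problem

In the unilateral rotenone rat model of Parkinson's disease, one cerebral
hemisphere carries a dopaminergic lesion while the other serves as a
within-animal control. After an intravenous L-DOPA infusion, serial plasma
samples and striatal microdialysate from both hemispheres (L-DOPA and the
dopamine metabolites DOPAC and HVA) let one ask whether the disease changes
(i) blood-brain-barrier (BBB) transport of L-DOPA and (ii) the intra-brain
conversion and elimination of its metabolites. `ldopapk` implements the full
analysis pipeline for this design: the structural model, a nonlinear
mixed-effects estimation engine, the hemisphere-symmetry hypothesis grid,
microdialysis recovery calibration, TH-staining responder classification,
and a synthetic-trial generator so that every stage is testable without
animal data.

## Structural model

Nine compartments: (1) central plasma, (2)-(3) peripheral plasma, (4)/(5)
brain extracellular fluid (ECF) L-DOPA in the control/diseased hemisphere,
(6)/(8) DOPAC and (7)/(9) HVA in the two hemispheres. Between dose events the
system is linear and time-invariant,

$$ \dot x = A\,x + b + \mathrm{dose}(t), $$

with central elimination $Cl/V_1$, inter-compartmental clearances
$Q_2, Q_3$ (plasma) and $Q_4, Q_5$ (plasma to brain ECF), brain-ECF
elimination rate constants $k_{40}, k_{50}$, a zero-order endogenous L-DOPA
formation input $K_{in}$ into each ECF compartment, metabolite formation
rate constants $k_{46}, k_{58}$ (DOPAC) and $k_{47}, k_{59}$ (HVA), and
metabolite elimination $k_{60}, k_{80}, k_{70}, k_{90}$. Saturable (LAT-1
type) BBB transport is deliberately out of scope: over the three-dose range
no transport asymmetry or concentration dependence is identifiable, so the
symmetric linear exchange `Q4`/`Q5` is the model of record.

Three modelling conventions deserve comment:

* **$K_{in}$ as a zero-order input.** The parameter is conventionally
  printed with unit 1/min, but a first-order constant needs a source
  amount the model does not contain; only a zero-order interpretation
  (ng/min into each ECF compartment) yields a finite nonzero baseline in a
  linear system. The printed unit label is kept as metadata
  (`param_units()`).
* **Concentration-scale metabolite compartments.** No metabolite volumes
  are estimable from dialysate data, so compartments 6-9 are modelled
  directly in concentration units with first-order formation from the
  parent ECF *concentration* ($k_{46} C_4$ etc.) and first-order loss. This
  matches additive-error concentration fits and avoids unidentifiable
  volumes. Conversion of L-DOPA "via dopamine" is collapsed into the
  formation constants; dopamine itself is below the quantification limit
  everywhere and is not a state variable.
* **Probe recovery scale.** L-DOPA dialysate is corrected to the ECF scale
  by the retrodialysis recovery; DOPAC/HVA are modelled on the dialysate
  concentration scale directly (their rate constants absorb the probe
  recovery), mirroring how the original analysis corrected only L-DOPA.

The solver (`solve_trajectory()`) is a piecewise-exact linear solver:
per parameter set the rate matrix is eigendecomposed once and states plus
*exact* window integrals (for interval-collected dialysate) are evaluated
per breakpoint segment; a scaled augmented matrix-exponential path is the
fallback for numerically defective systems. A generic stiff integrator
(deSolve) serves as an independent cross-check in the tests, never as the
implementation.

`steady_state()` solves $0 = Ax + b$ for the endogenous-input-only system.
With the reference values the ECF L-DOPA baseline is within about 1% of the
plasma-sink approximation $K_{in}/(k_{40} V_4)$; the implied plasma baseline
(~0.4 ng/mL) is far below the 1 ng/mL plasma LLQ, consistent with
endogenous plasma L-DOPA being unmeasurable.

## Reference parameter values

`reference_parameters()` carries the population estimates for this study
design — the three-compartment plasma disposition (Cl 30 mL/min, V1 98 mL,
V2 157 mL, V3 599 mL, Q2 22, Q3 11 mL/min), the symmetric brain side
(V4 13300 mL, Q4 22 mL/min, k40 0.175 1/min, K_in 5.8), and the four
metabolite blocks, e.g. control DOPAC k46 4.4e-5, k40 0.53, k60 0.0053
(1/min) with additive residual SD 0.0020. V4 is an *apparent* volume; its
physiologically enormous value is reported as estimated and not
reinterpreted. Printed residual-error magnitudes are treated as standard
deviations (the plasma proportional error 0.087 corresponds to an 8.7%
CV), and `omega^2` entries as variances of log-scale random effects.
Where the published record is internally inconsistent (an HVA control
elimination printed once as 0.044 1/min and once as 0.0044), the tabulated
value (0.0044) is authoritative.

## Synthetic-trial generator

`study_design()` defaults encode the study conditions: dose groups 10/25/50
mg/kg infused over 20 min (dose = level x body weight, weight ~ N(288 g,
13 g); the bicarbonate co-infusion is kinetically ignored); the printed
plasma sampling schedule (-5 to 360 min); dialysate fractions of 10 min to
120 min, 20 min to 180 min, 30 min to 360 min; a 6-fraction retrodialysis
phase (perfusate 10/100/200 ng/mL by dose group) followed by washout; and
the printed per-stream animal counts (13 plasma profiles, 12 control-ECF,
7 diseased-responder ECF, 12/8 control/diseased metabolite hemispheres,
17 rats). Because the original study did not state which fractions defined
"baseline", the generator places three 10-min pre-dose baseline fractions
in the half hour before the infusion, after the washout tail is discarded.

Inter-individual variability is exponential, $P_i = \theta e^{\eta_i}$,
$\eta_i \sim N(0, \omega^2)$, drawn independently per parameter and
subject. The diseased-hemisphere parameters (V5, Q5, k50) share the
control-side random effect when they carry no $\omega^2$ of their own —
there is one brain per animal, and without this the symmetric and
unconstrained fits would disagree at identical parameter values. Residual
error is proportional for plasma and ECF L-DOPA and additive for
DOPAC/HVA; negative additive draws are truncated at zero and flagged
rather than resampled (resampling would bias the error distribution).
Plasma values below the 1 ng/mL LLQ are flagged and excluded from fitting
(M1 method; no censoring likelihood is attempted because none was specified
for the original analysis). Dialysate observations are exact time-averages
of the model concentration over each collection window — a 2 uL/min probe
collects continuously — with a midpoint-sampling mode available as a
sensitivity switch. A per-animal true probe recovery is drawn once
(N(0.30, 0.06) truncated to (0, 1]) and shared across both probes, since
recovery was found not to depend on disease condition.

Randomness policy: one root seed; per-subject child seeds are derived from
it and recorded on each subject, so populations and trials are reproducible
bit-for-bit.

The generator emulates design, kinetics, IIV, measurement error, recovery
and responder status; it does not emulate analytical chemistry, probe
failure beyond an exclusion flag, circadian or food effects, or any
model-misspecification that real data would carry. Passing round-trip tests
therefore demonstrates correctness of the machinery, not validity of the
structural model for real animals.

For the baseline-contrast stage, metabolite baselines are also generated
directly from an empirical distribution (`draw_baseline_population()`):
per-subject means are lognormal with moment-matched group mean and SEM
(concentrations are positive; a normal draw would need ad hoc truncation
that biases the mean), with 5% multiplicative fraction noise.

## Estimation engine

`laplace_objective()` is minus twice the marginal log-likelihood with a
Laplace approximation per subject: the conditional mode $\hat\eta_i$ is
found by a damped Newton search with Gauss-Newton curvature
($J^T W J + \Omega^{-1}$, with finite-difference sensitivities $J$ of the
predictions with respect to $\eta$), and the same curvature supplies the
log-determinant term. The residual variance is evaluated at the
conditional predictions (the "interaction" term): $\sigma^2 f^2$
proportional, $\sigma^2$ additive. This is the FOCE-with-interaction
family of approximations; it is not an instruction-for-instruction
re-implementation of any specific software, and absolute objective values
include the $2\pi$ constants, so they differ from NONMEM's by a
data-dependent constant. Only *differences* between nested models are
comparable, which is all the likelihood-ratio machinery uses. Acceptance of
the engine rests on parameter recovery from simulated trials, not on
objective-value equality with other software.

`fit_popmodel()` minimises the objective over log-transformed free
parameters (typical values, $\omega^2$, residual SDs) with `nlminb`
(outer relative tolerance 1e-5, inner Newton tolerance 1e-6). The eta
search is warm-started across outer iterations but validated against a
cold start at $\eta = 0$ whenever the warm path fails, so the objective
does not depend on optimisation history. Standard errors come from the
inverse Hessian at the optimum (finite differences on the log scale, delta
method back to natural scale), CIs as estimate +/- 1.96 SE and CV% as
100 SE/estimate — matching the reporting convention of the published
tables, including the possibility of negative lower CI limits for
variance-like parameters. A non-positive-definite Hessian leaves the SEs
missing with a warning, the analogue of a terminated covariance step.
Multi-start (initial values scaled by 2 and 1/2) is available through
`control$n_starts`; the default is a single start because from
reference-scale initial values the objective is well behaved at this
study's data sizes, and the model-selection grid already restarts the
unconstrained reference fit from the best constrained cell, which is where
multi-start value concentrates in practice.

The inner search is performed in C++ (RcppArmadillo), as is the trajectory
solver; this is what makes the 8-cell selection grid and the seed-replicated
recovery studies tractable on one CPU.

### Sequential metabolite analysis

`sequential_metabolite_fit()` fixes each rat's parent L-DOPA trajectory at
its empirical Bayes (post hoc) parameters from the parent fit and estimates
the metabolite block — formation, the hemisphere's own brain-ECF L-DOPA
elimination ($k_{40}$ or $k_{50}$, re-estimated by the sub-model as in the
published sequential workflow), metabolite elimination, their $\omega^2$
and the additive residual SD. DOPAC and HVA and the two hemispheres are
fitted independently. The parent model of record keeps a single shared
$k_{40} (= k_{50}) = 0.175$ 1/min from the accepted symmetric model, while
the metabolite sub-models re-estimate their own values (0.53/0.36 for
DOPAC, 0.19/0.14 for HVA) — reproducing the structure in which both sets
of published estimates coexist.

### Hypothesis grid and model selection

`symmetry_grid()` fits all 8 combinations of the hemisphere-symmetry
constraints {Q5=Q4, V5=V4, k50=k40} and selects the most parsimonious model
not significantly worse than the unconstrained one. The criterion is the
likelihood-ratio test at p = 0.001: a 10.8-point rise in the objective for
one constrained parameter, $\chi^2_{0.999}(df)$ for multi-constraint
cells. Constrained cells are warm-started from the unconstrained
estimates, per-cell failures are recorded in place (the analogue of a
minimisation-terminated row) and the grid continues; finally the
unconstrained reference is restarted from the best cell so the LRT
reference is not a stalled optimum. On symmetric truth the fully
constrained model is selected; on a 5-fold $k_{50}$ asymmetry every
k50=k40 cell is rejected.

## Microdialysis calibration and baseline statistics

Retrodialysis: per-fraction relative loss $(C_{in}-C_{out})/C_{in}$;
`estimate_recovery()` returns mean and SD across fractions, flagging and
excluding apparent gains. A single pooled across-animal mean recovery is
applied to all L-DOPA dialysate rows by default (`correct_to_ecf()`),
as in the original analysis; per-subject correction is available but off by
default. The antioxidant dilution of dialysate vials is treated as
corrected upstream.

`baseline_summary()` takes each subject's baseline as the mean of its
pre-dose fractions, summarises groups (analyte x hemisphere) as mean +/-
SEM across animals (the SEM convention is across animals, not fractions),
and compares hemispheres with Welch's unequal-variance t-test
(Welch-Satterthwaite df). Degenerate cases are handled explicitly:
single-subject groups report summaries with the test omitted; two constant
equal groups report p = 1.

## TH staining and responder status

Striatal mean grey values are corrected by subtracting the cortical MGV
(corpus callosum selectable), TH% is the corrected treated/untreated ratio
x 100 computed on the dorsal striatum (CPu) by default — the dialysis
target region; which region drove the published classification is not
stated — and a rat is a responder iff TH% is strictly below 40%. The
boundary value 40.0 is a non-responder by the strict inequality. Slide
background MGV is recorded but does not enter the stated correction, so it
is not applied. In the pipeline, non-responders are excluded from
diseased-hemisphere fits while their control hemispheres are retained,
reproducing the published stream sizes.

## Numerical choices and degenerate inputs

* Eigendecomposition is accepted only if it reconstructs the rate matrix to
  1e-9 relative (Frobenius); otherwise the augmented matrix exponential
  (input column scaled to unit norm) is used.
* Residual variances are floored at 1e-24 to keep the objective finite at
  zero predictions; inner-search failures contribute a large sentinel and
  flag the subject rather than aborting the fit.
* Log-scale optimisation bounds (+/-18 on the log of each parameter) act as
  boundary detectors: a formation constant whose truth is zero runs to the
  bound and is flagged, not silently truncated.
* LRT deltas slightly below zero (within optimizer noise) warn about
  nesting/convergence instead of being clipped silently.

## Problem sizes used in the tests

The test-suite fits use the printed design or modest inflations of it
(8 rats per dose group for the recovery checks, 10 seeds; 6 two-hemisphere
rats with a thinned dialysate schedule for the 2 x 20-seed selection-grid
study), sizes chosen so the whole suite exercises every stage at meaningful
power while staying pleasant to run. The acceptance script uses the printed
stream counts exactly (13/12/7 hemispheres, 17 animals) with 10-20 seeds
per quantity.

## Known limitations

* The engine is a Laplace/FOCE-I-family approximation with Gauss-Newton
  curvature; it is asymptotically equivalent to, but not bit-identical
  with, other implementations. Absolute objective values are not
  comparable across software.
* Random effects are assumed uncorrelated (diagonal $\Omega$); whether the
  original analysis allowed correlations is unstated.
* Below-LOQ data are excluded (M1), not integrated into the likelihood.
* TH% is generated directly (responders uniform below 40%, non-responders
  above 90%, matching the published bimodal outcome); no image-analysis
  stage is modelled, and TH% is not used as a covariate — its observed
  range is too bimodal to support covariate modelling.
* The baseline generator and the kinetic model are separate routes to
  metabolite baselines: the kinetic model's endogenous route (via
  $K_{in}$ and the formation constants) produces far smaller baselines
  than measured dialysate, because the measured metabolite baselines are
  dominated by endogenous dopamine turnover that the model deliberately
  does not contain. Baseline contrasts are therefore an empirical stage,
  not a model prediction.
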