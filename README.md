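# ldopapk

Population pharmacokinetics of intravenous L-DOPA blood-brain-barrier (BBB)
transport and intra-brain metabolism in the unilateral rat rotenone model of
Parkinson's disease.

The package is for pharmacometricians and neuropharmacologists who want to
analyse (or simulate) the paired-hemisphere microdialysis design: rats with a
unilateral rotenone lesion receive a 20-min IV L-DOPA infusion (10, 25 or
50 mg/kg); serial plasma samples and interval-collected striatal dialysate
from the control and diseased hemispheres (L-DOPA, DOPAC, HVA) are analysed
together, and tyrosine-hydroxylase (TH) immunostaining classifies each rat as
a rotenone responder (TH% < 40) or not.

## The model

A nine-compartment parent-metabolite model, linear between dose events:

- compartments 1-3: L-DOPA plasma disposition (`Cl`, `V1`-`V3`, `Q2`, `Q3`);
- compartments 4/5: brain-ECF L-DOPA in the control/diseased hemisphere
  (`V4`/`V5`, `Q4`/`Q5`, `k40`/`k50`), each receiving a zero-order endogenous
  formation input `K_in`;
- compartments 6/8 (DOPAC) and 7/9 (HVA): dialysate-scale metabolite
  kinetics, first-order formation from the parent ECF concentration
  (`k46`, `k58`, `k47`, `k59`) and first-order elimination
  (`k60`, `k80`, `k70`, `k90`).

Inter-individual variability is exponential, `P_i = theta * exp(eta_i)`,
`eta ~ N(0, omega^2)`; residual error is proportional for L-DOPA
(plasma and ECF) and additive for DOPAC/HVA. Estimation is approximate
maximum likelihood with a Laplace (FOCE-with-interaction style) objective,
implemented in C++ for speed; model selection uses the likelihood-ratio test
(10.8-point objective drop for one parameter, p = 0.001). The
hemisphere-symmetry question — does the lesion change BBB transport? — is an
8-cell grid over the constraints `{Q5=Q4, V5=V4, k50=k40}`. Microdialysis
probe recovery is calibrated by retrodialysis (relative loss of L-DOPA from
the perfusate) and applied as a pooled across-animal correction.

See the methods vignette (`vignettes/ldopa-poppk-methods.Rmd`) for the full
model account, assumptions and numerical choices.

## Worked example

Simulate a full synthetic trial at the reference population values, correct
the dialysate, and fit the parent plasma + brain-ECF model:

```r
library(ldopapk)

sim <- simulate_trial(study_design(), seed = 1,
                      params = list(parent = reference_parameters("parent")),
                      streams = c("plasma", "ecf_control", "ecf_diseased",
                                  "retro"))

# pooled in vivo recovery from the retrodialysis fractions
retro <- subset(as.data.frame(sim$data), DVID == "retro_LDOPA")
rec <- mean(sapply(split(retro, retro$ID),
                   function(x) estimate_recovery(x$DV, x$PERF[1])$mean))
#> rec = 0.292  (true population mean recovery: 0.30)

dat <- correct_to_ecf(sim$data, rec)
fit <- fit_popmodel(dat, parent_model_spec(), reference_parameters("parent"),
                    control = list(se = FALSE))
round(fit$params$theta[c("Cl", "V1", "V4", "Q4", "k40", "K_in")], 3)
#>     Cl      V1        V4     Q4   k40  K_in
#> 29.446 101.840 13300.201 22.127 0.174 5.784
```

The recovered typical values sit on the generating values: total plasma
clearance 29.4 mL/min (truth 30), apparent brain-ECF volume 13300 mL,
plasma-to-ECF clearance 22.1 mL/min, ECF elimination 0.174 1/min and
endogenous formation 5.78 ng/min (printed label 1/min). The symmetry grid on
the same data selects the fully symmetric model (`symmetry_grid(dat)`), i.e.
no hemisphere difference in BBB transport, and `sequential_metabolite_fit()`
then estimates the DOPAC/HVA blocks from the parent's post hoc parameters.
`run_pipeline()` drives all stages (recovery, TH classification, parent fit,
grid, metabolite fits, baseline Welch contrasts) from a single config.

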