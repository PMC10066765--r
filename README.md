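# mrnapkpd

Translational population PK/PD modelling for lipid-nanoparticle (LNP)
delivered mRNA enzyme replacement therapy, built around the motivating case
of dual PCCA/PCCB mRNA therapy for propionic acidemia: restoring
propionyl-CoA carboxylase (PCC) in the liver and suppressing the disease
biomarkers 2-methyl citrate (2-MC), 3-hydroxypropionate (3-HP) and the
propionyl/acetyl carnitine ratio (C3/C2).

The package is aimed at pharmacometricians who need a fully scripted,
testable version of this class of analysis: structural ODE models, synthetic
study generation, nonlinear mixed-effects estimation, goodness-of-fit
diagnostics, and allometric extrapolation of the dose–response to humans.

## The model

**mRNA disposition.** A linear three-compartment system: an IV dose
compartment (1) drains into tissue (2), which exchanges with the plasma
observation compartment (3); elimination occurs from tissue. Compartments 1
and 3 share the volume *V*; tissue has volume *V₂*. With first-order rates
*k₁₂ = CL₁₂/V*, *k₂₃ = CL₂₃/V₂*, *k₃₂ = CL₃₂/V*, *k₂₀ = CL₂₀/V₂*:

    da1/dt = −k12·a1 + u(t)
    da2/dt =  k12·a1 + k32·a3 − (k23 + k20)·a2
    da3/dt =  k23·a2 − k32·a3

The observed plasma concentration is *a₃/V*; this topology produces the
delayed plasma peak seen after IV administration of mRNA-LNPs, reflecting
distribution into and redistribution out of tissue. Clearances scale allometrically with body
weight: CL₁₂ and CL₃₂ share the exponent α (Clα), CL₂₃ and CL₂₀ share β
(Clβ), volumes scale with exponent 1.

**Protein expression.** An effect compartment equilibrates with the observed
concentration at rate *k*ₑ₀ and drives hepatic protein synthesis linearly
(gain *k*_syn); the protein distributes between two pools (rate *k*_q) with
first-order degradation *k*_deg — a two-compartment indirect-response model
whose slow eigenvalue sets the 7-day terminal protein half-life.

**Biomarkers.** A direct sigmoidal maximum-inhibition (Imax) model on total
hepatic protein *p*:

    level(p) = E0 + base · (1 − Imax · p^γ / (IC50^γ + p^γ))

*E₀* is the pool not suppressible by treatment; *base/(E₀+base)* is the
amenable fraction.

**Population model and estimation.** A log-normal random effect on CL₃₂ and
proportional residual error per observable. Subject marginal likelihoods are
computed by adaptive Gauss–Hermite quadrature (or Laplace) around the
empirical-Bayes mode, with the M3 censored-likelihood term for observations
below the limit of quantification; `-2·logLik` is minimised on
log-parameters with deterministic multi-start, and %RSE comes from the
inverse numerical Hessian. Estimation runs through a compiled
exact propagator for the (linear) state equations.

## Worked example

```r
library(mrnapkpd)
truth <- default_truth()           # published typical values + calibrated PD

protein_terminal_halflife(truth$pd) / 24
#> [1] 7                            # days

sapply(truth$biomarkers, amenable_fraction)
#>   2mc   3hp  c3c2
#> 0.637 0.998 0.869                # fraction of baseline suppressible

# one PCC-deficient mouse, 1 mg/kg IV bolus
sim <- simulate_pkpd(truth$pk, truth$pd, wt = 0.025,
                     doses = dose_event(0, 0.025),
                     times = c(1, 4, 24, 168, 504))
round(sim, 3)
#>   time      conc       ce  p_total
#> 1    1 11877.129  890.714   20.795
#> 2    4  9080.813 3358.391  392.792
#> 3   24  1374.375 3055.128 3946.786
#> 4  168     0.002    0.019  931.240
#> 5  504     0.000    0.000  218.804
```

`conc` is the plasma mRNA concentration (ng/mL): it peaks early and is gone
within days, while liver PCC protein (`p_total`, µg/g) peaks around 1–2 days
and decays with a 7-day terminal half-life. Steady-state dose–response under
three-weekly dosing:

```r
dr <- dose_response_summary(c(0.5, 2), truth$pk, truth$pd, truth$biomarkers,
                            truth$pop, wt = 0.025, n_subjects = 100, seed = 1)
subset(dr, output == "2mc")
#>   dose_per_kg output trough_protein suppression_pct   lo   hi pi_width
#> 1         0.5    2mc            119            54.1 47.9 59.2    11.29
#> 4         2.0    2mc            475            60.9 58.8 62.5     3.66
```

Median 2-MC suppression at the 2 mg/kg trough is 60.9% — about 96% of the
theoretical ceiling 63.7% × 0.999 — and the 90% prediction interval narrows
as dose increases.

The full synthetic analysis (generate the 55-subject mouse/rat/monkey PK
study, fit the interspecies model; generate the mouse PD studies, run the
sequential protein and biomarker fits) is wrapped in
`interspecies_pk_fit(seed)` and `mouse_pd_sequential_fit(seed, pk, omega)`.

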