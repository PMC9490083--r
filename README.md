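# cefoneo

Developmental population pharmacokinetics and dose evaluation of
cefotaxime in neonates with early-onset sepsis (EOS).

Cefotaxime is a standard empirical antibiotic for EOS, a systemic
infection arising in the first 72 h of life. Its clearance in newborns is
driven by body size and rapid postnatal renal maturation, and
pharmacokinetic sampling in this population is opportunistic — a couple of
scavenged samples per neonate — so dosing questions must be answered with
a nonlinear mixed-effects (population) model. `cefoneo` implements that
analysis as a reusable, tested R package:

* **Structural model** — one-compartment disposition with first-order
  elimination and intravenous infusion input, closed form with
  superposition and analytic steady state:

  `V = θ₁`,  `CL = θ₂ · (CW/2310)^θ₃ · (PNA/1)^θ₄`

  with current weight `CW` (g), postnatal age `PNA` (days), exponential
  inter-individual variability `Pᵢ = P·exp(η)`, `η ~ N(0, ω²)`, and
  proportional residual error `y = f·(1+ε)`. The published final
  estimates ship as a preset (`cefotaximeParams()`): θ₁ = 0.873 L,
  θ₂ = 0.0803 L/h, θ₃ = 1.68, θ₄ = 0.444, IIV 20.0 % (CL) / 21.1 % (V),
  residual 14.2 %.
* **Estimation** — first-order conditional estimation with interaction
  (FOCE-I): per-subject conditional η modes by damped Newton with
  analytic model derivatives (compiled, Rcpp/RcppArmadillo), objective by
  linearization about the mode with interaction, outer quasi-Newton on
  log-transformed parameters, standard errors from the inverse Hessian.
* **Covariate analysis** — forward inclusion (ΔOFV > 3.84, p < 0.05) and
  backward elimination (ΔOFV > 6.635, p < 0.01) over BW, GA, CW, PNA and
  PMA as power functions, with a fully replayable decision trace, plus an
  estimated-vs-fixed (0.75) allometry comparison.
* **Model evaluation** — conditional weighted residuals, non-parametric
  bootstrap, normalized prediction distribution errors (NPDE) and a
  prediction-corrected visual predictive check (pcVPC), all seeded and
  deterministic.
* **Dose evaluation** — steady-state free-concentration target
  (70 % fT>MIC, MIC 2 mg/L, free fraction 0.6) and AUC₀₋₂₄ = daily
  dose / CL, with Monte Carlo probability of target attainment over
  virtual cohorts.
* **Synthetic cohort** — a generator calibrated to the study's covariate
  summaries (GA 30.0–41.1 wk, PNA 1–3 d, weight 1220–3970 g, median
  2310 g) and its sparse design (101 samples over 51 neonates), so the
  complete pipeline runs without patient data.

## Worked example

Simulate the study-like design under the reference model, refit it, and
evaluate the study regimen:

```r
library(cefoneo)

p <- cefotaximeParams()
individualClearance(p, list(CW = 2310, PNA = 1))  # 0.0803 L/h
individualVolume(p)                               # 0.873 L

cohort <- sampleCohort(cohortSpec(nSubjects = 51), seed = 1)
ds <- simulateDataset(cohort, p, designSpec(totalObservations = 101), seed = 2)
ds
#> PKDataset: 51 subjects, 101 observations, 357 dose events
#>   current weight 1544.35-3798.51 g (median 2561.04)

fit <- fitModel(ds)
fit
#> FOCE-I fit: 51 subjects, 101 observations, OFV 886.062 (converged)
#>   theta1                     0.9072  (RSE 5.17%)
#>   theta2                    0.08262  (RSE 6.29%)
#>   beta.CL.CW                  1.629  (RSE 10.7%)
#>   beta.CL.PNA                0.4424  (RSE 21.2%)
#>   IIV Cl (%CV)                25.87  (RSE 12.6%)
#>   IIV V (%CV)                  13.8  (RSE 51.7%)
#>   prop. residual (%CV)        15.79  (RSE 12.3%)

pta <- populationPta(p, sampleCohort(1000, seed = 5), regimenSpec(),
                     targetSpec(), seed = 6)
pta
#> PTA: 99.5% of 1000 subjects attained the target
#>   AUC(0-24) at steady state: 752-5850 mg*h/L (median 2423)
```

The refit recovers the generating fixed effects (compare θ₂ = 0.0803,
θ₃ = 1.68, θ₄ = 0.444) from only two samples per neonate, and essentially
the whole virtual cohort attains the 70 % fT>MIC target on
50 mg/kg BID — free concentrations at 70 % of the interval sit far above
the 2 mg/L breakpoint (56 mg/L for the typical neonate).

`runFullAnalysis(runConfig(outDir = "run"))` chains
simulate → fit → covariate search → bootstrap/NPDE/pcVPC → PTA and writes
the parameter table, diagnostics CSVs and figures; the same pipeline is
scriptable from a shell via `inst/exec/cefoneo`
(subcommands `simulate`, `fit`, `covsearch`, `bootstrap`, `npde`, `vpc`,
`pta`, `full`).

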