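---
title: "Methods: developmental population pharmacokinetics of cefotaxime in neonates"
author: "cefoneo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: developmental population pharmacokinetics of cefotaxime in neonates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cefoneo)
```

## The problem

Cefotaxime is a third-generation cephalosporin widely used against
early-onset neonatal sepsis, a systemic infection with onset in the first
72 hours of life. Its clearance in newborns depends strongly on body size
and on postnatal renal maturation, and plasma can only be sampled
opportunistically (scavenged from routine draws, at most about two study
samples per neonate), so dose evaluation has to go through a population
(nonlinear mixed-effects) model rather than per-patient curve fitting.
This package implements that analysis end to end: structural model,
FOCE-I estimation, stepwise covariate selection, bootstrap / NPDE / pcVPC
model evaluation, and steady-state evaluation of the 50 mg/kg twice-daily
regimen against a 70% fT>MIC target. A synthetic-cohort generator
reproduces the covariate structure and sparse sampling design of a
51-neonate study so the whole pipeline runs, and is tested, without any
patient data.

## Structural and statistical model

One-compartment disposition with first-order elimination and zero-order
(infusion) input. For an infusion of rate $R$ starting at $t_0$ with
duration $D$, the contribution to the plasma concentration is

$$C(t) = \frac{R}{CL}\left(1 - e^{-k_e (t - t_0)}\right), \qquad
t_0 < t \le t_0 + D,$$

decaying as $C(t_0+D)\,e^{-k_e (t - t_0 - D)}$ afterwards, with
$k_e = CL/V$; doses superpose. Steady state under a $\tau$-periodic
regimen uses the closed-form accumulation factor
$1/(1 - e^{-k_e \tau})$ rather than simulating doses to convergence (a
superposition cross-check at dose 15 is in the test suite).

Covariates enter as multiplicative power functions. The final model is

$$V = \theta_1, \qquad
CL = \theta_2 \left(\frac{CW}{2310}\right)^{\theta_3}
     \left(\frac{PNA}{1}\right)^{\theta_4},$$

with current weight $CW$ in grams and postnatal age $PNA$ in days. The
reference points 2310 g and 1 day are the study medians and are fixed
constants of the shipped preset (`cefotaximeParams()`), not recomputed
from loaded data, so the parameter set is portable. Volume carries no
covariate in the final model. Inter-individual variability is exponential,
$P_i = P\,e^{\eta_i}$ with $\eta \sim N(0, \omega^2)$ and a diagonal
covariance (no CL-V correlation is estimated); residual error is
proportional, $y = f\,(1 + \varepsilon)$,
$\varepsilon \sim N(0, \sigma^2)$. The preset values are
$\theta_1 = 0.873$ L, $\theta_2 = 0.0803$ L/h, $\theta_3 = 1.68$,
$\theta_4 = 0.444$, IIV 20.0% (CL) and 21.1% (V), residual 14.2%.

## Estimation: FOCE with interaction

The marginal likelihood of each subject's sparse observation vector has no
closed form. The package uses first-order conditional estimation with
interaction: for each subject, the conditional mode
$\hat\eta$ of $(\eta_{CL}, \eta_V)$ is located by a damped
Gauss-Newton/exact-Newton hybrid (analytic first derivatives of the
infusion model with respect to $\eta$; the exact Hessian, from central
differences of that gradient, takes over near the mode for quadratic
terminal convergence at gradient norm $10^{-8}$). With one or two
observations per subject the penalized surface can be bimodal, so the
iteration is restarted from a fixed set of offsets ($\pm 1.5$ prior
standard deviations per component) and the lowest mode kept; taking the
pointwise minimum keeps the outer objective continuous across
mode-exchange boundaries, which single-start conditional estimation
violates (we observed objective cliffs of several units that stall the
outer optimizer). The subject's objective contribution is the
$-2\log$-likelihood of the model linearized about $\hat\eta$, with the
residual variance evaluated at the conditional prediction (the
"interaction"):

$$-2\,\ell_i \approx \log\det V_i + r_i^\top V_i^{-1} r_i + n_i \log 2\pi,
\qquad
V_i = G_i\,\Omega\,G_i^\top + \mathrm{diag}(\sigma^2 f_i(\hat\eta)^2),$$

with $G_i = \partial f_i/\partial\eta |_{\hat\eta}$ and
$r_i = y_i - f_i(\hat\eta) + G_i \hat\eta$. The $2\pi$ constants are kept
so the objective is comparable to an exact marginal likelihood; the test
suite checks agreement with a 2-D adaptive Gauss-Hermite quadrature oracle
within 2 objective units on a 5-subject toy, tightening to 0.05 in the
small-variance limit where the linearization becomes exact.

The outer problem maximizes over $(\theta, \omega^2, \sigma^2)$ with
positivity enforced by log transformation (covariate exponents are
unconstrained), using a quasi-Newton minimizer. The inner Newton always
restarts from $\eta = 0$, which makes the outer objective a smooth, pure
function of the population parameters — important because the outer
optimizer differentiates it numerically. Standard errors come from the
inverse numerical Hessian of the objective
($\mathrm{cov} = 2 H^{-1}$), with relative standard errors reported as
$100\,SE/\widehat{|\cdot|}$; variance components are reported as %CV
($100\sqrt{\omega^2}$) with the delta-method factor of one half on their
relative error. The per-subject likelihood machinery is compiled
(Rcpp/RcppArmadillo): the bootstrap and the stepwise search need hundreds
of complete fits, and a single fit of the 51-subject design takes about a
second.

**Initialization.** With at most two samples per neonate, per-subject
(two-stage) regression is under-identified, so starting values for the
fixed effects come from a naive-pooled ($\eta = 0$) least-squares fit on
the log scale, with 30% starting variability and 20% starting residual
error. Estimation itself is deterministic; every stochastic routine in the
package takes an explicit seed.

**Degenerate inputs.** A subject with no observations contributes zero to
the objective and gets full empirical-Bayes shrinkage $(\hat\eta = 0)$;
fitting requires at least one observation per subject. A fit to exactly
noise-free data is degenerate under a proportional-error maximum
likelihood (the log-variance runs to $-\infty$), so the noise-free checks
in the test suite hold the variances fixed or use small-but-nonzero
generating noise.

## Covariate search

Candidates are birth weight, gestational age, current weight, postnatal
age and postmenstrual age, each as a power function normalized to its
dataset median; collinear candidates are all offered and the
likelihood-ratio test decides. Forward inclusion adds, one candidate per
fit, the largest objective-function drop exceeding
$\chi^2_{1,0.05} = 3.84$; after no candidate qualifies, backward
elimination deletes any term whose removal raises the objective by at most
$\chi^2_{1,0.01} = 6.635$. Every decision is logged with its OFVs so the
trace can be replayed and audited.

Tie-breaking is the one place the package departs from a pure
largest-drop/lexicographic rule: in a cohort sampled in the first days of
life, birth weight duplicates current weight (the study reports identical
distributions for both), so the two candidates produce *exactly* tied
drops. Ties within 0.01 objective units go to the model with fewer
parameters, then to covariates describing the current clinical state over
birth-time covariates (CW, PNA, PMA, GA, BW) — mirroring the clinical
reading that concurrent weight, not birth weight, drives clearance.

`compareAllometricForms()` reports the drop for weight-on-clearance with
the exponent estimated versus fixed at 0.75, the two standard allometric
conventions.

## Model evaluation

* **CWRES** — FOCE-linearized standardized residuals,
  $L^{-1}(y - f(\hat\eta) + G\hat\eta)$ with $LL^\top = V_i$; pooled mean
  near 0 and variance near 1 under a correct model. With $\omega^2 = 0$
  they reduce to $(y-f)/(\sigma f)$, which the tests use as an exact
  closed-form oracle.
* **Bootstrap** — plain (unstratified) resampling of subjects with
  replacement to the original subject count, refit per replicate
  (warm-started at the original estimates), medians and 5th-95th
  percentiles over converged replicates; failures are dropped and
  reported, never imputed.
* **NPDE** — $K$ simulated replicates of the dataset at the observed
  design; per subject, observed and simulated vectors are decorrelated
  with the simulation mean and a Cholesky square root of the simulation
  covariance; ranks are continuity-corrected as
  $p = (\mathrm{rank} + 0.5)/(K + 1)$ before $\Phi^{-1}$. Cholesky
  decorrelation is this implementation's stated choice.
* **pcVPC** — equal-count bins on time after dose (default 6);
  observations and simulations are rescaled by the bin-median population
  prediction over their own population prediction; observed 5th/50th/95th
  percentiles are compared with their 2.5-97.5% simulation envelopes.

The NPDE and pcVPC simulators and the synthetic-data generator share one
simulation code path — there is a single implementation of the
concentration model (the compiled engine) and a single
simulate-at-design routine.

Reference sizes are $B = 1000$ bootstrap replicates and $K = 1000$
simulations; the defaults used in the package's own desk-scale runs and
tests are $B = 200$ and $K = 500$, which the test suite shows are ample
for median/variance summaries at this design size.

## Dose evaluation (fT>MIC)

The target is free cefotaxime concentration above the MIC for 70% of the
dosing interval at steady state, with MIC 2 mg/L (covering the prevalent
early-onset sepsis pathogens) and free fraction 0.6 — reported protein
binding spans roughly 27-50%, and 40% binding is the conventional figure,
exposed as a parameter. Because the post-infusion profile declines
monotonically, attainment is evaluated at the single instant
$0.7\,\tau$ measured from infusion start (a declared convention; the
source analysis states the fraction but not the origin), which is
equivalent to fT>MIC $\ge$ 70% whenever that instant falls after the end
of the infusion. Steady state is computed analytically via the
accumulation factor. AUC$_{0-24}$ at steady state is daily dose over
clearance. Population attainment defaults to Monte Carlo over sampled
$\eta$ — the original subject-level empirical-Bayes computation cannot be
replicated without the patient data, so agreement with the published 100%
is a distribution-level statement (free troughs sit far above 2 mg/L at
this dose).

## The synthetic cohort

What is known about the real cohort are marginal summaries: GA median
35.7 (range 30.0-41.1) weeks, PNA median 1 (1-3) days, current and birth
weight median 2310 (1220-3970) g, 101 concentrations over 51 neonates
restricted to about two samples each, observed concentrations
7.18-347.61 mg/L. The generator's defaults are calibrated to those
figures and then frozen:

* GA $\sim$ truncated normal(35.7, 3) on [30.0, 41.1];
* PNA $\in \{1, 2, 3\}$ days with probabilities 0.5/0.3/0.2 (median 1,
  range 1-3);
* $\log CW = 4.603 + 0.088\,GA + N(0, 0.25)$, truncated to [1220, 3970] g.
  The slope reflects late-gestation growth (weight roughly doubling from
  30 to 40 weeks); the 0.25 log-sd matches the spread of weight-for-age
  growth charts, lets the simulated range actually cover the published
  one, and keeps weight and gestational age informative as *separate*
  covariates — a tighter coupling would make GA/PMA near-duplicates of
  weight, which the published per-covariate likelihood drops (weight far
  ahead of gestational-age measures) contradict;
* BW = CW (the study reports identical distributions at these ages);
  PMA = GA + PNA/7;
* dosing 50 mg/kg every 12 h as 0.5-h infusions; sampling times uniform
  on 0.5-72 h after the first dose (opportunistic scavenged-sample times
  are otherwise unreported), two per subject with one singleton so the
  total is 101.

What the generator does **not** emulate: real scavenged-sample time
clustering around clinical draws, assay error structure beyond a
proportional term, within-treatment covariate change (PNA is frozen at
baseline over the 3-day sampling window), below-quantification censoring
(the emulated design produces essentially no concentrations under the
0.5 mg/L limit), or any covariate effect on volume. Passing tests
therefore demonstrate internal consistency of estimator, diagnostics and
dose evaluation under the stated data-generating model — not performance
against the idiosyncrasies of real opportunistic data.

## Numerical choices and limitations

* Inner Newton: analytic gradient, finite-difference Hessian, gradient
  tolerance $10^{-8}$, Levenberg regularization and step halving for
  robustness; always restarted from zero for smoothness of the outer
  objective.
* Outer optimizer: `nlminb` on the transformed scale, relative tolerance
  $10^{-10}$, iteration budget 500; candidate fits in the stepwise search
  retry once from the default start if a warm start fails to converge.
* Model predictions are floored at $10^{-12}$ mg/L so proportional-error
  variances stay positive at pre-dose times.
* Problem sizes in the shipped tests: the 51/101 study design for fits,
  10 replicate fits for the bias check, $B = 200$ / $K = 500$ for
  bootstrap and NPDE, 1000 virtual neonates for attainment — sizes at
  which each check runs in seconds to a few minutes on one core.
* Known limitations: no two-compartment or metabolite
  (desacetylcefotaxime) kinetics, no inter-occasion variability, no SAEM
  or full Bayesian alternative, no MIC-distribution-weighted response
  fraction, and no support for oral dosing records. The FOCE-I objective
  matches this package's stated approximation and its quadrature oracle;
  bit-for-bit agreement with any specific NONMEM version is not claimed.
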