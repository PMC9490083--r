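#' Individual clearance under the covariate model
#'
#' CL = theta2 * (CW/2310)^theta3 * (PNA/1)^theta4 * exp(etaCl). Strictly
#' increasing in current weight and postnatal age when the exponents are
#' positive.
#'
#' @param p a [PopulationParams-class]
#' @param cov list or one-row data.frame with elements CW (g) and PNA (days)
#' @param etaCl log-scale random effect (default 0, the typical subject)
#' @return clearance in L/h
#' @examples
#' individualClearance(cefotaximeParams(), list(CW = 2310, PNA = 1)) # 0.0803
#' @export
individualClearance <- function(p, cov, etaCl = 0) {
  cw <- as.numeric(cov$CW)
  pna <- as.numeric(cov$PNA)
  if (any(!(cw > 0)) || any(!(pna > 0)))
    stop("CW and PNA must be positive")
  p@theta2 * (cw / 2310)^p@theta3 * (pna / 1)^p@theta4 * exp(etaCl)
}

#' Individual volume of distribution
#'
#' V = theta1 * exp(etaV); the final model carries no covariate on volume.
#'
#' @param p a [PopulationParams-class]
#' @param etaV log-scale random effect (default 0)
#' @return volume in L
#' @export
individualVolume <- function(p, etaV = 0) {
  p@theta1 * exp(etaV)
}

#' Assemble individual parameters
#'
#' @inheritParams individualClearance
#' @param etaV log-scale random effect on volume
#' @return list with CL (L/h), V (L) and ke = CL/V (1/h)
#' @export
individualParams <- function(p, cov, etaCl = 0, etaV = 0) {
  CL <- individualClearance(p, cov, etaCl)
  V <- individualVolume(p, etaV)
  list(CL = CL, V = V, ke = CL / V)
}

#' Dose event table constructor
#'
#' @param time infusion start times, h since first dose
#' @param amount dose amounts, mg
#' @param duration infusion durations, h
#' @return data.frame with columns time, amount, duration, rate (mg/h)
#' @export
doseEvents <- function(time, amount, duration) {
  if (any(!(amount > 0))) stop("dose amounts must be positive")
  if (any(!(duration > 0))) stop("infusion durations must be positive")
  data.frame(time = time, amount = amount, duration = duration,
             rate = amount / duration)
}

#' Concentration from superposed intravenous infusions
#'
#' Closed-form one-compartment solution with first-order elimination: during
#' an infusion started at t0 with rate R the dose contributes
#' (R/CL)(1 - exp(-ke (t - t0))); after it ends at t0 + D the contribution
#' decays as (R/CL)(1 - exp(-ke D)) exp(-ke (t - t0 - D)). Contributions of
#' all doses are summed; times before every dose give 0.
#'
#' @param ind individual parameters from [individualParams()] (list with CL
#'   and V)
#' @param doses data.frame from [doseEvents()]
#' @param t time(s) in h since first dose (vectorized)
#' @return concentration(s) in mg/L
#' @export
concentration <- function(ind, doses, t) {
  if (any(t < 0)) stop("t must be non-negative")
  if (!(ind$CL > 0) || !(ind$V > 0)) stop("CL and V must be positive")
  .concProfileCpp(as.numeric(t), ind$CL, ind$V,
                  as.numeric(doses$time), as.numeric(doses$rate),
                  as.numeric(doses$duration))
}

#' Steady-state concentration within a dosing interval
#'
#' Analytic accumulation for a repeated infusion regimen: the post-infusion
#' profile equals the single-dose profile divided by (1 - exp(-ke tau)); the
#' within-infusion segment adds the accumulated tail of all previous doses.
#' `t` is measured from the start of an infusion at steady state.
#'
#' @param ind individual parameters (list with CL, V)
#' @param regimen a [RegimenSpec-class]
#' @param t time(s) within the interval, h from infusion start, in [0, tau)
#' @param cw current weight in g (converts dose/kg to mg)
#' @return concentration(s) in mg/L
#' @examples
#' ind <- individualParams(cefotaximeParams(), list(CW = 2310, PNA = 1))
#' steadyStateConcentration(ind, regimenSpec(), 8.4, cw = 2310) # ~93.5 mg/L
#' @export
steadyStateConcentration <- function(ind, regimen, t, cw) {
  stopifnot(is(regimen, "RegimenSpec"))
  tau <- regimen@tau
  D <- regimen@duration
  if (any(t < 0) || any(t >= tau)) stop("t must lie in [0, tau)")
  amt <- regimen@dosePerKg * cw / 1000
  R <- amt / D
  ke <- ind$CL / ind$V
  acc <- 1 / (1 - exp(-ke * tau))
  post <- (R / ind$CL) * (1 - exp(-ke * D)) * exp(-ke * (t - D)) * acc
  # within the infusion: current rising limb plus the accumulated tail of
  # all earlier doses, which decays from its end-of-interval value
  tail <- (R / ind$CL) * (1 - exp(-ke * D)) * exp(-ke * (t + tau - D)) * acc
  during <- (R / ind$CL) * (1 - exp(-ke * t)) + tail
  ifelse(t >= D, post, during)
}
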