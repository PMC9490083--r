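#' Longitudinal pharmacokinetic event dataset
#'
#' An S4 container for NONMEM-style longitudinal event records: one row per
#' dose or observation, chronological within subject, with the neonatal
#' covariates carried on every row. Doses are intravenous infusions (AMT in
#' mg, RATE in mg/h, infusion duration = AMT/RATE); observations are plasma
#' concentrations in mg/L (identical to ug/ml). Covariates are current weight
#' CW (g), birth weight BW (g), gestational age GA (weeks), postnatal age PNA
#' (days) and postmenstrual age PMA (weeks).
#'
#' @slot events data.frame with columns ID, TIME, AMT, RATE, DV, MDV, CW, BW,
#'   GA, PNA, PMA. Dose rows have MDV = 1 and AMT > 0; observation rows have
#'   MDV = 0 and a DV value.
#'
#' @seealso [pkDataset()], [readDataset()], [validateDataset()]
#' @export
setClass("PKDataset", representation(events = "data.frame"))

.PK_COLS <- c("ID", "TIME", "AMT", "RATE", "DV", "MDV",
              "CW", "BW", "GA", "PNA", "PMA")

setValidity("PKDataset", function(object) {
  ev <- object@events
  miss <- setdiff(.PK_COLS, names(ev))
  if (length(miss) > 0)
    return(paste("missing event columns:", paste(miss, collapse = ", ")))
  if (nrow(ev) == 0) return(TRUE)
  if (!is.character(ev$ID)) return("ID must be character")
  num <- setdiff(.PK_COLS, "ID")
  bad <- num[!vapply(ev[num], is.numeric, logical(1))]
  if (length(bad) > 0)
    return(paste("non-numeric columns:", paste(bad, collapse = ", ")))
  if (!all(ev$MDV %in% c(0, 1))) return("MDV must be 0 or 1")
  TRUE
})

#' Population pharmacokinetic parameters
#'
#' Fixed effects, inter-individual variances and residual variance of the
#' one-compartment cefotaxime model. The typical value of the volume of
#' distribution is `theta1` (L). Typical clearance at the covariate reference
#' point (current weight 2310 g, postnatal age 1 day) is `theta2` (L/h) and
#' scales as `theta2 * (CW/2310)^theta3 * (PNA/1)^theta4`. Inter-individual
#' variability is exponential, `P_i = P_typ * exp(eta)` with
#' `eta ~ N(0, omega2)`; residual error is proportional,
#' `y = f * (1 + eps)`, `eps ~ N(0, sigma2Prop)`.
#'
#' @slot theta1 typical volume of distribution, L
#' @slot theta2 typical clearance at CW 2310 g and PNA 1 day, L/h
#' @slot theta3 allometric current-weight exponent on clearance
#' @slot theta4 postnatal-age maturation exponent on clearance
#' @slot omega2Cl variance of the log-scale clearance random effect
#' @slot omega2V variance of the log-scale volume random effect
#' @slot sigma2Prop proportional residual error variance
#'
#' @seealso [populationParams()], [cefotaximeParams()]
#' @export
setClass("PopulationParams",
  representation(theta1 = "numeric", theta2 = "numeric", theta3 = "numeric",
                 theta4 = "numeric", omega2Cl = "numeric", omega2V = "numeric",
                 sigma2Prop = "numeric"))

setValidity("PopulationParams", function(object) {
  lens <- lengths(list(object@theta1, object@theta2, object@theta3,
                       object@theta4, object@omega2Cl, object@omega2V,
                       object@sigma2Prop))
  if (all(lens == 0)) return(TRUE) # uninitialized placeholder
  sc <- c(theta1 = object@theta1, theta2 = object@theta2,
          theta3 = object@theta3, theta4 = object@theta4,
          omega2Cl = object@omega2Cl, omega2V = object@omega2V,
          sigma2Prop = object@sigma2Prop)
  if (any(lengths(list(object@theta1, object@theta2, object@theta3,
                       object@theta4, object@omega2Cl, object@omega2V,
                       object@sigma2Prop)) != 1))
    return("all parameter slots must be length 1")
  if (any(!is.finite(sc))) return("parameters must be finite")
  if (object@theta1 <= 0 || object@theta2 <= 0)
    return("theta1 and theta2 must be positive")
  if (object@omega2Cl < 0 || object@omega2V < 0 || object@sigma2Prop < 0)
    return("variance components must be non-negative")
  TRUE
})

#' Structural model specification for estimation and covariate search
#'
#' Describes which multiplicative power-function covariate terms act on
#' clearance and on volume. Each term is `(cov/ref)^exponent` with the
#' exponent either estimated or fixed (e.g. 0.75 for fixed allometry).
#'
#' @slot clTerms data.frame with columns cov, ref, exponent, estimated: terms
#'   on clearance. `exponent` holds the fixed value when `estimated` is FALSE
#'   and the initial value when TRUE.
#' @slot vTerms same, for volume of distribution.
#'
#' @seealso [pkModel()], [baseModel()], [finalCefotaximeModel()]
#' @export
setClass("PKModelSpec",
  representation(clTerms = "data.frame", vTerms = "data.frame"))

.TERM_COLS <- c("cov", "ref", "exponent", "estimated")

setValidity("PKModelSpec", function(object) {
  for (tm in list(object@clTerms, object@vTerms)) {
    if (!all(.TERM_COLS %in% names(tm)))
      return(paste("term tables need columns:", paste(.TERM_COLS, collapse = ", ")))
    if (nrow(tm) > 0) {
      if (any(!tm$cov %in% c("CW", "BW", "GA", "PNA", "PMA")))
        return("covariates must be among CW, BW, GA, PNA, PMA")
      if (any(tm$ref <= 0)) return("normalization constants must be positive")
    }
  }
  TRUE
})

#' Result of a FOCE-I model fit
#'
#' @slot estimates named numeric vector of all estimated quantities on their
#'   natural scale (theta1, theta2, covariate exponents, omega2Cl, omega2V,
#'   sigma2Prop).
#' @slot model the [PKModelSpec-class] that was fitted.
#' @slot params the estimates repackaged as [PopulationParams-class] when the
#'   model has the canonical CW+PNA-on-clearance form, otherwise a
#'   zero-length placeholder; see [popParams()].
#' @slot ofv objective function value, -2 times the FOCE-I approximate
#'   log-likelihood (includes the 2*pi constants).
#' @slot se named numeric vector of asymptotic standard errors (NA when the
#'   Hessian was singular or not requested).
#' @slot rse named numeric vector of relative standard errors in percent.
#' @slot ebes matrix (subjects x 2) of empirical Bayes eta estimates, columns
#'   etaCl and etaV, rownames the subject ids.
#' @slot converged logical convergence flag from the outer optimizer.
#' @slot nObs,nSubjects observation and subject counts.
#' @export
setClass("FitResult",
  representation(estimates = "numeric", model = "PKModelSpec",
                 params = "PopulationParams", ofv = "numeric",
                 se = "numeric", rse = "numeric", ebes = "matrix",
                 converged = "logical", nObs = "numeric",
                 nSubjects = "numeric"))

#' Dosing regimen specification
#'
#' @slot dosePerKg dose per administration, mg/kg of current weight
#' @slot tau dosing interval, h
#' @slot duration infusion duration, h (must be shorter than tau)
#' @seealso [regimenSpec()]
#' @export
setClass("RegimenSpec",
  representation(dosePerKg = "numeric", tau = "numeric", duration = "numeric"))

setValidity("RegimenSpec", function(object) {
  if (object@dosePerKg <= 0) return("dosePerKg must be positive")
  if (object@duration <= 0) return("infusion duration must be positive")
  if (object@tau <= object@duration)
    return("dosing interval must exceed the infusion duration")
  TRUE
})

#' Pharmacokinetic-pharmacodynamic target specification
#'
#' The target is attainment of free drug concentration above the MIC at a
#' stated fraction of the dosing interval at steady state (fT>MIC logic for a
#' monotonically declining post-infusion profile).
#'
#' @slot mic minimum inhibitory concentration, mg/L
#' @slot fu free (unbound) fraction, in (0, 1]
#' @slot fraction fraction of the dosing interval at which the free
#'   concentration is evaluated, in (0, 1]
#' @seealso [targetSpec()]
#' @export
setClass("TargetSpec",
  representation(mic = "numeric", fu = "numeric", fraction = "numeric"))

setValidity("TargetSpec", function(object) {
  if (object@mic <= 0) return("mic must be positive")
  if (object@fu <= 0 || object@fu > 1) return("fu must be in (0, 1]")
  if (object@fraction <= 0 || object@fraction > 1)
    return("fraction must be in (0, 1]")
  TRUE
})

#' Probability-of-target-attainment result
#'
#' @slot attained logical per-subject attainment flags
#' @slot percentage population attainment percentage, 100 * attained / total
#' @slot auc per-subject steady-state AUC over 24 h, mg*h/L
#' @slot freeConc per-subject free concentration at the evaluation time, mg/L
#' @export
setClass("PtaResult",
  representation(attained = "logical", percentage = "numeric",
                 auc = "numeric", freeConc = "numeric"))

#' Non-parametric bootstrap result
#'
#' @slot estimates matrix (replicates x parameters) of replicate estimates
#'   (non-converged replicates dropped)
#' @slot summary data.frame with parameter, median, p5, p95
#' @slot nReplicates requested replicate count
#' @slot nFailed replicates dropped for non-convergence
#' @export
setClass("BootstrapResult",
  representation(estimates = "matrix", summary = "data.frame",
                 nReplicates = "numeric", nFailed = "numeric"))

#' Normalized prediction distribution errors
#'
#' @slot npde per-observation NPDE values
#' @slot mean,variance pooled summary statistics (N(0,1) expected under a
#'   correct model)
#' @slot shapiroW,shapiroP Shapiro-Wilk normality test of the pooled NPDE
#' @export
setClass("NpdeResult",
  representation(npde = "numeric", mean = "numeric", variance = "numeric",
                 shapiroW = "numeric", shapiroP = "numeric"))

#' Prediction-corrected visual predictive check result
#'
#' @slot bins data.frame with one row per time bin: lo, hi, mid, n, observed
#'   prediction-corrected 5th/50th/95th percentiles (obs5, obs50, obs95) and
#'   the 2.5--97.5\% simulation envelope of each percentile
#'   (lo5/hi5, lo50/hi50, lo95/hi95)
#' @slot nSim number of simulated replicate datasets
#' @export
setClass("VpcResult",
  representation(bins = "data.frame", nSim = "numeric"))

#' Stepwise covariate search trace
#'
#' @slot steps data.frame recording every tested model: phase
#'   (forward/backward), candidate covariate and target parameter, reference
#'   OFV, candidate OFV, deltaOfv, threshold, decision
#' @slot finalModel the retained [PKModelSpec-class]
#' @slot finalFit the [FitResult-class] of the final model
#' @export
setClass("SearchTrace",
  representation(steps = "data.frame", finalModel = "PKModelSpec",
                 finalFit = "FitResult"))
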