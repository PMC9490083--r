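# FOCE-I estimation: the inner problem (conditional eta modes) and the
# per-subject objective contributions live in src/focei.cpp; this file owns
# the outer optimization, standard errors and the user-facing wrappers.

# evaluate the FOCE-I objective for a model at natural-scale estimates;
# sl is a flattened .subjectList()
.engineOfv <- function(model, est, sl, detail = FALSE) {
  tv <- .typicalValues(model, as.list(est), sl$cov)
  .foceiOfvCpp(sl$subjects, tv$tvcl, tv$tvv,
               est[["omega2Cl"]], est[["omega2V"]], est[["sigma2Prop"]],
               detail)
}

# estimates vector of the canonical (final cefotaxime) model from params
.canonicalEstimates <- function(p) {
  c(theta1 = p@theta1, theta2 = p@theta2, beta.CL.CW = p@theta3,
    beta.CL.PNA = p@theta4, omega2Cl = p@omega2Cl, omega2V = p@omega2V,
    sigma2Prop = p@sigma2Prop)
}

.isCanonical <- function(model) {
  ct <- model@clTerms
  nrow(model@vTerms) == 0 && nrow(ct) == 2 &&
    identical(ct$cov, c("CW", "PNA")) && all(ct$estimated) &&
    identical(ct$ref, c(2310, 1))
}

#' FOCE-I conditional objective function
#'
#' For each subject the conditional mode of the random effects
#' (etaCl, etaV) is located by a damped Newton iteration; the subject's
#' objective contribution is the -2 log-likelihood of the first-order
#' expansion of the model about that mode, with the residual variance
#' evaluated at the conditional prediction (the "interaction" term). The
#' total objective is the sum over subjects plus the normalizing constants,
#' so nested models are comparable by likelihood-ratio tests.
#'
#' @param p a [PopulationParams-class] (the canonical covariate model)
#' @param data a [PKDataset-class]; every subject needs at least one
#'   observation for a finite contribution (dose-only subjects contribute 0)
#' @return list with elements `ofv`, `eta` (subjects x 2 matrix of
#'   conditional modes) and `contrib` (per-subject contributions)
#' @export
conditionalObjective <- function(p, data) {
  stopifnot(is(p, "PopulationParams"), is(data, "PKDataset"))
  sl <- .subjectList(data)
  r <- .engineOfv(finalCefotaximeModel(), .canonicalEstimates(p), sl)
  if (!all(r$ok))
    warning("inner optimization flagged for subject(s): ",
            paste(names(sl$subjects)[!r$ok], collapse = ", "))
  rownames(r$eta) <- names(sl$subjects)
  colnames(r$eta) <- c("etaCl", "etaV")
  list(ofv = r$ofv, eta = r$eta, contrib = r$contrib)
}

#' Empirical Bayes estimates for one or more subjects
#'
#' The posterior mode of (etaCl, etaV) given the subject's observations
#' under fixed population parameters. Subjects without observations get
#' (0, 0) (full shrinkage); as omega2 tends to 0 the estimates shrink to 0
#' regardless of the data.
#'
#' @param p a [PopulationParams-class]
#' @param data a [PKDataset-class] (may hold a single subject)
#' @return matrix (subjects x 2) with columns etaCl, etaV
#' @export
empiricalBayes <- function(p, data) {
  conditionalObjective(p, data)$eta
}

#' Optimizer settings for model fitting
#'
#' @param iterMax,evalMax outer iteration and evaluation budgets
#' @param relTol relative convergence tolerance on the objective
#' @param computeSe compute standard errors from the inverse numerical
#'   Hessian of the objective
#' @return settings list
#' @export
fitSettings <- function(iterMax = 500, evalMax = 2000, relTol = 1e-10,
                        computeSe = TRUE) {
  list(iterMax = iterMax, evalMax = evalMax, relTol = relTol,
       computeSe = computeSe)
}

#' Fit a population model by FOCE with interaction
#'
#' Maximizes the FOCE-I approximate likelihood over the fixed effects,
#' inter-individual variances and residual variance. Positivity of theta1,
#' theta2 and the variance components is enforced by log transformation;
#' covariate exponents are unconstrained. The default starting point is a
#' naive-pooled (eta = 0) log-scale least-squares fit of the fixed effects
#' with 30\% starting variability and 20\% starting residual error.
#'
#' @param data a [PKDataset-class]; every subject must have at least one
#'   observation
#' @param model a [PKModelSpec-class] (default: the final cefotaxime model)
#' @param start optional starting values: a [PopulationParams-class] (for
#'   the canonical model) or a named natural-scale vector as in
#'   `fit@estimates`
#' @param settings from [fitSettings()]
#' @return a [FitResult-class]
#' @export
fitModel <- function(data, model = finalCefotaximeModel(), start = NULL,
                     settings = fitSettings()) {
  stopifnot(is(data, "PKDataset"), is(model, "PKModelSpec"))
  sl <- .subjectList(data)
  nObsPer <- vapply(sl$subjects, function(s) length(s$y), numeric(1))
  if (any(nObsPer == 0))
    stop("subject(s) without observations: ",
         paste(names(sl$subjects)[nObsPer == 0], collapse = ", "))
  nm <- .parNames(model)
  if (is.null(start)) {
    est0 <- .defaultStart(data, model)
  } else if (is(start, "PopulationParams")) {
    if (!.isCanonical(model))
      stop("PopulationParams start requires the canonical model; ",
           "supply a named vector instead")
    est0 <- .canonicalEstimates(start)
  } else {
    if (!all(nm %in% names(start)))
      stop("start is missing parameter(s): ",
           paste(setdiff(nm, names(start)), collapse = ", "))
    est0 <- start[nm]
  }
  x0 <- .toOpt(est0, model)
  objfun <- function(x) {
    r <- .engineOfv(model, .fromOpt(x, model), sl)
    r$ofv
  }
  opt <- nlminb(x0, objfun,
                control = list(iter.max = settings$iterMax,
                               eval.max = settings$evalMax,
                               rel.tol = settings$relTol))
  isConverged <- opt$convergence == 0
  if (!isConverged) {
    # the PORT routines report "false convergence" when started at (or
    # stepping onto) a stationary point; accept the solution if the
    # numerical gradient is flat there
    g <- vapply(seq_along(opt$par), function(k) {
      h <- 1e-5 * max(1, abs(opt$par[k]))
      xp <- xm <- opt$par
      xp[k] <- xp[k] + h
      xm[k] <- xm[k] - h
      (objfun(xp) - objfun(xm)) / (2 * h)
    }, numeric(1))
    isConverged <- all(is.finite(g)) && max(abs(g)) < 0.5
  }
  est <- .fromOpt(opt$par, model)
  fin <- .engineOfv(model, est, sl)
  eta <- fin$eta
  rownames(eta) <- names(sl$subjects)
  colnames(eta) <- c("etaCl", "etaV")

  se <- rse <- setNames(rep(NA_real_, length(nm)), nm)
  if (isTRUE(settings$computeSe)) {
    H <- try(optimHess(opt$par, objfun), silent = TRUE)
    covx <- if (!inherits(H, "try-error"))
      try(2 * solve(H), silent = TRUE) else H
    if (!inherits(covx, "try-error") && all(diag(covx) > 0)) {
      sex <- sqrt(diag(covx))
      logScale <- nm %in% c("theta1", "theta2",
                            "omega2Cl", "omega2V", "sigma2Prop")
      # log-normal parameters: SE on the natural scale by the delta method
      se[logScale] <- est[logScale] * sex[logScale]
      se[!logScale] <- sex[!logScale]
      rse <- 100 * se / abs(est)
      # variances are reported as %CV = 100*sqrt(omega2); delta method
      # halves the relative error
      vr <- nm %in% c("omega2Cl", "omega2V", "sigma2Prop")
      rse[vr] <- rse[vr] / 2
    } else {
      warning("Hessian singular or not positive definite; ",
              "standard errors unavailable")
    }
  }
  params <- if (.isCanonical(model)) {
    populationParams(theta1 = est[["theta1"]], theta2 = est[["theta2"]],
                     theta3 = est[["beta.CL.CW"]],
                     theta4 = est[["beta.CL.PNA"]],
                     omega2Cl = est[["omega2Cl"]],
                     omega2V = est[["omega2V"]],
                     sigma2Prop = est[["sigma2Prop"]])
  } else new("PopulationParams")
  new("FitResult", estimates = est, model = model, params = params,
      ofv = fin$ofv, se = se, rse = rse, ebes = eta,
      converged = isConverged, nObs = sum(nObsPer),
      nSubjects = length(sl$subjects))
}

#' @rdname popParams
#' @export
setMethod("popParams", "FitResult", function(object) {
  if (length(object@params@theta1) == 0)
    stop("fit does not use the canonical covariate model; ",
         "use object@estimates")
  object@params
})

#' @rdname ofv
#' @export
setMethod("ofv", "FitResult", function(object) object@ofv)

#' @rdname ebes
#' @export
setMethod("ebes", "FitResult", function(object) object@ebes)

#' @rdname converged
#' @export
setMethod("converged", "FitResult", function(object) object@converged)

#' @describeIn fitModel estimates as a named vector
#' @param object a `FitResult`
#' @param ... ignored
#' @export
setMethod("coef", "FitResult", function(object, ...) object@estimates)

#' @rdname FitResult-class
#' @param object a `FitResult`
#' @export
setMethod("show", "FitResult", function(object) {
  cat(sprintf("FOCE-I fit: %d subjects, %d observations, OFV %.3f (%s)\n",
              object@nSubjects, object@nObs, object@ofv,
              if (object@converged) "converged" else "NOT converged"))
  est <- object@estimates
  rse <- object@rse
  cv <- function(v) 100 * sqrt(v)
  lab <- names(est)
  val <- ifelse(grepl("^omega2|^sigma2", lab), cv(est), est)
  lab <- sub("^omega2(.*)$", "IIV \\1 (%CV)", lab)
  lab <- sub("^sigma2Prop$", "prop. residual (%CV)", lab)
  for (k in seq_along(est))
    cat(sprintf("  %-22s %10.4g  (RSE %.3g%%)\n", lab[k], val[k], rse[k]))
})

# per-observation prediction table: PRED (eta = 0), IPRED (at the EBEs)
.predTable <- function(fit, data) {
  sl <- .subjectList(data)
  est <- fit@estimates
  tv <- .typicalValues(fit@model, as.list(est), sl$cov)
  eta <- fit@ebes
  rows <- list()
  for (i in seq_along(sl$subjects)) {
    si <- sl$subjects[[i]]
    if (length(si$y) == 0) next
    pred <- .concProfileCpp(si$t, tv$tvcl[i], tv$tvv[i],
                            si$doseT, si$rate, si$dur)
    ipred <- .concProfileCpp(si$t, tv$tvcl[i] * exp(eta[i, 1]),
                             tv$tvv[i] * exp(eta[i, 2]),
                             si$doseT, si$rate, si$dur)
    # time after the most recent dose, for binning
    tad <- vapply(si$t, function(tt) {
      prev <- si$doseT[si$doseT <= tt]
      if (length(prev) == 0) tt else tt - max(prev)
    }, numeric(1))
    rows[[i]] <- data.frame(ID = names(sl$subjects)[i], TIME = si$t,
                            TAD = tad, DV = si$y, PRED = pred,
                            IPRED = ipred, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
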