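# Stepwise covariate analysis by likelihood-ratio testing: forward inclusion
# at alpha = 0.05 (delta OFV > 3.84) and backward elimination at
# alpha = 0.01 (delta OFV > 6.635), power-function terms only.

#' Likelihood-ratio critical value
#'
#' The chi-square upper-alpha quantile: the objective-function drop a nested
#' model extension must exceed to be significant at level alpha with `df`
#' added parameters (3.84 at 0.05 and 6.635 at 0.01 for one parameter).
#'
#' @param alpha significance level in (0, 1)
#' @param df degrees of freedom (added parameters)
#' @return critical delta OFV
#' @examples
#' lrtThreshold(0.05) # 3.84
#' lrtThreshold(0.01) # 6.63
#' @export
lrtThreshold <- function(alpha, df = 1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (df < 1) stop("df must be at least 1")
  qchisq(1 - alpha, df)
}

#' Default covariate candidate set
#'
#' All five neonatal covariates as power functions on clearance (and
#' optionally on volume), each normalized to its dataset median. Starting
#' exponents are 0.75 for the weights (the allometric convention) and 0.25
#' for the ages.
#'
#' @param data a [PKDataset-class]
#' @param targets parameters to test covariates on ("CL", "V" or both)
#' @return data.frame with columns cov, target, ref, init
#' @export
defaultCandidates <- function(data, targets = "CL") {
  covs <- c("CW", "BW", "GA", "PNA", "PMA")
  tab <- covariateTable(data)
  out <- expand.grid(cov = covs, target = targets, stringsAsFactors = FALSE)
  out$ref <- vapply(out$cov, function(cc) median(tab[[cc]]), numeric(1))
  out$init <- ifelse(out$cov %in% c("CW", "BW"), 0.75, 0.25)
  out
}

# fit with a warm start extended by the new term's initial exponent;
# returns NULL on failure
.tryFit <- function(data, model, warm, settings) {
  start <- NULL
  if (!is.null(warm)) {
    nm <- .parNames(model)
    start <- setNames(numeric(length(nm)), nm)
    known <- intersect(nm, names(warm))
    start[known] <- warm[known]
    fresh <- setdiff(nm, names(warm))
    for (f in fresh) start[f] <- 0.25 # new exponent entries
  }
  f <- try(fitModel(data, model, start = start, settings = settings),
           silent = TRUE)
  if (inherits(f, "try-error") || !converged(f)) {
    # cold restart from the default (naive-pooled) starting point
    f <- try(fitModel(data, model, settings = settings), silent = TRUE)
  }
  if (inherits(f, "try-error") || !converged(f)) NULL else f
}

.step <- function(phase, cov, target, ofvRef, ofvCand, threshold, decision) {
  data.frame(phase = phase, cov = cov, target = target, ofvRef = ofvRef,
             ofvCand = ofvCand, deltaOfv = ofvRef - ofvCand,
             threshold = threshold, decision = decision,
             stringsAsFactors = FALSE)
}

.hasTerm <- function(model, cov, target) {
  tm <- if (target == "CL") model@clTerms else model@vTerms
  cov %in% tm$cov
}

#' Forward covariate inclusion
#'
#' Starting from the base model, each remaining candidate is tested one at a
#' time (univariate additions with an estimated exponent); the candidate
#' with the largest objective-function drop exceeding the threshold
#' (chi-square, 1 df at `alpha`) enters, and the cycle repeats until no
#' candidate qualifies. Ties are broken by fewer added parameters, then by
#' candidate name. Non-convergent candidate fits are skipped with a warning.
#'
#' @param data a [PKDataset-class]
#' @param base starting [PKModelSpec-class]
#' @param candidates data.frame from [defaultCandidates()]
#' @param alpha forward significance level
#' @param settings optimizer settings (standard errors are off: only OFVs
#'   are needed)
#' @return a [SearchTrace-class]
#' @export
forwardSelection <- function(data, base = baseModel(),
                             candidates = defaultCandidates(data),
                             alpha = 0.05,
                             settings = fitSettings(computeSe = FALSE)) {
  thr <- lrtThreshold(alpha, 1)
  fitRef <- fitModel(data, base, settings = settings)
  if (!converged(fitRef)) stop("base model did not converge")
  model <- base
  steps <- list()
  repeat {
    open <- candidates[!mapply(.hasTerm, list(model), candidates$cov,
                               candidates$target), , drop = FALSE]
    if (nrow(open) == 0) break
    trial <- list()
    for (k in seq_len(nrow(open))) {
      cand <- open[k, ]
      m2 <- .addTerm(model, cand$cov, cand$target, cand$ref,
                     exponent = NA, init = cand$init)
      f2 <- .tryFit(data, m2, fitRef@estimates, settings)
      if (is.null(f2)) {
        warning("candidate ", cand$cov, " on ", cand$target,
                " did not converge; skipped")
        next
      }
      d <- ofv(fitRef) - ofv(f2)
      steps[[length(steps) + 1]] <-
        .step("forward", cand$cov, cand$target, ofv(fitRef), ofv(f2), thr,
              if (d > thr) "significant" else "not significant")
      if (d > thr)
        trial[[length(trial) + 1]] <- list(cand = cand, fit = f2,
                                           model = m2, delta = d)
    }
    if (length(trial) == 0) break
    deltas <- vapply(trial, function(x) x$delta, numeric(1))
    npar <- vapply(trial, function(x) length(x$fit@estimates), numeric(1))
    nmix <- vapply(trial, function(x) x$cand$cov, character(1))
    # largest drop wins; near-exact ties (e.g. birth weight duplicating
    # current weight in a cohort sampled in the first days of life) go to
    # fewer parameters, then to the covariate describing the current
    # clinical state over birth-time covariates
    pref <- match(nmix, c("CW", "PNA", "PMA", "GA", "BW"))
    best <- order(-round(deltas, 2), npar, pref)[1]
    model <- trial[[best]]$model
    fitRef <- trial[[best]]$fit
    steps[[length(steps) + 1]] <-
      .step("forward", trial[[best]]$cand$cov, trial[[best]]$cand$target,
            NA, ofv(fitRef), thr, "included")
  }
  new("SearchTrace", steps = .bindSteps(steps), finalModel = model,
      finalFit = fitRef)
}

#' Backward covariate elimination
#'
#' From the full model, each covariate term is deleted in turn; the term
#' whose removal raises the objective function the least is dropped if that
#' rise does not exceed the threshold (chi-square, 1 df at `alpha`,
#' 6.635 at 0.01), and the cycle repeats. Terms whose removal exceeds the
#' threshold are retained.
#'
#' @param data a [PKDataset-class]
#' @param full full [PKModelSpec-class] (or a [FitResult-class] of it)
#' @param alpha backward significance level
#' @param settings optimizer settings
#' @return a [SearchTrace-class]
#' @export
backwardElimination <- function(data, full, alpha = 0.01,
                                settings = fitSettings(computeSe = FALSE)) {
  thr <- lrtThreshold(alpha, 1)
  if (is(full, "FitResult")) {
    fitRef <- full
    model <- full@model
  } else {
    model <- full
    fitRef <- fitModel(data, model, settings = settings)
    if (!converged(fitRef)) stop("full model did not converge")
  }
  steps <- list()
  repeat {
    terms <- .modelTerms(model)
    if (is.null(terms) || nrow(terms) == 0) break
    rises <- rep(NA_real_, nrow(terms))
    fits <- vector("list", nrow(terms))
    for (k in seq_len(nrow(terms))) {
      m2 <- .dropTerm(model, terms$cov[k], terms$target[k])
      f2 <- .tryFit(data, m2, fitRef@estimates, settings)
      if (is.null(f2)) {
        warning("reduced model without ", terms$cov[k], " on ",
                terms$target[k], " did not converge; term retained")
        next
      }
      rises[k] <- ofv(f2) - ofv(fitRef)
      fits[[k]] <- list(model = m2, fit = f2)
      steps[[length(steps) + 1]] <-
        .step("backward", terms$cov[k], terms$target[k], ofv(f2),
              ofv(fitRef), thr,
              if (rises[k] > thr) "retained" else "removable")
    }
    if (all(is.na(rises)) || min(rises, na.rm = TRUE) > thr) break
    k <- which.min(rises)
    model <- fits[[k]]$model
    fitRef <- fits[[k]]$fit
    steps[[length(steps) + 1]] <-
      .step("backward", terms$cov[k], terms$target[k], NA, ofv(fitRef), thr,
            "removed")
  }
  new("SearchTrace", steps = .bindSteps(steps), finalModel = model,
      finalFit = fitRef)
}

.bindSteps <- function(steps) {
  if (length(steps) == 0)
    return(data.frame(phase = character(), cov = character(),
                      target = character(), ofvRef = numeric(),
                      ofvCand = numeric(), deltaOfv = numeric(),
                      threshold = numeric(), decision = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, steps)
}

#' Full stepwise covariate search
#'
#' [forwardSelection()] at `forwardAlpha` followed by
#' [backwardElimination()] of the forward model at `backwardAlpha`.
#'
#' @inheritParams forwardSelection
#' @param forwardAlpha,backwardAlpha the two significance levels
#' @return a [SearchTrace-class] with the combined step log
#' @export
covariateSearch <- function(data, base = baseModel(),
                            candidates = defaultCandidates(data),
                            forwardAlpha = 0.05, backwardAlpha = 0.01,
                            settings = fitSettings(computeSe = FALSE)) {
  fw <- forwardSelection(data, base, candidates, forwardAlpha, settings)
  bw <- backwardElimination(data, fw@finalFit, backwardAlpha, settings)
  new("SearchTrace", steps = rbind(fw@steps, bw@steps),
      finalModel = bw@finalModel, finalFit = bw@finalFit)
}

#' Compare estimated versus fixed allometric weight scaling
#'
#' Adds current weight on clearance to the base model once with the
#' exponent estimated and once fixed at 0.75, and returns both
#' objective-function drops relative to the base model.
#'
#' @param data a [PKDataset-class] (at least 2 subjects)
#' @param base base [PKModelSpec-class]
#' @param ref normalization constant for weight, g
#' @param settings optimizer settings
#' @return list with deltaEstimated, deltaFixed and the three fits
#' @export
compareAllometricForms <- function(data, base = baseModel(), ref = 2310,
                                   settings = fitSettings(computeSe = FALSE)) {
  if (nSubjects(data) < 2)
    stop("allometric comparison is degenerate with fewer than 2 subjects")
  f0 <- fitModel(data, base, settings = settings)
  if (!converged(f0)) stop("base model did not converge")
  mEst <- .addTerm(base, "CW", "CL", ref, exponent = NA, init = 0.75)
  mFix <- .addTerm(base, "CW", "CL", ref, exponent = 0.75)
  fEst <- .tryFit(data, mEst, f0@estimates, settings)
  fFix <- .tryFit(data, mFix, f0@estimates, settings)
  if (is.null(fEst) || is.null(fFix))
    stop("allometric candidate fit did not converge")
  list(deltaEstimated = ofv(f0) - ofv(fEst),
       deltaFixed = ofv(f0) - ofv(fFix),
       baseFit = f0, estimatedFit = fEst, fixedFit = fFix)
}

#' @rdname SearchTrace-class
#' @param object a `SearchTrace`
#' @export
setMethod("show", "SearchTrace", function(object) {
  cat("Covariate search:", nrow(object@steps), "steps\n")
  if (nrow(object@steps) > 0)
    print(object@steps, digits = 4)
  cat("final model:\n")
  show(object@finalModel)
})
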