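# Model evaluation: conditional weighted residuals, non-parametric
# bootstrap, normalized prediction distribution errors and the
# prediction-corrected visual predictive check.

# normalize an evaluator argument: FitResult or PopulationParams ->
# list(model, est)
.modelEst <- function(x) {
  if (is(x, "FitResult"))
    return(list(model = x@model, est = x@estimates))
  if (is(x, "PopulationParams"))
    return(list(model = finalCefotaximeModel(), est = .canonicalEstimates(x)))
  stop("expected a FitResult or PopulationParams")
}

#' Conditional weighted residuals
#'
#' FOCE-linearized standardized residuals: per subject,
#' CWRES = L^-1 (y - (f(etahat) - G etahat)) where G is the gradient of the
#' model at the conditional mode and L L' is the FOCE-I covariance of y
#' (G Omega G' + diagonal interaction residual variance). Under a correct
#' model the pooled values are approximately N(0, 1).
#'
#' @param fit a [FitResult-class] (or [PopulationParams-class] to evaluate a
#'   known model)
#' @param data a [PKDataset-class]
#' @return data.frame with columns ID, TIME, DV, CWRES
#' @export
cwres <- function(fit, data) {
  me <- .modelEst(fit)
  sl <- .subjectList(data)
  r <- .engineOfv(me$model, me$est, sl, detail = TRUE)
  out <- list()
  for (i in seq_along(sl$subjects)) {
    si <- sl$subjects[[i]]
    if (length(si$y) == 0) next
    d <- r$details[[i]]
    L <- try(t(chol(d$Vy)), silent = TRUE)
    if (inherits(L, "try-error"))
      stop("singular FOCE covariance for subject ", names(sl$subjects)[i])
    resid <- si$y - d$fhat + d$G %*% r$eta[i, ]
    w <- forwardsolve(L, resid)
    out[[length(out) + 1]] <- data.frame(ID = names(sl$subjects)[i],
                                         TIME = si$t, DV = si$y,
                                         CWRES = as.numeric(w),
                                         stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Non-parametric bootstrap of a model fit
#'
#' Resamples subjects with replacement to the original subject count, refits
#' each replicate dataset, and summarizes the converged replicate estimates
#' by their median and 5th-95th percentiles. Replicates that fail to
#' converge are dropped and counted in `nFailed`. Deterministic for a fixed
#' seed.
#'
#' @param data a [PKDataset-class]
#' @param model a [PKModelSpec-class]
#' @param B replicate count (the reference analysis used 1000)
#' @param seed integer seed
#' @param start optional warm-start estimates (typically the original fit's),
#'   passed to [fitModel()]
#' @param settings optimizer settings; standard errors are off by default
#'   for speed
#' @return a [BootstrapResult-class]
#' @export
bootstrapFit <- function(data, model = finalCefotaximeModel(), B = 1000,
                         seed = 1, start = NULL,
                         settings = fitSettings(computeSe = FALSE)) {
  stopifnot(B >= 1)
  set.seed(seed)
  ids <- subjectIds(data)
  n <- length(ids)
  idx <- lapply(seq_len(B), function(b) sample.int(n, n, replace = TRUE))
  .bootstrapCore(data, model, idx, start, settings)
}

# core shared with tests that force specific resamples
.bootstrapCore <- function(data, model, idx, start, settings) {
  ids <- subjectIds(data)
  ev <- data@events
  blocks <- split(seq_len(nrow(ev)), ev$ID)
  est <- list()
  nFail <- 0
  for (b in seq_along(idx)) {
    take <- idx[[b]]
    bev <- do.call(rbind, lapply(seq_along(take), function(k) {
      block <- ev[blocks[[ids[take[k]]]], , drop = FALSE]
      block$ID <- sprintf("b%03d", k)
      block
    }))
    f <- try(fitModel(pkDataset(bev), model, start = start,
                      settings = settings), silent = TRUE)
    if (inherits(f, "try-error") || !converged(f)) {
      nFail <- nFail + 1
    } else {
      est[[length(est) + 1]] <- f@estimates
    }
  }
  if (length(est) == 0) stop("all bootstrap replicates failed")
  m <- do.call(rbind, est)
  sm <- data.frame(parameter = colnames(m),
                   median = apply(m, 2, median),
                   p5 = apply(m, 2, quantile, 0.05),
                   p95 = apply(m, 2, quantile, 0.95),
                   row.names = NULL, stringsAsFactors = FALSE)
  new("BootstrapResult", estimates = m, summary = sm,
      nReplicates = length(idx), nFailed = nFail)
}

#' @rdname BootstrapResult-class
#' @param object a `BootstrapResult`
#' @export
setMethod("show", "BootstrapResult", function(object) {
  cat(sprintf("Bootstrap: %d replicates (%d failed)\n",
              object@nReplicates, object@nFailed))
  print(object@summary, digits = 4)
})

#' Normalized prediction distribution errors
#'
#' Simulates `K` replicate datasets under the evaluated model at the
#' observed design. Per subject, observed and simulated vectors are
#' decorrelated with the simulation mean and the Cholesky square root of the
#' simulation covariance; each decorrelated observation's rank among its
#' decorrelated simulations gives a probability p = (rank + 0.5) / (K + 1)
#' (continuity-corrected so p avoids 0 and 1), and NPDE = qnorm(p). Under a
#' correct model the pooled NPDE are approximately standard normal.
#'
#' @param fit a [FitResult-class] or [PopulationParams-class]
#' @param data a [PKDataset-class]
#' @param K simulation replicate count (at least 100)
#' @param seed integer seed
#' @return an [NpdeResult-class]
#' @export
npde <- function(fit, data, K = 1000, seed = 1) {
  if (K < 100) stop("K must be at least 100 for usable rank resolution")
  me <- .modelEst(fit)
  sl <- .subjectList(data)
  set.seed(seed)
  sims <- .simulateAtDesign(sl, me$model, me$est, nrep = K)
  vals <- list()
  for (i in seq_along(sl$subjects)) {
    yi <- sl$subjects[[i]]$y
    ni <- length(yi)
    if (ni == 0) next
    S <- do.call(rbind, lapply(sims, function(s) s[[i]])) # K x ni
    mu <- colMeans(S)
    Sc <- stats::cov(S)
    L <- try(t(chol(Sc + diag(1e-10, ni))), silent = TRUE)
    if (inherits(L, "try-error"))
      stop("singular simulation covariance for subject ",
           names(sl$subjects)[i])
    dObs <- forwardsolve(L, yi - mu)
    dSim <- t(forwardsolve(L, t(S) - mu)) # K x ni
    p <- vapply(seq_len(ni), function(j)
      (sum(dSim[, j] < dObs[j]) + 0.5) / (K + 1), numeric(1))
    vals[[length(vals) + 1]] <- qnorm(p)
  }
  v <- unlist(vals)
  sw <- shapiro.test(v)
  new("NpdeResult", npde = v, mean = mean(v), variance = var(v),
      shapiroW = unname(sw$statistic), shapiroP = sw$p.value)
}

#' @rdname NpdeResult-class
#' @param object a `NpdeResult`
#' @export
setMethod("show", "NpdeResult", function(object) {
  cat(sprintf(
    "NPDE: n = %d, mean %.3f, variance %.3f (Shapiro-Wilk W %.3f, p %.3g)\n",
    length(object@npde), object@mean, object@variance, object@shapiroW,
    object@shapiroP))
})

#' Prediction-corrected visual predictive check
#'
#' Observed and simulated concentrations are rescaled by
#' (bin median population prediction) / (own population prediction) within
#' equal-count bins on time after dose, then the observed 5th/50th/95th
#' percentiles per bin are compared with the 2.5-97.5\% envelope of the same
#' percentiles across `nSim` simulated replicates of the dataset.
#'
#' @param fit a [FitResult-class] or [PopulationParams-class]
#' @param data a [PKDataset-class]
#' @param nSim simulated replicate count (at least 100)
#' @param bins number of equal-count time-after-dose bins
#' @param seed integer seed
#' @return a [VpcResult-class]
#' @export
pcvpc <- function(fit, data, nSim = 500, bins = 6, seed = 1) {
  if (nSim < 100) stop("nSim must be at least 100")
  me <- .modelEst(fit)
  sl <- .subjectList(data)
  # population predictions and time-after-dose, in engine observation order
  tv <- .typicalValues(me$model, as.list(me$est), sl$cov)
  pred <- tad <- obs <- numeric(0)
  for (i in seq_along(sl$subjects)) {
    si <- sl$subjects[[i]]
    if (length(si$y) == 0) next
    pr <- .concProfileCpp(si$t, tv$tvcl[i], tv$tvv[i],
                          si$doseT, si$rate, si$dur)
    td <- vapply(si$t, function(tt) {
      prev <- si$doseT[si$doseT <= tt]
      if (length(prev) == 0) tt else tt - max(prev)
    }, numeric(1))
    pred <- c(pred, pr); tad <- c(tad, td); obs <- c(obs, si$y)
  }
  if (any(pred <= 0)) stop("non-positive population prediction")
  edges <- unique(quantile(tad, probs = seq(0, 1, length.out = bins + 1)))
  binIdx <- cut(tad, edges, include.lowest = TRUE, labels = FALSE)
  if (length(unique(binIdx)) < bins)
    stop("empty bin: reduce the number of bins")
  binMedPred <- tapply(pred, binIdx, median)
  corr <- binMedPred[binIdx] / pred
  pcObs <- obs * corr
  qs <- c(0.05, 0.5, 0.95)
  obsQ <- t(vapply(seq_len(max(binIdx)), function(b)
    quantile(pcObs[binIdx == b], qs), numeric(3)))
  set.seed(seed)
  sims <- .simulateAtDesign(sl, me$model, me$est, nrep = nSim)
  simQ <- array(NA_real_, c(nSim, max(binIdx), 3))
  for (r in seq_len(nSim)) {
    ys <- unlist(sims[[r]]) * corr
    for (b in seq_len(max(binIdx)))
      simQ[r, b, ] <- quantile(ys[binIdx == b], qs)
  }
  env <- function(k, pq) apply(simQ[, , k, drop = FALSE], 2, quantile, pq)
  out <- data.frame(
    lo = edges[-length(edges)], hi = edges[-1],
    mid = tapply(tad, binIdx, median), n = as.numeric(table(binIdx)),
    obs5 = obsQ[, 1], obs50 = obsQ[, 2], obs95 = obsQ[, 3],
    lo5 = env(1, 0.025), hi5 = env(1, 0.975),
    lo50 = env(2, 0.025), hi50 = env(2, 0.975),
    lo95 = env(3, 0.025), hi95 = env(3, 0.975), row.names = NULL)
  new("VpcResult", bins = out, nSim = nSim)
}

#' @rdname VpcResult-class
#' @param object a `VpcResult`
#' @export
setMethod("show", "VpcResult", function(object) {
  cat(sprintf("pcVPC: %d bins, %d simulated replicates\n",
              nrow(object@bins), object@nSim))
  inEnv <- with(object@bins, obs50 >= lo50 & obs50 <= hi50)
  cat(sprintf("  observed median inside its envelope in %d/%d bins\n",
              sum(inEnv), length(inEnv)))
})
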