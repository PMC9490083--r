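# Synthetic neonatal cohorts and sparse opportunistic sampling designs.
#
# The covariate generator emulates the published cohort summaries: GA
# truncated normal (mean 35.7, sd 3, bounds 30.0-41.1 weeks); PNA 1-3 days
# with probabilities 0.5/0.3/0.2 (median 1, range 1-3); current weight
# log-linear in GA, CW = exp(4.603 + 0.088 GA + e), e ~ N(0, 0.25),
# truncated to 1220-3970 g so the median sits near 2310 g and the range
# covers the published one (the 0.25 log-sd reflects the wide
# weight-for-age variability of intrauterine growth charts and keeps weight
# and gestational age informative as separate covariates); birth weight
# equals current weight at these ages, as in the published cohort;
# PMA = GA + PNA/7. Only the marginal
# medians and ranges of the real cohort are known, so the joint
# weight-age model is a documented generator convention.

#' Cohort generator settings
#'
#' @param nSubjects number of virtual neonates
#' @param gaMean,gaSd,gaRange gestational-age truncated normal, weeks
#' @param pnaProbs probabilities of postnatal age 1, 2, 3 days
#' @param cwIntercept,cwSlope,cwSd log-linear weight model
#'   log CW = cwIntercept + cwSlope * GA + N(0, cwSd)
#' @param cwRange admissible current weight range, g
#' @return settings list
#' @export
cohortSpec <- function(nSubjects = 51, gaMean = 35.7, gaSd = 3,
                       gaRange = c(30.0, 41.1), pnaProbs = c(0.5, 0.3, 0.2),
                       cwIntercept = 4.603, cwSlope = 0.088, cwSd = 0.25,
                       cwRange = c(1220, 3970)) {
  if (nSubjects < 1) stop("nSubjects must be at least 1")
  if (gaRange[1] >= gaRange[2] || cwRange[1] >= cwRange[2])
    stop("infeasible range settings")
  if (abs(sum(pnaProbs) - 1) > 1e-8 || any(pnaProbs < 0))
    stop("pnaProbs must be a probability vector over 1, 2, 3 days")
  list(nSubjects = nSubjects, gaMean = gaMean, gaSd = gaSd,
       gaRange = gaRange, pnaProbs = pnaProbs, cwIntercept = cwIntercept,
       cwSlope = cwSlope, cwSd = cwSd, cwRange = cwRange)
}

.rtrunc <- function(n, draw, lo, hi) {
  out <- numeric(n)
  done <- 0
  while (done < n) {
    x <- draw(max(n - done, 16))
    x <- x[x >= lo & x <= hi]
    take <- min(length(x), n - done)
    if (take > 0) out[(done + 1):(done + take)] <- x[seq_len(take)]
    done <- done + take
  }
  out
}

#' Sample a virtual neonatal cohort
#'
#' @param spec settings from [cohortSpec()], or a subject count (uses the
#'   default spec)
#' @param seed integer seed; the same seed reproduces the cohort exactly
#' @return data.frame with columns ID, CW, BW, GA, PNA, PMA
#' @examples
#' cohort <- sampleCohort(51, seed = 1)
#' range(cohort$CW) # within 1220-3970 g
#' @export
sampleCohort <- function(spec = cohortSpec(), seed = 1) {
  if (is.numeric(spec)) spec <- cohortSpec(nSubjects = spec)
  set.seed(seed)
  n <- spec$nSubjects
  ga <- .rtrunc(n, function(m) rnorm(m, spec$gaMean, spec$gaSd),
                spec$gaRange[1], spec$gaRange[2])
  pna <- sample(1:3, n, replace = TRUE, prob = spec$pnaProbs)
  cw <- vapply(ga, function(g)
    .rtrunc(1, function(m) exp(spec$cwIntercept + spec$cwSlope * g +
                                 rnorm(m, 0, spec$cwSd)),
            spec$cwRange[1], spec$cwRange[2]), numeric(1))
  # the published cohort reports identical birth- and current-weight
  # distributions at these ages, so BW = CW
  data.frame(ID = sprintf("v%03d", seq_len(n)), CW = cw, BW = cw, GA = ga,
             PNA = pna, PMA = ga + pna / 7, stringsAsFactors = FALSE)
}

#' Sparse opportunistic sampling design
#'
#' The dosing schedule is the study regimen (50 mg/kg per dose, every 12 h,
#' 0.5-h infusions) over `nDoses` administrations; sampling times are drawn
#' uniformly over `sampleWindow` after the first dose, reflecting
#' opportunistic scavenged-sample timing, with `samplesPerSubject` draws per
#' neonate. `totalObservations` optionally trims the last subjects to fewer
#' samples so the study's total (101 over 51 neonates) can be matched.
#'
#' @param dosePerKg,tau,duration regimen (mg/kg, h, h)
#' @param nDoses number of administered doses
#' @param samplesPerSubject target samples per neonate
#' @param sampleWindow sampling window, h after first dose
#' @param totalObservations optional total observation count
#' @return settings list
#' @export
designSpec <- function(dosePerKg = 50, tau = 12, duration = 0.5, nDoses = 7,
                       samplesPerSubject = 2, sampleWindow = c(0.5, 72),
                       totalObservations = NULL) {
  if (tau <= duration) stop("tau must exceed the infusion duration")
  if (sampleWindow[2] > nDoses * tau)
    stop("sampling window extends past the treatment window")
  list(dosePerKg = dosePerKg, tau = tau, duration = duration,
       nDoses = nDoses, samplesPerSubject = samplesPerSubject,
       sampleWindow = sampleWindow, totalObservations = totalObservations)
}

# simulate concentrations at a fixed design; this single engine is used by
# simulateDataset(), npde() and pcvpc() so every simulation shares one code
# path. sl as from .subjectList(); model/est describe the generating model
# (natural-scale named estimates); returns a list (replicates) of lists
# (subjects) of simulated observation vectors.
.simulateAtDesign <- function(sl, model, est, nrep = 1) {
  tv <- .typicalValues(model, as.list(est), sl$cov)
  om2cl <- est[["omega2Cl"]]
  om2v <- est[["omega2V"]]
  sig2 <- est[["sigma2Prop"]]
  lapply(seq_len(nrep), function(r) {
    lapply(seq_along(sl$subjects), function(i) {
      si <- sl$subjects[[i]]
      if (length(si$t) == 0) return(numeric(0))
      eta <- c(rnorm(1, 0, sqrt(om2cl)), rnorm(1, 0, sqrt(om2v)))
      f <- .concProfileCpp(si$t, tv$tvcl[i] * exp(eta[1]),
                           tv$tvv[i] * exp(eta[2]), si$doseT, si$rate, si$dur)
      y <- f * (1 + rnorm(length(f), 0, sqrt(sig2)))
      pmax(y, 0)
    })
  })
}

#' Simulate a sparse pharmacokinetic dataset
#'
#' For each neonate: the BID infusion schedule is built from current weight,
#' sampling times are drawn per the design, a subject-level (etaCl, etaV)
#' pair is drawn from N(0, omega2), concentrations follow the closed-form
#' one-compartment model, and proportional residual error y = f (1 + eps) is
#' applied. Negative simulated concentrations (possible only at very large
#' residual error) are truncated at zero with a message.
#'
#' @param cohort covariate table from [sampleCohort()] (columns ID, CW, BW,
#'   GA, PNA, PMA)
#' @param p a [PopulationParams-class]
#' @param design settings from [designSpec()]
#' @param seed integer seed
#' @return a [PKDataset-class] that passes [validateDataset()]
#' @export
simulateDataset <- function(cohort, p = cefotaximeParams(),
                            design = designSpec(), seed = 1) {
  stopifnot(is(p, "PopulationParams"))
  # force promises before seeding: a nested sampleCohort() call in the
  # cohort argument must not reseed the stream after set.seed below
  force(cohort)
  force(design)
  set.seed(seed)
  n <- nrow(cohort)
  nPer <- rep(design$samplesPerSubject, n)
  if (!is.null(design$totalObservations)) {
    excess <- sum(nPer) - design$totalObservations
    if (excess < 0) stop("totalObservations exceeds samplesPerSubject * n")
    i <- n
    while (excess > 0 && i >= 1) {
      drop <- min(excess, nPer[i] - 1)
      nPer[i] <- nPer[i] - drop
      excess <- excess - drop
      i <- i - 1
    }
    if (excess > 0) stop("cannot reach totalObservations with >= 1 sample each")
  }
  doseT <- (seq_len(design$nDoses) - 1) * design$tau
  rows <- list()
  subj <- vector("list", n)
  for (i in seq_len(n)) {
    amt <- design$dosePerKg * cohort$CW[i] / 1000
    tt <- sort(runif(nPer[i], design$sampleWindow[1], design$sampleWindow[2]))
    subj[[i]] <- list(y = numeric(length(tt)), t = tt, doseT = doseT,
                      rate = rep(amt / design$duration, length(doseT)),
                      dur = rep(design$duration, length(doseT)))
  }
  sl <- list(subjects = subj, cov = cohort)
  ysim <- .simulateAtDesign(sl, finalCefotaximeModel(),
                            .canonicalEstimates(p), nrep = 1)[[1]]
  nTrunc <- sum(vapply(seq_len(n), function(i)
    sum(ysim[[i]] == 0), numeric(1)))
  if (nTrunc > 0)
    message(nTrunc, " simulated concentration(s) truncated at 0")
  for (i in seq_len(n)) {
    s <- subj[[i]]
    amt <- design$dosePerKg * cohort$CW[i] / 1000
    cv <- cohort[i, c("CW", "BW", "GA", "PNA", "PMA")]
    rows[[i]] <- data.frame(
      ID = cohort$ID[i],
      TIME = c(s$doseT, s$t),
      AMT = c(rep(amt, length(s$doseT)), rep(NA, length(s$t))),
      RATE = c(s$rate, rep(NA, length(s$t))),
      DV = c(rep(NA, length(s$doseT)), ysim[[i]]),
      MDV = c(rep(1, length(s$doseT)), rep(0, length(s$t))),
      cv, row.names = NULL, stringsAsFactors = FALSE)
  }
  pkDataset(do.call(rbind, rows))
}

#' Write a canonical synthetic fixture dataset
#'
#' Presets: "study-like" is the 51-neonate, 101-observation opportunistic
#' design simulated under the reference cefotaxime parameters. The file is
#' byte-stable for a fixed seed.
#'
#' @param name preset id
#' @param seed integer seed
#' @param path output CSV path
#' @return the [PKDataset-class], invisibly; the CSV is written to `path`
#' @export
makeFixture <- function(name = "study-like", seed = 1,
                        path = file.path(tempdir(), paste0(name, ".csv"))) {
  if (name != "study-like") stop("unknown preset: ", name)
  cohort <- sampleCohort(cohortSpec(nSubjects = 51), seed = seed)
  ds <- simulateDataset(cohort, cefotaximeParams(),
                        designSpec(totalObservations = 101), seed = seed + 1)
  writeDataset(ds, path)
  invisible(ds)
}
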