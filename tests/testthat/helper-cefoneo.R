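# Shared fixtures and independent oracles. Everything is generated in code;
# oracles never call the code paths they check.

# study-like synthetic dataset: 51 neonates, 101 sparse samples, generated
# under the reference parameter truth
studyLikeDataset <- function(seed = 1) {
  cohort <- sampleCohort(cohortSpec(nSubjects = 51), seed = seed)
  simulateDataset(cohort, cefotaximeParams(),
                  designSpec(totalObservations = 101), seed = seed + 1)
}

# a rich-design dataset (many samples per subject) for recovery checks
richDataset <- function(nSubjects = 30, nObsPer = 10, p = cefotaximeParams(),
                        seed = 1) {
  cohort <- sampleCohort(cohortSpec(nSubjects = nSubjects), seed = seed)
  simulateDataset(cohort, p,
                  designSpec(samplesPerSubject = nObsPer), seed = seed + 1)
}

# independent numeric oracle for the one-compartment infusion model:
# integrate dC/dt = R(t)/V - ke C with deSolve, piecewise between the
# infusion on/off breakpoints so the solver never steps across a
# discontinuity of the forcing function
odeConcentration <- function(CL, V, doses, tout) {
  ke <- CL / V
  bps <- sort(unique(c(0, doses$time, doses$time + doses$duration, tout)))
  conc <- numeric(length(bps)) # concentration at each breakpoint
  C <- 0
  for (k in seq_len(length(bps) - 1)) {
    a <- bps[k]
    b <- bps[k + 1]
    mid <- (a + b) / 2
    R <- sum(doses$rate[mid >= doses$time &
                          mid < doses$time + doses$duration])
    f <- function(t, y, parms) list(R / V - ke * y[1])
    o <- deSolve::lsoda(c(C = C), c(a, b), f, NULL,
                        rtol = 1e-10, atol = 1e-12)
    C <- unname(o[nrow(o), "C"])
    conc[k + 1] <- C
  }
  conc[match(tout, bps)]
}

# adaptive 2-D Gauss-Hermite marginal -2 log-likelihood oracle for the
# nonlinear mixed model with proportional error; independent of the FOCE
# engine (uses its own prediction function written from the closed form)
refConc <- function(t, CL, V, doseT, rateV, dur) {
  ke <- CL / V
  sapply(t, function(tt) {
    c0 <- 0
    for (d in seq_along(doseT)) {
      if (tt <= doseT[d]) next
      if (tt <= doseT[d] + dur[d]) {
        c0 <- c0 + (rateV[d] / CL) * (1 - exp(-ke * (tt - doseT[d])))
      } else {
        c0 <- c0 + (rateV[d] / CL) * (1 - exp(-ke * dur[d])) *
          exp(-ke * (tt - doseT[d] - dur[d]))
      }
    }
    c0
  })
}

aghMarginalOfv <- function(subjects, tvcl, tvv, om2cl, om2v, sig2,
                           nNodes = 21) {
  gh <- pracma::gaussHermite(nNodes)
  total <- 0
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    logJoint <- function(eta) {
      f <- refConc(s$t, tvcl[i] * exp(eta[1]), tvv[i] * exp(eta[2]),
                   s$doseT, s$rate, s$dur)
      v <- sig2 * f^2
      ll <- sum(dnorm(s$y, f, sqrt(v), log = TRUE))
      ll + dnorm(eta[1], 0, sqrt(om2cl), log = TRUE) +
        dnorm(eta[2], 0, sqrt(om2v), log = TRUE)
    }
    opt <- optim(c(0, 0), function(e) -logJoint(e), method = "BFGS")
    m <- opt$par
    H <- optimHess(m, function(e) -logJoint(e))
    Sig <- solve(H)
    Cu <- chol(Sig)
    # accumulate on the log scale (log-sum-exp) so tight variances do not
    # underflow the joint density
    lw <- numeric(nNodes * nNodes)
    idx <- 1
    for (a in seq_len(nNodes)) {
      for (b in seq_len(nNodes)) {
        z <- c(gh$x[a], gh$x[b])
        eta <- m + sqrt(2) * as.numeric(t(Cu) %*% z)
        lw[idx] <- log(gh$w[a]) + log(gh$w[b]) + logJoint(eta) + sum(z^2)
        idx <- idx + 1
      }
    }
    m0 <- max(lw)
    total <- total -
      2 * (log(2 * sqrt(det(Sig))) + m0 + log(sum(exp(lw - m0))))
  }
  total
}

# tiny hand-built dataset: n subjects on the study regimen with stated
# observation times (hours)
tinyDataset <- function(times, cw = 2310, pna = 1, p = cefotaximeParams(),
                        seed = 42, nDoses = 4) {
  set.seed(seed)
  n <- length(times)
  rows <- list()
  for (i in seq_len(n)) {
    amt <- 50 * cw / 1000
    doseT <- (seq_len(nDoses) - 1) * 12
    eta <- c(rnorm(1, 0, sqrt(p@omega2Cl)), rnorm(1, 0, sqrt(p@omega2V)))
    ind <- individualParams(p, list(CW = cw, PNA = pna), eta[1], eta[2])
    tt <- times[[i]]
    f <- concentration(ind, doseEvents(doseT, rep(amt, nDoses),
                                       rep(0.5, nDoses)), tt)
    y <- f * (1 + rnorm(length(tt), 0, sqrt(p@sigma2Prop)))
    rows[[i]] <- data.frame(
      ID = sprintf("s%02d", i), TIME = c(doseT, tt),
      AMT = c(rep(amt, nDoses), rep(NA, length(tt))),
      RATE = c(rep(amt / 0.5, nDoses), rep(NA, length(tt))),
      DV = c(rep(NA, nDoses), y), MDV = c(rep(1, nDoses), rep(0, length(tt))),
      CW = cw, BW = cw, GA = 35.7, PNA = pna, PMA = 35.7 + pna / 7)
  }
  pkDataset(do.call(rbind, rows))
}
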