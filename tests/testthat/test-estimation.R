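test_that("noise-free data give zero conditional modes and a minimum at the truth", {
  p <- cefotaximeParams()
  pNoNoise <- populationParams(p@theta1, p@theta2, p@theta3, p@theta4,
                               omega2Cl = 0.04, omega2V = 0.04,
                               sigma2Prop = 1e-4)
  cohort <- sampleCohort(12, seed = 5)
  dsExact <- simulateDataset(cohort,
    populationParams(p@theta1, p@theta2, p@theta3, p@theta4, 0, 0, 0),
    designSpec(samplesPerSubject = 3), seed = 6)
  r <- conditionalObjective(pNoNoise, dsExact)
  expect_lt(max(abs(r$eta)), 1e-4)
  # the generating theta minimizes the objective over a local grid
  for (mult in c(0.9, 1.1)) {
    for (slot in 1:2) {
      th <- c(p@theta1, p@theta2)
      th[slot] <- th[slot] * mult
      alt <- populationParams(th[1], th[2], p@theta3, p@theta4,
                              0.04, 0.04, 1e-4)
      expect_gt(conditionalObjective(alt, dsExact)$ofv, r$ofv)
    }
  }
})

test_that("objective is invariant to subject relabeling", {
  ds <- studyLikeDataset(seed = 11)
  p <- cefotaximeParams()
  o1 <- conditionalObjective(p, ds)$ofv
  ev <- as.data.frame(ds)
  ev$ID <- paste0("zz-", ev$ID)
  o2 <- conditionalObjective(p, pkDataset(ev))$ofv
  expect_equal(o1, o2, tolerance = 1e-10)
})

test_that("FOCE-I objective matches adaptive Gauss-Hermite marginal likelihood", {
  skip_if_not_installed("pracma")
  # 5-subject toy with a few observations each
  ds <- tinyDataset(list(c(1, 6, 18), c(0.75, 30), c(3, 11), c(2, 26, 40),
                         c(5, 13)), seed = 9)
  p <- cefotaximeParams()
  got <- conditionalObjective(p, ds)$ofv
  sl <- cefoneo:::.subjectList(ds)
  tv <- rep(p@theta2, 5) # CW = 2310, PNA = 1: typical values are theta2
  oracle <- aghMarginalOfv(sl$subjects, tv, rep(p@theta1, 5),
                           p@omega2Cl, p@omega2V, p@sigma2Prop)
  expect_lt(abs(got - oracle), 2)
  # the agreement tightens in the near-linear small-variance limit (data
  # generated under the same small variances, so the model fits and the
  # linearization is exact to first order)
  pSmall <- populationParams(p@theta1, p@theta2, p@theta3, p@theta4,
                             1e-4, 1e-4, 1e-4)
  dsS <- tinyDataset(list(c(1, 6, 18), c(0.75, 30), c(3, 11), c(2, 26, 40),
                          c(5, 13)), p = pSmall, seed = 9)
  slS <- cefoneo:::.subjectList(dsS)
  gotS <- conditionalObjective(pSmall, dsS)$ofv
  oracleS <- aghMarginalOfv(slS$subjects, tv, rep(p@theta1, 5),
                            1e-4, 1e-4, 1e-4)
  expect_lt(abs(gotS - oracleS), 0.05)
})

test_that("fitModel recovers generating values at small variability", {
  truth <- populationParams(0.873, 0.0803, 1.68, 0.444,
                            omega2Cl = 0.05^2, omega2V = 0.05^2,
                            sigma2Prop = 0.02^2)
  ds <- richDataset(nSubjects = 30, nObsPer = 10, p = truth, seed = 21)
  fit <- fitModel(ds, settings = fitSettings(computeSe = FALSE))
  expect_true(converged(fit))
  est <- coef(fit)
  expect_equal(est[["theta1"]], 0.873, tolerance = 0.03)
  expect_equal(est[["theta2"]], 0.0803, tolerance = 0.03)
  expect_equal(est[["beta.CL.CW"]], 1.68, tolerance = 0.1)
  expect_equal(est[["beta.CL.PNA"]], 0.444, tolerance = 0.25)
})

test_that("doubling every concentration halves fitted clearance and volume", {
  ds <- studyLikeDataset(seed = 31)
  fit1 <- fitModel(ds, settings = fitSettings(computeSe = FALSE))
  ev <- as.data.frame(ds)
  ev$DV[ev$MDV == 0] <- 2 * ev$DV[ev$MDV == 0]
  fit2 <- fitModel(pkDataset(ev), settings = fitSettings(computeSe = FALSE),
                   start = coef(fit1))
  expect_equal(coef(fit2)[["theta2"]] / coef(fit1)[["theta2"]], 0.5,
               tolerance = 0.02)
  expect_equal(coef(fit2)[["theta1"]] / coef(fit1)[["theta1"]], 0.5,
               tolerance = 0.02)
})

test_that("parameter recovery across replicates of the sparse study design", {
  # median relative bias of the typical values < 10%, of the exponents < 20%
  reps <- 10
  est <- matrix(NA_real_, reps, 4)
  for (r in seq_len(reps)) {
    ds <- studyLikeDataset(seed = 100 + 7 * r)
    fit <- fitModel(ds, settings = fitSettings(computeSe = FALSE))
    est[r, ] <- coef(fit)[c("theta1", "theta2", "beta.CL.CW",
                            "beta.CL.PNA")]
  }
  truth <- c(0.873, 0.0803, 1.68, 0.444)
  relBias <- abs(apply(est, 2, median) - truth) / truth
  expect_lt(relBias[1], 0.10)
  expect_lt(relBias[2], 0.10)
  expect_lt(relBias[3], 0.20)
  expect_lt(relBias[4], 0.20)
})

test_that("empirical Bayes estimates recover eta with rich data and shrink without", {
  p <- cefotaximeParams()
  # rich-data subject with a known eta
  set.seed(77)
  etaTrue <- c(0.25, -0.15)
  ind <- individualParams(p, list(CW = 2310, PNA = 1), etaTrue[1],
                          etaTrue[2])
  doseT <- (0:5) * 12
  # 20 samples spanning the rising limb and washout of repeated intervals,
  # so both clearance and volume are well identified
  tt <- sort(as.numeric(outer(c(0.75, 2, 5, 8, 11), (0:3) * 12, "+")))
  f <- concentration(ind, doseEvents(doseT, rep(115.5, 6), rep(0.5, 6)), tt)
  y <- f * (1 + rnorm(20, 0, 0.05))
  ev <- data.frame(ID = "rich", TIME = c(doseT, tt),
                   AMT = c(rep(115.5, 6), rep(NA, 20)),
                   RATE = c(rep(231, 6), rep(NA, 20)),
                   DV = c(rep(NA, 6), y), MDV = c(rep(1, 6), rep(0, 20)),
                   CW = 2310, BW = 2310, GA = 35.7, PNA = 1, PMA = 35.84)
  pRich <- populationParams(p@theta1, p@theta2, p@theta3, p@theta4,
                            0.04, 0.04, 0.05^2)
  eb <- empiricalBayes(pRich, pkDataset(ev))
  expect_lt(max(abs(eb[1, ] - etaTrue)), 0.05)

  # zero-observation subject: full shrinkage to (0, 0)
  evDoseOnly <- ev[ev$MDV == 1, ]
  eb0 <- empiricalBayes(pRich, pkDataset(evDoseOnly))
  expect_identical(as.numeric(eb0[1, ]), c(0, 0))

  # prior dominance: omega2 -> 0 forces eta -> 0 regardless of the data
  pTight <- populationParams(p@theta1, p@theta2, p@theta3, p@theta4,
                             1e-10, 1e-10, 0.05^2)
  ebT <- empiricalBayes(pTight, pkDataset(ev))
  expect_lt(max(abs(ebT)), 1e-4)
})
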