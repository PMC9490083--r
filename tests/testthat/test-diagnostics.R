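test_that("CWRES match the closed form when variability is pinned to zero", {
  p <- cefotaximeParams()
  # omega2 = 0: the FOCE covariance is diagonal and
  # CWRES = (y - f) / (sigma * f) exactly
  p0 <- populationParams(p@theta1, p@theta2, p@theta3, p@theta4,
                         0, 0, p@sigma2Prop)
  ds <- tinyDataset(list(c(2, 14.5), 26, c(1, 8, 30)), seed = 13)
  cw <- cwres(p0, ds)
  sl <- cefoneo:::.subjectList(ds)
  sg <- sqrt(p@sigma2Prop)
  for (i in seq_along(sl$subjects)) {
    si <- sl$subjects[[i]]
    ind <- individualParams(p0, list(CW = 2310, PNA = 1))
    f <- concentration(ind, doseEvents(si$doseT, si$rate * si$dur, si$dur),
                       si$t)
    ref <- (si$y - f) / (sg * f)
    expect_equal(cw$CWRES[cw$ID == names(sl$subjects)[i]], ref,
                 tolerance = 1e-8)
  }
})

test_that("noise-free observations give zero CWRES", {
  p <- cefotaximeParams()
  exact <- populationParams(p@theta1, p@theta2, p@theta3, p@theta4, 0, 0, 0)
  cohort <- sampleCohort(8, seed = 3)
  ds <- simulateDataset(cohort, exact, designSpec(samplesPerSubject = 3),
                        seed = 4)
  cw <- cwres(p, ds) # evaluator keeps the reference variances
  # the interaction term (residual variance proportional to f^2) shifts
  # the conditional mode away from zero at order sigma2, so noise-free
  # residuals vanish to that order rather than exactly
  expect_lt(max(abs(cw$CWRES)), 0.01)
})

test_that("pooled CWRES of self-simulated data are near N(0, 1)", {
  # pool three replicate datasets (303 residuals) so the moment estimates
  # are tight enough for the stated bands
  cw <- do.call(rbind, lapply(61:63, function(s)
    cwres(cefotaximeParams(), studyLikeDataset(seed = s))))
  expect_equal(nrow(cw), 303)
  # 0.15 is the 99% central null interval for the mean of 303 unit-variance
  # residuals (2.58 / sqrt(303))
  expect_lt(abs(mean(cw$CWRES)), 0.15)
  expect_gt(var(cw$CWRES), 0.8)
  expect_lt(var(cw$CWRES), 1.2)
})

test_that("a bootstrap replicate equal to the original data reproduces the fit", {
  ds <- studyLikeDataset(seed = 63)
  fit <- fitModel(ds, settings = fitSettings(computeSe = FALSE))
  br <- cefoneo:::.bootstrapCore(ds, finalCefotaximeModel(),
                                 idx = list(seq_len(51)),
                                 start = coef(fit),
                                 settings = fitSettings(computeSe = FALSE))
  expect_equal(br@nFailed, 0)
  expect_equal(as.numeric(br@estimates[1, ]), as.numeric(coef(fit)),
               tolerance = 1e-5)
})

test_that("bootstrap intervals widen when the generating variability doubles", {
  p <- cefotaximeParams()
  pWide <- populationParams(p@theta1, p@theta2, p@theta3, p@theta4,
                            2 * p@omega2Cl, 2 * p@omega2V,
                            2 * p@sigma2Prop)
  B <- 25
  widths <- sapply(list(p, pWide), function(gen) {
    cohort <- sampleCohort(cohortSpec(nSubjects = 40), seed = 71)
    ds <- simulateDataset(cohort, gen, designSpec(), seed = 72)
    fit <- fitModel(ds, settings = fitSettings(computeSe = FALSE))
    bs <- bootstrapFit(ds, finalCefotaximeModel(), B = B, seed = 73,
                       start = coef(fit))
    s <- bs@summary
    s$p95[s$parameter == "theta2"] - s$p5[s$parameter == "theta2"]
  })
  expect_gt(widths[2], widths[1])
})

test_that("NPDE is N(0,1)-like under the generating model and shifts under misspecification", {
  ds <- studyLikeDataset(seed = 81)
  p <- cefotaximeParams()
  np <- npde(p, ds, K = 500, seed = 82)
  expect_equal(length(np@npde), 101)
  expect_lt(abs(np@mean), 0.15)
  expect_equal(np@variance, 1, tolerance = 0.15)

  # doubling the evaluator's volume biases predictions low early and the
  # pooled NPDE mean away from zero
  pBad <- populationParams(2 * p@theta1, p@theta2, p@theta3, p@theta4,
                           p@omega2Cl, p@omega2V, p@sigma2Prop)
  npBad <- npde(pBad, ds, K = 500, seed = 82)
  expect_gt(abs(npBad@mean), 0.3)

  expect_error(npde(p, ds, K = 50), "at least 100")
})

test_that("NPDE is deterministic for a fixed seed", {
  ds <- studyLikeDataset(seed = 83)
  p <- cefotaximeParams()
  a <- npde(p, ds, K = 120, seed = 9)
  b <- npde(p, ds, K = 120, seed = 9)
  expect_identical(a@npde, b@npde)
})

test_that("prediction correction is the identity when all predictions agree", {
  # identical subjects sampled at identical times: PRED constant per bin
  ds <- tinyDataset(list(c(2, 6), c(2, 6), c(2, 6), c(2, 6)), seed = 15)
  vp <- pcvpc(cefotaximeParams(), ds, nSim = 100, bins = 2, seed = 16)
  obs <- as.data.frame(ds)
  obs <- obs$DV[obs$MDV == 0]
  early <- sort(obs[rep(c(TRUE, FALSE), 4)])
  expect_equal(vp@bins$obs50[1], median(early), tolerance = 1e-10)
})

test_that("pcVPC covers self-simulated data and flags a shifted dataset", {
  ds <- studyLikeDataset(seed = 85)
  p <- cefotaximeParams()
  vp <- pcvpc(p, ds, nSim = 400, bins = 10, seed = 86)
  inEnv <- with(vp@bins, obs50 >= lo50 & obs50 <= hi50)
  expect_gte(sum(inEnv), 9)

  shifted <- as.data.frame(ds)
  shifted$DV[shifted$MDV == 0] <- 2 * shifted$DV[shifted$MDV == 0]
  vp2 <- pcvpc(p, pkDataset(shifted), nSim = 400, bins = 10, seed = 86)
  outEnv <- with(vp2@bins, obs50 < lo50 | obs50 > hi50)
  expect_gt(sum(outEnv), 5)
})
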