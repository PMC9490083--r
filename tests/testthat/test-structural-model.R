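refP <- cefotaximeParams()

test_that("typical-value algebra matches the reference estimates", {
  expect_equal(individualClearance(refP, list(CW = 2310, PNA = 1)), 0.0803)
  expect_equal(individualVolume(refP), 0.873)
  # direct hand evaluation of the power law at the smallest study weight
  expect_equal(individualClearance(refP, list(CW = 1220, PNA = 1)),
               0.0803 * (1220 / 2310)^1.68, tolerance = 1e-12)
  expect_equal(individualClearance(refP, list(CW = 1220, PNA = 1)),
               0.02747, tolerance = 1e-3)
})

test_that("random effects act exponentially and weight scaling is homogeneous", {
  cov <- list(CW = 2310, PNA = 1)
  expect_equal(individualClearance(refP, cov, log(2)),
               2 * individualClearance(refP, cov))
  expect_equal(individualVolume(refP, log(1.5)) / individualVolume(refP), 1.5)
  expect_equal(
    individualClearance(refP, list(CW = 2 * 2310, PNA = 1)) /
      individualClearance(refP, cov),
    2^refP@theta3)
  expect_error(individualClearance(refP, list(CW = -1, PNA = 1)), "positive")
})

test_that("sampled volumes are log-normal around the typical value", {
  set.seed(1)
  eta <- rnorm(1e5, 0, sqrt(refP@omega2V))
  v <- individualVolume(refP, eta)
  expect_equal(mean(log(v)), log(0.873), tolerance = 1e-2)
  expect_equal(sd(log(v)), 0.211, tolerance = 1e-2)
})

test_that("concentration honors superposition boundary behavior", {
  ind <- individualParams(refP, list(CW = 2310, PNA = 1))
  d <- doseEvents(0, 115.5, 0.5)
  expect_equal(concentration(ind, d, 0), 0)
  # never-ending infusion approaches R/CL
  dinf <- doseEvents(0, 231 * 5000, 5000)
  expect_equal(concentration(ind, dinf, 4999), 231 / ind$CL,
               tolerance = 1e-6)
  # monotone decline on any interval with no active infusion
  tt <- seq(0.6, 11.9, by = 0.1)
  cc <- concentration(ind, d, tt)
  expect_true(all(diff(cc) < 0))
  # dose linearity
  d3 <- doseEvents(c(0, 12), c(100, 100), c(0.5, 0.5))
  d3x <- doseEvents(c(0, 12), 3 * c(100, 100), c(0.5, 0.5))
  expect_equal(concentration(ind, d3x, c(5, 13, 20)),
               3 * concentration(ind, d3, c(5, 13, 20)))
})

test_that("closed form agrees with numeric ODE integration to <0.1%", {
  skip_if_not_installed("deSolve")
  set.seed(7)
  for (k in 1:25) {
    CL <- runif(1, 0.02, 0.3)
    V <- runif(1, 0.3, 1.5)
    nd <- sample(1:5, 1)
    doses <- doseEvents(time = sort(runif(nd, 0, 48)),
                        amount = runif(nd, 30, 250),
                        duration = runif(nd, 0.25, 2))
    tout <- sort(runif(40, 0.1, 60))
    ref <- odeConcentration(CL, V, doses, tout)
    got <- concentration(list(CL = CL, V = V, ke = CL / V), doses, tout)
    keep <- ref > 1e-6
    expect_lt(max(abs(got[keep] - ref[keep]) / ref[keep]), 1e-3)
  }
})

test_that("steady-state accumulation matches the closed-form factor and superposition", {
  ind <- individualParams(refP, list(CW = 2310, PNA = 1))
  reg <- regimenSpec() # 50 mg/kg q12h, 0.5 h infusion
  # accumulation factor 1/(1 - exp(-ke tau)) at the reference ke
  expect_equal(1 / (1 - exp(-ind$ke * 12)), 1.496, tolerance = 1e-3)
  # post-infusion steady state = single dose x accumulation factor
  single <- concentration(ind, doseEvents(0, 115.5, 0.5), 8.4)
  expect_equal(steadyStateConcentration(ind, reg, 8.4, cw = 2310),
               single / (1 - exp(-ind$ke * 12)), tolerance = 1e-10)
  expect_equal(steadyStateConcentration(ind, reg, 8.4, cw = 2310), 93.5,
               tolerance = 1e-3)
  # agreement with explicit superposition at dose 15, during and after
  # the infusion
  nDoses <- 15
  d <- doseEvents((0:(nDoses - 1)) * 12, rep(115.5, nDoses),
                  rep(0.5, nDoses))
  for (tw in c(0.25, 1, 8.4, 11.5)) {
    expect_equal(steadyStateConcentration(ind, reg, tw, cw = 2310),
                 concentration(ind, d, (nDoses - 1) * 12 + tw),
                 tolerance = 1e-3)
  }
  # huge ke * tau: accumulation factor collapses to 1
  fast <- list(CL = 5, V = 0.5, ke = 10)
  expect_equal(steadyStateConcentration(fast, reg, 8, cw = 2310),
               concentration(fast, doseEvents(0, 115.5, 0.5), 8),
               tolerance = 1e-8)
  expect_error(steadyStateConcentration(ind, regimenSpec(tau = 0.4,
                                                         duration = 0.5),
                                        0.2, 2310))
})
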