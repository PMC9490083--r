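test_that("likelihood-ratio thresholds are the chi-square quantiles", {
  expect_equal(lrtThreshold(0.05, 1), 3.84, tolerance = 1e-3)
  expect_equal(lrtThreshold(0.01, 1), 6.635, tolerance = 1e-4)
  expect_equal(lrtThreshold(0.999, 1), 0, tolerance = 1e-4)
  expect_gt(lrtThreshold(0.05, 2), lrtThreshold(0.05, 1))
  expect_error(lrtThreshold(1.2), "alpha")
})

test_that("search trace decisions replay from the recorded OFVs and thresholds", {
  ds <- studyLikeDataset(seed = 41)
  tr <- covariateSearch(ds)
  st <- tr@steps
  tested <- st[st$decision %in% c("significant", "not significant"), ]
  expect_true(all((tested$deltaOfv > tested$threshold) ==
                    (tested$decision == "significant")))
  # backward rows log the OFV rise on deletion as deltaOfv
  bw <- st[st$decision %in% c("retained", "removable"), ]
  expect_true(all((bw$deltaOfv > bw$threshold) == (bw$decision == "retained")))
})

test_that("search on study-like data retains current weight and postnatal age", {
  ds <- studyLikeDataset(seed = 41)
  tr <- covariateSearch(ds)
  final <- tr@finalModel
  expect_setequal(final@clTerms$cov, c("CW", "PNA"))
  expect_equal(nrow(final@vTerms), 0)
})

test_that("forward selection with no candidates returns the base model", {
  ds <- studyLikeDataset(seed = 41)
  none <- defaultCandidates(ds)[0, ]
  tr <- forwardSelection(ds, candidates = none)
  expect_equal(nrow(tr@steps), 0)
  expect_equal(nrow(tr@finalModel@clTerms), 0)
})

test_that("backward elimination drops a spurious term and is the identity without terms", {
  ds <- studyLikeDataset(seed = 43)
  # full model with a spurious GA effect on V (no such effect generated)
  full <- finalCefotaximeModel()
  full@vTerms <- covariateTerm("GA", 35.7, init = 0.3)
  tr <- backwardElimination(ds, full)
  expect_false("GA" %in% tr@finalModel@vTerms$cov)
  expect_setequal(tr@finalModel@clTerms$cov, c("CW", "PNA"))

  # no covariates: nothing to eliminate
  tr0 <- backwardElimination(ds, baseModel())
  expect_equal(nrow(tr0@steps), 0)
})

test_that("null-effect data keep the base model at rates consistent with the levels", {
  nullP <- populationParams(0.873, 0.0803, 0, 0, omega2Cl = 0.04,
                            omega2V = 0.211^2, sigma2Prop = 0.142^2)
  reps <- 12
  emptyForward <- 0
  baseFinal <- 0
  for (r in seq_len(reps)) {
    cohort <- sampleCohort(cohortSpec(nSubjects = 51), seed = 300 + r)
    ds <- simulateDataset(cohort, nullP,
                          designSpec(totalObservations = 101),
                          seed = 400 + r)
    tr <- suppressWarnings(covariateSearch(ds))
    fw <- tr@steps[tr@steps$decision == "included", ]
    if (nrow(fw) == 0) emptyForward <- emptyForward + 1
    if (nrow(tr@finalModel@clTerms) == 0 && nrow(tr@finalModel@vTerms) == 0)
      baseFinal <- baseFinal + 1
  }
  # with 5 correlated candidates at alpha 0.05 the no-inclusion probability
  # is at least ~0.75, and backward elimination at 0.01 restores the base
  # model in ~95% of replicates; binomial bounds at reps = 12
  expect_gte(emptyForward, 7)
  expect_gte(baseFinal, 10)
})

test_that("estimated allometry outperforms the fixed exponent when growth is steeper", {
  ds <- studyLikeDataset(seed = 47) # generated with exponent 1.68
  cmp <- compareAllometricForms(ds)
  expect_gt(cmp$deltaEstimated, cmp$deltaFixed)
  expect_gt(cmp$deltaEstimated, lrtThreshold(0.05, 1))

  # generated at exactly 0.75 the two forms are statistically equivalent
  p075 <- populationParams(0.873, 0.0803, 0.75, 0, omega2Cl = 0.04,
                           omega2V = 0.211^2, sigma2Prop = 0.142^2)
  cohort <- sampleCohort(cohortSpec(nSubjects = 51), seed = 53)
  ds075 <- simulateDataset(cohort, p075,
                           designSpec(totalObservations = 101), seed = 54)
  cmp075 <- compareAllometricForms(ds075)
  expect_lt(cmp075$deltaEstimated - cmp075$deltaFixed, lrtThreshold(0.05, 1))

  # degenerate with a single subject
  one <- ds[1]
  expect_error(compareAllometricForms(one), "fewer than 2 subjects")
})
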