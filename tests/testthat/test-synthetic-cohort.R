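# Synthetic cohort generator: schema validity, determinism, calibration.

test_that("generated cohorts are schema-valid and deterministic", {
  cfg <- cohortConfig(n = 1000, seed = 7)
  pairs <- syntheticPairs(cfg)
  expect_equal(nrow(pairs), 1000)
  expect_true(all(pairs[["A-R"]] >= 18 & pairs[["A-R"]] <= 83, na.rm = TRUE))
  expect_silent(validatePairs(pairs))
  expect_identical(pairs, syntheticPairs(cfg))          # same seed, same cohort
  # no missingness when the rate is zero
  expect_false(anyNA(syntheticPairs(cohortConfig(n = 200, seed = 7,
                                                 missingRate = 0))))
})

test_that("missingness uses its own substream and never perturbs values", {
  a <- syntheticPairs(cohortConfig(n = 300, seed = 5, missingRate = 0))
  b <- syntheticPairs(cohortConfig(n = 300, seed = 5, missingRate = 0.10))
  for (f in schemaFields()) {
    obs <- !is.na(b[[f]])
    expect_identical(b[[f]][obs], a[[f]][obs])
  }
  expect_gt(mean(is.na(as.matrix(b))), 0.05)
  # rates above the schema screening cap are rejected
  expect_error(cohortConfig(n = 10, seed = 1, missingRate = 0.5), "0.10")
})

test_that("intercept calibration hits the target mean probability", {
  pairs <- tinyCohort(n = 2000, seed = 3)
  model <- loadPublishedModel()
  for (tgt in c(survivalPrevalence("5Y"), survivalPrevalence("3M"))) {
    b <- calibrateIntercept(pairs, model, target = tgt)
    expect_equal(mean(groundTruthProbabilities(pairs, model, intercept = b)),
                 tgt, tolerance = 0.005)
  }
  # symmetric case: all-zero weights need intercept 0 to reach 0.5
  zero <- new("LogisticModel",
              weights = setNames(rep(0, 49), canonicalFeatureNames()),
              intercept = 0, scaling = identityScaling())
  expect_equal(calibrateIntercept(pairs, zero, target = 0.5), 0,
               tolerance = 1e-6)
  expect_error(calibrateIntercept(pairs, model, target = 1.5))
})

test_that("Bernoulli labels follow the ground-truth probabilities", {
  expect_identical(generateLabels(rep(1, 50), seed = 1), rep(1L, 50))
  expect_identical(generateLabels(rep(0, 50), seed = 1), rep(0L, 50))
  # law of large numbers at n = 50,000: prevalence within 3 binomial SEs
  co <- generateCohort(cohortConfig(n = 50000, seed = 21, missingRate = 0),
                       endpoint = "5Y")
  tgt <- survivalPrevalence("5Y")
  se <- sqrt(tgt * (1 - tgt) / 50000)
  expect_lt(abs(mean(co$labels) - tgt), 3 * se + 0.005)
})

test_that("longer waiting-list time lowers ground-truth survival", {
  co <- generateCohort(cohortConfig(n = 5000, seed = 11, missingRate = 0))
  dw <- co$complete[["DW-R"]]
  longWait <- dw > median(dw)
  expect_lt(mean(co$probs[longWait]), mean(co$probs[!longWait]))
})

test_that("cohort CSV dialect round-trips exactly and records provenance", {
  co <- generateCohort(cohortConfig(n = 100, seed = 13), endpoint = "2Y")
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeCohortCSV(co$pairs, tmp, outcomes = co$outcomes,
                 provenance = list(seed = 13))
  back <- readCohortCSV(tmp)
  expect_identical(back[, schemaFields()], co$pairs)
  expect_identical(back$failure_day, co$outcomes$failure_day)
  prov <- jsonlite::read_json(paste0(tmp, ".provenance.json"))
  expect_equal(prov$seed, 13)
  expect_true(nzchar(prov$configHash))
  # outcome times are consistent with the generated labels
  lab <- labelEndpoint(back$failure_day, back$followup_day,
                       back$unrelated_death, endPoint("2Y"))
  expect_identical(as.integer(lab == "survival"), co$labels)
})
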