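# D-R data model: validation, one-hot encoding, imputation, end-point labels.

test_that("encoding a complete pair yields the canonical 49-component vector", {
  x <- encodePair(completePair(), identityScaling())
  expect_length(x, 49L)
  expect_identical(names(x), canonicalFeatureNames())
  # every one-hot block sums to exactly 1
  for (f in schemaFields("nominal")) {
    lv <- loadSchema()[[f]]$levels
    expect_equal(sum(x[paste0(f, "(", lv, ")")]), 1)
  }
  # binary components are 0/1
  binComp <- intersect(canonicalFeatureNames(), schemaFields("binary"))
  expect_true(all(x[binComp] %in% c(0, 1)))
})

test_that("one-hot indicators and binary pass-through behave as identities", {
  x <- encodePair(completePair(list(`DI-R` = 0, `N-D` = 1)), identityScaling())
  expect_equal(unname(x["DI-R(0)"]), 1)
  expect_equal(unname(x[paste0("DI-R(", 1:5, ")")]), rep(0, 5))
  expect_equal(unname(x["N-D"]), 1)
  # numeric fields are shifted and scaled by the supplied statistics
  sc <- new("ScalingStats",
            location = setNames(c(20, 0, 0, 0, 0, 0, 0, 0),
                                schemaFields("numeric")),
            scale = setNames(c(10, 1, 1, 1, 1, 1, 1, 1),
                             schemaFields("numeric")))
  x2 <- encodePair(completePair(list(`A-R` = 30)), sc)
  expect_equal(unname(x2["A-R"]), 1)   # (30 - 20) / 10
})

test_that("one-hot decoding recovers the original category codes", {
  pairs <- tinyCohort(n = 40, seed = 9)
  x <- encodeCohort(pairs, identityScaling())
  for (i in sample(nrow(pairs), 10)) {
    codes <- decodeOneHot(x[i, ])
    for (f in names(codes)) expect_equal(unname(codes[f]), pairs[[f]][i])
  }
})

test_that("schema violations raise errors naming the field and value", {
  expect_error(encodePair(completePair(list(`DI-R` = 9))), "DI-R.*9")
  expect_error(validatePairs(completePair(list(`ME-R` = 100))), "ME-R")
  expect_error(encodePair(completePair(list(`ME-R` = NA))), "impute first")
  noCol <- completePair(); noCol[["G-T"]] <- NULL
  expect_error(validatePairs(noCol), "G-T")
})

test_that("imputer fills with training mean (numeric) and mode (categorical)", {
  pairs <- do.call(rbind, lapply(1:4, function(i) completePair()))
  pairs[["ME-R"]] <- c(10, 20, 30, NA)       # mean of observed = 20
  pairs[["T-R"]] <- c(0, 0, 1, NA)           # mode = 0
  pairs[["DI-R"]] <- c(2, 2, 3, 3)           # tie -> smallest code
  stats <- fitImputer(pairs)
  expect_equal(stats@fills[["ME-R"]], 20)
  expect_equal(stats@fills[["T-R"]], 0)
  expect_equal(stats@fills[["DI-R"]], 2)
  filled <- applyImputer(pairs, stats)
  expect_false(anyNA(filled))
  expect_equal(filled[["ME-R"]][4], 20)
  # observed values unchanged; complete input is returned identically
  expect_equal(filled[["ME-R"]][1:3], c(10, 20, 30))
  expect_identical(applyImputer(filled, stats), filled)
  # a fully unobserved field cannot be imputed
  pairs[["CR-D"]] <- NA_real_
  expect_error(fitImputer(pairs), "CR-D")
})

test_that("imputation statistics come from the training split only", {
  train <- tinyCohort(n = 30, seed = 2)
  test <- tinyCohort(n = 10, seed = 3)
  test[["ME-R"]][1] <- NA
  stats <- fitImputer(train)
  # the fill equals the training mean regardless of what the test fold holds
  expect_equal(stats@fills[["ME-R"]], mean(train[["ME-R"]]))
  filled <- applyImputer(test, stats)
  expect_equal(filled[["ME-R"]][1], mean(train[["ME-R"]]))
})

test_that("end-point labelling applies the censoring and exclusion rules", {
  ep3m <- endPoint("3M"); ep1y <- endPoint("1Y")
  expect_equal(as.character(labelEndpoint(60, 60, 0, ep3m)), "non-survival")
  expect_equal(as.character(labelEndpoint(400, 400, 0, ep1y)), "survival")
  expect_equal(as.character(labelEndpoint(NA, 200, 0, ep1y)), "excluded")
  expect_equal(as.character(labelEndpoint(NA, 400, 1, ep1y)), "excluded")
  expect_error(labelEndpoint(-5, 10, 0, ep1y), "negative")
  expect_error(labelEndpoint(300, 200, 0, ep1y), "follow-up")
  # horizons follow the calendar convention and are overridable
  expect_equal(endPoint("5Y")@horizon, 1825)
  expect_equal(endPoint("3M", horizon = 92)@horizon, 92)
})

test_that("end-point labels are monotone and partition the cohort", {
  eps <- lapply(c("3M", "1Y", "2Y", "5Y"), endPoint)
  set.seed(4)
  failure <- ifelse(runif(200) < 0.4, ceiling(runif(200, 0, 2000)), NA)
  followup <- ifelse(is.na(failure), ceiling(runif(200, 0, 2200)), failure)
  labs <- lapply(eps, function(ep) labelEndpoint(failure, followup, 0, ep))
  for (l in labs) {
    n <- table(l)
    expect_equal(sum(n[c("survival", "non-survival")]), 200 - n[["excluded"]])
  }
  # non-survival at an early horizon stays non-survival at every later one
  early <- labs[[1]] == "non-survival"
  for (l in labs[-1]) expect_true(all(l[early] == "non-survival"))
})
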