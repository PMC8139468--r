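# Published logistic model, probability predictions, L1 fitting, harness.

test_that("the packaged model matches the published coefficients", {
  m <- loadPublishedModel()
  w <- coef(m)
  expect_length(w, 49L)
  expect_equal(unname(w["ME-R"]), -1.450)
  expect_equal(unname(w["C-D"]), 0.012)
  expect_equal(names(w)[49], "C-D")                     # lowest rank
  expect_equal(names(w)[1], "DW-R")                     # top-ranked variable
  expect_equal(unname(w["DW-R"]), -1.916)
  # re-ranking by |weight| reproduces the frozen order
  expect_equal(rank(-abs(w), ties.method = "first"), seq_len(49),
               ignore_attr = TRUE)
  tab <- publishedWeightTable()
  expect_identical(tab$name, names(w))
})

test_that("the unpublished intercept and scaling are explicit knobs", {
  expect_equal(loadPublishedModel()@intercept, 0)
  expect_equal(loadPublishedModel(intercept = -0.7)@intercept, -0.7)
  expect_error(loadPublishedModel(scaling = "identity"), "refused")
  m <- loadPublishedModel(scaling = "identity", force = TRUE)
  expect_true(all(m@scaling@scale == 1))
})

test_that("predictProbability is the sigmoid of the linear predictor", {
  m0 <- new("LogisticModel",
            weights = setNames(rep(0, 49), canonicalFeatureNames()),
            intercept = 0, scaling = identityScaling())
  expect_equal(predictProbability(m0, rep(0, 49)), 0.5)
  toy <- new("LogisticModel", weights = c(a = 1, b = -1), intercept = 0,
             scaling = identityScaling(character(0)))
  expect_equal(predictProbability(toy, c(a = 2, b = 1)), plogis(1))
  expect_equal(predictProbability(toy, c(a = 2, b = 1)), 0.7311,
               tolerance = 1e-4)
  expect_error(predictProbability(toy, c(1, 2, 3)), "dimension")
})

test_that("probabilities move monotonically with each coefficient's sign", {
  m <- loadPublishedModel()
  x <- encodePair(completePair(), m@scaling)
  p0 <- predictProbability(m, x)
  for (j in c(1, 2, 9, 22, 49)) {       # mix of negative and positive weights
    x2 <- x; x2[j] <- x2[j] + 0.5
    expect_equal(sign(predictProbability(m, x2) - p0),
                 unname(sign(coef(m)[j])))
  }
  # raising waiting-list days lowers survival on the data-frame route too
  pShort <- predictProbability(m, completePair(list(`DW-R` = 100)))
  pLong <- predictProbability(m, completePair(list(`DW-R` = 2000)))
  expect_lt(pLong, pShort)
})

test_that("scaling commutes with encoding for numeric fields", {
  pairs <- tinyCohort(n = 30, seed = 8)
  sc <- fitScaling(pairs)
  a <- encodeCohort(pairs, sc)
  b <- encodeCohort(pairs, identityScaling())
  for (f in schemaFields("numeric"))
    expect_equal(a[, f], (b[, f] - sc@location[[f]]) / sc@scale[[f]])
})

test_that("L1 logistic fits honour the inverse-regularisation convention", {
  set.seed(1)
  n <- 200
  x <- cbind(f1 = rnorm(n), f2 = rnorm(n))
  y <- as.integer(x[, 1] > 0)                       # separable on f1
  strong <- fitL1Logistic(x, y, C = 1e4)
  expect_equal(mean((predictProbability(strong, x) >= 0.5) == y), 1)
  # C -> 0+ shrinks all weights away and predictions collapse to prevalence
  weak <- fitL1Logistic(x, y, C = 1e-6)
  expect_true(all(coef(weak) == 0))
  expect_equal(unique(round(predictProbability(weak, x), 6)),
               round(mean(y), 6))
  expect_error(fitL1Logistic(x, rep(1, n), C = 1), "single class")
})

test_that("the harness enumerates the packaged grids", {
  expect_equal(nrow(enumerateGrid(classifierSpec("kNN"))), 4)     # k 2..5
  expect_equal(nrow(enumerateGrid(classifierSpec("RF"))), 3 * 2 * 5 * 8)
  expect_equal(nrow(enumerateGrid(classifierSpec("LR"))), 9)
  expect_equal(nrow(enumerateGrid(classifierSpec("NB"))), 1)      # no params
  expect_length(defaultGrid("NB"), 0)
  expect_error(classifierSpec("ANN"), "valid methods")
})

test_that("trainWithSpec matches the LR contract and warns off-grid", {
  co <- generateCohort(cohortConfig(n = 300, seed = 6, missingRate = 0))
  x <- encodeCohort(co$complete, fitScaling(co$complete))
  direct <- fitL1Logistic(x, co$labels, C = 1)
  viaSpec <- trainWithSpec(classifierSpec("LR"), x, co$labels,
                           params = list(C = 1))
  expect_equal(predictProb(viaSpec, x), predictProbability(direct, x))
  expect_warning(
    trainWithSpec(classifierSpec("LR"), x, co$labels, params = list(C = 7)),
    "outside the packaged grid")
  # a second backend honours the same contract
  skip_if_not_installed("e1071")
  nb <- trainWithSpec(classifierSpec("NB"), x, co$labels)
  p <- predictProb(nb, x)
  expect_length(p, nrow(x))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("fitting on simulated data recovers the generating weights", {
  co <- generateCohort(cohortConfig(n = 20000, seed = 17, missingRate = 0))
  x <- encodeCohort(co$complete, fitScaling(co$complete))
  fit <- fitL1Logistic(x, co$labels, C = 100)
  true <- coef(loadPublishedModel())
  top10 <- names(true)[1:10]
  expect_identical(sign(coef(fit)[top10]), sign(true[top10]))
})
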