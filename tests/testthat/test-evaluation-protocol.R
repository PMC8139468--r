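# Metrics and the nested cross-validation benchmark.

test_that("Minimum Sensitivity is the smaller per-class recall", {
  expect_equal(minimumSensitivity(confusionMatrix(50, 0, 0, 50)), 1)
  # trivial all-survival classifier on imbalanced data
  triv <- confusionFromScores(c(rep(1, 90), rep(0, 10)), rep(1, 100))
  expect_equal(minimumSensitivity(triv), 0)
  expect_gt(accuracy(triv), 0.85)
  expect_equal(minimumSensitivity(confusionMatrix(30, 70, 10, 90)), 0.30)
  expect_error(minimumSensitivity(confusionMatrix(0, 0, 10, 90)), "survival")
  expect_error(minimumSensitivity(confusionMatrix(10, 90, 0, 0)),
               "non-survival")
})

test_that("MS <= Acc <= max sensitivity on random confusion matrices", {
  set.seed(31)
  for (i in 1:1000) {
    cm <- randomCM()
    sens <- cm@tp / (cm@tp + cm@fn)
    spec <- cm@tn / (cm@tn + cm@fp)
    expect_lte(minimumSensitivity(cm), accuracy(cm) + 1e-12)
    expect_lte(accuracy(cm), max(sens, spec) + 1e-12)
  }
})

test_that("AUC is the Mann-Whitney statistic", {
  expect_equal(aucScore(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(aucScore(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1)), 0)
  expect_equal(aucScore(c(0.5, 0.5), c(1, 0)), 0.5)     # ties count one half
  expect_error(aucScore(1:5, rep(1, 5)), "both classes")
  # null distribution: scores independent of labels concentrate at 1/2
  set.seed(12)
  s <- runif(10000); l <- rbinom(10000, 1, 0.5)
  se <- sqrt((10000 + 1) / (12 * sum(l == 1) * sum(l == 0)))
  expect_lt(abs(aucScore(s, l) - 0.5), 3 * se)
})

test_that("AUC is invariant under monotone transforms and matches pROC", {
  set.seed(8)
  s <- runif(500); l <- rbinom(500, 1, 0.4)
  a <- aucScore(s, l)
  expect_equal(aucScore(qlogis(s), l), a)
  expect_equal(aucScore(s^3, l), a)
  skip_if_not_installed("pROC")
  expect_equal(a, as.numeric(pROC::auc(pROC::roc(
    l, s, quiet = TRUE, direction = "<", levels = c(0, 1)))))
})

test_that("stratified folds preserve prevalence and reject empty classes", {
  y <- c(rep(1L, 80), rep(0L, 20))
  fold <- stratifiedFolds(y, 10, seed = 3)
  for (j in 1:10) expect_equal(sum(y[fold == j] == 0), 2)
  # 4 minority cases cannot stratify into 10 folds without empty classes
  expect_error(stratifiedFolds(c(rep(1L, 96), rep(0L, 4)), 10, seed = 3),
               "single class")
})

test_that("nested CV conserves the cohort and selects within the grid", {
  co <- generateCohort(cohortConfig(n = 400, seed = 19, missingRate = 0.02))
  plan <- cvPlan(classifierSpec("LR", grid = list(C = c(0.01, 1))),
                 outerFolds = 5, innerFolds = 3, seed = 19)
  res <- runNestedCV(co$pairs, co$labels, plan)
  expect_equal(length(res$pooled), 400)                   # partition conservation
  expect_length(res$perFold, 5)
  for (p in res$selected) expect_true(p$C %in% c(0.01, 1))
  for (r in res$perFold)
    expect_lte(minimumSensitivity(r), accuracy(r) + 1e-12)
  # a single-configuration grid is selected trivially
  plan1 <- cvPlan(classifierSpec("LR", grid = list(C = 1)),
                  outerFolds = 4, innerFolds = 3, seed = 7)
  res1 <- runNestedCV(co$pairs, co$labels, plan1)
  expect_true(all(vapply(res1$selected, function(p) p$C == 1, logical(1))))
})

test_that("seeded benchmark runs are reproducible end to end", {
  co <- generateCohort(cohortConfig(n = 300, seed = 23, missingRate = 0))
  plan <- cvPlan(classifierSpec("LR", grid = list(C = c(0.1, 1))),
                 outerFolds = 4, innerFolds = 3, seed = 23)
  r1 <- runNestedCV(co$pairs, co$labels, plan)
  r2 <- runNestedCV(co$pairs, co$labels, plan)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$foldAssign, r2$foldAssign)
  expect_identical(chosenRecipients(allocateMatrix(fixtureScenario("mediumMELD"))),
                   chosenRecipients(allocateMatrix(fixtureScenario("mediumMELD"))))
})

test_that("rankSummary marks best and second with deterministic ties", {
  one <- rankSummary(list(LR = c(Acc = 0.6, MS = 0.55, AUC = 0.65)))
  expect_equal(one$rank_AUC, "best")
  two <- rankSummary(list(NB = c(Acc = 0.5, MS = 0.4, AUC = 0.60),
                          LR = c(Acc = 0.6, MS = 0.5, AUC = 0.60)))
  expect_equal(two$method[two$rank_AUC == "best"], "LR")  # alphabetical tie
  expect_true("AUC" %in% attr(two, "ties"))
  eight <- rankSummary(setNames(
    lapply(1:8, function(i) c(Acc = 0.5 + i / 100, MS = 0.4, AUC = 0.6)),
    c("C4.5", "GB", "LR", "MLP", "NB", "RF", "SVM", "kNN")))
  expect_equal(nrow(eight), 8)
  expect_equal(sum(eight$rank_Acc == "best"), 1)
  expect_equal(sum(eight$rank_Acc == "second"), 1)
})
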