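# Rule-based allocation: candidate sets, fallback chain, simulations.

d1 <- c(0.379, 0.293, 0.410, 0.411, 0.522)   # first-simulation donor column
meld6 <- c(27, 26, 25, 24, 23)

test_that("candidate sets contain everyone within tau of the maximum", {
  expect_equal(candidateSet(d1, tau = 0.14), c(3, 4, 5))
  expect_equal(candidateSet(0.7, tau = 0.14), 1)
  expect_equal(candidateSet(d1, tau = 1), 1:5)
  expect_error(candidateSet(numeric(0)), "empty")
  # the boundary is inclusive: a difference of exactly tau stays in
  expect_true(2 %in% candidateSet(c(0.675, 0.535), tau = 0.14))
})

test_that("allocation walks the probability -> MELD -> waiting-time chain", {
  res <- allocate(d1, meld6, rep(0, 5), allocationConfig(tau = 0.14))
  expect_equal(res$chosen, 3)
  expect_equal(res$stage, "MELD")
  # threshold boundary case from the extended-criteria simulation
  res8 <- allocate(c(0.497, 0.535, 0.528, 0.553, 0.675),
                   c(36, 28, 25, 23, 21), rep(0, 5))
  expect_equal(res8$chosen, 2)
  # equal probabilities everywhere degenerate to the pure MELD rule
  resM <- allocate(rep(0.5, 5), meld6, rep(0, 5))
  expect_equal(resM$chosen, 1)
  expect_equal(resM$stage, "MELD")
  # MELD tie resolved by waiting time
  resW <- allocate(c(0.245, 0.334, 0.356, 0.491, 0.497),
                   c(40, 39, 38, 35, 35), c(50, 120, 200, 310, 460))
  expect_equal(resW$chosen, 5)
  expect_equal(resW$stage, "waiting-time")
  # full tie falls back to the lowest index and is flagged
  resT <- allocate(rep(0.4, 3), rep(20, 3), rep(10, 3))
  expect_equal(resT$chosen, 1)
  expect_equal(resT$stage, "index-fallback")
  expect_error(allocate(d1, meld6[1:3], rep(0, 5)), "per recipient")
})

test_that("all three packaged simulations reproduce their printed rows", {
  printed <- printedAllocations()
  for (tab in names(printed)) {
    res <- allocateMatrix(fixtureScenario(tab))
    expect_equal(unname(chosenRecipients(res)), printed[[tab]],
                 info = tab)
    expect_true(all(vapply(seq_along(res@chosen), function(j)
      res@chosen[j] %in% res@candidates[[j]], logical(1))))
  }
  # a donor whose best match dominates is decided by the model alone
  t8 <- allocateMatrix(fixtureScenario("ecd"))
  expect_equal(unname(decisionStages(t8)["D7"]), "probability-dominance")
})

test_that("sigma threshold follows the chosen variance convention", {
  expect_equal(sigmaThreshold(rep(0.3, 10)), 0)
  expect_equal(sigmaThreshold(c(0, 1)), 0.5)
  expect_equal(sigmaThreshold(c(0, 1), population = FALSE), sd(c(0, 1)))
  expect_error(sigmaThreshold(0.4), "at least 2")
  # two-pass oracle on a large sample
  set.seed(40)
  p <- runif(10000)
  mu <- sum(p) / length(p)
  twoPass <- sqrt(sum((p - mu)^2) / length(p))
  expect_equal(sigmaThreshold(p), twoPass)
})

test_that("candidate sets grow with tau and tau extremes match known policies", {
  set.seed(50)
  for (i in 1:50) {
    p <- round(runif(6), 3)
    meld <- sample(6:40, 6)
    prev <- candidateSet(p, 0)
    for (tau in seq(0.05, 1, by = 0.05)) {
      cur <- candidateSet(p, tau)
      expect_true(all(prev %in% cur))
      prev <- cur
    }
    # tau = 0: argmax by probability (MELD only among exact ties)
    expect_equal(candidateSet(p, 0), which(p == max(p)))
    # tau = 1: everyone is a candidate, so the highest MELD wins outright
    res <- allocate(p, meld, rep(0, 6), allocationConfig(tau = 1))
    expect_equal(res$chosen, which.max(meld))
  }
})

test_that("allocation is invariant to a constant shift of a column", {
  set.seed(60)
  for (i in 1:20) {
    p <- runif(5, 0.2, 0.7)
    meld <- sample(6:40, 5)
    wait <- sample(0:500, 5)
    a <- allocate(p, meld, wait)
    b <- allocate(p + 0.2, meld, wait)
    expect_equal(a$chosen, b$chosen)
    expect_equal(a$candidates, b$candidates)
  }
})

test_that("the allocator agrees with brute-force enumeration", {
  set.seed(70)
  for (i in 1:1000) {
    n <- sample(2:6, 1)
    p <- round(runif(n), 3)
    meld <- sample(6:40, n, replace = TRUE)
    wait <- sample(0:500, n, replace = TRUE)
    tau <- sample(c(0, 0.05, 0.14, 0.3), 1)
    expect_equal(allocate(p, meld, wait, allocationConfig(tau = tau))$chosen,
                 bruteForceAllocate(p, meld, wait, tau))
  }
})

test_that("sequential mode removes matched recipients between donors", {
  sc <- allocationScenario(matrix(c(0.9, 0.2, 0.9, 0.2), 2, 2),
                           meld = c(30, 20))
  seqRes <- allocateMatrix(sc, allocationConfig(tau = 0.1, sequential = TRUE))
  expect_equal(unname(chosenRecipients(seqRes)), c(1, 2))
  indepRes <- allocateMatrix(sc, allocationConfig(tau = 0.1))
  expect_equal(unname(chosenRecipients(indepRes)), c(1, 1))
})

test_that("scenario objects validate their clinical ranges", {
  expect_error(allocationScenario(matrix(0.5, 2, 2), meld = c(5, 20)),
               "MELD")
  expect_error(allocationScenario(matrix(1.5, 2, 2), meld = c(20, 20)),
               "probs")
  sc <- fixtureScenario("highMELD")
  expect_equal(unname(recipientMELD(sc)), c(40, 39, 38, 35, 35))
  expect_equal(unname(waitingDays(sc)), c(50, 120, 200, 310, 460))
  expect_equal(dim(scenarioProbs(sc)), c(5, 10))
})
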