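# Shared test fixtures, built in code.

# one complete, schema-valid D-R pair
completePair <- function(overrides = list()) {
  pair <- list(
    `A-R` = 52, `B-R` = 27.4, `CA-R` = 0, `C-R` = 1, `DW-R` = 180,
    `DA-R` = 2, `DI-R` = 1, `DL-R` = 1, `E-R` = 0, `MC-R` = 1,
    `ME-R` = 21, `PM-R` = 0, `PU-R` = 0, `R-R` = 0, `T-R` = 0,
    `A-D` = 44, `B-D` = 24.1, `COD-D` = 2, `CDC-D` = 0, `CR-D` = 0.9,
    `C-D` = 0, `E-D` = 0, `HE-D` = 0, `HH-D` = 1, `HD-D` = 0, `N-D` = 0,
    `A-T` = 1, `G-T` = 0)
  pair[names(overrides)] <- overrides
  as.data.frame(pair, check.names = FALSE)
}

# small complete synthetic cohort
tinyCohort <- function(n = 50, seed = 1) {
  syntheticPairs(cohortConfig(n = n, seed = seed, missingRate = 0))
}

# literal restatement of the allocation rule, written as plain enumeration,
# independent of the package implementation
bruteForceAllocate <- function(probs, meld, wait, tau) {
  n <- length(probs)
  cand <- c()
  for (r in seq_len(n)) {
    significantlyWorse <- FALSE
    for (s in seq_len(n))
      if (probs[s] - probs[r] > tau + 1e-9) significantlyWorse <- TRUE
    if (!significantlyWorse) cand <- c(cand, r)
  }
  best <- cand
  best <- best[sapply(best, function(r) all(meld[r] >= meld[best]))]
  best <- best[sapply(best, function(r) all(wait[r] >= wait[best]))]
  min(best)
}

# random confusion matrix with both classes represented
randomCM <- function() {
  repeat {
    k <- sample(0:200, 4, replace = TRUE)
    if (k[1] + k[2] > 0 && k[3] + k[4] > 0) break
  }
  confusionMatrix(tp = k[1], fn = k[2], fp = k[3], tn = k[4])
}
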