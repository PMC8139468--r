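## Train-only mean/mode imputation of missing D-R fields.

#' Fit imputation statistics on a training cohort
#'
#' Computes one fill value per schema field from training records only: the
#' mean for continuous variables, the mode for binary and nominal variables.
#' Applying the resulting statistics to a held-out fold therefore never lets
#' test values influence the fills.
#'
#' @param pairs training cohort data frame (schema columns, `NA` = missing).
#' @return an [ImputerStats-class] object.
#' @examples
#' train <- syntheticPairs(cohortConfig(n = 20, seed = 1, missingRate = 0.05))
#' fitImputer(train)
#' @export
fitImputer <- function(pairs) {
  validatePairs(pairs)
  sch <- loadSchema()
  fills <- list()
  for (fname in names(sch)) {
    v <- pairs[[fname]]
    obs <- v[!is.na(v)]
    if (length(obs) == 0)
      stop("field '", fname, "' has no observed values; cannot fit a fill",
           call. = FALSE)
    fills[[fname]] <- if (sch[[fname]]$type == "numeric") mean(obs)
                      else .modeValue(obs)
  }
  new("ImputerStats", fills = fills)
}

## Mode with a deterministic tie-break: the smallest category code wins.
.modeValue <- function(x) {
  tab <- table(x)
  codes <- as.numeric(names(tab))
  winners <- codes[tab == max(tab)]
  min(winners)
}

#' Fill missing values with fitted imputation statistics
#'
#' Observed values are left untouched; every `NA` is replaced by the fill
#' fitted on the training split.
#'
#' @param pairs cohort data frame with possible `NA` entries.
#' @param stats an [ImputerStats-class] fitted with [fitImputer()] on the
#'   training split only.
#' @return the cohort with no missing schema fields.
#' @export
applyImputer <- function(pairs, stats) {
  stopifnot(is(stats, "ImputerStats"))
  validatePairs(pairs)
  for (fname in schemaFields()) {
    idx <- is.na(pairs[[fname]])
    if (any(idx)) pairs[[fname]][idx] <- stats@fills[[fname]]
  }
  pairs
}

#' @describeIn ImputerStats-class compact display of the fitted fills.
#' @param object an `ImputerStats` object.
#' @export
setMethod("show", "ImputerStats", function(object) {
  cat("ImputerStats across", length(object@fills), "fields\n")
  f <- unlist(object@fills)
  cat("  ", paste0(names(f)[1:5], "=", signif(f[1:5], 4), collapse = ", "),
      ", ...\n", sep = "")
})
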