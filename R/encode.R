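## One-hot encoding of D-R pairs into the canonical 49-component vector.
##
## Every nominal variable is expanded into a full one-hot block (no dropped
## reference level: the published model carries a weight for every level), and
## numeric fields are shifted/scaled by the supplied ScalingStats. Binary
## fields pass through unchanged.

#' Construct scaling statistics
#'
#' `fitScaling()` computes mean/standard-deviation z-scoring statistics for
#' the numeric schema fields of a (complete) cohort. `identityScaling()`
#' returns pass-through statistics (location 0, scale 1), i.e. raw-scale
#' encoding. `syntheticScaling()` returns the analytic moments of the default
#' synthetic marginals (uniform over each admissible range): this is the
#' scaling block packaged with the published model and is synthetic, not the
#' unpublished scaling of the original fit.
#'
#' @param pairs complete cohort data frame.
#' @return a [ScalingStats-class] object.
#' @export
fitScaling <- function(pairs) {
  validatePairs(pairs, allowMissing = FALSE)
  fields <- schemaFields("numeric")
  loc <- vapply(fields, function(f) mean(pairs[[f]]), numeric(1))
  sc <- vapply(fields, function(f) stats::sd(pairs[[f]]), numeric(1))
  if (any(sc == 0))
    stop("numeric field(s) ", paste(fields[sc == 0], collapse = ", "),
         " are constant; cannot z-score", call. = FALSE)
  new("ScalingStats", location = loc, scale = sc)
}

#' @rdname fitScaling
#' @param fields field names to cover; defaults to all numeric schema fields.
#' @export
identityScaling <- function(fields = schemaFields("numeric")) {
  new("ScalingStats",
      location = stats::setNames(rep(0, length(fields)), fields),
      scale = stats::setNames(rep(1, length(fields)), fields))
}

#' @rdname fitScaling
#' @export
syntheticScaling <- function() {
  raw <- jsonlite::read_json(fixturePath("published_lr_weights.json"))
  new("ScalingStats",
      location = unlist(raw$scaling$location),
      scale = unlist(raw$scaling$scale))
}

#' Encode a cohort into the canonical feature matrix
#'
#' @param pairs complete (imputed) cohort data frame; any missing value is an
#'   error instructing to impute first.
#' @param scaling a [ScalingStats-class] applied to numeric fields.
#' @return numeric matrix, one row per pair, 49 columns named by
#'   [canonicalFeatureNames()]. Each one-hot block sums to exactly 1 per row.
#' @examples
#' pairs <- syntheticPairs(cohortConfig(n = 5, seed = 1, missingRate = 0))
#' x <- encodeCohort(pairs, identityScaling())
#' dim(x)   # 5 x 49
#' @export
encodeCohort <- function(pairs, scaling = identityScaling()) {
  stopifnot(is(scaling, "ScalingStats"))
  sch <- loadSchema()
  for (fname in names(sch))
    if (fname %in% names(pairs) && anyNA(pairs[[fname]]))
      stop("field '", fname, "' contains missing values; impute first",
           call. = FALSE)
  validatePairs(pairs, allowMissing = FALSE)
  canon <- canonicalFeatureNames()
  n <- nrow(pairs)
  x <- matrix(0, nrow = n, ncol = length(canon),
              dimnames = list(rownames(pairs), canon))
  for (j in seq_along(canon)) {
    comp <- .parseComponent(canon[j])
    f <- sch[[comp$field]]
    v <- pairs[[comp$field]]
    if (!is.na(comp$level)) {            # one-hot indicator
      x[, j] <- as.numeric(v == comp$level)
    } else if (f$type == "numeric") {
      x[, j] <- (v - scaling@location[[comp$field]]) /
        scaling@scale[[comp$field]]
    } else {                             # binary passes through
      x[, j] <- as.numeric(v)
    }
  }
  x
}

#' Encode a single D-R pair
#'
#' @param pair a one-row data frame or a named list with the 28 schema fields.
#' @inheritParams encodeCohort
#' @return named numeric vector of length 49.
#' @export
encodePair <- function(pair, scaling = identityScaling()) {
  if (!is.data.frame(pair)) pair <- as.data.frame(pair, check.names = FALSE)
  if (nrow(pair) != 1L) stop("encodePair expects exactly one pair")
  encodeCohort(pair, scaling)[1L, ]
}

#' Decode the one-hot blocks of an encoded vector
#'
#' Inverse of the nominal part of the encoding: recovers the original category
#' code of every nominal field from its indicator block. Used to check that
#' encoding is injective up to the one-hot structure.
#'
#' @param x encoded vector (canonical order).
#' @return named numeric vector of category codes, one per nominal field.
#' @export
decodeOneHot <- function(x) {
  canon <- canonicalFeatureNames()
  stopifnot(length(x) == length(canon))
  names(x) <- canon
  out <- numeric(0)
  for (fname in schemaFields("nominal")) {
    lv <- loadSchema()[[fname]]$levels
    block <- x[paste0(fname, "(", lv, ")")]
    if (!isTRUE(all.equal(sum(block), 1)) || sum(block == 1) != 1L)
      stop("one-hot block of '", fname, "' does not sum to a single indicator")
    out[fname] <- lv[which(block == 1)]
  }
  out
}
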