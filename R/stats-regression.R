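#' Ordinary or stratified common-slope regression on an ordinal predictor
#'
#' Least-squares fit of the parallelism model
#' Y = beta0 + beta1 * X + sum_s beta_s I_s + e: a common slope on the
#' ordinal phenotype code X with stratum-specific intercept offsets (dummy
#' variables I_s).  The baseline stratum is the lexicographically first
#' label; \code{beta0} is its intercept and the offsets are relative to it.
#' The slope p-value comes from the t-statistic of beta1.
#'
#' @param y numeric response.
#' @param x ordinal predictor codes.
#' @param strata optional stratum factor; a single level is equivalent to
#'   no stratification.
#' @return a [RegressionResult-class].
#' @examples
#' olsTrend(c(1, 2, 3), c(1, 2, 3))
#' @export
olsTrend <- function(y, x, strata = NULL) {
  keep <- if (is.null(strata)) stats::complete.cases(x, y)
          else stats::complete.cases(x, y, strata)
  y <- y[keep]; x <- as.numeric(x)[keep]
  if (!is.null(strata)) strata <- factor(as.character(strata)[keep])
  if (length(unique(x)) < 2)
    stop("the ordinal predictor must take at least 2 distinct values")
  useStrata <- !is.null(strata) && nlevels(strata) > 1
  nPar <- 2L + if (useStrata) nlevels(strata) - 1L else 0L
  if (length(y) < nPar + 1L)
    stop("not enough observations for ", nPar, " parameters")
  fit <- if (useStrata) stats::lm(y ~ x + strata) else stats::lm(y ~ x)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    bad <- names(cf)[is.na(cf)]
    bad <- sub("^strata", "", bad)
    stop("rank-deficient design; stratum confounded with the predictor: ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  offsets <- if (useStrata) {
    o <- cf[grep("^strata", names(cf))]
    stats::setNames(as.numeric(o), sub("^strata", "", names(o)))
  } else stats::setNames(numeric(0), character(0))
  new("RegressionResult",
      beta0 = unname(cf["(Intercept)"]), beta1 = unname(cf["x"]),
      strataOffsets = offsets,
      seSlope = unname(sm["x", "Std. Error"]),
      pSlope = unname(sm["x", "Pr(>|t|)"]),
      n = length(y))
}

#' @rdname RegressionResult-class
#' @param x a [RegressionResult-class].
#' @export
slopeCoef <- function(x) x@beta1

#' @rdname RegressionResult-class
#' @export
slopeP <- function(x) x@pSlope

#' @rdname RegressionResult-class
#' @export
slopeSE <- function(x) x@seSlope

#' @rdname RegressionResult-class
#' @export
interceptCoef <- function(x) x@beta0

#' @rdname RegressionResult-class
#' @export
strataOffsets <- function(x) x@strataOffsets

setMethod("show", "RegressionResult", function(object) {
  cat("Common-slope regression on the ordinal phenotype code\n")
  cat(sprintf("  beta0 = %.4g (baseline stratum), beta1 = %.4g (se %.3g), p = %.4g, n = %d\n",
              object@beta0, object@beta1, object@seSlope, object@pSlope,
              object@n))
  if (length(object@strataOffsets)) {
    cat("  stratum offsets:\n")
    for (s in names(object@strataOffsets))
      cat(sprintf("    %s: %+.4g\n", s, object@strataOffsets[[s]]))
  }
})
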