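## Mann-Kendall trend statistics.  The ordinal phenotype code plays the role
## of time; heavy ties in it are the norm (group codes), so the full
## Kendall tie-corrected variance (including both cross-product terms) is
## used.  The blocked ("cumulative") version sums S and var(S) over many
## alignments, in the style of the seasonal Kendall test.

.trendFromTotals <- function(S, varS, nBlocks, nObs, flags = character()) {
  if (S == 0 || varS <= 0) {
    Z <- 0
    p <- 1
  } else {
    Z <- (S - sign(S)) / sqrt(varS)
    p <- min(1, 2 * stats::pnorm(-abs(Z)))
  }
  new("TrendResult", S = as.numeric(S), varS = as.numeric(varS),
      Z = Z, p = p, nBlocks = as.integer(nBlocks),
      nObs = as.integer(nObs), flags = flags)
}

## S and tie-corrected variance for one block; no normalization.
.mkBlock <- function(x, y) {
  n <- length(x)
  ut <- upper.tri(matrix(0, n, n))
  S <- sum((sign(outer(x, x, function(a, b) b - a)) *
              sign(outer(y, y, function(a, b) b - a)))[ut])
  tx <- as.numeric(table(x))
  ty <- as.numeric(table(y))
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  varS <- (v0 - vt - vu) / 18
  if (n > 2)
    varS <- varS + sum(tx * (tx - 1) * (tx - 2)) *
      sum(ty * (ty - 1) * (ty - 2)) / (9 * n * (n - 1) * (n - 2))
  varS <- varS + sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  list(S = S, varS = varS, n = n)
}

#' Mann-Kendall trend test of a response against an ordinal predictor
#'
#' Computes S = sum over pairs i < j of sign(x_j - x_i) * sign(y_j - y_i),
#' its tie-corrected variance (standard Kendall handling of ties in both x
#' and y), and the continuity-corrected normal deviate
#' Z = (S - sign(S)) / sqrt(var S) with a two-sided p-value.  When all x or
#' all y are identical the result is degenerate: S = 0, p = 1, flagged.
#'
#' @param x ordinal predictor (e.g. phenotype group codes).
#' @param y numeric response.
#' @return a [TrendResult-class].
#' @examples
#' mannKendall(c(1, 2, 3), c(1.2, 3.4, 5.6))
#' @export
mannKendall <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("Mann-Kendall needs at least 3 observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    return(.trendFromTotals(0, 0, 1L, n, flags = "degenerate"))
  b <- .mkBlock(x, y)
  .trendFromTotals(b$S, b$varS, 1L, n)
}

#' Cumulative (blocked) Mann-Kendall trend test
#'
#' Sums the Mann-Kendall S statistic and its tie-corrected variance over
#' many blocks (typically one block per protein alignment) and tests the
#' total with the continuity-corrected normal deviate.  Blocks with fewer
#' than 3 observations or with a constant x or y are skipped with a
#' warning.
#'
#' @param blocks a list; each element is a list or data.frame with
#'   components \code{x} (ordinal codes) and \code{y} (numeric response).
#' @return a [TrendResult-class] on the totals.
#' @examples
#' b <- list(x = c(1, 2, 3), y = c(0.1, 0.5, 0.9))
#' cumulativeMannKendall(list(b, b))
#' @export
cumulativeMannKendall <- function(blocks) {
  if (!length(blocks)) stop("no blocks supplied")
  S <- 0; varS <- 0; nb <- 0L; nObs <- 0L; skipped <- 0L
  for (bl in blocks) {
    x <- bl$x; y <- bl$y
    keep <- stats::complete.cases(x, y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3 || length(unique(x)) < 2 || length(unique(y)) < 2) {
      skipped <- skipped + 1L
      next
    }
    b <- .mkBlock(x, y)
    S <- S + b$S; varS <- varS + b$varS
    nb <- nb + 1L; nObs <- nObs + b$n
  }
  if (nb == 0L) stop("no block satisfies the Mann-Kendall preconditions")
  flags <- character()
  if (skipped > 0L) {
    warning(skipped, " block(s) skipped (too small or degenerate)")
    flags <- "blocks_skipped"
  }
  .trendFromTotals(S, varS, nb, nObs, flags)
}

#' @rdname TrendResult-class
#' @param x a [TrendResult-class].
#' @export
trendS <- function(x) x@S

#' @rdname TrendResult-class
#' @export
trendVarS <- function(x) x@varS

#' @rdname TrendResult-class
#' @export
trendZ <- function(x) x@Z

#' @rdname TrendResult-class
#' @export
trendP <- function(x) x@p

#' @rdname TrendResult-class
#' @export
trendFlags <- function(x) x@flags

setMethod("show", "TrendResult", function(object) {
  cat("Cumulative Mann-Kendall trend test\n")
  cat(sprintf("  S = %g, var(S) = %g, Z = %.4f, two-sided p = %.4g\n",
              object@S, object@varS, object@Z, object@p))
  cat(sprintf("  %d block(s), %d observations%s\n", object@nBlocks,
              object@nObs,
              if (length(object@flags))
                paste0(" [", paste(object@flags, collapse = ", "), "]")
              else ""))
})
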