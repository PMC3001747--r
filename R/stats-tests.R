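#' Construct a 2 x 2 contingency table
#'
#' Cells are laid out as adaptation (forward, M -> P) counts in row 1 and
#' background (within-M) counts in row 2; column 1 counts substitutions
#' into the target residue y, column 2 into any other residue.
#'
#' @param a,b,c,d nonnegative cell counts, row-wise:
#'   \code{(a, b)} = adaptation row, \code{(c, d)} = background row.
#' @param rowLabels,colLabels semantic labels.
#' @return a [ContingencyTable2x2-class].
#' @examples
#' contingency2x2(89, 1754, 14, 514)
#' @export
contingency2x2 <- function(a, b, c, d,
                           rowLabels = c("adaptation M->P",
                                         "background M->M"),
                           colLabels = c("y", "not y")) {
  new("ContingencyTable2x2", a = as.numeric(a), b = as.numeric(b),
      c = as.numeric(c), d = as.numeric(d),
      rowLabels = rowLabels, colLabels = colLabels)
}

#' @rdname contingency2x2
#' @param x a [ContingencyTable2x2-class].
#' @param ... unused.
#' @export
setMethod("as.matrix", "ContingencyTable2x2", function(x, ...)
  matrix(c(x@a, x@c, x@b, x@d), 2, 2,
         dimnames = list(x@rowLabels, x@colLabels)))

setMethod("show", "ContingencyTable2x2", function(object) {
  print(as.matrix(object))
})

.asTable2x2 <- function(t) {
  if (is(t, "ContingencyTable2x2")) return(c(t@a, t@b, t@c, t@d))
  if (is.matrix(t) && all(dim(t) == 2L)) return(c(t[1, 1], t[1, 2],
                                                  t[2, 1], t[2, 2]))
  if (is.numeric(t) && length(t) == 4L) return(as.numeric(t))
  stop("expected a ContingencyTable2x2, 2x2 matrix, or length-4 vector")
}

.withFlags <- function(p, flags = character(), ...) {
  attr(p, "flags") <- flags
  extra <- list(...)
  for (nm in names(extra)) attr(p, nm) <- extra[[nm]]
  p
}

#' Mid-p Fisher exact test for a 2 x 2 table
#'
#' Exact conditional test on the hypergeometric null with fixed margins,
#' with the mid-p adjustment for discreteness: the observed table
#' contributes only half its probability.  One-sided:
#' p = P(more extreme) + 0.5 P(observed).  Two-sided (probability
#' ordering): p = sum of the probabilities of tables strictly less probable
#' than the observed plus half the total probability of tables tied with
#' it (tie detection at relative tolerance 1e-7).  The mid-p is therefore
#' always the conventional exact p minus half the tied probability mass,
#' and is less conservative than the standard exact test.
#'
#' @param t a [ContingencyTable2x2-class], 2x2 matrix, or c(a, b, c, d).
#' @param alternative \code{"two_sided"} (default), \code{"greater"} or
#'   \code{"less"}; directions refer to the (1,1) cell.
#' @return the mid-p value, with attribute \code{flags}
#'   (\code{"not_testable"} when a margin is empty).
#' @examples
#' midPFisher(contingency2x2(1, 1, 1, 1))   # 2/3
#' @export
midPFisher <- function(t, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  cells <- .asTable2x2(t)
  if (any(cells != round(cells)))
    stop("mid-p Fisher needs integer counts; round representative counts first")
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    return(.withFlags(1, flags = "not_testable"))
  k <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(k, r1, r2, c1)
  pobs <- stats::dhyper(a, r1, r2, c1)
  p <- switch(alternative,
    greater = sum(probs[k > a]) + 0.5 * pobs,
    less    = sum(probs[k < a]) + 0.5 * pobs,
    two_sided = {
      tied <- abs(probs - pobs) <= 1e-7 * pobs
      sum(probs[probs < pobs & !tied]) + 0.5 * sum(probs[tied])
    })
  .withFlags(min(1, max(0, p)))
}

#' Pearson chi-square test for a 2 x 2 table
#'
#' Pearson chi-square on 1 df without Yates continuity correction -- the
#' large-count alternative to the mid-p exact test (the mid-p adjustment
#' already addresses discreteness in the exact branch).
#'
#' @inheritParams midPFisher
#' @return the p-value, with attributes \code{statistic} (the chi-square)
#'   and \code{flags} (\code{"not_testable"} when an expected cell is 0).
#' @export
chiSquare2x2 <- function(t) {
  cells <- .asTable2x2(t)
  m <- matrix(cells[c(1, 3, 2, 4)], 2, 2)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0))
    return(.withFlags(1, flags = "not_testable", statistic = NA_real_))
  ct <- stats::chisq.test(m, correct = FALSE)
  .withFlags(unname(ct$p.value), statistic = unname(ct$statistic))
}

#' Mantel-Haenszel test over stratified 2 x 2 tables
#'
#' Continuity-corrected Mantel-Haenszel chi-square on 1 df and the
#' Mantel-Haenszel common odds-ratio estimate
#' sum(a_k d_k / n_k) / sum(b_k c_k / n_k), computed through
#' [stats::mantelhaen.test()].  Strata with an empty table are dropped.
#'
#' @param tables list of 2 x 2 tables (one per stratum), each a
#'   [ContingencyTable2x2-class], matrix or length-4 vector.
#' @return list with \code{chi2}, \code{p}, \code{commonOR},
#'   \code{nStrata} and \code{flags}.
#' @export
mantelHaenszel <- function(tables) {
  if (!length(tables)) stop("no stratum tables supplied")
  cells <- lapply(tables, .asTable2x2)
  cells <- cells[vapply(cells, sum, 0) > 0]
  if (!length(cells))
    return(list(chi2 = NA_real_, p = 1, commonOR = NA_real_,
                nStrata = 0L, flags = "not_testable"))
  K <- length(cells)
  num <- sum(vapply(cells, function(x) x[1] * x[4] / sum(x), 0))
  den <- sum(vapply(cells, function(x) x[2] * x[3] / sum(x), 0))
  commonOR <- if (den > 0) num / den else Inf
  arr <- array(unlist(lapply(cells, function(x) x[c(1, 3, 2, 4)])),
               dim = c(2, 2, K))
  res <- tryCatch(stats::mantelhaen.test(arr, correct = TRUE,
                                         exact = FALSE),
                  error = function(e) NULL)
  if (is.null(res)) {
    ## single-stratum or degenerate-variance edge: same statistic by hand
    E <- vapply(cells, function(x) (x[1] + x[2]) * (x[1] + x[3]) / sum(x), 0)
    V <- vapply(cells, function(x) {
      n <- sum(x)
      if (n < 2) return(0)
      (x[1] + x[2]) * (x[3] + x[4]) * (x[1] + x[3]) * (x[2] + x[4]) /
        (n^2 * (n - 1))
    }, 0)
    if (sum(V) == 0)
      return(list(chi2 = NA_real_, p = 1, commonOR = commonOR,
                  nStrata = K, flags = "not_testable"))
    obsA <- sum(vapply(cells, `[`, 0, 1))
    chi2 <- (abs(obsA - sum(E)) - 0.5)^2 / sum(V)
    return(list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE),
                commonOR = commonOR, nStrata = K, flags = character()))
  }
  list(chi2 = unname(res$statistic), p = unname(res$p.value),
       commonOR = commonOR, nStrata = K, flags = character())
}

#' Wilcoxon paired signed-rank test on a vector of paired differences
#'
#' Zeros are dropped (Wilcoxon convention).  The exact signed-rank
#' distribution is used for n <= 25 without ties in |delta|, a full 2^n
#' sign enumeration for tied samples with n <= 12, and the tie-corrected
#' normal approximation otherwise.
#'
#' @param deltas numeric vector of paired differences.
#' @return two-sided p-value, with attributes \code{statistic} (W+) and
#'   \code{flags} (\code{"degenerate"} when all deltas are zero,
#'   \code{"small_n"} when fewer than 5 nonzero deltas remain).
#' @export
wilcoxonPaired <- function(deltas) {
  d <- deltas[!is.na(deltas)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(.withFlags(1, flags = "degenerate",
                                statistic = NA_real_))
  flags <- if (n < 5) "small_n" else character()
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  if (!ties && n <= 25) {
    p <- 2 * min(stats::psignrank(W, n),
                 stats::psignrank(W - 1, n, lower.tail = FALSE))
  } else if (n <= 12) {
    ## exact under ties: enumerate all 2^n sign assignments of the midranks
    Wall <- .allSignedRankSums(r)
    p <- 2 * min(mean(Wall >= W), mean(Wall <= W))
  } else {
    mu <- n * (n + 1) / 4
    tieTab <- as.numeric(table(abs(d)))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tieTab^3 - tieTab) / 48
    if (sigma2 <= 0 || W == mu) {
      p <- 1
    } else {
      z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  .withFlags(min(1, p), flags = flags, statistic = W)
}

.allSignedRankSums <- function(r) {
  n <- length(r)
  sums <- 0
  for (i in seq_len(n)) sums <- c(sums, sums + r[i])
  sums
}

#' One-way or stratified two-way ANOVA group effect
#'
#' With no stratum, an ordinary one-way ANOVA F-test of the 2-level group
#' factor.  With a stratum, the additive (no-interaction) two-way model is
#' fitted and the group effect is tested by its Type II sum of squares,
#' i.e. the group sum of squares adjusted for the stratum.
#'
#' @param y numeric response (one value per sequence).
#' @param group 2-level factor (or coercible).
#' @param stratum optional blocking factor (taxonomic order).
#' @return list with \code{F}, \code{p}, \code{df1}, \code{df2}.
#' @export
anovaGroupEffect <- function(y, group, stratum = NULL) {
  g <- factor(group)
  if (nlevels(g) != 2)
    stop("ANOVA group comparison needs exactly 2 groups; ",
         "use regression or cumulative Mann-Kendall for more")
  if (any(table(g) < 2))
    stop("each group needs at least 2 observations")
  if (is.null(stratum)) {
    fit <- stats::lm(y ~ g)
    an <- stats::anova(fit)
    return(list(F = an$`F value`[1], p = an$`Pr(>F)`[1],
                df1 = an$Df[1], df2 = an$Df[2]))
  }
  s <- factor(stratum)
  ## sequential ANOVA with group last = SS(group | stratum): Type II for
  ## the additive model
  fit <- stats::lm(y ~ s + g)
  an <- stats::anova(fit)
  i <- which(rownames(an) == "g")
  list(F = an$`F value`[i], p = an$`Pr(>F)`[i],
       df1 = an$Df[i], df2 = an$Df[nrow(an)])
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up false discovery rate control valid under arbitrary dependence:
#' adjusted_(i) = min over j >= i of min(1, p_(j) * m * c(m) / j) with
#' c(m) the m-th harmonic number.  NaN/NA inputs are propagated and
#' excluded from m.
#'
#' @param pvals numeric vector of p-values in \[0,1\] (NA/NaN allowed).
#' @return adjusted q-values in the input order.
#' @examples
#' benjaminiYekutieli(c(0.01, 0.02, 0.03))   # all 0.055
#' @export
benjaminiYekutieli <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0,1]")
  out <- rep(NaN, length(pvals))
  out[ok] <- stats::p.adjust(pvals[ok], method = "BY")
  out
}
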