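## Synthetic annotated alignments with controllable group-dependent
## compositional shifts, directional substitution biases and property
## slopes.  The generative model is deliberately site-independent (no
## phylogeny within groups), matching the independence assumption of the
## statistical models; the collapse-to-group-means analysis paths cover
## the dependent case.

## Default base frequencies: rounded average amino-acid frequencies of
## UniProtKB/Swiss-Prot (order AA_CODES), renormalized.
.defaultBaseFreq <- function() {
  f <- c(A = 0.0825, R = 0.0553, N = 0.0406, D = 0.0546, C = 0.0137,
         Q = 0.0393, E = 0.0672, G = 0.0707, H = 0.0227, I = 0.0596,
         L = 0.0966, K = 0.0580, M = 0.0242, F = 0.0386, P = 0.0470,
         S = 0.0657, T = 0.0534, W = 0.0108, Y = 0.0292, V = 0.0687)
  f / sum(f)
}

#' Specify a synthetic alignment fixture
#'
#' Describes a set of protein families to simulate: per family an
#' ancestral sequence is drawn from \code{baseFreq}; each sequence of
#' group g resamples every site independently with probability
#' \code{divergence}, drawing from a group-specific distribution
#' constructed so that the expected composition of group g is exactly
#' \code{baseFreq + (g-1) * shift} (the resampling distribution is
#' inflated by \code{1/divergence}; an infeasible combination is a hard
#' error).  Amino acids not named in \code{compositionShift} absorb the
#' compensating mass in proportion to their base frequency.
#'
#' @param nFamilies number of protein families (alignments).
#' @param groups named integer vector: ordered group labels ->
#'   sequences per group (order defines the ordinal codes 1..K).
#' @param nSites alignment length.
#' @param baseFreq 20-vector of base amino-acid frequencies (sums to 1);
#'   default: average database composition.
#' @param compositionShift named numeric vector: per-group-step additive
#'   frequency delta for the named amino acids.
#' @param substitutionBias optional \code{list(x =, y =, multiplier =)}:
#'   sequences of the groups above the baseline additionally convert
#'   residue \code{x} to \code{y} with probability
#'   \code{(multiplier - 1) * divergence * q_y}, making the forward
#'   x -> y substitution rate \code{multiplier} times the undirected
#'   background rate.
#' @param propertySlope optional \code{list(scale =, beta1 =, noiseSd =)}:
#'   \code{scale} a [PropertyScale-class] (or bundled scale name); the
#'   group compositions are shifted along the property direction so the
#'   expected per-sequence mean property increases by \code{beta1} per
#'   group step, with optional per-sequence slope noise.
#' @param divergence per-site resampling probability (default 0.3).
#' @param gapRate per-site gap-injection probability (default 0.02).
#' @param annotate also generate secondary-structure (3-state Markov
#'   chain) and RSA (i.i.d. decile) annotation.
#' @param strata optional character vector of stratum labels cycled over
#'   the replicates within each group.
#' @param seed RNG seed; the output is fully deterministic given the spec.
#' @return a \code{FixtureSpec} list.
#' @export
fixtureSpec <- function(nFamilies = 10,
                        groups = c(meso = 2L, inter = 2L, psychro = 2L),
                        nSites = 200,
                        baseFreq = NULL,
                        compositionShift = NULL,
                        substitutionBias = NULL,
                        propertySlope = NULL,
                        divergence = 0.3,
                        gapRate = 0.02,
                        annotate = FALSE,
                        strata = NULL,
                        seed = 1L) {
  base <- baseFreq %||% .defaultBaseFreq()
  stopifnot(length(base) == 20L, abs(sum(base) - 1) < 1e-8,
            all(base > 0), divergence > 0, divergence <= 1,
            gapRate >= 0, gapRate < 1, nFamilies >= 1, nSites >= 1,
            length(groups) >= 2, all(groups >= 1))
  if (is.null(names(base))) names(base) <- AA_CODES
  base <- base[AA_CODES]

  delta <- stats::setNames(rep(0, 20L), AA_CODES)
  if (!is.null(compositionShift)) {
    stopifnot(!is.null(names(compositionShift)),
              all(names(compositionShift) %in% AA_CODES))
    delta[names(compositionShift)] <-
      delta[names(compositionShift)] + compositionShift
    others <- setdiff(AA_CODES, names(compositionShift))
    delta[others] <- delta[others] -
      sum(compositionShift) * base[others] / sum(base[others])
  }
  propDir <- NULL
  if (!is.null(propertySlope)) {
    sc <- propertySlope$scale
    if (is.character(sc)) sc <- loadPropertyScales()[[sc]]
    stopifnot(is(sc, "PropertyScale"))
    v <- scaleValues(sc)[AA_CODES]
    vbar <- sum(base * v)
    w <- base * (v - vbar)            # sums to 0; sum(w * v) = Var_base(v)
    propDir <- w / sum(w * v)
    delta <- delta + propertySlope$beta1 * propDir
  }
  K <- length(groups)
  for (g in seq_len(K)) {
    fg <- base + (g - 1) * delta
    qg <- base + (g - 1) * delta / divergence
    if (any(fg < 0) || any(qg < 0))
      stop("infeasible composition shift: negative frequency in group ", g,
           " (reduce the shift or raise the divergence)")
  }
  spec <- list(nFamilies = as.integer(nFamilies), groups = groups,
               nSites = as.integer(nSites), baseFreq = base,
               delta = delta, propDir = propDir,
               propNoiseSd = propertySlope$noiseSd %||% 0,
               substitutionBias = substitutionBias,
               divergence = divergence, gapRate = gapRate,
               annotate = isTRUE(annotate), strata = strata,
               seed = as.integer(seed))
  class(spec) <- "FixtureSpec"
  spec
}

#' Generate synthetic annotated alignments
#'
#' Draws the families described by a [fixtureSpec()].  The result is
#' byte-for-byte deterministic given the spec (the caller's RNG state is
#' left untouched).  Optionally writes the extended-FASTA file and the
#' group configuration that round-trip through [readAnnotatedFasta()] and
#' [readGroupConfig()].
#'
#' @param spec a \code{FixtureSpec}.
#' @param dir optional directory; when given, \code{alignments.fasta} and
#'   \code{groups.yaml} are written there.
#' @return list of group-assigned [AnnotatedAlignment-class] objects with
#'   the [GroupScheme-class] as attribute \code{"scheme"}.
#' @examples
#' alns <- simulateAlignments(fixtureSpec(nFamilies = 2, nSites = 50))
#' length(alns)
#' @export
simulateAlignments <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "FixtureSpec"))
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(oldSeed)) suppressWarnings(rm(".Random.seed",
                                              envir = globalenv()))
    else assign(".Random.seed", oldSeed, envir = globalenv())
  })
  set.seed(spec$seed)

  K <- length(spec$groups)
  labels <- names(spec$groups)
  bias <- spec$substitutionBias
  pdirByGroup <- if (!is.null(bias)) .biasConversionProb(spec) else NULL
  alns <- vector("list", spec$nFamilies)
  allIds <- character(); allGroups <- character(); allStrata <- character()

  for (f in seq_len(spec$nFamilies)) {
    famId <- sprintf("fam%03d", f)
    ancestor <- sample(AA_CODES, spec$nSites, replace = TRUE,
                       prob = spec$baseFreq)
    seqs <- list(); ssList <- list(); rsaList <- list()
    ids <- character(); gcodes <- integer(); strat <- character()
    ssChain <- if (spec$annotate) .ssMarkov(spec$nSites) else NULL
    for (g in seq_len(K)) {
      for (r in seq_len(spec$groups[[g]])) {
        id <- sprintf("%s_%s_%d", famId, labels[g], r)
        deltaSeq <- (g - 1) * spec$delta
        if (!is.null(spec$propDir) && spec$propNoiseSd > 0)
          deltaSeq <- deltaSeq +
            stats::rnorm(1, 0, spec$propNoiseSd) * spec$propDir
        q <- spec$baseFreq + deltaSeq / spec$divergence
        q <- pmax(q, 0); q <- q / sum(q)
        s <- ancestor
        resample <- stats::runif(spec$nSites) < spec$divergence
        if (any(resample))
          s[resample] <- sample(AA_CODES, sum(resample), replace = TRUE,
                                prob = q)
        if (!is.null(bias) && g > 1) {
          hit <- s == bias$x & stats::runif(spec$nSites) < pdirByGroup[g]
          if (any(hit)) s[hit] <- bias$y
        }
        if (spec$gapRate > 0) {
          gap <- stats::runif(spec$nSites) < spec$gapRate
          s[gap] <- GAP_CHAR
        }
        seqs[[id]] <- paste(s, collapse = "")
        if (spec$annotate) {
          ssList[[id]] <- paste(ssChain, collapse = "")
          rsaList[[id]] <- (sample(0:9, spec$nSites, replace = TRUE) +
                              0.5) / 10
        }
        ids <- c(ids, id); gcodes <- c(gcodes, g)
        strat <- c(strat, if (is.null(spec$strata)) NA_character_
                   else spec$strata[(r - 1L) %% length(spec$strata) + 1L])
      }
    }
    aln <- AnnotatedAlignment(famId, unlist(seqs),
                              ss = if (spec$annotate) ssList else NULL,
                              rsa = if (spec$annotate) rsaList else NULL,
                              group = gcodes, stratum = strat,
                              groupLabels = labels)
    alns[[f]] <- aln
    allIds <- c(allIds, ids)
    allGroups <- c(allGroups, labels[gcodes])
    allStrata <- c(allStrata, strat)
  }
  scheme <- GroupScheme(labels, stats::setNames(allGroups, allIds),
                        stats::setNames(allStrata, allIds))
  attr(alns, "scheme") <- scheme
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeAnnotatedFasta(alns, file.path(dir, "alignments.fasta"))
    writeGroupConfig(scheme, file.path(dir, "groups.yaml"))
  }
  alns
}

## Per-group probability of the directed x -> y conversion that realizes a
## `multiplier`-fold forward substitution rate.  With site-wise resampling,
## P(residue = z | ancestor = w) = (1-d) 1[w==z] + d q_g[z]; the undirected
## forward x -> y cell rate is n_f = sum_w base_w P_1(x|w) P_g(y|w) (the
## same coincidence structure as the within-group background), so directed
## conversions at current-x sites of the adapted sequences must add
## (multiplier - 1) n_f, i.e. pdir = (multiplier - 1) n_f / P(m=x, p=x).
.biasConversionProb <- function(spec) {
  bias <- spec$substitutionBias
  d <- spec$divergence
  K <- length(spec$groups)
  resProb <- function(g, z) {
    q <- spec$baseFreq + (g - 1) * spec$delta / d
    p <- d * q[[z]] + (1 - d) * as.numeric(AA_CODES == z)
    stats::setNames(p, AA_CODES)
  }
  pdir <- numeric(K)
  for (g in 2:K) {
    p1x <- resProb(1, bias$x)
    pgx <- resProb(g, bias$x)
    pgy <- resProb(g, bias$y)
    nf <- sum(spec$baseFreq * p1x * pgy)
    pxx <- sum(spec$baseFreq * p1x * pgx)
    pdir[g] <- (bias$multiplier - 1) * nf / pxx
    if (pdir[g] > 1)
      stop("infeasible substitution bias: required conversion probability ",
           "exceeds 1 in group ", g)
  }
  pdir
}

## 3-state secondary-structure Markov chain (sticky transitions so helices
## and sheets come in runs, as real structure does).
.ssMarkov <- function(n, stay = 0.85) {
  states <- SS_CODES
  s <- character(n)
  s[1] <- sample(states, 1)
  for (i in seq_len(n - 1L)) {
    if (stats::runif(1) < stay) s[i + 1L] <- s[i]
    else s[i + 1L] <- sample(setdiff(states, s[i]), 1)
  }
  s
}
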