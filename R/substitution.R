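## Substitution-pair (SP) analysis: Jones-method pairing of sequences,
## 21x21 SP count matrices (20 amino acids + gap '~'), Table-style 2x2
## adaptation-vs-background contingency tables and bias tests.

.stateOf <- function(res) ifelse(.isGap(res), GAP_LABEL, res)

.emptyCounts <- function()
  matrix(0, 21L, 21L, dimnames = list(SUB_STATES, SUB_STATES))

#' Pairwise sequence identity over both-aligned columns
#'
#' Fraction of matching residues among the columns where both sequences
#' are non-gap.  If no such column exists the identity is 0, flagged
#' \code{no_overlap}.
#'
#' @param a,b residue strings or character vectors of equal length.
#' @return identity fraction in \[0,1\].
#' @examples
#' pairwiseIdentity("AAAA", "AAAT")   # 0.75
#' @export
pairwiseIdentity <- function(a, b) {
  a <- .residueVector(a); b <- .residueVector(b)
  if (length(a) != length(b)) stop("sequences have different lengths")
  both <- !.isGap(a) & !.isGap(b)
  if (!any(both)) {
    out <- 0
    attr(out, "flags") <- "no_overlap"
    return(out)
  }
  sum(a[both] == b[both]) / sum(both)
}

.residueVector <- function(x) {
  if (length(x) == 1L && nchar(x[1L]) > 1L)
    strsplit(toupper(.normalizeGaps(x)), "", fixed = TRUE)[[1L]]
  else toupper(.normalizeGaps(x))
}

.asResidueMatrix <- function(x) {
  if (is.matrix(x)) return(x)
  stopifnot(!is.null(names(x)))
  do.call(rbind, lapply(stats::setNames(names(x), names(x)),
                        function(id) .residueVector(x[[id]])))
}

#' Jones-method maximum-identity sequence pairing
#'
#' Greedily forms the maximum number of disjoint sequence pairs by highest
#' pairwise identity, each sequence used at most once (this avoids
#' oversampling when tallying substitutions).  Between two groups the
#' number of pairs is min(|A|, |B|); within one group (\code{b = NULL}) it
#' is floor(n/2).  Ties are broken by lexicographic (idA, idB) order.  The
#' greedy procedure is deliberate (it mirrors the pair-the-most-identical
#' description of the method); \code{method = "optimal"} solves the
#' maximum-total-identity assignment instead (small groups only).
#'
#' @param a,b named character vectors of aligned sequences, or residue
#'   matrices with id rownames; \code{b = NULL} pairs within \code{a}.
#' @param method \code{"greedy"} (default) or \code{"optimal"}.
#' @return list with \code{pairs} (data.frame idA, idB, identity) and
#'   \code{unpaired} (character vector of leftover ids).
#' @export
jonesPairing <- function(a, b = NULL, method = c("greedy", "optimal")) {
  method <- match.arg(method)
  A <- .asResidueMatrix(a)
  within <- is.null(b)
  B <- if (within) A else .asResidueMatrix(b)
  if (!nrow(A) || !nrow(B)) stop("both groups must be non-empty")
  idsA <- rownames(A); idsB <- rownames(B)
  cand <- expand.grid(i = seq_len(nrow(A)), j = seq_len(nrow(B)))
  if (within) cand <- cand[cand$i < cand$j, , drop = FALSE]
  cand$ident <- mapply(function(i, j)
    as.numeric(pairwiseIdentity(A[i, ], B[j, ])), cand$i, cand$j)
  if (method == "optimal" && !within) {
    return(.optimalPairing(A, B, cand))
  }
  ord <- order(-cand$ident, idsA[cand$i], idsB[cand$j])
  cand <- cand[ord, , drop = FALSE]
  usedA <- logical(nrow(A)); usedB <- logical(nrow(B))
  if (within) usedB <- usedA
  pairs <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (within) {
      if (usedA[i] || usedA[j]) next
      usedA[i] <- usedA[j] <- TRUE
    } else {
      if (usedA[i] || usedB[j]) next
      usedA[i] <- TRUE; usedB[j] <- TRUE
    }
    pairs[[length(pairs) + 1L]] <- data.frame(
      idA = idsA[i], idB = idsB[j], identity = cand$ident[k],
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
           else data.frame(idA = character(), idB = character(),
                           identity = numeric())
  unpaired <- if (within) idsA[!usedA]
              else c(idsA[!usedA], idsB[!usedB])
  list(pairs = pairs, unpaired = unpaired)
}

## Exhaustive maximum-total-identity assignment; exponential, so only for
## small groups (the default analysis path is greedy).
.optimalPairing <- function(A, B, cand) {
  nA <- nrow(A); nB <- nrow(B)
  if (min(nA, nB) > 8L)
    stop("optimal pairing is only available for groups of up to 8 sequences")
  im <- matrix(0, nA, nB)
  im[cbind(cand$i, cand$j)] <- cand$ident
  swap <- nA > nB
  M <- if (swap) t(im) else im
  k <- nrow(M); other <- ncol(M)
  best <- NULL; bestTotal <- -Inf
  perms <- .permutations(seq_len(other))
  for (r in seq_len(nrow(perms))) {
    sel <- perms[r, seq_len(k)]
    tot <- sum(M[cbind(seq_len(k), sel)])
    if (tot > bestTotal) { bestTotal <- tot; best <- sel }
  }
  ii <- if (swap) best else seq_len(k)
  jj <- if (swap) seq_len(k) else best
  pairs <- data.frame(idA = rownames(A)[ii], idB = rownames(B)[jj],
                      identity = im[cbind(ii, jj)],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$idA), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       unpaired = c(setdiff(rownames(A), pairs$idA),
                    setdiff(rownames(B), pairs$idB)))
}

.permutations <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1L))
  out <- vector("list", n)
  for (i in seq_len(n))
    out[[i]] <- cbind(v[i], .permutations(v[-i]))
  do.call(rbind, out)
}

## Tally one sequence pair into a 21x21 count table (ordered direction
## a -> b); both-gap columns skipped, single-gap columns count as
## substitutions to/from the gap state.
.pairCounts <- function(ra, rb) {
  sa <- .stateOf(ra); sb <- .stateOf(rb)
  idx <- which(sa != sb)
  if (!length(idx)) return(.emptyCounts())
  unclass(table(factor(sa[idx], levels = SUB_STATES),
                factor(sb[idx], levels = SUB_STATES)))
}

.groupRows <- function(aln, code) {
  which(!is.na(groupCodes(aln)) & groupCodes(aln) == code)
}

#' Build a substitution-pair (SP) matrix
#'
#' Accumulates substitution-pair counts over one or more alignments.  For
#' \code{kind = "directional_between"}, sequences of the source and target
#' groups are Jones-paired and, at each column where the paired residues
#' differ (and are not both gaps), \code{counts[x, y]} is incremented for
#' the source residue x and target residue y; the gap participates as the
#' 21st state \code{~}.  For \code{kind = "symmetric_within"}
#' (\code{groupFrom == groupTo}), disjoint pairs are formed within the
#' group and each unordered exchange increments both \code{counts[x, y]}
#' and \code{counts[y, x]}.
#'
#' @param alns list of group-assigned [AnnotatedAlignment-class] objects.
#' @param groupFrom,groupTo ordinal group codes.
#' @param kind \code{"directional_between"} or \code{"symmetric_within"}.
#' @param sites optional [SiteFilter-class].
#' @param pairing \code{"greedy"} (default) or \code{"optimal"} Jones
#'   pairing.
#' @return an [SPMatrix-class].
#' @export
spMatrix <- function(alns, groupFrom, groupTo,
                     kind = c("directional_between", "symmetric_within"),
                     sites = NULL, pairing = c("greedy", "optimal")) {
  kind <- match.arg(kind)
  pairing <- match.arg(pairing)
  if (is(alns, "AnnotatedAlignment")) alns <- list(alns)
  if (kind == "symmetric_within" && groupFrom != groupTo)
    stop("within-group SP-matrix requires groupFrom == groupTo")
  counts <- .emptyCounts()
  nPairs <- 0L
  for (aln in alns) {
    if (!is.null(sites)) aln <- filterSites(aln, sites)
    res <- residueMatrix(aln)
    rowsF <- .groupRows(aln, groupFrom)
    if (kind == "directional_between") {
      rowsT <- .groupRows(aln, groupTo)
      if (!length(rowsF) || !length(rowsT)) next
      pr <- jonesPairing(res[rowsF, , drop = FALSE],
                         res[rowsT, , drop = FALSE], method = pairing)
      for (k in seq_len(nrow(pr$pairs)))
        counts <- counts + .pairCounts(res[pr$pairs$idA[k], ],
                                       res[pr$pairs$idB[k], ])
    } else {
      if (length(rowsF) < 2L) next
      pr <- jonesPairing(res[rowsF, , drop = FALSE], method = pairing)
      for (k in seq_len(nrow(pr$pairs))) {
        tt <- .pairCounts(res[pr$pairs$idA[k], ],
                          res[pr$pairs$idB[k], ])
        counts <- counts + tt + t(tt)
      }
    }
    nPairs <- nPairs + nrow(pr$pairs)
  }
  if (nPairs == 0L)
    stop("no Jones pairs could be formed for groups ", groupFrom, " -> ",
         groupTo)
  new("SPMatrix", counts = counts, kind = kind,
      groupFrom = as.integer(groupFrom), groupTo = as.integer(groupTo),
      nPairs = nPairs, gMP = 0)
}

#' Representative (per-ordered-pair average) SP-matrix
#'
#' Accumulates substitution-pair counts over all ordered cross-group
#' sequence pairs (not just the disjoint Jones pairs) and divides
#' elementwise by G_MP, the number of ordered pairs, giving the average
#' counting per pair: a dependence-robust description that treats each
#' group as one observation.  Counts are fractional.
#'
#' @inheritParams spMatrix
#' @return an [SPMatrix-class] of kind \code{"representative"}.
#' @export
representativeSPMatrix <- function(alns, groupFrom, groupTo, sites = NULL) {
  if (is(alns, "AnnotatedAlignment")) alns <- list(alns)
  counts <- .emptyCounts()
  gMP <- 0
  for (aln in alns) {
    if (!is.null(sites)) aln <- filterSites(aln, sites)
    res <- residueMatrix(aln)
    rowsF <- .groupRows(aln, groupFrom)
    rowsT <- .groupRows(aln, groupTo)
    if (!length(rowsF) || !length(rowsT)) next
    for (i in rowsF) for (j in rowsT)
      counts <- counts + .pairCounts(res[i, ], res[j, ])
    gMP <- gMP + length(rowsF) * length(rowsT)
  }
  if (gMP == 0) stop("no ordered cross-group sequence pairs found")
  new("SPMatrix", counts = counts / gMP, kind = "representative",
      groupFrom = as.integer(groupFrom), groupTo = as.integer(groupTo),
      nPairs = as.integer(gMP), gMP = gMP)
}

#' Pool substitutions sharing an outcome residue
#'
#' Pools the substitutions x -> target over all source residues x (the
#' column of the SP-matrix into the target state) and, for the reverse
#' direction, target -> y over all outcomes y (the row out of the target).
#'
#' @param m a directional [SPMatrix-class].
#' @param target an amino-acid one-letter code or \code{"~"} for the gap.
#' @return list with \code{into} (named column vector), \code{outOf}
#'   (named row vector) and their totals \code{totalInto},
#'   \code{totalOutOf}.
#' @export
poolSubstitutions <- function(m, target) {
  stopifnot(is(m, "SPMatrix"))
  target <- .stateOf(.normalizeGaps(target))
  if (!target %in% SUB_STATES) stop("unknown residue state: ", target)
  cts <- m@counts
  list(into = cts[, target], outOf = cts[target, ],
       totalInto = sum(cts[, target]), totalOutOf = sum(cts[target, ]))
}

## Extract the adaptation-vs-background table for one (x, y).
.biasTable <- function(forward, background, x, y) {
  fx <- forward@counts[x, ]; bx <- background@counts[x, ]
  a <- fx[[y]]; b <- sum(fx) - a
  cc <- bx[[y]]; d <- sum(bx) - cc
  cells <- c(a, b, cc, d)
  if (any(cells != round(cells))) {
    warning("fractional (representative) counts rounded half-to-even ",
            "for exact testing")
    cells <- round(cells)
  }
  contingency2x2(cells[1], cells[2], cells[3], cells[4],
                 colLabels = c(y, paste0("not ", y)))
}

#' Test one substitution pair for adaptation bias
#'
#' Builds the 2 x 2 table comparing the forward (adaptation, M -> P)
#' substitutions x -> y against x -> anything-else, versus the same split
#' in the within-M background matrix, and tests it with the mid-p Fisher
#' exact test (default) or Pearson chi-square.  The direction is
#' \code{"favoured"} when the forward odds of producing y exceed the
#' background odds (upward-triangle semantics in the bubble plot),
#' \code{"non_favoured"} when smaller, \code{"undefined"} when equal.
#' A pair with no forward substitutions out of x is reported as not
#' testable rather than as evidence of no effect.
#'
#' @param forward directional M -> P [SPMatrix-class].
#' @param background within-M symmetric [SPMatrix-class].
#' @param x,y source and target residue states (one-letter code or
#'   \code{"~"}).
#' @param method \code{"mid_p_fisher"} (default) or \code{"chi_square"}.
#' @return list with \code{table} ([ContingencyTable2x2-class]), \code{p},
#'   \code{direction} and \code{flags}.
#' @export
substitutionBiasTest <- function(forward, background, x, y,
                                 method = c("mid_p_fisher", "chi_square")) {
  method <- match.arg(method)
  stopifnot(is(forward, "SPMatrix"), is(background, "SPMatrix"))
  if (forward@kind == "symmetric_within")
    stop("'forward' must be a directional (between-group) SP-matrix")
  x <- .stateOf(.normalizeGaps(x)); y <- .stateOf(.normalizeGaps(y))
  tab <- .biasTable(forward, background, x, y)
  a <- tab@a; b <- tab@b; cc <- tab@c; d <- tab@d
  if (a + b == 0 || (a + b == 0 && cc + d == 0))
    return(list(table = tab, p = NA_real_, direction = NA_character_,
                flags = "not_testable"))
  p <- if (method == "mid_p_fisher") midPFisher(tab) else chiSquare2x2(tab)
  flags <- attr(p, "flags") %||% character()
  direction <- if (a * d > cc * b) "favoured"
               else if (a * d < cc * b) "non_favoured"
               else "undefined"
  list(table = tab, p = as.numeric(p), direction = direction,
       flags = flags)
}

#' Scan all substitution pairs for adaptation bias
#'
#' Applies [substitutionBiasTest()] to every ordered residue pair (x, y),
#' x != y, over the 21 states (20 amino acids + gap, or 20 x 20 with
#' \code{includeGap = FALSE}), and attaches Benjamini-Yekutieli q-values
#' over the testable pairs.
#'
#' @inheritParams substitutionBiasTest
#' @param includeGap include the gap state \code{~} (default TRUE).
#' @param alpha significance level recorded for downstream plotting.
#' @return data.frame with columns \code{x}, \code{y}, \code{a}, \code{b},
#'   \code{c}, \code{d}, \code{count}, \code{p}, \code{qBY},
#'   \code{direction}.
#' @export
substitutionScan <- function(forward, background,
                             method = c("mid_p_fisher", "chi_square"),
                             includeGap = TRUE, alpha = 0.05) {
  method <- match.arg(method)
  states <- if (includeGap) SUB_STATES else AA_CODES
  rows <- list()
  for (x in states) for (y in states) {
    if (x == y) next
    bt <- substitutionBiasTest(forward, background, x, y, method = method)
    rows[[length(rows) + 1L]] <- data.frame(
      x = x, y = y, a = bt$table@a, b = bt$table@b, c = bt$table@c,
      d = bt$table@d, count = forward@counts[x, y], p = bt$p,
      direction = if (is.na(bt$direction)) NA_character_ else bt$direction,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$qBY <- benjaminiYekutieli(out$p)
  attr(out, "alpha") <- alpha
  attr(out, "method") <- method
  out
}

#' Stratified (Mantel-Haenszel) substitution bias test
#'
#' Builds one adaptation-vs-background table per taxonomic stratum for a
#' single substitution pair and combines them with the Mantel-Haenszel
#' test, so that like is compared with like across strata.
#'
#' @param forwardByStratum,backgroundByStratum named lists of
#'   [SPMatrix-class] objects, one per stratum (names must match), or a
#'   list of ready-made 2 x 2 tables in \code{forwardByStratum} with
#'   \code{backgroundByStratum = NULL}.
#' @param x,y residue states (ignored when ready-made tables are given).
#' @return as [mantelHaenszel()], plus \code{tables}.
#' @export
mantelHaenszelBias <- function(forwardByStratum, backgroundByStratum = NULL,
                               x = NULL, y = NULL) {
  if (is.null(backgroundByStratum)) {
    tabs <- forwardByStratum
  } else {
    stopifnot(identical(names(forwardByStratum),
                        names(backgroundByStratum)),
              !is.null(x), !is.null(y))
    x <- .stateOf(.normalizeGaps(x)); y <- .stateOf(.normalizeGaps(y))
    tabs <- lapply(names(forwardByStratum), function(s)
      .biasTable(forwardByStratum[[s]], backgroundByStratum[[s]], x, y))
    names(tabs) <- names(forwardByStratum)
  }
  res <- mantelHaenszel(tabs)
  res$tables <- tabs
  res
}

#' @rdname SPMatrix-class
#' @export
setMethod("spCounts", "SPMatrix", function(x) x@counts)

#' @rdname SPMatrix-class
#' @export
setMethod("spKind", "SPMatrix", function(x) x@kind)

setMethod("show", "SPMatrix", function(object) {
  cat("SPMatrix (", object@kind, "), groups ", object@groupFrom, " -> ",
      object@groupTo, "\n", sep = "")
  cat("  ", object@nPairs, " sequence pair(s); total count ",
      format(sum(object@counts)), "\n", sep = "")
  if (object@kind == "representative")
    cat("  averaged over G_MP = ", object@gMP, " ordered pairs\n", sep = "")
})

#' Serialize an SP-matrix as a tab-separated table
#'
#' Writes the 21 x 21 count matrix with one-letter amino-acid headers and
#' \code{~} for the gap state.
#'
#' @param m an [SPMatrix-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSPMatrix <- function(m, path) {
  stopifnot(is(m, "SPMatrix"))
  df <- data.frame(state = rownames(m@counts), m@counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
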