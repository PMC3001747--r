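#' Amino-acid category schemes
#'
#' A category scheme maps named categories to disjoint sets of amino acids
#' (a partition or subset of the 20).  [builtinChargeScheme()] returns the
#' classical four-way charge partition: negatively charged (D, E),
#' positively charged (K, R), uncharged polar (C, S, T, Y, N, Q, W, H) and
#' hydrophobic (G, A, V, L, I, F, P, M).
#'
#' @param categories named list of character vectors of one-letter
#'   amino-acid codes.
#' @return a validated named list of class \code{CategoryScheme}.
#' @examples
#' builtinChargeScheme()
#' @export
categoryScheme <- function(categories) {
  stopifnot(is.list(categories), !is.null(names(categories)))
  aas <- unlist(categories)
  if (!all(aas %in% AA_CODES))
    stop("unknown amino-acid code(s): ",
         paste(setdiff(aas, AA_CODES), collapse = ", "))
  if (anyDuplicated(aas))
    stop("amino acid(s) in more than one category: ",
         paste(unique(aas[duplicated(aas)]), collapse = ", "))
  structure(lapply(categories, as.character), class = "CategoryScheme")
}

#' @rdname categoryScheme
#' @export
builtinChargeScheme <- function() {
  categoryScheme(list(
    negative       = c("D", "E"),
    positive       = c("K", "R"),
    uncharged_polar = c("C", "S", "T", "Y", "N", "Q", "W", "H"),
    hydrophobic    = c("G", "A", "V", "L", "I", "F", "P", "M")
  ))
}

#' Composition of a single aligned sequence
#'
#' Frequencies of the 20 amino acids (or of scheme categories) over the
#' non-gap residues of the sequence, optionally restricted to a site
#' subset.  Gaps never enter the denominator.
#'
#' @param residues a residue string (gaps \code{-}, \code{.}, \code{~}) or
#'   character vector of single residues.
#' @param scheme optional \code{CategoryScheme}; with a scheme the result
#'   is per-category totals.
#' @param sites optional integer vector of 1-based site positions.
#' @return named frequency vector summing to 1, with attribute
#'   \code{nResidues} (the non-gap count used as denominator).  An all-gap
#'   selection yields NA frequencies flagged \code{not_computable}.
#' @examples
#' compositionVector("D-K~")
#' compositionVector("DEKR", scheme = builtinChargeScheme())
#' @export
compositionVector <- function(residues, scheme = NULL, sites = NULL) {
  if (length(residues) == 1L && nchar(residues[1L]) > 1L)
    residues <- strsplit(toupper(.normalizeGaps(residues)), "",
                         fixed = TRUE)[[1L]]
  else residues <- toupper(.normalizeGaps(residues))
  if (!is.null(sites)) residues <- residues[sites]
  residues <- residues[!.isGap(residues)]
  n <- length(residues)
  if (n == 0L) {
    feats <- if (is.null(scheme)) AA_CODES else names(scheme)
    out <- stats::setNames(rep(NA_real_, length(feats)), feats)
    attr(out, "nResidues") <- 0L
    attr(out, "flags") <- "not_computable"
    return(out)
  }
  aaFreq <- tabulate(factor(residues, levels = AA_CODES), 20L) / n
  names(aaFreq) <- AA_CODES
  out <- if (is.null(scheme)) aaFreq
         else vapply(scheme, function(a) sum(aaFreq[a]), 0)
  attr(out, "nResidues") <- n
  out
}

## Per-sequence feature-frequency matrix for one alignment (rows follow
## seqIds); NA rows for all-gap sequences.
.featureMatrix <- function(aln, scheme = NULL, sites = NULL) {
  res <- residueMatrix(aln)
  if (!is.null(sites)) res <- res[, sites, drop = FALSE]
  feats <- if (is.null(scheme)) AA_CODES else names(scheme)
  out <- matrix(NA_real_, nrow(res), length(feats),
                dimnames = list(rownames(res), feats))
  for (i in seq_len(nrow(res))) {
    v <- compositionVector(res[i, ], scheme = scheme)
    out[i, ] <- as.numeric(v)
  }
  out
}

## Group-mean composition within one alignment, optionally collapsing
## phylogenetically dependent sequences to per-stratum means first.
.groupMeanComposition <- function(fm, groups, strataVec, code, collapse) {
  sel <- which(!is.na(groups) & groups == code &
                 !is.na(fm[, 1, drop = TRUE]))
  if (!length(sel)) return(NULL)
  if (!collapse) return(colMeans(fm[sel, , drop = FALSE]))
  st <- strataVec[sel]
  st[is.na(st)] <- "<none>"
  cellMeans <- rowsum(fm[sel, , drop = FALSE], st) /
    as.vector(table(st)[sort(unique(st))])
  colMeans(cellMeans)
}

#' Mean compositional change between two phenotypic groups
#'
#' For each alignment containing both groups, the per-feature delta is the
#' mean composition in the target group minus the mean in the source group
#' (the direction of adaptation, e.g. mesophile to psychrophile).  With
#' \code{collapseDependent}, sequence compositions are first averaged
#' within group at each stratum, so dependent sequences count as one
#' observation.  Returned are the across-alignment mean delta, empirical
#' standard deviation and alignment count per feature.
#'
#' @param alns list of group-assigned [AnnotatedAlignment-class] objects.
#' @param groupFrom,groupTo ordinal codes of the source and target groups.
#' @param scheme optional \code{CategoryScheme}.
#' @param sites optional [SiteFilter-class] applied to each alignment.
#' @param collapseDependent average within group/stratum cells before
#'   differencing (default FALSE).
#' @return data.frame with columns \code{feature}, \code{meanDelta},
#'   \code{sd}, \code{n}.
#' @export
deltaComposition <- function(alns, groupFrom, groupTo, scheme = NULL,
                             sites = NULL, collapseDependent = FALSE) {
  if (is(alns, "AnnotatedAlignment")) alns <- list(alns)
  deltas <- list()
  for (aln in alns) {
    if (!is.null(sites)) aln <- filterSites(aln, sites)
    fm <- .featureMatrix(aln, scheme)
    g <- groupCodes(aln)
    s <- strata(aln)
    mFrom <- .groupMeanComposition(fm, g, s, groupFrom, collapseDependent)
    mTo <- .groupMeanComposition(fm, g, s, groupTo, collapseDependent)
    if (is.null(mFrom) || is.null(mTo)) next
    deltas[[length(deltas) + 1L]] <- mTo - mFrom
  }
  if (!length(deltas))
    stop("group ", groupFrom, " or ", groupTo,
         " is absent from every alignment")
  dm <- do.call(rbind, deltas)
  data.frame(feature = colnames(dm),
             meanDelta = colMeans(dm),
             sd = apply(dm, 2, stats::sd),
             n = nrow(dm),
             row.names = NULL, stringsAsFactors = FALSE)
}

.designsFor2Groups <- c("anova", "wilcoxon")

#' Trend test of one compositional feature across phenotypic groups
#'
#' Dispatches to the statistical kernel prescribed by the design matrix:
#' ANOVA and paired Wilcoxon compare exactly 2 groups; linear regression
#' and the cumulative Mann-Kendall test accept 2 or more ordered groups.
#' The per-sequence feature frequency is the response and the ordinal
#' group code the predictor; for the cumulative Mann-Kendall test each
#' alignment is one block, and for the Wilcoxon test the per-alignment
#' paired group-mean deltas form the sample.
#'
#' @param alns list of group-assigned [AnnotatedAlignment-class] objects.
#' @param feature an amino-acid code or a category name of \code{scheme}.
#' @param design \code{"anova"}, \code{"regression"},
#'   \code{"cumulative_mk"} or \code{"wilcoxon"}.
#' @param scheme optional \code{CategoryScheme} (required when
#'   \code{feature} is a category).
#' @param sites optional [SiteFilter-class].
#' @param collapseDependent for \code{"cumulative_mk"}: collapse each
#'   block to its group/stratum means first.
#' @return list with \code{design}, \code{p} and the kernel's full result
#'   in \code{detail}.
#' @export
compositionTrend <- function(alns, feature,
                             design = c("cumulative_mk", "anova",
                                        "regression", "wilcoxon"),
                             scheme = NULL, sites = NULL,
                             collapseDependent = FALSE) {
  design <- match.arg(design)
  if (is(alns, "AnnotatedAlignment")) alns <- list(alns)
  if (!is.null(sites)) alns <- lapply(alns, filterSites, filter = sites)
  fms <- lapply(alns, .featureMatrix, scheme = scheme)
  if (!all(vapply(fms, function(m) feature %in% colnames(m), TRUE)))
    stop("unknown feature: ", feature)
  codes <- sort(unique(stats::na.omit(unlist(lapply(alns, groupCodes)))))
  if (design %in% .designsFor2Groups && length(codes) != 2)
    stop(design, " requires exactly 2 phenotypic groups (the design ",
         "matrix assigns regression / cumulative Mann-Kendall to >2 ",
         "ordered groups); found ", length(codes))
  if (length(codes) < 2) stop("at least 2 phenotypic groups are required")

  perSeq <- function() {
    y <- unlist(lapply(seq_along(alns), function(i) fms[[i]][, feature]))
    x <- unlist(lapply(alns, groupCodes))
    ok <- !is.na(y) & !is.na(x)
    list(x = x[ok], y = y[ok])
  }
  res <- switch(design,
    anova = {
      d <- perSeq()
      anovaGroupEffect(d$y, d$x)
    },
    regression = {
      d <- perSeq()
      olsTrend(d$y, d$x)
    },
    cumulative_mk = {
      blocks <- lapply(seq_along(alns), function(i) {
        y <- fms[[i]][, feature]
        x <- groupCodes(alns[[i]])
        if (collapseDependent) {
          s <- strata(alns[[i]])
          s[is.na(s)] <- "<none>"
          cell <- interaction(x, s, drop = TRUE)
          y <- tapply(y, cell, mean, na.rm = TRUE)
          x <- tapply(x, cell, unique)
        }
        list(x = as.numeric(x), y = as.numeric(y))
      })
      cumulativeMannKendall(blocks)
    },
    wilcoxon = {
      d <- deltaCompositionPerAlignment(alns, codes[1], codes[2],
                                        scheme = scheme)
      wilcoxonPaired(d[, feature])
    })
  p <- if (is(res, "TrendResult")) trendP(res)
       else if (is(res, "RegressionResult")) slopeP(res)
       else if (is.list(res)) res$p
       else as.numeric(res)
  list(design = design, p = p, detail = res)
}

## Per-alignment matrix of group-mean deltas (rows = alignments).
deltaCompositionPerAlignment <- function(alns, groupFrom, groupTo,
                                         scheme = NULL,
                                         collapseDependent = FALSE) {
  rows <- list()
  for (aln in alns) {
    fm <- .featureMatrix(aln, scheme)
    g <- groupCodes(aln)
    s <- strata(aln)
    mF <- .groupMeanComposition(fm, g, s, groupFrom, collapseDependent)
    mT <- .groupMeanComposition(fm, g, s, groupTo, collapseDependent)
    if (is.null(mF) || is.null(mT)) next
    rows[[length(rows) + 1L]] <- mT - mF
  }
  if (!length(rows)) stop("no alignment contains both groups")
  do.call(rbind, rows)
}

#' Per-feature composition scan with FDR control
#'
#' Runs [deltaComposition()] and [compositionTrend()] for every feature (20
#' amino acids, or the categories of \code{scheme}) between the lowest and
#' highest phenotypic group, and reports Benjamini-Yekutieli q-values
#' alongside the raw p-values.  This is the tabular form behind the
#' mean-compositional-change bar plot.
#'
#' @inheritParams compositionTrend
#' @param alpha significance level used downstream, recorded as an
#'   attribute (default 0.05).
#' @return data.frame with columns \code{feature}, \code{meanDelta},
#'   \code{sd}, \code{n}, \code{p}, \code{qBY}.
#' @export
compositionScan <- function(alns,
                            design = c("cumulative_mk", "anova",
                                       "regression", "wilcoxon"),
                            scheme = NULL, sites = NULL,
                            collapseDependent = FALSE, alpha = 0.05) {
  design <- match.arg(design)
  if (is(alns, "AnnotatedAlignment")) alns <- list(alns)
  codes <- sort(unique(stats::na.omit(unlist(lapply(alns, groupCodes)))))
  tab <- deltaComposition(alns, min(codes), max(codes), scheme = scheme,
                          sites = sites,
                          collapseDependent = collapseDependent)
  ## rare features routinely yield degenerate (constant) blocks in small
  ## families; the per-feature trend call warns about them, which is noise
  ## at scan level
  tab$p <- vapply(tab$feature, function(f)
    suppressWarnings(
      compositionTrend(alns, f, design = design, scheme = scheme,
                       sites = sites,
                       collapseDependent = collapseDependent)$p), 0)
  tab$qBY <- benjaminiYekutieli(tab$p)
  attr(tab, "alpha") <- alpha
  attr(tab, "design") <- design
  tab
}
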