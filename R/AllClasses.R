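## Central S4 containers.  Matrices are used row-per-sequence so that column
## (site) operations vectorize; optional annotations are same-shape matrices
## with NA rows for unannotated sequences.

#' AnnotatedAlignment: an aligned protein family with optional annotation
#'
#' Equal-length aligned protein sequences with optional per-site secondary
#' structure (H/E/C) and relative accessible surface area (RSA in \[0,1\])
#' annotation, and per-sequence ordinal phenotypic group codes and taxonomic
#' strata.
#'
#' @slot alignmentId single identifier string.
#' @slot residues character matrix (sequences x sites) of one-letter
#'   amino-acid codes; gaps are stored as \code{"-"}.
#' @slot ss character matrix of secondary-structure states \code{H}, \code{E},
#'   \code{C} or gap; all-NA rows mark unannotated sequences.
#' @slot rsa numeric matrix of relative accessible surface areas in \[0,1\];
#'   NA allowed (always allowed at gap sites).
#' @slot group integer vector of ordinal phenotype codes (NA = unassigned).
#' @slot stratum character vector of taxonomic strata (NA = none).
#' @slot groupLabels ordered group labels; position = ordinal code.
#' @slot siteIndex 1-based column indices into the original alignment; kept
#'   through site filtering so reports can cite original coordinates.
#'
#' @exportClass AnnotatedAlignment
setClass("AnnotatedAlignment",
  representation(
    alignmentId = "character",
    residues    = "matrix",
    ss          = "matrix",
    rsa         = "matrix",
    group       = "integer",
    stratum     = "character",
    groupLabels = "character",
    siteIndex   = "integer"
  )
)

setValidity("AnnotatedAlignment", function(object) {
  msgs <- character()
  res <- object@residues
  if (nrow(res) < 2L)
    msgs <- c(msgs, "an alignment needs at least 2 sequences")
  if (is.null(rownames(res)))
    msgs <- c(msgs, "residue matrix must carry sequence ids as rownames")
  ok <- res %in% c(AA_CODES, GAP_CHAR)
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    msgs <- c(msgs, sprintf("illegal residue character '%s' (sequence %s, column %d)",
                            res[bad], rownames(res)[(bad - 1L) %% nrow(res) + 1L],
                            (bad - 1L) %/% nrow(res) + 1L))
  }
  for (nm in c("ss", "rsa")) {
    m <- slot(object, nm)
    if (!identical(dim(m), dim(res)))
      msgs <- c(msgs, sprintf("%s matrix dimensions do not match residues", nm))
  }
  if (!all(object@ss %in% c(SS_CODES, GAP_CHAR, NA)))
    msgs <- c(msgs, "secondary-structure states must be H, E, C or gap")
  rs <- object@rsa[!is.na(object@rsa)]
  if (length(rs) && (min(rs) < 0 || max(rs) > 1))
    msgs <- c(msgs, "rsa values must lie in [0,1]")
  if (length(object@group) != nrow(res) || length(object@stratum) != nrow(res))
    msgs <- c(msgs, "group/stratum length must equal the number of sequences")
  if (any(!is.na(object@group) & object@group < 1L))
    msgs <- c(msgs, "group codes must be positive integers")
  if (length(object@siteIndex) != ncol(res))
    msgs <- c(msgs, "siteIndex length must equal the number of sites")
  if (length(msgs)) msgs else TRUE
})

#' GroupScheme: ordinal phenotype groups and per-sequence assignment
#'
#' An ordered list of phenotypic group labels (position in the list is the
#' ordinal code 1..K) together with a per-sequence assignment of group and
#' optional taxonomic stratum.
#'
#' @slot labels ordered group labels; code of \code{labels[k]} is \code{k}.
#' @slot groups named character vector: sequence id -> group label.
#' @slot strata named character vector: sequence id -> stratum (NA = none).
#'
#' @exportClass GroupScheme
setClass("GroupScheme",
  representation(labels = "character", groups = "character",
                 strata = "character"))

setValidity("GroupScheme", function(object) {
  msgs <- character()
  if (!length(object@labels) || anyDuplicated(object@labels))
    msgs <- c(msgs, "group labels must be non-empty and unique")
  if (is.null(names(object@groups)))
    msgs <- c(msgs, "group assignment must be named by sequence id")
  bad <- setdiff(unique(object@groups), object@labels)
  if (length(bad))
    msgs <- c(msgs, paste0("assigned label(s) not in the ordered group list: ",
                           paste(bad, collapse = ", ")))
  if (!identical(names(object@groups), names(object@strata)))
    msgs <- c(msgs, "strata must be named identically to groups")
  if (length(msgs)) msgs else TRUE
})

#' SiteFilter: structural constraints on alignment columns
#'
#' Restricts alignment columns by secondary-structure class and/or solvent
#' exposure.  A column passes when the fraction of annotated non-gap
#' sequences satisfying the constraint is at least \code{consensus}.
#'
#' @slot ssClasses subset of H, E, C (empty = no secondary-structure
#'   constraint).
#' @slot exposure one of \code{"any"}, \code{"surface"}, \code{"core"};
#'   surface means RSA >= threshold, core means RSA < threshold.
#' @slot rsaThreshold RSA cut between core and surface, default 0.25.
#' @slot consensus fraction of annotated non-gap sequences that must satisfy
#'   the constraint (\code{>=} comparison), default 0.5.
#'
#' @exportClass SiteFilter
setClass("SiteFilter",
  representation(ssClasses = "character", exposure = "character",
                 rsaThreshold = "numeric", consensus = "numeric"))

setValidity("SiteFilter", function(object) {
  msgs <- character()
  if (!all(object@ssClasses %in% SS_CODES))
    msgs <- c(msgs, "ssClasses must be a subset of H, E, C")
  if (!object@exposure %in% c("any", "surface", "core"))
    msgs <- c(msgs, "exposure must be 'any', 'surface' or 'core'")
  if (object@rsaThreshold < 0 || object@rsaThreshold > 1)
    msgs <- c(msgs, "rsaThreshold must lie in [0,1]")
  if (object@consensus <= 0 || object@consensus > 1)
    msgs <- c(msgs, "consensus must lie in (0,1]")
  if (length(msgs)) msgs else TRUE
})

#' SPMatrix: substitution-pair count matrix
#'
#' A 21 x 21 (20 amino acids + gap, labelled \code{~}) matrix of
#' substitution-pair counts n(x,y) between or within phenotypic groups,
#' summed over all alignment sites where x != y.
#'
#' @slot counts 21 x 21 nonnegative matrix, zero diagonal; rows = replaced
#'   residue x (source group), columns = replacement residue y.
#' @slot kind \code{"directional_between"}, \code{"symmetric_within"} or
#'   \code{"representative"}.
#' @slot groupFrom,groupTo ordinal codes of the source and target groups.
#' @slot nPairs number of sequence pairs tallied.
#' @slot gMP representative kind only: number of ordered cross-group
#'   sequence pairs used as the averaging denominator.
#'
#' @exportClass SPMatrix
setClass("SPMatrix",
  representation(counts = "matrix", kind = "character",
                 groupFrom = "integer", groupTo = "integer",
                 nPairs = "integer", gMP = "numeric"))

setValidity("SPMatrix", function(object) {
  msgs <- character()
  cts <- object@counts
  if (!identical(dim(cts), c(21L, 21L)) ||
      !identical(rownames(cts), SUB_STATES))
    msgs <- c(msgs, "counts must be 21 x 21 with amino-acid + '~' dimnames")
  if (any(cts < 0)) msgs <- c(msgs, "counts must be nonnegative")
  if (any(diag(cts) != 0))
    msgs <- c(msgs, "diagonal must be zero (pairs are counted only where x != y)")
  if (!object@kind %in% c("directional_between", "symmetric_within",
                          "representative"))
    msgs <- c(msgs, "unknown SPMatrix kind")
  if (object@kind == "symmetric_within" && !isTRUE(all.equal(cts, t(cts))))
    msgs <- c(msgs, "within-group SP-matrix must be symmetric")
  if (length(msgs)) msgs else TRUE
})

#' ContingencyTable2x2: adaptation-vs-background substitution table
#'
#' The 2 x 2 layout comparing forward (adaptation, M -> P) counts of a
#' substitution pair against background (within-M) counts: row 1 is
#' adaptation, row 2 background; column 1 counts substitutions into the
#' target residue y, column 2 into any other residue.
#'
#' @slot a,b,c,d nonnegative cell counts: (a,b) = adaptation row,
#'   (c,d) = background row.
#' @slot rowLabels,colLabels semantic labels for reports.
#'
#' @exportClass ContingencyTable2x2
setClass("ContingencyTable2x2",
  representation(a = "numeric", b = "numeric", c = "numeric", d = "numeric",
                 rowLabels = "character", colLabels = "character"))

setValidity("ContingencyTable2x2", function(object) {
  cells <- c(object@a, object@b, object@c, object@d)
  if (any(cells < 0)) return("all cells must be nonnegative")
  TRUE
})

#' TrendResult: (cumulative) Mann-Kendall test result
#'
#' @slot S sum of concordance signs over all blocks.
#' @slot varS tie-corrected variance of S.
#' @slot Z continuity-corrected normal deviate.
#' @slot p two-sided p-value.
#' @slot nBlocks number of contributing blocks.
#' @slot nObs total number of observations across contributing blocks.
#' @slot flags diagnostic flags such as \code{"degenerate"} or
#'   \code{"blocks_skipped"}.
#'
#' @exportClass TrendResult
setClass("TrendResult",
  representation(S = "numeric", varS = "numeric", Z = "numeric",
                 p = "numeric", nBlocks = "integer", nObs = "integer",
                 flags = "character"))

#' RegressionResult: common-slope (optionally stratified) linear fit
#'
#' Ordinary least squares of a response on the ordinal group code, with
#' optional stratum-specific intercepts (parallelism model): the fitted
#' model is Y = beta0 + beta1 * X + sum_s beta_s I_s + e, where beta0 is the
#' intercept of the baseline stratum and I_s are stratum dummies.
#'
#' @slot beta0 intercept of the baseline (first-sorted) stratum.
#' @slot beta1 common slope on the ordinal predictor.
#' @slot strataOffsets named vector of stratum-specific intercept offsets;
#'   empty when a single stratum is supplied.
#' @slot seSlope standard error of the slope.
#' @slot pSlope two-sided p-value of the slope t-statistic.
#' @slot n number of observations.
#'
#' @exportClass RegressionResult
setClass("RegressionResult",
  representation(beta0 = "numeric", beta1 = "numeric",
                 strataOffsets = "numeric", seSlope = "numeric",
                 pSlope = "numeric", n = "integer"))

#' PropertyScale: a physicochemical property of the 20 amino acids
#'
#' @slot name scale name.
#' @slot values named numeric vector over the 20 standard amino acids.
#' @slot source provenance string (bundled citation or user file path).
#'
#' @exportClass PropertyScale
setClass("PropertyScale",
  representation(name = "character", values = "numeric", source = "character"))

setValidity("PropertyScale", function(object) {
  v <- object@values
  if (length(v) != 20L || !setequal(names(v), AA_CODES))
    return("a property scale needs exactly the 20 standard amino acids")
  if (any(!is.finite(v))) return("all scale values must be finite")
  TRUE
})
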