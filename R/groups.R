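#' Construct a GroupScheme
#'
#' @param labels ordered character vector of group labels; the position of a
#'   label is its ordinal code (1 = first, e.g. mesophile; K = last, e.g.
#'   psychrophile).
#' @param groups named character vector mapping sequence id to group label.
#' @param strata optional named character vector mapping sequence id to
#'   taxonomic stratum.
#' @return a [GroupScheme-class] object.
#' @examples
#' sch <- GroupScheme(c("meso", "psychro"),
#'                    c(s1 = "meso", s2 = "psychro"))
#' groupCode(sch, "psychro")
#' @export
GroupScheme <- function(labels, groups, strata = NULL) {
  groups <- unlist(groups)
  if (is.null(strata)) {
    strata <- stats::setNames(rep(NA_character_, length(groups)),
                              names(groups))
  } else {
    strata <- unlist(strata)[names(groups)]
    names(strata) <- names(groups)
  }
  new("GroupScheme", labels = as.character(labels), groups = groups,
      strata = stats::setNames(as.character(strata), names(groups)))
}

#' @rdname GroupScheme
#' @param scheme a [GroupScheme-class].
#' @param label group label(s).
#' @export
groupCode <- function(scheme, label) match(label, scheme@labels)

#' @rdname GroupScheme
#' @export
setMethod("groupLabels", "GroupScheme", function(x) x@labels)

setMethod("show", "GroupScheme", function(object) {
  cat("GroupScheme with ", length(object@labels), " ordered groups: ",
      paste(sprintf("%s(%d)", object@labels, seq_along(object@labels)),
            collapse = " < "), "\n", sep = "")
  cat("  ", length(object@groups), " assigned sequence id(s); ",
      sum(!is.na(object@strata)), " with strata\n", sep = "")
})

#' Attach ordinal group codes and strata to an alignment
#'
#' Each sequence of the alignment receives the ordinal phenotype code and
#' (optional) taxonomic stratum recorded for its id in the scheme.  The
#' input alignment is not modified.
#'
#' @param aln an [AnnotatedAlignment-class].
#' @param scheme a [GroupScheme-class] covering every sequence id of
#'   \code{aln}.
#' @return a new [AnnotatedAlignment-class] with group and stratum set.
#' @examples
#' aln <- AnnotatedAlignment("fam1", c(s1 = "ACDE", s2 = "ACDF"))
#' sch <- GroupScheme(c("meso", "psychro"),
#'                    c(s1 = "meso", s2 = "psychro"))
#' groupCodes(assignGroups(aln, sch))
#' @export
assignGroups <- function(aln, scheme) {
  stopifnot(is(aln, "AnnotatedAlignment"), is(scheme, "GroupScheme"))
  ids <- seqIds(aln)
  missing <- setdiff(ids, names(scheme@groups))
  if (length(missing))
    stop("sequence id(s) missing from the group scheme: ",
         paste(missing, collapse = ", "))
  codes <- groupCode(scheme, scheme@groups[ids])
  empty <- setdiff(seq_along(scheme@labels), unique(codes))
  if (length(empty))
    warning("group(s) with zero sequences in alignment '", aln@alignmentId,
            "': ", paste(scheme@labels[empty], collapse = ", "))
  new("AnnotatedAlignment", alignmentId = aln@alignmentId,
      residues = aln@residues, ss = aln@ss, rsa = aln@rsa,
      group = as.integer(codes),
      stratum = unname(scheme@strata[ids]),
      groupLabels = scheme@labels, siteIndex = aln@siteIndex)
}

#' Construct a SiteFilter
#'
#' @param ss secondary-structure classes to keep (subset of \code{"H"},
#'   \code{"E"}, \code{"C"}); \code{NULL} means no constraint.
#' @param exposure \code{"any"}, \code{"surface"} (RSA >= threshold) or
#'   \code{"core"} (RSA < threshold).
#' @param rsaThreshold RSA cut separating core from surface, default 0.25.
#' @param consensus minimum fraction of annotated non-gap sequences that
#'   must satisfy the constraint for a column to pass (default 0.5, compared
#'   with \code{>=}).
#' @return a [SiteFilter-class].
#' @export
siteFilter <- function(ss = NULL, exposure = c("any", "surface", "core"),
                       rsaThreshold = 0.25, consensus = 0.5) {
  exposure <- match.arg(exposure)
  new("SiteFilter", ssClasses = as.character(ss %||% character()),
      exposure = exposure, rsaThreshold = rsaThreshold,
      consensus = consensus)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "SiteFilter", function(object) {
  ssTxt <- if (length(object@ssClasses))
    paste(object@ssClasses, collapse = "/") else "any"
  cat("SiteFilter: ss = ", ssTxt, ", exposure = ", object@exposure,
      " (RSA threshold ", object@rsaThreshold, "), consensus >= ",
      object@consensus, "\n", sep = "")
})

#' Filter alignment columns by structural constraints
#'
#' Keeps the columns where the fraction of annotated, non-gap sequences
#' satisfying the filter's constraints is at least the consensus fraction.
#' Surface means RSA >= \code{rsaThreshold}; core means RSA < threshold.
#' Kept columns retain their original 1-based coordinates in
#' \code{siteIndex()}.
#'
#' @param aln an [AnnotatedAlignment-class].
#' @param filter a [SiteFilter-class].
#' @return the column-subset [AnnotatedAlignment-class].
#' @examples
#' aln <- AnnotatedAlignment("fam1",
#'   c(s1 = "ACDEF", s2 = "ACDEF"),
#'   ss = list(s1 = "HHEEC", s2 = "HHEEC"))
#' siteIndex(filterSites(aln, siteFilter(ss = "H")))
#' @export
filterSites <- function(aln, filter) {
  stopifnot(is(aln, "AnnotatedAlignment"), is(filter, "SiteFilter"))
  useSS <- length(filter@ssClasses) > 0L
  useRSA <- filter@exposure != "any"
  if (!useSS && !useRSA) return(aln)
  hasSS <- rowSums(!is.na(aln@ss)) > 0
  hasRSA <- rowSums(!is.na(aln@rsa)) > 0
  if (useSS && !any(hasSS))
    stop("filter requires secondary-structure annotation but no sequence has it")
  if (useRSA && !any(hasRSA))
    stop("filter requires RSA annotation but no sequence has it")

  nonGap <- !.isGap(aln@residues)
  annotated <- nonGap
  ok <- matrix(TRUE, nrow(annotated), ncol(annotated))
  if (useSS) {
    annotated <- annotated & !is.na(aln@ss)
    ok <- ok & !is.na(aln@ss) & (aln@ss %in% filter@ssClasses)
  }
  if (useRSA) {
    annotated <- annotated & !is.na(aln@rsa)
    pass <- if (filter@exposure == "surface")
      aln@rsa >= filter@rsaThreshold else aln@rsa < filter@rsaThreshold
    pass[is.na(pass)] <- FALSE
    ok <- ok & pass
  }
  ok <- ok & annotated
  denom <- colSums(annotated)
  frac <- ifelse(denom > 0, colSums(ok) / denom, 0)
  keep <- which(frac >= filter@consensus & denom > 0)
  .subsetSites(aln, keep)
}
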