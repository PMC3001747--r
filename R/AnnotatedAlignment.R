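#' Construct an AnnotatedAlignment
#'
#' @param alignmentId identifier string for the alignment (protein family).
#' @param residues named character vector of aligned sequences (equal
#'   length, one string per sequence), or a sequences x sites character
#'   matrix with sequence ids as rownames.  Gap characters \code{-},
#'   \code{.} and \code{~} are accepted and normalized.
#' @param ss optional named character vector/list of secondary-structure
#'   strings over H, E, C and gap (names = sequence ids; sequences may be
#'   omitted).
#' @param rsa optional named list of numeric vectors of relative accessible
#'   surface area in \[0,1\] (names = sequence ids).
#' @param group optional integer vector of ordinal group codes per sequence.
#' @param stratum optional character vector of strata per sequence.
#' @param groupLabels optional ordered group labels (position = code).
#' @param siteIndex optional original 1-based column indices.
#' @return an [AnnotatedAlignment-class] object.
#' @examples
#' aln <- AnnotatedAlignment("fam1", c(s1 = "ACDE", s2 = "ACDF"))
#' nSites(aln)
#' @export
AnnotatedAlignment <- function(alignmentId, residues, ss = NULL, rsa = NULL,
                               group = NULL, stratum = NULL,
                               groupLabels = character(),
                               siteIndex = NULL) {
  if (!is.matrix(residues)) {
    stopifnot(!is.null(names(residues)))
    resStrings <- toupper(.normalizeGaps(residues))
    lens <- nchar(resStrings)
    if (length(unique(lens)) != 1L)
      stop("aligned sequences must all have the same length")
    residues <- matrix(unlist(strsplit(resStrings, "", fixed = TRUE)),
                       nrow = length(resStrings), byrow = TRUE,
                       dimnames = list(names(resStrings), NULL))
  } else {
    residues[] <- toupper(.normalizeGaps(residues))
  }
  n <- nrow(residues)
  p <- ncol(residues)
  ids <- rownames(residues)

  ssMat <- matrix(NA_character_, n, p, dimnames = list(ids, NULL))
  if (!is.null(ss)) {
    for (id in names(ss)) {
      if (!id %in% ids)
        stop("annotation record for unknown sequence: ", id)
      s <- ss[[id]]
      if (length(s) == 1L && is.character(s))
        s <- strsplit(toupper(.normalizeGaps(s)), "", fixed = TRUE)[[1L]]
      if (length(s) != p)
        stop("secondary-structure record length mismatch for sequence ", id)
      ssMat[id, ] <- s
    }
  }
  rsaMat <- matrix(NA_real_, n, p, dimnames = list(ids, NULL))
  if (!is.null(rsa)) {
    for (id in names(rsa)) {
      if (!id %in% ids)
        stop("annotation record for unknown sequence: ", id)
      v <- rsa[[id]]
      if (length(v) != p)
        stop("rsa record length mismatch for sequence ", id)
      rsaMat[id, ] <- v
    }
  }
  if (is.null(group)) group <- rep(NA_integer_, n)
  if (is.null(stratum)) stratum <- rep(NA_character_, n)
  if (is.null(siteIndex)) siteIndex <- seq_len(p)
  new("AnnotatedAlignment", alignmentId = as.character(alignmentId),
      residues = residues, ss = ssMat, rsa = rsaMat,
      group = as.integer(group), stratum = as.character(stratum),
      groupLabels = as.character(groupLabels),
      siteIndex = as.integer(siteIndex))
}

#' @rdname AnnotatedAlignment-class
#' @export
setMethod("alignmentId", "AnnotatedAlignment", function(x) x@alignmentId)

#' @rdname AnnotatedAlignment-class
#' @export
setMethod("nSites", "AnnotatedAlignment", function(x) ncol(x@residues))

#' @rdname AnnotatedAlignment-class
#' @export
setMethod("nSeqs", "AnnotatedAlignment", function(x) nrow(x@residues))

#' @rdname AnnotatedAlignment-class
#' @export
setMethod("seqIds", "AnnotatedAlignment", function(x) rownames(x@residues))

#' @rdname AnnotatedAlignment-class
#' @export
setMethod("residueMatrix", "AnnotatedAlignment", function(x) x@residues)

#' @rdname AnnotatedAlignment-class
#' @export
setMethod("ssMatrix", "AnnotatedAlignment", function(x) x@ss)

#' @rdname AnnotatedAlignment-class
#' @export
setMethod("rsaMatrix", "AnnotatedAlignment", function(x) x@rsa)

#' @rdname AnnotatedAlignment-class
#' @export
setMethod("groupCodes", "AnnotatedAlignment", function(x)
  stats::setNames(x@group, rownames(x@residues)))

#' @rdname AnnotatedAlignment-class
#' @export
setMethod("strata", "AnnotatedAlignment", function(x)
  stats::setNames(x@stratum, rownames(x@residues)))

#' @rdname AnnotatedAlignment-class
#' @export
setMethod("siteIndex", "AnnotatedAlignment", function(x) x@siteIndex)

#' @rdname AnnotatedAlignment-class
#' @export
setMethod("groupLabels", "AnnotatedAlignment", function(x) x@groupLabels)

setMethod("show", "AnnotatedAlignment", function(object) {
  cat("AnnotatedAlignment '", object@alignmentId, "': ",
      nSeqs(object), " sequences x ", nSites(object), " sites\n", sep = "")
  nss <- sum(rowSums(!is.na(object@ss)) > 0)
  nrsa <- sum(rowSums(!is.na(object@rsa)) > 0)
  cat("  2D (secondary structure) on ", nss, " sequence(s); ",
      "3D (RSA) on ", nrsa, " sequence(s)\n", sep = "")
  if (any(!is.na(object@group))) {
    tab <- table(factor(object@group))
    cat("  groups: ", paste(sprintf("%s=%d", names(tab), tab),
                            collapse = ", "), "\n", sep = "")
  } else cat("  groups: unassigned\n")
})

## Subset columns of an alignment, keeping original site coordinates.
.subsetSites <- function(aln, keep) {
  keep <- as.integer(keep)
  new("AnnotatedAlignment", alignmentId = aln@alignmentId,
      residues = aln@residues[, keep, drop = FALSE],
      ss = aln@ss[, keep, drop = FALSE],
      rsa = aln@rsa[, keep, drop = FALSE],
      group = aln@group, stratum = aln@stratum,
      groupLabels = aln@groupLabels,
      siteIndex = aln@siteIndex[keep])
}
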