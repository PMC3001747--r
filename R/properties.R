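#' Load physicochemical property scales
#'
#' Returns the bundled scales -- hydrophobicity (Kyte-Doolittle),
#' residue volume (Zamyatnin), net charge at pH 7, polarity (Grantham)
#' and flexibility (Vihinen) -- plus any user scales parsed from
#' \code{path}.  A user file is either the simple 20-line
#' \code{AA<TAB>value} format (optional \code{# name:} header line), or an
#' AAindex1 flat file, detected by its \code{H} record.
#'
#' @param path optional path to a user scale file.
#' @return named list of [PropertyScale-class] objects.
#' @examples
#' names(loadPropertyScales())
#' @export
loadPropertyScales <- function(path = NULL) {
  bundled <- system.file("extdata", "property_scales.tsv",
                         package = "protrend", mustWork = TRUE)
  tab <- utils::read.delim(bundled, comment.char = "#",
                           stringsAsFactors = FALSE)
  scales <- lapply(split(tab, tab$scale), function(d) {
    new("PropertyScale", name = d$scale[1],
        values = stats::setNames(d$value, d$aa)[AA_CODES],
        source = d$source[1])
  })
  if (!is.null(path)) {
    user <- readPropertyScaleFile(path)
    scales[names(user)] <- user
  }
  scales
}

#' @rdname loadPropertyScales
#' @export
readPropertyScaleFile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^H ", lines))) return(.readAAindex(lines, path))
  nameLine <- grep("^#\\s*name:", lines, value = TRUE)
  name <- if (length(nameLine))
    trimws(sub("^#\\s*name:", "", nameLine[1])) else basename(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  aa <- toupper(vapply(parts, `[`, "", 1L))
  val <- as.numeric(vapply(parts, `[`, "", 2L))
  missing <- setdiff(AA_CODES, aa)
  if (length(missing))
    stop("scale '", name, "' is missing amino acid(s): ",
         paste(missing, collapse = ", "))
  sc <- new("PropertyScale", name = name,
            values = stats::setNames(val, aa)[AA_CODES],
            source = paste0("user file ", path))
  stats::setNames(list(sc), name)
}

## AAindex1 flat-file records: H <id>, D <description>, I <AA header> then
## two lines of 10 values in the order A R N D C Q E G H I / L K M F P S T
## W Y V, terminated by //.
.readAAindex <- function(lines, path) {
  order1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I")
  order2 <- c("L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  recs <- list()
  i <- 1L
  cur <- NULL
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^H ", ln)) cur <- list(id = trimws(sub("^H ", "", ln)))
    if (grepl("^D ", ln) && !is.null(cur))
      cur$desc <- trimws(sub("^D ", "", ln))
    if (grepl("^I ", ln) && !is.null(cur)) {
      v1 <- as.numeric(strsplit(trimws(lines[i + 1L]), "[ \t]+")[[1L]])
      v2 <- as.numeric(strsplit(trimws(lines[i + 2L]), "[ \t]+")[[1L]])
      if (length(v1) != 10L || length(v2) != 10L || anyNA(c(v1, v2)))
        stop("malformed AAindex value block for record ", cur$id)
      vals <- stats::setNames(c(v1, v2), c(order1, order2))[AA_CODES]
      recs[[cur$id]] <- new("PropertyScale", name = cur$id, values = vals,
                            source = paste0("AAindex record ", cur$id,
                                            " (", path, ")"))
      i <- i + 2L
    }
    i <- i + 1L
  }
  if (!length(recs)) stop("no AAindex records found in ", path)
  recs
}

#' @rdname PropertyScale-class
#' @export
setMethod("scaleValues", "PropertyScale", function(x) x@values)

#' @rdname PropertyScale-class
#' @export
setMethod("scaleName", "PropertyScale", function(x) x@name)

setMethod("show", "PropertyScale", function(object) {
  cat("PropertyScale '", object@name, "' (", object@source, ")\n",
      sep = "")
  print(round(object@values, 3))
})

#' Mean physicochemical property of a sequence
#'
#' Arithmetic mean of the scale values over the non-gap residues of the
#' sequence, optionally restricted to a site subset.  Gaps carry no
#' property value.
#'
#' @param residues residue string or character vector.
#' @param scale a [PropertyScale-class].
#' @param sites optional 1-based site positions.
#' @return the mean property value; NA (flagged \code{not_computable})
#'   for an all-gap selection.
#' @export
meanProperty <- function(residues, scale, sites = NULL) {
  stopifnot(is(scale, "PropertyScale"))
  r <- .residueVector(residues)
  if (!is.null(sites)) r <- r[sites]
  r <- r[!.isGap(r)]
  if (!length(r)) {
    out <- NA_real_
    attr(out, "flags") <- "not_computable"
    return(out)
  }
  mean(scale@values[r])
}

.maybeAssign <- function(alns, groups) {
  if (is(alns, "AnnotatedAlignment")) alns <- list(alns)
  if (!is.null(groups)) alns <- lapply(alns, assignGroups, scheme = groups)
  alns
}

## Per-sequence (X, Y) data for one alignment.
.propertyXY <- function(aln, scale, sites = NULL) {
  if (!is.null(sites)) aln <- filterSites(aln, sites)
  res <- residueMatrix(aln)
  y <- vapply(seq_len(nrow(res)), function(i)
    as.numeric(meanProperty(res[i, ], scale)), 0)
  list(x = as.numeric(groupCodes(aln)), y = y,
       stratum = as.character(strata(aln)))
}

#' Per-family property slopes
#'
#' For every alignment with at least two distinct group codes, the
#' ordinary least-squares slope of the per-sequence mean property on the
#' ordinal group code.  Alignments failing the precondition are skipped
#' with a warning.  The ranked distribution of these slopes is the
#' standard visual summary; significance should come from
#' [propertyTrendTest()].
#'
#' @param alns list of [AnnotatedAlignment-class] objects.
#' @param scale a [PropertyScale-class].
#' @param groups optional [GroupScheme-class] to assign on the fly.
#' @param sites optional [SiteFilter-class].
#' @return data.frame with columns \code{alignmentId}, \code{beta1},
#'   \code{nSeqs}, \code{scaleName}.
#' @export
familySlopes <- function(alns, scale, groups = NULL, sites = NULL) {
  alns <- .maybeAssign(alns, groups)
  rows <- list(); skipped <- 0L
  for (aln in alns) {
    d <- .propertyXY(aln, scale, sites)
    ok <- !is.na(d$x) & !is.na(d$y)
    x <- d$x[ok]; y <- d$y[ok]
    if (length(x) < 2 || length(unique(x)) < 2) {
      skipped <- skipped + 1L
      next
    }
    beta1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    rows[[length(rows) + 1L]] <- data.frame(
      alignmentId = alignmentId(aln), beta1 = beta1,
      nSeqs = length(x), scaleName = scale@name,
      stringsAsFactors = FALSE)
  }
  if (skipped > 0L)
    warning(skipped, " alignment(s) skipped (fewer than 2 distinct groups)")
  if (!length(rows))
    stop("no alignment has at least 2 distinct phenotypic groups")
  do.call(rbind, rows)
}

#' Cumulative Mann-Kendall trend test of a property across families
#'
#' Each alignment contributes one Mann-Kendall block of (group code, mean
#' property) pairs; blocks are combined by summing S and var(S).  With
#' \code{collapseDependent}, phylogenetically dependent sequences are
#' first collapsed to their group/stratum mean, so each cell counts once.
#'
#' @inheritParams familySlopes
#' @param collapseDependent collapse each block to group/stratum means.
#' @return a [TrendResult-class].
#' @export
propertyTrendTest <- function(alns, scale, groups = NULL, sites = NULL,
                              collapseDependent = FALSE) {
  alns <- .maybeAssign(alns, groups)
  blocks <- lapply(alns, function(aln) {
    d <- .propertyXY(aln, scale, sites)
    x <- d$x; y <- d$y
    if (collapseDependent) {
      s <- d$stratum
      s[is.na(s)] <- "<none>"
      cell <- interaction(x, s, drop = TRUE)
      y <- as.numeric(tapply(y, cell, mean, na.rm = TRUE))
      x <- as.numeric(tapply(x, cell, unique))
    }
    list(x = x, y = y)
  })
  cumulativeMannKendall(blocks)
}

#' Stratified regression of a property on the phenotype code
#'
#' Fits the parallelism model (common slope on the ordinal code, one
#' intercept offset per taxonomic stratum) to the sequences of a single
#' alignment.  When fewer than 2 usable strata (each with at least 2
#' sequences and 2 distinct codes overall) are present, the fit falls
#' back to the unstratified regression with a warning.
#'
#' @param aln a single [AnnotatedAlignment-class].
#' @param scale a [PropertyScale-class].
#' @param groups optional [GroupScheme-class].
#' @param sites optional [SiteFilter-class].
#' @return a [RegressionResult-class].
#' @export
stratifiedPropertyRegression <- function(aln, scale, groups = NULL,
                                         sites = NULL) {
  if (!is.null(groups)) aln <- assignGroups(aln, groups)
  d <- .propertyXY(aln, scale, sites)
  ok <- !is.na(d$x) & !is.na(d$y)
  x <- d$x[ok]; y <- d$y[ok]; s <- d$stratum[ok]
  usable <- names(which(table(s[!is.na(s)]) >= 2))
  if (length(usable) < 2) {
    warning("fewer than 2 usable strata; falling back to unstratified ",
            "regression")
    return(olsTrend(y, x))
  }
  olsTrend(y, x, strata = s)
}
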