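## Extended-FASTA dialect: plain aligned FASTA, optionally carrying per-site
## annotation as extra records whose headers are "<seq_id>|2D" (secondary
## structure, H/E/C/gap string) and "<seq_id>|3D" (relative accessible
## surface area; either a digit string with digit d -> (d+0.5)/10, or
## whitespace-separated decimals, values > 1 interpreted as percentages).
## Several alignments may share one file, separated by a comment line
## ("# id" or "; id") naming the next alignment.

#' Read annotated protein alignments from an extended-FASTA file
#'
#' Accepts plain aligned FASTA as well as the annotated dialect in which a
#' record \code{>id|2D} attaches a secondary-structure string (H, E, C or
#' gap) and \code{>id|3D} attaches relative accessible surface areas to
#' sequence \code{id}.  A 3D body that is a plain digit string is decoded by
#' digit d -> (d + 0.5)/10 (decile bin midpoints); otherwise the body is
#' whitespace-separated numbers in \[0,1\] (values > 1 are divided by 100;
#' \code{NA} and \code{-} mark missing values).  Multiple alignments in one
#' file are separated by a comment line (\code{#} or \code{;}) giving the
#' next alignment's id.
#'
#' @param path path to the file.
#' @return a list of [AnnotatedAlignment-class] objects.
#' @export
readAnnotatedFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[ \t\r]+$", "", lines)

  blocks <- list()
  cur <- character()
  curId <- NULL
  defaultId <- sub("\\.[^.]*$", "", basename(path))
  flush <- function() {
    if (length(cur))
      blocks[[length(blocks) + 1L]] <<- list(id = curId %||% defaultId,
                                             lines = cur)
    cur <<- character()
  }
  for (ln in lines) {
    if (grepl("^[#;]", ln)) {
      flush()
      id <- trimws(sub("^[#;]+", "", ln))
      curId <- if (nzchar(id)) id else NULL
    } else if (nzchar(trimws(ln))) {
      cur <- c(cur, ln)
    }
  }
  flush()
  if (!length(blocks)) stop("no FASTA records found in ", path)
  if (length(blocks) > 1L) {
    ids <- vapply(blocks, `[[`, "", "id")
    dup <- duplicated(ids)
    if (any(dup))
      for (i in which(dup)) blocks[[i]]$id <- paste0(ids[i], "_", i)
  }
  lapply(blocks, function(b) .parseAlignmentBlock(b$lines, b$id))
}

.parseAlignmentBlock <- function(lines, alignmentId) {
  headerAt <- grep("^>", lines)
  if (!length(headerAt)) stop("no FASTA records in alignment block '",
                              alignmentId, "'")
  if (headerAt[1L] != 1L)
    stop("sequence data before the first FASTA header in '", alignmentId, "'")
  ends <- c(headerAt[-1L] - 1L, length(lines))
  seqs <- list(); ss <- list(); rsa <- list()
  for (k in seq_along(headerAt)) {
    header <- trimws(sub("^>", "", lines[headerAt[k]]))
    header <- strsplit(header, "[ \t]")[[1L]][1L]
    body <- lines[seq(headerAt[k] + 1L, length.out = ends[k] - headerAt[k])]
    if (grepl("\\|2D$", header, ignore.case = TRUE)) {
      id <- sub("\\|2D$", "", header, ignore.case = TRUE)
      ss[[id]] <- paste(gsub("[ \t]", "", body), collapse = "")
    } else if (grepl("\\|3D$", header, ignore.case = TRUE)) {
      id <- sub("\\|3D$", "", header, ignore.case = TRUE)
      rsa[[id]] <- .parseRsaBody(body, id)
    } else {
      seqs[[header]] <- paste(gsub("[ \t]", "", body), collapse = "")
    }
  }
  if (!length(seqs))
    stop("alignment block '", alignmentId, "' has only annotation records")
  orphan <- setdiff(c(names(ss), names(rsa)), names(seqs))
  if (length(orphan))
    stop("annotation record(s) with no matching sequence: ",
         paste(unique(orphan), collapse = ", "))
  nsites <- nchar(seqs[[1L]])
  rsa <- lapply(stats::setNames(names(rsa), names(rsa)),
                function(id) .decodeRsaBody(rsa[[id]], id, nsites))
  AnnotatedAlignment(alignmentId, unlist(seqs), ss = ss, rsa = rsa)
}

.parseRsaBody <- function(body, id) paste(body, collapse = " ")

## A 3D body that is a pure digit string of exactly one character per site
## is decile-encoded (digit d -> bin midpoint (d+0.5)/10, '-' = missing);
## anything else is whitespace-separated numbers, with values > 1 read as
## percentages of the full surface area.
.decodeRsaBody <- function(joined, id, nsites) {
  compact <- gsub("[ \t]", "", joined)
  if (grepl("^[0-9-]+$", compact) && nchar(compact) == nsites) {
    digits <- strsplit(compact, "", fixed = TRUE)[[1L]]
    return(ifelse(digits == "-", NA_real_, (as.numeric(digits) + 0.5) / 10))
  }
  toks <- strsplit(trimws(joined), "[ \t]+")[[1L]]
  missing <- toupper(toks) %in% c("NA", "NAN", "-")
  v <- suppressWarnings(as.numeric(ifelse(missing, NA, toks)))
  if (any(is.na(v) & !missing))
    stop("unparseable RSA value in 3D record for sequence ", id)
  v[!is.na(v) & v > 1] <- v[!is.na(v) & v > 1] / 100
  if (any(!is.na(v) & (v < 0 | v > 1)))
    stop("RSA values out of range for sequence ", id)
  v
}

#' Write annotated alignments in the extended-FASTA dialect
#'
#' The inverse of [readAnnotatedFasta()]: sequences are written as plain
#' FASTA records, secondary structure as \code{>id|2D} records and RSA as
#' \code{>id|3D} records (decimals to three places, \code{NA} for missing).
#' Several alignments are separated by a \code{# id} comment line.
#'
#' @param alns an [AnnotatedAlignment-class] or list of them.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotatedFasta <- function(alns, path) {
  if (is(alns, "AnnotatedAlignment")) alns <- list(alns)
  out <- character()
  for (k in seq_along(alns)) {
    aln <- alns[[k]]
    if (k > 1L) out <- c(out, "")
    out <- c(out, paste0("# ", alignmentId(aln)))
    for (i in seq_len(nSeqs(aln))) {
      id <- seqIds(aln)[i]
      out <- c(out, paste0(">", id),
               paste(aln@residues[i, ], collapse = ""))
      if (any(!is.na(aln@ss[i, ])))
        out <- c(out, paste0(">", id, "|2D"),
                 paste(ifelse(is.na(aln@ss[i, ]), GAP_CHAR, aln@ss[i, ]),
                       collapse = ""))
      if (any(!is.na(aln@rsa[i, ])))
        out <- c(out, paste0(">", id, "|3D"),
                 paste(ifelse(is.na(aln@rsa[i, ]), "NA",
                              sprintf("%.3f", aln@rsa[i, ])),
                       collapse = " "))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a group/stratum configuration file
#'
#' The configuration is YAML with an ordered \code{groups} list and an
#' \code{assignments} map from sequence id to either a group label or a
#' \code{\{group: ..., stratum: ...\}} pair.
#'
#' @param path path to the YAML configuration.
#' @return a [GroupScheme-class].
#' @export
readGroupConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$groups) || is.null(cfg$assignments))
    stop("group config needs 'groups' (ordered list) and 'assignments'")
  labels <- as.character(unlist(cfg$groups))
  ids <- names(cfg$assignments)
  groups <- vapply(cfg$assignments, function(a)
    if (is.list(a)) as.character(a$group) else as.character(a), "")
  strata <- vapply(cfg$assignments, function(a)
    if (is.list(a) && !is.null(a$stratum)) as.character(a$stratum)
    else NA_character_, "")
  GroupScheme(labels, stats::setNames(groups, ids),
              stats::setNames(strata, ids))
}

#' Write a group/stratum configuration file
#'
#' @param scheme a [GroupScheme-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGroupConfig <- function(scheme, path) {
  assignments <- lapply(names(scheme@groups), function(id) {
    if (is.na(scheme@strata[[id]])) scheme@groups[[id]]
    else list(group = scheme@groups[[id]], stratum = scheme@strata[[id]])
  })
  names(assignments) <- names(scheme@groups)
  yaml::write_yaml(list(groups = as.list(scheme@labels),
                        assignments = assignments), path)
  invisible(path)
}
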