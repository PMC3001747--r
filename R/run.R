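#' Run a full analysis from a configuration
#'
#' Executes the whole pipeline: read alignments, assign groups, filter
#' sites, run the selected analysis (composition, substitutions or
#' properties) with the design prescribed by the model matrix, apply
#' Benjamini-Yekutieli FDR control, and write result tables (TSV),
#' figures (PDF + PNG) and a run log.  On any error the partial outputs
#' of this run are removed.
#'
#' @param config a named list, or the path of a YAML file, with fields:
#'   \describe{
#'     \item{input}{path(s) to extended-FASTA alignment files.}
#'     \item{groups}{path to the YAML group configuration
#'       ([readGroupConfig()]).}
#'     \item{analysis}{\code{"composition"}, \code{"substitutions"} or
#'       \code{"properties"}.}
#'     \item{design}{test design for composition
#'       (\code{cumulative_mk}, \code{anova}, \code{regression},
#'       \code{wilcoxon}); substitutions use \code{mid_p_fisher} or
#'       \code{chi_square}.}
#'     \item{scale}{property-scale name (properties analysis), default
#'       \code{"hydrophobicity"}.}
#'     \item{filter}{optional list(ss =, exposure =, rsaThreshold =,
#'       consensus =) defining a [SiteFilter-class].}
#'     \item{alpha}{FDR significance level, default 0.05.}
#'     \item{collapseDependent}{collapse group/stratum means first,
#'       default FALSE.}
#'     \item{out}{output directory.}
#'     \item{seed}{RNG seed recorded in the log (the analyses themselves
#'       are deterministic).}
#'   }
#' @return invisibly, a list with the result tables and figure paths.
#' @export
runAnalysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  for (f in c("input", "groups", "analysis", "out"))
    if (is.null(config[[f]])) stop("config is missing field '", f, "'")
  alpha <- config$alpha %||% 0.05
  seed <- as.integer(config$seed %||% 1L)
  set.seed(seed)
  outDir <- config$out
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  written <- character()
  note <- function(path) written <<- c(written, path)

  logLines <- c(sprintf("protrend %s",
                        as.character(utils::packageVersion("protrend"))),
                sprintf("date: %s", format(Sys.time(), "%Y-%m-%d")),
                sprintf("seed: %d", seed),
                sprintf("alpha (BY-FDR): %g", alpha),
                sprintf("analysis: %s", config$analysis),
                "settings in effect:",
                "  gap symbols -, ., ~ normalized; '~' rendered in outputs",
                "  composition denominators exclude gaps",
                "  Jones pairing: greedy, ties broken lexicographically",
                "  background SP counts: Jones pairs within the baseline group",
                "  mid-p two-sided: probability ordering, tie tol 1e-7",
                "  Mann-Kendall: tie-corrected variance, continuity-corrected Z")

  res <- tryCatch({
    alns <- unlist(lapply(config$input, readAnnotatedFasta),
                   recursive = FALSE)
    scheme <- readGroupConfig(config$groups)
    alns <- lapply(alns, assignGroups, scheme = scheme)
    filt <- NULL
    if (!is.null(config$filter)) {
      fl <- config$filter
      filt <- siteFilter(ss = fl$ss,
                         exposure = fl$exposure %||% "any",
                         rsaThreshold = fl$rsaThreshold %||% 0.25,
                         consensus = fl$consensus %||% 0.5)
      alns <- lapply(alns, filterSites, filter = filt)
      logLines <- c(logLines, sprintf("site filter: ss=%s exposure=%s",
                                      paste(fl$ss %||% "any",
                                            collapse = ""),
                                      fl$exposure %||% "any"))
    }
    codes <- sort(unique(stats::na.omit(unlist(lapply(alns, groupCodes)))))
    logLines <- c(logLines,
                  sprintf("alignments: %d; groups present: %s",
                          length(alns), paste(codes, collapse = ",")))

    out <- list(figures = character())
    writeTab <- function(d, name) {
      path <- file.path(outDir, name)
      utils::write.table(d, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      note(path)
      path
    }
    if (config$analysis == "composition") {
      design <- config$design %||% "cumulative_mk"
      tab <- compositionScan(alns, design = design,
                             collapseDependent =
                               isTRUE(config$collapseDependent),
                             alpha = alpha)
      writeTab(tab, "composition.tsv")
      fig <- file.path(outDir, "composition")
      plotDeltaComposition(tab, alpha = alpha, file = fig)
      note(paste0(fig, c(".pdf", ".png")))
      out$composition <- tab
      out$figures <- paste0(fig, c(".pdf", ".png"))
    } else if (config$analysis == "substitutions") {
      method <- config$method %||%
        (if (!is.null(config$design) &&
             config$design %in% c("mid_p_fisher", "chi_square"))
           config$design else "mid_p_fisher")
      fwd <- spMatrix(alns, min(codes), max(codes),
                      kind = "directional_between")
      bg <- spMatrix(alns, min(codes), min(codes),
                     kind = "symmetric_within")
      note(writeSPMatrix(fwd, file.path(outDir, "sp_forward.tsv")))
      note(writeSPMatrix(bg, file.path(outDir, "sp_background.tsv")))
      scan <- substitutionScan(fwd, bg, method = method, alpha = alpha)
      writeTab(scan, "substitutions.tsv")
      fig <- file.path(outDir, "substitutions")
      plotSubstitutionBubbles(scan, alpha = alpha, file = fig)
      note(paste0(fig, c(".pdf", ".png")))
      out$substitutions <- scan
      out$figures <- paste0(fig, c(".pdf", ".png"))
    } else if (config$analysis == "properties") {
      scales <- loadPropertyScales(config$scaleFile %||% NULL)
      scName <- config$scale %||% "hydrophobicity"
      if (!scName %in% names(scales))
        stop("unknown property scale: ", scName)
      sc <- scales[[scName]]
      slopes <- familySlopes(alns, sc)
      trend <- propertyTrendTest(alns, sc,
                                 collapseDependent =
                                   isTRUE(config$collapseDependent))
      writeTab(slopes, "slopes.tsv")
      writeTab(data.frame(scale = scName, S = trendS(trend),
                          varS = trendVarS(trend), Z = trendZ(trend),
                          p = trendP(trend)),
               "property_trend.tsv")
      fig <- file.path(outDir, "ranked_slopes")
      plotRankedSlopes(slopes, trendP = trendP(trend), file = fig)
      note(paste0(fig, c(".pdf", ".png")))
      out$slopes <- slopes
      out$trend <- trend
      out$figures <- paste0(fig, c(".pdf", ".png"))
    } else {
      stop("unknown analysis '", config$analysis,
           "'; expected composition, substitutions or properties")
    }
    logLines <- c(logLines, "status: success")
    writeLines(logLines, file.path(outDir, "run.log"))
    out
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
  invisible(res)
}
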