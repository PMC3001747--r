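## The three signature figures.  Each function returns the ggplot object
## (so the drawn data can be inspected programmatically) and optionally
## writes it as both vector (PDF) and raster (PNG) files.

.writeFigure <- function(p, file, width = 8, height = 5) {
  if (is.null(file)) return(invisible(NULL))
  ggplot2::ggsave(paste0(file, ".pdf"), p, width = width, height = height)
  ggplot2::ggsave(paste0(file, ".png"), p, width = width, height = height,
                  dpi = 150)
  invisible(c(paste0(file, ".pdf"), paste0(file, ".png")))
}

#' Bar plot of mean compositional changes
#'
#' One bar per feature (amino acid or category) showing the mean
#' across-alignment compositional delta in the direction of adaptation,
#' with error bars for the empirical standard deviation; features
#' significant at q < alpha (Benjamini-Yekutieli) are marked.
#'
#' @param tab output of [compositionScan()] (or [deltaComposition()];
#'   significance marks then require \code{p}/\code{qBY} columns).
#' @param alpha significance level (default: the table's recorded alpha,
#'   else 0.05).
#' @param file optional path stem; writes \code{<file>.pdf} and
#'   \code{<file>.png}.
#' @return the ggplot object, invisibly when \code{file} is given.
#' @export
plotDeltaComposition <- function(tab, alpha = NULL, file = NULL) {
  if (is.null(tab) || !nrow(tab)) stop("empty composition table")
  alpha <- alpha %||% attr(tab, "alpha") %||% 0.05
  tab$feature <- factor(tab$feature, levels = tab$feature)
  tab$significant <- if ("qBY" %in% names(tab))
    !is.na(tab$qBY) & tab$qBY < alpha else FALSE
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$feature,
                                         y = .data$meanDelta,
                                         fill = .data$significant)) +
    ggplot2::geom_col(show.legend = TRUE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$meanDelta - .data$sd,
                                        ymax = .data$meanDelta + .data$sd),
                           width = 0.3) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick"),
                               name = sprintf("q < %.3g", alpha)) +
    ggplot2::labs(x = NULL, y = "mean compositional change",
                  title = "Compositional change toward the adapted group") +
    ggplot2::theme_minimal()
  .writeFigure(p, file)
  if (is.null(file)) p else invisible(p)
}

#' Bubble plot of the substitution-pair scan
#'
#' A 21 x 21 grid (20 amino acids + the gap state \code{~}) with marker
#' size and colour proportional to the substitution count.  Pairs
#' significant at p < alpha are drawn as upward-pointing triangles when
#' favoured in the adaptation direction and downward-pointing triangles
#' when non-favoured; all other observed pairs are circles.
#'
#' @param scan output of [substitutionScan()].
#' @param alpha significance level (default: the scan's recorded alpha).
#' @param useQ mark significance on the BY-adjusted q instead of raw p.
#' @param file optional path stem for PDF + PNG output.
#' @return the ggplot object.
#' @export
plotSubstitutionBubbles <- function(scan, alpha = NULL, useQ = FALSE,
                                    file = NULL) {
  if (is.null(scan) || !nrow(scan)) stop("empty substitution scan")
  alpha <- alpha %||% attr(scan, "alpha") %||% 0.05
  d <- scan[scan$count > 0, , drop = FALSE]
  if (!nrow(d)) stop("no observed substitutions to plot")
  crit <- if (useQ) d$qBY else d$p
  d$shape <- "observed"
  sig <- !is.na(crit) & crit < alpha
  d$shape[sig & d$direction == "favoured"] <- "favoured"
  d$shape[sig & d$direction == "non_favoured"] <- "non-favoured"
  d$x <- factor(d$x, levels = SUB_STATES)
  d$y <- factor(d$y, levels = SUB_STATES)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$y, y = .data$x,
                                       size = .data$count,
                                       fill = .data$count,
                                       shape = .data$shape)) +
    ggplot2::geom_point(colour = "grey20") +
    ggplot2::scale_shape_manual(values = c(observed = 21,
                                           favoured = 24,
                                           `non-favoured` = 25),
                                name = sprintf("p < %.3g", alpha)) +
    ggplot2::scale_fill_viridis_c(name = "count") +
    ggplot2::scale_size_continuous(range = c(1, 6), guide = "none") +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::scale_y_discrete(drop = FALSE, limits = rev(SUB_STATES)) +
    ggplot2::labs(x = "replacement residue (adapted group)",
                  y = "replaced residue (baseline group)",
                  title = "Substitution pairs between phenotypic groups") +
    ggplot2::theme_minimal()
  .writeFigure(p, file, width = 8, height = 7)
  if (is.null(file)) p else invisible(p)
}

#' Ranked distribution of per-family property slopes
#'
#' Slope coefficients from [familySlopes()] sorted ascending against
#' their rank, with a zero reference line and the cumulative Mann-Kendall
#' p-value in the annotation.
#'
#' @param slopes output of [familySlopes()].
#' @param trendP optional p-value (e.g. from [propertyTrendTest()]) to
#'   print on the figure.
#' @param file optional path stem for PDF + PNG output.
#' @return the ggplot object.
#' @export
plotRankedSlopes <- function(slopes, trendP = NULL, file = NULL) {
  if (is.null(slopes) || !nrow(slopes)) stop("no slopes to plot")
  d <- data.frame(rank = seq_len(nrow(slopes)),
                  beta1 = sort(slopes$beta1))
  subtitle <- if (!is.null(trendP))
    sprintf("cumulative Mann-Kendall p = %.3g", trendP) else NULL
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$beta1)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3,
                        colour = "grey40") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "rank", y = expression(beta[1]),
                  title = sprintf("Ranked per-family slopes (%s)",
                                  slopes$scaleName[1]),
                  subtitle = subtitle) +
    ggplot2::theme_minimal()
  .writeFigure(p, file, width = 6, height = 4.5)
  if (is.null(file)) p else invisible(p)
}
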