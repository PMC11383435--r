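#' Histogram of essential-gene overabundances
#'
#' @param perGene table with \code{class} and \code{log10_o} (essential
#'   genes); sufficient genes appear in the o = 1 bin.
#' @param ... passed to [graphics::hist()].
#' @return invisibly, the histogram object.
#' @export
plotOverabundanceHistogram <- function(perGene, ...) {
  keep <- perGene$class %in% c("sufficient", "overabundant")
  h <- graphics::hist(perGene$log10_o[keep],
    breaks = 20,
    xlab = expression(log[10] ~ overabundance),
    main = "Essential-gene overabundance", col = "grey80", ...
  )
  invisible(h)
}

#' Expression-overabundance cloud, trend and RLTO curve
#'
#' @param perGene table with \code{mu_m} and \code{log10_o}.
#' @param trend output of [trendCurve()].
#' @param rltoCurve optional output of [predictedCurve()].
#' @return invisibly \code{NULL}.
#' @export
plotTrendComparison <- function(perGene, trend, rltoCurve = NULL) {
  keep <- !is.na(perGene$log10_o) & perGene$mu_m > 0
  graphics::plot(log10(perGene$mu_m[keep]), perGene$log10_o[keep],
    pch = 16, col = grDevices::adjustcolor("grey40", 0.4),
    xlab = expression(log[10] ~ "message number"),
    ylab = expression(log[10] ~ overabundance)
  )
  graphics::lines(trend$center_log10_mu, trend$mean_log10_o,
    col = "blue", lwd = 2
  )
  graphics::arrows(trend$center_log10_mu,
    trend$mean_log10_o - trend$se_log10_o,
    trend$center_log10_mu, trend$mean_log10_o + trend$se_log10_o,
    length = 0.02, angle = 90, code = 3, col = "blue"
  )
  if (!is.null(rltoCurve)) {
    graphics::lines(log10(rltoCurve$mu_m), rltoCurve$log10_o_star,
      col = "red", lwd = 2
    )
  }
  graphics::abline(v = 0, lty = 3) # one-message-rule threshold
  invisible(NULL)
}

#' @importFrom grDevices adjustcolor
NULL
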