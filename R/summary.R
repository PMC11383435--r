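## Genome-scale summaries: class fractions by essentiality, the median and
## expression-weighted mean overabundance (the two superficially conflicting
## statistics: the median is dominated by low-expression genes with large
## overabundance, the weighted mean by high-expression genes near
## sufficiency), the windowed expression-overabundance trend, and its
## comparison with the RLTO prediction.

#' Class fractions by essentiality
#'
#' Fractions of genes per (essentiality x class) cell. Unclassifiable
#' genes are excluded from denominators and reported separately.
#'
#' @param perGene \code{data.frame} with \code{essential}
#'   (logical or 0/1) and \code{class} columns.
#' @return \code{data.frame} with \code{essential}, \code{class}, \code{n},
#'   \code{fraction}; attribute \code{"n_unclassifiable"}.
#' @export
classFractions <- function(perGene) {
  if (nrow(perGene) == 0L) stop("empty per-gene table")
  if (!all(c("essential", "class") %in% names(perGene))) {
    stop("per-gene table needs essential and class columns")
  }
  ess <- as.logical(perGene$essential)
  uncl <- perGene$class == "unclassifiable" | is.na(perGene$class)
  keep <- perGene[!uncl, , drop = FALSE]
  ess <- ess[!uncl]
  rows <- list()
  for (e in unique(ess)) {
    sub <- keep$class[ess == e]
    tab <- table(sub)
    rows[[length(rows) + 1L]] <- data.frame(
      essential = e, class = names(tab), n = as.integer(tab),
      fraction = as.numeric(tab) / length(sub)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_unclassifiable") <- sum(uncl)
  out
}

#' Median and expression-weighted mean overabundance
#'
#' Over classified essential genes (sufficient genes enter at their
#' measured value o = 1): the median overabundance and the mean weighted
#' by the message number, \code{sum(mu_m * o) / sum(mu_m)}. The message
#' number is the expression proxy available in this pipeline; set
#' \code{weights} to substitute e.g. protein abundances.
#'
#' @param perGene joined per-gene table with \code{essential},
#'   \code{class}, \code{log10_o}, \code{mu_m}.
#' @param overabundantOnly restrict both statistics to genes classified
#'   overabundant (default \code{FALSE}: all classified essential genes).
#' @param weights optional per-gene weight vector overriding \code{mu_m}.
#' @return list with \code{median_o}, \code{weighted_mean_o}, \code{n}.
#' @export
overabundanceStatistics <- function(perGene, overabundantOnly = FALSE,
                                    weights = NULL) {
  ess <- as.logical(perGene$essential)
  cls <- perGene$class
  keep <- ess & cls %in% c("sufficient", "overabundant")
  if (overabundantOnly) keep <- ess & cls == "overabundant"
  if (!any(keep)) stop("no classified essential genes")
  o <- 10^perGene$log10_o[keep]
  w <- if (is.null(weights)) perGene$mu_m[keep] else weights[keep]
  list(
    median_o = stats::median(o),
    weighted_mean_o = sum(w * o) / sum(w),
    n = sum(keep)
  )
}

#' Windowed expression-overabundance trend
#'
#' Mean log10 overabundance in sliding windows of log10 message number
#' (fixed width, sliding by half a width). Windows with fewer than
#' \code{minPerWindow} genes are widened symmetrically until they reach
#' the minimum (the merge rule for sparse windows); with degenerate
#' expression (all mu_m equal) a single window is returned.
#'
#' @param perGene table with \code{log10_o} and \code{mu_m}; only
#'   classified essential genes should be passed in (rows with \code{NA}
#'   in either column are dropped).
#' @param windowWidth window width in log10 mu_m (default 0.25).
#' @param step window step (default half the width).
#' @param minPerWindow minimum genes per window (default 5).
#' @return \code{data.frame} with \code{center_log10_mu}, \code{width},
#'   \code{n}, \code{mean_log10_o}, \code{se_log10_o}.
#' @export
trendCurve <- function(perGene, windowWidth = 0.25, step = windowWidth / 2,
                       minPerWindow = 5L) {
  keep <- !is.na(perGene$log10_o) & !is.na(perGene$mu_m) & perGene$mu_m > 0
  x <- log10(perGene$mu_m[keep])
  y <- perGene$log10_o[keep]
  if (!length(x)) stop("no usable genes for the trend")
  if (diff(range(x)) < 1e-12) {
    return(data.frame(
      center_log10_mu = x[1], width = windowWidth, n = length(y),
      mean_log10_o = mean(y),
      se_log10_o = stats::sd(y) / sqrt(length(y))
    ))
  }
  centers <- seq(min(x), max(x), by = step)
  rows <- lapply(centers, function(ct) {
    w <- windowWidth
    repeat {
      inWin <- abs(x - ct) <= w / 2
      if (sum(inWin) >= minPerWindow || w > 2 * diff(range(x))) break
      w <- w * 1.5
    }
    if (sum(inWin) < 2L) {
      return(NULL)
    }
    data.frame(
      center_log10_mu = ct, width = w, n = sum(inWin),
      mean_log10_o = mean(y[inWin]),
      se_log10_o = stats::sd(y[inWin]) / sqrt(sum(inWin))
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare a measured trend with the RLTO prediction
#'
#' Differences between the windowed data trend and the model curve
#' evaluated (by interpolation in log10 mu) at the window centers. No
#' fitting is performed: the model keeps its defaults, honouring its
#' parameter-free character.
#'
#' @param trend output of [trendCurve()].
#' @param rltoCurve output of [predictedCurve()].
#' @return \code{data.frame} per window: \code{center_log10_mu}, \code{n},
#'   \code{data_mean_log10_o}, \code{se}, \code{model_log10_o},
#'   \code{difference}; attributes \code{"mean_difference"},
#'   \code{"n_positive"}, \code{"n_negative"}, \code{"max_abs_difference"}.
#' @export
compareToRlto <- function(trend, rltoCurve) {
  if (nrow(trend) == 0L || nrow(rltoCurve) == 0L) {
    stop("no overlap between the trend and the model curve")
  }
  lgMu <- log10(rltoCurve$mu_m)
  lo <- max(min(lgMu), min(trend$center_log10_mu))
  hi <- min(max(lgMu), max(trend$center_log10_mu))
  if (lo > hi) stop("no overlap between the trend and the model curve")
  keep <- trend$center_log10_mu >= lo - 1e-9 &
    trend$center_log10_mu <= hi + 1e-9
  tr <- trend[keep, , drop = FALSE]
  model <- stats::approx(lgMu, rltoCurve$log10_o_star,
    xout = tr$center_log10_mu, rule = 2
  )$y
  out <- data.frame(
    center_log10_mu = tr$center_log10_mu, n = tr$n,
    data_mean_log10_o = tr$mean_log10_o, se = tr$se_log10_o,
    model_log10_o = model,
    difference = tr$mean_log10_o - model
  )
  attr(out, "mean_difference") <- mean(out$difference)
  attr(out, "n_positive") <- sum(out$difference > 0)
  attr(out, "n_negative") <- sum(out$difference < 0)
  attr(out, "max_abs_difference") <- max(abs(out$difference))
  out
}

#' Genome summary of a knockout-depletion analysis
#'
#' Assembles the per-gene table, class fractions, overabundance statistics
#' and the expression-overabundance trend in one object.
#'
#' @param classification output of [classifyLibrary()].
#' @param expression output of [messageNumberFromCounts()].
#' @param annotation \code{data.frame} with \code{gene_id},
#'   \code{essential} (0/1 or logical).
#' @param rltoCurve optional [predictedCurve()] output for the model
#'   comparison.
#' @param ... passed to [trendCurve()].
#' @return list with \code{per_gene}, \code{fractions},
#'   \code{statistics}, \code{trend} and (when a curve is given)
#'   \code{comparison}.
#' @export
genomeSummary <- function(classification, expression, annotation,
                          rltoCurve = NULL, ...) {
  perGene <- joinOverabundanceExpression(classification, expression)
  perGene <- merge(perGene, annotation, by = "gene_id")
  perGene$essential <- as.logical(perGene$essential)
  fr <- classFractions(perGene)
  st <- overabundanceStatistics(perGene)
  essCl <- perGene[
    perGene$essential & perGene$class %in% c("sufficient", "overabundant"),
  ]
  tr <- trendCurve(essCl, ...)
  out <- list(
    per_gene = perGene, fractions = fr, statistics = st, trend = tr
  )
  if (!is.null(rltoCurve)) {
    out$comparison <- compareToRlto(tr, rltoCurve)
  }
  out
}
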