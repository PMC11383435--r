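## TFNseq trajectory classification. Each mutant's log relative abundance
## y(t) is fit by three nested growth models:
##   M0 (no effect):    y = c
##   M1 (sufficiency):  y = c - s*t,                    s in [0, 2*k0]
##   M2 (overabundance): y = c for t <= T, c - s*(t-T),  T in [0, t_last]
## M1 is M2 at T = 0 and M0 is M2 at s = 0, so rss(M2) <= rss(M1) <= rss(M0)
## by construction. Two successive F-tests select the class: test 1 rejects
## M0 against M2 (2 extra parameters), test 2 rejects M1 against M2 (1
## extra). The arrest time of an overabundant mutant converts to
## overabundance via o = exp(k0 * T): the mutant stops growing while the
## library continues at the wild-type rate, so its relative abundance falls
## at k0 and the fold depletion at arrest equals the fold growth forgone.

#' Log relative abundance of an insertion trajectory
#'
#' \code{y_t = log((counts_t + p) / (totals_t + p))}, anchored so the first
#' fraction is zero. Per-point weights come from the delta-method binomial
#' variance of the log ratio, \code{var(y_t) ~ 1/(counts_t + p)} (small
#' count shares), so late near-zero fractions are down-weighted rather than
#' dropped.
#'
#' @param counts mapped reads per fraction.
#' @param totals per-fraction library sizes (> 0).
#' @param pseudocount added to counts and totals before the log
#'   (default 0.5).
#' @return list with \code{y} (anchored log relative abundance),
#'   \code{weights} (inverse variances) and \code{informative} (number of
#'   nonzero-count fractions; fewer than 4 flags the trajectory
#'   unclassifiable).
#' @examples
#' logRelativeAbundance(c(8, 4, 2, 1), rep(100, 4))$y # ~ -log(2) steps
#' @export
logRelativeAbundance <- function(counts, totals, pseudocount = 0.5) {
  if (any(totals <= 0)) stop("totals must be positive")
  if (length(counts) != length(totals)) {
    stop("counts and totals must have equal length")
  }
  y <- log((counts + pseudocount) / (totals + pseudocount))
  list(
    y = y - y[1],
    weights = counts + pseudocount,
    informative = sum(counts > 0)
  )
}

## weighted LS of y = c + s*x with s clamped to [0, sMax]; returns c, s, rss
.wlsClamped <- function(x, y, w, sMax) {
  sw <- sum(w)
  xb <- sum(w * x) / sw
  yb <- sum(w * y) / sw
  sxx <- sum(w * (x - xb)^2)
  if (sxx <= 0) {
    s <- 0
  } else {
    s <- sum(w * (x - xb) * (y - yb)) / sxx
    s <- min(max(s, 0), sMax)
  }
  c0 <- yb - s * xb
  r <- y - c0 - s * x
  list(c = c0, s = s, rss = sum(w * r^2))
}

#' Fit the three nested trajectory models
#'
#' Weighted least squares for the no-effect, sufficiency and overabundance
#' models. The arrest time T of the overabundance model is profiled on a
#' grid over [0, t_last] with spacing one tenth of the fraction interval,
#' then refined by golden-section search on the bracketing interval. The
#' post-arrest slope s is free on [0, \code{sMax}] (default 2*k0); set
#' \code{postSlope = "fixed"} to pin it to k0 (the mechanistic value) as a
#' diagnostic variant.
#'
#' @param times fraction times (h), >= 4 points.
#' @param y log relative abundance (anchored).
#' @param weights per-point weights (inverse variances).
#' @param k0 wild-type growth rate (1/h), positive.
#' @param sMax upper slope bound (1/h).
#' @param postSlope \code{"free"} or \code{"fixed"}.
#' @param gridStep T grid spacing (h); default one tenth of the first
#'   fraction interval.
#' @return list of per-model fits \code{m0} (c, rss), \code{m1} (c, s,
#'   rss), \code{m2} (c, s, T, rss), plus \code{n} and the settings.
#' @export
fitTrajectoryModels <- function(times, y, weights = rep(1, length(y)),
                                k0, sMax = 2 * k0,
                                postSlope = c("free", "fixed"),
                                gridStep = diff(times[1:2]) / 10) {
  postSlope <- match.arg(postSlope)
  if (k0 <= 0) stop("k0 must be positive")
  n <- length(times)
  if (n < 4L) stop("at least 4 fractions are required")
  if (length(y) != n || length(weights) != n) {
    stop("times, y and weights must have equal length")
  }
  sBound <- if (postSlope == "fixed") k0 else sMax

  fitAt <- function(T) {
    x <- -pmax(0, times - T)
    if (postSlope == "fixed") {
      ## slope pinned: c is the weighted mean of y - k0*x... y = c + k0*x
      c0 <- sum(weights * (y - k0 * x)) / sum(weights)
      r <- y - c0 - k0 * x
      list(c = c0, s = k0, rss = sum(weights * r^2))
    } else {
      .wlsClamped(x, y, weights, sBound)
    }
  }

  ## M0: constant
  c0 <- sum(weights * y) / sum(weights)
  m0 <- list(c = c0, rss = sum(weights * (y - c0)^2))
  ## M1: immediate decline (breakpoint model at T = 0)
  m1f <- fitAt(0)
  m1 <- list(c = m1f$c, s = m1f$s, rss = m1f$rss)
  ## M2: profile T on the grid, then golden-section refinement
  tLast <- times[n]
  grid <- seq(0, tLast, by = gridStep)
  if (grid[length(grid)] < tLast) grid <- c(grid, tLast)
  rssGrid <- vapply(grid, function(T) fitAt(T)$rss, numeric(1))
  i <- which.min(rssGrid)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  gss <- .goldenMin(function(T) fitAt(T)$rss, lo, hi, tol = 1e-6)
  Tstar <- if (gss$fmin <= rssGrid[i]) gss$xmin else grid[i]
  m2f <- fitAt(Tstar)
  m2 <- list(c = m2f$c, s = m2f$s, T = Tstar, rss = m2f$rss)

  list(
    m0 = m0, m1 = m1, m2 = m2, n = n, times = times, y = y,
    weights = weights, k0 = k0, postSlope = postSlope,
    gridStep = gridStep, rssFun = function(T) fitAt(T)$rss
  )
}

## golden-section minimisation on [a, b]
.goldenMin <- function(f, a, b, tol = 1e-6) {
  if (b - a < tol) {
    x <- (a + b) / 2
    return(list(xmin = x, fmin = f(x)))
  }
  phi <- (sqrt(5) - 1) / 2
  x1 <- b - phi * (b - a)
  x2 <- a + phi * (b - a)
  f1 <- f(x1)
  f2 <- f(x2)
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- x2
      x2 <- x1
      f2 <- f1
      x1 <- b - phi * (b - a)
      f1 <- f(x1)
    } else {
      a <- x1
      x1 <- x2
      f1 <- f2
      x2 <- a + phi * (b - a)
      f2 <- f(x2)
    }
  }
  if (f1 <= f2) list(xmin = x1, fmin = f1) else list(xmin = x2, fmin = f2)
}

#' Classify a fitted trajectory by two successive F-tests
#'
#' Test 1 takes the no-effect model as the null against the overabundance
#' model (2 extra parameters: slope and breakpoint); failure to reject at
#' \code{alpha1} yields class \code{no_effect}. Test 2 takes the
#' sufficiency model as the null (the T = 0 boundary of the breakpoint
#' family) against the overabundance model (1 extra parameter); failure to
#' reject at \code{alpha2} yields \code{sufficient} with log10 o = 0,
#' rejection yields \code{overabundant} with o = exp(k0 * T). The standard
#' error of log10 o comes from the local curvature of the profiled rss in
#' T.
#'
#' @param fits output of [fitTrajectoryModels()].
#' @param alpha1,alpha2 test levels (applied to the supplied p-values; when
#'   classifying a whole library use [classifyLibrary()], which
#'   Benjamini-Hochberg-adjusts across genes within each stage).
#' @return one-row \code{data.frame}: \code{class}, \code{p_no_effect},
#'   \code{p_sufficiency}, \code{arrest_time_h}, \code{slope},
#'   \code{log10_o}, \code{se_log10_o}, \code{rss0}, \code{rss1},
#'   \code{rss2}.
#' @export
classifyTrajectory <- function(fits, alpha1 = 0.05, alpha2 = 0.05) {
  n <- fits$n
  dfRes <- n - 3L
  if (dfRes < 1L) {
    return(data.frame(
      class = "unclassifiable", p_no_effect = NA_real_,
      p_sufficiency = NA_real_, arrest_time_h = NA_real_,
      slope = NA_real_, log10_o = NA_real_, se_log10_o = NA_real_,
      rss0 = NA_real_, rss1 = NA_real_, rss2 = NA_real_
    ))
  }
  rss0 <- fits$m0$rss
  rss1 <- fits$m1$rss
  rss2 <- fits$m2$rss
  p1 <- .fTestP(rss0, rss2, 2L, dfRes)
  p2 <- .fTestP(rss1, rss2, 1L, dfRes)
  k0 <- fits$k0

  if (p1 >= alpha1) {
    cls <- "no_effect"
    T <- NA_real_
    l10 <- NA_real_
    se <- NA_real_
    sl <- NA_real_
  } else if (p2 >= alpha2) {
    cls <- "sufficient"
    T <- NA_real_
    l10 <- 0
    se <- NA_real_
    sl <- fits$m1$s
  } else {
    cls <- "overabundant"
    T <- fits$m2$T
    l10 <- k0 * T / log(10)
    sl <- fits$m2$s
    ## curvature of the profiled rss in T
    d <- fits$gridStep
    tLast <- fits$times[n]
    Tm <- max(0, T - d)
    Tp <- min(tLast, T + d)
    d2 <- (fits$rssFun(Tp) - 2 * rss2 + fits$rssFun(Tm)) /
      ((Tp - T) * (T - Tm) + 1e-12)
    sigma2 <- rss2 / dfRes
    se <- if (is.finite(d2) && d2 > 0) {
      k0 * sqrt(2 * sigma2 / d2) / log(10)
    } else {
      NA_real_
    }
  }
  data.frame(
    class = cls, p_no_effect = p1, p_sufficiency = p2,
    arrest_time_h = T, slope = sl, log10_o = l10, se_log10_o = se,
    rss0 = rss0, rss1 = rss1, rss2 = rss2
  )
}

.fTestP <- function(rssNull, rssAlt, dfExtra, dfRes) {
  if (rssAlt <= .Machine$double.eps * max(1, rssNull)) {
    return(if (rssNull > rssAlt * (1 + 1e-9) || rssNull > 1e-12) 0 else 1)
  }
  f <- ((rssNull - rssAlt) / dfExtra) / (rssAlt / dfRes)
  stats::pf(max(f, 0), dfExtra, dfRes, lower.tail = FALSE)
}

#' Classify every mutant trajectory in a library
#'
#' Runs [logRelativeAbundance()], [fitTrajectoryModels()] and
#' [classifyTrajectory()] per gene, with Benjamini-Hochberg adjustment of
#' the stage-1 p-values across all classifiable genes and of the stage-2
#' p-values across the genes that passed stage 1 (the spec of a
#' genome-wide sequential test). Trajectories with fewer than 4
#' nonzero-count fractions are flagged \code{unclassifiable}.
#'
#' @param x a \linkS4class{TfnseqExperiment}, or a counts matrix (genes x
#'   fractions).
#' @param times fraction times (h); taken from \code{x} when it is a
#'   \linkS4class{TfnseqExperiment}.
#' @param k0 wild-type growth rate (1/h).
#' @param alpha1,alpha2 test levels applied to the BH-adjusted p-values.
#' @param pseudocount see [logRelativeAbundance()].
#' @param adjust p-value adjustment method (\code{stats::p.adjust}),
#'   default \code{"BH"}.
#' @param postSlope see [fitTrajectoryModels()].
#' @return \code{data.frame} with one row per gene: \code{gene_id},
#'   \code{class}, \code{p_no_effect}, \code{p_sufficiency} (both
#'   adjusted), \code{arrest_time_h}, \code{slope}, \code{log10_o},
#'   \code{se_log10_o}, \code{n_informative}. Attribute
#'   \code{"class_counts"} tabulates the classes.
#' @export
classifyLibrary <- function(x, times = NULL, k0, alpha1 = 0.05,
                            alpha2 = 0.05, pseudocount = 0.5,
                            adjust = "BH", postSlope = "free") {
  if (is(x, "TfnseqExperiment")) {
    counts <- SummarizedExperiment::assay(x, "counts")
    times <- fractionTimes(x)
  } else {
    counts <- as.matrix(x)
    if (is.null(times)) stop("times are required for a bare matrix")
  }
  totals <- colSums(counts)
  ids <- rownames(counts)
  if (is.null(ids)) ids <- sprintf("gene_%04d", seq_len(nrow(counts)))

  rows <- vector("list", nrow(counts))
  for (i in seq_len(nrow(counts))) {
    lra <- logRelativeAbundance(counts[i, ], totals, pseudocount)
    if (lra$informative < 4L) {
      rows[[i]] <- data.frame(
        class = "unclassifiable", p_no_effect = NA_real_,
        p_sufficiency = NA_real_, arrest_time_h = NA_real_,
        slope = NA_real_, log10_o = NA_real_, se_log10_o = NA_real_,
        rss0 = NA_real_, rss1 = NA_real_, rss2 = NA_real_,
        n_informative = lra$informative,
        .T = NA_real_, .s2 = NA_real_, .s1 = NA_real_, .se = NA_real_
      )
      next
    }
    fits <- fitTrajectoryModels(times, lra$y, lra$weights,
      k0 = k0,
      postSlope = postSlope
    )
    cl <- classifyTrajectory(fits, alpha1 = -1, alpha2 = -1) # raw p only
    cl$class <- NA_character_ # assigned after adjustment
    cl$n_informative <- lra$informative
    ## keep the fitted quantities for possible reassignment
    cl$.T <- fits$m2$T
    cl$.s2 <- fits$m2$s
    cl$.s1 <- fits$m1$s
    cl$.se <- .seLog10o(fits)
    rows[[i]] <- cl
  }
  res <- do.call(rbind, rows)
  res$gene_id <- ids

  ok <- is.na(res$class) & !is.na(res$p_no_effect)
  p1adj <- rep(NA_real_, nrow(res))
  p1adj[ok] <- stats::p.adjust(res$p_no_effect[ok], method = adjust)
  reject1 <- ok & p1adj < alpha1
  p2adj <- rep(NA_real_, nrow(res))
  p2adj[reject1] <- stats::p.adjust(res$p_sufficiency[reject1],
    method = adjust
  )
  reject2 <- reject1 & p2adj < alpha2

  res$class[ok] <- "no_effect"
  res$class[reject1] <- "sufficient"
  res$class[reject2] <- "overabundant"
  res$class[is.na(res$class)] <- "unclassifiable"
  res$p_no_effect <- p1adj
  res$p_sufficiency <- p2adj
  k0ln10 <- k0 / log(10)
  res$arrest_time_h <- ifelse(res$class == "overabundant", res$.T, NA_real_)
  res$slope <- ifelse(res$class == "overabundant", res$.s2,
    ifelse(res$class == "sufficient", res$.s1, NA_real_)
  )
  res$log10_o <- ifelse(res$class == "overabundant",
    k0ln10 * res$.T,
    ifelse(res$class == "sufficient", 0, NA_real_)
  )
  res$se_log10_o <- ifelse(res$class == "overabundant", res$.se, NA_real_)
  res <- res[, c(
    "gene_id", "class", "p_no_effect", "p_sufficiency",
    "arrest_time_h", "slope", "log10_o", "se_log10_o", "n_informative"
  )]
  rownames(res) <- NULL
  attr(res, "class_counts") <- table(res$class)
  res
}

.seLog10o <- function(fits) {
  n <- fits$n
  dfRes <- n - 3L
  if (dfRes < 1L) {
    return(NA_real_)
  }
  T <- fits$m2$T
  d <- fits$gridStep
  tLast <- fits$times[n]
  Tm <- max(0, T - d)
  Tp <- min(tLast, T + d)
  d2 <- (fits$rssFun(Tp) - 2 * fits$m2$rss + fits$rssFun(Tm)) /
    ((Tp - T) * (T - Tm) + 1e-12)
  sigma2 <- fits$m2$rss / dfRes
  if (is.finite(d2) && d2 > 0) {
    fits$k0 * sqrt(2 * sigma2 / d2) / log(10)
  } else {
    NA_real_
  }
}

#' Convert an arrest time to overabundance
#'
#' A mutant that arrests at time T has forgone \code{exp(k0 * T)}-fold
#' growth relative to the wild type; by the dilution model that fold is
#' exactly the fold depletion the protein tolerated, i.e. the
#' overabundance \code{o = exp(k0 * T)}.
#'
#' @param k0 wild-type growth rate (1/h), positive.
#' @param T arrest time (h), >= 0 (vectorised).
#' @return \code{data.frame} with \code{o} and \code{log10_o}.
#' @examples
#' overabundanceFromArrest(log(2), 2) # o = 4
#' @export
overabundanceFromArrest <- function(k0, T) {
  if (k0 <= 0) stop("k0 must be positive")
  if (any(T < 0)) stop("arrest times must be >= 0")
  data.frame(o = exp(k0 * T), log10_o = k0 * T / log(10))
}

#' Wild-type growth rate for the arrest-time conversion
#'
#' Relative abundances alone cannot determine k0, so either a measured
#' value is supplied (passthrough, \code{method = "supplied"}) or absolute
#' library abundances (e.g. spike-in normalised totals) are fit by a
#' log-linear regression over time (\code{method = "spike_in"}).
#'
#' @param k0 user-supplied wild-type growth rate (1/h), or \code{NULL}.
#' @param absoluteTotals absolute library abundance per fraction, or
#'   \code{NULL}.
#' @param times fraction times (h), required with \code{absoluteTotals}.
#' @return list with \code{k0} and \code{method}.
#' @export
estimateK0 <- function(k0 = NULL, absoluteTotals = NULL, times = NULL) {
  if (!is.null(k0)) {
    if (k0 <= 0) stop("k0 must be positive")
    return(list(k0 = k0, method = "supplied"))
  }
  if (!is.null(absoluteTotals)) {
    if (is.null(times) || length(times) != length(absoluteTotals)) {
      stop("times matching absoluteTotals are required")
    }
    fit <- stats::lm(log(absoluteTotals) ~ times)
    return(list(k0 = unname(stats::coef(fit)[2]), method = "spike_in"))
  }
  stop(
    "k0 cannot be determined: supply a measured value or absolute ",
    "(spike-in normalised) library totals"
  )
}
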