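## Single-cell lineage analysis: the dilution model, areal growth rates,
## arrest detection, the empirical fitness landscape and imaging-based
## overabundance. Area is used as the volume proxy throughout: the areal
## growth rate d/dt ln A avoids defining a cell length for the aberrant
## morphologies that essential-gene depletion produces.

#' Dilution-model concentration
#'
#' After the knockout, no new protein is made, so the concentration over
#' the progeny is set purely by growth: \code{C(t) = C0 * V0 / V(t)}, where
#' V is the total volume (area) of the progeny.
#'
#' @param C0 progenitor concentration at the knockout.
#' @param V0 progenitor volume proxy (area), positive.
#' @param Vt volume-proxy series, each >= V0 for a growing lineage.
#' @return concentration series \code{C0 * V0 / Vt}.
#' @examples
#' dilutionConcentration(2, 1, c(1, 2, 8)) # 2, 1, 0.25
#' @export
dilutionConcentration <- function(C0, V0, Vt) {
  if (V0 <= 0 || any(Vt <= 0)) stop("volumes must be positive")
  C0 * V0 / Vt
}

#' Sliding-window areal growth rate
#'
#' The single-cell areal growth rate k(t) = d/dt ln A(t), estimated as the
#' least-squares slope of ln(area) against time in a centred sliding window
#' of \code{window} samples; windows are truncated at the track endpoints so
#' short post-division tracks remain usable. The returned series is aligned
#' to the input times.
#'
#' @param times sample times (h), strictly increasing.
#' @param areas areas (um^2), positive, same length.
#' @param window window size in samples (odd, >= 3).
#' @return numeric growth-rate series (1/h), or an error for tracks shorter
#'   than \code{window} (callers flag and exclude such tracks).
#' @examples
#' t <- seq(0, 3, 0.1)
#' arealGrowthRate(t, 2 * exp(0.7 * t)) # 0.7 everywhere
#' @export
arealGrowthRate <- function(times, areas, window = 5L) {
  if (window < 3L) stop("window must be >= 3 samples")
  n <- length(times)
  if (n < window) stop("track shorter than window: flag and exclude")
  if (length(areas) != n) stop("times and areas must have equal length")
  if (any(areas <= 0)) stop("areas must be positive")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  y <- log(areas)
  h <- window %/% 2L
  k <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - h):min(n, i + h)
    tc <- times[j] - mean(times[j])
    k[i] <- sum(tc * (y[j] - mean(y[j]))) / sum(tc^2)
  }
  k
}

## A mother's final frame coincides with her daughters' first frame (areas
## and protein are conserved across the division); she is no longer a live
## cell at that instant, so her terminal record is dropped from live-cell
## aggregations to avoid double counting.
.liveTracks <- function(tr) {
  if (nrow(tr) == 0L) stop("empty lineage")
  firstT <- tapply(tr$time_h, tr$cell_id, min)
  births <- tr[!is.na(tr$parent_id), c("cell_id", "parent_id")]
  births <- births[!duplicated(births$cell_id), ]
  exclude <- unique(paste(
    births$parent_id, firstT[as.character(births$cell_id)]
  ))
  tr[!(paste(tr$cell_id, tr$time_h) %in% exclude), , drop = FALSE]
}

#' Total live area of a lineage over time
#'
#' At each sample time (union over cells), sums the areas of all cells
#' observed at that time. Cells lost to tracking contribute up to their
#' last frame (right censoring). For a growing lineage with conserved area
#' at division the series is continuous across divisions and monotone
#' non-decreasing.
#'
#' @param tree a \linkS4class{LineageTree}.
#' @return \code{data.frame} with \code{time_h} and \code{total_area_um2}
#'   (and \code{total_fluor_au} when fluorescence is present).
#' @export
totalAreaSeries <- function(tree) {
  stopifnot(is(tree, "LineageTree"))
  tr <- .liveTracks(cellTracks(tree))
  tt <- sort(unique(tr$time_h))
  tot <- vapply(tt, function(t) {
    sum(tr$area_um2[abs(tr$time_h - t) < 1e-9])
  }, numeric(1))
  out <- data.frame(time_h = tt, total_area_um2 = tot)
  if ("fluor_au" %in% names(tr) && !all(tr$fluor_au < 0)) {
    out$total_fluor_au <- vapply(tt, function(t) {
      sum(tr$fluor_au[abs(tr$time_h - t) < 1e-9])
    }, numeric(1))
  }
  out
}

#' Aggregate growth rate of a lineage
#'
#' Windowed areal growth rate of the total-area series; robust to division
#' events because total area is conserved across them.
#'
#' @param tree a \linkS4class{LineageTree}.
#' @param window sliding-window size in samples.
#' @return \code{data.frame} with \code{time_h} and \code{growth_rate}.
#' @export
aggregateGrowthRate <- function(tree, window = 5L) {
  ts <- totalAreaSeries(tree)
  data.frame(
    time_h = ts$time_h,
    growth_rate = arealGrowthRate(ts$time_h, ts$total_area_um2, window)
  )
}

#' Detect growth arrest from a growth-rate series
#'
#' Arrest is called at the earliest time after which the (already smoothed)
#' growth-rate series stays below \code{frac * k0} for at least
#' \code{minRun} consecutive samples through the end of the series;
#' \code{NA} if growth never arrests.
#'
#' @param times sample times (h).
#' @param k growth-rate series (1/h), e.g. from [aggregateGrowthRate()].
#' @param k0 wild-type growth rate (1/h), positive.
#' @param frac threshold fraction of k0 in (0, 1), default 0.5.
#' @param minRun minimum number of consecutive sub-threshold samples.
#' @return arrest time (h) or \code{NA_real_}.
#' @examples
#' t <- 0:10
#' detectArrest(t, ifelse(t < 4, 0.7, 0), k0 = 0.7) # 4
#' @export
detectArrest <- function(times, k, k0, frac = 0.5, minRun = 2L) {
  if (k0 <= 0) stop("k0 must be positive")
  if (frac <= 0 || frac >= 1) stop("frac must lie in (0, 1)")
  n <- length(k)
  below <- k < frac * k0
  ## earliest i with below[i:n] all TRUE and a run of at least minRun
  idx <- which(rev(cumprod(rev(below))) == 1)
  if (!length(idx)) {
    return(NA_real_)
  }
  i <- idx[1]
  if (n - i + 1L < minRun) {
    return(NA_real_)
  }
  times[i]
}

#' Imaging-based overabundance of a lineage
#'
#' By the dilution model, the concentration at arrest is
#' \code{C_A = C0 * V0 / V(T)}, so the overabundance \code{o = C0 / C_A}
#' equals the fold growth of the progeny at arrest: \code{o_elongation =
#' V(T) / V0} (total area at T over total progenitor area, log-interpolated
#' between samples). A second, septation-based metric counts divisions:
#' \code{o_septation = } final live-cell count / progenitor count.
#'
#' @param tree a \linkS4class{LineageTree}.
#' @param arrestTime arrest time T (h) within the observed range.
#' @return \code{data.frame} (one row): \code{arrest_time_h},
#'   \code{o_elongation}, \code{log10_o_elongation}, \code{o_septation},
#'   \code{log10_o_septation}, \code{n_cells}, \code{n_progenitors}.
#' @export
overabundanceFromLineage <- function(tree, arrestTime) {
  stopifnot(is(tree, "LineageTree"))
  ts <- totalAreaSeries(tree)
  if (is.na(arrestTime) || arrestTime < min(ts$time_h) ||
    arrestTime > max(ts$time_h)) {
    stop("arrestTime must lie within the observed time range")
  }
  V0 <- ts$total_area_um2[1]
  if (V0 <= 0) stop("zero progenitor area")
  vT <- exp(stats::approx(ts$time_h, log(ts$total_area_um2),
    xout = arrestTime
  )$y)
  tr <- .liveTracks(cellTracks(tree))
  lastT <- max(tr$time_h)
  nFinal <- length(unique(tr$cell_id[abs(tr$time_h - lastT) < 1e-9]))
  nProg <- length(progenitors(tree))
  oE <- vT / V0
  oS <- nFinal / nProg
  data.frame(
    arrest_time_h = arrestTime,
    o_elongation = oE, log10_o_elongation = log10(oE),
    o_septation = oS, log10_o_septation = log10(oS),
    n_cells = nFinal, n_progenitors = nProg
  )
}

#' Analyse a lineage end to end
#'
#' Convenience wrapper: total-area series, aggregate growth rate, arrest
#' detection and overabundance in one call.
#'
#' @param tree a \linkS4class{LineageTree}.
#' @param k0 wild-type growth rate (1/h).
#' @param frac arrest threshold fraction (see [detectArrest()]).
#' @param window growth-rate window (samples).
#' @return the [overabundanceFromLineage()] row, or a row of \code{NA}s
#'   (with counts filled in) when no arrest is detected.
#' @export
analyzeLineage <- function(tree, k0, frac = 0.5, window = 5L) {
  kk <- aggregateGrowthRate(tree, window)
  tArr <- detectArrest(kk$time_h, kk$growth_rate, k0, frac)
  if (is.na(tArr)) {
    tr <- .liveTracks(cellTracks(tree))
    lastT <- max(tr$time_h)
    return(data.frame(
      arrest_time_h = NA_real_,
      o_elongation = NA_real_, log10_o_elongation = NA_real_,
      o_septation = NA_real_, log10_o_septation = NA_real_,
      n_cells = length(unique(tr$cell_id[abs(tr$time_h - lastT) < 1e-9])),
      n_progenitors = length(progenitors(tree))
    ))
  }
  overabundanceFromLineage(tree, tArr)
}

#' Empirical fitness landscape of a lineage
#'
#' Combines the dilution model with the aggregate growth rate: each time
#' point yields a pair (relative abundance C/C0 = V0/V(t), growth rate
#' k(t)), traversed from wild-type abundance down to the abundance reached
#' at the end of the experiment. The arrest abundance C_A/C0 is set where
#' [detectArrest()] fires.
#'
#' @param tree a \linkS4class{LineageTree}.
#' @param k0 wild-type growth rate (1/h).
#' @param frac,window see [detectArrest()] / [aggregateGrowthRate()].
#' @return a \linkS4class{FitnessLandscape}.
#' @export
fitnessLandscape <- function(tree, k0, frac = 0.5, window = 5L) {
  ts <- totalAreaSeries(tree)
  kk <- arealGrowthRate(ts$time_h, ts$total_area_um2, window)
  rel <- ts$total_area_um2[1] / ts$total_area_um2
  tArr <- detectArrest(ts$time_h, kk, k0, frac)
  arrRel <- if (is.na(tArr)) {
    NA_real_
  } else {
    rel[which.min(abs(ts$time_h - tArr))]
  }
  ord <- order(rel, decreasing = TRUE)
  new("FitnessLandscape",
    relAbundance = pmin(rel[ord], 1), growthRate = kk[ord],
    arrestRelAbundance = arrRel
  )
}

#' Check a lineage against the dilution-model prediction
#'
#' Compares the mean protein concentration over the progeny (total
#' fluorescence / total area) with the dilution prediction
#' \code{C0 * V0 / V(t)} and reports the relative RMS deviation. Also
#' verifies that arrested cells (constant area at the end of the series)
#' hold their concentration, the behaviour observed for arrested cells in
#' imaging.
#'
#' @param tree a \linkS4class{LineageTree} with fluorescence.
#' @param C0 progenitor concentration; defaults to the observed initial
#'   total fluorescence / total area.
#' @return list with \code{rel_rms} (relative RMS deviation of observed vs
#'   predicted mean concentration), \code{table} (per-time observed and
#'   predicted), \code{arrested_conc_cv} (max CV of concentration across an
#'   arrested cell's frames, \code{NA} if no arrested cell).
#' @export
fluorescenceDilutionCheck <- function(tree, C0 = NULL) {
  stopifnot(is(tree, "LineageTree"))
  tr <- cellTracks(tree)
  if (!"fluor_au" %in% names(tr) || all(tr$fluor_au < 0)) {
    stop("fluorescence is required for the dilution check")
  }
  ts <- totalAreaSeries(tree)
  if (!"total_fluor_au" %in% names(ts)) stop("fluorescence missing")
  obs <- ts$total_fluor_au / ts$total_area_um2
  if (is.null(C0)) C0 <- obs[1]
  pred <- dilutionConcentration(C0, ts$total_area_um2[1], ts$total_area_um2)
  relRms <- sqrt(mean(((obs - pred) / pred)^2))

  ## arrested cells: constant area over their last 3+ frames
  ccv <- NA_real_
  sp <- split(tr, tr$cell_id)
  for (cell in sp) {
    n <- nrow(cell)
    if (n >= 3) {
      tail3 <- cell[(n - 2):n, ]
      if (max(abs(diff(tail3$area_um2))) < 1e-9 * tail3$area_um2[1]) {
        conc <- tail3$fluor_au / tail3$area_um2
        cv <- stats::sd(conc) / mean(conc)
        ccv <- if (is.na(ccv)) cv else max(ccv, cv)
      }
    }
  }
  list(
    rel_rms = relRms,
    table = data.frame(
      time_h = ts$time_h, observed_conc = obs,
      predicted_conc = pred
    ),
    arrested_conc_cv = ccv
  )
}
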