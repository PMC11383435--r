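# Brute-force fine-grid breakpoint oracle: exhaustive scan of the arrest
# time with the clamped WLS profile recomputed independently (vectorised
# over the grid; shares no code with the package's grid + golden-section
# estimator).
oracleBreakpoint <- function(times, y, w, k0, dT = 0.001, sMax = 2 * k0) {
  Ts <- seq(0, max(times), by = dT)
  n <- length(times)
  X <- pmax(outer(times, Ts, "-"), 0) # regression covariate is -X
  sw <- sum(w)
  xb <- colSums(w * -X) / sw
  yb <- sum(w * y) / sw
  Xc <- -X - matrix(xb, n, length(Ts), byrow = TRUE)
  sxx <- colSums(w * Xc^2)
  sxy <- colSums(w * Xc * (y - yb))
  s <- ifelse(sxx > 0, pmin(pmax(sxy / sxx, 0), sMax), 0)
  cc <- yb - s * xb
  fit <- matrix(cc, n, length(Ts), byrow = TRUE) + sweep(-X, 2, s, "*")
  rss <- colSums(w * (y - fit)^2)
  list(T = Ts[which.min(rss)], rss = min(rss))
}

# Exhaustive log-grid maximiser of the RLTO fitness (independent of the
# package's scan-and-refine optimiser).
oracleRltoOptimum <- function(params, nPoints = 1e4, oRange = c(1e-2, 1e4)) {
  lg <- seq(log10(oRange[1]), log10(oRange[2]), length.out = nPoints)
  f <- rltoFitness(10^lg, params)
  10^lg[which.max(f)]
}

# Hand-built lineage for structural tests.
makeTree <- function(tracks, progenitors = NULL) {
  if (is.null(progenitors)) {
    progenitors <- unique(tracks$cell_id[is.na(tracks$parent_id)])
  }
  new("LineageTree",
    tracks = tracks, progenitorIds = as.integer(progenitors),
    metadata = list()
  )
}
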