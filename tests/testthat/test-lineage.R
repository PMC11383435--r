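test_that("dilution concentration is C0*V0/V", {
  expect_equal(dilutionConcentration(1, 1, 1), 1)
  expect_equal(dilutionConcentration(1, 1, 2), 0.5)
  expect_equal(dilutionConcentration(2, 1, 8), 0.25)
  expect_error(dilutionConcentration(1, 0, 1), "positive")
  expect_error(dilutionConcentration(1, 1, c(1, -2)), "positive")
})

test_that("areal growth rate recovers an exact exponential", {
  t <- seq(0, 3, 0.1)
  expect_equal(arealGrowthRate(t, 2 * exp(0.7 * t)), rep(0.7, length(t)),
    tolerance = 1e-9
  )
  expect_equal(arealGrowthRate(t, rep(3, length(t))), rep(0, length(t)))
  expect_error(arealGrowthRate(t, 2 * exp(0.7 * t), window = 2), "window")
  expect_error(arealGrowthRate(t[1:3], exp(t[1:3]), window = 5), "shorter")
})

test_that("per-cell growth rates recover k0 under noise", {
  k0 <- log(2)
  tr <- simulateLineage(
    k0 = k0, oTrue = 1e4, dt = 0.1, tMax = 4,
    growthNoiseCV = 0.1, seed = 21
  )
  tk <- cellTracks(tr)
  rates <- vapply(split(tk, tk$cell_id), function(cell) {
    if (nrow(cell) < 5L) {
      return(NA_real_)
    }
    mean(arealGrowthRate(cell$time_h, cell$area_um2))
  }, numeric(1))
  rates <- rates[!is.na(rates)]
  se <- stats::sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - k0), 3 * se + 1e-9)
})

test_that("total area series sums live cells and is continuous", {
  # single non-dividing cell: its own series
  t <- seq(0, 1, 0.25)
  one <- makeTree(data.frame(
    cell_id = 1L, parent_id = NA_integer_, time_h = t,
    area_um2 = exp(t)
  ))
  expect_equal(totalAreaSeries(one)$total_area_um2, exp(t))
  # one division with conserved area: continuous total
  tr <- simulateLineage(k0 = log(2), oTrue = 100, dt = 0.05, tMax = 2, seed = 1)
  ts <- totalAreaSeries(tr)
  expect_true(all(diff(log(ts$total_area_um2)) > 0))
  expect_lt(max(abs(diff(log(ts$total_area_um2)) - log(2) * 0.05)), 1e-9)
})

test_that("arrest detection finds the step and ignores steady growth", {
  t <- 0:10
  expect_true(is.na(detectArrest(t, rep(0.7, 11), k0 = 0.7)))
  expect_equal(detectArrest(t, ifelse(t < 4, 0.7, 0), k0 = 0.7), 4)
  expect_error(detectArrest(t, rep(0.5, 11), k0 = 0), "k0")
  expect_error(detectArrest(t, rep(0.5, 11), k0 = 0.7, frac = 1.2), "frac")
})

test_that("lineage overabundance matches area growth and cell counts", {
  t <- seq(0, 2, 0.5)
  # no growth by T: o_elongation = 1
  flat <- makeTree(data.frame(
    cell_id = 1L, parent_id = NA_integer_, time_h = t, area_um2 = rep(2, 5)
  ))
  expect_equal(overabundanceFromLineage(flat, 2)$o_elongation, 1)
  # area exactly quadruples: o_elongation = 4
  quad <- makeTree(data.frame(
    cell_id = 1L, parent_id = NA_integer_, time_h = t,
    area_um2 = 2^(2 * t / 2)
  ))
  expect_equal(overabundanceFromLineage(quad, 2)$o_elongation, 4,
    tolerance = 1e-9
  )
  # 4 progenitors, 4 final cells: septation o = 1, log10 = 0
  four <- makeTree(do.call(rbind, lapply(1:4, function(i) {
    data.frame(
      cell_id = i, parent_id = NA_integer_, time_h = t,
      area_um2 = rep(1, 5)
    )
  })))
  r <- overabundanceFromLineage(four, 1)
  expect_equal(r$o_septation, 1)
  expect_equal(r$log10_o_septation, 0)
  expect_equal(r$n_progenitors, 4)
  expect_error(overabundanceFromLineage(flat, 99), "time range")
})

test_that("elongation overabundance is consistent with exp(k0*T)", {
  k0 <- log(2)
  tr <- simulateLineage(k0 = k0, oTrue = 8, dt = 0.1, tMax = 4.5, seed = 1)
  res <- analyzeLineage(tr, k0 = k0)
  # within one sampling interval of growth
  expect_lt(
    abs(log(res$o_elongation) - k0 * res$arrest_time_h),
    k0 * 0.1 + 1e-9
  )
})

test_that("elongation overabundance is non-decreasing in the arrest time", {
  tr <- simulateLineage(
    k0 = log(2), oTrue = 1e4, dt = 0.1, tMax = 4,
    growthNoiseCV = 0.1, seed = 5
  )
  ts <- totalAreaSeries(tr)
  o <- vapply(ts$time_h[-1], function(T) {
    overabundanceFromLineage(tr, T)$o_elongation
  }, numeric(1))
  expect_true(all(diff(o) >= -1e-9))
})

test_that("median recovered overabundance tracks the truth across seeds", {
  k0 <- log(2)
  for (l10 in c(0.5, 1.5)) {
    o <- 10^l10
    rec <- vapply(1:8, function(s) {
      tr <- simulateLineage(
        k0 = k0, oTrue = o, dt = 0.1, tMax = log(o) / k0 + 3,
        growthNoiseCV = 0.1, divisionAsymmetryCV = 0.05, seed = s
      )
      analyzeLineage(tr, k0 = k0)$log10_o_elongation
    }, numeric(1))
    expect_lt(abs(median(rec) - l10), 0.1)
  }
})

test_that("the reconstructed fitness landscape is step-like", {
  k0 <- log(2)
  # zero noise, o_true = 8: k = k0 above the threshold, ~0 below
  tr <- simulateLineage(k0 = k0, oTrue = 8, dt = 0.1, tMax = 5, seed = 1)
  fl <- fitnessLandscape(tr, k0 = k0)
  above <- relAbundance(fl) > 1.2 / 8
  expect_true(mean(growthRate(fl)[above] > 0.5 * k0) > 0.95)
  below <- relAbundance(fl) < 1 / 8 / 1.2
  expect_true(all(growthRate(fl)[below] < 0.2 * k0))
  expect_equal(arrestRelAbundance(fl), 1 / 8, tolerance = 0.15)
  # o_true = 1: landscape collapses near C/C0 = 1
  tr1 <- simulateLineage(k0 = k0, oTrue = 1, dt = 0.1, tMax = 1, seed = 1)
  fl1 <- fitnessLandscape(tr1, k0 = k0)
  expect_true(all(relAbundance(fl1) > 0.99))
})

test_that("arrest abundance is recovered within 15% across noisy seeds", {
  k0 <- log(2)
  est <- vapply(1:20, function(s) {
    tr <- simulateLineage(
      k0 = k0, oTrue = 8, dt = 0.1, tMax = 5.5,
      growthNoiseCV = 0.1, seed = s
    )
    arrestRelAbundance(fitnessLandscape(tr, k0 = k0))
  }, numeric(1))
  expect_lt(abs(median(est) - 1 / 8), 0.15 / 8)
})

test_that("fluorescence dilution check validates conservation", {
  tr <- simulateLineage(k0 = log(2), oTrue = 50, dt = 0.1, tMax = 3, seed = 2)
  chk <- fluorescenceDilutionCheck(tr)
  expect_lt(chk$rel_rms, 1e-6)
  # negative control: inject synthesis, deviation grows with time
  bad <- simulateLineage(
    k0 = log(2), oTrue = 50, dt = 0.1, tMax = 3,
    synthesisRate = 0.5, seed = 2
  )
  chkBad <- fluorescenceDilutionCheck(bad)
  expect_gt(chkBad$rel_rms, 0.05)
  dev <- abs(chkBad$table$observed_conc - chkBad$table$predicted_conc)
  expect_gt(dev[length(dev)], dev[2])
  # arrested cells hold their concentration
  arr <- simulateLineage(k0 = log(2), oTrue = 2, dt = 0.1, tMax = 3, seed = 2)
  expect_lt(fluorescenceDilutionCheck(arr)$arrested_conc_cv, 1e-9)
  noF <- makeTree(data.frame(
    cell_id = 1L, parent_id = NA_integer_, time_h = 0:3,
    area_um2 = exp(0:3)
  ))
  expect_error(fluorescenceDilutionCheck(noF), "fluorescence")
})
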