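test_that("protein is conserved and area additive at divisions", {
  tr <- simulateLineage(
    k0 = log(2), oTrue = 10, dt = 0.1, tMax = 4,
    growthNoiseCV = 0.1, divisionAsymmetryCV = 0.1, seed = 3
  )
  ts <- totalAreaSeries(tr)
  expect_true(all(abs(ts$total_fluor_au - ts$total_fluor_au[1]) <
    1e-6 * ts$total_fluor_au[1]))
  tk <- cellTracks(tr)
  kids <- tk[!is.na(tk$parent_id) & !duplicated(tk$cell_id), ]
  for (p in unique(kids$parent_id)) {
    born <- kids[kids$parent_id == p, ]
    momLast <- max(tk$time_h[tk$cell_id == p])
    momArea <- tk$area_um2[tk$cell_id == p & tk$time_h == momLast]
    expect_equal(sum(born$area_um2), momArea, tolerance = 1e-12)
    expect_true(all(born$time_h == momLast))
  }
})

test_that("zero-noise concentration follows the dilution model exactly", {
  k0 <- log(2)
  tr <- simulateLineage(k0 = k0, oTrue = 100, dt = 0.1, tMax = 3, seed = 1)
  ts <- totalAreaSeries(tr)
  conc <- ts$total_fluor_au / ts$total_area_um2
  pred <- dilutionConcentration(conc[1], ts$total_area_um2[1], ts$total_area_um2)
  expect_equal(conc, pred, tolerance = 1e-9)
  # total area grows at exactly k0 before arrest
  expect_equal(ts$total_area_um2, ts$total_area_um2[1] * exp(k0 * ts$time_h),
    tolerance = 1e-9
  )
})

test_that("arrest times match the dilution threshold", {
  k0 <- log(2)
  # o = 4: all cells arrest when total progeny area reaches 4x, at t = 2 h
  tr <- simulateLineage(k0 = k0, oTrue = 4, dt = 0.1, tMax = 3, seed = 1)
  expect_equal(unique(tr@metadata$arrestTimes), 2)
  ts <- totalAreaSeries(tr)
  expect_equal(max(ts$total_area_um2) / ts$total_area_um2[1], 4,
    tolerance = 1e-9
  )
  # o = 1: arrest at t = 0, no growth beyond one sampling step
  tr1 <- simulateLineage(k0 = k0, oTrue = 1, dt = 0.1, tMax = 1, seed = 1)
  expect_equal(unique(tr1@metadata$arrestTimes), 0)
  ts1 <- totalAreaSeries(tr1)
  expect_lt(max(ts1$total_area_um2) / ts1$total_area_um2[1], exp(k0 * 0.1) + 1e-12)
  # o = 10^1.5 (dnaN scale): k0*T/ln10 = 1.5
  o <- 10^1.5
  tr2 <- simulateLineage(k0 = k0, oTrue = o, dt = 0.001, tMax = 5.2, seed = 1)
  T <- unique(tr2@metadata$arrestTimes)
  expect_equal(k0 * T / log(10), 1.5, tolerance = 1e-2)
})

test_that("seeded lineage simulations are bit-reproducible", {
  a <- simulateLineage(oTrue = 8, growthNoiseCV = 0.2, seed = 7, tMax = 4)
  b <- simulateLineage(oTrue = 8, growthNoiseCV = 0.2, seed = 7, tMax = 4)
  c <- simulateLineage(oTrue = 8, growthNoiseCV = 0.2, seed = 8, tMax = 4)
  expect_identical(cellTracks(a), cellTracks(b))
  expect_false(identical(cellTracks(a), cellTracks(c)))
})

test_that("lineage simulation rejects invalid configuration", {
  expect_error(simulateLineage(dt = 0), "dt and tMax")
  expect_error(simulateLineage(tMax = -1), "dt and tMax")
  expect_error(simulateLineage(oTrue = 0.5), "oTrue")
  expect_error(simulateLineage(growthNoiseCV = 1), "growthNoiseCV")
})

test_that("library counts are multinomial at the configured depth", {
  se <- simulateTfnseqLibrary(
    nGenesPerClass = c(no_effect = 10, sufficient = 10, overabundant = 10),
    depth = 12345, seed = 2
  )
  cnt <- SummarizedExperiment::assay(se, "counts")
  expect_true(all(colSums(cnt) == 12345))
  expect_error(
    simulateTfnseqLibrary(nGenesPerClass = c(
      no_effect = 0, sufficient = 0, overabundant = 0
    )),
    "empty"
  )
})

test_that("expected library trajectories follow the three class models", {
  # near-infinite depth makes empirical shares track expectations
  se <- simulateTfnseqLibrary(
    nGenesPerClass = c(no_effect = 5, sufficient = 0, overabundant = 5),
    sampleTimes = seq(0, 12, 2), depth = 1e7, k0 = log(2),
    overabundanceRange = c(1.2041, 1.2041), # log10 o for T = 4 h at k0 = ln2
    seed = 4
  )
  cnt <- SummarizedExperiment::assay(se, "counts")
  tt <- truthTable(se)
  times <- fractionTimes(se)
  rel <- sweep(cnt, 2, colSums(cnt), "/")
  y <- log2(rel / rel[, 1])
  iO <- which(tt$class == "overabundant")[1]
  expected <- -pmax(times - 4, 0) # log2 units at k0 = ln2
  # shares are relative: subtract a no-effect gene's trajectory to remove
  # the library-composition drift before comparing with the growth model
  iN <- which(tt$class == "no_effect")[1]
  expect_equal(unname(y[iO, ] - y[iN, ]), expected, tolerance = 0.05)
  # in an all-no-effect library every trajectory is flat at high depth
  seN <- simulateTfnseqLibrary(
    nGenesPerClass = c(no_effect = 10, sufficient = 0, overabundant = 0),
    sampleTimes = seq(0, 12, 2), depth = 1e7, seed = 5
  )
  cN <- SummarizedExperiment::assay(seN, "counts")
  relN <- sweep(cN, 2, colSums(cN), "/")
  expect_lt(max(abs(log2(relN / relN[, 1]))), 0.05)
})

test_that("rnaseq counts split by message number and seed out zeros", {
  r <- simulateRnaseq(c(a = 30, b = 30), depth = 1e5, seed = 1)
  expect_equal(r$count[1] / sum(r$count), 0.5, tolerance = 0.02)
  r0 <- simulateRnaseq(c(a = 10, b = 0), depth = 1e4, seed = 1)
  expect_identical(r0$count[2], 0L)
  expect_error(simulateRnaseq(c(a = 0, b = 0)), "zero")
  expect_error(simulateRnaseq(c(a = -1, b = 2)), ">= 0")
})
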