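test_that("log relative abundance is anchored and scales as expected", {
  r <- logRelativeAbundance(c(10, 10, 10), rep(100, 3))
  expect_equal(r$y, rep(0, 3))
  h <- logRelativeAbundance(c(80, 40, 20, 10), rep(1000, 4), pseudocount = 0)
  expect_equal(diff(h$y), rep(-log(2), 3))
  z <- logRelativeAbundance(c(0, 0, 0, 0), rep(100, 4))
  expect_identical(z$informative, 0L)
  expect_error(logRelativeAbundance(c(1, 2), c(10, 0)), "positive")
})

test_that("noiseless model fits are exactly identifiable and nested", {
  k0 <- log(2)
  times <- seq(0, 12, 2)
  # exact breakpoint data: T = 4 recovered, rss ~ 0
  y2 <- -k0 * pmax(times - 4, 0)
  f <- fitTrajectoryModels(times, y2, k0 = k0)
  expect_equal(f$m2$T, 4, tolerance = 1e-4)
  expect_lt(f$m2$rss, 1e-12)
  expect_gt(f$m1$rss, 0.1)
  # exact flat data: every model reaches rss ~ 0
  f0 <- fitTrajectoryModels(times, rep(0, 7), k0 = k0)
  expect_lt(f0$m0$rss, 1e-12)
  expect_lt(f0$m1$rss, 1e-12)
  expect_lt(f0$m2$rss, 1e-12)
})

test_that("model nesting holds for arbitrary noisy trajectories", {
  k0 <- log(2)
  times <- seq(0, 24, 2)
  set.seed(42)
  for (i in 1:50) {
    y <- cumsum(rnorm(length(times), sd = 0.5))
    w <- runif(length(times), 0.5, 2)
    f <- fitTrajectoryModels(times, y, w, k0 = k0)
    expect_lte(f$m2$rss, f$m1$rss + 1e-9)
    expect_lte(f$m1$rss, f$m0$rss + 1e-9)
  }
})

test_that("grid-plus-refinement matches the brute-force breakpoint oracle", {
  k0 <- log(2)
  times <- seq(0, 24, 2)
  set.seed(7)
  for (i in 1:25) {
    Tt <- runif(1, 1, 20)
    y <- -k0 * pmax(times - Tt, 0)
    if (i > 12) y <- y + rnorm(length(y), sd = 0.05)
    f <- fitTrajectoryModels(times, y, k0 = k0)
    orc <- oracleBreakpoint(times, y, rep(1, length(y)), k0)
    expect_lt(abs(f$m2$T - orc$T), 0.01)
  }
})

test_that("sequential tests separate the three trajectory classes", {
  k0 <- log(2)
  times <- seq(0, 24, 2)
  set.seed(11)
  # flat trajectory (recF-like non-essential): no effect
  fFlat <- fitTrajectoryModels(times, rnorm(13, sd = 0.05), k0 = k0)
  expect_identical(classifyTrajectory(fFlat)$class, "no_effect")
  # immediate decline at the wild-type rate (dnaA-like): sufficient, o = 1
  yS <- -k0 * times + rnorm(13, sd = 0.1)
  cS <- classifyTrajectory(fitTrajectoryModels(times, yS, k0 = k0))
  expect_identical(cS$class, "sufficient")
  expect_identical(cS$log10_o, 0)
  # late breakpoint: overabundant with o = exp(k0*T)
  yO <- -k0 * pmax(times - 8, 0) + rnorm(13, sd = 0.05)
  cO <- classifyTrajectory(fitTrajectoryModels(times, yO, k0 = k0))
  expect_identical(cO$class, "overabundant")
  expect_equal(cO$log10_o, k0 * 8 / log(10), tolerance = 0.05)
  expect_true(is.finite(cO$se_log10_o))
})

test_that("ftsN-scale overabundance is recovered from deep libraries", {
  # true log10 o = 2.6, depth 1e5, fractions every 2 h over 24 h
  k0 <- log(2)
  hit <- vapply(1:20, function(s) {
    se <- simulateTfnseqLibrary(
      nGenesPerClass = c(no_effect = 30, sufficient = 0, overabundant = 10),
      depth = 1e5, k0 = k0, overabundanceRange = c(2.6, 2.6), seed = s
    )
    res <- classifyLibrary(se, k0 = k0)
    tt <- truthTable(se)
    i <- tt$class == "overabundant"
    mean(res$class[i] == "overabundant" &
      abs(res$log10_o[i] - 2.6) <= 0.2)
  }, numeric(1))
  expect_gte(mean(hit), 0.9)
})

test_that("balanced library classification is accurate with small bias", {
  k0 <- log(2)
  se <- simulateTfnseqLibrary(
    nGenesPerClass = c(no_effect = 60, sufficient = 60, overabundant = 60),
    depth = 1e5, k0 = k0, seed = 13
  )
  res <- classifyLibrary(se, k0 = k0)
  tt <- truthTable(se)
  expect_gt(mean(res$class == tt$class), 0.9)
  iO <- tt$class == "overabundant" & res$class == "overabundant"
  expect_lte(median(abs(res$log10_o[iO] - tt$log10_o[iO])), 0.15)
})

test_that("trajectories with sparse counts are flagged unclassifiable", {
  counts <- rbind(
    gene_a = c(100, 90, 110, 95, 105, 98, 102),
    gene_b = c(3, 0, 0, 1, 0, 0, 0)
  )
  res <- classifyLibrary(counts, times = seq(0, 12, 2), k0 = log(2))
  expect_identical(res$class[res$gene_id == "gene_b"], "unclassifiable")
  expect_true(is.na(res$log10_o[res$gene_id == "gene_b"]))
})

test_that("near-zero arrest times collapse to the sufficiency boundary", {
  k0 <- log(2)
  times <- seq(0, 24, 2)
  set.seed(3)
  l10 <- vapply(1:20, function(i) {
    y <- -k0 * pmax(times - 0.2, 0) + rnorm(13, sd = 0.05)
    cl <- classifyTrajectory(fitTrajectoryModels(times, y, k0 = k0))
    if (cl$class %in% c("sufficient", "overabundant")) cl$log10_o else NA_real_
  }, numeric(1))
  expect_true(all(!is.na(l10))) # never called no-effect
  expect_lt(median(l10), 0.15) # estimated overabundance collapses to ~0
})

test_that("arrest times convert to overabundance via o = exp(k0*T)", {
  expect_equal(overabundanceFromArrest(log(2), 0)$o, 1)
  expect_equal(overabundanceFromArrest(log(2), 2)$o, 4)
  # dnaN TFNseq value: log10 o = 1.5 at T = 4.983 h, k0 = ln2
  expect_equal(overabundanceFromArrest(log(2), 4.983)$log10_o, 1.5,
    tolerance = 1e-3
  )
  expect_error(overabundanceFromArrest(log(2), -1), ">= 0")
  expect_error(overabundanceFromArrest(0, 1), "k0")
})

test_that("k0 comes from config or spike-in totals, never from thin air", {
  expect_identical(estimateK0(k0 = 0.9)$k0, 0.9)
  expect_identical(estimateK0(k0 = 0.9)$method, "supplied")
  tt <- seq(0, 10, 2)
  est <- estimateK0(absoluteTotals = 100 * exp(0.8 * tt), times = tt)
  expect_equal(est$k0, 0.8, tolerance = 0.02 * 0.8)
  expect_identical(est$method, "spike_in")
  expect_error(estimateK0(), "cannot be determined")
})
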