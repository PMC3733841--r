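test_that("signal model obeys its limits and closed form", {
  ## zero magnetization and full-recovery/no-decay limits
  expect_equal(modelSignal(1.2, 11, 0, 500, 20), 0)
  expect_equal(modelSignal(1000, 11.79, 70, 2860, 0), 70, tolerance = 1e-12)
  ## white-matter-like inputs against an independent evaluation of the form
  expect_equal(modelSignal(1.38, 11.79, 70, 2860, 14),
               70 * (1 - exp(-2.86 * 1.38)) * exp(-0.014 * 11.79),
               tolerance = 1e-15)
  ## monotonic in delay, anti-monotonic in echo
  delays <- seq(50, 2800, by = 250)
  sig <- modelSignal(1, 10, 100, delays, 20)
  expect_true(all(diff(sig) > 0))
  echoes <- seq(10, 80, by = 10)
  sig <- modelSignal(1, 10, 100, 1000, echoes)
  expect_true(all(diff(sig) < 0))
  expect_error(modelSignal(-0.1, 10, 100, 100, 10), "nonnegative")
  expect_error(modelSignal(1, 10, NA, 100, 10), "finite")
})

test_that("protocol invariants are enforced and defaults give 20 images", {
  pr <- defaultProtocol()
  expect_equal(imagesPerSlice(pr), 20L)
  expect_equal(pr@saturationDelays, c(100, 400, 1380, 2860))
  expect_error(acquisitionProtocol(c(400, 100), c(14, 28), 2950),
               "increasing")
  expect_error(acquisitionProtocol(c(100, 3000), c(14, 28), 2950),
               "repetition")
})

test_that("noise-free voxel fits invert the forward model exactly", {
  pr <- defaultProtocol()
  for (r1 in c(0.2, 0.7, 1.38, 2)) {
    for (r2 in c(2, 8, 11.79, 20)) {
      S <- outer(pr@saturationDelays, pr@echoTimes,
                 function(d, e) modelSignal(r1, r2, 1000, d, e))
      f <- fitVoxel(S, pr)
      expect_lt(abs(f$R1 - r1) / r1, 1e-6)
      expect_lt(abs(f$R2 - r2) / r2, 1e-6)
      expect_lt(abs(f$M0 - 1000) / 1000, 1e-6)
      expect_true(f$converged)
    }
  }
})

test_that("log-linear echo regression at the longest delay recovers R2", {
  pr <- defaultProtocol()
  y <- cleanSignal(pr, 1.1, 9.3, 500)
  atLast <- matrix(y, nrow = 4)[4, ]
  slope <- stats::coef(stats::lm(log(atLast) ~ I(pr@echoTimes * 1e-3)))[2]
  expect_equal(unname(-slope), 9.3, tolerance = 1e-9)
})

test_that("noisy recovery is accurate and matches the grid-search oracle", {
  pr <- defaultProtocol()
  clean <- cleanSignal(pr, 1.38, 11.79, 1000)
  set.seed(101)
  Y <- matrix(pmax(clean + stats::rnorm(20 * 1000, sd = 10), 0), nrow = 20)
  fe <- qmapnorm:::fitEngine(Y, pr)
  expect_lt(abs(stats::median(fe$R1) - 1.38) / 1.38, 0.02)
  expect_lt(abs(stats::median(fe$R2) - 11.79) / 11.79, 0.02)
  ## oracle equivalence on 100 voxels: the optimizer's objective beats a
  ## dense 0.01 1/s grid around the physiological neighbourhood
  r1Grid <- seq(1.0, 1.8, by = 0.01)
  r2Grid <- seq(9.5, 14, by = 0.01)
  for (v in 1:100) {
    g <- gridFitOracle(Y[, v], pr, r1Grid, r2Grid)
    ours <- fitObjective(Y[, v], pr, fe$R1[v], fe$R2[v], fe$M0[v])
    expect_lte(ours, g$cost + 1e-6 * g$cost + 1e-9)
  }
})

test_that("recovery error grows monotonically with noise level", {
  pr <- defaultProtocol()
  clean <- cleanSignal(pr, 1.38, 11.79, 1000)
  rmse <- vapply(c(0.005, 0.01, 0.02, 0.05), function(fr) {
    set.seed(round(1e4 * fr))
    Y <- matrix(pmax(clean + stats::rnorm(20 * 400, sd = fr * 1000), 0),
                nrow = 20)
    fe <- qmapnorm:::fitEngine(Y, pr)
    sqrt(mean((fe$R1 - 1.38)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) > 0))
})

test_that("unusable voxels are flagged, never silently zeroed", {
  pr <- defaultProtocol()
  f <- fitVoxel(matrix(0, 4, 5), pr)
  expect_true(is.nan(f$R1))
  expect_false(f$converged)
  expect_equal(f$code, 1L)
  expect_error(fitVoxel(matrix(1, 3, 5), pr), "extents")
})

test_that("volume fitting honours the mask and is deterministic", {
  ph <- tinyPhantom()
  ser <- simulateAcquisition(ph$maps)
  mask <- validMask(ph$maps)
  maps1 <- fitVolume(ser, mask = mask)
  ## noise-free round trip inside the mask
  v <- validMask(maps1) & mask
  expect_lt(max(abs(r1Map(maps1)[v] - r1Map(ph$maps)[v]) /
                r1Map(ph$maps)[v]), 1e-5)
  expect_lt(max(abs(pdMap(maps1)[v] - pdMap(ph$maps)[v]) /
                pdMap(ph$maps)[v]), 1e-5)
  ## masked-out voxels carry the sentinel
  out <- which(!mask)[1]
  expect_true(is.nan(r1Map(maps1)[out]))
  expect_false(validMask(maps1)[out])
  ## bit-identical rerun
  maps2 <- fitVolume(ser, mask = mask)
  expect_identical(r1Map(maps1), r1Map(maps2))
  expect_identical(fitQuality(maps1), fitQuality(maps2))
})

test_that("PD calibration rescales to percent and preserves ratios", {
  ph <- tinyPhantom()
  maps <- ph$maps
  maps@pdUnit <- "arbitrary"
  ref <- array(maps@valid & ph$labels@labels == 6L, dim(maps@PD))
  cal <- calibratePD(maps, ref)
  expect_equal(stats::median(pdMap(cal)[ref]), 100)
  expect_equal(cal@pdUnit, "percent")
  ## linear rescaling: a voxel at 70% of the reference median
  med <- stats::median(pdMap(maps)[ref])
  wm <- which(ph$labels@labels == 1L)[1]
  expect_equal(pdMap(cal)[wm], 100 * pdMap(maps)[wm] / med, tolerance = 1e-12)
  ## ratios invariant
  v2 <- which(ph$labels@labels == 2L)[1]
  expect_equal(pdMap(cal)[wm] / pdMap(cal)[v2],
               pdMap(maps)[wm] / pdMap(maps)[v2], tolerance = 1e-12)
  ## idempotent
  cal2 <- calibratePD(cal, ref)
  expect_equal(pdMap(cal2), pdMap(cal), tolerance = 1e-12)
  ## R1/R2 untouched
  expect_identical(r1Map(cal), r1Map(maps))
  expect_error(calibratePD(maps, array(FALSE, dim(maps@PD))), "empty")
})
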