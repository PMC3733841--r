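test_that("phantom anatomy is reproducible and correctly labeled", {
  spec <- tinySpec()
  p1 <- makePhantom(spec, seed = 5)
  p2 <- makePhantom(spec, seed = 5)
  expect_identical(p1$labels@labels, p2$labels@labels)
  expect_identical(r1Map(p1$maps), r1Map(p2$maps))
  p3 <- makePhantom(spec, seed = 6)
  expect_false(identical(r1Map(p1$maps), r1Map(p3$maps)))
  ## every labeled voxel carries its class's assigned values
  can <- makePhantom(spec, vary = FALSE)
  cl <- defaultTissueClasses()
  for (i in seq_len(nrow(cl))) {
    sel <- can$labels@labels == cl$code[i]
    if (any(sel)) {
      expect_true(all(r1Map(can$maps)[sel] == cl$r1[i]))
      expect_true(all(pdMap(can$maps)[sel] == cl$pd[i]))
    }
  }
  ## unlabeled voxels are invalid
  expect_true(all(is.nan(r1Map(can$maps)[can$labels@labels == 0L])))
  expect_equal(validMask(can$maps), array(can$labels@labels > 0L,
                                          dim(can$labels@labels)))
})

test_that("the ventricle fraction hits its target within voxelization error", {
  for (spec in list(phantomSpec(), statsSpec())) {
    ph <- makePhantom(spec, vary = FALSE)
    lvf <- 100 * sum(ph$labels@labels == 6L) / sum(ph$icvMask)
    expect_lt(abs(lvf - 100 * spec@ventricleFraction), 0.2)
  }
})

test_that("an unfolded single-shell spec matches the analytic ellipsoid volume", {
  ## with folding off, the intracranial boundary is the 1.1-scaled ellipsoid
  spec <- phantomSpec(dim = c(48, 58, 44), spacing = 2, foldAmplitude = 0)
  ph <- makePhantom(spec, vary = FALSE)
  analytic <- 4 / 3 * pi * prod(c(33, 41, 30) * 1.1)
  voxel <- sum(ph$icvMask) * prod(spec@spacing)
  expect_lt(abs(voxel - analytic) / analytic, 0.02)
})

test_that("lesions live in white matter and carry the configured contrast", {
  spec <- phantomSpec(dim = c(32, 38, 30), spacing = 3,
                      lesions = list(n = 3, radiusRange = c(5, 7)))
  ph <- makePhantom(spec, seed = 12, vary = FALSE)
  les <- ph$labels@labels == 8L
  expect_gt(sum(les), 20)
  expect_equal(unique(r1Map(ph$maps)[les]), 1.38 - 0.35, tolerance = 1e-12)
  expect_equal(unique(r2Map(ph$maps)[les]), 11.79 - 3.0, tolerance = 1e-12)
  expect_equal(unique(pdMap(ph$maps)[les]), 70 + 10, tolerance = 1e-12)
  ## lesion label table entry exists
  expect_true("lesion" %in% ph$labels@table$name)
})

test_that("simulated acquisitions match the forward model and protocol", {
  ph <- tinyPhantom()
  ser <- simulateAcquisition(ph$maps)
  d <- dim(ser@data)
  expect_equal(d[1] * d[2], 20L)        # 4 delays x 5 echoes per slice
  pr <- protocol(ser)
  ## noise-free: exact forward-model values
  vox <- which(ph$labels@labels == 1L)[1]
  ijk <- arrayInd(vox, dim(ph$labels@labels))
  expect_equal(ser@data[2, 3, ijk[1], ijk[2], ijk[3]],
               modelSignal(1.38, 11.79, 70, pr@saturationDelays[2],
                           pr@echoTimes[3]), tolerance = 1e-12)
  ## seeded reproducibility
  s1 <- simulateAcquisition(ph$maps, noiseSigma = 0.7, seed = 3)
  s2 <- simulateAcquisition(ph$maps, noiseSigma = 0.7, seed = 3)
  expect_identical(s1@data, s2@data)
  expect_error(simulateAcquisition(ph$maps, noiseSigma = -1), "nonnegative")
})

test_that("Rician noise converges to the Gaussian mean at high SNR", {
  g <- makeGeometry(c(10, 10, 10), 2)
  d <- g@dim
  maps <- new("QuantMaps", R1 = array(1.38, d), R2 = array(11.79, d),
              PD = array(70, d), valid = array(TRUE, d),
              fitQuality = array(0, d), geometry = g, pdUnit = "percent")
  pr <- defaultProtocol()
  clean <- modelSignal(1.38, 11.79, 70, pr@saturationDelays[4],
                       pr@echoTimes[1])
  sigma <- 0.7
  rs <- simulateAcquisition(maps, pr, noiseSigma = sigma,
                            noiseModel = "rician", seed = 4)
  riceMean <- mean(rs@data[4, 1, , , ])
  ## exact Rician mean via the half-order Laguerre polynomial; the
  ## exponentially scaled Bessel terms absorb exp(x/2) for x < 0
  x <- -clean^2 / (2 * sigma^2)
  lag <- (1 - x) * besselI(-x / 2, 0, expon.scaled = TRUE) -
    x * besselI(-x / 2, 1, expon.scaled = TRUE)
  exact <- sigma * sqrt(pi / 2) * lag
  expect_lt(abs(riceMean - exact) / exact, 0.01)
  expect_lt(abs(exact - clean) / clean, 0.01)   # high-SNR regime
})

test_that("cohorts are reproducible byte for byte and respect their spec", {
  spec <- tinySpec()
  cs <- cohortSpec(n = 4, seed = 9,
                   jitterSd = c(trans = 2, rot = 0.02, zoom = 0.01,
                                shear = 0.005))
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  makeCohort(spec, cs, simulate = FALSE, outDir = d1)
  makeCohort(spec, cs, simulate = FALSE, outDir = d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  coh <- makeCohort(spec, cs, simulate = FALSE)
  ages <- vapply(coh$subjects, `[[`, numeric(1), "age")
  expect_true(all(ages >= 26 & ages <= 67))
  expect_equal(nrow(coh$table), 4L)
  ## jitter moved the anatomy
  can <- tinyPhantom()
  expect_false(identical(coh$subjects[[1]]$labels@labels, can$labels@labels))
})

test_that("injected age slopes shift tissue values as specified", {
  slopes <- data.frame(className = "white_matter", parameter = "r1",
                       slopePerYear = -0.004)
  cs <- cohortSpec(n = 6, slopes = slopes, noiseSigma = 0, seed = 13)
  coh <- makeCohort(tinySpec(), cs, simulate = FALSE)
  ## reconstruct each subject's WM draw without the slope: the injected
  ## offset is slope * (age - 45)
  csNo <- cohortSpec(n = 6, slopes = NULL, noiseSigma = 0, seed = 13)
  cohNo <- makeCohort(tinySpec(), csNo, simulate = FALSE)
  for (i in 1:6) {
    wmWith <- coh$subjects[[i]]$classValues
    wmNo <- cohNo$subjects[[i]]$classValues
    dr1 <- wmWith$r1[wmWith$name == "white_matter"] -
      wmNo$r1[wmNo$name == "white_matter"]
    expect_equal(dr1, -0.004 * (coh$subjects[[i]]$age - 45),
                 tolerance = 1e-10)
  }
})

test_that("a noise-free jitter-free pipeline yields zero deviations", {
  ph <- tinyPhantom()
  ser <- simulateAcquisition(ph$maps)
  f0 <- fitVolume(ser, mask = validMask(ph$maps))
  tpl <- tinyTemplate()
  n0 <- normalizeSubject(f0, tpl, levels = c(8, 4), maxit = c(150L, 100L))
  atl <- buildReference(list(n0$maps, n0$maps, n0$maps))
  dev <- deviate(n0$maps, atl)
  interior <- interiorMask(ph, 1)
  expect_lt(max(abs(dev@z$R1[interior]), na.rm = TRUE), 0.1)
  expect_lt(max(dev@S[interior], na.rm = TRUE), 0.1)
})
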