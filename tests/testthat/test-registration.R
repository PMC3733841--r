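test_that("affine parameters and matrices round-trip exactly", {
  set.seed(4)
  for (k in 1:20) {
    tr <- affineTransform(translation = stats::runif(3, -10, 10),
                          rotation = stats::runif(3, -0.3, 0.3),
                          zoom = stats::runif(3, 0.85, 1.15),
                          shear = stats::runif(3, -0.12, 0.12))
    rt <- affineFromMatrix(transformMatrix(tr))
    expect_lt(max(abs(transformParams(rt) - transformParams(tr))), 1e-9)
  }
  expect_error(affineFromMatrix(diag(c(1, 1, 0, 1))), "singular")
  expect_error(affineTransform(zoom = c(-1, 1, 1)), "zoom")
})

test_that("inversion and composition behave as a group", {
  expect_lt(max(abs(transformMatrix(invertTransform(identityTransform())) -
                    diag(4))), 1e-12)
  t1 <- affineTransform(translation = c(3, -2, 1), rotation = c(0.1, 0, -0.2),
                        zoom = c(1.05, 0.95, 1.0), shear = c(0.03, 0, -0.05))
  comp <- composeTransforms(invertTransform(t1), t1)
  expect_lt(max(abs(transformMatrix(comp) - diag(4))), 1e-9)
  ## compose(a, b)(x) = a(b(x)) on random points
  t2 <- affineTransform(translation = c(-1, 4, 2), rotation = c(0, 0.15, 0))
  set.seed(5)
  pts <- matrix(stats::rnorm(30, sd = 20), 3)
  expect_equal(transformPoints(composeTransforms(t1, t2), pts),
               transformPoints(t1, transformPoints(t2, pts)),
               tolerance = 1e-10)
})

test_that("resampling respects identity, inverses and constants", {
  ph <- tinyPhantom()
  g <- geometry(ph$maps)
  vol <- synthesize(ph$maps)
  idn <- applyTransform(vol, g, identityTransform(), g, "nearest")
  expect_identical(idn, vol)
  idt <- applyTransform(vol, g, identityTransform(), g, "trilinear")
  expect_equal(idt, vol, tolerance = 1e-12)
  ## +1 voxel then -1 voxel translation with nearest restores the interior
  sh <- affineTransform(translation = c(4, 0, 0))   # one 4 mm voxel
  fwd <- applyTransform(vol, g, sh, g, "nearest")
  back <- applyTransform(fwd, g, invertTransform(sh), g, "nearest")
  interior <- 3:(dim(vol)[1] - 2)
  expect_equal(back[interior, , ], vol[interior, , ])
  ## constants stay constant on in-field voxels
  const <- array(2.5, g@dim)
  tr <- affineTransform(translation = c(3, -2, 1), rotation = c(0.05, 0, 0.1))
  rs <- applyTransform(const, g, tr, g, "trilinear")
  expect_equal(rs[is.finite(rs)],
               rep(2.5, sum(is.finite(rs))), tolerance = 1e-12)
  ## out-of-field voxels carry the NaN sentinel
  big <- affineTransform(translation = c(60, 0, 0))
  out <- applyTransform(vol, g, big, g, "trilinear")
  expect_true(any(is.nan(out)))
  expect_error(applyTransform(vol, g, sh, g, "cubic"))
})

test_that("nearest-resampled label volumes contain no novel values", {
  ph <- tinyPhantom()
  g <- geometry(ph$maps)
  lab <- array(as.numeric(ph$labels@labels), g@dim)
  tr <- affineTransform(translation = c(3, 5, -2), rotation = c(0.1, -0.05, 0.08),
                        zoom = c(1.06, 0.94, 1.02))
  rs <- applyTransform(lab, g, tr, g, "nearest")
  expect_true(all(rs[is.finite(rs)] %in% unique(as.vector(lab))))
})

test_that("registering an image to itself returns the identity", {
  tpl <- tinyTemplate()
  g <- tpl@geometry
  sm <- gaussianSmooth(tpl@volume, 8, g)
  est <- estimateAffine(sm, g, sm, g, levels = c(8, 4))
  expect_lt(max(abs(transformParams(est$transform) -
                    transformParams(identityTransform()))), 1e-3)
  expect_lte(est$cost, est$initialCost)
})

test_that("a known affine perturbation is recovered", {
  tpl <- defaultTemplateCached()
  g <- tpl@geometry
  sm <- gaussianSmooth(tpl@volume, 8, g)
  truth <- affineTransform(translation = c(4, -3, 2),
                           rotation = c(0.03, -0.05, 0.0873),
                           zoom = c(1.05, 0.97, 1.02),
                           shear = c(0.04, 0, -0.03))
  src <- applyTransform(sm, g, truth, g, "trilinear")
  src[!is.finite(src)] <- 0
  est <- estimateAffine(src, g, sm, g)
  ## composed estimate . truth should move brain voxels < 0.5 mm on average
  brain <- which(tpl@volume > 5)
  W <- qmapnorm:::worldGrid(g)[, brain]
  M <- transformMatrix(composeTransforms(est$transform, truth))
  disp <- sqrt(colSums(((M[1:3, 1:3] %*% W) + M[1:3, 4] - W)^2))
  expect_lt(mean(disp), 1)
  expect_lte(est$cost, est$initialCost)
  ## determinism: a second run gives the identical transform
  est2 <- estimateAffine(src, g, sm, g)
  expect_identical(transformParams(est$transform),
                   transformParams(est2$transform))
})

test_that("integer-voxel translations are recovered to sub-voxel accuracy", {
  tpl <- defaultTemplateCached()
  g <- tpl@geometry
  sm <- gaussianSmooth(tpl@volume, 8, g)
  truth <- affineTransform(translation = c(4, -6, 2))  # 2, -3, 1 voxels
  src <- applyTransform(sm, g, truth, g, "trilinear")
  src[!is.finite(src)] <- 0
  est <- estimateAffine(src, g, sm, g)
  recovered <- -transformParams(est$transform)[1:3]    # inverse mapping
  expect_lt(max(abs(recovered - c(4, -6, 2))), 0.25 * 2)
  expect_error(estimateAffine(array(1, g@dim), g, sm, g), "degenerate")
})

test_that("normalization of an already-normalized subject is near-identity", {
  ph <- tinyPhantom()
  tpl <- tinyTemplate()
  norm <- normalizeSubject(ph$maps, tpl, levels = c(8, 4),
                           maxit = c(150L, 100L))
  v <- validMask(norm$maps) & validMask(ph$maps)
  expect_gt(sum(v), 0.9 * sum(validMask(ph$maps)))
  expect_lt(stats::median(abs(r1Map(norm$maps)[v] - r1Map(ph$maps)[v])), 0.02)
  ## the estimated transform is close to the identity
  expect_lt(max(abs(transformParams(norm$transform)[1:3])), 1)
  ## determinism of the full stage
  norm2 <- normalizeSubject(ph$maps, tpl, levels = c(8, 4),
                            maxit = c(150L, 100L))
  expect_identical(transformParams(norm$transform),
                   transformParams(norm2$transform))
})

test_that("an affinely perturbed phantom normalizes back onto the template", {
  spec <- phantomSpec()
  can <- defaultPhantom()
  tpl <- defaultTemplateCached()
  g <- geometry(can$maps)
  jit <- affineTransform(translation = c(2, -2.3, 1.8),
                         rotation = c(-0.01, -0.003, 0.068),
                         zoom = c(0.989, 0.998, 1.015),
                         shear = c(-0.024, 0.009, -0.006))
  warp <- function(v, interp) applyTransform(v, g, jit, g, interp)
  R1 <- warp(r1Map(can$maps), "trilinear")
  R2 <- warp(r2Map(can$maps), "trilinear")
  PD <- warp(pdMap(can$maps), "trilinear")
  valid <- is.finite(R1) & is.finite(R2) & is.finite(PD) & PD > 1
  R1[!valid] <- NaN; R2[!valid] <- NaN; PD[!valid] <- NaN
  subj <- new("QuantMaps", R1 = R1, R2 = R2, PD = PD, valid = valid,
              fitQuality = array(0, g@dim), geometry = g, pdUnit = "percent")
  norm <- normalizeSubject(subj, tpl)
  interior <- interiorMask(can, 3) & validMask(norm$maps)
  err <- mean(abs(r1Map(norm$maps)[interior] - r1Map(can$maps)[interior]))
  ## below 5% of the WM-CSF R1 contrast (1.38 - 0.38 = 1.0 1/s)
  expect_lt(err, 0.05 * 1.0)
})
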