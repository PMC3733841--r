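## Shared fixtures, built in code and cached for the test run.

.fixtures <- new.env(parent = emptyenv())

cachedFixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

## Small grids: 4 mm for cheap unit tests, 3 mm for the Monte-Carlo cohorts,
## the 2 mm default for registration-scale tests.
tinySpec <- function() phantomSpec(dim = c(24, 28, 22), spacing = 4)
statsSpec <- function() phantomSpec(dim = c(32, 38, 30), spacing = 3)

tinyPhantom <- function() cachedFixture("tinyPhantom",
  function() makePhantom(tinySpec(), vary = FALSE))
tinyTemplate <- function() cachedFixture("tinyTemplate",
  function() defaultTemplate(tinySpec(), targetSpacing = 4))
defaultPhantom <- function() cachedFixture("defaultPhantom",
  function() makePhantom(phantomSpec(), vary = FALSE))
defaultTemplateCached <- function() cachedFixture("defaultTemplateCached",
  function() defaultTemplate())

## Interior tissue mask (brain parenchyma eroded one voxel) for a phantom.
interiorMask <- function(ph, iter = 1L) {
  tissue <- array(ph$labels@labels %in% 1:5, dim(ph$labels@labels))
  qmapnorm:::erode3d(tissue, iter)
}

## Reference atlas of 31 fitted, noise-perturbed subjects on the 3 mm grid,
## shared by the null-calibration and lesion-detection checks.
statsAtlas <- function() cachedFixture("statsAtlas", function() {
  coh <- makeCohort(statsSpec(), cohortSpec(n = 31, noiseSigma = 0.7, seed = 11))
  fitted <- lapply(coh$subjects, function(s)
    fitVolume(s$series, mask = validMask(s$maps)))
  buildReference(fitted)
})

## Independent dense grid-search oracle for the voxel fit: profile M0
## analytically and scan (R1, R2) over a cartesian grid.
gridFitOracle <- function(y, protocol, r1Grid, r2Grid) {
  td <- protocol@saturationDelays * 1e-3
  te <- protocol@echoTimes * 1e-3
  tdv <- rep(td, times = length(te))
  tev <- rep(te, each = length(td))
  A <- 1 - exp(-outer(tdv, r1Grid))      # nObs x nR1
  B <- exp(-outer(tev, r2Grid))          # nObs x nR2
  num <- crossprod(A, y * B)             # nR1 x nR2 : sum_i y_i a_i b_i
  den <- crossprod(A^2, B^2)             # nR1 x nR2 : sum_i a_i^2 b_i^2
  cost <- sum(y^2) - num^2 / den
  ij <- arrayInd(which.min(cost), dim(cost))
  list(R1 = r1Grid[ij[1]], R2 = r2Grid[ij[2]],
       M0 = num[ij] / den[ij], cost = cost[ij])
}

## Sum-of-squares objective of a fit result against a signal vector.
fitObjective <- function(y, protocol, R1, R2, M0) {
  td <- protocol@saturationDelays
  te <- protocol@echoTimes
  mu <- as.vector(outer(td, te, function(d, e) modelSignal(R1, R2, M0, d, e)))
  sum((y - mu)^2)
}

## Noise-free signal vector (delay fastest) for given parameters.
cleanSignal <- function(protocol, R1, R2, M0) {
  as.vector(outer(protocol@saturationDelays, protocol@echoTimes,
                  function(d, e) modelSignal(R1, R2, M0, d, e)))
}
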