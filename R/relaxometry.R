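## Relaxometry: per-voxel estimation of R1, R2 and proton density from a
## multi-delay multi-echo saturation-recovery series.
##
## Signal model (ideal saturation recovery with complete spoiling and
## mono-exponential transverse decay):
##   S(TD, TE) = M0 * (1 - exp(-TD * R1)) * exp(-TE * R2)
## with TD, TE converted from ms to s at the boundary and rates in 1/s.

MS2S <- 1e-3

#' Construct an acquisition protocol
#'
#' @param saturationDelays numeric, saturation delays in ms (strictly
#'   increasing, positive, all below \code{repetitionTime}).
#' @param echoTimes numeric, echo times in ms (strictly increasing, positive).
#' @param repetitionTime repetition time in ms.
#' @return an \linkS4class{AcquisitionProtocol}.
#' @examples
#' defaultProtocol()
#' @export
acquisitionProtocol <- function(saturationDelays, echoTimes, repetitionTime) {
  new("AcquisitionProtocol",
      saturationDelays = as.numeric(saturationDelays),
      echoTimes = as.numeric(echoTimes),
      repetitionTime = as.numeric(repetitionTime))
}

#' @rdname acquisitionProtocol
#' @details \code{defaultProtocol()} returns the 4-delay, 5-echo protocol
#'   (TD = 100, 400, 1380, 2860 ms; TE = 14, 28, 42, 56, 70 ms;
#'   TR = 2950 ms), giving 4 x 5 = 20 images per slice.
#' @export
defaultProtocol <- function() {
  acquisitionProtocol(c(100, 400, 1380, 2860), c(14, 28, 42, 56, 70), 2950)
}

#' Number of images per slice for a protocol
#' @param protocol an \linkS4class{AcquisitionProtocol}.
#' @export
imagesPerSlice <- function(protocol) {
  length(protocol@saturationDelays) * length(protocol@echoTimes)
}

#' Construct an acquisition series
#'
#' @param data 5D array indexed (delay, echo, x, y, z), arbitrary signal
#'   units, finite and nonnegative.
#' @param protocol an \linkS4class{AcquisitionProtocol}.
#' @param geom an \linkS4class{ImageGeometry} for the spatial axes.
#' @export
acquisitionSeries <- function(data, protocol, geom) {
  new("AcquisitionSeries", data = data, protocol = protocol, geometry = geom)
}

#' Saturation-recovery spin-echo signal model
#'
#' Evaluates S = M0 * (1 - exp(-delay * R1)) * exp(-echo * R2). Arguments
#' are recycled; times are in ms, rates in 1/s. The signal is nonnegative,
#' increasing in the saturation delay and decreasing in the echo time.
#'
#' @param R1,R2 relaxation rates in 1/s (nonnegative).
#' @param M0 equilibrium magnetization, arbitrary units.
#' @param delay saturation delay in ms.
#' @param echo echo time in ms.
#' @return signal in the units of \code{M0}.
#' @examples
#' modelSignal(1.38, 11.79, 70, delay = 2860, echo = 14)
#' @export
modelSignal <- function(R1, R2, M0, delay, echo) {
  if (any(R1 < 0) || any(R2 < 0))
    stop("relaxation rates must be nonnegative")
  if (any(!is.finite(R1)) || any(!is.finite(R2)) || any(!is.finite(M0)) ||
      any(!is.finite(delay)) || any(!is.finite(echo)))
    stop("all arguments must be finite")
  if (any(delay < 0) || any(echo < 0))
    stop("delay and echo must be nonnegative")
  M0 * (1 - exp(-delay * MS2S * R1)) * exp(-echo * MS2S * R2)
}

## ---- internal fitting engine -------------------------------------------
## Vectorized variable-projection Levenberg-Marquardt over voxels.
## Y: (nObs x nVox) matrix, observation order = delays fastest (R's natural
## flattening of a (nDelay, nEcho) block). Rates optimized in log space so
## positivity is structural; M0 is profiled out analytically each iteration.
fitEngine <- function(Y, protocol, tol = 1e-8, maxit = 200L) {
  td <- protocol@saturationDelays * MS2S
  te <- protocol@echoTimes * MS2S
  nd <- length(td); ne <- length(te)
  if (nd < 2L || ne < 2L)
    stop("fitting needs at least 2 saturation delays and 2 echoes")
  tdv <- rep(td, times = ne)          # per-observation delay (s)
  tev <- rep(te, each = nd)           # per-observation echo (s)
  nVox <- ncol(Y)

  out <- list(R1 = rep(NaN, nVox), R2 = rep(NaN, nVox), M0 = rep(NaN, nVox),
              residual = rep(NaN, nVox), code = rep(1L, nVox))
  ok <- apply(is.finite(Y), 2L, all) & colSums(Y) > 0
  if (!any(ok)) return(out)
  Y <- Y[, ok, drop = FALSE]
  n <- ncol(Y)
  eps <- pmax(apply(Y, 2L, max) * 1e-9, .Machine$double.xmin)

  ## R2 init: log-linear regression over echoes at the longest delay.
  lastDelay <- which(tdv == td[nd])
  ly <- log(pmax(Y[lastDelay, , drop = FALSE], rep(eps, each = length(lastDelay))))
  teL <- tev[lastDelay]
  slope <- colSums((teL - mean(teL)) * t(t(ly) - colMeans(ly))) /
    sum((teL - mean(teL))^2)
  R2 <- pmin(pmax(-slope, 0.1), 60)

  ## R1 init: echo-collapsed recovery amplitudes at first/last delay, then a
  ## few Newton steps on the two-point recovery ratio.
  decay <- exp(-outer(tev, R2))
  Aamp <- matrix(0, nd, n)
  for (d in seq_len(nd)) {
    rows <- which(tdv == td[d])
    Aamp[d, ] <- colSums(Y[rows, , drop = FALSE] * decay[rows, , drop = FALSE]) /
      colSums(decay[rows, , drop = FALSE]^2)
  }
  ratio <- pmin(pmax(Aamp[1, ] / pmax(Aamp[nd, ], eps), 1e-4), 1 - 1e-4)
  R1 <- rep(1, n)
  for (it in 1:12) {
    e1 <- exp(-td[1] * R1); eN <- exp(-td[nd] * R1)
    f <- (1 - e1) - ratio * (1 - eN)
    fp <- td[1] * e1 - ratio * td[nd] * eN
    step <- f / ifelse(abs(fp) > 1e-12, fp, 1e-12)
    R1 <- pmin(pmax(R1 - step, 0.02), 20)
  }

  p1 <- log(R1); p2 <- log(R2)
  lambda <- rep(1e-3, n)
  code <- rep(2L, n)

  evalCost <- function(p1, p2, idx) {
    A <- 1 - exp(-outer(tdv, exp(p1)))
    B <- exp(-outer(tev, exp(p2)))
    W <- A * B
    M0 <- colSums(Y[, idx, drop = FALSE] * W) / pmax(colSums(W * W), 1e-300)
    R <- Y[, idx, drop = FALSE] - rep(M0, each = nrow(Y)) * W
    list(cost = colSums(R * R), M0 = M0, A = A, B = B, W = W, R = R)
  }

  act <- seq_len(n)
  st <- evalCost(p1, p2, act)
  cost <- st$cost
  M0 <- st$M0
  for (iter in seq_len(maxit)) {
    na <- length(act)
    if (na == 0L) break
    A <- st$A; B <- st$B; R <- st$R
    M0a <- st$M0
    r1a <- exp(p1[act]); r2a <- exp(p2[act])
    ## Jacobian wrt log-rates
    J1 <- rep(M0a, each = nrow(Y)) * (tdv * exp(-outer(tdv, r1a))) * B *
      rep(r1a, each = nrow(Y))
    J2 <- -rep(M0a, each = nrow(Y)) * tev * A * B * rep(r2a, each = nrow(Y))
    g1 <- colSums(J1 * R); g2 <- colSums(J2 * R)
    H11 <- colSums(J1 * J1); H12 <- colSums(J1 * J2); H22 <- colSums(J2 * J2)
    lam <- lambda[act]
    A11 <- H11 * (1 + lam) + 1e-300; A22 <- H22 * (1 + lam) + 1e-300
    det <- A11 * A22 - H12 * H12
    d1 <- (A22 * g1 - H12 * g2) / det
    d2 <- (A11 * g2 - H12 * g1) / det
    d1[!is.finite(d1)] <- 0; d2[!is.finite(d2)] <- 0
    q1 <- pmin(pmax(p1[act] + d1, log(1e-3)), log(1e3))
    q2 <- pmin(pmax(p2[act] + d2, log(1e-3)), log(1e3))
    trial <- evalCost(q1, q2, act)
    better <- trial$cost <= cost[act] * (1 + 1e-14)
    ## accept / reject per voxel
    p1[act[better]] <- q1[better]
    p2[act[better]] <- q2[better]
    cost[act[better]] <- trial$cost[better]
    M0[act[better]] <- trial$M0[better]
    lambda[act[better]] <- pmax(lambda[act[better]] / 10, 1e-12)
    lambda[act[!better]] <- pmin(lambda[act[!better]] * 10, 1e12)
    conv <- better & pmax(abs(d1), abs(d2)) < tol
    code[act[conv]] <- 0L
    act <- act[!conv]
    if (length(act) > 0L) st <- evalCost(p1[act], p2[act], act)
  }

  R1f <- exp(p1); R2f <- exp(p2)
  res <- rep(NaN, n)
  pos <- M0 > 0
  res[pos] <- sqrt(cost[pos] / nrow(Y)) / M0[pos]
  out$R1[ok] <- R1f; out$R2[ok] <- R2f; out$M0[ok] <- M0
  out$residual[ok] <- res
  out$code[ok] <- code
  out
}

#' Fit one voxel's signal matrix
#'
#' Nonlinear least squares of the saturation-recovery spin-echo model against
#' a (delay x echo) signal matrix. Rates are optimized in log space (so the
#' fit is positivity-constrained by construction) with the equilibrium
#' magnetization profiled out analytically; initialization is deterministic
#' (log-linear R2 from the longest delay's echo train, two-point recovery
#' ratio for R1), convergence at 1e-8 relative parameter change, at most 200
#' iterations.
#'
#' @param signals numeric matrix (nDelays x nEchoes).
#' @param protocol an \linkS4class{AcquisitionProtocol} matching the matrix.
#' @return list with \code{R1}, \code{R2} (1/s), \code{M0} (signal units),
#'   \code{residual} (RMS misfit / M0), \code{converged}, and \code{code}
#'   (0 = converged, 1 = unusable input, 2 = iteration limit). Unusable
#'   voxels yield NaN parameters, not an error.
#' @examples
#' pr <- defaultProtocol()
#' S <- outer(pr@saturationDelays, pr@echoTimes,
#'            function(d, e) modelSignal(1, 10, 1000, d, e))
#' fitVoxel(S, pr)[c("R1", "R2", "M0")]
#' @export
fitVoxel <- function(signals, protocol) {
  signals <- as.matrix(signals)
  if (nrow(signals) != length(protocol@saturationDelays) ||
      ncol(signals) != length(protocol@echoTimes))
    stop("signal matrix extents do not match the protocol")
  f <- fitEngine(matrix(as.vector(signals), ncol = 1L), protocol)
  list(R1 = f$R1[1], R2 = f$R2[1], M0 = f$M0[1], residual = f$residual[1],
       converged = f$code[1] == 0L, code = f$code[1])
}

#' Fit quantitative maps for a whole acquisition series
#'
#' Applies the voxelwise saturation-recovery fit to every voxel of a series
#' (optionally restricted to a mask). Voxels outside the mask, or with
#' unusable signal, carry NaN in all maps and FALSE in the validity mask.
#' The returned PD is in raw M0 units until \code{\link{calibratePD}} is
#' applied. Deterministic: identical inputs give identical maps.
#'
#' @param series an \linkS4class{AcquisitionSeries}.
#' @param mask optional logical array on the series grid.
#' @return a \linkS4class{QuantMaps}.
#' @export
fitVolume <- function(series, mask = NULL) {
  d <- dim(series@data)
  geom <- series@geometry
  nObs <- d[1] * d[2]
  nVox <- prod(d[3:5])
  Y <- series@data
  dim(Y) <- c(nObs, nVox)
  if (!is.null(mask)) {
    if (!all(dim(mask) == geom@dim))
      stop("mask is not on the series grid")
    sel <- which(as.logical(mask))
  } else sel <- seq_len(nVox)
  f <- fitEngine(Y[, sel, drop = FALSE], series@protocol)
  mk <- function(vals) {
    a <- array(NaN, geom@dim)
    a[sel] <- vals
    a
  }
  valid <- array(FALSE, geom@dim)
  valid[sel] <- f$code != 1L
  new("QuantMaps", R1 = mk(f$R1), R2 = mk(f$R2), PD = mk(f$M0),
      valid = valid, fitQuality = mk(f$residual), geometry = geom,
      pdUnit = "arbitrary")
}

#' Calibrate proton density to percent of pure water
#'
#' Rescales the PD volume so that the median M0 within a free-water-like
#' reference region (typically ventricular CSF) maps to 100%. R1 and R2 are
#' untouched. Applying the calibration twice with the same mask is the
#' identity, and PD ratios between voxels are preserved.
#'
#' @param maps a \linkS4class{QuantMaps}.
#' @param waterReferenceMask logical array on the maps' grid, nonempty.
#' @return the calibrated \linkS4class{QuantMaps} (\code{pdUnit = "percent"}).
#' @export
calibratePD <- function(maps, waterReferenceMask) {
  if (!all(dim(waterReferenceMask) == maps@geometry@dim))
    stop("reference mask is not on the maps' grid")
  sel <- as.logical(waterReferenceMask) & maps@valid
  if (!any(sel)) stop("water reference mask is empty")
  med <- stats::median(maps@PD[sel], na.rm = TRUE)
  if (!is.finite(med) || med <= 0)
    stop("reference median PD is not positive")
  maps@PD <- maps@PD * (100 / med)
  maps@pdUnit <- "percent"
  maps
}
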