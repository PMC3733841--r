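## Internal helpers shared across modules: small image-processing primitives
## (Otsu threshold, shift-based morphology, 3D connected components) and
## seed-scoped RNG evaluation.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's
## RNG state afterwards. All package randomness flows through this.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Derive a reproducible child seed from a master seed; kept within 32-bit
## integer range.
childSeed <- function(seed, i) {
  as.integer((as.double(seed) * 1000003 + i * 7919) %% 2147483587L)
}

## Otsu's histogram threshold on a numeric vector/array (arbitrary scale).
otsuThreshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no finite values for threshold estimation")
  r <- range(x)
  if (r[1] == r[2]) stop("constant image: cannot derive a foreground threshold")
  h <- tabulate(pmin(nbins, 1L + as.integer((x - r[1]) / (r[2] - r[1]) * nbins)),
                nbins)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(nbins) - 0.5) * (r[2] - r[1]) / nbins
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[nbins]
  sigmaB <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  sigmaB[!is.finite(sigmaB)] <- -Inf
  mids[which.max(sigmaB)]
}

## Shift a 3D array by one voxel along axis `ax` in direction `dir` (+1/-1),
## replicating the edge (used by morphology and component propagation).
shiftArray <- function(x, ax, dir) {
  d <- dim(x)
  idx <- lapply(d, seq_len)
  i <- idx[[ax]]
  idx[[ax]] <- if (dir > 0) pmax(i - 1L, 1L) else pmin(i + 1L, d[ax])
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

## 6-neighbourhood binary dilation / erosion, `iter` passes.
dilate3d <- function(mask, iter = 1L) {
  for (k in seq_len(iter)) {
    out <- mask
    for (ax in 1:3) for (dir in c(-1L, 1L))
      out <- out | shiftArray(mask, ax, dir)
    mask <- out
  }
  mask
}

erode3d <- function(mask, iter = 1L) {
  for (k in seq_len(iter)) {
    out <- mask
    for (ax in 1:3) for (dir in c(-1L, 1L))
      out <- out & shiftArray(mask, ax, dir)
    mask <- out
  }
  mask
}

closing3d <- function(mask, iter = 1L) erode3d(dilate3d(mask, iter), iter)

## Largest 6-connected component of a binary 3D mask, found by vectorized
## frontier propagation (BFS via dilation restricted to the unvisited mask).
largestComponent <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  remaining <- mask
  best <- NULL
  bestSize <- 0L
  while (any(remaining)) {
    seedIdx <- which(remaining)[1L]
    comp <- array(FALSE, dim(mask))
    comp[seedIdx] <- TRUE
    repeat {
      grown <- dilate3d(comp) & remaining
      if (sum(grown) == sum(comp)) break
      comp <- grown
    }
    sz <- sum(comp)
    if (sz > bestSize) { best <- comp; bestSize <- sz }
    remaining <- remaining & !comp
  }
  if (is.null(best)) stop("empty mask: no connected component")
  best
}

## Sample quantile-free robust scale guard used for cov epsilon.
finiteMedian <- function(x) stats::median(x[is.finite(x)])

assertScalarNumeric <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a finite scalar in [%g, %g]", name, lower, upper))
  invisible(x)
}
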