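## 12-parameter affine registration by sum-of-squared-differences (SSD)
## minimization, plus resampling onto template grids.
##
## Parameter convention (fixed for reproducibility and recorded in transform
## files): matrix = Translation %*% Rz %*% Ry %*% Rx %*% Shear %*% Zoom,
## acting on world (mm, RAS) coordinates; voxel indices 0-based; grids
## half-open. A transform maps SOURCE world coordinates to TARGET world
## coordinates; resampling onto the target grid pulls values back through
## its inverse.

TRANSFORM_CONVENTION <-
  "world-mm-RAS; matrix = T * Rz * Ry * Rx * Shear * Zoom; voxel 0-based"

paramNames <- c("tx", "ty", "tz", "rx", "ry", "rz",
                "zx", "zy", "zz", "sxy", "sxz", "syz")

rotX <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3)
rotY <- function(b) matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3)
rotZ <- function(c) matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3)
shearMat <- function(s) matrix(c(1, 0, 0, s[1], 1, 0, s[2], s[3], 1), 3)

composeAffineMatrix <- function(p) {
  A3 <- rotZ(p[6]) %*% rotY(p[5]) %*% rotX(p[4]) %*%
    shearMat(p[10:12]) %*% diag(p[7:9])
  M <- diag(4)
  M[1:3, 1:3] <- A3
  M[1:3, 4] <- p[1:3]
  M
}

## Analytic derivative of the 4x4 matrix wrt parameter k (used by the
## registration gradient).
dRotX <- function(a) matrix(c(0, 0, 0, 0, -sin(a), cos(a), 0, -cos(a), -sin(a)), 3)
dRotY <- function(b) matrix(c(-sin(b), 0, -cos(b), 0, 0, 0, cos(b), 0, -sin(b)), 3)
dRotZ <- function(c) matrix(c(-sin(c), cos(c), 0, -cos(c), -sin(c), 0, 0, 0, 0), 3)

affineMatrixDeriv <- function(p, k) {
  D <- matrix(0, 4, 4)
  if (k <= 3L) { D[k, 4] <- 1; return(D) }
  Rx <- rotX(p[4]); Ry <- rotY(p[5]); Rz <- rotZ(p[6])
  Sh <- shearMat(p[10:12]); Z <- diag(p[7:9])
  D3 <- switch(as.character(k),
    "4" = Rz %*% Ry %*% dRotX(p[4]) %*% Sh %*% Z,
    "5" = Rz %*% dRotY(p[5]) %*% Rx %*% Sh %*% Z,
    "6" = dRotZ(p[6]) %*% Ry %*% Rx %*% Sh %*% Z,
    "7" = , "8" = , "9" = {
      dZ <- matrix(0, 3, 3); dZ[k - 6L, k - 6L] <- 1
      Rz %*% Ry %*% Rx %*% Sh %*% dZ
    },
    "10" = , "11" = , "12" = {
      dS <- matrix(0, 3, 3)
      ij <- list(c(1, 2), c(1, 3), c(2, 3))[[k - 9L]]
      dS[ij[1], ij[2]] <- 1
      Rz %*% Ry %*% Rx %*% dS %*% Z
    })
  D[1:3, 1:3] <- D3
  D
}

#' Construct a 12-parameter affine transform
#'
#' @param translation numeric(3), mm.
#' @param rotation numeric(3), radians (applied as Rz, Ry, Rx).
#' @param zoom numeric(3), unitless scale factors (> 0).
#' @param shear numeric(3), unitless (xy, xz, yz upper-triangular entries).
#' @return an \linkS4class{AffineTransform}.
#' @examples
#' t <- affineTransform(translation = c(4, 0, 0), rotation = c(0, 0, 0.1))
#' transformMatrix(t)
#' @export
affineTransform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                            zoom = c(1, 1, 1), shear = c(0, 0, 0)) {
  p <- as.numeric(c(translation, rotation, zoom, shear))
  names(p) <- paramNames
  new("AffineTransform", params = p, matrix = composeAffineMatrix(p))
}

#' @rdname affineTransform
#' @export
identityTransform <- function() affineTransform()

#' Recover the 12 parameters from a 4x4 affine matrix
#'
#' Decomposes the 3x3 block as rotation times an upper-triangular
#' shear-and-zoom factor (QR with positive diagonal), then extracts the
#' z-y-x Euler angles. Round-tripping params -> matrix -> params is identity
#' to 1e-9 for non-degenerate transforms.
#'
#' @param M 4x4 homogeneous matrix with positive-determinant 3x3 block.
#' @return an \linkS4class{AffineTransform}.
#' @export
affineFromMatrix <- function(M) {
  A <- M[1:3, 1:3]
  if (abs(det(A)) < 1e-12) stop("singular matrix")
  if (det(A) < 0) stop("reflections are not representable (negative determinant)")
  qrd <- qr(A)
  Q <- qr.Q(qrd); U <- qr.R(qrd)
  s <- sign(diag(U)); s[s == 0] <- 1
  Q <- Q %*% diag(s); U <- diag(s) %*% U
  zoom <- diag(U)
  Sh <- U %*% diag(1 / zoom)
  ry <- asin(max(-1, min(1, -Q[3, 1])))
  rx <- atan2(Q[3, 2], Q[3, 3])
  rz <- atan2(Q[2, 1], Q[1, 1])
  affineTransform(translation = M[1:3, 4], rotation = c(rx, ry, rz),
                  zoom = zoom, shear = c(Sh[1, 2], Sh[1, 3], Sh[2, 3]))
}

#' Invert and compose affine transforms
#'
#' \code{composeTransforms(a, b)} applies \code{b} first:
#' \code{compose(a, b)(x) = a(b(x))}. \code{invertTransform(t)} satisfies
#' \code{compose(invert(t), t) = identity} to 1e-9.
#'
#' @param transform,a,b \linkS4class{AffineTransform} objects.
#' @export
invertTransform <- function(transform) {
  affineFromMatrix(solve(transform@matrix))
}

#' @rdname invertTransform
#' @export
composeTransforms <- function(a, b) {
  affineFromMatrix(a@matrix %*% b@matrix)
}

#' Apply a transform to world-space points
#' @param transform an \linkS4class{AffineTransform}.
#' @param points 3 x n matrix of world coordinates (mm).
#' @export
transformPoints <- function(transform, points) {
  (transform@matrix[1:3, 1:3] %*% points) + transform@matrix[1:3, 4]
}

#' Construct a template space
#'
#' @param volume 3D template array (finite, nonnegative).
#' @param geom its \linkS4class{ImageGeometry}.
#' @param targetSpacing isotropic output grid spacing in mm (default 2).
#' @export
templateSpace <- function(volume, geom, targetSpacing = 2) {
  if (length(targetSpacing) == 1L) targetSpacing <- rep(targetSpacing, 3L)
  new("TemplateSpace", volume = volume, geometry = geom,
      targetSpacing = as.numeric(targetSpacing))
}

## ---- sampling ----------------------------------------------------------

## Trilinear sampling of one or more volumes (shared weights) at continuous
## 0-based voxel coordinates V (3 x N). oob: "nan" flags out-of-field
## samples NaN; "clamp" replicates the edge.
sampleTrilinear <- function(vols, dims, V, oob = c("nan", "clamp")) {
  oob <- match.arg(oob)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  bad <- V[1, ] < -1e-6 | V[1, ] > nx - 1 + 1e-6 |
         V[2, ] < -1e-6 | V[2, ] > ny - 1 + 1e-6 |
         V[3, ] < -1e-6 | V[3, ] > nz - 1 + 1e-6
  x <- pmin(pmax(V[1, ], 0), nx - 1)
  y <- pmin(pmax(V[2, ], 0), ny - 1)
  z <- pmin(pmax(V[3, ], 0), nz - 1)
  x0 <- pmin(floor(x), nx - 2); y0 <- pmin(floor(y), ny - 2)
  z0 <- pmin(floor(z), nz - 2)
  if (nx < 2 || ny < 2 || nz < 2) stop("volume too small to interpolate")
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  base <- 1 + x0 + nx * (y0 + ny * z0)
  offs <- c(0, 1, nx, nx + 1, nx * ny, nx * ny + 1, nx * ny + nx, nx * ny + nx + 1)
  w <- list((1 - fx) * (1 - fy) * (1 - fz), fx * (1 - fy) * (1 - fz),
            (1 - fx) * fy * (1 - fz), fx * fy * (1 - fz),
            (1 - fx) * (1 - fy) * fz, fx * (1 - fy) * fz,
            (1 - fx) * fy * fz, fx * fy * fz)
  single <- !is.list(vols)
  if (single) vols <- list(vols)
  out <- lapply(vols, function(v) {
    acc <- 0
    for (c8 in 1:8) acc <- acc + w[[c8]] * v[base + offs[c8]]
    if (oob == "nan") acc[bad] <- NaN
    acc
  })
  if (single) out[[1]] else out
}

sampleNearest <- function(vol, dims, V, oob = c("nan", "clamp")) {
  oob <- match.arg(oob)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  bad <- V[1, ] < -0.5 | V[1, ] > nx - 0.5 |
         V[2, ] < -0.5 | V[2, ] > ny - 0.5 |
         V[3, ] < -0.5 | V[3, ] > nz - 0.5
  i <- pmin(pmax(round(V[1, ]), 0), nx - 1)
  j <- pmin(pmax(round(V[2, ]), 0), ny - 1)
  k <- pmin(pmax(round(V[3, ]), 0), nz - 1)
  out <- vol[1 + i + nx * (j + ny * k)]
  if (oob == "nan") out[bad] <- NaN
  out
}

#' Resample a volume through an affine transform onto a target grid
#'
#' The transform maps source world coordinates to target world coordinates;
#' each target voxel is pulled back through its inverse and interpolated in
#' the source. Target voxels mapping outside the source field of view are
#' set to NaN (the package's sentinel). Use trilinear interpolation for
#' continuous maps and nearest-neighbour for masks and labels.
#'
#' @param volume 3D numeric array.
#' @param geom the source \linkS4class{ImageGeometry}.
#' @param transform an \linkS4class{AffineTransform} (source -> target world).
#' @param target a \linkS4class{TemplateSpace} or \linkS4class{ImageGeometry}
#'   defining the output grid.
#' @param interpolation \code{"trilinear"} or \code{"nearest"}.
#' @return 3D array on the target grid.
#' @export
applyTransform <- function(volume, geom, transform, target,
                           interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  tgtGeom <- if (is(target, "TemplateSpace")) target@geometry else target
  if (!is(tgtGeom, "ImageGeometry")) stop("'target' must define a grid")
  P <- solve(geom@affine) %*% solve(transform@matrix) %*% tgtGeom@affine
  G <- voxelGrid(tgtGeom@dim)
  V <- (P[1:3, 1:3] %*% G) + P[1:3, 4]
  vals <- if (interpolation == "trilinear")
    sampleTrilinear(volume, geom@dim, V, oob = "nan")
  else sampleNearest(volume, geom@dim, V, oob = "nan")
  array(vals, tgtGeom@dim)
}

## ---- multiresolution SSD estimation ------------------------------------

## Axis-aligned grid with spacing s covering the world bounding box of a
## geometry (used to build pyramid levels).
levelGeometry <- function(geom, s) {
  corners <- as.matrix(expand.grid(c(0, geom@dim[1] - 1),
                                   c(0, geom@dim[2] - 1),
                                   c(0, geom@dim[3] - 1)))
  w <- voxelToWorld(geom, t(corners))
  lo <- apply(w, 1, min); hi <- apply(w, 1, max)
  dims <- pmax(2L, as.integer(floor((hi - lo) / s)) + 1L)
  ## centre the level grid on the world bounding box
  orig <- (lo + hi) / 2 - s * (dims - 1) / 2
  makeGeometry(dims, s, origin = orig)
}

makePyramidLevel <- function(vol, geom, s) {
  fw <- sqrt(max(s^2 - min(geom@spacing)^2, 0))
  sm <- gaussianSmooth(vol, fw, geom)
  lg <- levelGeometry(geom, s)
  lv <- applyTransform(sm, geom, identityTransform(), lg, "trilinear")
  lv[!is.finite(lv)] <- 0
  list(vol = lv, geom = lg)
}

standardizeLevel <- function(vol) {
  thr <- otsuThreshold(vol)
  fg <- vol > thr
  fg <- dilate3d(fg, 2L)
  mu <- mean(vol[fg]); sdv <- stats::sd(vol[fg])
  if (!is.finite(sdv) || sdv == 0) stop("degenerate (constant) image")
  list(z = (vol - mu) / sdv, mask = fg)
}

## Fused SSD cost and analytic gradient at one pyramid level.
levelObjective <- function(p, ctx, wantGrad = FALSE) {
  M <- composeAffineMatrix(p)
  Minv <- solve(M)
  Pm <- ctx$srcInv %*% Minv %*% ctx$tgtAff
  V <- Pm[1:3, ] %*% ctx$X
  if (!wantGrad) {
    sv <- sampleTrilinear(ctx$srcZ, ctx$srcDim, V, oob = "clamp")
    r <- sv - ctx$tz
    return(list(cost = mean(r * r)))
  }
  sm <- sampleTrilinear(list(ctx$srcZ, ctx$gx, ctx$gy, ctx$gz),
                        ctx$srcDim, V, oob = "clamp")
  r <- sm[[1]] - ctx$tz
  gmat <- rbind(sm[[2]], sm[[3]], sm[[4]])
  grad <- numeric(12)
  for (k in 1:12) {
    Ck <- -(ctx$srcInv %*% Minv %*% affineMatrixDeriv(p, k) %*% Minv %*%
              ctx$tgtAff)
    dV <- Ck[1:3, ] %*% ctx$X
    grad[k] <- 2 * mean(r * colSums(gmat * dV))
  }
  list(cost = mean(r * r), grad = grad)
}

centralDiffGradients <- function(vol) {
  d <- dim(vol)
  g <- lapply(1:3, function(ax)
    (shiftArray(vol, ax, -1) - shiftArray(vol, ax, 1)) / 2)
  names(g) <- c("gx", "gy", "gz")
  g
}

#' Estimate the affine transform from a source image to a template
#'
#' Minimizes the masked sum of squared differences between the
#' intensity-standardized source (resampled through the transform) and
#' template over a multiresolution pyramid (8, 4, 2 mm by default), using
#' BFGS with an analytic gradient. Both images are standardized to zero
#' mean / unit variance within an Otsu-derived foreground mask, so arbitrary
#' signal units on either side are acceptable. Initialization is the
#' identity plus a center-of-mass translation (or \code{init}); the whole
#' procedure is deterministic — no random restarts.
#'
#' Both images should already carry comparable smoothing (the pipeline
#' smooths the synthetic source and the template with the same 8 mm kernel
#' before calling this).
#'
#' @param source 3D array (e.g. a smoothed synthetic T2-weighted image).
#' @param sourceGeom its \linkS4class{ImageGeometry}.
#' @param template 3D template array.
#' @param templateGeom its \linkS4class{ImageGeometry}.
#' @param init optional \linkS4class{AffineTransform} initial guess
#'   (source world -> template world).
#' @param levels pyramid level spacings in mm, coarse to fine.
#' @param maxit iterations per level (recycled).
#' @return a list: \code{transform} (the estimated
#'   \linkS4class{AffineTransform}), \code{cost} (final mean squared
#'   difference on the finest level), \code{initialCost} (same objective at
#'   the initialization).
#' @export
estimateAffine <- function(source, sourceGeom, template, templateGeom,
                           init = NULL, levels = c(8, 4, 2),
                           maxit = c(150L, 100L, 40L)) {
  if (length(unique(as.vector(source))) < 2L ||
      length(unique(as.vector(template))) < 2L)
    stop("degenerate (constant) source or template")
  maxit <- rep_len(as.integer(maxit), length(levels))

  if (is.null(init)) {
    sStd0 <- standardizeLevel(source)
    tStd0 <- standardizeLevel(template)
    comOf <- function(vol, geom, mask) {
      wts <- pmax(vol, 0) * mask
      wg <- worldGrid(geom)
      (wg %*% as.vector(wts)) / sum(wts)
    }
    t0 <- comOf(template, templateGeom, tStd0$mask) -
      comOf(source, sourceGeom, sStd0$mask)
    p <- affineTransform(translation = as.vector(t0))@params
  } else p <- init@params

  pscale <- c(rep(2, 3), rep(0.02, 3), rep(0.02, 3), rep(0.02, 3))
  finalCost <- NA_real_
  initialCost <- NA_real_
  pInit <- p
  for (li in seq_along(levels)) {
    s <- levels[li]
    srcL <- makePyramidLevel(source, sourceGeom, s)
    tplL <- makePyramidLevel(template, templateGeom, s)
    tStd <- standardizeLevel(tplL$vol)
    sStd <- standardizeLevel(srcL$vol)
    gr3 <- centralDiffGradients(sStd$z)
    sel <- which(tStd$mask)
    G <- voxelGrid(tplL$geom@dim)[, sel, drop = FALSE]
    ctx <- list(srcZ = sStd$z, srcDim = srcL$geom@dim,
                srcInv = solve(srcL$geom@affine),
                tgtAff = tplL$geom@affine,
                X = rbind(G, 1), tz = tStd$z[sel],
                gx = gr3$gx, gy = gr3$gy, gz = gr3$gz)
    cache <- new.env(parent = emptyenv())
    fn <- function(par) {
      o <- levelObjective(par, ctx, wantGrad = TRUE)
      assign("last", list(par = par, o = o), envir = cache)
      o$cost
    }
    gr <- function(par) {
      l <- if (exists("last", envir = cache)) get("last", envir = cache) else NULL
      if (!is.null(l) && all(l$par == par)) return(l$o$grad)
      levelObjective(par, ctx, wantGrad = TRUE)$grad
    }
    opt <- stats::optim(p, fn, gr, method = "BFGS",
                        control = list(parscale = pscale, maxit = maxit[li],
                                       reltol = 1e-10))
    if (opt$value <= fn(p)) p <- opt$par
    if (li == length(levels)) {
      finalCost <- levelObjective(p, ctx)$cost
      initialCost <- levelObjective(pInit, ctx)$cost
      if (initialCost < finalCost) {   # deterministic safeguard
        p <- pInit
        finalCost <- initialCost
      }
    }
  }
  names(p) <- paramNames
  list(transform = new("AffineTransform", params = p,
                       matrix = composeAffineMatrix(p)),
       cost = finalCost, initialCost = initialCost)
}

#' Spatially normalize quantitative maps to a template
#'
#' The full normalization stage: synthesize a T2-weighted image from the
#' maps (TE = 100 ms / TR = 4500 ms by default), smooth it and the template
#' with the same Gaussian kernel (8 mm by default), estimate the affine
#' transform by SSD minimization, then apply that single transform to the
#' R1, R2 and PD maps with trilinear interpolation (the validity mask with
#' nearest-neighbour) and re-grid to the template's isotropic target grid
#' (2 mm by default).
#'
#' @param maps a fitted \linkS4class{QuantMaps}.
#' @param template a \linkS4class{TemplateSpace}.
#' @param fwhm smoothing kernel for the registration pair, mm.
#' @param settings \code{ContrastSettings} for the synthetic source image.
#' @param init,levels,maxit passed to \code{\link{estimateAffine}}.
#' @return list: \code{maps} (normalized \linkS4class{QuantMaps} on the
#'   target grid), \code{transform}, \code{cost}, \code{initialCost}.
#' @export
normalizeSubject <- function(maps, template, fwhm = 8,
                             settings = t2wSettings(), init = NULL,
                             levels = c(8, 4, 2), maxit = c(150L, 100L, 40L)) {
  synth <- synthesize(maps, settings)
  synthSm <- gaussianSmooth(synth, fwhm, maps@geometry)
  tplSm <- gaussianSmooth(template@volume, fwhm, template@geometry)
  est <- estimateAffine(synthSm, maps@geometry, tplSm, template@geometry,
                        init = init, levels = levels, maxit = maxit)
  tgtGeom <- if (all(abs(template@geometry@spacing - template@targetSpacing) <
                     1e-9)) template@geometry
  else levelGeometry(template@geometry, template@targetSpacing[1])
  warp <- function(v, interp) applyTransform(v, maps@geometry, est$transform,
                                             tgtGeom, interp)
  ## invalid voxels are zero-filled for interpolation so the NaN sentinel
  ## does not erode the brain rim; validity is decided by the
  ## nearest-neighbour mask below (edge voxels then carry the same
  ## partial-volume dilution for every subject)
  fill0 <- function(v) { v[!maps@valid | !is.finite(v)] <- 0; v }
  R1 <- warp(fill0(maps@R1), "trilinear")
  R2 <- warp(fill0(maps@R2), "trilinear")
  PD <- warp(fill0(maps@PD), "trilinear")
  fq <- warp(fill0(maps@fitQuality), "trilinear")
  vn <- warp(array(as.numeric(maps@valid), maps@geometry@dim), "nearest")
  valid <- !is.na(vn) & vn > 0.5 & is.finite(R1) & is.finite(R2) & is.finite(PD)
  R1[!valid] <- NaN; R2[!valid] <- NaN; PD[!valid] <- NaN; fq[!valid] <- NaN
  out <- new("QuantMaps", R1 = R1, R2 = R2, PD = PD, valid = valid,
             fitQuality = fq, geometry = tgtGeom, pdUnit = maps@pdUnit)
  list(maps = out, transform = est$transform, cost = est$cost,
       initialCost = est$initialCost)
}
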