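## Voxel-grid geometry: constructors and coordinate mappings.

#' Construct an axis-aligned image geometry
#'
#' Builds an \linkS4class{ImageGeometry} with the world origin either at the
#' volume centre (the package's convention for phantom and template grids,
#' which keeps rotations and zooms well-conditioned about the head centre) or
#' at the first voxel.
#'
#' @param dim integer(3), grid extents.
#' @param spacing numeric(3) or scalar, voxel size in mm.
#' @param origin \code{"center"} or numeric(3): world coordinates of voxel
#'   (0,0,0).
#' @return an \linkS4class{ImageGeometry}.
#' @examples
#' g <- makeGeometry(c(10, 12, 8), 2)
#' voxelToWorld(g, cbind(c(0, 0, 0)))
#' @export
makeGeometry <- function(dim, spacing, origin = "center") {
  dim <- as.integer(dim)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  aff <- diag(c(spacing, 1))
  if (identical(origin, "center")) {
    aff[1:3, 4] <- -spacing * (dim - 1) / 2
  } else {
    aff[1:3, 4] <- as.numeric(origin)
  }
  new("ImageGeometry", affine = aff, dim = dim, spacing = as.numeric(spacing))
}

#' @rdname makeGeometry
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices).
#' @export
geometryFromAffine <- function(affine, dim) {
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  new("ImageGeometry", affine = affine, dim = as.integer(dim),
      spacing = spacing)
}

#' Map voxel indices to world coordinates (and back)
#'
#' @param geom an \linkS4class{ImageGeometry}.
#' @param vox,world 3 x n matrices of 0-based voxel indices / world mm.
#' @return a 3 x n matrix.
#' @export
voxelToWorld <- function(geom, vox) {
  (geom@affine[1:3, 1:3] %*% vox) + geom@affine[1:3, 4]
}

#' @rdname voxelToWorld
#' @export
worldToVoxel <- function(geom, world) {
  inv <- solve(geom@affine)
  (inv[1:3, 1:3] %*% world) + inv[1:3, 4]
}

## Strict grid-identity check used wherever two volumes must share a grid.
sameGrid <- function(a, b, tol = 1e-6) {
  all(a@dim == b@dim) && all(abs(a@affine - b@affine) < tol)
}

stopIfGridMismatch <- function(a, b, what = "volumes") {
  if (!sameGrid(a, b))
    stop(sprintf("%s are not on the same voxel grid", what))
  invisible(TRUE)
}

## 3 x N matrix of all 0-based voxel indices of a grid (x fastest).
voxelGrid <- function(dim) {
  rbind(rep(seq_len(dim[1]) - 1, times = dim[2] * dim[3]),
        rep(rep(seq_len(dim[2]) - 1, each = dim[1]), times = dim[3]),
        rep(seq_len(dim[3]) - 1, each = dim[1] * dim[2]))
}

## World coordinates (3 x N) of every voxel of a geometry.
worldGrid <- function(geom) voxelToWorld(geom, voxelGrid(geom@dim))
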