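## Voxelwise normative reference maps over a cohort of normalized maps.

#' Build a voxelwise reference atlas from normalized cohort maps
#'
#' Computes, for each parameter (R1, R2, PD) and each voxel, the sample mean
#' and sample standard deviation (n - 1 denominator) over the subjects whose
#' validity mask covers that voxel, plus the coefficient of variation
#' CoV = sd/mean. The per-voxel count of contributing subjects is recorded;
#' voxels covered by fewer than 2 subjects carry NaN statistics. The CoV is
#' set to NaN (sentinel) wherever the mean is below 1% of the parameter's
#' cohort-median in-brain value, so background voxels cannot produce
#' exploding ratios; values are never clipped in the data.
#'
#' The n - 1 denominator matches the t-distribution machinery used for
#' deviation thresholds (df = n - 1).
#'
#' @param subjects list of \linkS4class{QuantMaps}, all on one template grid.
#' @return a \linkS4class{ReferenceAtlas}.
#' @examples
#' g <- makeGeometry(c(4, 4, 4), 2)
#' mk <- function(v) new("QuantMaps", R1 = array(v, c(4,4,4)),
#'   R2 = array(10, c(4,4,4)), PD = array(70, c(4,4,4)),
#'   valid = array(TRUE, c(4,4,4)), fitQuality = array(0, c(4,4,4)),
#'   geometry = g, pdUnit = "percent")
#' atl <- buildReference(list(mk(1), mk(3)))
#' atlasMean(atl, "R1")[1, 1, 1]  # 2
#' atlasSd(atl, "R1")[1, 1, 1]    # sqrt(2)
#' @export
buildReference <- function(subjects) {
  n <- length(subjects)
  if (n < 2L) stop("a reference atlas needs at least 2 subjects")
  geom <- subjects[[1]]@geometry
  for (i in seq_len(n))
    stopIfGridMismatch(subjects[[i]]@geometry, geom,
                       sprintf("subject %d and the reference grid", i))
  dims <- geom@dim
  nVox <- prod(dims)
  coverage <- array(0L, dims)
  for (s in subjects) coverage <- coverage + as.integer(s@valid)

  stats3 <- function(param) {
    s1 <- numeric(nVox); s2 <- numeric(nVox)
    for (s in subjects) {
      v <- slot(s, param)
      v[!s@valid] <- 0
      v[!is.finite(v)] <- 0
      s1 <- s1 + as.vector(v)
      s2 <- s2 + as.vector(v)^2
    }
    cnt <- as.vector(coverage)
    mn <- rep(NaN, nVox)
    vr <- rep(NaN, nVox)
    ok <- cnt >= 2L
    mn[cnt >= 1L] <- s1[cnt >= 1L] / cnt[cnt >= 1L]
    vr[ok] <- pmax(s2[ok] - s1[ok]^2 / cnt[ok], 0) / (cnt[ok] - 1L)
    sd <- sqrt(vr)
    ## cov guard: mean above 1% of the cohort-median in-brain mean
    inBrain <- cnt == n
    epsRef <- finiteMedian(abs(mn[inBrain]))
    eps <- 0.01 * ifelse(is.finite(epsRef), epsRef, 0)
    cv <- rep(NaN, nVox)
    use <- ok & is.finite(mn) & mn > eps
    cv[use] <- sd[use] / mn[use]
    list(mean = array(mn, dims), sd = array(sd, dims), cov = array(cv, dims))
  }

  st <- lapply(c(R1 = "R1", R2 = "R2", PD = "PD"), stats3)
  new("ReferenceAtlas",
      mean = lapply(st, `[[`, "mean"),
      sd = lapply(st, `[[`, "sd"),
      cov = lapply(st, `[[`, "cov"),
      n = as.integer(n), coverage = coverage, geometry = geom)
}
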