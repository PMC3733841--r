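## Single-subject deviation mapping against a reference atlas: normalized
## difference (z) maps, significance thresholds, and the combined
## vector-sum statistic S = sqrt(zR1^2 + zR2^2 + zPD^2).

#' Normalized difference maps of a subject against a reference
#'
#' z_p = (subject_p - mean_p) / sd_p for each parameter, computed wherever
#' the subject is valid, the atlas sd is positive and at least 2 subjects
#' cover the voxel; NaN (sentinel) elsewhere. Values are signed: positive
#' means the subject lies above the reference mean.
#'
#' Degenerate zero-variance voxels (sd negligible relative to the mean, as
#' in a noise-free cohort of identical subjects) yield z = 0 when the
#' subject matches the reference mean to the same relative tolerance, and
#' the NaN sentinel otherwise — a zero difference is no deviation even when
#' the reference variance vanishes.
#'
#' @param subject a normalized \linkS4class{QuantMaps} on the atlas grid.
#' @param atlas a \linkS4class{ReferenceAtlas}.
#' @return named list of 3D arrays \code{R1}, \code{R2}, \code{PD}.
#' @export
zMaps <- function(subject, atlas) {
  stopIfGridMismatch(subject@geometry, atlas@geometry,
                     "subject and atlas")
  lapply(c(R1 = "R1", R2 = "R2", PD = "PD"), function(p) {
    sd <- atlas@sd[[p]]
    mn <- atlas@mean[[p]]
    covered <- subject@valid & is.finite(sd) & atlas@coverage >= 2L
    sdFloor <- 1e-6 * pmax(abs(mn), 1e-12)
    ok <- covered & sd > sdFloor
    z <- array(NaN, subject@geometry@dim)
    z[ok] <- (slot(subject, p)[ok] - mn[ok]) / sd[ok]
    zero <- covered & sd <= sdFloor &
      abs(slot(subject, p) - mn) <= sdFloor
    z[zero] <- 0
    z
  })
}

#' Two-sided significance threshold for normalized differences
#'
#' The two-sided critical value of the t distribution with nRef - 1 degrees
#' of freedom at level alpha. For a reference group of 31 subjects at
#' alpha = 0.05 this is 2.04; in the large-group Gaussian limit
#' (\code{nRef = Inf}) it is 1.96.
#'
#' @param nRef reference group size (>= 2; may be \code{Inf}).
#' @param alpha two-sided significance level in (0, 1).
#' @return the critical value (unitless).
#' @examples
#' significanceThreshold(31, 0.05)   # 2.04
#' significanceThreshold(Inf, 0.05)  # 1.96
#' @export
significanceThreshold <- function(nRef, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (!is.numeric(nRef) || length(nRef) != 1L || nRef < 2)
    stop("nRef must be at least 2")
  if (is.infinite(nRef)) return(stats::qnorm(1 - alpha / 2))
  stats::qt(1 - alpha / 2, df = nRef - 1)
}

#' Vector-sum magnitude of the three normalized difference maps
#'
#' S = sqrt(zR1^2 + zR2^2 + zPD^2) voxelwise; NaN wherever any component is
#' NaN. Under independent standard-normal components S follows a
#' 3-degree-of-freedom chi distribution.
#'
#' @param zR1,zR2,zPD co-registered 3D z arrays (or a list of the three as
#'   the first argument).
#' @return 3D array of S values (nonnegative).
#' @export
vectorSum <- function(zR1, zR2 = NULL, zPD = NULL) {
  if (is.list(zR1)) { zPD <- zR1$PD; zR2 <- zR1$R2; zR1 <- zR1$R1 }
  if (!all(dim(zR1) == dim(zR2)) || !all(dim(zR1) == dim(zPD)))
    stop("z maps must share one grid")
  sqrt(zR1^2 + zR2^2 + zPD^2)
}

#' Binary mask of supra-threshold combined deviations
#'
#' @param S vector-sum array.
#' @param threshold display/significance threshold (default 5; strict
#'   inequality).
#' @return logical array: \code{S > threshold} (NaN treated as FALSE).
#' @export
combinedMask <- function(S, threshold = 5) {
  assertScalarNumeric(threshold, "threshold", lower = 1e-12)
  m <- S > threshold
  m[is.na(m)] <- FALSE
  m
}

#' Expected number of false-positive pixels under a null distribution
#'
#' nPixels times the two-sided tail probability of the chosen null at the
#' threshold. With \code{alpha} given the tail probability is alpha itself
#' (the definition of the level): a 256 x 256 image at alpha = 0.05 yields
#' over 3000 chance pixels, while a Gaussian threshold of 5 yields fewer
#' than 0.5.
#'
#' @param nPixels number of pixels tested (>= 1).
#' @param threshold two-sided threshold on |z|; ignored when \code{alpha}
#'   is given.
#' @param alpha optional significance level; expected count = nPixels * alpha.
#' @param null \code{"gaussian"} or \code{"t"} (with \code{df}).
#' @param df degrees of freedom for the t null.
#' @return expected false-positive count.
#' @examples
#' expectedFalsePositives(256^2, alpha = 0.05)          # 3276.8
#' expectedFalsePositives(256^2, threshold = 5)         # 0.0376
#' @export
expectedFalsePositives <- function(nPixels, threshold = NULL, alpha = NULL,
                                   null = c("gaussian", "t"), df = NULL) {
  null <- match.arg(null)
  assertScalarNumeric(nPixels, "nPixels", lower = 1)
  if (!is.null(alpha)) {
    if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
    return(nPixels * alpha)
  }
  if (is.null(threshold)) stop("give either 'threshold' or 'alpha'")
  assertScalarNumeric(threshold, "threshold", lower = 0)
  tail2 <- switch(null,
    gaussian = 2 * stats::pnorm(-threshold),
    t = {
      if (is.null(df)) stop("the t null needs 'df'")
      2 * stats::pt(-threshold, df = df)
    })
  nPixels * tail2
}

#' Full deviation analysis of one subject against a reference atlas
#'
#' Computes the three z maps, per-parameter two-sided significance masks at
#' the per-voxel t critical value (degrees of freedom = per-voxel coverage
#' minus 1, which equals nRef - 1 at full coverage), the vector-sum map S,
#' and the combined mask at \code{sThreshold}.
#'
#' @param subject normalized \linkS4class{QuantMaps} on the atlas grid.
#' @param atlas a \linkS4class{ReferenceAtlas}.
#' @param alpha two-sided level for the per-parameter masks (default 0.05).
#' @param sThreshold threshold for the combined mask (default 5).
#' @return a \linkS4class{DeviationResult}.
#' @export
deviate <- function(subject, atlas, alpha = 0.05, sThreshold = 5) {
  z <- zMaps(subject, atlas)
  dims <- atlas@geometry@dim
  cov <- atlas@coverage
  tcrit <- array(NaN, dims)
  ok <- cov >= 2L
  tcrit[ok] <- stats::qt(1 - alpha / 2, df = cov[ok] - 1L)
  masks <- lapply(z, function(zz) {
    m <- abs(zz) > tcrit
    m[is.na(m)] <- FALSE
    m
  })
  S <- vectorSum(z)
  masks$S <- combinedMask(S, sThreshold)
  new("DeviationResult", z = z, S = S, masks = masks,
      thresholds = list(alpha = alpha,
                        zCritical = significanceThreshold(atlas@n, alpha),
                        sThreshold = sThreshold),
      nRef = atlas@n, geometry = atlas@geometry)
}
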