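## Synthetic contrast generation from quantitative maps, and Gaussian
## smoothing in millimetre units.

#' Contrast settings for synthetic image generation
#'
#' @param echoTime TE in ms (>= 0).
#' @param repetitionTime TR in ms (> TE).
#' @param inversionTime optional TI in ms (< TR); when set, the
#'   inversion-recovery signal equation is used.
#' @return a list of class \code{"ContrastSettings"}.
#' @export
contrastSettings <- function(echoTime, repetitionTime, inversionTime = NULL) {
  assertScalarNumeric(echoTime, "echoTime", lower = 0)
  assertScalarNumeric(repetitionTime, "repetitionTime", lower = 0)
  if (repetitionTime <= echoTime)
    stop("repetitionTime must exceed echoTime")
  if (!is.null(inversionTime)) {
    assertScalarNumeric(inversionTime, "inversionTime", lower = 0)
    if (inversionTime >= repetitionTime)
      stop("inversionTime must be below repetitionTime")
  }
  structure(list(echoTime = echoTime, repetitionTime = repetitionTime,
                 inversionTime = inversionTime), class = "ContrastSettings")
}

#' @rdname contrastSettings
#' @details \code{t2wSettings()} returns the default T2-weighted settings
#'   (TE = 100 ms, TR = 4500 ms) used for registration source images.
#' @export
t2wSettings <- function() contrastSettings(100, 4500)

#' Synthesize a contrast-weighted image from quantitative maps
#'
#' Spin-echo signal equation
#' \deqn{S = PD \cdot e^{-TE \cdot R2} (1 - e^{-TR \cdot R1})}
#' or, with an inversion time set,
#' \deqn{S = PD \cdot |1 - 2 e^{-TI \cdot R1} + e^{-TR \cdot R1}| \cdot
#'   e^{-TE \cdot R2}.}
#' Invalid voxels map to 0; the output is nonnegative, strictly decreasing
#' in R2 and proportional to PD.
#'
#' @param maps a \linkS4class{QuantMaps}.
#' @param settings a \code{ContrastSettings} (default T2-weighted,
#'   TE = 100 ms / TR = 4500 ms).
#' @return 3D numeric array on the maps' grid, arbitrary signal units.
#' @examples
#' ph <- makePhantom(phantomSpec(dim = c(24, 28, 22), spacing = 4), seed = 1)
#' t2w <- synthesize(ph$maps)
#' @export
synthesize <- function(maps, settings = t2wSettings()) {
  if (!inherits(settings, "ContrastSettings"))
    stop("'settings' must come from contrastSettings()")
  te <- settings$echoTime * MS2S
  tr <- settings$repetitionTime * MS2S
  R1 <- maps@R1; R2 <- maps@R2; PD <- maps@PD
  if (is.null(settings$inversionTime)) {
    S <- PD * exp(-te * R2) * (1 - exp(-tr * R1))
  } else {
    ti <- settings$inversionTime * MS2S
    S <- PD * abs(1 - 2 * exp(-ti * R1) + exp(-tr * R1)) * exp(-te * R2)
  }
  S[!maps@valid | !is.finite(S)] <- 0
  S
}

## 1D Gaussian kernel for a FWHM given in mm on a voxel axis of size `dx` mm.
gaussKernel1d <- function(fwhm, dx) {
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / dx   # in voxels
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r):r / sigma)^2)
  k / sum(k)
}

## Separable convolution along one axis with replicate (nearest) boundaries,
## implemented as a weighted sum of index-clamped shifted arrays.
convolveAxis <- function(x, k, ax) {
  r <- (length(k) - 1L) / 2L
  d <- dim(x)
  n <- d[ax]
  out <- array(0, d)
  idx <- lapply(d, seq_len)
  for (t in (-r):r) {
    ix <- idx
    ix[[ax]] <- pmin(pmax(seq_len(n) + t, 1L), n)
    out <- out + k[t + r + 1L] * do.call(`[`, c(list(x), ix, list(drop = FALSE)))
  }
  out
}

#' Gaussian smoothing of a volume, kernel specified in mm
#'
#' Separable Gaussian convolution with the full width at half maximum given
#' in millimetres and converted per axis to voxel units, so anisotropic
#' voxels are honoured. Boundaries are handled by edge replication. When a
#' mask is supplied, invalid voxels are excluded from the smoothing support
#' via normalized masked convolution (no NaN bleed); voxels outside the mask
#' are returned as 0. \code{fwhm = 0} is the identity.
#'
#' @param volume 3D numeric array.
#' @param fwhm full width at half maximum in mm (>= 0).
#' @param spacing numeric(3) voxel sizes in mm, or an
#'   \linkS4class{ImageGeometry}.
#' @param mask optional logical array; support of the convolution.
#' @return smoothed 3D array.
#' @export
gaussianSmooth <- function(volume, fwhm, spacing, mask = NULL) {
  if (is(spacing, "ImageGeometry")) spacing <- spacing@spacing
  assertScalarNumeric(fwhm, "fwhm", lower = 0)
  if (fwhm == 0) return(volume)
  ks <- lapply(1:3, function(ax) gaussKernel1d(fwhm, spacing[ax]))
  smoothOne <- function(x) {
    for (ax in 1:3) x <- convolveAxis(x, ks[[ax]], ax)
    x
  }
  if (is.null(mask)) return(smoothOne(volume))
  m <- array(as.numeric(mask), dim(volume))
  v <- volume
  v[!mask] <- 0
  num <- smoothOne(v)
  den <- smoothOne(m)
  out <- array(0, dim(volume))
  inside <- as.logical(mask) & den > 1e-12
  out[inside] <- num[inside] / den[inside]
  out
}
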