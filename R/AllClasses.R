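## S4 class definitions for the package's central data objects.

#' ImageGeometry: voxel grid geometry of a 3D volume
#'
#' Couples the array dimensions of a volume with its voxel spacing (mm) and
#' the 4x4 homogeneous affine mapping 0-based voxel indices to world (RAS, mm)
#' coordinates.
#'
#' @slot affine 4x4 numeric matrix, voxel (0-based) to world (mm, RAS).
#' @slot dim integer(3), array extents.
#' @slot spacing numeric(3), voxel edge lengths in mm.
#' @export
setClass("ImageGeometry",
  representation(affine = "matrix", dim = "integer", spacing = "numeric"),
  validity = function(object) {
    if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4x4")
    if (length(object@dim) != 3L || any(object@dim < 1L))
      return("dim must be three positive integers")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      return("spacing must be three positive numbers")
    if (abs(det(object@affine[1:3, 1:3])) < 1e-12)
      return("affine is singular")
    TRUE
  })

#' AcquisitionProtocol: timing of a multi-delay multi-echo acquisition
#'
#' Saturation delays and echo times of a multi spin-echo saturation-recovery
#' sequence. All times are entered in milliseconds and converted to seconds
#' once, at the model boundary.
#'
#' @slot saturationDelays numeric, saturation delays in ms, strictly
#'   increasing, all below the repetition time.
#' @slot echoTimes numeric, echo times in ms, strictly increasing.
#' @slot repetitionTime numeric scalar, repetition time in ms.
#' @export
setClass("AcquisitionProtocol",
  representation(saturationDelays = "numeric", echoTimes = "numeric",
                 repetitionTime = "numeric"),
  validity = function(object) {
    td <- object@saturationDelays; te <- object@echoTimes
    if (length(td) < 1L || any(td <= 0) || is.unsorted(td, strictly = TRUE))
      return("saturation delays must be positive and strictly increasing")
    if (length(te) < 1L || any(te <= 0) || is.unsorted(te, strictly = TRUE))
      return("echo times must be positive and strictly increasing")
    if (length(object@repetitionTime) != 1L || object@repetitionTime <= 0)
      return("repetition time must be a positive scalar")
    if (any(td >= object@repetitionTime))
      return("all saturation delays must be below the repetition time")
    TRUE
  })

#' AcquisitionSeries: 4D multi-delay multi-echo image stack
#'
#' The raw input to relaxometry fitting: one image volume per
#' (saturation delay, echo time) combination, stored as a 5D array indexed
#' (delay, echo, x, y, z), plus the protocol and voxel geometry.
#'
#' @slot data 5D numeric array, dimensions (nDelays, nEchoes, nx, ny, nz);
#'   finite, nonnegative signal in arbitrary units.
#' @slot protocol an \linkS4class{AcquisitionProtocol}.
#' @slot geometry an \linkS4class{ImageGeometry} for the spatial axes.
#' @export
setClass("AcquisitionSeries",
  representation(data = "array", protocol = "AcquisitionProtocol",
                 geometry = "ImageGeometry"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 5L) return("data must be a 5D array (delay, echo, x, y, z)")
    if (d[1] != length(object@protocol@saturationDelays))
      return("first array extent must equal the number of saturation delays")
    if (d[2] != length(object@protocol@echoTimes))
      return("second array extent must equal the number of echo times")
    if (!all(d[3:5] == object@geometry@dim))
      return("spatial extents disagree with geometry")
    if (any(!is.finite(object@data)) || any(object@data < 0))
      return("all intensities must be finite and nonnegative")
    TRUE
  })

#' QuantMaps: co-registered quantitative parameter maps
#'
#' The central currency of the pipeline: longitudinal relaxation rate R1
#' (1/s), transverse relaxation rate R2 (1/s) and proton density PD (either
#' raw M0 units or percent of pure water at 37 degrees C), sharing one voxel
#' geometry. Voxels that could not be fitted carry NaN in the map volumes and
#' FALSE in the companion validity mask; they are never silently zeroed.
#'
#' @slot R1,R2,PD 3D numeric arrays on the shared grid.
#' @slot valid 3D logical array: TRUE where the maps hold fitted values.
#' @slot fitQuality 3D numeric array, per-voxel root-mean-square misfit
#'   normalized by M0 (unitless); NaN where not fitted.
#' @slot geometry an \linkS4class{ImageGeometry}.
#' @slot pdUnit character, \code{"arbitrary"} (raw M0) or \code{"percent"}.
#' @export
setClass("QuantMaps",
  representation(R1 = "array", R2 = "array", PD = "array", valid = "array",
                 fitQuality = "array", geometry = "ImageGeometry",
                 pdUnit = "character"),
  validity = function(object) {
    d <- object@geometry@dim
    for (nm in c("R1", "R2", "PD", "valid", "fitQuality"))
      if (!all(dim(slot(object, nm)) == d))
        return(sprintf("'%s' does not match the geometry", nm))
    v <- object@valid
    if (!is.logical(v)) return("valid must be a logical array")
    for (nm in c("R1", "R2"))
      if (any(slot(object, nm)[v] < 0, na.rm = TRUE))
        return(sprintf("%s must be nonnegative where fitted", nm))
    if (any(object@PD[v] < 0, na.rm = TRUE))
      return("PD must be nonnegative where fitted")
    if (!object@pdUnit %in% c("arbitrary", "percent"))
      return("pdUnit must be 'arbitrary' or 'percent'")
    TRUE
  })

#' AffineTransform: 12-parameter spatial mapping between world spaces
#'
#' Translation (mm), rotation (radians), zoom and shear, composed into a 4x4
#' homogeneous matrix as \code{T \%*\% Rz \%*\% Ry \%*\% Rx \%*\% Shear \%*\%
#' Zoom}, acting on world (mm, RAS) coordinates. The parameter vector and the
#' matrix are kept consistent; round-tripping params -> matrix -> params is
#' identity to 1e-9.
#'
#' @slot params named numeric(12): tx, ty, tz (mm); rx, ry, rz (rad);
#'   zx, zy, zz; sxy, sxz, syz.
#' @slot matrix 4x4 homogeneous matrix.
#' @export
setClass("AffineTransform",
  representation(params = "numeric", matrix = "matrix"),
  validity = function(object) {
    if (length(object@params) != 12L) return("params must have length 12")
    if (!all(dim(object@matrix) == c(4L, 4L))) return("matrix must be 4x4")
    z <- object@params[7:9]
    if (any(!is.finite(object@params))) return("params must be finite")
    if (any(z <= 0)) return("zooms must be positive")
    if (abs(det(object@matrix[1:3, 1:3])) < 1e-12)
      return("matrix is singular")
    TRUE
  })

#' TemplateSpace: registration target
#'
#' A template volume with its geometry plus the isotropic grid spacing that
#' normalized maps are resampled to (2 mm by default).
#'
#' @slot volume 3D numeric array (finite, nonnegative).
#' @slot geometry an \linkS4class{ImageGeometry}.
#' @slot targetSpacing numeric(3), output grid spacing in mm.
#' @export
setClass("TemplateSpace",
  representation(volume = "array", geometry = "ImageGeometry",
                 targetSpacing = "numeric"),
  validity = function(object) {
    if (!all(dim(object@volume) == object@geometry@dim))
      return("volume does not match the geometry")
    if (any(!is.finite(object@volume)) || any(object@volume < 0))
      return("template must be finite and nonnegative")
    if (length(object@targetSpacing) != 3L || any(object@targetSpacing <= 0))
      return("targetSpacing must be three positive numbers")
    TRUE
  })

#' ReferenceAtlas: voxelwise normative reference maps
#'
#' Per-parameter voxelwise sample mean, sample SD (n-1 denominator) and
#' coefficient of variation (CoV = sd/mean) over a cohort of spatially
#' normalized \linkS4class{QuantMaps}, with the per-voxel count of
#' contributing subjects.
#'
#' @slot mean,sd,cov named lists of 3D arrays, one per parameter
#'   (\code{R1}, \code{R2}, \code{PD}).
#' @slot n integer, cohort size.
#' @slot coverage 3D integer array, contributing subjects per voxel.
#' @slot geometry the shared template-space \linkS4class{ImageGeometry}.
#' @export
setClass("ReferenceAtlas",
  representation(mean = "list", sd = "list", cov = "list", n = "integer",
                 coverage = "array", geometry = "ImageGeometry"),
  validity = function(object) {
    pars <- c("R1", "R2", "PD")
    for (sl in c("mean", "sd", "cov")) {
      l <- slot(object, sl)
      if (!all(pars %in% names(l))) return(sprintf("'%s' must have R1/R2/PD", sl))
      for (p in pars)
        if (!all(dim(l[[p]]) == object@geometry@dim))
          return(sprintf("%s$%s does not match the geometry", sl, p))
    }
    if (object@n < 2L) return("a reference needs at least 2 subjects")
    if (any(object@coverage > object@n)) return("coverage cannot exceed n")
    for (p in pars)
      if (any(object@sd[[p]] < 0, na.rm = TRUE)) return("sd must be nonnegative")
    TRUE
  })

#' DeviationResult: single-subject deviation maps against a reference
#'
#' Per-parameter normalized difference maps z = (subject - mean)/sd, the
#' combined vector-sum magnitude S = sqrt(zR1^2 + zR2^2 + zPD^2), and binary
#' significance masks at the thresholds used.
#'
#' @slot z named list of 3D arrays (\code{R1}, \code{R2}, \code{PD}), signed.
#' @slot S 3D numeric array, vector-sum magnitude (nonnegative).
#' @slot masks named list of logical arrays: per-parameter two-sided
#'   significance masks and the combined \code{S} mask.
#' @slot thresholds named list: \code{alpha}, \code{zCritical} (at full
#'   coverage), \code{sThreshold}.
#' @slot nRef integer, reference group size.
#' @slot geometry template-space \linkS4class{ImageGeometry}.
#' @export
setClass("DeviationResult",
  representation(z = "list", S = "array", masks = "list", thresholds = "list",
                 nRef = "integer", geometry = "ImageGeometry"),
  validity = function(object) {
    if (any(object@S < 0, na.rm = TRUE)) return("S must be nonnegative")
    if (!all(c("R1", "R2", "PD") %in% names(object@z)))
      return("z must have R1/R2/PD components")
    TRUE
  })

#' LabelAtlas: integer region-of-interest labels on a grid
#'
#' @slot labels 3D integer array of region codes; 0 is background.
#' @slot table data.frame with columns \code{code} and \code{name}; every
#'   nonzero code present in the volume appears in the table.
#' @slot geometry an \linkS4class{ImageGeometry}.
#' @export
setClass("LabelAtlas",
  representation(labels = "array", table = "data.frame",
                 geometry = "ImageGeometry"),
  validity = function(object) {
    if (!all(dim(object@labels) == object@geometry@dim))
      return("labels do not match the geometry")
    if (!all(c("code", "name") %in% colnames(object@table)))
      return("label table needs 'code' and 'name' columns")
    present <- setdiff(unique(as.integer(object@labels)), 0L)
    if (!all(present %in% object@table$code))
      return("labels present in the volume are missing from the table")
    TRUE
  })

#' PhantomSpec: parameters of the digital brain phantom
#'
#' Parametric-geometric brain-like anatomy: a sinusoidally folded cortical
#' shell around a white-matter core, deep grey nuclei, lateral ventricles
#' sized to a target fraction of the intracranial volume, a subarachnoid CSF
#' shell, and optional white-matter lesions. Tissue-class R1/R2/PD means and
#' between-subject SDs default to published in-vivo values.
#'
#' @slot dim integer(3) grid size; @slot spacing numeric(3) voxel mm.
#' @slot classes data.frame: code, name, r1, r2, pd, sdR1, sdR2, sdPD.
#' @slot ventricleFraction target lateral-ventricle / intracranial fraction.
#' @slot foldAmplitude relative amplitude of the cortical folding.
#' @slot textureFraction voxelwise within-tissue SD as a fraction of the
#'   tissue's between-subject SD.
#' @slot lesions list or NULL: n, radiusRange (mm), effect (dR1, dR2, dPD).
#' @export
setClass("PhantomSpec",
  representation(dim = "integer", spacing = "numeric", classes = "data.frame",
                 ventricleFraction = "numeric", foldAmplitude = "numeric",
                 textureFraction = "numeric", lesions = "ANY"),
  validity = function(object) {
    if (length(object@dim) != 3L || any(object@dim < 8L))
      return("grid must be at least 8 voxels per axis")
    cl <- object@classes
    need <- c("code", "name", "r1", "r2", "pd", "sdR1", "sdR2", "sdPD")
    if (!all(need %in% colnames(cl))) return("classes table incomplete")
    if (any(cl$r1 <= 0 | cl$r1 > 5) || any(cl$r2 <= 0 | cl$r2 > 50) ||
        any(cl$pd <= 0 | cl$pd > 120))
      return("class values outside physiological ranges")
    if (object@ventricleFraction <= 0 || object@ventricleFraction > 0.2)
      return("ventricleFraction must be in (0, 0.2]")
    TRUE
  })

#' CohortSpec: parameters of a simulated subject cohort
#'
#' @slot n number of subjects (>= 2).
#' @slot ageRange,ageMean,ageSd age distribution (years; truncated normal).
#' @slot jitterSd named numeric: between-subject anatomical affine jitter
#'   SDs — translation (mm), rotation (rad), zoom, shear.
#' @slot slopes data.frame or NULL: injected linear age trends with columns
#'   className, parameter ("r1"/"r2"/"pd"), slopePerYear (centred on ageMean).
#' @slot noiseSigma acquisition noise SD in signal units; @slot noiseModel
#'   "gaussian" or "rician".
#' @slot seed master seed; all per-subject randomness derives from it.
#' @export
setClass("CohortSpec",
  representation(n = "integer", ageRange = "numeric", ageMean = "numeric",
                 ageSd = "numeric", jitterSd = "numeric", slopes = "ANY",
                 noiseSigma = "numeric", noiseModel = "character",
                 seed = "integer"),
  validity = function(object) {
    if (object@n < 2L) return("a cohort needs at least 2 subjects")
    if (object@noiseSigma < 0) return("noiseSigma must be nonnegative")
    if (!object@noiseModel %in% c("gaussian", "rician"))
      return("noiseModel must be 'gaussian' or 'rician'")
    if (!all(c("trans", "rot", "zoom", "shear") %in% names(object@jitterSd)))
      return("jitterSd must name trans, rot, zoom, shear")
    TRUE
  })
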