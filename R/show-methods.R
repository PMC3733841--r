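## show() methods for the package's classes.

setMethod("show", "ImageGeometry", function(object) {
  cat(sprintf("ImageGeometry: %s voxels, %s mm\n",
              paste(object@dim, collapse = " x "),
              paste(signif(object@spacing, 4), collapse = " x ")))
})

setMethod("show", "AcquisitionProtocol", function(object) {
  cat(sprintf(
    "AcquisitionProtocol: %d delays x %d echoes (%d images per slice)\n",
    length(object@saturationDelays), length(object@echoTimes),
    imagesPerSlice(object)))
  cat("  TD (ms):", paste(object@saturationDelays, collapse = ", "), "\n")
  cat("  TE (ms):", paste(object@echoTimes, collapse = ", "), "\n")
  cat("  TR (ms):", object@repetitionTime, "\n")
})

setMethod("show", "AcquisitionSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("AcquisitionSeries: %d x %d images of %s voxels\n",
              d[1], d[2], paste(d[3:5], collapse = " x ")))
  show(object@geometry)
})

setMethod("show", "QuantMaps", function(object) {
  nv <- sum(object@valid)
  cat(sprintf("QuantMaps: %s voxels, %d fitted (%.1f%%), PD unit: %s\n",
              paste(object@geometry@dim, collapse = " x "), nv,
              100 * nv / prod(object@geometry@dim), object@pdUnit))
  if (nv > 0)
    cat(sprintf("  median R1 %.3f 1/s, R2 %.3f 1/s, PD %.1f\n",
                stats::median(object@R1[object@valid]),
                stats::median(object@R2[object@valid]),
                stats::median(object@PD[object@valid])))
})

setMethod("show", "AffineTransform", function(object) {
  p <- object@params
  cat("AffineTransform (world mm, T*Rz*Ry*Rx*Shear*Zoom):\n")
  cat(sprintf("  translation % .3f % .3f % .3f mm\n", p[1], p[2], p[3]))
  cat(sprintf("  rotation    % .4f % .4f % .4f rad\n", p[4], p[5], p[6]))
  cat(sprintf("  zoom        % .4f % .4f % .4f\n", p[7], p[8], p[9]))
  cat(sprintf("  shear       % .4f % .4f % .4f\n", p[10], p[11], p[12]))
})

setMethod("show", "TemplateSpace", function(object) {
  cat("TemplateSpace\n  ")
  show(object@geometry)
  cat(sprintf("  target grid: %s mm\n",
              paste(object@targetSpacing, collapse = " x ")))
})

setMethod("show", "ReferenceAtlas", function(object) {
  cat(sprintf("ReferenceAtlas: n = %d subjects, %s voxels\n", object@n,
              paste(object@geometry@dim, collapse = " x ")))
  full <- sum(object@coverage == object@n)
  cat(sprintf("  %d voxels at full coverage\n", full))
})

setMethod("show", "DeviationResult", function(object) {
  cat(sprintf("DeviationResult vs reference of n = %d\n", object@nRef))
  cat(sprintf("  thresholds: |z| > %.3f (alpha = %g), S > %g\n",
              object@thresholds$zCritical, object@thresholds$alpha,
              object@thresholds$sThreshold))
  cat(sprintf(
    "  suprathreshold voxels: R1 %d, R2 %d, PD %d, combined %d\n",
    sum(object@masks$R1), sum(object@masks$R2), sum(object@masks$PD),
    sum(object@masks$S)))
})

setMethod("show", "LabelAtlas", function(object) {
  cat(sprintf("LabelAtlas: %d regions on %s voxels\n",
              nrow(object@table),
              paste(object@geometry@dim, collapse = " x ")))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %s voxels at %s mm, %d tissue classes%s\n",
              paste(object@dim, collapse = " x "),
              paste(object@spacing, collapse = " x "),
              nrow(object@classes),
              if (is.null(object@lesions)) ""
              else sprintf(", %d lesions", object@lesions$n)))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: n = %d, ages %g-%g (mean %g), noise sigma %g (%s)\n",
    object@n, object@ageRange[1], object@ageRange[2], object@ageMean,
    object@noiseSigma, object@noiseModel))
})
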