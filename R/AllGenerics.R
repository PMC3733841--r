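## Generics for accessors shared across the package's classes.

#' Extract the voxel-grid geometry of an object
#' @param x an object with a spatial grid.
#' @return an \linkS4class{ImageGeometry}.
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname QuantMaps-accessors
#' @export
setGeneric("r1Map", function(x) standardGeneric("r1Map"))
#' @rdname QuantMaps-accessors
#' @export
setGeneric("r2Map", function(x) standardGeneric("r2Map"))
#' @rdname QuantMaps-accessors
#' @export
setGeneric("pdMap", function(x) standardGeneric("pdMap"))
#' @rdname QuantMaps-accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname QuantMaps-accessors
#' @export
setGeneric("fitQuality", function(x) standardGeneric("fitQuality"))

#' Acquisition protocol of a series
#' @param x an \linkS4class{AcquisitionSeries}.
#' @export
setGeneric("protocol", function(x) standardGeneric("protocol"))

#' @rdname AffineTransform-accessors
#' @export
setGeneric("transformParams", function(x) standardGeneric("transformParams"))
#' @rdname AffineTransform-accessors
#' @export
setGeneric("transformMatrix", function(x) standardGeneric("transformMatrix"))

#' @rdname ReferenceAtlas-accessors
#' @export
setGeneric("atlasMean", function(x, parameter) standardGeneric("atlasMean"))
#' @rdname ReferenceAtlas-accessors
#' @export
setGeneric("atlasSd", function(x, parameter) standardGeneric("atlasSd"))
#' @rdname ReferenceAtlas-accessors
#' @export
setGeneric("covMap", function(x, parameter) standardGeneric("covMap"))
#' @rdname ReferenceAtlas-accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

## geometry() methods for all spatial containers
#' @rdname geometry
#' @aliases geometry,AcquisitionSeries-method
setMethod("geometry", "AcquisitionSeries", function(x) x@geometry)
#' @rdname geometry
setMethod("geometry", "QuantMaps", function(x) x@geometry)
#' @rdname geometry
setMethod("geometry", "TemplateSpace", function(x) x@geometry)
#' @rdname geometry
setMethod("geometry", "ReferenceAtlas", function(x) x@geometry)
#' @rdname geometry
setMethod("geometry", "DeviationResult", function(x) x@geometry)
#' @rdname geometry
setMethod("geometry", "LabelAtlas", function(x) x@geometry)

#' Accessors for QuantMaps
#'
#' \code{r1Map}, \code{r2Map} and \code{pdMap} return the parameter volumes
#' (NaN outside the validity mask); \code{validMask} the logical mask of
#' fitted voxels; \code{fitQuality} the per-voxel normalized RMS misfit.
#'
#' @param x a \linkS4class{QuantMaps}.
#' @name QuantMaps-accessors
NULL

#' @rdname QuantMaps-accessors
setMethod("r1Map", "QuantMaps", function(x) x@R1)
#' @rdname QuantMaps-accessors
setMethod("r2Map", "QuantMaps", function(x) x@R2)
#' @rdname QuantMaps-accessors
setMethod("pdMap", "QuantMaps", function(x) x@PD)
#' @rdname QuantMaps-accessors
setMethod("validMask", "QuantMaps", function(x) x@valid)
#' @rdname QuantMaps-accessors
setMethod("fitQuality", "QuantMaps", function(x) x@fitQuality)

#' @rdname protocol
setMethod("protocol", "AcquisitionSeries", function(x) x@protocol)

#' Accessors for AffineTransform
#'
#' @param x an \linkS4class{AffineTransform}.
#' @name AffineTransform-accessors
NULL

#' @rdname AffineTransform-accessors
setMethod("transformParams", "AffineTransform", function(x) x@params)
#' @rdname AffineTransform-accessors
setMethod("transformMatrix", "AffineTransform", function(x) x@matrix)

#' Accessors for ReferenceAtlas
#'
#' @param x a \linkS4class{ReferenceAtlas}.
#' @param parameter one of \code{"R1"}, \code{"R2"}, \code{"PD"}.
#' @name ReferenceAtlas-accessors
NULL

checkParameter <- function(parameter) {
  if (!is.character(parameter) || length(parameter) != 1L ||
      !parameter %in% c("R1", "R2", "PD"))
    stop("'parameter' must be one of \"R1\", \"R2\", \"PD\"")
  parameter
}

#' @rdname ReferenceAtlas-accessors
setMethod("atlasMean", "ReferenceAtlas",
  function(x, parameter) x@mean[[checkParameter(parameter)]])
#' @rdname ReferenceAtlas-accessors
setMethod("atlasSd", "ReferenceAtlas",
  function(x, parameter) x@sd[[checkParameter(parameter)]])
#' @rdname ReferenceAtlas-accessors
setMethod("covMap", "ReferenceAtlas",
  function(x, parameter) x@cov[[checkParameter(parameter)]])
#' @rdname ReferenceAtlas-accessors
setMethod("nSubjects", "ReferenceAtlas", function(x) x@n)
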