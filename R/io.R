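## NIfTI-1 and JSON/TSV serialization of the package's objects.

niftiFromArray <- function(arr, geom) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- geom@spacing
  RNifti::`sform<-`(img, structure(geom@affine, code = 2L))
}

writeVolume <- function(arr, geom, path) {
  RNifti::writeNifti(niftiFromArray(arr, geom), path)
  invisible(path)
}

readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  d <- dim(img)
  list(vol = array(as.numeric(img), d),
       geom = geometryFromAffine(matrix(as.numeric(aff), 4, 4), d[1:3]))
}

#' Read and write quantitative maps as NIfTI-1 volumes
#'
#' Writes \code{<prefix>_R1.nii.gz}, \code{_R2}, \code{_PD},
#' \code{_valid} (uint8-style 0/1) and \code{_fitq}, plus a small JSON
#' sidecar recording the PD unit. \code{readQuantMaps} reverses this.
#'
#' @param maps a \linkS4class{QuantMaps}.
#' @param prefix output path prefix.
#' @export
writeQuantMaps <- function(maps, prefix) {
  g <- maps@geometry
  writeVolume(maps@R1, g, paste0(prefix, "_R1.nii.gz"))
  writeVolume(maps@R2, g, paste0(prefix, "_R2.nii.gz"))
  writeVolume(maps@PD, g, paste0(prefix, "_PD.nii.gz"))
  writeVolume(array(as.numeric(maps@valid), g@dim), g,
              paste0(prefix, "_valid.nii.gz"))
  writeVolume(maps@fitQuality, g, paste0(prefix, "_fitq.nii.gz"))
  jsonlite::write_json(list(pdUnit = maps@pdUnit),
                       paste0(prefix, "_maps.json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname writeQuantMaps
#' @export
readQuantMaps <- function(prefix) {
  r1 <- readVolume(paste0(prefix, "_R1.nii.gz"))
  r2 <- readVolume(paste0(prefix, "_R2.nii.gz"))
  pd <- readVolume(paste0(prefix, "_PD.nii.gz"))
  vl <- readVolume(paste0(prefix, "_valid.nii.gz"))
  fq <- readVolume(paste0(prefix, "_fitq.nii.gz"))
  meta <- if (file.exists(paste0(prefix, "_maps.json")))
    jsonlite::read_json(paste0(prefix, "_maps.json"))
  else list(pdUnit = "arbitrary")
  new("QuantMaps", R1 = r1$vol, R2 = r2$vol, PD = pd$vol,
      valid = array(vl$vol > 0.5, r1$geom@dim), fitQuality = fq$vol,
      geometry = r1$geom, pdUnit = meta$pdUnit)
}

#' Read and write an acquisition series (4D NIfTI + protocol sidecar)
#'
#' The 4D NIfTI's fourth axis enumerates (delay, echo) pairs with the delay
#' varying fastest; the JSON sidecar holds \code{saturation_delays_ms},
#' \code{echo_times_ms} and \code{repetition_time_ms}.
#'
#' @param series an \linkS4class{AcquisitionSeries}.
#' @param prefix path prefix (writes \code{<prefix>.nii.gz} and
#'   \code{<prefix>_protocol.json}).
#' @export
writeAcquisitionSeries <- function(series, prefix) {
  d <- dim(series@data)
  arr <- series@data
  dim(arr) <- c(d[1] * d[2], d[3], d[4], d[5])
  arr <- aperm(arr, c(2, 3, 4, 1))
  writeVolume(arr, series@geometry, paste0(prefix, ".nii.gz"))
  pr <- series@protocol
  jsonlite::write_json(list(saturation_delays_ms = pr@saturationDelays,
                            echo_times_ms = pr@echoTimes,
                            repetition_time_ms = pr@repetitionTime),
                       paste0(prefix, "_protocol.json"), digits = NA)
  invisible(prefix)
}

#' @rdname writeAcquisitionSeries
#' @param protocolPath optional explicit sidecar path.
#' @export
readAcquisitionSeries <- function(prefix, protocolPath = NULL) {
  path <- if (file.exists(prefix)) prefix else paste0(prefix, ".nii.gz")
  if (is.null(protocolPath))
    protocolPath <- paste0(sub("\\.nii(\\.gz)?$", "", path), "_protocol.json")
  if (!file.exists(path))
    stop("series file not found: ", path)
  if (!file.exists(protocolPath))
    stop("protocol sidecar not found: ", protocolPath)
  pj <- jsonlite::read_json(protocolPath, simplifyVector = TRUE)
  pr <- acquisitionProtocol(pj$saturation_delays_ms, pj$echo_times_ms,
                            pj$repetition_time_ms)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop("series file must be 4D")
  arr <- array(as.numeric(img), d)
  nd <- length(pr@saturationDelays); ne <- length(pr@echoTimes)
  if (d[4] != nd * ne)
    stop("4th dimension does not match the protocol's delay x echo count")
  aff <- RNifti::xform(img)
  geom <- geometryFromAffine(matrix(as.numeric(aff), 4, 4), d[1:3])
  arr <- aperm(arr, c(4, 1, 2, 3))
  dim(arr) <- c(nd, ne, d[1:3])
  acquisitionSeries(arr, pr, geom)
}

#' Read and write an affine transform as JSON
#'
#' Stores the 12 named parameters, the 4x4 matrix row-major, and the
#' composition-convention string; the round trip is exact.
#'
#' @param transform an \linkS4class{AffineTransform}.
#' @param path JSON file path.
#' @export
writeAffineTransform <- function(transform, path) {
  jsonlite::write_json(
    list(parameters = as.list(transform@params),
         matrix_row_major = as.vector(t(transform@matrix)),
         convention = TRANSFORM_CONVENTION),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeAffineTransform
#' @export
readAffineTransform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- unlist(j$parameters)[paramNames]
  new("AffineTransform", params = p, matrix = composeAffineMatrix(p))
}

#' Read and write a reference atlas directory
#'
#' One NIfTI per statistic (\code{mean_R1.nii.gz}, \code{sd_R1.nii.gz},
#' \code{cov_R1.nii.gz}, ... , \code{coverage.nii.gz}) plus
#' \code{atlas.json} with the group size and grid.
#'
#' @param atlas a \linkS4class{ReferenceAtlas}.
#' @param dir output directory.
#' @export
writeReferenceAtlas <- function(atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- atlas@geometry
  for (p in c("R1", "R2", "PD")) {
    writeVolume(atlas@mean[[p]], g, file.path(dir, sprintf("mean_%s.nii.gz", p)))
    writeVolume(atlas@sd[[p]], g, file.path(dir, sprintf("sd_%s.nii.gz", p)))
    writeVolume(atlas@cov[[p]], g, file.path(dir, sprintf("cov_%s.nii.gz", p)))
  }
  writeVolume(array(as.numeric(atlas@coverage), g@dim), g,
              file.path(dir, "coverage.nii.gz"))
  jsonlite::write_json(list(n = atlas@n, dim = g@dim, spacing = g@spacing),
                       file.path(dir, "atlas.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname writeReferenceAtlas
#' @export
readReferenceAtlas <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "atlas.json"),
                              simplifyVector = TRUE)
  rd <- function(f) readVolume(file.path(dir, f))
  first <- rd("mean_R1.nii.gz")
  g <- first$geom
  grab <- function(stat) {
    out <- lapply(c(R1 = "R1", R2 = "R2", PD = "PD"), function(p)
      rd(sprintf("%s_%s.nii.gz", stat, p))$vol)
    out
  }
  cov0 <- rd("coverage.nii.gz")$vol
  storage.mode(cov0) <- "integer"
  new("ReferenceAtlas", mean = grab("mean"), sd = grab("sd"),
      cov = grab("cov"), n = as.integer(meta$n), coverage = cov0,
      geometry = g)
}

#' Read and write a label atlas (NIfTI labels + TSV table)
#'
#' @param atlas a \linkS4class{LabelAtlas}.
#' @param prefix writes \code{<prefix>.nii.gz} and \code{<prefix>.tsv}
#'   (columns \code{code}, \code{name}).
#' @export
writeLabelAtlas <- function(atlas, prefix) {
  writeVolume(array(as.numeric(atlas@labels), atlas@geometry@dim),
              atlas@geometry, paste0(prefix, ".nii.gz"))
  utils::write.table(atlas@table, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' @rdname writeLabelAtlas
#' @export
readLabelAtlas <- function(prefix) {
  v <- readVolume(paste0(prefix, ".nii.gz"))
  tab <- utils::read.delim(paste0(prefix, ".tsv"))
  lab <- v$vol
  storage.mode(lab) <- "integer"
  labelAtlas(lab, tab, v$geom)
}

#' Write a deviation result (z/S volumes, masks, summary TSV)
#'
#' @param result a \linkS4class{DeviationResult}.
#' @param dir output directory.
#' @export
writeDeviationResult <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- result@geometry
  for (p in c("R1", "R2", "PD")) {
    writeVolume(result@z[[p]], g, file.path(dir, sprintf("z_%s.nii.gz", p)))
    writeVolume(array(as.numeric(result@masks[[p]]), g@dim), g,
                file.path(dir, sprintf("mask_%s.nii.gz", p)))
  }
  writeVolume(result@S, g, file.path(dir, "S.nii.gz"))
  writeVolume(array(as.numeric(result@masks$S), g@dim), g,
              file.path(dir, "mask_S.nii.gz"))
  summ <- data.frame(
    measure = c("z_R1", "z_R2", "z_PD", "S"),
    threshold = c(rep(result@thresholds$zCritical, 3),
                  result@thresholds$sThreshold),
    suprathreshold_voxels = c(sum(result@masks$R1), sum(result@masks$R2),
                              sum(result@masks$PD), sum(result@masks$S)))
  utils::write.table(summ, file.path(dir, "summary.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
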