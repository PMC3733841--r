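## Atlas-ROI summaries, age regression, and brain/ventricle volume fractions.

#' Construct a label atlas
#'
#' @param labels 3D integer array of region codes (0 = background).
#' @param table data.frame with columns \code{code}, \code{name}.
#' @param geom an \linkS4class{ImageGeometry}.
#' @export
labelAtlas <- function(labels, table, geom) {
  storage.mode(labels) <- "integer"
  new("LabelAtlas", labels = labels, table = as.data.frame(table),
      geometry = geom)
}

#' Per-ROI mean parameter values for one subject
#'
#' Mean R1, R2 and PD over the valid voxels carrying each ROI's code, with
#' the contributing voxel count. Empty ROIs are flagged (NA means,
#' \code{empty = TRUE}), never silently dropped.
#'
#' @param maps a \linkS4class{QuantMaps} on the atlas grid.
#' @param atlas a \linkS4class{LabelAtlas}.
#' @return data.frame: code, name, nVoxels, empty, R1, R2, PD.
#' @export
roiMeans <- function(maps, atlas) {
  stopIfGridMismatch(maps@geometry, atlas@geometry, "maps and label atlas")
  codes <- sort(atlas@table$code)
  lab <- as.vector(atlas@labels)
  valid <- as.vector(maps@valid)
  out <- data.frame(code = codes,
                    name = atlas@table$name[match(codes, atlas@table$code)],
                    nVoxels = 0L, empty = TRUE,
                    R1 = NA_real_, R2 = NA_real_, PD = NA_real_)
  for (i in seq_along(codes)) {
    sel <- lab == codes[i] & valid
    n <- sum(sel)
    out$nVoxels[i] <- n
    if (n > 0L) {
      out$empty[i] <- FALSE
      out$R1[i] <- mean(maps@R1[sel])
      out$R2[i] <- mean(maps@R2[sel])
      out$PD[i] <- mean(maps@PD[sel])
    }
  }
  out
}

#' Cohort ROI table with age regression
#'
#' Per (ROI, parameter): across-subject mean and SD of the subject-level ROI
#' means, the ordinary least-squares slope against age (units per year) with
#' its two-sided p value and 95% confidence interval, and a significance
#' flag at p < 0.05. ROI means are computed per subject first and then
#' aggregated (subject-level SDs, not pooled voxels).
#'
#' @param subjects list of \linkS4class{QuantMaps} on the atlas grid.
#' @param ages numeric vector of subject ages in years.
#' @param atlas a \linkS4class{LabelAtlas}.
#' @return data.frame, one row per (code, parameter): mean, sd, slope,
#'   slopeSE, slopeP, ciLow, ciHigh, significant.
#' @export
cohortRoiTable <- function(subjects, ages, atlas) {
  n <- length(subjects)
  if (n < 3L) stop("age regression needs at least 3 subjects")
  if (length(ages) != n) stop("one age per subject required")
  if (any(ages <= 0)) stop("ages must be positive")
  perSubject <- lapply(subjects, roiMeans, atlas = atlas)
  codes <- perSubject[[1]]$code
  rows <- list()
  constantAges <- stats::var(ages) == 0
  for (ci in seq_along(codes)) {
    for (p in c("R1", "R2", "PD")) {
      vals <- vapply(perSubject, function(t) t[[p]][ci], numeric(1))
      slope <- se <- pval <- lo <- hi <- NA_real_
      if (constantAges) {
        regFlag <- "constant ages"
      } else if (sum(is.finite(vals)) >= 3L) {
        fit <- stats::lm(vals ~ ages)
        ## a zero-residual cohort (identical maps) is legitimate here
        cf <- withCallingHandlers(
          summary(fit)$coefficients,
          warning = function(w) {
            if (grepl("essentially perfect fit", conditionMessage(w)))
              invokeRestart("muffleWarning")
          })
        if (nrow(cf) == 2L) {
          slope <- cf[2, 1]; se <- cf[2, 2]; pval <- cf[2, 4]
          qv <- stats::qt(0.975, df = fit$df.residual)
          lo <- slope - qv * se; hi <- slope + qv * se
        }
        regFlag <- "ok"
      } else regFlag <- "insufficient data"
      rows[[length(rows) + 1L]] <- data.frame(
        code = codes[ci],
        name = perSubject[[1]]$name[ci],
        parameter = p,
        mean = mean(vals, na.rm = TRUE),
        sd = stats::sd(vals[is.finite(vals)]),
        slope = slope, slopeSE = se, slopeP = pval,
        ciLow = lo, ciHigh = hi,
        significant = is.finite(pval) && pval < 0.05,
        regression = regFlag)
    }
  }
  do.call(rbind, rows)
}

#' Rule-based tissue masks from calibrated quantitative maps
#'
#' Intracranial mask: largest 6-connected component of the fitted foreground
#' after a morphological closing. CSF: intracranial voxels with PD above
#' \code{pdThreshold} (percent) and R1 below \code{r1Threshold} (1/s).
#' Parenchyma: intracranial minus CSF. Boundary voxels with mixed tissue are
#' assigned deterministically by the same thresholds.
#'
#' @param maps a calibrated \linkS4class{QuantMaps} (PD in percent).
#' @param pdThreshold CSF proton-density threshold, percent (default 85).
#' @param r1Threshold CSF R1 upper bound, 1/s (default 0.6).
#' @param closingIter closing iterations for the intracranial mask.
#' @return list of logical arrays: \code{parenchyma}, \code{csf},
#'   \code{intracranial}.
#' @export
tissueMasks <- function(maps, pdThreshold = 85, r1Threshold = 0.6,
                        closingIter = 2L) {
  fg <- maps@valid & is.finite(maps@PD) & maps@PD > 1
  if (!any(fg)) stop("empty intracranial mask: no fitted foreground voxels")
  icv <- largestComponent(closing3d(fg, closingIter)) & fg
  if (!any(icv)) stop("empty intracranial mask")
  csf <- icv & maps@PD > pdThreshold & maps@R1 < r1Threshold
  csf[is.na(csf)] <- FALSE
  parenchyma <- icv & !csf
  list(parenchyma = parenchyma, csf = csf, intracranial = icv)
}

#' Brain parenchymal and lateral ventricle volume fractions
#'
#' BPF = 100 * |parenchyma| / |intracranial|; LVF = 100 * |ventricles| /
#' |intracranial|. Voxel volume cancels, so the fractions are computed on
#' voxel counts.
#'
#' @param parenchyma,ventricles,intracranial logical arrays on one grid.
#' @return list with \code{BPF} and \code{LVF}, in percent.
#' @export
volumeFractions <- function(parenchyma, ventricles, intracranial) {
  nIcv <- sum(intracranial)
  if (nIcv == 0L) stop("empty intracranial mask")
  if (any(ventricles & !intracranial))
    stop("ventricle mask must lie inside the intracranial mask")
  list(BPF = 100 * sum(parenchyma & intracranial) / nIcv,
       LVF = 100 * sum(ventricles) / nIcv)
}
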