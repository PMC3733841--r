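## Digital brain phantom: parametric-geometric anatomy (nested folded
## ellipsoids), ground-truth quantitative maps, simulated acquisitions, and
## whole cohorts with between-subject variation, so every pipeline stage can
## be exercised and validated without patient data.

#' Default tissue classes of the phantom
#'
#' Tissue-class R1/R2/PD means and between-subject SDs (rates in 1/s, PD in
#' percent of pure water), seeded from published in-vivo reference values
#' for healthy adults. The subarachnoid CSF shell shares the ventricular
#' CSF values.
#'
#' @return data.frame: code, name, r1, r2, pd, sdR1, sdR2, sdPD.
#' @export
defaultTissueClasses <- function() {
  data.frame(
    code = 1:7,
    name = c("white_matter", "cortical_gray", "thalamus", "caudate",
             "putamen", "lateral_ventricles", "csf"),
    r1  = c(1.38, 1.04, 1.33, 1.00, 1.25, 0.38, 0.38),
    r2  = c(11.79, 9.87, 12.81, 10.61, 13.07, 3.89, 3.89),
    pd  = c(70.0, 75.1, 72.5, 80.3, 75.2, 94.3, 94.3),
    sdR1 = c(0.05, 0.09, 0.07, 0.15, 0.05, 0.32, 0.32),
    sdR2 = c(0.26, 0.44, 0.21, 1.51, 0.42, 2.35, 2.35),
    sdPD = c(1.0, 2.4, 1.9, 2.8, 1.6, 8.8, 8.8))
}

LESION_CODE <- 8L

#' Specify a digital brain phantom
#'
#' @param dim integer(3) grid size (default 48 x 58 x 44).
#' @param spacing voxel size in mm (default 2, isotropic).
#' @param classes tissue table as \code{\link{defaultTissueClasses}}.
#' @param ventricleFraction target lateral-ventricle / intracranial volume
#'   fraction (default 0.011); the ventricle ellipsoid radii are solved from
#'   it analytically.
#' @param foldAmplitude relative amplitude of the sinusoidal cortical
#'   folding (default 0.06).
#' @param textureFraction voxelwise within-tissue variability, as a fraction
#'   of each class's between-subject SD (default 0.5).
#' @param lesions NULL or list(n, radiusRange (mm), effect = c(dR1, dR2,
#'   dPD)): white-matter lesions with, by default, MS-like contrast
#'   (R1 and R2 decreased, PD increased relative to white matter).
#' @return a \linkS4class{PhantomSpec}.
#' @examples
#' spec <- phantomSpec(dim = c(24, 28, 22), spacing = 4)
#' ph <- makePhantom(spec, seed = 7)
#' table(ph$labels@labels)[1:3]
#' @export
phantomSpec <- function(dim = c(48L, 58L, 44L), spacing = 2,
                        classes = defaultTissueClasses(),
                        ventricleFraction = 0.011, foldAmplitude = 0.06,
                        textureFraction = 0.5, lesions = NULL) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (!is.null(lesions)) {
    lesions <- utils::modifyList(
      list(n = 4L, radiusRange = c(4, 7),
           effect = c(dR1 = -0.35, dR2 = -3.0, dPD = 10)), lesions)
  }
  new("PhantomSpec", dim = as.integer(dim), spacing = as.numeric(spacing),
      classes = classes, ventricleFraction = ventricleFraction,
      foldAmplitude = foldAmplitude, textureFraction = textureFraction,
      lesions = lesions)
}

## Normalized ellipsoid "radius" of world points for semi-axes ax, centre ct.
ellipsoidRho <- function(W, ct, ax) {
  u <- (W[1, ] - ct[1]) / ax[1]
  v <- (W[2, ] - ct[2]) / ax[2]
  w <- (W[3, ] - ct[3]) / ax[3]
  list(rho = sqrt(u^2 + v^2 + w^2), u = u, v = v, w = w)
}

#' Generate a phantom: label volume and ground-truth maps
#'
#' Builds the anatomy (folded cortical shell over a white-matter core, deep
#' grey nuclei, ventricles sized to the spec's target fraction, subarachnoid
#' CSF shell, optional white-matter lesions; overlaps resolved by the fixed
#' priority ventricles > deep nuclei > lesions > white matter > cortex >
#' CSF shell) and assigns each labeled voxel its class's (R1, R2, PD).
#' With \code{vary = TRUE}, class values are drawn per subject from the
#' between-subject SDs, and voxelwise texture (spec's
#' \code{textureFraction}) is added; draws are truncated to physiological
#' ranges. Deterministic given \code{seed}; the label volume doubles as the
#' ROI atlas for regional statistics.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param seed integer seed for the subject-level draws.
#' @param vary draw class values from the between-subject distribution
#'   (FALSE gives the canonical phantom at the class means, no texture).
#' @param classOffsets optional data.frame(className, parameter, offset)
#'   of additive shifts (used for injected age trends).
#' @return list: \code{labels} (\linkS4class{LabelAtlas}), \code{maps}
#'   (ground-truth \linkS4class{QuantMaps}, PD in percent), \code{classValues}
#'   (the values actually assigned), \code{icvMask}.
#' @export
makePhantom <- function(spec, seed = NULL, vary = !is.null(seed),
                        classOffsets = NULL) {
  geom <- makeGeometry(spec@dim, spec@spacing)
  W <- worldGrid(geom)
  dims <- geom@dim
  nVox <- prod(dims)

  brainAx <- c(33, 41, 30)
  e <- ellipsoidRho(W, c(0, 0, 0), brainAx)
  theta <- atan2(e$v, e$u)
  phi <- atan2(e$w, sqrt(e$u^2 + e$v^2))
  R <- 1 + spec@foldAmplitude * sin(6 * theta) * cos(3 * phi)
  gmOuter <- e$rho < R
  wmCore <- e$rho < 0.80 * R
  icv <- e$rho < 1.10 * R

  lab <- integer(nVox)
  lab[icv] <- 7L                    # subarachnoid CSF shell
  lab[gmOuter] <- 2L                # cortical ribbon
  lab[wmCore] <- 1L                 # white matter core

  ## ventricles solved to the target fraction of the analytic ICV
  icvVol <- sum(icv) * prod(spec@spacing)
  ratios <- c(1, 2.4, 1.1)
  s3 <- (spec@ventricleFraction / 2) * icvVol / (4 / 3 * pi * prod(ratios))
  vs <- s3^(1 / 3)
  ventAx <- ratios * vs
  deep <- list(
    list(code = 3L, centers = list(c(9, -8, 1), c(-9, -8, 1)),
         ax = c(6, 9, 6)),                                   # thalamus
    list(code = 4L, centers = list(c(11, 6, 6), c(-11, 6, 6)),
         ax = c(4, 9, 4)),                                   # caudate
    list(code = 5L, centers = list(c(19, 0, 0), c(-19, 0, 0)),
         ax = c(5, 9, 5)))                                   # putamen

  lesionMask <- logical(nVox)
  if (!is.null(spec@lesions)) {
    les <- spec@lesions
    wmIdx <- which(lab == 1L)
    drawn <- withSeed(if (is.null(seed)) 1L else childSeed(seed, 91L), {
      centers <- W[, sample(wmIdx, les$n), drop = FALSE]
      radii <- stats::runif(les$n, les$radiusRange[1], les$radiusRange[2])
      list(centers = centers, radii = radii)
    })
    for (i in seq_len(les$n)) {
      d2 <- colSums((W - drawn$centers[, i])^2)
      lesionMask <- lesionMask | d2 < drawn$radii[i]^2
    }
    lesionMask <- lesionMask & lab == 1L   # lesions live in white matter
    lab[lesionMask] <- LESION_CODE
  }

  for (st in deep)
    for (ct in st$centers)
      lab[ellipsoidRho(W, ct, st$ax)$rho < 1 & lab %in% c(1L, 2L, LESION_CODE)] <- st$code
  for (ct in list(c(7, -2, 2), c(-7, -2, 2)))
    lab[ellipsoidRho(W, ct, ventAx)$rho < 1] <- 6L

  ## class values: means, optional subject draw, optional injected offsets
  cl <- spec@classes
  vals <- cl[, c("r1", "r2", "pd")]
  if (vary) {
    z <- withSeed(childSeed(if (is.null(seed)) 1L else seed, 17L),
                  matrix(stats::rnorm(nrow(cl) * 3), nrow(cl), 3))
    vals$r1 <- cl$r1 + cl$sdR1 * z[, 1]
    vals$r2 <- cl$r2 + cl$sdR2 * z[, 2]
    vals$pd <- cl$pd + cl$sdPD * z[, 3]
  }
  if (!is.null(classOffsets)) {
    for (i in seq_len(nrow(classOffsets))) {
      ci <- match(classOffsets$className[i], cl$name)
      if (is.na(ci)) stop("unknown class in classOffsets: ",
                          classOffsets$className[i])
      p <- classOffsets$parameter[i]
      vals[[p]][ci] <- vals[[p]][ci] + classOffsets$offset[i]
    }
  }
  vals$r1 <- pmax(vals$r1, 0.05)
  vals$r2 <- pmax(vals$r2, 0.5)
  vals$pd <- pmin(pmax(vals$pd, 5), 115)
  ## lesion = (possibly drawn) white matter plus the lesion effect
  wmRow <- match("white_matter", cl$name)
  lesVals <- c(vals$r1[wmRow], vals$r2[wmRow], vals$pd[wmRow])
  if (!is.null(spec@lesions))
    lesVals <- pmax(lesVals + spec@lesions$effect, c(0.05, 0.5, 5))

  R1 <- R2 <- PD <- rep(NaN, nVox)
  for (ci in seq_len(nrow(cl))) {
    sel <- lab == cl$code[ci]
    R1[sel] <- vals$r1[ci]; R2[sel] <- vals$r2[ci]; PD[sel] <- vals$pd[ci]
  }
  sel <- lab == LESION_CODE
  R1[sel] <- lesVals[1]; R2[sel] <- lesVals[2]; PD[sel] <- lesVals[3]

  if (vary && spec@textureFraction > 0) {
    sdv <- list(r1 = "sdR1", r2 = "sdR2", pd = "sdPD")
    tex <- withSeed(childSeed(if (is.null(seed)) 1L else seed, 23L),
                    matrix(stats::rnorm(nVox * 3), nVox, 3))
    sdMapR1 <- sdMapR2 <- sdMapPD <- rep(0, nVox)
    for (ci in seq_len(nrow(cl))) {
      sel <- lab == cl$code[ci]
      sdMapR1[sel] <- cl$sdR1[ci]; sdMapR2[sel] <- cl$sdR2[ci]
      sdMapPD[sel] <- cl$sdPD[ci]
    }
    sel <- lab == LESION_CODE
    sdMapR1[sel] <- cl$sdR1[wmRow]; sdMapR2[sel] <- cl$sdR2[wmRow]
    sdMapPD[sel] <- cl$sdPD[wmRow]
    f <- spec@textureFraction
    R1 <- pmax(R1 + f * sdMapR1 * tex[, 1], 0.05)
    R2 <- pmax(R2 + f * sdMapR2 * tex[, 2], 0.5)
    PD <- pmin(pmax(PD + f * sdMapPD * tex[, 3], 5), 115)
  }

  valid <- lab > 0L
  mk <- function(x) array(x, dims)
  fq <- rep(NaN, nVox); fq[valid] <- 0
  tab <- rbind(cl[, c("code", "name")],
               data.frame(code = LESION_CODE, name = "lesion"))
  maps <- new("QuantMaps", R1 = mk(R1), R2 = mk(R2), PD = mk(PD),
              valid = mk(valid), fitQuality = mk(fq), geometry = geom,
              pdUnit = "percent")
  list(labels = labelAtlas(mk(lab), tab, geom), maps = maps,
       classValues = cbind(cl[, c("code", "name")], vals),
       icvMask = mk(icv))
}

#' The canonical template: noise-free synthetic T2w of the mean phantom
#'
#' Regenerated deterministically in code (it is a synthetic stand-in for a
#' population template, at 2 mm by default). A user-supplied template can be
#' used anywhere this one is accepted.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param targetSpacing output grid spacing for normalized maps, mm.
#' @return a \linkS4class{TemplateSpace}.
#' @export
defaultTemplate <- function(spec = phantomSpec(), targetSpacing = 2) {
  ph <- makePhantom(spec, vary = FALSE)
  templateSpace(synthesize(ph$maps), ph$maps@geometry, targetSpacing)
}

#' Simulate a multi-delay multi-echo acquisition of ground-truth maps
#'
#' Evaluates the saturation-recovery spin-echo forward model at every
#' (delay, echo) of the protocol — 20 images per slice at the default 4 x 5
#' protocol — using the maps' PD as the equilibrium magnetization, and adds
#' acquisition noise: additive Gaussian (clipped at zero, magnitude data) or
#' Rician (\code{sqrt((S + n1)^2 + n2^2)}). Seeded and reproducible.
#'
#' @param maps ground-truth \linkS4class{QuantMaps}.
#' @param protocol an \linkS4class{AcquisitionProtocol}.
#' @param noiseSigma noise SD in signal units (>= 0).
#' @param noiseModel \code{"gaussian"} or \code{"rician"}.
#' @param seed integer seed.
#' @return an \linkS4class{AcquisitionSeries}.
#' @export
simulateAcquisition <- function(maps, protocol = defaultProtocol(),
                                noiseSigma = 0,
                                noiseModel = c("gaussian", "rician"),
                                seed = NULL) {
  noiseModel <- match.arg(noiseModel)
  if (noiseSigma < 0) stop("noiseSigma must be nonnegative")
  td <- protocol@saturationDelays
  te <- protocol@echoTimes
  nd <- length(td); ne <- length(te)
  dims <- maps@geometry@dim
  R1 <- as.vector(maps@R1); R2 <- as.vector(maps@R2); M0 <- as.vector(maps@PD)
  bad <- !as.vector(maps@valid) | !is.finite(R1)
  R1[bad] <- 0; R2[bad] <- 0; M0[bad] <- 0
  nVox <- prod(dims)
  data <- array(0, c(nd, ne, dims))
  block <- matrix(0, nd * ne, nVox)
  for (d in seq_len(nd)) for (e2 in seq_len(ne))
    block[d + (e2 - 1L) * nd, ] <- modelSignal(R1, R2, M0, td[d], te[e2])
  if (noiseSigma > 0) {
    block <- withSeed(seed, {
      if (noiseModel == "gaussian") {
        pmax(block + stats::rnorm(length(block), sd = noiseSigma), 0)
      } else {
        n1 <- stats::rnorm(length(block), sd = noiseSigma)
        n2 <- stats::rnorm(length(block), sd = noiseSigma)
        sqrt((block + n1)^2 + n2^2)
      }
    })
  }
  dim(block) <- c(nd, ne, dims)
  acquisitionSeries(block, protocol, maps@geometry)
}

#' Specify a simulated cohort
#'
#' @param n number of subjects (default 31).
#' @param ageRange,ageMean,ageSd age distribution in years (truncated
#'   normal; defaults 26-67, 45, 11).
#' @param jitterSd anatomical affine jitter SDs: \code{trans} (mm),
#'   \code{rot} (radians), \code{zoom}, \code{shear}. Zero by default for
#'   cohorts used to validate the deviation statistics on a common grid.
#' @param slopes NULL or data.frame(className, parameter ("r1","r2","pd"),
#'   slopePerYear): injected linear age trends, centred on \code{ageMean}.
#' @param noiseSigma acquisition noise SD in signal (PD-percent) units;
#'   default 0.7, about 1% of the white-matter M0.
#' @param noiseModel "gaussian" or "rician".
#' @param seed master seed; every per-subject draw derives from it.
#' @return a \linkS4class{CohortSpec}.
#' @export
cohortSpec <- function(n = 31L, ageRange = c(26, 67), ageMean = 45,
                       ageSd = 11,
                       jitterSd = c(trans = 0, rot = 0, zoom = 0, shear = 0),
                       slopes = NULL, noiseSigma = 0.7,
                       noiseModel = "gaussian", seed = 1L) {
  js <- c(trans = 0, rot = 0, zoom = 0, shear = 0)
  js[names(jitterSd)] <- jitterSd
  new("CohortSpec", n = as.integer(n), ageRange = as.numeric(ageRange),
      ageMean = ageMean, ageSd = ageSd, jitterSd = js, slopes = slopes,
      noiseSigma = noiseSigma, noiseModel = noiseModel,
      seed = as.integer(seed))
}

#' Generate a simulated cohort
#'
#' Per subject: draw an age and tissue values (between-subject variation,
#' plus any injected age trends), apply a random affine anatomical jitter to
#' the phantom anatomy, optionally simulate the acquisition, and keep the
#' ground truth for recovery testing. With \code{outDir} set, writes each
#' subject's series (NIfTI + protocol sidecar), truth maps and labels, and a
#' cohort CSV. Fully reproducible from the cohort spec's master seed.
#'
#' @param pspec a \linkS4class{PhantomSpec}.
#' @param cspec a \linkS4class{CohortSpec}.
#' @param protocol acquisition protocol for simulation.
#' @param simulate simulate the acquisition series per subject.
#' @param outDir optional output directory.
#' @return list: \code{table} (data.frame subject_id, age_years, sex,
#'   maps_prefix), \code{subjects} (list with per-subject \code{maps}
#'   (truth), \code{labels}, \code{jitter}, \code{age}, \code{sex}, and
#'   \code{series} when simulated).
#' @export
makeCohort <- function(pspec, cspec, protocol = defaultProtocol(),
                       simulate = TRUE, outDir = NULL) {
  n <- cspec@n
  subjects <- vector("list", n)
  ids <- sprintf("sub%03d", seq_len(n))
  ages <- numeric(n)
  sexes <- rep(c("F", "M"), length.out = n)
  geom <- makeGeometry(pspec@dim, pspec@spacing)
  for (i in seq_len(n)) {
    sseed <- childSeed(cspec@seed, i)
    age <- withSeed(childSeed(sseed, 1L), {
      a <- stats::rnorm(1, cspec@ageMean, cspec@ageSd)
      min(max(a, cspec@ageRange[1]), cspec@ageRange[2])
    })
    ages[i] <- age
    offsets <- NULL
    if (!is.null(cspec@slopes)) {
      offsets <- data.frame(className = cspec@slopes$className,
                            parameter = cspec@slopes$parameter,
                            offset = cspec@slopes$slopePerYear *
                              (age - cspec@ageMean))
    }
    ph <- makePhantom(pspec, seed = childSeed(sseed, 2L), vary = TRUE,
                      classOffsets = offsets)
    js <- cspec@jitterSd
    jitter <- withSeed(childSeed(sseed, 3L), affineTransform(
      translation = stats::rnorm(3, 0, js["trans"]),
      rotation = stats::rnorm(3, 0, js["rot"]),
      zoom = exp(stats::rnorm(3, 0, js["zoom"])),
      shear = stats::rnorm(3, 0, js["shear"])))
    maps <- ph$maps
    labels <- ph$labels
    if (any(js > 0)) {
      warp <- function(v, interp) applyTransform(v, geom, jitter, geom, interp)
      lab <- warp(array(as.numeric(labels@labels), geom@dim), "nearest")
      lab[!is.finite(lab)] <- 0
      storage.mode(lab) <- "integer"
      R1 <- warp(maps@R1, "trilinear"); R2 <- warp(maps@R2, "trilinear")
      PD <- warp(maps@PD, "trilinear"); fq <- warp(maps@fitQuality, "trilinear")
      valid <- lab > 0L & is.finite(R1) & is.finite(R2) & is.finite(PD)
      R1[!valid] <- NaN; R2[!valid] <- NaN; PD[!valid] <- NaN; fq[!valid] <- NaN
      maps <- new("QuantMaps", R1 = R1, R2 = R2, PD = PD, valid = valid,
                  fitQuality = fq, geometry = geom, pdUnit = "percent")
      labels <- labelAtlas(lab, labels@table, geom)
    }
    subj <- list(id = ids[i], age = age, sex = sexes[i], maps = maps,
                 labels = labels, jitter = jitter,
                 classValues = ph$classValues)
    if (simulate)
      subj$series <- simulateAcquisition(maps, protocol,
                                         noiseSigma = cspec@noiseSigma,
                                         noiseModel = cspec@noiseModel,
                                         seed = childSeed(sseed, 4L))
    subjects[[i]] <- subj
  }
  prefixes <- rep(NA_character_, n)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      pre <- file.path(outDir, ids[i])
      writeQuantMaps(subjects[[i]]$maps, paste0(pre, "_truth"))
      writeLabelAtlas(subjects[[i]]$labels, paste0(pre, "_labels"))
      writeAffineTransform(subjects[[i]]$jitter, paste0(pre, "_jitter.json"))
      if (simulate)
        writeAcquisitionSeries(subjects[[i]]$series, paste0(pre, "_series"))
      prefixes[i] <- pre
    }
    ## prefixes inside the CSV are relative to the directory, so a cohort
    ## directory is byte-identical across runs and relocatable
    tab <- data.frame(subject_id = ids, age_years = ages, sex = sexes,
                      maps_prefix = ids)
    utils::write.csv(tab, file.path(outDir, "cohort.csv"), row.names = FALSE)
  }
  list(table = data.frame(subject_id = ids, age_years = ages, sex = sexes,
                          maps_prefix = prefixes),
       subjects = subjects)
}
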