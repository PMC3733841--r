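test_that("ROI means summarize valid voxels per region", {
  ph <- tinyPhantom()
  ## uniform map: every ROI mean equals the constant
  g <- geometry(ph$maps)
  uni <- ph$maps
  uni@R1[uni@valid] <- 0.9
  tab <- roiMeans(uni, ph$labels)
  expect_true(all(abs(tab$R1[!tab$empty] - 0.9) < 1e-12))
  ## phantom truth: WM-ROI means equal the class values
  tab <- roiMeans(ph$maps, ph$labels)
  wm <- tab[tab$name == "white_matter", ]
  expect_equal(wm$R1, 1.38, tolerance = 1e-9)
  expect_equal(wm$R2, 11.79, tolerance = 1e-9)
  expect_equal(wm$PD, 70.0, tolerance = 1e-9)
  ## empty ROI flagged, not dropped
  expect_true("lesion" %in% tab$name)
  expect_true(tab$empty[tab$name == "lesion"])
  expect_true(is.na(tab$R1[tab$name == "lesion"]))
  ## single-voxel ROI returns that voxel's value
  lab2 <- ph$labels@labels
  vox <- which(lab2 == 1L)[1]
  lab2[vox] <- 99L
  atl2 <- labelAtlas(lab2, rbind(ph$labels@table,
                                 data.frame(code = 99L, name = "probe")), g)
  tab2 <- roiMeans(ph$maps, atl2)
  expect_equal(tab2$R1[tab2$name == "probe"], r1Map(ph$maps)[vox])
  expect_equal(tab2$nVoxels[tab2$name == "probe"], 1L)
})

test_that("ROI means are invariant under label permutations", {
  ph <- tinyPhantom()
  perm <- c(5L, 3L, 1L, 2L, 4L, 7L, 6L, 8L)
  lab <- ph$labels@labels
  relab <- array(0L, dim(lab))
  for (i in seq_along(perm)) relab[lab == i] <- perm[i]
  tabPerm <- data.frame(code = perm[ph$labels@table$code],
                        name = ph$labels@table$name)
  atlPerm <- labelAtlas(relab, tabPerm, geometry(ph$maps))
  t1 <- roiMeans(ph$maps, ph$labels)
  t2 <- roiMeans(ph$maps, atlPerm)
  for (nm in t1$name[!t1$empty])
    expect_equal(t2$R1[t2$name == nm], t1$R1[t1$name == nm],
                 tolerance = 1e-12)
})

test_that("cohort table regression behaves like OLS", {
  ph <- tinyPhantom()
  subs <- list(ph$maps, ph$maps, ph$maps, ph$maps)
  ages <- c(30, 40, 50, 60)
  tab <- cohortRoiTable(subs, ages, ph$labels)
  wm <- tab[tab$name == "white_matter" & tab$parameter == "R1", ]
  ## identical maps with varying ages: slope 0, p ~ 1, sd 0
  expect_equal(wm$slope, 0, tolerance = 1e-12)
  expect_equal(wm$sd, 0)
  ## slope is invariant under shifting all ages by a constant
  slopes <- data.frame(className = "white_matter", parameter = "r1",
                       slopePerYear = -0.004)
  cs <- cohortSpec(n = 8, slopes = slopes, noiseSigma = 0, seed = 77)
  coh <- makeCohort(tinySpec(), cs, simulate = FALSE)
  maps <- lapply(coh$subjects, `[[`, "maps")
  ages <- vapply(coh$subjects, `[[`, numeric(1), "age")
  t1 <- cohortRoiTable(maps, ages, coh$subjects[[1]]$labels)
  t2 <- cohortRoiTable(maps, ages + 13, coh$subjects[[1]]$labels)
  r1 <- t1[t1$name == "white_matter" & t1$parameter == "R1", ]
  r2 <- t2[t2$name == "white_matter" & t2$parameter == "R1", ]
  expect_equal(r1$slope, r2$slope, tolerance = 1e-10)
  ## constant ages are flagged, not an exception
  t3 <- cohortRoiTable(subs[1:3], c(40, 40, 40), ph$labels)
  expect_true(all(t3$regression == "constant ages"))
  expect_true(all(is.na(t3$slope)))
  expect_error(cohortRoiTable(subs[1:2], c(30, 40), ph$labels), "at least 3")
})

test_that("tissue masks classify phantom classes correctly", {
  ph <- tinyPhantom()
  tm <- tissueMasks(ph$maps)
  lab <- ph$labels@labels
  ## interior voxels: CSF classes inside the head are CSF, tissue is brain
  interiorAll <- qmapnorm:::erode3d(array(lab > 0L, dim(lab)), 1)
  isCsfClass <- lab %in% c(6L, 7L)
  expect_true(all(tm$csf[interiorAll & isCsfClass]))
  expect_true(all(!tm$csf[interiorAll & !isCsfClass]))
  expect_true(all(tm$parenchyma[interiorAll & !isCsfClass]))
  ## BPF + CSF fraction = 100 by construction
  vent <- array(lab == 6L, dim(lab))
  vf <- volumeFractions(tm$parenchyma, vent, tm$intracranial)
  csfFrac <- 100 * sum(tm$csf) / sum(tm$intracranial)
  expect_equal(vf$BPF + csfFrac, 100, tolerance = 1e-9)
  expect_error(volumeFractions(tm$parenchyma, array(TRUE, dim(lab)),
                               tm$intracranial), "inside")
})

test_that("volume fractions are simple voxel-count ratios", {
  d <- c(6, 6, 6)
  icv <- array(TRUE, d)
  expect_equal(volumeFractions(icv, array(FALSE, d), icv)$BPF, 100)
  half <- array(rep(c(TRUE, FALSE), each = prod(d) / 2), d)
  expect_equal(volumeFractions(half, array(FALSE, d), icv)$BPF, 50)
  expect_equal(volumeFractions(icv & !half, half, icv)$LVF, 50)
  expect_error(volumeFractions(half, half, array(FALSE, d)), "empty")
})

test_that("the phantom ventricle fraction is recovered through the masks", {
  ph <- defaultPhantom()
  tm <- tissueMasks(ph$maps)
  vent <- array(ph$labels@labels == 6L, dim(ph$labels@labels))
  vf <- volumeFractions(tm$parenchyma, vent, tm$intracranial)
  expect_lt(abs(vf$LVF - 1.1), 0.2)
  expect_gt(vf$BPF, 70)
})
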