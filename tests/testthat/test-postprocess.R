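# Atlas construction, ICP registration, bone-area reconstruction,
# cartilage linking and automated correction.

test_that("a single-mask atlas is that surface, centered", {
  ph <- coarsePhantom(1)
  atlas <- buildAtlas(list(ph$mask), "MT")
  srf <- boneAreaSurface(ph$mask, "MT", withNormals = FALSE)
  centered <- sweep(surfacePoints(srf), 2, colMeans(surfacePoints(srf)))
  expect_equal(surfacePoints(atlas), centered, tolerance = 1e-9)
  expect_equal(unname(colMeans(surfacePoints(atlas))), c(0, 0, 0),
               tolerance = 1e-9)
})

test_that("replicated and translated inputs leave the atlas congruent", {
  ph <- coarsePhantom(1)
  ## k identical masks behave like n = 1
  atlas1 <- buildAtlas(list(ph$mask), "LT")
  atlas3 <- buildAtlas(list(ph$mask, ph$mask, ph$mask), "LT")
  expect_equal(surfacePoints(atlas3), surfacePoints(atlas1),
               tolerance = 1e-6)
  ## a translated copy: translation is absorbed by the alignment
  shifted <- ph$mask
  shifted@origin <- shifted@origin + c(5, 0, 0)
  atlas2 <- buildAtlas(list(ph$mask, shifted), "LT")
  d1 <- sort(cartMorph:::crossDist2(surfacePoints(atlas1),
                                    surfacePoints(atlas1))[1, ])
  d2 <- sort(cartMorph:::crossDist2(surfacePoints(atlas2),
                                    surfacePoints(atlas2))[1, ])
  expect_equal(d2, d1, tolerance = 1e-6)
  expect_error(buildAtlas(list(), "MT"), "absent")
})

test_that("ICP on identical clouds returns the identity", {
  ph <- coarsePhantom(1)
  atlas <- buildAtlas(list(ph$mask), "cMF")
  tf <- registerICP(surfacePoints(atlas), atlas)
  expect_lt(tf@residual, 1e-6)
  expect_lt(rotationAngleDeg(tf@rotation), 1e-4)
  expect_lt(sqrt(sum(tf@translation^2)), 1e-6)
})

test_that("ICP recovers known rigid transforms within 0.1 mm / 0.1 deg", {
  ph <- coarsePhantom(1)
  atlas <- buildAtlas(list(ph$mask), "cMF")
  pts <- surfacePoints(atlas)
  for (ang in c(10, -15)) {
    R0 <- rotZ(ang); t0 <- c(3, -2, 1)
    moved <- sweep(tcrossprod(pts, R0), 2, t0, "+")
    tf <- registerICP(moved, atlas)
    ## composed transform must invert the applied one
    compR <- tf@rotation %*% R0
    compT <- as.numeric(tf@rotation %*% t0) + tf@translation
    expect_lt(rotationAngleDeg(compR), 0.1)
    expect_lt(sqrt(sum(compT^2)), 0.1)
  }
})

test_that("ICP recovers transforms from a 60% subset within 0.5 mm RMS", {
  ph <- coarsePhantom(1)
  atlas <- buildAtlas(list(ph$mask), "cMF")
  pts <- surfacePoints(atlas)
  set.seed(42)
  keep <- sample.int(nrow(pts), round(0.6 * nrow(pts)))
  moved <- sweep(tcrossprod(pts[keep, ], rotZ(10)), 2, c(3, -2, 1), "+")
  tf <- registerICP(moved, atlas)
  back <- applyTransform(moved, tf)
  rms <- sqrt(mean(rowSums((back - pts[keep, ])^2)))
  expect_lt(rms, 0.5)
})

test_that("degenerate sources are rejected and residuals never increase", {
  line <- cbind(1:20, 2 * (1:20), 3 * (1:20))
  ph <- coarsePhantom(1)
  atlas <- buildAtlas(list(ph$mask), "MT")
  expect_error(registerICP(line, atlas), "degenerate")
  expect_error(registerICP(line[1:2, ], atlas), "at least 3")
  set.seed(1)
  noisy <- surfacePoints(atlas) + matrix(rnorm(3 * nrow(surfacePoints(atlas)),
                                               0, 0.3), ncol = 3)
  tf <- registerICP(sweep(tcrossprod(noisy, rotZ(8)), 2, c(2, 1, -1), "+"),
                    atlas, icpConfig(trimFactor = Inf))
  expect_true(all(diff(tf@trace) <= 1e-9))
})

test_that("reconstruction adds nothing to a complete surface and never removes points", {
  ph <- coarsePhantom(1)
  atlas <- buildAtlas(list(coarsePhantom(2)$mask), "MT")
  srf <- boneAreaSurface(ph$mask, "MT", withNormals = FALSE)
  tf <- registerICP(srf, atlas)
  rec <- reconstructBoneArea(srf, atlas, tf, corrRadius = 1.0)
  expect_gte(nrow(rec@points), nrow(srf@points))
  expect_equal(rec@points[seq_len(nrow(srf@points)), ], srf@points)
  expect_equal(nrow(rec@points), nrow(srf@points))
  expect_error(reconstructBoneArea(
    new("PlateSurface", points = matrix(numeric(), 0, 3), plate = "MT"),
    atlas, tf), "empty")
  expect_error(reconstructBoneArea(
    boneAreaSurface(ph$mask, "LT", withNormals = FALSE), atlas, tf),
    "plate mismatch")
})

test_that("reconstruction fills a 20% hole to within 3% of the full area", {
  ph <- coarsePhantom(1)
  atlas <- buildAtlas(lapply(2:3, function(s) coarsePhantom(s)$mask), "MT")
  full <- boneAreaSurface(ph$mask, "MT", withNormals = FALSE)
  holey <- corruptMask(ph$mask,
                       corruptionConfig(deleteBoneFraction = 0.2,
                                        plates = "MT"),
                       seed = 11, spec = coarseSpec(1))
  partial <- boneAreaSurface(holey, "MT", withNormals = FALSE)
  tf <- registerICP(partial, atlas)
  rec <- reconstructBoneArea(partial, atlas, tf, corrRadius = 0.7)
  expect_equal(nrow(rec@points) / nrow(full@points), 1, tolerance = 0.03)
  ## the hole region is covered: every deleted point has a nearby
  ## reconstructed point
  deleted <- full@points[!(paste(full@points[, 1], full@points[, 2],
                                 full@points[, 3]) %in%
                             paste(partial@points[, 1], partial@points[, 2],
                                   partial@points[, 3])), , drop = FALSE]
  nn <- cartMorph:::nearestNeighbor(deleted, rec@points)
  expect_lt(max(nn$distance), 1.5)
})

test_that("cartilage linking flags covered and denuded extremes", {
  ph <- coarsePhantom(1)
  srf <- boneAreaSurface(ph$mask, "MT")
  linked <- linkCartilage(ph$mask, srf)
  expect_equal(mean(coveredStatus(linked)), 1)
  bare <- ph$mask
  lab <- voxelData(bare); lab[lab == cartLabels()["MT"]] <- 0L
  bare@data <- lab
  linked0 <- linkCartilage(bare, srf)
  expect_equal(mean(coveredStatus(linked0)), 0)
})

test_that("a 10% denuded lesion is detected within a one-voxel band", {
  ph <- memo("lesionPh",
             makePhantom(phantomSpec(lesions = mtLesion(10), seed = 3)))
  srf <- boneAreaSurface(ph$mask, "MT")
  linked <- linkCartilage(ph$mask, srf)
  denPct <- 100 * mean(!coveredStatus(linked))
  an <- ph$summary$dab_pct[ph$summary$region == "MT"]
  ## one-voxel band around the lesion perimeter, as area percentage
  r <- mtLesion(10)$radius
  band <- 100 * (2 * pi * r * max(voxelSpacing(ph$mask))) / (19 * 12.6)
  expect_lt(abs(denPct - an), band)
})

test_that("autocorrect leaves a clean mask identical with an empty log", {
  ph <- coarsePhantom(1)
  ac <- autocorrect(ph$mask, plateSurfaces(ph$mask))
  expect_identical(voxelData(ac$mask), voxelData(ph$mask))
  expect_equal(nrow(ac$log), 0)
})

test_that("small injected fragments are removed and logged individually", {
  ph <- coarsePhantom(1)
  lab <- voxelData(ph$mask)
  ## three 5-voxel fragments in free space away from everything
  spots <- list(c(3, 3, 30), c(8, 3, 32), c(13, 3, 34))
  for (s in spots) {
    lab[s[1] + 0:4, s[2], s[3]] <- cartLabels()["MT"]
  }
  bad <- ph$mask; bad@data <- lab
  expect_equal(componentCount(bad, "MT"), 4)
  ac <- autocorrect(bad, plateSurfaces(bad))
  expect_equal(componentCount(ac$mask, "MT"), 1)
  frag <- ac$log[ac$log$action == "fragment_removed", ]
  expect_equal(nrow(frag), 3)
  expect_equal(frag$voxels, rep(5L, 3))
})

test_that("a narrow slit is closed and thickness there matches its neighbours", {
  spec <- phantomSpec(noiseAmp = 0, apGradient = 0, baseThickness = 2.0,
                      seed = 6)
  ph <- makePhantom(spec)
  cut <- corruptMask(ph$mask, corruptionConfig(gapWidths = 1.5,
                                               plates = "MT"),
                     seed = 3, spec = spec)
  ac <- autocorrect(cut, list(boneAreaSurface(cut, "MT",
                                              withNormals = FALSE)))
  expect_gt(sum(ac$log$voxels[ac$log$action %in%
                                c("gap_closed", "gap_filled")]), 0)
  tm <- computeThickness(ac$mask, boneAreaSurface(ac$mask, "MT"))
  ## slit columns (known from the ground truth) vs the plate at large
  slit <- voxelData(ph$mask) == cartLabels()["MT"] &
    voxelData(cut) != cartLabels()["MT"]
  sIdx <- which(slit, arr.ind = TRUE)
  xr <- range(cartMorph:::indexToWorld(sIdx, voxelSpacing(cut),
                                       voxelOrigin(cut))[, 1])
  inSlit <- surfacePoints(tm)[, 1] >= xr[1] & surfacePoints(tm)[, 1] <= xr[2]
  expect_gt(sum(inSlit), 0)
  expect_equal(mean(thicknessValues(tm)[inSlit]),
               mean(thicknessValues(tm)[!inSlit]), tolerance = 0.05)
})

test_that("autocorrect is idempotent on corrupted masks", {
  ph <- coarsePhantom(1)
  cmask <- corruptMask(ph$mask,
                       corruptionConfig(gapWidths = 1.5, nFragments = 2),
                       seed = 5, spec = coarseSpec(1))
  srfs <- plateSurfaces(cmask)
  a1 <- autocorrect(cmask, srfs)
  a2 <- autocorrect(a1$mask, srfs)
  expect_identical(voxelData(a1$mask), voxelData(a2$mask))
})

test_that("implausibly distant cartilage is cropped", {
  ph <- coarsePhantom(1)
  lab <- voxelData(ph$mask)
  d <- dim(lab)
  lab[2:3, 2:3, d[3] - (1:2)] <- cartLabels()["LT"]  # far from any bone
  bad <- ph$mask; bad@data <- lab
  ac <- autocorrect(bad, list(boneAreaSurface(bad, "LT",
                                              withNormals = FALSE)))
  expect_identical(voxelData(ac$mask), voxelData(ph$mask))
  acts <- ac$log$action
  expect_true(any(acts %in% c("implausible_cropped", "fragment_removed")))
})
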