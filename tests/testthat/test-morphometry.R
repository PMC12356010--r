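# Landmarks, femoral ROI, thickness computation and region summaries.

test_that("detected landmarks match the generator's within one voxel", {
  ph <- dessPhantom(1)
  fem <- detectLandmarks(boneAreaSurface(ph$mask, "femur",
                                         withNormals = FALSE))
  lm <- fem@landmarks
  tol <- max(voxelSpacing(ph$mask))
  expect_lt(sqrt(sum((lm$notch - ph$landmarks$notch)^2)), tol)
  expect_lt(sqrt(sum((lm$posterior - ph$landmarks$posterior)^2)), tol)
})

test_that("landmarks swap AP roles consistently on a rotated surface", {
  ph <- dessPhantom(1)
  fem <- boneAreaSurface(ph$mask, "femur", withNormals = FALSE)
  lm0 <- detectLandmarks(fem)@landmarks
  ## rotate 180 degrees about the vertical axis through the volume center
  ctr <- c(15, 16.5, 0)
  rot <- fem
  rot@points <- cbind(2 * ctr[1] - fem@points[, 1],
                      2 * ctr[2] - fem@points[, 2],
                      fem@points[, 3])
  lm1 <- detectLandmarks(rot)@landmarks
  ## the detected notch of the rotated surface is the rotated posterior end
  expect_lt(abs(lm1$notch[1] - (2 * ctr[1] - lm0$posterior[1])), 0.5)
  expect_lt(abs(lm1$posterior[1] - (2 * ctr[1] - lm0$notch[1])), 0.5)
})

test_that("degenerate surfaces are rejected by landmark detection", {
  tiny <- new("PlateSurface", points = diag(3), plate = "femur")
  expect_error(detectLandmarks(tiny), "too small")
})

test_that("ROI fraction 1 is the identity", {
  ph <- coarsePhantom(1)
  srf <- boneAreaSurface(ph$mask, "cMF", withNormals = FALSE)
  expect_identical(extractFemoralROI(srf, 1), srf)
  expect_error(extractFemoralROI(srf, 0), "\\(0, 1\\]")
  expect_error(extractFemoralROI(srf, 1.2), "\\(0, 1\\]")
})

test_that("ROI trimming keeps the requested area fraction on a uniform slab", {
  ## synthetic uniform-density flat surface with chord landmarks
  g <- expand.grid(x = seq(0, 20, by = 0.25), y = seq(0, 10, by = 0.25))
  srf <- new("PlateSurface", points = cbind(g$x, g$y, 0), plate = "cMF",
             landmarks = list(notch = c(0, 5, 0), posterior = c(20, 5, 0)))
  roi <- extractFemoralROI(srf, 0.6)
  expect_equal(nrow(roi@points) / nrow(srf@points), 0.6, tolerance = 0.02)
})

test_that("ROI(0.6) is nested in ROI(0.75)", {
  ph <- dessPhantom(1)
  srf <- detectLandmarks(boneAreaSurface(ph$mask, "femur",
                                         withNormals = FALSE))
  s1 <- extractFemoralROI(srf, 0.6)
  s2 <- extractFemoralROI(srf, 0.75)
  key <- function(p) paste(p[, 1], p[, 2], p[, 3])
  expect_true(all(key(s1@points) %in% key(s2@points)))
  expect_lt(nrow(s1@points), nrow(s2@points))
})

test_that("with posteriorly thinning cartilage the 60% ROI reads thicker", {
  ## negative AP gradient: posterior cartilage thinner
  spec <- phantomSpec(apGradient = -0.03, noiseAmp = 0, seed = 2)
  s60 <- analyticSummary(spec, roiFraction = 0.60)
  s75 <- analyticSummary(spec, roiFraction = 0.75)
  expect_gt(s60$mean_thickness_mm[s60$region == "cMF"],
            s75$mean_thickness_mm[s75$region == "cMF"])
  ## and the measured pipeline agrees
  ph <- makePhantom(spec)
  m60 <- measureMask(ph$mask, 0.60)
  m75 <- measureMask(ph$mask, 0.75)
  expect_gt(m60$mean_thickness_mm[m60$region == "cMF"],
            m75$mean_thickness_mm[m75$region == "cMF"])
})

test_that("a parallel slab of 2.0 mm cartilage measures 2.00 +/- 0.05 mm", {
  ph <- memo("slab", makePhantom(phantomSpec(noiseAmp = 0, apGradient = 0,
                                             baseThickness = 2.0,
                                             seed = 1)))
  srf <- boneAreaSurface(ph$mask, "MT")
  tm <- computeThickness(ph$mask, srf)
  s <- summarizeThickness(tm, "MT")
  expect_equal(s$mean_thickness_mm, 2.0, tolerance = 0.025)
})

test_that("a hemicylindrical shell measures its radial thickness", {
  ## inner radius 20 mm, outer 22 mm: mean 2.0 mm within 3%
  g <- phantomGeometry()
  g$extent <- c(56, 33, 66)
  g$femurCenter <- c(x = 28, z = 40)
  g$femurRadius <- 20
  g$tibiaZ <- c(2, 8.13)
  g$tibiaX <- c(4, 52); g$plateX <- c(5.5, 50.5)
  spec <- phantomSpec(spacing = c(0.5, 0.8, 0.5), noiseAmp = 0,
                      apGradient = 0, baseThickness = 2.0, geometry = g,
                      seed = 1)
  ph <- makePhantom(spec)
  srf <- boneAreaSurface(ph$mask, "cLF")
  tm <- computeThickness(ph$mask, srf)
  s <- summarizeThickness(tm, "cLF")
  expect_equal(s$mean_thickness_mm, 2.0, tolerance = 0.03)
})

test_that("no cartilage gives an all-zero, fully denuded map", {
  ph <- coarsePhantom(1)
  empty <- ph$mask
  lab <- voxelData(empty)
  lab[lab == cartLabels()["MT"]] <- 0L
  empty@data <- lab
  srf <- boneAreaSurface(empty, "MT")
  tm <- computeThickness(empty, srf)
  expect_true(all(thicknessValues(tm) == 0))
  expect_true(all(!coveredStatus(tm)))
})

test_that("summaries do the thickness-over-tAB arithmetic", {
  g <- expand.grid(x = seq(0, 9.5, by = 0.5), y = seq(0, 9.5, by = 0.5))
  n <- nrow(g)
  half <- seq_len(n) <= n / 2
  tm <- new("ThicknessMap", points = cbind(g$x, g$y, 0),
            thickness = ifelse(half, 2, 0), region = rep("MT", n),
            covered = half)
  s <- summarizeThickness(tm, "MT")
  expect_equal(s$mean_thickness_mm, 1.0, tolerance = 1e-6)
  expect_equal(s$dab_pct, 50, tolerance = 1e-6)
  expect_error(summarizeThickness(tm, "LT"), "not present")
})

test_that("covered and denuded percentages sum to exactly 100", {
  ph <- memo("lesionPh",
             makePhantom(phantomSpec(lesions = mtLesion(10), seed = 3)))
  srf <- boneAreaSurface(ph$mask, "MT")
  tm <- computeThickness(ph$mask, srf)
  w <- cartMorph:::surfaceAreaWeights(surfacePoints(tm))
  covPct <- 100 * sum(w * coveredStatus(tm)) / sum(w)
  s <- summarizeThickness(tm, "MT")
  expect_equal(covPct + s$dab_pct, 100, tolerance = 1e-9)
})

test_that("compartment aggregation adds tibial and femoral thickness", {
  row <- function(region, th) data.frame(knee_id = "k", visit = "BL",
                                         method = "m", region = region,
                                         mean_thickness_mm = th,
                                         dab_pct = 0)
  expect_equal(aggregateCompartment(row("MT", 1.6),
                                    row("cMF", 1.6))$mean_thickness_mm, 3.2)
  expect_equal(aggregateCompartment(row("LT", 0),
                                    row("cLF", 1.9))$mean_thickness_mm, 1.9)
  r <- aggregateCompartment(row("MT", 1.45), row("cMF", 1.76))
  expect_equal(r$mean_thickness_mm, 3.21)
  expect_equal(r$region, "MFTC")
  expect_error(aggregateCompartment(row("MT", 1), row("cLF", 1)),
               "region mismatch")
})

test_that("scaling the phantom geometry scales thickness by the same factor", {
  s <- 1.3
  spec1 <- coarseSpec(seed = 2)
  g <- spec1@geometry
  g2 <- g
  for (nm in c("extent", "tibiaX", "tibiaY", "tibiaZ", "plateX", "medialY",
               "lateralY", "femurRadius", "femurY"))
    g2[[nm]] <- g[[nm]] * s
  g2$femurCenter <- g$femurCenter * s
  spec2 <- phantomSpec(spacing = spec1@spacing * s,
                       baseThickness = spec1@baseThickness * s,
                       noiseAmp = spec1@noiseAmp * s,
                       noiseCorrLength = spec1@noiseCorrLength * s,
                       geometry = g2, seed = 2)
  m1 <- measureMask(makePhantom(spec1)$mask, 0.75)
  m2 <- measureMask(makePhantom(spec2)$mask, 0.75)
  expect_equal(m2$mean_thickness_mm, s * m1$mean_thickness_mm,
               tolerance = 0.002)
})
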