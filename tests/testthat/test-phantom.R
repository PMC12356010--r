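# Synthetic knee generator: analytic ground truth, determinism, corruption.

test_that("constant thickness field gives the analytic slab summary", {
  spec <- phantomSpec(noiseAmp = 0, apGradient = 0, baseThickness = 2.0,
                      seed = 1)
  s <- analyticSummary(spec)
  expect_equal(s$mean_thickness_mm, rep(2.0, 4), tolerance = 1e-12)
  expect_equal(s$dab_pct, rep(0, 4))
})

test_that("a residual-0 lesion covering 10% of MT yields dAB(MT) = 10%", {
  spec <- phantomSpec(lesions = mtLesion(10), seed = 2)
  s <- analyticSummary(spec)
  expect_equal(s$dab_pct[s$region == "MT"], 10, tolerance = 0.05)
  expect_equal(s$dab_pct[s$region != "MT"], rep(0, 3))
})

test_that("analytic mean matches an independent brute-force quadrature", {
  ## oracle: dense midpoint quadrature of the same continuous field,
  ## written out independently of analyticSummary's internals
  spec <- phantomSpec(apGradient = -0.026, seed = 3)
  for (p in c("MT", "cMF")) {
    uMax <- if (p == "MT") 19 else
      cartMorph:::roiArcLength(spec, spec@roiFraction)
    vMax <- 12.6
    ng <- 901
    u <- (seq_len(ng) - 0.5) / ng * uMax
    v <- (seq_len(301) - 0.5) / 301 * vMax
    tot <- 0
    for (vv in v) tot <- tot + sum(fieldThickness(spec, p, u, rep(vv, ng)))
    oracle <- tot / (ng * 301)
    s <- analyticSummary(spec)
    expect_equal(s$mean_thickness_mm[s$region == p], oracle,
                 tolerance = 2e-4)
  }
})

test_that("identical spec and seed give a bit-identical phantom", {
  a <- makePhantom(coarseSpec(seed = 5))
  b <- makePhantom(coarseSpec(seed = 5))
  expect_identical(voxelData(a$mask), voxelData(b$mask))
  expect_identical(voxelData(a$volume), voxelData(b$volume))
  d <- makePhantom(coarseSpec(seed = 6))
  expect_false(identical(voxelData(a$volume), voxelData(d$volume)))
})

test_that("invalid phantom specs are rejected with a message", {
  expect_error(phantomSpec(spacing = c(0, 1, 1)), "spacing")
  expect_error(phantomSpec(lesions = data.frame(plate = "MT", u = 1, v = 1,
                                                radius = 5, residual = 0)),
               "outside plate")
  expect_error(phantomSpec(lesions = data.frame(plate = "MT", u = 9, v = 6,
                                                radius = 2, residual = 1.4)),
               "residual")
  expect_error(phantomSpec(baseThickness = 0.3), "negative")
})

test_that("stored landmarks lie on the femoral bone surface", {
  spec <- phantomSpec(seed = 1)
  lm <- phantomLandmarks(spec)
  g <- spec@geometry
  for (p in lm) {
    r <- sqrt((p[1] - g$femurCenter["x"])^2 + (p[3] - g$femurCenter["z"])^2)
    expect_equal(unname(r), g$femurRadius, tolerance = 1e-9)
  }
  expect_gt(lm$notch[1], lm$posterior[1])  # notch is anterior
})

test_that("zero corruption returns the identical mask", {
  ph <- coarsePhantom(1)
  out <- corruptMask(ph$mask, corruptionConfig(), seed = 3,
                     spec = coarseSpec(1))
  expect_identical(voxelData(out), voxelData(ph$mask))
})

test_that("n fragments add exactly n connected components", {
  ph <- coarsePhantom(1)
  before <- componentCount(ph$mask, "MT")
  out <- corruptMask(ph$mask,
                     corruptionConfig(nFragments = 3, plates = "MT"),
                     seed = 4, spec = coarseSpec(1))
  expect_equal(componentCount(out, "MT"), before + 3)
})

test_that("bone-area deletion removes the requested voxel fraction", {
  ph <- coarsePhantom(1)
  L <- cartLabels()
  n0 <- sum(voxelData(ph$mask) == L["tAB_MT"])
  out <- corruptMask(ph$mask,
                     corruptionConfig(deleteBoneFraction = 0.3,
                                      plates = "MT"),
                     seed = 5, spec = coarseSpec(1))
  n1 <- sum(voxelData(out) == L["tAB_MT"])
  expect_equal(n1, n0 - round(0.3 * n0))
  expect_error(corruptionConfig(deleteBoneFraction = 1.2), "\\[0, 1\\]")
})

test_that("corruption is deterministic under a fixed seed", {
  ph <- coarsePhantom(1)
  cfg <- corruptionConfig(gapWidths = 1.5, nFragments = 2,
                          deleteBoneFraction = 0.2)
  a <- corruptMask(ph$mask, cfg, seed = 9, spec = coarseSpec(1))
  b <- corruptMask(ph$mask, cfg, seed = 9, spec = coarseSpec(1))
  expect_identical(voxelData(a), voxelData(b))
})

test_that("exact-moment cohorts reproduce requested moments to machine precision", {
  tbl <- simulateCohort(cohortSpec(seed = 7), exact = TRUE)
  ch <- changeScores(tbl)
  xp <- ch$delta_um[ch$stratum == "progressor"]
  xr <- ch$delta_um[ch$stratum == "non-progressor"]
  expect_equal(length(xp), 157L)
  expect_equal(mean(xp), -160, tolerance = 1e-10)
  expect_equal(sd(xp), 223, tolerance = 1e-10)
  expect_equal(mean(xr), -8, tolerance = 1e-10)
  expect_equal(sd(xr), 110, tolerance = 1e-10)
})

test_that("zero change and zero noise leave follow-up equal to baseline", {
  spec <- cohortSpec(
    strata = data.frame(name = "flat", n = 20L),
    changeMoments = data.frame(stratum = "flat", region = "MFTC",
                               mean_um = 0, sd_um = 1e-9),
    seed = 3)
  expect_error(validObject(spec), NA)
  tbl <- simulateCohort(spec)
  bl <- tbl$thickness_mm[tbl$visit == "BL"]
  fu <- tbl$thickness_mm[tbl$visit == "24M"]
  expect_equal(fu, bl, tolerance = 1e-10)
})

test_that("stochastic cohorts recover the stratum mean within 2 SE", {
  spec <- cohortSpec(
    strata = data.frame(name = "s", n = 10000L),
    changeMoments = data.frame(stratum = "s", region = "MFTC",
                               mean_um = -100, sd_um = 200),
    seed = 21)
  ch <- changeScores(simulateCohort(spec))
  expect_lt(abs(mean(ch$delta_um) + 100), 2 * 200 / sqrt(10000))
})

test_that("cohort simulation is deterministic and validates its spec", {
  a <- simulateCohort(cohortSpec(seed = 5))
  b <- simulateCohort(cohortSpec(seed = 5))
  expect_identical(a, b)
  expect_error(cohortSpec(strata = data.frame(name = "x", n = 1L)), ">= 2")
  expect_error(cohortSpec(changeMoments = data.frame(
    stratum = "progressor", region = "MFTC", mean_um = 0, sd_um = 0)),
    "> 0")
})

test_that("the FLASH protocol offset shifts both visits additively", {
  cs <- cohortSpec(seed = 2)
  dess <- simulateCohort(cs, protocol = "sagittal-DESS")
  flash <- simulateCohort(cs, protocol = "coronal-FLASH")
  expect_equal(flash$thickness_mm, dess$thickness_mm + 0.15,
               tolerance = 1e-12)
})
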