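# Biomarker qualification statistics: SRM, BCa bootstrap, Cohen's D,
# t-tests, progressor classification, chi-square, cohort report.

affine <- function(x, m, s) (x - mean(x)) / sd(x) * s + m

test_that("SRM reproduces the published progressor values at 2 decimals", {
  set.seed(1)
  x1 <- affine(rnorm(157), -160, 223)
  expect_equal(round(srm(x1), 2), -0.72)
  x2 <- affine(rnorm(157), -181, 245)
  expect_equal(round(srm(x2), 2), -0.74)
  expect_equal(srm(affine(rnorm(50), 0, 5)), 0, tolerance = 1e-12)
})

test_that("SRM is unit-invariant, sign-antisymmetric, and guards degeneracy", {
  set.seed(2)
  for (i in 1:20) {
    x <- rnorm(30, runif(1, -2, 2), runif(1, 0.5, 3))
    expect_equal(srm(x * 1000), srm(x), tolerance = 1e-12)  # um vs mm
    expect_equal(srm(-x), -srm(x), tolerance = 1e-12)
  }
  expect_error(srm(c(1)), "n >= 2")
  expect_error(srm(rep(3, 10)), "standard deviation")
})

test_that("BCa collapses on near-constant samples and guards edge cases", {
  set.seed(21)
  x <- 5 + rnorm(30, 0, 1e-9)
  ci <- bcaCI(x, statistic = mean, seed = 1)
  expect_lt(diff(ci), 1e-6 * abs(mean(x)))
  expect_error(bcaCI(rnorm(5), seed = 1), "n >= 8")
  expect_error(bcaCI(rep(2, 20), seed = 1), "degenerate")
})

test_that("BCa is bit-reproducible under a fixed seed", {
  set.seed(3)
  x <- rnorm(50, -0.4, 1)
  a <- bcaCI(x, srm, nBoot = 500, seed = 11)
  b <- bcaCI(x, srm, nBoot = 500, seed = 11)
  expect_identical(a, b)
})

test_that("BCa approaches the percentile interval for a symmetric statistic", {
  set.seed(4)
  x <- rnorm(400)
  ci <- bcaCI(x, statistic = mean, nBoot = 3000, seed = 5)
  boots <- withr::with_seed(5, {
    idx <- matrix(sample.int(400, 400 * 3000, replace = TRUE), 400, 3000)
    colMeans(matrix(x[idx], 400, 3000))
  })
  perc <- unname(quantile(boots, c(0.025, 0.975)))
  expect_equal(unname(ci), perc, tolerance = 0.15)
})

test_that("BCa agrees with the reference implementation on the same data", {
  skip_if_not_installed("boot")
  set.seed(5)
  x <- rexp(80) - 1.3
  ours <- bcaCI(x, statistic = mean, nBoot = 5000, seed = 2)
  bt <- withr::with_seed(2, boot::boot(x, function(d, i) mean(d[i]),
                                       R = 5000))
  ref <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  expect_equal(unname(ours), ref, tolerance = 0.05)
})

test_that("Cohen's D reproduces the published effect sizes at 2 decimals", {
  expect_equal(round(cohensD(list(meanDiff = -152, sdA = 223, nA = 157,
                                  sdB = 110, nB = 165))$d, 2), -0.87)
  expect_equal(round(cohensD(list(meanDiff = -151, sdA = 245, nA = 157,
                                  sdB = 182, nB = 165))$d, 2), -0.70)
  expect_equal(round(cohensD(list(meanDiff = -196, sdA = 270, nA = 157,
                                  sdB = 203, nB = 165))$d, 2), -0.82)
  ## full-sample comparison
  expect_equal(round(cohensD(list(meanDiff = -166, sdA = 246, nA = 297,
                                  sdB = 111, nB = 303))$d, 2), -0.87)
  ## noncentral-t interval brackets the estimate and matches the published
  ## interval for the manual-segmentation row
  d <- cohensD(list(meanDiff = -152, sdA = 223, nA = 157, sdB = 110,
                    nB = 165))
  expect_equal(round(unname(d$ci), 2), c(-1.10, -0.64))
})

test_that("Cohen's D from raw samples equals its summary-statistics form", {
  set.seed(6)
  a <- rnorm(40, -1, 2); b <- rnorm(55, 0.5, 1.5)
  raw <- cohensD(a, b)
  summ <- cohensD(list(meanDiff = mean(a) - mean(b), sdA = sd(a),
                       nA = 40, sdB = sd(b), nB = 55))
  expect_identical(raw$d, summ$d)
  expect_equal(raw$ci, summ$ci, tolerance = 1e-9)
  expect_equal(cohensD(a, a)$d, 0)
  expect_error(cohensD(rep(1, 5), rep(1, 6)), "pooled SD")
  ## normal approximation stays close to the noncentral-t interval
  nrm <- cohensD(a, b, ciMethod = "normal")
  expect_equal(nrm$ci, raw$ci, tolerance = 0.05)
})

test_that("t-tests behave at the trivial and powered extremes", {
  set.seed(7)
  x <- rnorm(30)
  tt <- tTests(x, x)
  expect_equal(tt$p_between, 1)
  expect_error(tTests(rep(0, 10), rnorm(10)), "zero variance")
  ## at the published group sizes and effect size, power is essentially 1
  a <- affine(rnorm(157), -160, 223)
  b <- affine(rnorm(165), -8, 110)
  expect_lt(tTests(a, b)$p_between, 0.001)
})

test_that("progressor classification applies the loss threshold", {
  r <- classifyProgressors(c(-300, -50, -150, 20), 100)
  expect_equal(sum(r$flags), 2)
  expect_equal(r$proportionPct, 50)
  expect_equal(classifyProgressors(c(-300, -50), 1e9)$proportionPct, 0)
  expect_error(classifyProgressors(c(-1), 0), "positive")
  ## Gaussian tail oracle: P(delta < -100) for N(-160, 223)
  set.seed(8)
  x <- rnorm(1e4, -160, 223)
  p <- classifyProgressors(x, 100)$proportionPct
  expected <- 100 * pnorm((-100 + 160) / 223)
  se <- 100 * sqrt(expected / 100 * (1 - expected / 100) / 1e4)
  expect_lt(abs(p - expected), 2 * se)
})

test_that("chi-square proportions test matches an exact-test oracle", {
  expect_gt(chisqProp(50, 100, 100, 200), 0.95)
  p1 <- chisqProp(100, 157, 40, 165)
  expect_lt(p1, 0.001)
  f1 <- fisher.test(matrix(c(100, 57, 40, 125), 2, 2))$p.value
  expect_lt(f1, 0.001)
  expect_equal(log10(p1), log10(f1), tolerance = 0.2)
  expect_lt(chisqProp(50, 50, 0, 50), 1e-6)
  expect_error(chisqProp(10, 5, 1, 5), "k <= n")
  ## continuity correction is available and more conservative
  expect_gt(chisqProp(8, 20, 3, 20, correct = TRUE),
            chisqProp(8, 20, 3, 20))
})

test_that("the cohort report reproduces the published cells from printed moments", {
  tbl <- simulateCohort(cohortSpec(seed = 11), exact = TRUE)
  rep <- cohortReport(changeScores(tbl), nBoot = 200, seed = 1)
  expect_equal(round(rep$srm_prog, 2), -0.72)
  expect_equal(round(rep$srm_ref, 2), -0.07)
  expect_equal(round(rep$cohens_d, 2), -0.87)
  expect_equal(round(rep$mean_prog_um), -160)
  expect_lt(rep$p_t_between, 0.001)
})

test_that("single-stratum reports fill SRM and leave comparisons empty", {
  ch <- data.frame(knee_id = sprintf("k%02d", 1:20), stratum = "progressor",
                   region = "MFTC", method = "m",
                   delta_um = affine(rnorm(20), -160, 223))
  rep <- cohortReport(ch, nBoot = 100, seed = 2)
  expect_equal(round(rep$srm_prog, 2), -0.72)
  expect_true(is.na(rep$cohens_d))
  expect_true(is.na(rep$p_t_between))
})

test_that("degenerate cells propagate as NA without aborting the table", {
  ch <- data.frame(knee_id = c(sprintf("a%d", 1:10), sprintf("b%d", 1:10)),
                   stratum = rep(c("progressor", "non-progressor"),
                                 each = 10),
                   region = "MFTC", method = "m", delta_um = 0)
  rep <- cohortReport(ch, nBoot = 100, seed = 3)
  expect_equal(nrow(rep), 1)
  expect_true(is.na(rep$srm_prog))
  expect_true(is.na(rep$cohens_d))
  expect_equal(rep$mean_prog_um, 0)
})

test_that("report thresholds are required per region when classification is on", {
  ch <- data.frame(knee_id = sprintf("k%d", 1:24),
                   stratum = rep(c("progressor", "non-progressor"), 12),
                   region = "MFTC", method = "m",
                   delta_um = rnorm(24, -100, 150))
  expect_error(cohortReport(ch, thresholds = c(MT = 50), nBoot = 50,
                            seed = 1), "missing progressor threshold")
  rep <- cohortReport(ch, thresholds = c(MFTC = 100), nBoot = 50, seed = 1)
  expect_false(is.na(rep$pct_prog_prog))
  expect_false(is.na(rep$p_chisq))
})
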