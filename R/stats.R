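# Longitudinal biomarker qualification statistics: standardized response
# mean (SRM) with BCa bootstrap confidence intervals, Cohen's D with a
# noncentral-t confidence interval, paired and two-sample t-tests,
# threshold-based progressor classification, chi-square comparison of
# progressor proportions, and the assembled cohort report.

#' Standardized response mean
#'
#' SRM = mean change divided by the standard deviation of the change over
#' the observation interval (sample SD, n - 1 denominator). Unit-free:
#' invariant under positive rescaling (um vs mm) and antisymmetric under
#' sign flips.
#'
#' @param x Numeric vector of change scores.
#' @return The SRM.
#' @export
#' @examples
#' srm(c(-2, -1, -3, 0))
srm <- function(x) {
  if (length(x) < 2) stop("SRM needs n >= 2")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("SRM undefined: standard deviation of change is 0")
  mean(x) / s
}

#' BCa bootstrap confidence interval
#'
#' Bias-corrected and accelerated bootstrap interval for an arbitrary
#' statistic: the bias correction z0 comes from the bootstrap CDF at the
#' point estimate, the acceleration a from the jackknife skewness, and the
#' percentile endpoints are adjusted accordingly.
#'
#' @param x Numeric sample (n >= 8; the acceleration term needs jackknife
#'   variability).
#' @param statistic Function of a numeric vector returning a scalar
#'   (default \code{\link{srm}}).
#' @param nBoot Bootstrap iterations (default 1000).
#' @param level Confidence level.
#' @param seed Integer seed (reproducible bit-for-bit).
#' @return Named numeric c(lower, upper).
#' @export
bcaCI <- function(x, statistic = srm, nBoot = 1000L, level = 0.95,
                  seed = 1) {
  n <- length(x)
  if (n < 8) stop("BCa interval needs n >= 8")
  if (stats::sd(x) == 0) stop("degenerate (constant) sample")
  t0 <- statistic(x)
  boots <- withSeed(seed, {
    idx <- matrix(sample.int(n, n * nBoot, replace = TRUE), n, nBoot)
    apply(idx, 2, function(i) statistic(x[i]))
  })
  boots <- boots[is.finite(boots)]
  B <- length(boots)
  if (B < 2) stop("all bootstrap replicates degenerate")
  pLess <- (sum(boots < t0) + 0.5 * sum(boots == t0)) / B
  pLess <- min(max(pLess, 1 / (B + 1)), B / (B + 1))
  z0 <- stats::qnorm(pLess)
  jack <- vapply(seq_len(n), function(i) statistic(x[-i]), numeric(1))
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * sum((jm - jack)^2)^1.5
  a <- if (den == 0) 0 else num / den
  alpha <- (1 - level) / 2
  adj <- function(al) {
    z <- z0 + stats::qnorm(al)
    stats::pnorm(z0 + z / (1 - a * z))
  }
  ci <- unname(stats::quantile(boots, c(adj(alpha), adj(1 - alpha)),
                               type = 7, names = FALSE))
  c(lower = ci[1], upper = ci[2])
}

#' Cohen's D effect size with confidence interval
#'
#' D = mean difference divided by the pooled SD (variances weighted by
#' n - 1). The confidence interval inverts the noncentral t distribution
#' (default), or uses the normal approximation for cross-checking.
#'
#' @param a Numeric sample of group A changes, or a named list/vector with
#'   summary statistics \code{meanDiff, sdA, nA, sdB, nB}.
#' @param b Numeric sample of group B (reference) changes; omit when
#'   summaries are given.
#' @param level Confidence level.
#' @param ciMethod "nct" (noncentral t) or "normal".
#' @return List with \code{d}, \code{ci} (lower, upper), \code{nA},
#'   \code{nB}.
#' @export
#' @examples
#' cohensD(list(meanDiff = -152, sdA = 223, nA = 157, sdB = 110, nB = 165))$d
cohensD <- function(a, b = NULL, level = 0.95, ciMethod = c("nct", "normal")) {
  ciMethod <- match.arg(ciMethod)
  if (is.list(a) || (!is.null(names(a)) && "meanDiff" %in% names(a))) {
    s <- as.list(a)
    meanDiff <- s$meanDiff; sdA <- s$sdA; nA <- s$nA; sdB <- s$sdB; nB <- s$nB
  } else {
    if (is.null(b)) stop("need either two samples or summary statistics")
    meanDiff <- mean(a) - mean(b)
    sdA <- stats::sd(a); nA <- length(a)
    sdB <- stats::sd(b); nB <- length(b)
  }
  if (nA < 2 || nB < 2) stop("Cohen's D needs n >= 2 per group")
  sp2 <- ((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / (nA + nB - 2)
  if (sp2 <= 0) stop("Cohen's D undefined: pooled SD is 0")
  d <- meanDiff / sqrt(sp2)
  nTilde <- nA * nB / (nA + nB)
  if (ciMethod == "normal") {
    se <- sqrt(1 / nTilde + d^2 / (2 * (nA + nB)))
    z <- stats::qnorm(1 - (1 - level) / 2)
    ci <- c(d - z * se, d + z * se)
  } else {
    tObs <- d * sqrt(nTilde)
    df <- nA + nB - 2
    ncpBound <- function(p) {
      ## pt() warns about reduced precision at large noncentrality; the
      ## residual error is far below the interval's own resolution
      f <- function(ncp) suppressWarnings(stats::pt(tObs, df, ncp)) - p
      lo <- tObs - 10 - 10 * abs(tObs)
      hi <- tObs + 10 + 10 * abs(tObs)
      stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
    }
    ci <- c(ncpBound(1 - (1 - level) / 2), ncpBound((1 - level) / 2)) /
      sqrt(nTilde)
  }
  list(d = d, ci = c(lower = ci[1], upper = ci[2]), nA = nA, nB = nB)
}

#' Within- and between-group t-tests on change scores
#'
#' The within-group test is the paired t-test of follow-up against baseline
#' (equivalently a one-sample t-test of the change scores against zero);
#' the between-group test compares the two groups' changes (Welch by
#' default). Both are reported.
#'
#' @param a,b Numeric vectors of change scores.
#' @param varEqual Use the pooled-variance two-sample test.
#' @return List: p_within_a, p_within_b, p_between.
#' @export
tTests <- function(a, b, varEqual = FALSE) {
  if (length(a) < 2 || length(b) < 2) stop("t-tests need n >= 2 per group")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("t-test undefined: zero variance in a group")
  list(p_within_a = stats::t.test(a)$p.value,
       p_within_b = stats::t.test(b)$p.value,
       p_between = stats::t.test(a, b, var.equal = varEqual)$p.value)
}

#' Classify individual progressor knees by a change threshold
#'
#' A knee is a progressor when its thickness loss exceeds the smallest
#' detectable change: change < -threshold. Gain is never progression.
#' Thresholds are test--retest derived and region specific; they are a
#' required input, the package ships no authoritative values.
#'
#' @param delta Numeric change scores (um).
#' @param threshold Positive threshold (um).
#' @return List: \code{flags} (logical) and \code{proportionPct}.
#' @export
#' @examples
#' classifyProgressors(c(-300, -50, -150, 20), 100)
classifyProgressors <- function(delta, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0)
    stop("threshold must be a single positive number")
  flags <- delta < -threshold
  list(flags = flags, proportionPct = 100 * mean(flags))
}

#' Chi-square test for a difference in proportions
#'
#' 2 x 2 chi-square test (without continuity correction by default) that
#' the progressor proportion differs between two cohorts.
#'
#' @param kA,nA Progressor count and size of cohort A.
#' @param kB,nB Progressor count and size of cohort B.
#' @param correct Apply Yates continuity correction.
#' @return p-value.
#' @export
chisqProp <- function(kA, nA, kB, nB, correct = FALSE) {
  if (kA > nA || kB > nB || min(kA, kB) < 0 || min(nA, nB) <= 0)
    stop("counts must satisfy 0 <= k <= n, n > 0")
  tabl <- matrix(c(kA, nA - kA, kB, nB - kB), 2, 2)
  suppressWarnings(stats::chisq.test(tabl, correct = correct)$p.value)
}

ciFmt <- function(est, lo, hi) c(est = est, lower = lo, upper = hi)

#' Assemble a cohort change-statistics report
#'
#' For every region and method in the change table, computes the full set of
#' group-level change statistics: per-group mean change with t-interval,
#' between-group mean difference with interval, Cohen's D with noncentral-t
#' interval, per-group SRM with BCa bootstrap interval, per-group progressor
#' percentage (when thresholds are given), the between-group t-test p-value
#' and the chi-square p-value for progressor proportions. Failures of
#' individual statistics are propagated as NA cells; the table is always
#' emitted.
#'
#' @param changes data.frame with columns knee_id, stratum, region, method,
#'   delta_um (see \code{\link{changeScores}}).
#' @param progressorStratum,referenceStratum Stratum names; Cohen's D is
#'   progressor vs reference.
#' @param thresholds Named numeric vector of per-region progressor
#'   thresholds (um), or NULL to skip classification.
#' @param nBoot Bootstrap iterations for SRM intervals.
#' @param level Confidence level.
#' @param seed Integer seed for the bootstrap.
#' @return Long data.frame, one row per region x method, with columns for
#'   each statistic (est/lower/upper triplets where applicable).
#' @export
cohortReport <- function(changes, progressorStratum = "progressor",
                         referenceStratum = "non-progressor",
                         thresholds = NULL, nBoot = 1000L, level = 0.95,
                         seed = 1) {
  need <- c("stratum", "region", "method", "delta_um")
  miss <- setdiff(need, names(changes))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  cells <- unique(changes[, c("region", "method")])
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    region <- cells$region[i]; method <- cells$method[i]
    sub <- changes[changes$region == region & changes$method == method, ]
    xp <- sub$delta_um[sub$stratum == progressorStratum]
    xr <- sub$delta_um[sub$stratum == referenceStratum]
    hasRef <- length(xr) >= 2
    cs <- childSeed(seed, i)
    srmP <- safe(srm(xp))
    srmPci <- tryCatch(bcaCI(xp, srm, nBoot, level, seed = cs),
                       error = function(e) c(NA_real_, NA_real_))
    srmR <- if (hasRef) safe(srm(xr)) else NA_real_
    srmRci <- if (hasRef)
      tryCatch(bcaCI(xr, srm, nBoot, level, seed = cs + 1),
               error = function(e) c(NA_real_, NA_real_))
      else c(NA_real_, NA_real_)
    dRes <- if (hasRef)
      tryCatch(cohensD(xp, xr, level = level),
               error = function(e) list(d = NA_real_,
                                        ci = c(NA_real_, NA_real_)))
      else list(d = NA_real_, ci = c(NA_real_, NA_real_))
    meanCI <- function(x) {
      if (length(x) < 2 || stats::sd(x) == 0)
        return(c(safe(mean(x)), NA_real_, NA_real_))
      tt <- stats::t.test(x, conf.level = level)
      c(mean(x), tt$conf.int[1], tt$conf.int[2])
    }
    mP <- meanCI(xp)
    mR <- if (length(xr)) meanCI(xr) else c(NA_real_, NA_real_, NA_real_)
    dMean <- if (hasRef && stats::sd(xp) > 0)
      tryCatch({
        tt <- stats::t.test(xp, xr, conf.level = level)
        c(mean(xp) - mean(xr), tt$conf.int[1], tt$conf.int[2])
      }, error = function(e) c(NA_real_, NA_real_, NA_real_))
      else c(NA_real_, NA_real_, NA_real_)
    pT <- if (hasRef) safe(tTests(xp, xr)$p_between) else NA_real_
    thr <- if (!is.null(thresholds)) unname(thresholds[region]) else NA_real_
    if (!is.null(thresholds) && is.na(thr))
      stop("missing progressor threshold for region ", region)
    progP <- if (!is.na(thr)) classifyProgressors(xp, thr) else NULL
    progR <- if (!is.na(thr) && hasRef) classifyProgressors(xr, thr)
             else NULL
    pChi <- if (!is.null(progP) && !is.null(progR))
      safe(chisqProp(sum(progP$flags), length(xp),
                     sum(progR$flags), length(xr)))
      else NA_real_
    rows[[i]] <- data.frame(
      region = region, method = method,
      n_prog = length(xp), n_ref = length(xr),
      mean_prog_um = mP[1], mean_prog_lo = mP[2], mean_prog_hi = mP[3],
      mean_ref_um = mR[1], mean_ref_lo = mR[2], mean_ref_hi = mR[3],
      mean_diff_um = dMean[1], mean_diff_lo = dMean[2],
      mean_diff_hi = dMean[3],
      cohens_d = dRes$d, cohens_d_lo = dRes$ci[1], cohens_d_hi = dRes$ci[2],
      srm_prog = srmP, srm_prog_lo = srmPci[1], srm_prog_hi = srmPci[2],
      srm_ref = srmR, srm_ref_lo = srmRci[1], srm_ref_hi = srmRci[2],
      pct_prog_prog = if (!is.null(progP)) progP$proportionPct else NA_real_,
      pct_prog_ref = if (!is.null(progR)) progR$proportionPct else NA_real_,
      p_t_between = pT, p_chisq = pChi)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Round report cells for display
#'
#' Two decimals for SRM and Cohen's D, whole um for changes.
#'
#' @param report Output of \code{\link{cohortReport}}.
#' @return data.frame with rounded display columns.
#' @export
formatReport <- function(report) {
  out <- report
  umCols <- grep("^mean_", names(out))
  out[umCols] <- lapply(out[umCols], round)
  esCols <- grep("^(srm|cohens_d)", names(out))
  out[esCols] <- lapply(out[esCols], round, digits = 2)
  out
}
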