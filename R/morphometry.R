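# Morphometry: subchondral bone surface extraction, surface normals,
# femoral landmark detection, chord-based femoral ROI definition, normal-ray
# cartilage thickness, and region summaries.
#
# Thickness metric: for each bone surface point, the cartilage chord length
# along the outward surface normal, obtained by integrating a trilinearly
# interpolated cartilage indicator along the ray (sub-voxel accurate,
# unbiased under uniform boundary offsets). Points whose normal exits the
# cartilage sideways fall back to a ray along the dominant axis of the
# normal. Denuded points carry thickness 0 and stay in the mean (mean over
# the total subchondral bone area).

#' Extract a plate's subchondral bone area surface
#'
#' Converts the voxels carrying a plate's total subchondral bone area (tAB)
#' label into a point cloud at voxel centers (world mm).
#'
#' @param mask A \linkS4class{LabelMask} with tAB labels.
#' @param plate One of MT, cMF, LT, cLF, or "femur" for the combined femoral
#'   surface (cMF + cLF), used for landmark detection.
#' @param withNormals Estimate outward normals (default TRUE).
#' @return A \linkS4class{PlateSurface}.
#' @export
boneAreaSurface <- function(mask, plate, withNormals = TRUE) {
  L <- labelDict(mask)
  labs <- if (plate == "femur") L[c("tAB_cMF", "tAB_cLF")]
          else L[paste0("tAB_", plate)]
  if (any(is.na(labs))) stop("mask does not declare bone-area label for ",
                             plate)
  arr <- voxelData(mask)
  idx <- which(array(arr %in% labs, dim(arr)), arr.ind = TRUE)
  if (!nrow(idx)) stop("no bone-area voxels for plate ", plate)
  pts <- indexToWorld(idx, voxelSpacing(mask), voxelOrigin(mask))
  srf <- new("PlateSurface", points = pts, plate = plate,
             spacing = voxelSpacing(mask))
  if (withNormals) srf@normals <- estimateSurfaceNormals(srf, mask)
  srf
}

#' Estimate outward surface normals from the smoothed bone occupancy
#'
#' The outward normal at each surface point is the negative gradient (in
#' physical mm units) of a smoothed bone indicator, evaluated at the point.
#' Gradients of a smoothed occupancy are robust on voxelized surfaces and,
#' unlike small-neighbourhood plane fits, do not degenerate on strongly
#' anisotropic grids (e.g. 1.5 mm slices with 0.31 mm in-plane spacing).
#'
#' @param surface A \linkS4class{PlateSurface}.
#' @param mask The source \linkS4class{LabelMask}.
#' @param smoothPasses Binomial smoothing passes applied per axis.
#' @return n x 3 matrix of outward unit normals.
#' @export
estimateSurfaceNormals <- function(surface, mask, smoothPasses = 3L,
                                   neighborAverage = 6L) {
  pts <- surfacePoints(surface)
  n <- nrow(pts)
  if (n < 4) stop("surface too small to estimate normals")
  L <- labelDict(mask)
  boneIds <- L[intersect(names(L),
                         c("tibia", "femur", paste0("tAB_", platesAll())))]
  arr <- voxelData(mask)
  boneInd <- array(0, dim(arr))
  boneInd[array(arr %in% boneIds, dim(arr))] <- 1
  ## separable binomial (1/4, 1/2, 1/4) smoothing
  smooth1 <- function(a, axis) {
    sh <- function(s) {
      v <- c(0, 0, 0); v[axis] <- s
      shiftArray(a, v[1], v[2], v[3], fill = 0)
    }
    0.5 * a + 0.25 * sh(1) + 0.25 * sh(-1)
  }
  for (pass in seq_len(smoothPasses)) for (ax in 1:3)
    boneInd <- smooth1(boneInd, ax)
  sp <- voxelSpacing(mask); or <- voxelOrigin(mask)
  idx <- worldToIndex(pts, sp, or)
  grad <- matrix(0, n, 3)
  for (ax in 1:3) {
    e <- matrix(0, 1, 3); e[ax] <- 1
    hi <- trilinear(boneInd, idx + e[rep(1, n), , drop = FALSE], fill = 0)
    lo <- trilinear(boneInd, idx - e[rep(1, n), , drop = FALSE], fill = 0)
    grad[, ax] <- (hi - lo) / (2 * sp[ax])
  }
  nrm <- sqrt(rowSums(grad^2))
  bad <- nrm < 1e-9
  if (any(bad)) {
    ## degenerate gradient: point away from the surface centroid
    ctr <- colMeans(pts)
    dir <- sweep(pts[bad, , drop = FALSE], 2, ctr)
    dn <- sqrt(rowSums(dir^2)); dn[dn < 1e-9] <- 1
    grad[bad, ] <- -dir / dn
    nrm[bad] <- 1
  }
  normals <- -grad / nrm
  ## average over the local neighbourhood to suppress staircase noise
  if (neighborAverage > 0 && n > neighborAverage + 1) {
    nb <- kNearest(pts, pts, neighborAverage, excludeSelf = TRUE)
    acc <- normals
    for (k in seq_len(neighborAverage)) acc <- acc + normals[nb[, k], ]
    normals <- acc / sqrt(rowSums(acc^2))
  }
  normals
}

## Local area weights for surface points: squared distance to the k-th
## nearest neighbour, proportional to the surface area each point
## represents. Corrects the angle-dependent density of boundary-voxel
## sampling on anisotropic grids.
surfaceAreaWeights <- function(points, k = 7L) {
  n <- nrow(points)
  if (n <= k + 1) return(rep(1, n))
  nb <- kNearest(points, points, k, excludeSelf = TRUE)
  w <- rowSums((points - points[nb[, k], , drop = FALSE])^2)
  ## clamp: plate-boundary points have inflated neighbour distances that do
  ## not reflect extra represented area
  pmin(w, 2 * stats::median(w))
}

#' Detect femoral landmarks: trochlear notch and posterior condyle end
#'
#' Fits a circle to the sagittal-plane (x, z) projection of the femoral bone
#' area, parameterizes the surface by the angle around the fitted center, and
#' returns the two arc endpoints. The anterior endpoint (larger x after
#' accounting for the arc orientation) is reported as the trochlear notch,
#' the other as the posterior condyle end; on a volume rotated 180 degrees
#' about the vertical axis the two consistently swap anatomical roles.
#'
#' @param femoralBone A \linkS4class{PlateSurface} of the femoral bone area
#'   (plate "femur", or a single femoral plate).
#' @return The input surface with \code{landmarks} set (list with
#'   \code{notch} and \code{posterior} world coordinates, mm).
#' @export
detectLandmarks <- function(femoralBone) {
  pts <- surfacePoints(femoralBone)
  if (nrow(pts) < 10) stop("surface too small to resolve the AP axis")
  x <- pts[, 1]; z <- pts[, 3]
  if (stats::sd(x) < 1e-9 || stats::sd(z) < 1e-9 ||
      abs(stats::cor(x, z)) > 0.9999)
    stop("surface too small to resolve the AP axis (degenerate projection)")
  ## algebraic (Kasa) circle fit in the sagittal projection
  A <- cbind(2 * x, 2 * z, 1)
  b <- x^2 + z^2
  sol <- stats::lm.fit(A, b)$coefficients
  xc <- sol[1]; zc <- sol[2]
  ang <- atan2(x - xc, -(z - zc))
  ## endpoints of the angular range, averaged over a one-voxel arc band
  dAng <- max(femoralBone@spacing) / sqrt(mean((x - xc)^2 + (z - zc)^2))
  endPoint <- function(hi) {
    a0 <- if (hi) max(ang) else min(ang)
    sel <- if (hi) ang >= a0 - dAng else ang <= a0 + dAng
    colMeans(pts[sel, , drop = FALSE])
  }
  e1 <- endPoint(TRUE)
  e2 <- endPoint(FALSE)
  if (e1[1] >= e2[1]) { notch <- e1; post <- e2 } else { notch <- e2; post <- e1 }
  femoralBone@landmarks <- list(notch = unname(notch),
                                posterior = unname(post))
  femoralBone
}

## Normalized AP coordinate of surface points: 0 at the notch, 1 at the
## posterior condyle end, along the notch->posterior chord projected on the
## sagittal (x, z) plane.
chordCoordinate <- function(points, landmarks) {
  d <- landmarks$posterior - landmarks$notch
  d[2] <- 0
  dd <- sum(d^2)
  if (dd <= 0) stop("degenerate landmarks")
  ((points[, 1] - landmarks$notch[1]) * d[1] +
     (points[, 3] - landmarks$notch[3]) * d[3]) / dd
}

#' Trim a femoral surface to a region of interest
#'
#' Keeps the points whose normalized AP chord coordinate (trochlear notch =
#' 0, posterior condyle end = 1) does not exceed \code{fraction}. Standard
#' fractions: 0.75 for sagittal DESS, 0.60 for coronal FLASH.
#'
#' @param surface A femoral \linkS4class{PlateSurface}; landmarks must be
#'   present (see \code{\link{detectLandmarks}}) or supplied.
#' @param fraction ROI fraction in (0, 1]; 1 returns the input unchanged.
#' @param landmarks Optional landmark list overriding the surface's.
#' @return The trimmed \linkS4class{PlateSurface}.
#' @export
extractFemoralROI <- function(surface, fraction, landmarks = NULL) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  if (fraction == 1) return(surface)
  lm <- landmarks %||%
    (if (length(surface@landmarks)) surface@landmarks else
       stop("landmarks unavailable; run detectLandmarks() first"))
  u <- chordCoordinate(surfacePoints(surface), lm)
  keep <- u <= fraction
  subsetSurface(surface, keep)
}

subsetSurface <- function(surface, keep) {
  surface@points <- surface@points[keep, , drop = FALSE]
  if (nrow(surface@normals))
    surface@normals <- surface@normals[keep, , drop = FALSE]
  if (length(surface@covered)) surface@covered <- surface@covered[keep]
  surface
}

## Ray sampler: integrate the trilinearly interpolated cartilage indicator
## of `labelId` along rays p + s*n, s in (0, maxDist]. Partial-volume
## interpolation places each boundary crossing halfway between the last
## inside and first outside voxel center, which is unbiased when boundary
## phases vary across a plate. Returns chord length and distance of first
## entry (Inf if never entered).
rayCartilageChord <- function(mask, labelId, points, normals,
                              maxDist = 8, step = NULL) {
  sp <- voxelSpacing(mask); or <- voxelOrigin(mask)
  step <- step %||% (min(sp) / 6)
  ind <- array(0, dim(voxelData(mask)))
  ind[voxelData(mask) == labelId] <- 1
  n <- nrow(points)
  chord <- numeric(n)
  entry <- rep(Inf, n)
  svals <- seq(step / 2, maxDist, by = step)
  for (s in svals) {
    v <- trilinear(ind, worldToIndex(points + s * normals, sp, or), fill = 0)
    chord <- chord + v * step
    newEntry <- v > 0.5 & !is.finite(entry)
    entry[newEntry] <- s
  }
  list(chord = chord, entry = entry)
}

## Snap each normal to its dominant axis (used as fallback for rays that
## exit the cartilage sideways).
snapNormals <- function(normals) {
  ax <- max.col(abs(normals), ties.method = "first")
  out <- matrix(0, nrow(normals), 3)
  out[cbind(seq_len(nrow(normals)), ax)] <-
    sign(normals[cbind(seq_len(nrow(normals)), ax)])
  out
}

#' Compute a cartilage thickness map over a bone surface
#'
#' For every subchondral bone surface point, cartilage thickness is the
#' chord length of the plate's cartilage along the outward surface normal;
#' denuded points (no cartilage within the search distance) carry 0.
#'
#' @param cartilageMask \linkS4class{LabelMask} containing the plate's
#'   cartilage label.
#' @param bone \linkS4class{PlateSurface} of one plate (normals estimated on
#'   demand). If cartilage linking has not been run, covered status is
#'   computed here (see \code{\link{linkCartilage}}).
#' @param maxThickness Ray length bound (mm).
#' @param searchDistance Covered/denuded decision distance (mm).
#' @return A \linkS4class{ThicknessMap}.
#' @export
computeThickness <- function(cartilageMask, bone, maxThickness = 8,
                             searchDistance = 2.5) {
  plate <- plateOf(bone)
  if (!plate %in% platesAll())
    stop("thickness needs a single-plate surface, got ", plate)
  if (!nrow(bone@normals))
    bone@normals <- estimateSurfaceNormals(bone, cartilageMask)
  if (!length(bone@covered))
    bone <- linkCartilage(cartilageMask, bone, searchDistance = searchDistance)
  labId <- labelDict(cartilageMask)[plate]
  pts <- surfacePoints(bone)
  ray <- rayCartilageChord(cartilageMask, labId, pts, bone@normals,
                           maxDist = maxThickness)
  th <- ray$chord
  ## fallback: covered points whose normal ray missed -> dominant-axis ray
  miss <- bone@covered & th < 1e-9
  if (any(miss)) {
    snapped <- snapNormals(bone@normals[miss, , drop = FALSE])
    ray2 <- rayCartilageChord(cartilageMask, labId,
                              pts[miss, , drop = FALSE], snapped,
                              maxDist = maxThickness)
    th[miss] <- ray2$chord
  }
  th[!bone@covered] <- 0
  new("ThicknessMap", points = pts, thickness = th,
      region = rep(plate, nrow(pts)), covered = bone@covered)
}

#' Summarize a thickness map into per-region values
#'
#' Mean cartilage thickness over all bone-area points of the region (denuded
#' points contribute 0: the mean is taken over the total subchondral bone
#' area) and the denuded-area percentage.
#'
#' The mean is area-weighted: every point carries a weight proportional to
#' the local surface area it represents (squared distance to its k-th
#' neighbour), which removes the angle-dependent sampling density of
#' boundary voxels on anisotropic grids.
#'
#' @param th A \linkS4class{ThicknessMap}.
#' @param region Region id present in the map.
#' @param kneeId,visit,method Optional identifiers carried into the row.
#' @param areaWeighted Use local-area weights (default) or plain means.
#' @return One-row data.frame: knee_id, visit, method, region,
#'   mean_thickness_mm, dab_pct.
#' @export
summarizeThickness <- function(th, region, kneeId = NA_character_,
                               visit = NA_character_,
                               method = NA_character_,
                               areaWeighted = TRUE) {
  sel <- regionOf(th) == region
  if (!any(sel)) stop("region ", region, " not present in thickness map")
  w <- if (areaWeighted) surfaceAreaWeights(surfacePoints(th)[sel, ,
                                                              drop = FALSE])
       else rep(1, sum(sel))
  tv <- thicknessValues(th)[sel]
  cv <- coveredStatus(th)[sel]
  data.frame(knee_id = kneeId, visit = visit, method = method,
             region = region,
             mean_thickness_mm = sum(w * tv) / sum(w),
             dab_pct = 100 * sum(w * !cv) / sum(w))
}

#' Aggregate plate summaries into a femorotibial compartment
#'
#' Compartment thickness is the sum of the tibial and the central femoral
#' plate thickness: MFTC = MT + cMF, LFTC = LT + cLF.
#'
#' @param tibial One-row summary (region MT or LT).
#' @param femoral One-row summary (region cMF or cLF), same knee and visit.
#' @return One-row data.frame with region MFTC or LFTC; dAB is reported as
#'   NA for compartments (denuded area is a per-plate construct).
#' @export
aggregateCompartment <- function(tibial, femoral) {
  pair <- c(tibial$region, femoral$region)
  comp <- if (identical(pair, c("MT", "cMF"))) "MFTC"
          else if (identical(pair, c("LT", "cLF"))) "LFTC"
          else stop("region mismatch: expected (MT, cMF) or (LT, cLF), got (",
                    pair[1], ", ", pair[2], ")")
  if (!identical(tibial$knee_id, femoral$knee_id) ||
      !identical(tibial$visit, femoral$visit))
    stop("summaries must come from the same knee and visit")
  data.frame(knee_id = tibial$knee_id, visit = tibial$visit,
             method = tibial$method, region = comp,
             mean_thickness_mm =
               tibial$mean_thickness_mm + femoral$mean_thickness_mm,
             dab_pct = NA_real_)
}
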