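# Post-processing of automated segmentations, with no human in the loop:
# build a per-plate bone-area atlas, register each knee's (possibly
# incomplete) bone-area segmentation to it with point-to-point ICP,
# reconstruct missing bone area from the atlas, link cartilage to bone, and
# auto-correct segmentation errors (gaps, disconnected fragments,
# implausible cartilage).

#' Build a subchondral bone-area atlas for one plate
#'
#' Extracts each mask's bone-area surface, rigidly aligns every surface to
#' the first one (ICP), and averages corresponding points (nearest-neighbour
#' correspondence after alignment). The atlas is centered so its centroid is
#' at the origin. A single input yields that surface, centered.
#'
#' @param boneMasks List of \linkS4class{LabelMask} objects containing the
#'   plate's bone-area label.
#' @param plate Plate name (MT, cMF, LT, cLF).
#' @param icp ICP configuration passed to \code{\link{registerICP}}.
#' @return A \linkS4class{BoneAtlas}.
#' @export
buildAtlas <- function(boneMasks, plate, icp = icpConfig()) {
  surfs <- list()
  for (i in seq_along(boneMasks)) {
    s <- try(boneAreaSurface(boneMasks[[i]], plate, withNormals = FALSE),
             silent = TRUE)
    if (!inherits(s, "try-error")) surfs[[length(surfs) + 1L]] <- s
  }
  if (!length(surfs))
    stop("bone-area label for plate ", plate, " absent from all masks")
  ref <- surfs[[1]]@points
  ref <- sweep(ref, 2, colMeans(ref))
  acc <- ref
  count <- 1
  if (length(surfs) > 1) for (k in 2:length(surfs)) {
    src <- surfs[[k]]
    tf <- registerICP(src, new("BoneAtlas", points = ref, plate = plate,
                               provenance = "ref"), icp)
    aligned <- applyTransform(src@points, tf)
    nn <- nearestNeighbor(ref, aligned)
    acc <- acc + aligned[nn$index, , drop = FALSE]
    count <- count + 1
  }
  pts <- acc / count
  pts <- sweep(pts, 2, colMeans(pts))
  new("BoneAtlas", points = pts, plate = plate,
      provenance = paste0("mask", seq_along(boneMasks)))
}

#' ICP configuration
#'
#' @param maxIter Maximum iterations.
#' @param tol Convergence tolerance on the RMS residual change (mm).
#' @param maxCorrDist Correspondence-distance rejection radius (mm);
#'   \code{Inf} disables rejection.
#' @param trimFactor Adaptive trimming: pairs farther than
#'   \code{trimFactor} times the median correspondence distance are
#'   dropped each iteration (robustness against partial overlap);
#'   \code{Inf} disables.
#' @return Named list.
#' @export
icpConfig <- function(maxIter = 50L, tol = 1e-4, maxCorrDist = Inf,
                      trimFactor = 3) {
  stopifnot(maxIter >= 1, tol > 0, maxCorrDist > 0, trimFactor > 0)
  list(maxIter = as.integer(maxIter), tol = tol, maxCorrDist = maxCorrDist,
       trimFactor = trimFactor)
}

## Apply a RigidTransform to points (n x 3): x' = R x + t.
#' Apply or invert a rigid transform
#' @param points n x 3 matrix.
#' @param transform A \linkS4class{RigidTransform}.
#' @param inverse Apply the inverse mapping.
#' @return Transformed n x 3 matrix.
#' @export
applyTransform <- function(points, transform, inverse = FALSE) {
  R <- transform@rotation
  t <- transform@translation
  if (inverse) sweep(points, 2, t) %*% R
  else sweep(tcrossprod(points, R), 2, t, "+")
}

## Kabsch: rotation + translation minimizing ||R a + t - b||.
kabsch <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  H <- crossprod(sweep(a, 2, ca), sweep(b, 2, cb))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = as.numeric(cb - R %*% ca))
}

#' Register a bone-area surface to an atlas by ICP
#'
#' Point-to-point iterative closest point with optional
#' correspondence-distance rejection. Initialization is centroid alignment
#' plus a principal-axes pre-rotation (the candidate orientation with the
#' lowest initial residual is used), so grossly different frames converge.
#'
#' @param source A \linkS4class{PlateSurface} (or n x 3 matrix of points).
#' @param atlas A \linkS4class{BoneAtlas}.
#' @param config See \code{\link{icpConfig}}.
#' @return A \linkS4class{RigidTransform} mapping source points into the
#'   atlas frame, with the residual RMS distance and the iteration trace.
#' @export
registerICP <- function(source, atlas, config = icpConfig()) {
  src <- if (is.matrix(source)) source else surfacePoints(source)
  if (nrow(src) < 3) stop("ICP needs at least 3 source points")
  sv <- svd(sweep(src, 2, colMeans(src)), nu = 0)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate (collinear or coincident) source points")
  dst <- surfacePoints(atlas)

  rmsTo <- function(p) {
    nn <- nearestNeighbor(p, dst)
    sqrt(mean(nn$distance^2))
  }
  ## initialization candidates: identity and principal-axes pre-rotations,
  ## each with centroid and bounding-box-center translations (the latter is
  ## robust to missing patches that shift the centroid)
  cs <- colMeans(src)
  es <- eigen(stats::cov(src), symmetric = TRUE)$vectors
  ed <- eigen(stats::cov(dst), symmetric = TRUE)$vectors
  bbc <- function(p) (apply(p, 2, min) + apply(p, 2, max)) / 2
  cands <- list(diag(3))
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    A <- es %*% diag(c(s1, s2, 1))
    if (det(A) < 0) A <- es %*% diag(c(s1, s2, -1))
    cands[[length(cands) + 1L]] <- ed %*% t(A)
  }
  best <- NULL; bestRms <- Inf
  for (R0 in cands) {
    rotated <- tcrossprod(src, R0)
    for (t0 in list(-as.numeric(R0 %*% cs),
                    as.numeric(bbc(dst) - bbc(rotated)))) {
      r <- rmsTo(sweep(rotated, 2, t0, "+"))
      if (r < bestRms) { bestRms <- r; best <- list(R = R0, t = t0) }
    }
  }
  R <- best$R; t <- best$t
  trace <- numeric(0)
  lastRms <- Inf
  iter <- 0L
  trimmed <- function(nn) {
    keep <- nn$distance <= config$maxCorrDist
    tf <- config$trimFactor %||% Inf
    if (is.finite(tf)) {
      med <- stats::median(nn$distance)
      if (med > 0) keep <- keep & nn$distance <= tf * med
    }
    keep
  }
  repeat {
    iter <- iter + 1L
    cur <- sweep(tcrossprod(src, R), 2, t, "+")
    nn <- nearestNeighbor(cur, dst)
    keep <- trimmed(nn)
    if (sum(keep) < 3) stop("ICP lost all correspondences (maxCorrDist too small)")
    fit <- kabsch(src[keep, , drop = FALSE],
                  dst[nn$index[keep], , drop = FALSE])
    R <- fit$R; t <- fit$t
    cur <- sweep(tcrossprod(src, R), 2, t, "+")
    nn <- nearestNeighbor(cur, dst)
    keep <- trimmed(nn)
    rms <- sqrt(mean(nn$distance[keep]^2))
    trace <- c(trace, rms)
    if (abs(lastRms - rms) < config$tol || iter >= config$maxIter) break
    lastRms <- rms
  }
  new("RigidTransform", rotation = R, translation = t, residual = rms,
      nIterations = iter, trace = trace)
}

#' Reconstruct an incomplete bone area from the atlas
#'
#' Transforms the atlas into the knee's frame (inverse of the registration
#' transform) and augments the partial surface with the atlas points that
#' have no partner in the partial surface within the correspondence radius.
#' A complete input gains no points; input points are never removed.
#'
#' @param partial \linkS4class{PlateSurface} of the (possibly incomplete)
#'   segmented bone area.
#' @param atlas \linkS4class{BoneAtlas} of the same plate.
#' @param transform \linkS4class{RigidTransform} from
#'   \code{\link{registerICP}} run on \code{partial}.
#' @param corrRadius Correspondence radius (mm): atlas points farther than
#'   this from every partial point are considered missing and added.
#' @return The augmented \linkS4class{PlateSurface} (normals and covered
#'   status cleared; re-estimate downstream).
#' @export
reconstructBoneArea <- function(partial, atlas, transform, corrRadius = 1.0) {
  if (!identical(plateOf(partial), plateOf(atlas)))
    stop("plate mismatch: surface is ", plateOf(partial), ", atlas is ",
         plateOf(atlas))
  if (nrow(partial@points) < 3) stop("cannot reconstruct an empty surface")
  atlasInKnee <- applyTransform(surfacePoints(atlas), transform,
                                inverse = TRUE)
  nn <- nearestNeighbor(atlasInKnee, surfacePoints(partial))
  add <- atlasInKnee[nn$distance > corrRadius, , drop = FALSE]
  out <- partial
  out@points <- rbind(partial@points, add)
  out@normals <- matrix(numeric(), 0, 3)
  out@covered <- logical()
  out
}

#' Link cartilage segmentation to a bone surface
#'
#' Marks every bone-area point as covered if cartilage voxels of that plate
#' lie within the search distance along the outward surface normal (with a
#' Euclidean nearest-cartilage fallback for rays that exit sideways), and
#' denuded otherwise.
#'
#' @param cartilageMask \linkS4class{LabelMask} with the plate's cartilage.
#' @param bone \linkS4class{PlateSurface} of one plate.
#' @param searchDistance Decision distance (mm).
#' @return The surface with per-point covered status set.
#' @export
linkCartilage <- function(cartilageMask, bone, searchDistance = 2.5) {
  plate <- plateOf(bone)
  if (!plate %in% platesAll()) stop("linkCartilage needs a single plate")
  if (max(abs(voxelSpacing(cartilageMask) - bone@spacing)) > 1e-6)
    stop("spatial frame mismatch between mask and surface")
  if (!nrow(bone@normals))
    bone@normals <- estimateSurfaceNormals(bone, cartilageMask)
  labId <- labelDict(cartilageMask)[plate]
  pts <- surfacePoints(bone)
  ray <- rayCartilageChord(cartilageMask, labId, pts, bone@normals,
                           maxDist = searchDistance)
  covered <- is.finite(ray$entry)
  ## fallback for rays that exit sideways (noisy normals at plate margins):
  ## re-test along the dominant axis of the normal; a vertical column stays
  ## empty over a denuded lesion, so denuded areas are preserved
  if (any(!covered)) {
    snapped <- snapNormals(bone@normals[!covered, , drop = FALSE])
    ray2 <- rayCartilageChord(cartilageMask, labId,
                              pts[!covered, , drop = FALSE], snapped,
                              maxDist = searchDistance)
    covered[!covered] <- is.finite(ray2$entry)
  }
  bone@covered <- covered
  bone
}

#' Rule set for automated segmentation correction
#'
#' @param maxGap Gaps in cartilage narrower than this are closed (mm).
#' @param minFragment Connected components smaller than this many voxels
#'   (other than the largest) are removed.
#' @param maxThickness Cartilage farther than this from its bone surface is
#'   implausible and cropped (mm).
#' @return Named list.
#' @export
autocorrectRules <- function(maxGap = 2, minFragment = 30, maxThickness = 8) {
  stopifnot(maxGap >= 0, minFragment >= 0, maxThickness > 0)
  list(maxGap = maxGap, minFragment = minFragment,
       maxThickness = maxThickness)
}

#' Automatically correct cartilage segmentation errors
#'
#' Applies, per plate, the three correction rules: (i) gaps narrower than
#' \code{maxGap} are closed by morphological closing restricted to the
#' plate's band (within \code{maxThickness} of the bone surface); (ii)
#' connected components other than the largest and below \code{minFragment}
#' voxels are removed; (iii) cartilage farther from the plate's bone surface
#' than \code{maxThickness} is cropped. Internally iterated to a fixed
#' point, so the operation is idempotent. Always returns a valid mask.
#'
#' @param cartilageMask \linkS4class{LabelMask}.
#' @param bone A \linkS4class{PlateSurface} or list of surfaces (one per
#'   plate to correct).
#' @param rules See \code{\link{autocorrectRules}}.
#' @return List with \code{mask} (corrected \linkS4class{LabelMask}) and
#'   \code{log} (data.frame: plate, action, voxels).
#' @export
autocorrect <- function(cartilageMask, bone, rules = autocorrectRules()) {
  if (is(bone, "PlateSurface")) bone <- list(bone)
  lab <- voxelData(cartilageMask)
  sp <- voxelSpacing(cartilageMask)
  or <- voxelOrigin(cartilageMask)
  logRows <- list()
  note <- function(plate, action, voxels) {
    if (voxels > 0)
      logRows[[length(logRows) + 1L]] <<-
        data.frame(plate = plate, action = action, voxels = voxels)
  }
  for (srf in bone) {
    plate <- plateOf(srf)
    labId <- labelDict(cartilageMask)[plate]
    ## plate band: within maxThickness (box metric) of the bone surface
    pts <- surfacePoints(srf)
    idxAll <- round(worldToIndex(pts, sp, or))
    ok <- idxAll[, 1] >= 1 & idxAll[, 1] <= dim(lab)[1] &
      idxAll[, 2] >= 1 & idxAll[, 2] <= dim(lab)[2] &
      idxAll[, 3] >= 1 & idxAll[, 3] <= dim(lab)[3]
    boneVox <- array(FALSE, dim(lab))
    boneVox[idxAll[ok, , drop = FALSE]] <- TRUE
    band <- dilateBox(boneVox, rules$maxThickness, sp)
    ## per-point covered status in the ORIGINAL mask: bone columns with no
    ## cartilage along the (snapped) outward normal are gap/denuded columns
    uncov <- NULL
    if (rules$maxGap > 0) {
      nrm <- if (nrow(srf@normals)) srf@normals
             else estimateSurfaceNormals(srf, cartilageMask)
      ray0 <- rayCartilageChord(cartilageMask, labId, pts, nrm,
                                maxDist = rules$maxThickness,
                                step = min(sp) / 2)
      uncov <- !is.finite(ray0$entry)
    }
    ## local fill ceiling per gap column: the median entry-plus-chord
    ## height of the nearest covered columns, so repairs stay flush with
    ## the surrounding cartilage surface
    tCeil <- rep(Inf, nrow(pts))
    if (rules$maxGap > 0 && any(uncov) && any(!uncov)) {
      covIdx <- which(!uncov)
      nnCov <- kNearest(pts[uncov, , drop = FALSE],
                        pts[covIdx, , drop = FALSE],
                        k = min(8L, length(covIdx)))
      tCeil[uncov] <- apply(nnCov, 1, function(r)
        stats::median(ray0$entry[covIdx[r]] + ray0$chord[covIdx[r]]))
    }
    ## qualify uncovered patches by scale: a patch whose deepest point is
    ## farther from covered bone than the gap rule allows is a genuine
    ## denuded area (full-thickness cartilage loss) and is left untouched
    gapNarrow <- rep(FALSE, nrow(pts))
    if (rules$maxGap > 0 && any(uncov) && any(!uncov)) {
      selU <- uncov & ok
      if (any(selU)) {
        uncovVox <- array(FALSE, dim(lab))
        uncovVox[idxAll[selU, , drop = FALSE]] <- TRUE
        conn <- labelComponentsCropped(dilateBox(uncovVox,
                                                 1.01 * max(sp), sp))
        compFull <- conn$expandLabels()
        compId <- compFull[idxAll[selU, , drop = FALSE]]
        dCov <- nearestNeighbor(pts[selU, , drop = FALSE],
                                pts[!uncov, , drop = FALSE])$distance
        thr <- rules$maxGap / 2 + 0.75 * max(sp)
        wide <- unique(compId[dCov > thr])
        gapNarrow[selU] <- !(compId %in% wide)
      }
    }
    pass <- 0L
    repeat {
      pass <- pass + 1L
      cart <- lab == labId
      ## (i) close narrow gaps: closing may only add voxels whose nearest
      ##     bone point lies in a qualifying narrow gap, so it bridges true
      ##     gaps without plating onto intact cartilage or filling denuded
      ##     areas
      if (rules$maxGap > 0 && any(gapNarrow)) {
        closed <- closeBox(cart, rules$maxGap / 2, sp)
        ## keep an added voxel only if its nearest bone point lies in a
        ## qualifying narrow gap and its height stays below the local
        ## cartilage-surface ceiling (so repairs are flush, voxel-center
        ## semantics as in the mask itself)
        filterAdds <- function(cand) {
          if (!nrow(cand)) return(cand)
          candPts <- indexToWorld(cand, sp, or)
          j <- nearestNeighbor(candPts, pts)$index
          h <- rowSums((candPts - pts[j, , drop = FALSE]) *
                         nrm[j, , drop = FALSE])
          cand[gapNarrow[j] & h < tCeil[j], , drop = FALSE]
        }
        cand <- filterAdds(which(closed & !cart & band & lab == 0L,
                                 arr.ind = TRUE))
        addVox <- array(FALSE, dim(lab))
        addVox[cand] <- TRUE
        if (pass == 1L) note(plate, "gap_closed", sum(addVox))
        cart <- cart | addVox
        ## (i-b) normal-ray infill for gap columns the closing could not
        ##       bridge (oblique slits in thin curved plates): fill along
        ##       the outward normal up to the median chord of the nearest
        ##       covered columns, checked only against gaps narrow enough
        ##       for the rule (neighbours within maxGap of the column)
        still <- uncov & gapNarrow
        if (any(still) && any(!uncov)) {
          tLoc <- tCeil[still]
          sSeq <- seq(min(sp) / 4, max(tLoc), by = min(sp) / 2)
          fillVox <- array(FALSE, dim(lab))
          sp2 <- pts[still, , drop = FALSE]
          nr2 <- nrm[still, , drop = FALSE]
          for (s in sSeq) {
            act <- s <= tLoc
            if (!any(act)) break
            fi <- round(worldToIndex(sp2[act, , drop = FALSE] +
                                       s * nr2[act, , drop = FALSE],
                                     sp, or))
            okf <- fi[, 1] >= 1 & fi[, 1] <= dim(lab)[1] &
              fi[, 2] >= 1 & fi[, 2] <= dim(lab)[2] &
              fi[, 3] >= 1 & fi[, 3] <= dim(lab)[3]
            fillVox[fi[okf, , drop = FALSE]] <- TRUE
          }
          fillVox <- fillVox & !cart & band & lab == 0L
          fcand <- filterAdds(which(fillVox, arr.ind = TRUE))
          fillVox <- array(FALSE, dim(lab))
          fillVox[fcand] <- TRUE
          if (pass == 1L) note(plate, "gap_filled", sum(fillVox))
          cart <- cart | fillVox
        }
      }
      ## (ii) remove small disconnected fragments (largest always kept)
      comp <- labelComponentsCropped(cart)
      nComp <- max(comp$labels)
      if (nComp > 1) {
        sizes <- tabulate(comp$labels[comp$labels > 0], nComp)
        drop <- which(seq_len(nComp) != which.max(sizes) &
                        sizes < rules$minFragment)
        if (length(drop)) {
          rm <- comp$expand(array(comp$labels %in% drop,
                                  dim(comp$labels)))
          if (pass == 1L) for (dc in drop)
            note(plate, "fragment_removed", sizes[dc])
          cart <- cart & !rm
        }
      }
      ## (iii) crop implausibly distant cartilage
      rmFar <- cart & !band
      if (pass == 1L) note(plate, "implausible_cropped", sum(rmFar))
      cart <- cart & band
      newLab <- lab
      newLab[lab == labId] <- 0L
      newLab[cart] <- labId
      if (identical(newLab, lab) || pass >= 4L) { lab <- newLab; break }
      lab <- newLab
    }
  }
  out <- cartilageMask
  out@data <- lab
  log <- if (length(logRows)) do.call(rbind, logRows)
         else data.frame(plate = character(), action = character(),
                         voxels = integer())
  list(mask = out, log = log)
}

## Connected-component labelling restricted to the bounding box of the mask
## (labelComponents3D on the cropped array); returns cropped labels plus an
## expander back to full size.
labelComponentsCropped <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(list(labels = array(0L, dim(mask)),
                expand = function(x) array(FALSE, dim(mask)),
                expandLabels = function() array(0L, dim(mask))))
  }
  lo <- pmax(apply(idx, 2, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2, max) + 1L, dim(mask))
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  labs <- labelComponents3D(sub)
  list(labels = labs,
       expand = function(x) {
         out <- array(FALSE, dim(mask))
         out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- x
         out
       },
       expandLabels = function() {
         out <- array(0L, dim(mask))
         out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- labs
         out
       })
}

#' Count connected components of one label
#'
#' 6-connected components of the given plate's cartilage (or any named)
#' label.
#'
#' @param mask A \linkS4class{LabelMask}.
#' @param label Label name (e.g. a plate) or integer id.
#' @return Integer component count.
#' @export
componentCount <- function(mask, label) {
  id <- if (is.character(label)) labelDict(mask)[label] else label
  comp <- labelComponentsCropped(voxelData(mask) == id)
  max(comp$labels)
}
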