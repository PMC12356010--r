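# Controlled corruption of ground-truth masks: slit-like gaps through
# cartilage plates, free-floating cartilage fragments, and contiguous
# deletion of part of a plate's segmented bone area. These are the failure
# modes the post-processing stage is designed to repair, generated with
# known magnitudes so repair can be quantified.

#' Corruption configuration
#'
#' @param gapWidths Numeric vector of slit widths (mm); one slit per entry
#'   is cut through each targeted plate's cartilage, perpendicular to the
#'   plate's anterior--posterior coordinate at a random position.
#' @param nFragments Number of small free-floating cartilage fragments to
#'   add in background, away from existing cartilage (each is a new
#'   connected component).
#' @param deleteBoneFraction Fraction in [0, 1] of each targeted plate's
#'   bone-area voxels to delete as one contiguous patch (the voxels revert
#'   to plain bone, emulating incomplete bone-area segmentation).
#' @param plates Plates to corrupt.
#' @return Named list.
#' @export
corruptionConfig <- function(gapWidths = numeric(), nFragments = 0L,
                             deleteBoneFraction = 0,
                             plates = platesAll()) {
  if (deleteBoneFraction < 0 || deleteBoneFraction > 1)
    stop("deleteBoneFraction must be in [0, 1]")
  stopifnot(all(gapWidths >= 0), nFragments >= 0)
  list(gapWidths = gapWidths, nFragments = as.integer(nFragments),
       deleteBoneFraction = deleteBoneFraction, plates = plates)
}

## Plate-local AP coordinate (u, mm) of given voxel world coordinates; used
## to place gap slits consistently on flat and curved plates.
plateULocal <- function(spec, plate, pts) {
  g <- spec@geometry
  if (plate %in% c("MT", "LT")) {
    g$plateX[2] - pts[, 1]
  } else {
    phi <- atan2(pts[, 1] - g$femurCenter["x"], -(pts[, 3] - g$femurCenter["z"]))
    g$femurRadius * (g$phiNotch - phi)
  }
}

#' Corrupt a label mask
#'
#' Applies the configured gap, fragment and bone-area-deletion corruptions.
#' With all magnitudes zero the mask is returned voxel-for-voxel identical.
#'
#' @param mask Ground-truth \linkS4class{LabelMask} (phantom output).
#' @param corruption See \code{\link{corruptionConfig}}.
#' @param seed Integer seed; identical seed and inputs give an identical
#'   corrupted mask.
#' @param spec The \linkS4class{PhantomSpec} the mask came from (needed to
#'   place gaps in plate-local coordinates; defaults to standard geometry).
#' @return Corrupted \linkS4class{LabelMask}.
#' @export
corruptMask <- function(mask, corruption = corruptionConfig(), seed = 1,
                        spec = phantomSpec()) {
  if (corruption$deleteBoneFraction < 0 || corruption$deleteBoneFraction > 1)
    stop("deleteBoneFraction must be in [0, 1]")
  lab <- voxelData(mask)
  L <- labelDict(mask)
  sp <- voxelSpacing(mask); or <- voxelOrigin(mask)
  withSeed(seed, {
    for (plate in corruption$plates) {
      cid <- L[plate]
      cIdx <- which(lab == cid, arr.ind = TRUE)
      if (nrow(cIdx) && length(corruption$gapWidths)) {
        u <- plateULocal(spec, plate, indexToWorld(cIdx, sp, or))
        for (w in corruption$gapWidths) {
          if (w <= 0) next
          u0 <- stats::runif(1, 0.25 * max(u), 0.75 * max(u))
          cut <- u >= u0 & u < u0 + w
          lab[cIdx[cut, , drop = FALSE]] <- 0L
        }
      }
      ## contiguous deletion of part of the bone-area label
      if (corruption$deleteBoneFraction > 0) {
        bid <- L[paste0("tAB_", plate)]
        bIdx <- which(lab == bid, arr.ind = TRUE)
        if (nrow(bIdx)) {
          nDel <- round(corruption$deleteBoneFraction * nrow(bIdx))
          if (nDel > 0) {
            seedPt <- bIdx[sample.int(nrow(bIdx), 1), , drop = FALSE]
            d2 <- rowSums(sweep(sweep(bIdx, 2, as.numeric(seedPt)), 2,
                                sp, "*")^2)
            del <- order(d2)[seq_len(nDel)]
            boneId <- if (plate %in% c("MT", "LT")) L["tibia"] else L["femur"]
            lab[bIdx[del, , drop = FALSE]] <- boneId
          }
        }
      }
    }
    ## free-floating fragments in background, away from any cartilage
    if (corruption$nFragments > 0) {
      cartAny <- array(lab %in% L[platesAll()], dim(lab))
      excl <- dilateBox(cartAny | lab != 0L, 2.5, sp)
      d <- dim(lab)
      placed <- 0L
      tries <- 0L
      fragLabel <- L[corruption$plates[1]]
      while (placed < corruption$nFragments && tries < 2000L) {
        tries <- tries + 1L
        i <- sample.int(d[1] - 3L, 1) + 1L
        j <- sample.int(d[2] - 3L, 1) + 1L
        k <- sample.int(d[3] - 3L, 1) + 1L
        blk <- excl[i:(i + 2L), j:(j + 2L), k:(k + 2L)]
        if (any(blk)) next
        lab[i:(i + 1L), j:(j + 1L), k:(k + 1L)] <- fragLabel
        excl[max(1, i - 4L):min(d[1], i + 5L),
             max(1, j - 4L):min(d[2], j + 5L),
             max(1, k - 4L):min(d[3], k + 5L)] <- TRUE
        placed <- placed + 1L
      }
      if (placed < corruption$nFragments)
        warning("placed only ", placed, " of ", corruption$nFragments,
                " fragments")
    }
  })
  out <- mask
  out@data <- lab
  out
}
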