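#' @import methods
NULL

#' Cartilage plate and label dictionary
#'
#' The package labels the four femorotibial cartilage plates (MT, cMF, LT,
#' cLF), the per-plate total subchondral bone areas (tAB), and the two bones.
#' All masks produced or consumed by the package use this dictionary unless a
#' mask carries its own.
#'
#' @return Named integer vector mapping label names to voxel values.
#' @export
#' @examples
#' cartLabels()
cartLabels <- function() {
  c(background = 0L,
    MT = 1L, cMF = 2L, LT = 3L, cLF = 4L,
    tAB_MT = 11L, tAB_cMF = 12L, tAB_LT = 13L, tAB_cLF = 14L,
    femur = 21L, tibia = 22L)
}

#' Names of the four cartilage plates
#' @return Character vector: MT, cMF, LT, cLF.
#' @export
platesAll <- function() c("MT", "cMF", "LT", "cLF")

## label id helpers (internal)
cartilageLabelOf <- function(plate) unname(cartLabels()[plate])
boneAreaLabelOf <- function(plate) unname(cartLabels()[paste0("tAB_", plate)])

validGeometry <- function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite numbers (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite numbers (mm)")
  if (length(msg)) msg else TRUE
}

#' VoxelVolume: a 3D scalar image grid
#'
#' A 3D scalar grid with anisotropic voxel spacing (mm), world origin (mm)
#' and an acquisition-protocol identity. Axis order is fixed throughout the
#' package: x = anterior--posterior (+x anterior), y = medial--lateral,
#' z = inferior--superior. Voxel indices are 1-based in R; world coordinates
#' of voxel (i,j,k) are \code{origin + (c(i,j,k) - 1) * spacing}.
#'
#' @slot data 3D numeric array of intensities.
#' @slot spacing Voxel spacing in mm, length 3.
#' @slot origin World position of voxel (1,1,1) in mm, length 3.
#' @slot protocol Acquisition protocol identity, e.g. \code{"sagittal-DESS"}
#'   or \code{"coronal-FLASH"}.
#' @export
setClass("VoxelVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric",
                 protocol = "character"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0),
            protocol = "sagittal-DESS"))

setValidity("VoxelVolume", validGeometry)

#' LabelMask: a 3D integer label grid
#'
#' Shares the geometry model of \linkS4class{VoxelVolume}; voxel values are
#' integer labels from a declared dictionary (see \code{\link{cartLabels}}).
#'
#' @slot data 3D integer array of labels.
#' @slot spacing,origin,protocol As in \linkS4class{VoxelVolume}.
#' @slot labels Named integer vector declaring the permitted labels.
#' @export
setClass("LabelMask",
  representation(data = "array", spacing = "numeric", origin = "numeric",
                 protocol = "character", labels = "integer"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0),
            protocol = "sagittal-DESS", labels = cartLabels()))

setValidity("LabelMask", function(object) {
  msg <- validGeometry(object)
  msg <- if (isTRUE(msg)) character() else msg
  if (is.null(names(object@labels)))
    msg <- c(msg, "labels must be a named integer vector")
  bad <- setdiff(unique(as.vector(object@data)), object@labels)
  if (length(bad))
    msg <- c(msg, paste0("mask contains undeclared label id(s): ",
                         paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' PlateSurface: point cloud of one plate's subchondral bone area
#'
#' Boundary voxels of one plate's total subchondral bone area (tAB),
#' converted to points at voxel centers in world mm. Optionally carries
#' outward surface normals, per-point covered/denuded status (after cartilage
#' linking), and femoral landmarks.
#'
#' @slot points n x 3 matrix of world coordinates (mm).
#' @slot normals n x 3 matrix of outward unit normals, or 0-row if unset.
#' @slot plate Plate name ("MT", "cMF", "LT", "cLF") or "femur" for a
#'   combined femoral surface.
#' @slot covered Logical per point: cartilage present above the point
#'   (length 0 before linking).
#' @slot landmarks Named list with entries \code{notch} and \code{posterior}
#'   (length-3 world coordinates), possibly empty.
#' @slot spacing Voxel spacing (mm) of the source mask; used for
#'   discretization-aware tolerances.
#' @export
setClass("PlateSurface",
  representation(points = "matrix", normals = "matrix", plate = "character",
                 covered = "logical", landmarks = "list", spacing = "numeric"),
  prototype(normals = matrix(numeric(), 0, 3), covered = logical(),
            landmarks = list(), spacing = c(1, 1, 1)))

setValidity("PlateSurface", function(object) {
  msg <- character()
  if (ncol(object@points) != 3L) msg <- c(msg, "points must be n x 3")
  if (nrow(object@normals) && nrow(object@normals) != nrow(object@points))
    msg <- c(msg, "normals must match points row-for-row")
  if (length(object@covered) && length(object@covered) != nrow(object@points))
    msg <- c(msg, "covered must match points")
  if (length(msg)) msg else TRUE
})

#' BoneAtlas: reference point cloud of a plate's bone area
#'
#' Average shape of one plate's total subchondral bone area, built from one
#' or more segmented masks; centered so the centroid is at the origin.
#'
#' @slot points n x 3 matrix (mm), centroid at origin.
#' @slot plate Plate name.
#' @slot provenance Character ids of the masks the atlas was built from.
#' @export
setClass("BoneAtlas",
  representation(points = "matrix", plate = "character",
                 provenance = "character"))

setValidity("BoneAtlas", function(object) {
  msg <- character()
  if (nrow(object@points) < 1L) msg <- c(msg, "atlas must contain points")
  if (ncol(object@points) != 3L) msg <- c(msg, "points must be n x 3")
  ctr <- colMeans(object@points)
  if (nrow(object@points) && max(abs(ctr)) > 1e-6)
    msg <- c(msg, "atlas centroid must be at the origin")
  if (length(msg)) msg else TRUE
})

#' RigidTransform: result of rigid point-cloud registration
#'
#' Maps source points into the atlas frame: \code{x' = R x + t}.
#'
#' @slot rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @slot translation Length-3 translation (mm).
#' @slot residual Final root-mean-square point-to-point distance (mm).
#' @slot nIterations Iterations used.
#' @slot trace RMS residual per iteration (mm).
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric",
                 residual = "numeric", nIterations = "integer",
                 trace = "numeric"))

setValidity("RigidTransform", function(object) {
  msg <- character()
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) msg <- c(msg, "rotation must be 3 x 3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-6)
      msg <- c(msg, "rotation must be orthonormal (R'R = I within 1e-6)")
    if (abs(det(R) - 1) > 1e-6) msg <- c(msg, "rotation must have det +1")
  }
  if (length(object@residual) != 1L || object@residual < 0)
    msg <- c(msg, "residual must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' ThicknessMap: per-point cartilage thickness over a bone surface
#'
#' One thickness value (mm, >= 0; exactly 0 where the bone is denuded) per
#' subchondral bone surface point, together with the region id of each point.
#'
#' @slot points n x 3 matrix of bone surface points (mm).
#' @slot thickness Numeric per point (mm).
#' @slot region Character per point, one of MT, cMF, LT, cLF.
#' @slot covered Logical per point.
#' @export
setClass("ThicknessMap",
  representation(points = "matrix", thickness = "numeric",
                 region = "character", covered = "logical"))

setValidity("ThicknessMap", function(object) {
  msg <- character()
  n <- nrow(object@points)
  if (length(object@thickness) != n || length(object@region) != n ||
      length(object@covered) != n)
    msg <- c(msg, "thickness, region and covered must match points")
  if (any(!is.finite(object@thickness)) || any(object@thickness < 0))
    msg <- c(msg, "thickness must be finite and >= 0")
  if (any(!object@covered & object@thickness != 0))
    msg <- c(msg, "denuded points must have thickness 0")
  if (length(msg)) msg else TRUE
})

#' SegModel: a trained (or oracle) segmentation model
#'
#' Opaque parameters of a compact 2D U-Net for one segmentation target
#' (cartilage or bone-area) and one acquisition protocol. The special
#' \code{oracle = TRUE} variant bypasses inference and returns the phantom's
#' ground-truth labels, so downstream stages never depend on training.
#'
#' @slot params List of network weights (empty for oracle models).
#' @slot target "cartilage" or "bone-area".
#' @slot protocol Protocol the model was trained for.
#' @slot classes Character names of output classes (background first).
#' @slot config The \linkS4class{TrainConfig} used (as a list snapshot).
#' @slot oracle Logical; if TRUE, prediction returns ground truth.
#' @export
setClass("SegModel",
  representation(params = "list", target = "character", protocol = "character",
                 classes = "character", config = "list", oracle = "logical"),
  prototype(params = list(), config = list(), oracle = FALSE))
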