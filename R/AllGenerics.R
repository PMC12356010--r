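#' Accessors for image-grid objects
#'
#' @param x A \linkS4class{VoxelVolume}, \linkS4class{LabelMask},
#'   \linkS4class{PlateSurface}, or other package object.
#' @return \code{voxelData} returns the 3D array; \code{voxelSpacing} and
#'   \code{voxelOrigin} length-3 numerics in mm; \code{protocolOf} the
#'   protocol string; \code{labelDict} the named label vector;
#'   \code{surfacePoints} / \code{surfaceNormals} n x 3 matrices;
#'   \code{plateOf} the plate name; \code{coveredStatus} the per-point
#'   logical.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))
#' @rdname accessors
#' @export
setGeneric("protocolOf", function(x) standardGeneric("protocolOf"))
#' @rdname accessors
#' @export
setGeneric("labelDict", function(x) standardGeneric("labelDict"))
#' @rdname accessors
#' @export
setGeneric("surfacePoints", function(x) standardGeneric("surfacePoints"))
#' @rdname accessors
#' @export
setGeneric("surfaceNormals", function(x) standardGeneric("surfaceNormals"))
#' @rdname accessors
#' @export
setGeneric("plateOf", function(x) standardGeneric("plateOf"))
#' @rdname accessors
#' @export
setGeneric("coveredStatus", function(x) standardGeneric("coveredStatus"))

#' @rdname accessors
#' @export
setMethod("voxelData", "VoxelVolume", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("voxelData", "LabelMask", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "VoxelVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "LabelMask", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelOrigin", "VoxelVolume", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("voxelOrigin", "LabelMask", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("protocolOf", "VoxelVolume", function(x) x@protocol)
#' @rdname accessors
#' @export
setMethod("protocolOf", "LabelMask", function(x) x@protocol)
#' @rdname accessors
#' @export
setMethod("protocolOf", "SegModel", function(x) x@protocol)
#' @rdname accessors
#' @export
setMethod("labelDict", "LabelMask", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("surfacePoints", "PlateSurface", function(x) x@points)
#' @rdname accessors
#' @export
setMethod("surfacePoints", "BoneAtlas", function(x) x@points)
#' @rdname accessors
#' @export
setMethod("surfacePoints", "ThicknessMap", function(x) x@points)
#' @rdname accessors
#' @export
setMethod("surfaceNormals", "PlateSurface", function(x) x@normals)
#' @rdname accessors
#' @export
setMethod("plateOf", "PlateSurface", function(x) x@plate)
#' @rdname accessors
#' @export
setMethod("plateOf", "BoneAtlas", function(x) x@plate)
#' @rdname accessors
#' @export
setMethod("coveredStatus", "PlateSurface", function(x) x@covered)
#' @rdname accessors
#' @export
setMethod("coveredStatus", "ThicknessMap", function(x) x@covered)

#' Per-point thickness values of a ThicknessMap
#' @param x A \linkS4class{ThicknessMap}.
#' @return Numeric vector (mm).
#' @export
setGeneric("thicknessValues", function(x) standardGeneric("thicknessValues"))
#' @rdname thicknessValues
#' @export
setMethod("thicknessValues", "ThicknessMap", function(x) x@thickness)

#' Region id of each point of a ThicknessMap
#' @param x A \linkS4class{ThicknessMap}.
#' @return Character vector of plate names.
#' @export
setGeneric("regionOf", function(x) standardGeneric("regionOf"))
#' @rdname regionOf
#' @export
setMethod("regionOf", "ThicknessMap", function(x) x@region)

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@data)
  cat("VoxelVolume ", paste(d, collapse = " x "),
      " | spacing ", paste(signif(object@spacing, 3), collapse = " x "),
      " mm | protocol ", object@protocol, "\n", sep = "")
  invisible(object)
})

setMethod("show", "LabelMask", function(object) {
  d <- dim(object@data)
  present <- sort(unique(as.vector(object@data)))
  nm <- names(object@labels)[match(present, object@labels)]
  cat("LabelMask ", paste(d, collapse = " x "),
      " | spacing ", paste(signif(object@spacing, 3), collapse = " x "),
      " mm | protocol ", object@protocol, "\n  labels present: ",
      paste(nm, collapse = ", "), "\n", sep = "")
  invisible(object)
})

setMethod("show", "PlateSurface", function(object) {
  cat("PlateSurface [", object@plate, "] ", nrow(object@points), " points",
      if (nrow(object@normals)) ", with normals" else "",
      if (length(object@covered))
        sprintf(", %.1f%% denuded", 100 * mean(!object@covered)) else "",
      "\n", sep = "")
  invisible(object)
})

setMethod("show", "BoneAtlas", function(object) {
  cat("BoneAtlas [", object@plate, "] ", nrow(object@points),
      " points, from ", length(object@provenance), " mask(s)\n", sep = "")
  invisible(object)
})

setMethod("show", "RigidTransform", function(object) {
  ang <- rotationAngleDeg(object@rotation)
  cat(sprintf(
    "RigidTransform: rotation %.2f deg, translation (%.2f, %.2f, %.2f) mm\n",
    ang, object@translation[1], object@translation[2], object@translation[3]))
  cat(sprintf("  RMS residual %.4f mm after %d iteration(s)\n",
              object@residual, object@nIterations))
  invisible(object)
})

setMethod("show", "ThicknessMap", function(object) {
  cat("ThicknessMap ", nrow(object@points), " points | regions: ",
      paste(unique(object@region), collapse = ", "),
      sprintf(" | mean %.2f mm, %.1f%% denuded\n",
              mean(object@thickness), 100 * mean(!object@covered)), sep = "")
  invisible(object)
})

setMethod("show", "SegModel", function(object) {
  cat("SegModel [", object@target, ", ", object@protocol, "] ",
      if (object@oracle) "ground-truth oracle"
      else paste0("U-Net, classes: ", paste(object@classes, collapse = ", ")),
      "\n", sep = "")
  invisible(object)
})
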