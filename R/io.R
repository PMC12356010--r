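# Volume/mask/table I/O. Volumes and masks are written as NIfTI (spacing in
# the NIfTI header; spacing, origin, protocol and the label dictionary
# duplicated in a JSON sidecar so round-trips are exact and
# self-describing). Tables are plain CSV with schema validation.

sidecarPath <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

niftiGeometry <- function(spacing, origin) {
  ## NIfTI affine: voxel indices (0-based) -> world mm
  aff <- diag(4)
  aff[1, 1] <- spacing[1]; aff[2, 2] <- spacing[2]; aff[3, 3] <- spacing[3]
  aff[1:3, 4] <- origin
  aff
}

#' Write / read a VoxelVolume as NIfTI
#'
#' Geometry (spacing, origin), protocol and -- for masks -- the label
#' dictionary are stored in a JSON sidecar next to the NIfTI file; the
#' NIfTI header carries the same spacing and affine.
#'
#' @param volume A \linkS4class{VoxelVolume}.
#' @param path Output path (.nii or .nii.gz).
#' @return \code{writeVolume} the path (invisibly); \code{readVolume} a
#'   \linkS4class{VoxelVolume}.
#' @export
writeVolume <- function(volume, path) {
  a <- voxelData(volume)
  attr(a, "pixdim") <- voxelSpacing(volume)
  RNifti::writeNifti(RNifti::asNifti(a), path)
  jsonlite::write_json(
    list(type = "VoxelVolume", spacing = voxelSpacing(volume),
         origin = voxelOrigin(volume), protocol = protocolOf(volume)),
    sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

readSidecar <- function(path, what) {
  sc <- sidecarPath(path)
  if (!file.exists(sc))
    stop("missing sidecar JSON for ", path)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (!identical(meta$type, what))
    stop("sidecar declares ", meta$type, ", expected ", what)
  meta
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  meta <- readSidecar(path, "VoxelVolume")
  img <- RNifti::readNifti(path)
  new("VoxelVolume", data = array(as.numeric(img), dim(img)),
      spacing = as.numeric(meta$spacing), origin = as.numeric(meta$origin),
      protocol = meta$protocol)
}

#' Write / read a LabelMask as NIfTI
#'
#' @param mask A \linkS4class{LabelMask}.
#' @param path Output path (.nii or .nii.gz).
#' @return \code{writeMask} the path (invisibly); \code{readMask} a
#'   validated \linkS4class{LabelMask} (undeclared label ids in the file are
#'   an error naming the ids).
#' @export
writeMask <- function(mask, path) {
  a <- voxelData(mask)
  attr(a, "pixdim") <- voxelSpacing(mask)
  RNifti::writeNifti(RNifti::asNifti(a, datatype = "int16"), path)
  jsonlite::write_json(
    list(type = "LabelMask", spacing = voxelSpacing(mask),
         origin = voxelOrigin(mask), protocol = protocolOf(mask),
         labels = as.list(labelDict(mask))),
    sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  meta <- readSidecar(path, "LabelMask")
  img <- RNifti::readNifti(path)
  labels <- unlist(meta$labels)
  mode(labels) <- "integer"
  new("LabelMask", data = array(as.integer(img), dim(img)),
      spacing = as.numeric(meta$spacing), origin = as.numeric(meta$origin),
      protocol = meta$protocol, labels = labels)
}

#' Write / read a CSV table with schema validation
#'
#' @param tbl data.frame.
#' @param path CSV path.
#' @param requiredColumns Character vector; on read, missing columns raise
#'   an error listing them.
#' @return \code{writeTable} the path (invisibly); \code{readTable} a
#'   data.frame.
#' @export
writeTable <- function(tbl, path) {
  utils::write.csv(tbl, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTable
#' @export
readTable <- function(path, requiredColumns = NULL) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(requiredColumns)) {
    miss <- setdiff(requiredColumns, names(tbl))
    if (length(miss))
      stop("schema error: missing column(s) ", paste(miss, collapse = ", "))
  }
  tbl
}
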