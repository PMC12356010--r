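# End-to-end driver: simulate a longitudinal phantom cohort, segment
# (ground-truth oracle or trained U-Net), optionally corrupt and
# post-process, measure per-plate thickness and denuded area, and qualify
# the change statistics. Deterministic under a fixed seed; emits CSV
# outputs plus a provenance log.

#' PipelineConfig: configuration of the end-to-end phantom pipeline
#'
#' @slot protocol Acquisition protocol.
#' @slot roiFraction Femoral ROI fraction; NA means the protocol default
#'   (0.75 sagittal DESS, 0.60 coronal FLASH).
#' @slot spacing Phantom voxel spacing for the driver (mm).
#' @slot strata data.frame(name, n, mean_um, sd_um): per-plate 24-month
#'   thickness change moments per stratum.
#' @slot segmentation "oracle" (ground truth) or "unet".
#' @slot corruption Corruption configuration list (see
#'   \code{\link{corruptionConfig}}) or empty list for none.
#' @slot postprocess Apply atlas reconstruction + autocorrection when
#'   corruption is enabled.
#' @slot rules Autocorrection rules (\code{\link{autocorrectRules}}).
#' @slot icp ICP configuration (\code{\link{icpConfig}}).
#' @slot corrRadius Reconstruction correspondence radius (mm).
#' @slot bootIter Bootstrap iterations for report intervals.
#' @slot seed Integer master seed; every stage seed derives from it and is
#'   recorded in the provenance log.
#' @export
setClass("PipelineConfig",
  representation(protocol = "character", roiFraction = "numeric",
                 spacing = "numeric", strata = "data.frame",
                 segmentation = "character", corruption = "list",
                 postprocess = "logical", rules = "list", icp = "list",
                 corrRadius = "numeric", bootIter = "numeric",
                 seed = "numeric"))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (!is.na(object@roiFraction) &&
      (object@roiFraction <= 0 || object@roiFraction > 1))
    msg <- c(msg, "roiFraction must be in (0, 1]")
  if (!object@segmentation %in% c("oracle", "unet"))
    msg <- c(msg, "segmentation must be 'oracle' or 'unet'")
  if (!all(c("name", "n", "mean_um", "sd_um") %in% names(object@strata)))
    msg <- c(msg, "strata needs columns name, n, mean_um, sd_um")
  else if (any(object@strata$n < 1))
    msg <- c(msg, "strata sizes must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a PipelineConfig
#'
#' Defaults: sagittal DESS-like protocol at a coarsened driver spacing, two
#' strata of 6 knees with per-plate change moments whose compartment sums
#' match the published medial-compartment progressor / non-progressor
#' structure, oracle segmentation, no corruption.
#'
#' @param protocol,roiFraction,spacing,strata,segmentation,corruption
#'   See slots.
#' @param postprocess,rules,icp,corrRadius,bootIter,seed See slots.
#' @return A validated \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(protocol = "sagittal-DESS", roiFraction = NA_real_,
                           spacing = c(0.7, 1.0, 0.7),
                           strata = data.frame(
                             name = c("progressor", "non-progressor"),
                             n = c(6L, 6L),
                             mean_um = c(-80, -4),
                             sd_um = c(158, 78)),
                           segmentation = "oracle",
                           corruption = list(), postprocess = TRUE,
                           rules = autocorrectRules(), icp = icpConfig(),
                           corrRadius = 1.0, bootIter = 200L, seed = 1) {
  new("PipelineConfig", protocol = protocol, roiFraction = roiFraction,
      spacing = spacing, strata = strata, segmentation = segmentation,
      corruption = corruption, postprocess = postprocess, rules = rules,
      icp = icp, corrRadius = corrRadius, bootIter = bootIter, seed = seed)
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig [", object@protocol, "] ",
      sum(object@strata$n), " knees in ", nrow(object@strata),
      " strata, segmentation ", object@segmentation,
      if (length(object@corruption)) ", with corruption" else "",
      ", seed ", object@seed, "\n", sep = "")
  invisible(object)
})

combinedFemoralSurface <- function(surfaces) {
  pts <- rbind(surfaces[["cMF"]]@points, surfaces[["cLF"]]@points)
  new("PlateSurface", points = pts, plate = "femur",
      spacing = surfaces[["cMF"]]@spacing)
}

#' Post-process a segmented mask
#'
#' Runs the full post-processing chain on one knee's mask: per-plate
#' bone-area surface extraction, ICP registration to the plate atlas and
#' reconstruction of missing bone area (when atlases are given), and
#' automated cartilage correction (gap closing, fragment removal,
#' implausible-cartilage cropping).
#'
#' @param mask Segmented \linkS4class{LabelMask}.
#' @param atlases Named list of \linkS4class{BoneAtlas} per plate, or NULL
#'   to skip reconstruction.
#' @param rules,icp,corrRadius See \code{\link{autocorrectRules}},
#'   \code{\link{icpConfig}}, \code{\link{reconstructBoneArea}}.
#' @return List: \code{mask} (corrected), \code{surfaces} (named list of
#'   per-plate \linkS4class{PlateSurface}), \code{log} (correction log).
#' @export
postprocessMask <- function(mask, atlases = NULL,
                            rules = autocorrectRules(), icp = icpConfig(),
                            corrRadius = 1.0) {
  surfaces <- list()
  for (p in platesAll()) {
    srf <- boneAreaSurface(mask, p, withNormals = FALSE)
    if (!is.null(atlases) && !is.null(atlases[[p]])) {
      tf <- registerICP(srf, atlases[[p]], icp)
      srf <- reconstructBoneArea(srf, atlases[[p]], tf,
                                 corrRadius = corrRadius)
    }
    surfaces[[p]] <- srf
  }
  ac <- autocorrect(mask, surfaces, rules)
  list(mask = ac$mask, surfaces = surfaces, log = ac$log)
}

#' Measure per-region morphometry of one knee mask
#'
#' Detects femoral landmarks, trims the femoral plates to the ROI fraction,
#' computes per-plate thickness maps, and emits the long region summary
#' (four plates plus the MFTC and LFTC compartment sums).
#'
#' @param mask \linkS4class{LabelMask} with cartilage and bone-area labels.
#' @param roiFraction Femoral ROI fraction in (0, 1].
#' @param surfaces Optional named list of per-plate surfaces (e.g. from
#'   \code{\link{postprocessMask}}); extracted from the mask otherwise.
#' @param kneeId,visit,method Identifiers for the rows.
#' @param maxThickness,searchDistance Thickness/link parameters (mm).
#' @return data.frame: knee_id, visit, method, region, mean_thickness_mm,
#'   dab_pct for MT, cMF, LT, cLF, MFTC, LFTC.
#' @export
measureMask <- function(mask, roiFraction = 0.75, surfaces = NULL,
                        kneeId = "knee", visit = "BL", method = "auto",
                        maxThickness = 8, searchDistance = 2.5) {
  if (roiFraction <= 0 || roiFraction > 1)
    stop("roiFraction must be in (0, 1]")
  if (is.null(surfaces)) {
    surfaces <- list()
    for (p in platesAll())
      surfaces[[p]] <- boneAreaSurface(mask, p, withNormals = FALSE)
  }
  fem <- detectLandmarks(combinedFemoralSurface(surfaces))
  lm <- fem@landmarks
  rows <- list()
  for (p in platesAll()) {
    srf <- surfaces[[p]]
    if (p %in% c("cMF", "cLF")) {
      srf@landmarks <- lm
      srf <- extractFemoralROI(srf, roiFraction)
    }
    tm <- computeThickness(mask, srf, maxThickness = maxThickness,
                           searchDistance = searchDistance)
    rows[[p]] <- summarizeThickness(tm, p, kneeId, visit, method)
  }
  out <- rbind(rows$MT, rows$cMF, rows$LT, rows$cLF,
               aggregateCompartment(rows$MT, rows$cMF),
               aggregateCompartment(rows$LT, rows$cLF))
  rownames(out) <- NULL
  out
}

#' Run the end-to-end phantom pipeline
#'
#' Simulates a longitudinal two-visit phantom cohort under the configured
#' strata, segments each visit (oracle ground truth or the optional U-Net),
#' optionally corrupts masks and repairs them by post-processing, measures
#' per-region thickness, and qualifies the change statistics. Identical
#' configuration yields byte-identical CSV outputs.
#'
#' @param config A \linkS4class{PipelineConfig}.
#' @param outDir Output directory (created if missing); NULL writes no
#'   files.
#' @return List: \code{morphometry} (long per-visit table), \code{changes}
#'   (per-knee change scores), \code{report}
#'   (\code{\link{cohortReport}} output), \code{provenance} (list),
#'   \code{failures} (per-knee error messages, normally empty).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
  validObject(config)
  fraction <- if (is.na(config@roiFraction))
    protocolRoiFraction(config@protocol) else config@roiFraction
  corrupt <- length(config@corruption) > 0
  atlases <- NULL
  if (corrupt && config@postprocess &&
      (config@corruption$deleteBoneFraction %||% 0) > 0) {
    atlases <- list()
    atlasMasks <- lapply(1:3, function(k) {
      makePhantom(phantomSpec(protocol = config@protocol,
                              spacing = config@spacing,
                              seed = childSeed(config@seed, 900 + k)))$mask
    })
    for (p in platesAll())
      atlases[[p]] <- buildAtlas(atlasMasks, p, config@icp)
  }
  rows <- list()
  failures <- list()
  kneeNo <- 0L
  for (si in seq_len(nrow(config@strata))) {
    st <- config@strata[si, ]
    for (ki in seq_len(st$n)) {
      kneeNo <- kneeNo + 1L
      kneeId <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "", st$name), ki)
      res <- tryCatch({
        kseed <- childSeed(config@seed, kneeNo)
        draws <- withSeed(kseed, {
          list(base = stats::rnorm(4, 0, 0.15),
               delta = stats::rnorm(4, st$mean_um, st$sd_um))
        })
        base0 <- c(MT = 1.6, cMF = 1.7, LT = 2.0, cLF = 1.9) + draws$base
        kneeRows <- list()
        for (vi in 1:2) {
          visit <- c("BL", "24M")[vi]
          thick <- if (vi == 1) base0 else base0 + draws$delta / 1000
          spec <- phantomSpec(protocol = config@protocol,
                              spacing = config@spacing,
                              baseThickness = thick, seed = kseed)
          ph <- makePhantom(spec)
          mask <- if (config@segmentation == "oracle") ph$mask
                  else stop("unet segmentation in runPipeline requires ",
                            "pretrained models; use the oracle driver")
          surfaces <- NULL
          if (corrupt) {
            mask <- corruptMask(mask, config@corruption,
                                seed = childSeed(kseed, vi), spec = spec)
            if (config@postprocess) {
              pp <- postprocessMask(mask, atlases, config@rules,
                                    config@icp, config@corrRadius)
              mask <- pp$mask
              surfaces <- pp$surfaces
            }
          }
          kneeRows[[vi]] <- measureMask(mask, fraction, surfaces,
                                        kneeId = kneeId, visit = visit,
                                        method = config@segmentation)
          kneeRows[[vi]]$stratum <- st$name
        }
        do.call(rbind, kneeRows)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[kneeId]] <- conditionMessage(res)
      } else {
        rows[[kneeId]] <- res
      }
    }
  }
  if (!length(rows)) stop("all knees failed: ",
                          paste(unlist(failures), collapse = "; "))
  morph <- do.call(rbind, rows)
  rownames(morph) <- NULL
  changes <- changeScores(morph)
  report <- cohortReport(changes,
                         progressorStratum = config@strata$name[1],
                         referenceStratum = config@strata$name[
                           min(2, nrow(config@strata))],
                         nBoot = config@bootIter,
                         seed = childSeed(config@seed, 7001))
  provenance <- list(
    configHash = configHash(config),
    seed = config@seed,
    stageSeeds = list(knees = "childSeed(seed, kneeNo)",
                      atlas = "childSeed(seed, 900+k)",
                      bootstrap = childSeed(config@seed, 7001)),
    package = as.character(utils::packageVersion("cartMorph")),
    protocol = config@protocol, roiFraction = fraction,
    nKnees = kneeNo, failures = length(failures))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeTable(morph, file.path(outDir, "morphometry.csv"))
    writeTable(changes, file.path(outDir, "changes.csv"))
    writeTable(report, file.path(outDir, "report.csv"))
    jsonlite::write_json(provenance, file.path(outDir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(morphometry = morph, changes = changes, report = report,
       provenance = provenance, failures = failures)
}

## md5 of the canonical JSON serialization of a config
configHash <- function(config) {
  sl <- sapply(methods::slotNames(class(config)), function(s)
    methods::slot(config, s), simplify = FALSE)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(sl, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}
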