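# Shared fixtures, built once per test run and memoized. Coarse spacing is
# used where sub-voxel accuracy is not under test.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

## standard DESS-resolution phantom
dessPhantom <- function(seed = 1) {
  memo(paste0("dess", seed), makePhantom(phantomSpec(seed = seed)))
}

## coarse phantom for structural (non-accuracy) tests
coarseSpec <- function(seed = 1, ...) {
  phantomSpec(spacing = c(0.8, 1.0, 0.8), seed = seed, ...)
}

coarsePhantom <- function(seed = 1) {
  memo(paste0("coarse", seed), makePhantom(coarseSpec(seed = seed)))
}

## plate surfaces of a mask, as a named list
plateSurfaces <- function(mask, normals = FALSE) {
  out <- list()
  for (p in platesAll())
    out[[p]] <- boneAreaSurface(mask, p, withNormals = normals)
  out
}

## a lesion covering a known fraction of the MT plate (area 19 x 12.6 mm)
mtLesion <- function(fracPct = 10, residual = 0) {
  area <- 19 * 12.6
  r <- sqrt(fracPct / 100 * area / pi)
  data.frame(plate = "MT", u = 9.5, v = 6.3, radius = r,
             residual = residual)
}

## analytic vs measured relative error (%) for the four plates
plateErrors <- function(ph, m) {
  mm <- merge(m[m$region %in% platesAll(),
                c("region", "mean_thickness_mm")],
              ph$summary, by = "region")
  100 * (mm$mean_thickness_mm.x / mm$mean_thickness_mm.y - 1)
}
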