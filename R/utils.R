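# Internal numerical utilities: seeded evaluation, geometry conversions,
# trilinear sampling, brute-force nearest neighbours, 3D connected
# components and axis-aligned morphological closing on anisotropic grids.

## Evaluate expr under a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Derive a child seed from a base seed; keeps results < 2^31.
childSeed <- function(seed, k) {
  (as.numeric(seed) * 7919 + 104729 * k) %% 2147483647
}

## world coords (n x 3, mm) of 1-based voxel indices (n x 3)
indexToWorld <- function(idx, spacing, origin) {
  sweep(sweep(idx - 1, 2, spacing, "*"), 2, origin, "+")
}

worldToIndex <- function(pts, spacing, origin) {
  sweep(sweep(pts, 2, origin, "-"), 2, spacing, "/") + 1
}

## Trilinear interpolation of a 3D array at fractional 1-based indices.
## Out-of-range samples return `fill`.
trilinear <- function(arr, idx, fill = 0) {
  d <- dim(arr)
  i0 <- floor(idx)
  f <- idx - i0
  val <- numeric(nrow(idx))
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  val[!ok] <- fill
  if (!any(ok)) return(val)
  i0 <- i0[ok, , drop = FALSE]
  f <- f[ok, , drop = FALSE]
  ## clamp so i0 and i0+1 are valid; adjust fraction at the upper edge
  for (a in 1:3) {
    hi <- i0[, a] >= d[a]
    i0[hi, a] <- d[a] - 1
    f[hi, a] <- 1
    lo <- i0[, a] < 1
    i0[lo, a] <- 1
    f[lo, a] <- 0
  }
  at <- function(dx, dy, dz) {
    arr[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  v <-
    at(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
    at(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
    at(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    at(1, 1, 0) * fx * fy * (1 - fz) +
    at(1, 0, 1) * fx * (1 - fy) * fz +
    at(0, 1, 1) * (1 - fx) * fy * fz +
    at(1, 1, 1) * fx * fy * fz
  val[ok] <- v
  val
}

## Squared Euclidean cross-distances between rows of a (n x 3) and b (m x 3).
crossDist2 <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

## For each row of `query`, index and distance of nearest row of `ref`.
## Chunked to bound memory at large n.
nearestNeighbor <- function(query, ref, chunk = 2000L) {
  n <- nrow(query)
  idx <- integer(n)
  dist <- numeric(n)
  s <- 1L
  while (s <= n) {
    e <- min(n, s + chunk - 1L)
    d2 <- crossDist2(query[s:e, , drop = FALSE], ref)
    j <- max.col(-d2, ties.method = "first")
    idx[s:e] <- j
    dist[s:e] <- sqrt(d2[cbind(seq_len(e - s + 1L), j)])
    s <- e + 1L
  }
  list(index = idx, distance = dist)
}

## k nearest neighbours (excluding self if query==ref and exclude = TRUE)
kNearest <- function(query, ref, k, excludeSelf = FALSE, chunk = 2000L) {
  n <- nrow(query)
  out <- matrix(0L, n, k)
  s <- 1L
  while (s <= n) {
    e <- min(n, s + chunk - 1L)
    d2 <- crossDist2(query[s:e, , drop = FALSE], ref)
    if (excludeSelf) d2[cbind(seq_len(e - s + 1L), s:e)] <- Inf
    for (r in seq_len(e - s + 1L)) {
      out[s + r - 1L, ] <- order(d2[r, ])[seq_len(k)]
    }
    s <- e + 1L
  }
  out
}

## Shift a 3D logical/numeric array by (dx,dy,dz), filling with `fill`.
shiftArray <- function(arr, dx, dy, dz, fill = FALSE) {
  d <- dim(arr)
  out <- array(fill, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- arr[sx - dx, sy - dy, sz - dz]
  out
}

## 6-connected component labelling of a 3D logical array by iterative
## minimum-label propagation. Returns integer array (0 = background) with
## components renumbered 1..k by decreasing size.
labelComponents3D <- function(mask) {
  d <- dim(mask)
  lab <- array(0, d)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    nb <- lab
    for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                    c(0, 0, 1), c(0, 0, -1))) {
      s <- shiftArray(lab, sh[1], sh[2], sh[3], fill = 0)
      upd <- mask & s > 0 & (nb == 0 | s < nb)
      nb[upd] <- s[upd]
    }
    if (identical(nb, lab)) break
    lab <- nb
  }
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids)) return(array(0L, d))
  sz <- tabulate(match(lab[lab > 0], ids))
  ord <- order(sz, decreasing = TRUE)
  remap <- integer(max(ids))
  remap[ids[ord]] <- seq_along(ids)
  out <- array(0L, d)
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

## Binary dilation with an axis-aligned box of physical half-width r (mm),
## honouring anisotropic spacing.
dilateBox <- function(mask, r, spacing) {
  steps <- pmin(ceiling(r / spacing - 1e-9), dim(mask) - 1)
  out <- mask
  for (a in 1:3) {
    if (steps[a] < 1) next
    acc <- out
    for (s in seq_len(steps[a])) {
      sh <- c(0, 0, 0); sh[a] <- s
      acc <- acc | shiftArray(out, sh[1], sh[2], sh[3]) |
        shiftArray(out, -sh[1], -sh[2], -sh[3])
    }
    out <- acc
  }
  out
}

erodeBox <- function(mask, r, spacing) {
  !dilateBox(!mask, r, spacing)
}

## Morphological closing with box structuring element of half-width r mm.
closeBox <- function(mask, r, spacing) {
  erodeBox(dilateBox(mask, r, spacing), r, spacing)
}

#' Rotation helpers
#'
#' \code{rotationAngleDeg} gives the rotation angle (degrees) of a 3 x 3
#' rotation matrix; \code{rotZ} builds the rotation about the z (vertical)
#' axis by the given angle. Convenient when constructing and checking rigid
#' transforms.
#'
#' @param R 3 x 3 rotation matrix.
#' @param deg Angle in degrees.
#' @return \code{rotationAngleDeg}: a scalar angle in degrees;
#'   \code{rotZ}: a 3 x 3 rotation matrix.
#' @export
rotationAngleDeg <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

#' @rdname rotationAngleDeg
#' @export
rotZ <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

## Geometry equality check between two grid objects.
sameGeometry <- function(a, b, tol = 1e-6) {
  identical(dim(a@data), dim(b@data)) &&
    max(abs(a@spacing - b@spacing)) < tol &&
    max(abs(a@origin - b@origin)) < tol
}

`%||%` <- function(a, b) if (is.null(a)) b else a
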