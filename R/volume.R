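#' 3-D scalar volume
#'
#' Container for a 3-D grid of non-negative integer intensities (e.g. a
#' HU-shifted 12-bit CT series) together with its voxel spacing. Intensities
#' must already be quantized: floating-point values are rejected rather than
#' rounded, because the affinity lookup table is exact only for integers.
#'
#' @param data 3-D array of non-negative integer-valued intensities.
#' @param spacing Numeric length-3 vector, mm per voxel along (x, y, z).
#' @param intensity_max Largest representable intensity (default 4095, the
#'   12-bit CT range). All voxels must lie in `[0, intensity_max]`.
#' @return An object of class `volume3d` with fields `data` (integer array),
#'   `spacing` and `intensity_max`.
#' @examples
#' vol <- volume3d(array(0:7, c(2, 2, 2)), spacing = c(0.7, 0.7, 1), intensity_max = 255)
#' dim(vol)
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), intensity_max = 4095L) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  if (any(dim(data) < 1L)) stop("all shape components must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers")
  intensity_max <- as.integer(intensity_max)
  if (length(intensity_max) != 1L || is.na(intensity_max) || intensity_max < 1L)
    stop("`intensity_max` must be a positive integer")
  v <- as.vector(data)
  if (anyNA(v)) stop("intensities must not contain NA")
  if (any(v < 0)) stop("intensities must be non-negative")
  if (is.double(v) && any(v != round(v)))
    stop("intensities must be integers; input must be pre-quantized")
  if (any(v > intensity_max))
    stop("intensities exceed `intensity_max`")
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing = spacing,
                 intensity_max = intensity_max),
            class = "volume3d")
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, intensities [%d, %d] (max representable %d)\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$data), max(x$data), x$intensity_max))
  invisible(x)
}

#' Seed voxel set
#'
#' One or more 0-based (x, y, z) voxel coordinates from which connectedness is
#' propagated. Coordinates must be distinct and, when a volume is supplied,
#' inside its bounds.
#'
#' @param coords Numeric vector of length 3, or an n-by-3 matrix, of 0-based
#'   voxel indices in (x, y, z) order.
#' @param vol Optional [volume3d()] used to bounds-check the coordinates.
#' @return An object of class `seed_set`: an n-by-3 integer matrix.
#' @examples
#' seed_set(c(1, 2, 0))
#' @export
seed_set <- function(coords, vol = NULL) {
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1L)
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || nrow(coords) < 1L)
    stop("`coords` must be an n-by-3 matrix of (x, y, z) voxel indices")
  if (anyNA(coords) || any(coords != round(coords)) || any(coords < 0))
    stop("seed coordinates must be non-negative integers")
  storage.mode(coords) <- "integer"
  if (anyDuplicated(as.data.frame(coords)) > 0L)
    stop("duplicate seed coordinates")
  if (!is.null(vol)) {
    d <- dim(vol)
    if (any(coords[, 1] >= d[1] | coords[, 2] >= d[2] | coords[, 3] >= d[3]))
      stop("seed coordinate outside the volume bounds")
  }
  colnames(coords) <- c("x", "y", "z")
  structure(coords, class = c("seed_set", "matrix"))
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set> %d seed(s), 0-based (x, y, z):\n", nrow(x)))
  print(unclass(x))
  invisible(x)
}

#' Fuzzy connectedness scene
#'
#' Per-voxel connectedness values in `[0, 1]`: each voxel carries the strength
#' of its best path to the seed set, a path's strength being its weakest link
#' (minimum pairwise affinity). Seed voxels carry exactly 1.
#'
#' @param values 3-D numeric array of connectedness values in `[0, 1]`.
#' @param seeds The [seed_set()] the scene was computed from.
#' @param spacing Voxel spacing carried over from the input volume.
#' @return An object of class `fuzzy_scene`.
#' @export
fuzzy_scene <- function(values, seeds, spacing = c(1, 1, 1)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  if (anyNA(values) || any(values < 0) || any(values > 1))
    stop("connectedness values must lie in [0, 1]")
  seeds <- seed_set(seeds)
  sv <- values[seeds + 1L]
  if (any(sv != 1))
    stop("scene values at seed coordinates must equal exactly 1")
  structure(list(values = values, seeds = seeds, spacing = as.numeric(spacing)),
            class = "fuzzy_scene")
}

#' @export
dim.fuzzy_scene <- function(x) dim(x$values)

#' @export
print.fuzzy_scene <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<fuzzy_scene> %d x %d x %d voxels, values [%.4g, %.4g], %d seed(s)\n",
              d[1], d[2], d[3], min(x$values), max(x$values), nrow(x$seeds)))
  invisible(x)
}

#' Face-adjacent neighbours of a voxel
#'
#' Returns the 6-adjacent (face-sharing) coordinates of `coord` that lie inside
#' the volume, in the fixed order (-x, +x, -y, +y, -z, +z) with out-of-bounds
#' entries omitted. The fixed order makes propagation traces reproducible; the
#' computed scenes are order-independent by the max-min algebra.
#'
#' @param coord 0-based (x, y, z) voxel coordinate.
#' @param vol A [volume3d()] (or anything with a 3-long `dim()`).
#' @return Integer matrix with up to 6 rows and columns (x, y, z).
#' @examples
#' vol <- volume3d(array(0L, c(3, 3, 3)), intensity_max = 1)
#' neighbors6(c(1, 1, 1), vol)   # interior voxel: 6 rows
#' neighbors6(c(0, 0, 0), vol)   # corner: 3 rows
#' @export
neighbors6 <- function(coord, vol) {
  d <- dim(vol)
  coord <- as.integer(coord)
  if (length(coord) != 3L || any(coord < 0) || any(coord >= d))
    stop("`coord` outside the volume bounds")
  offs <- matrix(c(-1L, 0L, 0L,  1L, 0L, 0L,
                   0L, -1L, 0L,  0L, 1L, 0L,
                   0L, 0L, -1L,  0L, 0L, 1L),
                 ncol = 3L, byrow = TRUE)
  nb <- sweep(offs, 2L, coord, `+`)
  keep <- nb[, 1] >= 0L & nb[, 1] < d[1] &
          nb[, 2] >= 0L & nb[, 2] < d[2] &
          nb[, 3] >= 0L & nb[, 3] < d[3]
  out <- nb[keep, , drop = FALSE]
  colnames(out) <- c("x", "y", "z")
  out
}

# 0-based linear index (x fastest) used by the compiled core
voxel_index <- function(coords, d) {
  coords[, 1] + d[1] * (coords[, 2] + d[2] * coords[, 3])
}
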