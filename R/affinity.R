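# Peak-normalized Gaussian, floored at the smallest positive normal double so
# every affinity stays strictly positive (the max-min closure then reaches
# every voxel). Peak normalization (max value 1) is required for the affinity
# to be a fuzzy relation bounded by 1.
gauss_peak <- function(x, m, v) {
  pmax(exp(-((x - m)^2) / (2 * v)), .Machine$double.xmin)
}

#' Gaussian intensity-pair affinity model
#'
#' Parameters of the fuzzy spel affinity
#' \deqn{\mu_k(c,d) = \mu_\alpha(c,d)\,\sqrt{g_1\!\big(\tfrac{f(c)+f(d)}{2}\big)\,
#'   g_2\!\big(\tfrac{|f(c)-f(d)|}{2}\big)}}
#' where \eqn{g_1} is a peak-normalized Gaussian with mean `m1` and variance
#' `v1` (the object intensity model), \eqn{g_2} is a zero-mean peak-normalized
#' Gaussian with variance `v2` (the homogeneity model), and \eqn{\mu_\alpha}
#' is the hard 6-face-adjacency indicator.
#'
#' @param m1 Mean object intensity (intensity units).
#' @param v1 Variance of the object intensity Gaussian (intensity^2 units);
#'   floored at `1e-6` to avoid division by zero on constant regions.
#' @param v2 Variance of the zero-mean intensity-difference Gaussian;
#'   defaults to `v1`.
#' @param intensity_max Intensity ceiling the model is meant for; used as the
#'   default table size by [build_lut()].
#' @return An object of class `affinity_model`.
#' @export
affinity_model <- function(m1, v1, v2 = v1, intensity_max = 4095L) {
  eps <- 1e-6
  if (!is.finite(m1)) stop("`m1` must be finite")
  if (!is.finite(v1) || v1 < 0) stop("`v1` must be non-negative")
  if (!is.finite(v2) || v2 < 0) stop("`v2` must be non-negative")
  structure(list(m1 = as.numeric(m1),
                 v1 = max(as.numeric(v1), eps),
                 v2 = max(as.numeric(v2), eps),
                 adjacency = "face6",
                 intensity_max = as.integer(intensity_max)),
            class = "affinity_model")
}

#' @export
print.affinity_model <- function(x, ...) {
  cat(sprintf("<affinity_model> g1: N(%.6g, %.6g), g2: N(0, %.6g), 6-face adjacency, intensity_max %d\n",
              x$m1, x$v1, x$v2, x$intensity_max))
  invisible(x)
}

#' Estimate the affinity model from a seed region
#'
#' Pools the intensities inside axis-aligned boxes of half-width `radius`
#' around each seed (clipped to the volume bounds) and sets `m1`, `v1` to
#' their sample mean and sample variance (denominator n - 1; a single-voxel
#' region gets the variance floor). `v2` is tied to `v1` by default, since
#' only the zero mean of the homogeneity Gaussian is prescribed.
#'
#' @param vol A [volume3d()].
#' @param seeds A [seed_set()].
#' @param radius Non-negative integer box half-width in voxels.
#' @param sigma2_mode Either `"equal_v1"` (default, `v2 = v1`) or a fixed
#'   numeric variance for `v2`.
#' @return An [affinity_model()].
#' @examples
#' vol <- volume3d(array(c(99L, 100L, 101L), c(3, 1, 1)), intensity_max = 255)
#' estimate_affinity(vol, seed_set(c(1, 0, 0)), radius = 1)
#' @export
estimate_affinity <- function(vol, seeds, radius = 2L, sigma2_mode = "equal_v1") {
  stopifnot(inherits(vol, "volume3d"))
  seeds <- seed_set(seeds, vol)
  radius <- as.integer(radius)
  if (radius < 0L) stop("`radius` must be >= 0")
  d <- dim(vol)
  sel <- array(FALSE, d)
  for (i in seq_len(nrow(seeds))) {
    lo <- pmax(seeds[i, ] - radius, 0L)
    hi <- pmin(seeds[i, ] + radius, d - 1L)
    sel[(lo[1]:hi[1]) + 1L, (lo[2]:hi[2]) + 1L, (lo[3]:hi[3]) + 1L] <- TRUE
  }
  vals <- as.numeric(vol$data[sel])
  if (length(vals) == 0L) stop("empty sample region")
  m1 <- mean(vals)
  v1 <- if (length(vals) > 1L) var(vals) else 0
  if (identical(sigma2_mode, "equal_v1")) {
    v2 <- v1
  } else if (is.numeric(sigma2_mode) && length(sigma2_mode) == 1L) {
    v2 <- sigma2_mode
  } else stop('`sigma2_mode` must be "equal_v1" or a single numeric variance')
  affinity_model(m1, v1, v2, intensity_max = vol$intensity_max)
}

#' Evaluate the affinity between two voxels directly
#'
#' Returns 1 when `c == d`, 0 when the voxels are not 6-face-adjacent, and
#' otherwise the Gaussian pair affinity of the model (see
#' [affinity_model()]). Symmetric in its two coordinates.
#'
#' @param model An [affinity_model()].
#' @param c,d 0-based (x, y, z) voxel coordinates.
#' @param vol The [volume3d()] supplying the intensities.
#' @return A value in `[0, 1]`.
#' @export
compute_affinity <- function(model, c, d, vol) {
  dims <- dim(vol)
  c <- as.integer(c); d <- as.integer(d)
  if (any(c < 0) || any(c >= dims) || any(d < 0) || any(d >= dims))
    stop("coordinate outside the volume bounds")
  if (all(c == d)) return(1.0)
  if (sum(abs(c - d)) != 1L) return(0.0)
  fc <- as.numeric(vol$data[c[1] + 1L, c[2] + 1L, c[3] + 1L])
  fd <- as.numeric(vol$data[d[1] + 1L, d[2] + 1L, d[3] + 1L])
  sqrt(gauss_peak((fc + fd) / 2, model$m1, model$v1)) *
    sqrt(gauss_peak(abs(fc - fd) / 2, 0, model$v2))
}

#' Precompute the exact affinity lookup table
#'
#' Because intensities are integers, `(f(c)+f(d))/2` takes only the
#' half-integer values `s/2` for integer `s` in `[0, 2*intensity_max]` and
#' `|f(c)-f(d)|/2` only `u/2` for `u` in `[0, intensity_max]`. Two 1-D tables
#' over those grids therefore make the affinity an exact pair-of-integers
#' lookup in O(`intensity_max`) memory — the memory-reduction device of the
#' block-parallel scheme.
#'
#' @param model An [affinity_model()].
#' @param intensity_max Table range; defaults to the model's.
#' @return An object of class `affinity_lut` with fields `sum_table`
#'   (`2*intensity_max + 1` entries, `g1(s/2)`), `diff_table`
#'   (`intensity_max + 1` entries, `g2(u/2)`), `model` and `intensity_max`.
#' @examples
#' lut <- build_lut(affinity_model(100, 100), intensity_max = 255)
#' lut$diff_table[1]  # g2(0) = 1: zero-mean Gaussian at its peak
#' @export
build_lut <- function(model, intensity_max = model$intensity_max) {
  stopifnot(inherits(model, "affinity_model"))
  intensity_max <- as.integer(intensity_max)
  if (intensity_max < 1L) stop("`intensity_max` must be >= 1")
  structure(list(
    sum_table = gauss_peak((0:(2L * intensity_max)) / 2, model$m1, model$v1),
    diff_table = gauss_peak((0:intensity_max) / 2, 0, model$v2),
    model = model,
    intensity_max = intensity_max
  ), class = "affinity_lut")
}

#' @export
print.affinity_lut <- function(x, ...) {
  cat(sprintf("<affinity_lut> intensity range [0, %d]: %d + %d table entries\n",
              x$intensity_max, length(x$sum_table), length(x$diff_table)))
  invisible(x)
}

#' Evaluate the affinity through the lookup table
#'
#' Identical contract to [compute_affinity()]; for integer intensities within
#' the table range the result is bit-exactly equal to the direct evaluation
#' (the same floating-point operations are applied to the table entries).
#'
#' @inheritParams compute_affinity
#' @param lut An [affinity_lut()][build_lut()].
#' @return A value in `[0, 1]`.
#' @export
lut_affinity <- function(lut, c, d, vol) {
  dims <- dim(vol)
  c <- as.integer(c); d <- as.integer(d)
  if (any(c < 0) || any(c >= dims) || any(d < 0) || any(d >= dims))
    stop("coordinate outside the volume bounds")
  if (all(c == d)) return(1.0)
  if (sum(abs(c - d)) != 1L) return(0.0)
  fc <- vol$data[c[1] + 1L, c[2] + 1L, c[3] + 1L]
  fd <- vol$data[d[1] + 1L, d[2] + 1L, d[3] + 1L]
  if (fc > lut$intensity_max || fd > lut$intensity_max)
    stop("intensity exceeds the lookup-table range")
  sqrt(lut$sum_table[fc + fd + 1L]) * sqrt(lut$diff_table[abs(fc - fd) + 1L])
}

#' Save or load affinity model parameters
#'
#' Serializes `m1`, `v1`, `v2` and `intensity_max` to YAML (`.yaml`/`.yml`)
#' or JSON (`.json`), chosen by extension, so a segmentation run is
#' reproducible from a config file.
#'
#' @param model An [affinity_model()].
#' @param path Destination (or source) file.
#' @return `write_affinity_model()` returns `path` invisibly;
#'   `read_affinity_model()` returns an [affinity_model()].
#' @export
write_affinity_model <- function(model, path) {
  stopifnot(inherits(model, "affinity_model"))
  rec <- list(m1 = model$m1, v1 = model$v1, v2 = model$v2,
              intensity_max = model$intensity_max)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(rec, path)
  }
  invisible(path)
}

#' @rdname write_affinity_model
#' @export
read_affinity_model <- function(path) {
  rec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  affinity_model(rec$m1, rec$v1, rec$v2, intensity_max = rec$intensity_max)
}
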