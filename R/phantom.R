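#' Specification of a synthetic tubular-vessel phantom
#'
#' Describes a 3-D volume containing a tube of foreground (vessel-like)
#' intensities against a darker background, emulating a contrast-enhanced
#' hepatic vessel in CT: voxels within `radius` (Euclidean, voxel units) of a
#' polyline centerline draw from `Normal(fg_mean, fg_sd)`, all others from
#' `Normal(bg_mean, bg_sd)`; draws are rounded and clamped to
#' `[0, intensity_max]` so the affinity lookup table applies exactly. The
#' defaults emulate a 12-bit HU-shifted portal-phase series: parenchymal
#' background around 1100 counts (sd 20) and an enhanced vessel around 1250
#' counts (sd 30), a helical centerline and a 2.5-voxel tube radius in a
#' 32-cubed grid.
#'
#' @param shape Integer length-3 volume shape.
#' @param centerline k-by-3 matrix of control points (continuous 0-based
#'   voxel units) defining a polyline; default a gentle helix through the
#'   volume from [helix_centerline()].
#' @param radius Tube radius in voxels (> 0).
#' @param fg_mean,fg_sd Foreground (vessel) intensity mean and sd.
#' @param bg_mean,bg_sd Background intensity mean and sd.
#' @param intensity_max Clamp ceiling (default 4095).
#' @param rng_seed Integer seed; identical specs and seeds give bit-identical
#'   phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32L, 32L, 32L), centerline = NULL,
                         radius = 2.5, fg_mean = 1250, fg_sd = 30,
                         bg_mean = 1100, bg_sd = 20,
                         intensity_max = 4095L, rng_seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("invalid `shape`")
  if (is.null(centerline)) centerline <- helix_centerline(shape)
  centerline <- as.matrix(centerline)
  if (ncol(centerline) != 3L || nrow(centerline) < 2L)
    stop("`centerline` must be a k-by-3 matrix with k >= 2")
  if (any(centerline < 0) ||
      any(sweep(centerline, 2L, shape - 1L, `>`)))
    stop("centerline outside the volume")
  if (radius <= 0) stop("`radius` must be > 0")
  if (fg_mean == bg_mean) stop("`fg_mean` must differ from `bg_mean`")
  if (fg_sd < 0 || bg_sd < 0) stop("intensity sds must be >= 0")
  if (fg_mean < 0 || fg_mean > intensity_max ||
      bg_mean < 0 || bg_mean > intensity_max)
    stop("means must lie within [0, intensity_max]")
  structure(list(shape = shape, centerline = centerline, radius = radius,
                 fg_mean = fg_mean, fg_sd = fg_sd,
                 bg_mean = bg_mean, bg_sd = bg_sd,
                 intensity_max = as.integer(intensity_max),
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' Helical centerline control points
#'
#' A helix running along z through the middle of the volume, sampled as a
#' polyline; degenerates to a straight axial line when `radius_frac = 0`.
#'
#' @param shape Volume shape the helix must fit in.
#' @param turns Number of full turns over the z extent.
#' @param radius_frac Helix radius as a fraction of the smaller x/y extent.
#' @param n Number of control points.
#' @return An n-by-3 matrix of control points in voxel units.
#' @export
helix_centerline <- function(shape, turns = 1.5, radius_frac = 0.25, n = 64L) {
  shape <- as.integer(shape)
  cx <- (shape[1] - 1) / 2
  cy <- (shape[2] - 1) / 2
  r <- radius_frac * min(shape[1] - 1, shape[2] - 1)
  t <- seq(0, 1, length.out = n)
  z <- t * max(shape[3] - 1, 0)
  ang <- 2 * pi * turns * t
  cbind(x = cx + r * cos(ang), y = cy + r * sin(ang), z = z)
}

# minimum Euclidean distance from each point (rows of `p`) to a polyline
dist_to_polyline <- function(p, line) {
  dmin <- rep(Inf, nrow(p))
  for (s in seq_len(nrow(line) - 1L)) {
    a <- line[s, ]; b <- line[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    rel <- sweep(p, 2L, a)
    t <- if (len2 > 0) pmin(pmax((rel %*% ab) / len2, 0), 1) else rep(0, nrow(p))
    dx <- rel - t %*% t(ab)
    dmin <- pmin(dmin, sqrt(rowSums(dx^2)))
  }
  dmin
}

#' Generate a synthetic tubular phantom
#'
#' Realizes a [phantom_spec()]: the ground-truth tube mask is defined
#' geometrically (pre-noise) as the voxels within `radius` of the
#' centerline, foreground/background Gaussian noise is added, and draws are
#' rounded then clamped to the intensity range. The suggested seed is the
#' voxel nearest the centerline midpoint.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom` with elements `volume` (a
#'   [volume3d()]), `mask` (logical ground-truth array) and `seeds` (a
#'   one-seed [seed_set()]).
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(9, 9, 4), rng_seed = 7))
#' sum(ph$mask)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  n <- prod(d)
  coords <- as.matrix(expand.grid(x = 0:(d[1] - 1L), y = 0:(d[2] - 1L),
                                  z = 0:(d[3] - 1L)))
  mask <- array(dist_to_polyline(coords, spec$centerline) <= spec$radius, d)
  z <- withr::with_seed(spec$rng_seed, rnorm(n))
  mean_v <- ifelse(mask, spec$fg_mean, spec$bg_mean)
  sd_v <- ifelse(mask, spec$fg_sd, spec$bg_sd)
  vals <- round(mean_v + sd_v * array(z, d))
  vals <- pmin(pmax(vals, 0), spec$intensity_max)
  vol <- volume3d(array(as.integer(vals), d), intensity_max = spec$intensity_max)
  mid <- spec$centerline[ceiling(nrow(spec$centerline) / 2), ]
  seed <- pmin(pmax(round(mid), 0), d - 1L)
  structure(list(volume = vol, mask = mask,
                 seeds = seed_set(seed, vol), spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s voxels, %d in tube mask, seed (%s)\n",
              paste(dim(x$volume), collapse = "x"), sum(x$mask),
              paste(x$seeds[1, ], collapse = ", ")))
  invisible(x)
}

#' Fixture reproducing the inter-block asynchrony failure
#'
#' A hand-crafted 24x3x1 volume cut into three 8-wide blocks (A | B | C, left
#' to right) with the seed in block C. Two corridors of vessel intensity
#' leave the seed: a "weak" corridor along the bottom row containing one
#' dimmer voxel (bottleneck affinity < 1), and a "strong" detour along the
#' top row of block C that rejoins the bottom row at the A-B-facing edge of
#' block C. The corridor lengths are tuned so that, under the explicit
#' block order A, B, C of the returned adversarial schedule, the strong value
#' arrives at block C's edge exactly one pass after the weak value: the edge
#' voxel of block B is then re-raised from block C in the very pass in which
#' its flag was consumed, the re-activation is lost, and every corridor voxel
#' downstream in blocks B and A keeps the weak value. Correction iterations
#' (the +x face is direction index 1, so any `correction_directions >= 2`)
#' repair the scene to the exact reference.
#'
#' @return A list with elements `volume`, `seeds`, `partition`, `schedule`
#'   and the matching `model` (m1 = 100, v1 = v2 = 100, intensity ceiling
#'   255).
#' @export
make_edge_race_fixture <- function() {
  nx <- 24L; ny <- 3L; nz <- 1L
  bg <- 0L; fg <- 100L; dim_v <- 90L
  dat <- array(bg, c(nx, ny, nz))
  dat[, 1, 1] <- fg                       # bottom (weak) corridor, y = 0
  dat[21L, 1, 1] <- dim_v                 # weak link at (20, 0, 0)
  dat[17:24, 3, 1] <- fg                  # strong corridor, y = 2, x = 16..23
  dat[24L, 2, 1] <- fg                    # seed column connector (23, 1, 0)
  dat[17L, 2, 1] <- fg                    # descent connector (16, 1, 0)
  vol <- volume3d(dat, intensity_max = 255L)
  seeds <- seed_set(c(23L, 1L, 0L), vol)
  part <- block_partition(vol, c(8L, 3L, 1L))
  sched <- block_schedule("adversarial", rng_seed = 1L,
                          order = seq_len(part$n_blocks))
  model <- affinity_model(100, 100, 100, intensity_max = 255L)
  list(volume = vol, seeds = seeds, partition = part, schedule = sched,
       model = model)
}
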