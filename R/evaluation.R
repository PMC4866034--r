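#' Voxelwise comparison of two fuzzy scenes
#'
#' Counts the error points: voxels whose connectedness values differ by more
#' than `tol` between a reference scene and a candidate scene. The default
#' `tol = 0` demands bit-exact agreement, which is the meaningful comparison
#' here: both solvers draw their values from the same finite set of
#' lookup-table affinities under min/max selection only, so any fixed-point
#' drift at all indicates a propagation error. A nonzero tolerance exists
#' only for comparing against external implementations with different
#' floating-point pipelines.
#'
#' @param ref,test [fuzzy_scene()] objects (or plain 3-D arrays) of the same
#'   shape.
#' @param tol Non-negative comparison tolerance (default 0).
#' @return An object of class `comparison_report`: a list with
#'   `error_points` (count of differing voxels), `max_abs_diff`, and
#'   `differing_coords` (0-based coordinates, capped at 1000 rows).
#' @export
error_points <- function(ref, test, tol = 0) {
  a <- if (inherits(ref, "fuzzy_scene")) ref$values else ref
  b <- if (inherits(test, "fuzzy_scene")) test$values else test
  if (!identical(dim(a), dim(b))) stop("scene shape mismatch")
  if (tol < 0) stop("`tol` must be >= 0")
  ad <- abs(a - b)
  bad <- which(ad > tol)
  coords <- NULL
  if (length(bad)) {
    idx <- arrayInd(bad[seq_len(min(length(bad), 1000L))], dim(a)) - 1L
    colnames(idx) <- c("x", "y", "z")
    coords <- idx
  }
  structure(list(error_points = length(bad),
                 max_abs_diff = max(ad),
                 differing_coords = coords),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d error point(s), max |diff| %.6g\n",
              x$error_points, x$max_abs_diff))
  invisible(x)
}

#' Threshold segmentation of a fuzzy scene
#'
#' Binarizes the connectedness map: a voxel belongs to the object iff its
#' connectedness to the seed is at least `theta`.
#'
#' @param scene A [fuzzy_scene()] (or plain 3-D array).
#' @param theta Threshold in `[0, 1]`.
#' @return Logical 3-D array mask.
#' @export
threshold_segment <- function(scene, theta) {
  v <- if (inherits(scene, "fuzzy_scene")) scene$values else scene
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta > 1)
    stop("`theta` must be a single value in [0, 1]")
  v >= theta
}

#' Error points as a function of correction directions
#'
#' Runs [run_block_iterative()] with `correction_directions` from 0 to 6 and
#' compares each result to the sequential reference — the direction-sweep
#' experiment. On every shipped fixture the counts are non-increasing and
#' reach 0 at 6 directions.
#'
#' @inheritParams run_block_iterative
#' @return A `data.frame` with columns `directions` (0:6) and
#'   `error_points`.
#' @export
direction_sweep <- function(vol, seeds, lut,
                            part = block_partition(vol),
                            sched = block_schedule(),
                            max_correction_rounds = 8L) {
  ref <- kfoe_reference(vol, seeds, lut)
  counts <- vapply(0:6, function(k) {
    sc <- run_block_iterative(vol, seeds, lut, part, sched,
                              correction_directions = k,
                              max_correction_rounds = max_correction_rounds)
    error_points(ref, sc)$error_points
  }, integer(1))
  data.frame(directions = 0:6, error_points = counts)
}
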