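#' Sequential reference fuzzy connectedness scene
#'
#' Computes, for every voxel, the max-min path strength from the seed set:
#' the maximum over all paths of the minimum pairwise affinity along the
#' path (the transitive max-min closure of the affinity relation). Solved as
#' a single-source widest-path problem by best-first extraction over a
#' priority queue (descending connectivity, FIFO tie-break, lazy
#' re-insertion). Seeds receive exactly 1; because all pairwise affinities
#' are strictly positive, every voxel receives a positive value.
#'
#' @param vol A [volume3d()].
#' @param seeds A [seed_set()].
#' @param lut An [affinity_lut()][build_lut()] covering the volume's
#'   intensity range.
#' @return A [fuzzy_scene()].
#' @examples
#' vol <- volume3d(array(c(100L, 100L, 40L), c(3, 1, 1)), intensity_max = 255)
#' lut <- build_lut(affinity_model(100, 100), 255)
#' kfoe_reference(vol, seed_set(c(0, 0, 0)), lut)$values
#' @export
kfoe_reference <- function(vol, seeds, lut) {
  stopifnot(inherits(vol, "volume3d"), inherits(lut, "affinity_lut"))
  seeds <- seed_set(seeds, vol)
  if (max(vol$data) > lut$intensity_max)
    stop("volume intensities exceed the lookup-table range")
  d <- dim(vol)
  vals <- cpp_reference(as.integer(vol$data), as.integer(d),
                        as.integer(voxel_index(seeds, d)),
                        lut$sum_table, lut$diff_table)
  fuzzy_scene(array(vals, d), seeds, spacing = vol$spacing)
}

#' Brute-force connectedness by exhaustive path enumeration
#'
#' Enumerates every simple path out of each seed by depth-first search,
#' recording for each voxel the maximum over paths of the per-path minimum
#' affinity. Exponential in the voxel count, so it is guarded to volumes of
#' at most 32 voxels; it exists purely as an independent test oracle for
#' [kfoe_reference()].
#'
#' @inheritParams kfoe_reference
#' @return A [fuzzy_scene()].
#' @export
brute_force_connectedness <- function(vol, seeds, lut) {
  stopifnot(inherits(vol, "volume3d"), inherits(lut, "affinity_lut"))
  seeds <- seed_set(seeds, vol)
  d <- dim(vol)
  n <- prod(d)
  if (n > 32L) stop("volume too large for brute-force enumeration (> 32 voxels)")

  # adjacency lists and per-edge affinities over 1-based linear indices
  coords <- as.matrix(expand.grid(x = 0:(d[1] - 1L), y = 0:(d[2] - 1L),
                                  z = 0:(d[3] - 1L)))
  adj <- vector("list", n)
  wt <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- neighbors6(coords[i, ], vol)
    if (nrow(nb) == 0L) { adj[[i]] <- integer(0); wt[[i]] <- numeric(0); next }
    adj[[i]] <- as.integer(voxel_index(nb, d) + 1L)
    wt[[i]] <- vapply(seq_len(nrow(nb)), function(k)
      lut_affinity(lut, coords[i, ], nb[k, ], vol), numeric(1))
  }

  best <- numeric(n)
  visited <- logical(n)
  dfs <- function(i, m) {
    if (m > best[i]) best[i] <<- m
    visited[i] <<- TRUE
    a <- adj[[i]]; w <- wt[[i]]
    for (k in seq_along(a)) {
      j <- a[k]
      if (!visited[j]) dfs(j, min(m, w[k]))
    }
    visited[i] <<- FALSE
  }
  seed_idx <- as.integer(voxel_index(seeds, d) + 1L)
  for (s in seed_idx) dfs(s, 1.0)
  best[seed_idx] <- 1.0
  fuzzy_scene(array(best, d), seeds, spacing = vol$spacing)
}

#' Check the max-min fixpoint certificate of a scene
#'
#' At the max-min closure every adjacent pair must satisfy
#' `values[d] >= min(values[c], mu_k(c, d))`, and seed values must equal 1.
#' Returns the number of violated ordered pairs (0 for a correct solver
#' output); checked exhaustively over all adjacent pairs.
#'
#' @param scene A [fuzzy_scene()].
#' @inheritParams kfoe_reference
#' @return Integer count of violations.
#' @export
fixpoint_violations <- function(scene, vol, lut) {
  stopifnot(inherits(scene, "fuzzy_scene"), inherits(vol, "volume3d"))
  d <- dim(vol)
  f <- vol$data
  vals <- scene$values
  viol <- 0L
  viol <- viol + sum(vals[scene$seeds + 1L] != 1)
  sum_t <- lut$sum_table; diff_t <- lut$diff_table
  for (ax in 1:3) {
    if (d[ax] < 2L) next
    idx_lo <- lapply(d, seq_len)
    idx_hi <- idx_lo
    idx_lo[[ax]] <- seq_len(d[ax] - 1L)
    idx_hi[[ax]] <- 2:d[ax]
    fa <- do.call(`[`, c(list(f), idx_lo, list(drop = FALSE)))
    fb <- do.call(`[`, c(list(f), idx_hi, list(drop = FALSE)))
    va <- do.call(`[`, c(list(vals), idx_lo, list(drop = FALSE)))
    vb <- do.call(`[`, c(list(vals), idx_hi, list(drop = FALSE)))
    mu <- sqrt(sum_t[fa + fb + 1L]) * sqrt(diff_t[abs(fa - fb) + 1L])
    viol <- viol + sum(vb < pmin(va, mu)) + sum(va < pmin(vb, mu))
  }
  viol
}
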