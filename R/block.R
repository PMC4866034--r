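#' Partition a volume into axis-aligned blocks
#'
#' Tiles the volume with blocks of shape `block_shape`; blocks at the upper
#' faces are clipped, so the tiling is exact and disjoint. Block order is
#' lexicographic by block origin (x fastest).
#'
#' @param vol A [volume3d()] (or anything with a 3-long `dim()`).
#' @param block_shape Integer length-3, voxels per block along (x, y, z).
#'   Default 8x8x8, small enough that desk-scale phantoms contain many
#'   inter-block faces.
#' @return An object of class `block_partition` with fields `block_shape`,
#'   `lo` and `hi` (n-by-3 matrices of 0-based inclusive voxel ranges) and
#'   `n_blocks`.
#' @examples
#' part <- block_partition(volume3d(array(0L, c(9, 8, 8)), intensity_max = 1), c(8, 8, 8))
#' part$n_blocks  # 2: an 8x8x8 block and a clipped 1x8x8 block
#' @export
block_partition <- function(vol, block_shape = c(8L, 8L, 8L)) {
  d <- dim(vol)
  bs <- as.integer(block_shape)
  if (length(bs) != 3L || any(bs < 1L)) stop("block shape components must be >= 1")
  starts <- lapply(1:3, function(ax) seq.int(0L, d[ax] - 1L, by = bs[ax]))
  g <- as.matrix(expand.grid(x = starts[[1]], y = starts[[2]], z = starts[[3]]))
  lo <- g[order(g[, 3], g[, 2], g[, 1]), , drop = FALSE]
  hi <- sweep(lo, 2L, bs - 1L, `+`)
  hi <- pmin(hi, matrix(d - 1L, nrow(lo), 3L, byrow = TRUE))
  storage.mode(lo) <- "integer"; storage.mode(hi) <- "integer"
  structure(list(block_shape = bs, lo = lo, hi = hi, n_blocks = nrow(lo)),
            class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  cat(sprintf("<block_partition> %d block(s) of shape %s\n", x$n_blocks,
              paste(x$block_shape, collapse = "x")))
  invisible(x)
}

#' Block execution schedule
#'
#' Controls how the emulator orders and synchronizes block updates within a
#' propagation pass:
#'
#' * `"synchronous"` — connectivity values are read from a pass-start
#'   snapshot and activation flags are double-buffered into the next pass.
#'   Block order is immaterial; quiescence implies the fixpoint.
#' * `"sequential_asynchronous"` — blocks run in a (seeded) shuffled order
#'   with live value and flag reads, so updates made earlier in a pass are
#'   visible to blocks running later; no re-activation is ever lost, so
#'   quiescence still implies the fixpoint.
#' * `"adversarial"` — as above, but reproducing the flag race of
#'   block-asynchronous hardware: when a voxel that was already processed in
#'   the current pass is re-raised from *another* block, its value is
#'   max-updated but its re-activation flag is lost, so the improved value
#'   never re-propagates. Quiescence may then stop short of the fixpoint;
#'   the correction iterations of [run_block_iterative()] repair this.
#'
#' @param policy One of `"synchronous"`, `"sequential_asynchronous"`,
#'   `"adversarial"`.
#' @param rng_seed Integer seed for the per-pass block order shuffle of the
#'   asynchronous policies (deterministic internal generator).
#' @param order Optional explicit block ordering (1-based block indices into
#'   the partition), applied every pass; overrides the shuffle.
#' @return An object of class `block_schedule`.
#' @export
block_schedule <- function(policy = c("synchronous", "sequential_asynchronous",
                                      "adversarial"),
                           rng_seed = 1L, order = NULL) {
  policy <- match.arg(policy)
  if (!is.null(order)) order <- as.integer(order)
  structure(list(policy = policy, rng_seed = as.integer(rng_seed),
                 order = order),
            class = "block_schedule")
}

#' @export
print.block_schedule <- function(x, ...) {
  cat(sprintf("<block_schedule> policy %s, rng_seed %d%s\n", x$policy,
              x$rng_seed,
              if (is.null(x$order)) "" else ", explicit block order"))
  invisible(x)
}

policy_code <- function(sched) {
  match(sched$policy,
        c("synchronous", "sequential_asynchronous", "adversarial")) - 1L
}

check_schedule_order <- function(sched, part) {
  if (is.null(sched$order)) return(integer(0))
  ord <- sched$order
  if (length(ord) != part$n_blocks || !setequal(ord, seq_len(part$n_blocks)))
    stop("`order` must be a permutation of the block indices")
  ord - 1L
}

#' Initialize a propagation state
#'
#' Seeds carry connectedness 1 and are the initially active voxels; all other
#' voxels start at 0 and inactive.
#'
#' @inheritParams kfoe_reference
#' @return An object of class `propagation_state` with fields `fc` (numeric
#'   array), `active` (logical array, the current flag set), and
#'   `pass_count`.
#' @export
init_propagation <- function(vol, seeds) {
  stopifnot(inherits(vol, "volume3d"))
  seeds <- seed_set(seeds, vol)
  d <- dim(vol)
  fc <- array(0, d)
  active <- array(FALSE, d)
  fc[seeds + 1L] <- 1
  active[seeds + 1L] <- TRUE
  structure(list(fc = fc, active = active, pass_count = 0L, seeds = seeds),
            class = "propagation_state")
}

#' Run one block-iterative propagation pass
#'
#' Executes a single pass over all blocks under the schedule's policy (see
#' [block_schedule()] for the exact read/flag semantics of each policy):
#' every active voxel is deactivated and offers `min(fc[c], mu_k(c, d))` to
#' each 6-neighbour `d`; an offer strictly above `fc[d]` is written (the
#' final value of concurrent writers is their maximum, the emulated atomic
#' max) and re-activates `d` for a later pass.
#'
#' @param state A [init_propagation()] state.
#' @param part A [block_partition()].
#' @param sched A [block_schedule()].
#' @inheritParams kfoe_reference
#' @return The updated `propagation_state` (with `pass_count` incremented).
#' @export
propagate_pass <- function(state, part, sched, lut, vol) {
  if (!inherits(state, "propagation_state")) stop("uninitialized state")
  stopifnot(inherits(part, "block_partition"), inherits(sched, "block_schedule"))
  d <- dim(vol)
  res <- cpp_block_solve(as.integer(vol$data), as.integer(d),
                         as.numeric(state$fc), as.logical(state$active),
                         lut$sum_table, lut$diff_table,
                         part$lo, part$hi,
                         policy_code(sched), check_schedule_order(sched, part),
                         sched$rng_seed + state$pass_count,
                         1L, 0L, 0L)
  state$fc <- array(res$fc, d)
  state$active <- array(res$active, d)
  state$pass_count <- state$pass_count + 1L
  state
}

#' Block-iterative fuzzy connectedness with correction iterations
#'
#' Emulates block-parallel propagation: passes run until the active set is
#' empty, then `max_correction_rounds` correction rounds re-activate every
#' voxel on a block face whose outward direction is among the first
#' `correction_directions` entries of the fixed order (-x, +x, -y, +y, -z,
#' +z), re-running passes to quiescence after each, and stopping early once a
#' round changes nothing. With all 6 directions and rounds iterated to a
#' change-free round, the result equals the sequential reference bit-exactly
#' under every schedule policy (a change-free full-face round certifies the
#' max-min fixpoint).
#'
#' @inheritParams propagate_pass
#' @param correction_directions Integer in `[0, 6]`: how many face directions
#'   are re-activated each correction round (0 disables correction).
#' @param max_correction_rounds Maximum correction rounds (default 8; two
#'   rounds repair a two-block crossing, three a three-block crossing, and
#'   iterating to a change-free round certifies exactness).
#' @return A [fuzzy_scene()] with attributes `passes` (total propagation
#'   passes) and `correction_rounds` (rounds actually run).
#' @examples
#' vol <- volume3d(array(100L, c(8, 4, 2)), intensity_max = 255)
#' lut <- build_lut(affinity_model(100, 100), 255)
#' sc <- run_block_iterative(vol, seed_set(c(0, 0, 0)), lut,
#'                           block_partition(vol, c(4, 4, 2)))
#' attr(sc, "passes")
#' @export
run_block_iterative <- function(vol, seeds, lut,
                                part = block_partition(vol),
                                sched = block_schedule(),
                                correction_directions = 6L,
                                max_correction_rounds = 8L) {
  stopifnot(inherits(vol, "volume3d"), inherits(lut, "affinity_lut"),
            inherits(part, "block_partition"), inherits(sched, "block_schedule"))
  seeds <- seed_set(seeds, vol)
  correction_directions <- as.integer(correction_directions)
  if (correction_directions < 0L || correction_directions > 6L)
    stop("`correction_directions` must be in [0, 6]")
  if (max(vol$data) > lut$intensity_max)
    stop("volume intensities exceed the lookup-table range")
  d <- dim(vol)
  st <- init_propagation(vol, seeds)
  res <- cpp_block_solve(as.integer(vol$data), as.integer(d),
                         as.numeric(st$fc), as.logical(st$active),
                         lut$sum_table, lut$diff_table,
                         part$lo, part$hi,
                         policy_code(sched), check_schedule_order(sched, part),
                         sched$rng_seed,
                         -1L, correction_directions,
                         as.integer(max_correction_rounds))
  out <- fuzzy_scene(array(res$fc, d), seeds, spacing = vol$spacing)
  attr(out, "passes") <- res$passes
  attr(out, "correction_rounds") <- res$rounds
  out
}
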