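test_that("partition tiles the volume exactly, clipping edge blocks", {
  expect_equal(block_partition(flat_volume(c(8, 8, 8)), c(8, 8, 8))$n_blocks, 1L)

  p2 <- block_partition(flat_volume(c(9, 8, 8)), c(8, 8, 8))
  expect_equal(p2$n_blocks, 2L)
  expect_equal(p2$hi[2, ] - p2$lo[2, ] + 1L, c(1L, 8L, 8L),
               ignore_attr = TRUE)

  # block larger than the volume: one clipped block
  p3 <- block_partition(flat_volume(c(3, 3, 1)), c(8, 8, 8))
  expect_equal(p3$n_blocks, 1L)
  expect_equal(p3$hi[1, ], c(2L, 2L, 0L), ignore_attr = TRUE)

  # disjoint exact cover
  p4 <- block_partition(flat_volume(c(5, 7, 3)), c(2, 3, 2))
  cover <- array(0L, c(5, 7, 3))
  for (b in seq_len(p4$n_blocks)) {
    rng <- lapply(1:3, function(ax) (p4$lo[b, ax]:p4$hi[b, ax]) + 1L)
    cover[rng[[1]], rng[[2]], rng[[3]]] <- cover[rng[[1]], rng[[2]], rng[[3]]] + 1L
  }
  expect_true(all(cover == 1L))
  expect_error(block_partition(flat_volume(c(4, 4, 4)), c(0, 2, 2)), ">= 1")
})

test_that("one synchronous pass advances the front a single step and activates it", {
  vol <- volume3d(array(c(100L, 105L, 110L), c(3, 1, 1)), intensity_max = 255)
  lut <- default_lut(vol)
  part <- block_partition(vol, c(8, 8, 8))
  st <- init_propagation(vol, seed_set(c(0, 0, 0), vol))
  st <- propagate_pass(st, part, block_schedule("synchronous"), lut, vol)
  a01 <- lut_affinity(lut, c(0, 0, 0), c(1, 0, 0), vol)
  expect_identical(as.vector(st$fc), c(1.0, a01, 0))
  expect_identical(as.vector(st$active), c(FALSE, TRUE, FALSE))
  expect_equal(st$pass_count, 1L)
  expect_error(propagate_pass(list(), part, block_schedule(), lut, vol),
               "uninitialized")
})

test_that("two writers into one voxel in a single pass leave the max candidate", {
  # seeds at both ends of a 3-chain offer different candidates to the middle
  vol <- volume3d(array(c(100L, 100L, 130L), c(3, 1, 1)), intensity_max = 255)
  lut <- default_lut(vol)
  part <- block_partition(vol, c(8, 8, 8))
  seeds <- seed_set(rbind(c(0, 0, 0), c(2, 0, 0)), vol)
  st <- init_propagation(vol, seeds)
  st <- propagate_pass(st, part, block_schedule("synchronous"), lut, vol)
  left <- lut_affinity(lut, c(0, 0, 0), c(1, 0, 0), vol)
  right <- lut_affinity(lut, c(2, 0, 0), c(1, 0, 0), vol)
  expect_gt(left, right)
  expect_identical(st$fc[2, 1, 1], max(left, right))
})

test_that("a single-block partition reproduces the reference with no correction", {
  set.seed(201)
  for (pol in c("synchronous", "sequential_asynchronous", "adversarial")) {
    vol <- random_tiny_volume(imax = 50L)
    seeds <- random_seed_in(vol)
    lut <- default_lut(vol, seeds)
    sc <- run_block_iterative(vol, seeds, lut,
                              block_partition(vol, dim(vol)),
                              block_schedule(pol, rng_seed = 5),
                              correction_directions = 0)
    expect_identical(sc$values, kfoe_reference(vol, seeds, lut)$values)
  }
})

test_that("propagation ascends monotonically and never overshoots the reference", {
  set.seed(203)
  vol <- volume3d(array(sample(80:120, 4 * 4 * 2, TRUE), c(4, 4, 2)),
                  intensity_max = 255)
  seeds <- seed_set(c(0, 0, 0), vol)
  lut <- default_lut(vol)
  ref <- kfoe_reference(vol, seeds, lut)$values
  part <- block_partition(vol, c(2, 2, 2))
  for (pol in c("synchronous", "sequential_asynchronous", "adversarial")) {
    st <- init_propagation(vol, seeds)
    prev <- st$fc
    for (p in 1:60) {
      st <- propagate_pass(st, part, block_schedule(pol, rng_seed = 7), lut, vol)
      expect_true(all(st$fc >= prev))        # monotone ascent
      expect_true(all(st$fc <= ref + 0))     # bounded by the closure
      prev <- st$fc
      if (!any(st$active)) break
    }
    expect_false(any(st$active))             # converged within the budget
  }
})

test_that("full 6-direction correction is bit-exact against the reference on noisy grids", {
  set.seed(205)
  for (i in 1:6) {
    vol <- volume3d(array(sample(900:1300, 12 * 10 * 6, TRUE), c(12, 10, 6)),
                    intensity_max = 4095)
    seeds <- random_seed_in(vol)
    lut <- build_lut(estimate_affinity(vol, seeds, radius = 2), 4095)
    ref <- kfoe_reference(vol, seeds, lut)
    for (pol in c("synchronous", "sequential_asynchronous", "adversarial")) {
      sc <- run_block_iterative(vol, seeds, lut,
                                block_partition(vol, c(4, 4, 4)),
                                block_schedule(pol, rng_seed = i),
                                correction_directions = 6)
      expect_identical(sc$values, ref$values)
    }
  }
})

test_that("the crafted three-block fixture errs without correction and heals with it", {
  fx <- make_edge_race_fixture()
  lut <- build_lut(fx$model, 255)
  ref <- kfoe_reference(fx$volume, fx$seeds, lut)
  un <- run_block_iterative(fx$volume, fx$seeds, lut, fx$partition,
                            fx$schedule, correction_directions = 0)
  rep_un <- error_points(ref, un)
  expect_gte(rep_un$error_points, 1L)
  # hand trace: the lost re-activation sits at the +x face of the middle
  # block; every bottom-row voxel downstream of it keeps the weak value
  expect_identical(rep_un$error_points, 15L)
  expect_true(all(rep_un$differing_coords[, "y"] == 0L))
  expect_true(all(rep_un$differing_coords[, "x"] <= 14L))

  co <- run_block_iterative(fx$volume, fx$seeds, lut, fx$partition,
                            fx$schedule, correction_directions = 6)
  expect_identical(co$values, ref$values)

  # snapshot (synchronous) policy re-flags changed voxels, so quiescence
  # already implies the fixpoint even with correction disabled
  sync <- run_block_iterative(fx$volume, fx$seeds, lut, fx$partition,
                              block_schedule("synchronous"),
                              correction_directions = 0)
  expect_identical(sync$values, ref$values)
})

test_that("interleaving enumeration yields all admissible orders", {
  expect_identical(enumerate_interleavings(list()), list(integer(0)))
  ev2 <- list(list(from = c(0, 0, 0), to = c(1, 0, 0)),
              list(from = c(0, 0, 0), to = c(0, 1, 0)))
  expect_length(enumerate_interleavings(ev2), 2L)
  expect_length(enumerate_interleavings(ev2, before = rbind(c(2L, 1L))), 1L)
  expect_error(enumerate_interleavings(rep(ev2, 6)), "too large")
  expect_error(enumerate_interleavings(ev2, before = rbind(c(1L, 2L), c(2L, 1L))),
               "cyclic")
})

test_that("replaying interleavings reproduces the asynchrony error classes", {
  # 2x2 grid: upstream pixel (0,0) must refresh (1,0) and (0,1) before they
  # propagate into (1,1); each update event fires once (consumed flags)
  vol <- flat_volume(c(2, 2, 1))
  lut <- default_lut(vol)
  fc0 <- array(0, c(2, 2, 1))
  fc0[1, 1, 1] <- 1          # upstream pixel already carries the seed value
  fc0[2, 1, 1] <- 0.6        # stale values about to be corrected
  fc0[1, 2, 1] <- 0.6
  ev <- list(list(from = c(0, 0, 0), to = c(1, 0, 0)),   # 1 -> 2
             list(from = c(0, 0, 0), to = c(0, 1, 0)),   # 1 -> 3
             list(from = c(1, 0, 0), to = c(1, 1, 0)),   # 2 -> 5
             list(from = c(0, 1, 0), to = c(1, 1, 0)))   # 3 -> 5
  orders <- enumerate_interleavings(ev)
  expect_length(orders, 24L)
  finals <- vapply(orders, function(o)
    apply_events(fc0, ev, o, lut, vol)[2, 2, 1], numeric(1))
  # all affinities are 1 here, so the correct final value at (1,1) is 1
  good <- vapply(orders, function(o)
    which(o == 1) < which(o == 3) || which(o == 2) < which(o == 4),
    logical(1))
  expect_true(all(finals[good] == 1))
  expect_true(all(finals[!good] == 0.6))
  expect_gt(sum(!good), 0L)

  # when the upstream pixel cannot improve its neighbours, order is immaterial
  fc_sat <- fc0; fc_sat[2, 1, 1] <- 1; fc_sat[1, 2, 1] <- 1
  finals_sat <- vapply(orders, function(o)
    apply_events(fc_sat, ev, o, lut, vol)[2, 2, 1], numeric(1))
  expect_true(all(finals_sat == 1))
})
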