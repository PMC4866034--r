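test_that("model estimation gives the sample mean and n-1 variance, with a variance floor", {
  vol <- volume3d(array(c(99L, 100L, 101L), c(3, 1, 1)), intensity_max = 255)
  m <- estimate_affinity(vol, seed_set(c(1, 0, 0)), radius = 1)
  expect_equal(m$m1, 100)
  expect_equal(m$v1, 1)
  expect_equal(m$v2, m$v1)

  flat <- flat_volume(c(3, 3, 1))
  mf <- estimate_affinity(flat, seed_set(c(1, 1, 0)), radius = 1)
  expect_equal(mf$m1, 100)
  expect_equal(mf$v1, 1e-6)  # zero-variance region hits the floor

  # a huge radius clips to the volume instead of erroring
  mc <- estimate_affinity(vol, seed_set(c(0, 0, 0)), radius = 50)
  expect_equal(mc$m1, 100)

  mfix <- estimate_affinity(vol, seed_set(c(1, 0, 0)), radius = 1,
                            sigma2_mode = 9)
  expect_equal(mfix$v2, 9)
})

test_that("direct affinity matches the closed form and adjacency rules", {
  model <- affinity_model(100, 100, 100, intensity_max = 255)
  vol <- volume3d(array(c(100L, 110L, 0L, 0L), c(2, 2, 1)),
                  intensity_max = 255)
  # reflexive
  expect_identical(compute_affinity(model, c(0, 0, 0), c(0, 0, 0), vol), 1.0)
  # diagonal (not 6-adjacent)
  expect_identical(compute_affinity(model, c(0, 0, 0), c(1, 1, 0), vol), 0.0)
  # hand evaluation: f = 100, 110 with m1 = v1 = v2 = 100 gives exp(-1/8)
  expect_equal(compute_affinity(model, c(0, 0, 0), c(1, 0, 0), vol),
               exp(-0.125), tolerance = 1e-12)
  expect_error(compute_affinity(model, c(0, 0, 0), c(2, 0, 0), vol), "bounds")
})

test_that("affinity is symmetric, in [0,1], and 1 only at the model peak", {
  set.seed(21)
  model <- affinity_model(60, 200, 150, intensity_max = 100)
  for (i in 1:25) {
    vol <- random_tiny_volume(imax = 100L)
    d <- dim(vol)
    a <- random_seed_in(vol)[1, ]
    nb <- neighbors6(a, vol)
    if (nrow(nb) == 0) next
    b <- nb[sample(nrow(nb), 1L), ]
    m1 <- compute_affinity(model, a, b, vol)
    m2 <- compute_affinity(model, b, a, vol)
    expect_identical(m1, m2)
    expect_gte(m1, 0); expect_lte(m1, 1)
    fa <- vol$data[a[1] + 1, a[2] + 1, a[3] + 1]
    fb <- vol$data[b[1] + 1, b[2] + 1, b[3] + 1]
    expect_equal(m1 == 1, fa == 60 && fb == 60)
  }
})

test_that("lookup tables have the prescribed sizes, range and peaks", {
  imax <- 255L
  lut <- build_lut(affinity_model(100, 100, 100), imax)
  expect_length(lut$sum_table, 2L * imax + 1L)
  expect_length(lut$diff_table, imax + 1L)
  expect_true(all(lut$sum_table > 0 & lut$sum_table <= 1))
  expect_true(all(lut$diff_table > 0 & lut$diff_table <= 1))
  expect_identical(lut$diff_table[1], 1.0)       # g2 peak at zero difference
  expect_identical(lut$sum_table[2L * 100L + 1L], 1.0)  # g1 peak at s = 2*m1
  expect_error(build_lut(affinity_model(100, 100), 0), ">= 1")
})

test_that("LUT evaluation is bit-exact against direct evaluation over all integer pairs", {
  imax <- 255L
  m1 <- 100; v1 <- 100; v2 <- 64
  lut <- build_lut(affinity_model(m1, v1, v2), imax)
  pairs <- expand.grid(a = 0:imax, b = 0:imax)
  # independent recomputation of the closed form
  floor0 <- .Machine$double.xmin
  g1 <- pmax(exp(-(((pairs$a + pairs$b) / 2 - m1)^2) / (2 * v1)), floor0)
  g2 <- pmax(exp(-((abs(pairs$a - pairs$b) / 2)^2) / (2 * v2)), floor0)
  direct <- sqrt(g1) * sqrt(g2)
  via_lut <- sqrt(lut$sum_table[pairs$a + pairs$b + 1L]) *
    sqrt(lut$diff_table[abs(pairs$a - pairs$b) + 1L])
  expect_identical(via_lut, direct)

  # and through the user-facing evaluators on actual voxel pairs
  set.seed(31)
  for (k in 1:200) {
    ab <- sample(0:imax, 2, replace = TRUE)
    vol <- volume3d(array(c(ab, 0L, 0L), c(2, 2, 1)), intensity_max = imax)
    expect_identical(lut_affinity(lut, c(0, 0, 0), c(1, 0, 0), vol),
                     compute_affinity(lut$model, c(0, 0, 0), c(1, 0, 0), vol))
  }
  expect_identical(lut_affinity(lut, c(0, 0, 0), c(0, 0, 0),
                                flat_volume(c(2, 2, 1))), 1.0)
  expect_identical(lut_affinity(lut, c(0, 0, 0), c(1, 1, 0),
                                flat_volume(c(2, 2, 1))), 0.0)
})

test_that("affinity is non-increasing in intensity difference at fixed mean", {
  lut <- build_lut(affinity_model(100, 100, 80), 255)
  # fixed sum s = 200, increasing |difference|
  u <- seq(0L, 100L, by = 2L)
  vals <- sqrt(lut$sum_table[201L]) * sqrt(lut$diff_table[u + 1L])
  expect_true(all(diff(vals) <= 0))
})

test_that("model parameters round-trip through YAML and JSON", {
  m <- affinity_model(1234.5, 678.9, 321.0, intensity_max = 4095)
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_affinity_model(m, path)
    back <- read_affinity_model(path)
    expect_equal(back$m1, m$m1)
    expect_equal(back$v1, m$v1)
    expect_equal(back$v2, m$v2)
    expect_identical(back$intensity_max, m$intensity_max)
  }
})
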