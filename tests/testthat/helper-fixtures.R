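# shared fixture builders; everything is generated in code at test time

# random tiny volume (<= 32 voxels) with integer intensities in [0, imax]
random_tiny_volume <- function(imax = 20L, max_xy = 3L, max_z = 2L) {
  d <- c(sample(seq_len(max_xy), 1L), sample(seq_len(max_xy), 1L),
         sample(seq_len(max_z), 1L))
  if (prod(d) < 2L) d[1] <- 2L
  volume3d(array(sample(0:imax, prod(d), replace = TRUE), d),
           intensity_max = imax)
}

random_seed_in <- function(vol) {
  d <- dim(vol)
  seed_set(c(sample(0:(d[1] - 1L), 1L), sample(0:(d[2] - 1L), 1L),
             sample(0:(d[3] - 1L), 1L)), vol)
}

# uniform-intensity volume: every adjacent affinity is exactly 1
flat_volume <- function(d, value = 100L, imax = 255L) {
  volume3d(array(value, d), intensity_max = imax)
}

default_lut <- function(vol, seeds = NULL, radius = 1L) {
  model <- if (is.null(seeds)) {
    affinity_model(100, 100, intensity_max = vol$intensity_max)
  } else {
    estimate_affinity(vol, seeds, radius = radius)
  }
  build_lut(model, vol$intensity_max)
}

# small straight-tube phantom spec (noise-free unless sds given)
straight_tube_spec <- function(shape = c(9L, 9L, 20L), radius = 2,
                               fg_sd = 0, bg_sd = 0, rng_seed = 1L) {
  mid <- (shape[1:2] - 1) / 2
  phantom_spec(shape = shape,
               centerline = rbind(c(mid, 0), c(mid, shape[3] - 1)),
               radius = radius, fg_mean = 1250, fg_sd = fg_sd,
               bg_mean = 1100, bg_sd = bg_sd, rng_seed = rng_seed)
}
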