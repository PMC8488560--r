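test_that("grid statistics follow the population convention used for contouring", {
  g0 <- voxel_grid(array(0, dim = c(4, 4, 4)), 1)
  expect_equal(grid_stats(g0), list(mean = 0, sigma = 0))

  g1 <- voxel_grid(array(c(1, rep(0, 7)), dim = c(2, 2, 2)), 1)
  st <- grid_stats(g1)
  expect_equal(st$mean, 0.125)
  expect_equal(st$sigma, sqrt(0.125 - 0.125^2))
  expect_equal(contour_level(g1, 3), 0.125 + 3 * st$sigma)
})

test_that("voxel_grid rejects invalid inputs", {
  expect_error(voxel_grid(matrix(0, 2, 2), 1), "3D array")
  expect_error(voxel_grid(array(0, dim = c(2, 2, 2)), -1), "positive")
  expect_error(voxel_grid(array(Inf, dim = c(2, 2, 2)), 1), "infinite")
  expect_error(voxel_grid(array(NaN, dim = c(2, 2, 2)), 1), "NaN")
})

test_that("MRC round trip preserves data, voxel size and origin", {
  g <- random_grid(8, voxel = 2.0, seed = 5, origin = c(-3, 1.5, 7))
  f <- withr::local_tempfile(fileext = ".mrc")
  write_map(g, f)
  r <- read_map(f)
  expect_equal(r$voxel_size, 2.0)
  expect_equal(r$origin, c(-3, 1.5, 7))
  expect_equal(r$data, g$data, tolerance = 1e-6)
  # second trip is bit-identical: values already representable in float32
  f2 <- withr::local_tempfile(fileext = ".mrc")
  write_map(r, f2)
  expect_identical(read_map(f2)$data, r$data)
})

test_that("malformed or anisotropic MRC volumes are rejected by header field", {
  f <- withr::local_tempfile(fileext = ".mrc")
  writeBin(raw(100), f)
  expect_error(read_map(f), "header")

  # hand-corrupt CELLA to make the voxel size anisotropic
  g <- random_grid(4, voxel = 2, seed = 1)
  write_map(g, f)
  con <- file(f, "r+b")
  seek(con, 10 * 4, rw = "write")   # CELLA x (word 11)
  writeBin(as.numeric(11.0), con, size = 4, endian = "little")
  close(con)
  expect_error(read_map(f), "anisotropic")
})

test_that("low-pass filter preserves DC, kills out-of-band tones, matches its oracle", {
  gc <- voxel_grid(array(3.7, dim = rep(16, 3)), 2)
  expect_lt(max(abs(lowpass_filter(gc, 11)$data - 3.7)), 1e-9)

  d <- 32
  tone <- array(rep(sin(2 * pi * (0:(d - 1)) / 4), d * d), dim = rep(d, 3))
  gs <- voxel_grid(tone, 1)   # wavelength 4 A
  expect_lt(max(abs(lowpass_filter(gs, 11)$data)), 1e-6)

  g <- random_grid(16, voxel = 2, seed = 3)
  expect_equal(lowpass_filter(g, 12)$data,
               oracle_lowpass(g$data, 2, 12), tolerance = 1e-8)
  expect_error(lowpass_filter(g, 3.9), "Nyquist")
})

test_that("radial amplitude profile matches the naive shell oracle", {
  gz <- voxel_grid(array(0, dim = rep(8, 3)), 1)
  expect_true(all(radial_amplitude_profile(gz)$mean_amplitude == 0))

  gc <- voxel_grid(array(2.5, dim = rep(8, 3)), 1)
  p <- radial_amplitude_profile(gc)
  expect_equal(p$mean_amplitude[1], 2.5 * 8^3)
  expect_equal(max(p$mean_amplitude[-1]), 0)
  expect_equal(p$shell_count[1], 1L)
  expect_true(all(diff(p$shell_frequency) > 0))

  g <- random_grid(8, voxel = 2, seed = 7)
  ref <- oracle_profile(g$data)
  got <- radial_amplitude_profile(g)
  expect_equal(got$mean_amplitude, ref$mean_amplitude, tolerance = 1e-8)
  expect_equal(got$shell_count, ref$shell_count)
})

test_that("profile scaling: identity, closed-form ratio, and B-factor inversion", {
  g <- random_grid(16, voxel = 2, seed = 9)
  p <- radial_amplitude_profile(g)
  expect_equal(scale_to_reference(g, p)$data, g$data, tolerance = 1e-6)

  doubled <- grid_with_data(g, 2 * g$data)
  expect_equal(scale_to_reference(doubled, p)$data, g$data, tolerance = 1e-6)

  att <- apply_radial_attenuation(g, 80)
  back <- scale_to_reference(att, p)
  expect_equal(radial_amplitude_profile(back)$mean_amplitude,
               p$mean_amplitude, tolerance = 1e-6)

  other <- random_grid(8, voxel = 2, seed = 9)
  expect_error(scale_to_reference(other, p), "geometry")
})

test_that("low-pass and fixed-profile scaling commute (both are radial multipliers)", {
  g <- random_grid(16, voxel = 2, seed = 13)
  p <- radial_amplitude_profile(random_grid(16, voxel = 2, seed = 14))
  tp <- radial_amplitude_profile(g)   # fixed factors from the unfiltered map
  ab <- lowpass_filter(scale_to_reference(g, p, target_profile = tp), 12)
  ba <- scale_to_reference(lowpass_filter(g, 12), p, target_profile = tp)
  expect_equal(ab$data, ba$data, tolerance = 1e-6)
})

test_that("soft mask: degenerate thresholds, oracle dilation, monotonicity", {
  g <- random_grid(16, voxel = 1, seed = 21)
  hi <- make_mask(g, mask_spec(sigma_threshold = 100, extend_px = 2, soften_px = 3))
  expect_true(all(hi$data == 0))
  lo <- make_mask(g, mask_spec(sigma_threshold = -100, extend_px = 0, soften_px = 0))
  expect_true(all(lo$data == 1))

  # spherical blob: binary + dilation stage against the set-operation oracle
  blob <- voxel_grid(
    exp(-(outer(outer((1:16 - 8)^2, (1:16 - 8)^2, "+"), (1:16 - 8)^2, "+")) / 18),
    1)
  m <- make_mask(blob, mask_spec(sigma_threshold = 3, extend_px = 2, soften_px = 0))
  thr <- contour_level(blob, 3)
  expect_identical(m$data == 1, oracle_binary_mask(blob$data, thr, 2))

  # raising the threshold never adds voxels to the binary stage
  m4 <- make_mask(blob, mask_spec(sigma_threshold = 4, extend_px = 0, soften_px = 0))
  m3 <- make_mask(blob, mask_spec(sigma_threshold = 3, extend_px = 0, soften_px = 0))
  expect_true(all(m3$data >= m4$data))

  soft <- make_mask(blob, mask_spec(sigma_threshold = 3, extend_px = 1, soften_px = 4))
  expect_true(all(soft$data >= 0 & soft$data <= 1))
  expect_true(any(soft$data > 0 & soft$data < 1))
})

test_that("FSC: self-correlation, sign flip, symmetry, scale invariance, noise decorrelation", {
  a <- random_grid(16, voxel = 2, seed = 31)
  curve <- fsc(a, a)
  expect_true(all(abs(curve$correlation - 1) < 1e-9, na.rm = TRUE))
  neg <- fsc(a, grid_with_data(a, -a$data))
  expect_true(all(abs(neg$correlation + 1) < 1e-9, na.rm = TRUE))

  b <- random_grid(16, voxel = 2, seed = 32)
  ab <- fsc(a, b)
  ba <- fsc(b, a)
  expect_equal(ab$correlation, ba$correlation)
  scaled <- fsc(grid_with_data(a, 5 * a$data), grid_with_data(b, 5 * b$data))
  expect_equal(scaled$correlation, ab$correlation, tolerance = 1e-9)

  w1 <- random_grid(32, voxel = 1, seed = 33)
  w2 <- random_grid(32, voxel = 1, seed = 34)
  noise <- fsc(w1, w2)
  inner <- noise$correlation[noise$shell > 2]
  expect_true(all(abs(inner) < 0.2, na.rm = TRUE))
  expect_lt(abs(mean(inner, na.rm = TRUE)), 0.05)

  expect_error(fsc(a, random_grid(8, voxel = 2, seed = 1)), "geometry")
})

test_that("FSC resolution is the first crossing below the cutoff", {
  gt <- make_ground_truth(dim_vox = 32)
  half <- function(seed) {
    set.seed(seed)
    g <- grid_with_data(gt, gt$data + array(rnorm(32^3, sd = 0.05), dim = rep(32, 3)))
    apply_radial_attenuation(g, 300)
  }
  curve <- fsc(half(1), half(2))
  res <- attr(curve, "resolution")
  expect_true(is.finite(res))
  expect_gt(res, 2 * gt$voxel_size)
  first_below <- which(curve$correlation < 0.143 & curve$shell > 1)[1]
  expect_lte(1 / res, curve$shell_frequency[first_below])
  expect_gte(1 / res, curve$shell_frequency[first_below - 1])
})
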