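test_that("PDB structures round-trip through bio3d at format precision", {
  m <- toy_ligand(6)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, f)
  r <- read_structure(f, receptor_chains = character(0), ligand_chains = "L")
  expect_equal(nrow(r$atoms), nrow(m$atoms))
  expect_equal(as.matrix(r$atoms[, c("x", "y", "z")]),
               as.matrix(m$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(unique(r$atoms[, c("chain", "resno")]),
               unique(m$atoms[, c("chain", "resno")]), ignore_attr = TRUE)
})

test_that("simulated density is a Gaussian sum with Z-proportional integral", {
  one <- atomic_model(
    data.frame(chain = "L", resno = 1, resid = "GLY", atom = "CA",
               element = "C", x = 0, y = 0, z = 0, stringsAsFactors = FALSE),
    character(0), "L")
  g <- simulate_density(one, voxel_size = 1, resolution_A = 6)
  peak <- which(g$data == max(g$data), arr.ind = TRUE)[1, ]
  ctr <- (c(0, 0, 0) - g$origin) / g$voxel_size + 1
  expect_true(all(abs(peak - ctr) <= 1))
  expect_equal(sum(g$data) * g$voxel_size^3, 6, tolerance = 0.01)

  # two atoms: exact sum of the single-atom fields on a shared geometry
  two <- atomic_model(
    data.frame(chain = "L", resno = 1:2, resid = "GLY", atom = "CA",
               element = c("C", "O"), x = c(0, 4), y = 0, z = 0,
               stringsAsFactors = FALSE),
    character(0), "L")
  gt <- simulate_density(two, 1, 6)
  a1 <- simulate_onto(atomic_model(two$atoms[1, ], character(0), "L"), gt, 6)
  a2 <- simulate_onto(atomic_model(two$atoms[2, ], character(0), "L"), gt, 6)
  expect_equal(gt$data, a1$data + a2$data, tolerance = 1e-12)
  expect_equal(sum(gt$data) * gt$voxel_size^3, 6 + 8, tolerance = 0.01)
})

test_that("fraction_inside counts atoms above the sigma contour", {
  lig <- toy_ligand()
  dens <- simulate_density(lig, 2, 8)
  expect_equal(fraction_inside(lig, dens, 3), 1.0)

  # atoms far outside the box count as outside
  far <- transform_model(lig, diag(3), c(500, 0, 0))
  expect_equal(fraction_inside(far, dens, 3), 0.0)

  # constructed half-in fixture, verified by a per-atom oracle loop
  half <- lig
  n <- nrow(half$atoms)
  sel <- seq_len(n) > n / 2
  half$atoms[sel, c("x", "y", "z")] <-
    half$atoms[sel, c("x", "y", "z")] + 500
  thr <- contour_level(dens, 3)
  oracle <- mean(vapply(seq_len(n), function(i) {
    p <- as.numeric(half$atoms[i, c("x", "y", "z")])
    idx <- (p - dens$origin) / dens$voxel_size
    if (any(idx < 0) || any(idx > dim(dens$data) - 1)) return(FALSE)
    dens$data[round(idx[1]) + 1, round(idx[2]) + 1, round(idx[3]) + 1] >= thr
  }, logical(1)))
  expect_equal(fraction_inside(half, dens, 3), 0.5)
  expect_equal(oracle, 0.5)

  # monotone non-increasing in the threshold
  fr <- vapply(c(0.5, 1, 2, 3, 5), function(k) fraction_inside(lig, dens, k),
               numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("correlation_of_fit matches a naive masked Pearson and its sign flips", {
  lig <- toy_ligand()
  dens <- simulate_density(lig, 2, 8)
  expect_gte(correlation_of_fit(lig, dens, 8), 0.99)
  expect_lte(correlation_of_fit(lig, grid_with_data(dens, -dens$data), 8,
                                mask = dens$data >= contour_level(dens, 3)),
             -0.99)

  set.seed(11)
  noisy <- grid_with_data(dens, dens$data + rnorm(length(dens$data), sd = 0.01))
  mask <- dens$data >= contour_level(dens, 3)
  sim <- simulate_onto(lig, dens, 8)
  expect_equal(correlation_of_fit(lig, noisy, 8, mask = mask),
               oracle_pearson(sim$data[mask], noisy$data[mask]),
               tolerance = 1e-10)
  expect_error(correlation_of_fit(lig, dens, 8, mask = dens$data > Inf),
               "mask")
})

test_that("scores are invariant under an exact 90-degree grid rotation of model and map", {
  lig <- toy_ligand()
  dens <- simulate_density(lig, 2, 8)
  d <- dim(dens$data)
  # rotate map 90 deg about z: (i,j,k) -> (j, ni+1-i, k); same for atoms
  rot_data <- aperm(dens$data, c(2, 1, 3))[, d[1]:1, ]
  rot_grid <- voxel_grid(array(rot_data, dim = dim(dens$data)[c(2, 1, 3)]),
                         dens$voxel_size, origin = c(0, 0, 0))
  xyz <- as.matrix(lig$atoms[, c("x", "y", "z")])
  idx <- sweep(xyz, 2, dens$origin) / dens$voxel_size
  rot_idx <- cbind(idx[, 2], (d[1] - 1) - idx[, 1], idx[, 3])
  rot_model <- lig
  rot_model$atoms[, c("x", "y", "z")] <- rot_idx * dens$voxel_size
  orig_grid <- voxel_grid(dens$data, dens$voxel_size, origin = c(0, 0, 0))
  orig_model <- lig
  orig_model$atoms[, c("x", "y", "z")] <- idx * dens$voxel_size
  expect_equal(fraction_inside(rot_model, rot_grid, 3),
               fraction_inside(orig_model, orig_grid, 3))
  expect_equal(correlation_of_fit(rot_model, rot_grid, 8),
               correlation_of_fit(orig_model, orig_grid, 8), tolerance = 1e-9)
})

test_that("rigid-body search recovers a planted offset within one grid step", {
  lig <- toy_ligand()
  pivot <- colMeans(as.matrix(lig$atoms[, c("x", "y", "z")]))
  posed <- transform_model(lig, euler_matrix(0, 0, 4), c(2, 0, 0), pivot)
  target <- simulate_density(posed, 2, 8)

  sg <- search_grid(rot_range = 6, rot_step = 2, trans_range = 4,
                    trans_step = 1, rot_axes = "z", trans_axes = "x")
  res <- rigid_body_search(lig, target, sg, 8)
  best <- select_best_fit(res)
  expect_lte(abs(best$rotation_deg["rz"] - 4), 2)
  expect_lte(abs(best$translation["tx"] - 2), 1)
  # zero offset: identity pose wins on its own density
  self <- simulate_density(lig, 2, 8)
  res0 <- rigid_body_search(lig, self, sg, 8)
  best0 <- select_best_fit(res0)
  expect_equal(unname(best0$rotation_deg), c(0, 0, 0))
  expect_equal(unname(best0$translation), c(0, 0, 0))
  # no grid pose beats the true pose on correlation
  expect_true(all(res0$poses$correlation <= best0$correlation + 1e-12))
  # single-basin fixture: top cluster out-hits every other cluster
  expect_gt(res0$clusters$hit_rate[1], max(res0$clusters$hit_rate[-1]))
  expect_equal(sum(res0$clusters$hit_rate), 1)
})

test_that("best-fit selection is deterministic and order-invariant", {
  poses <- data.frame(
    rx = 0, ry = 0, rz = c(2, -2, 0, 4, 6),
    tx = c(1, 0, 0, 2, 1), ty = 0, tz = 0,
    correlation = c(0.6, 0.9, 0.9, 0.5, 0.8),
    fraction_inside = c(0.9, 0.8, 0.8, 0.7, 0.9),
    cluster = 1:5)
  res <- structure(list(poses = poses, clusters = NULL, pivot = c(0, 0, 0),
                        rot_step = 2, trans_step = 1), class = "fit_search")
  best <- select_best_fit(res)
  expect_equal(best$fraction_inside, 0.9)
  expect_equal(best$correlation, 0.8)   # 0.9-occupancy tie broken by correlation

  # ties on both scores resolved by pose ordering; invariant to shuffling
  perms <- list(1:5, 5:1, c(3, 1, 4, 5, 2), c(2, 4, 1, 5, 3))
  sels <- lapply(perms, function(p) {
    r <- res; r$poses <- poses[p, ]
    select_best_fit(r)
  })
  for (s in sels[-1]) expect_equal(s, sels[[1]])

  tied <- res
  tied$poses$fraction_inside <- 0.8
  tied$poses$correlation <- c(0.9, 0.9, 0.6, 0.5, 0.8)
  best_t <- select_best_fit(tied)
  expect_equal(unname(best_t$rotation_deg["rz"]), -2)  # lexicographic tie-break
})

test_that("quaternions from the search rotations are normalized", {
  for (ang in list(c(0, 0, 0), c(10, -8, 4), c(-10, 10, -10))) {
    q <- rotation_quaternion(euler_matrix(ang[1], ang[2], ang[3]))
    expect_equal(sum(q^2), 1, tolerance = 1e-9)
    expect_gte(q[1], 0)
  }
})
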