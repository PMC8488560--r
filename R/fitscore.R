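# Rigid-body fit scoring: simulated density from atomic models, the two
# fit scores of the occupancy-vs-correlation analysis (fraction of atoms
# inside the sigma contour; masked Pearson correlation of fit), exhaustive
# local pose search, pose clustering with hit-rates, and occupancy-based
# best-fit selection.

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

# Accumulate per-atom Gaussians (amplitude proportional to atomic number,
# unit integral times Z) onto an existing grid geometry.
accumulate_density <- function(data, origin, voxel, model, resolution_A,
                               truncate_sigmas = 4) {
  sg <- resolution_A * FWHM_TO_SIGMA
  norm <- 1 / ((2 * pi)^1.5 * sg^3)
  d <- dim(data)
  rad <- ceiling(truncate_sigmas * sg / voxel)
  xyz <- atom_coords(model)
  zn <- model$atoms$z_number
  for (i in seq_len(nrow(xyz))) {
    cidx <- (xyz[i, ] - origin) / voxel          # 0-based fractional index
    lo <- pmax(floor(cidx) - rad, 0)
    hi <- pmin(ceiling(cidx) + rad, d - 1)
    if (any(lo > hi)) next                       # atom entirely outside
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    dx2 <- (ix - cidx[1])^2; dy2 <- (iy - cidx[2])^2; dz2 <- (iz - cidx[3])^2
    r2 <- outer(outer(dx2, dy2, "+"), dz2, "+") * voxel^2
    data[ix + 1, iy + 1, iz + 1] <- data[ix + 1, iy + 1, iz + 1] +
      zn[i] * norm * exp(-r2 / (2 * sg^2))
  }
  data
}

#' Simulate a density map from an atomic model
#'
#' Each atom contributes an isotropic Gaussian of FWHM `resolution_A`,
#' amplitude proportional to its atomic number (unit-integral Gaussian times
#' Z, so the integrated density is proportional to the summed atomic
#' numbers).  The grid is padded by `2 * resolution_A` around the atoms.
#'
#' @param model an `atomic_model`.
#' @param voxel_size grid sampling in Angstrom.
#' @param resolution_A nominal resolution (Gaussian FWHM) in Angstrom; must
#'   be at least `2 * voxel_size`.
#' @return a [voxel_grid()].
#' @export
simulate_density <- function(model, voxel_size = 2, resolution_A = 8) {
  if (nrow(model$atoms) == 0L) stop("cannot simulate density for an empty model")
  if (resolution_A < 2 * voxel_size)
    stop("resolution_A must be >= 2 * voxel_size")
  xyz <- atom_coords(model)
  margin <- 2 * resolution_A
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  d <- pmax(as.integer(ceiling((hi - lo) / voxel_size)) + 1L, 8L)
  data <- array(0, dim = d)
  data <- accumulate_density(data, lo, voxel_size, model, resolution_A)
  voxel_grid(data, voxel_size, origin = lo)
}

#' Simulate model density on the geometry of an existing grid
#'
#' @param model an `atomic_model`.
#' @param grid a [voxel_grid()] providing the target geometry.
#' @param resolution_A Gaussian FWHM in Angstrom.
#' @return a [voxel_grid()] with the same geometry as `grid`.
#' @export
simulate_onto <- function(model, grid, resolution_A = 8) {
  if (nrow(model$atoms) == 0L) stop("cannot simulate density for an empty model")
  data <- accumulate_density(array(0, dim = dim(grid$data)), grid$origin,
                             grid$voxel_size, model, resolution_A)
  grid_with_data(grid, data)
}

# Trilinear interpolation of grid values at Angstrom positions; NA outside.
trilinear <- function(grid, pts) {
  d <- dim(grid$data)
  idx <- sweep(pts, 2, grid$origin) / grid$voxel_size   # 0-based
  n <- nrow(idx)
  vals <- rep(NA_real_, n)
  inb <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
         idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
         idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
  if (!any(inb)) return(vals)
  p <- idx[inb, , drop = FALSE]
  f0 <- pmin(floor(p), matrix(rep(d - 2, each = nrow(p)), ncol = 3))
  fr <- p - f0
  acc <- 0
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (cx * fr[, 1] + (1 - cx) * (1 - fr[, 1])) *
         (cy * fr[, 2] + (1 - cy) * (1 - fr[, 2])) *
         (cz * fr[, 3] + (1 - cz) * (1 - fr[, 3]))
    lin <- (f0[, 1] + cx) + d[1] * ((f0[, 2] + cy) + d[2] * (f0[, 3] + cz)) + 1
    acc <- acc + w * grid$data[lin]
  }
  vals[inb] <- acc
  vals
}

#' Fraction of atoms inside the density contour
#'
#' The fraction of the model's atoms whose trilinearly interpolated map
#' value is at or above `mean + sigma_threshold * sigma` of the map (the
#' standard display contour, default 3 sigma).  Atoms outside the grid count
#' as outside the contour, so poses near the box edge remain comparable.
#'
#' @param model an `atomic_model`.
#' @param grid a [voxel_grid()].
#' @param sigma_threshold contour level in sigmas above the map mean.
#' @return fraction in `[0, 1]`.
#' @export
fraction_inside <- function(model, grid, sigma_threshold = 3) {
  vals <- trilinear(grid, atom_coords(model))
  thr <- contour_level(grid, sigma_threshold)
  mean(!is.na(vals) & vals >= thr)
}

#' Correlation of fit between a model and a density map
#'
#' Pearson correlation (about the mean) between the model's simulated
#' density and the experimental map, over the voxels of the evaluation mask
#' (default: the map's region at or above its 3-sigma contour).
#'
#' @param model an `atomic_model`.
#' @param grid a [voxel_grid()].
#' @param resolution_A Gaussian FWHM for the simulated density.
#' @param mask optional logical array or [voxel_grid()] (weights >= 0.5 kept)
#'   selecting the evaluation region.
#' @param sigma_threshold contour defining the default mask.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
correlation_of_fit <- function(model, grid, resolution_A = 8, mask = NULL,
                               sigma_threshold = 3) {
  if (is.null(mask)) {
    mask <- grid$data >= contour_level(grid, sigma_threshold)
  } else if (is.voxel_grid(mask)) {
    assert_same_geometry(grid, mask, "map and correlation mask")
    mask <- mask$data >= 0.5
  }
  if (!any(mask)) stop("empty correlation mask: no voxels at the contour level")
  sim <- simulate_onto(model, grid, resolution_A)
  stats::cor(sim$data[mask], grid$data[mask])
}

#' Local rigid-body search grid
#'
#' Exhaustive grid over intrinsic Euler rotations about the ligand centroid
#' and Cartesian translations, with the classic local-refinement defaults of
#' -10..10 degrees in 2 degree steps and -10..10 Angstrom in 1 Angstrom
#' steps.  Axes can be restricted (`rot_axes`, `trans_axes`) to search a
#' reduced subset of the six degrees of freedom.
#'
#' @param rot_range,rot_step rotation range and step, degrees.
#' @param trans_range,trans_step translation range and step, Angstrom.
#' @param rot_axes,trans_axes subset of `c("x","y","z")` to vary.
#' @return a `search_grid` with a data.frame of poses
#'   (`rx, ry, rz, tx, ty, tz`).
#' @export
search_grid <- function(rot_range = 10, rot_step = 2,
                        trans_range = 10, trans_step = 1,
                        rot_axes = c("x", "y", "z"),
                        trans_axes = c("x", "y", "z")) {
  if (rot_step <= 0 || trans_step <= 0) stop("steps must be > 0")
  if (rot_range < rot_step && length(rot_axes))
    stop("rotation range must be >= step")
  if (trans_range < trans_step && length(trans_axes))
    stop("translation range must be >= step")
  ax <- function(name, axes, range, step)
    if (name %in% axes) seq(-range, range, by = step) else 0
  poses <- expand.grid(
    rx = ax("x", rot_axes, rot_range, rot_step),
    ry = ax("y", rot_axes, rot_range, rot_step),
    rz = ax("z", rot_axes, rot_range, rot_step),
    tx = ax("x", trans_axes, trans_range, trans_step),
    ty = ax("y", trans_axes, trans_range, trans_step),
    tz = ax("z", trans_axes, trans_range, trans_step)
  )
  structure(list(poses = poses, rot_step = rot_step, trans_step = trans_step),
            class = "search_grid")
}

#' Euler angles (degrees) to rotation matrix
#'
#' Intrinsic rotations applied in z, y, x order: `R = Rz %*% Ry %*% Rx`.
#' @param rx,ry,rz rotations about x, y, z in degrees.
#' @return 3x3 rotation matrix.
#' @export
euler_matrix <- function(rx, ry, rz) {
  a <- rx * pi / 180; b <- ry * pi / 180; c <- rz * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3)
  Rz <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

#' Rotation matrix to unit quaternion
#' @param R 3x3 rotation matrix.
#' @return length-4 numeric `(w, x, y, z)`, normalized, `w >= 0`.
#' @export
rotation_quaternion <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- 0.25 * s
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  q
}

#' Exhaustive local rigid-body search
#'
#' Evaluates both fit scores for every pose of the search grid (rotations
#' about the ligand centroid, then translation), merges poses into clusters
#' whose parameters lie within one search step of a cluster exemplar in
#' every degree of freedom, and reports per-cluster hit-rates as the
#' fraction of all evaluated poses.
#'
#' @param model the ligand `atomic_model`, initially placed near the target
#'   density.
#' @param grid the experimental [voxel_grid()].
#' @param search a [search_grid()].
#' @param resolution_A Gaussian FWHM for simulated density.
#' @param sigma_threshold contour level for both scores.
#' @return a `fit_search`: list with `poses` (data.frame of pose parameters,
#'   `correlation`, `fraction_inside`, `cluster`), `clusters` (per-cluster
#'   size and `hit_rate`), `pivot`, and the search steps.
#' @export
rigid_body_search <- function(model, grid, search = search_grid(),
                              resolution_A = 8, sigma_threshold = 3) {
  poses <- search$poses
  if (nrow(poses) == 0L) stop("search grid contains no poses")
  pivot <- colMeans(atom_coords(model))
  mask <- grid$data >= contour_level(grid, sigma_threshold)
  if (!any(mask)) stop("empty contour mask: nothing to fit into")
  thr <- contour_level(grid, sigma_threshold)
  gmask <- grid$data[mask]

  corr <- frac <- numeric(nrow(poses))
  for (i in seq_len(nrow(poses))) {
    m <- transform_model(model, euler_matrix(poses$rx[i], poses$ry[i], poses$rz[i]),
                         c(poses$tx[i], poses$ty[i], poses$tz[i]), pivot)
    vals <- trilinear(grid, atom_coords(m))
    frac[i] <- mean(!is.na(vals) & vals >= thr)
    sim <- simulate_onto(m, grid, resolution_A)
    corr[i] <- stats::cor(sim$data[mask], gmask)
  }
  poses$correlation <- corr
  poses$fraction_inside <- frac

  # greedy clustering in descending occupancy order (deterministic)
  ord <- order(-frac, -corr, poses$rx, poses$ry, poses$rz,
               poses$tx, poses$ty, poses$tz)
  cluster <- integer(nrow(poses))
  ex <- list()
  for (i in ord) {
    assigned <- FALSE
    for (k in seq_along(ex)) {
      e <- ex[[k]]
      if (all(abs(c(poses$rx[i], poses$ry[i], poses$rz[i]) - e[1:3]) <= search$rot_step) &&
          all(abs(c(poses$tx[i], poses$ty[i], poses$tz[i]) - e[4:6]) <= search$trans_step)) {
        cluster[i] <- k; assigned <- TRUE; break
      }
    }
    if (!assigned) {
      ex[[length(ex) + 1]] <- c(poses$rx[i], poses$ry[i], poses$rz[i],
                                poses$tx[i], poses$ty[i], poses$tz[i])
      cluster[i] <- length(ex)
    }
  }
  poses$cluster <- cluster
  tab <- table(cluster)
  clusters <- data.frame(cluster = as.integer(names(tab)),
                         n = as.integer(tab),
                         hit_rate = as.integer(tab) / nrow(poses))
  clusters <- clusters[order(-clusters$hit_rate, clusters$cluster), ]
  rownames(clusters) <- NULL
  structure(list(poses = poses, clusters = clusters, pivot = pivot,
                 rot_step = search$rot_step, trans_step = search$trans_step),
            class = "fit_search")
}

#' Select the best fit by density occupancy
#'
#' The pose maximizing `fraction_inside`; ties broken by higher correlation,
#' then by deterministic lexicographic pose ordering, so the selection is
#' invariant to the order in which poses were evaluated.
#'
#' @param result a `fit_search`.
#' @return a `fit_pose`: list with `rotation_deg`, `quaternion`,
#'   `translation`, `correlation`, `fraction_inside`, `cluster`.
#' @export
select_best_fit <- function(result) {
  p <- result$poses
  if (is.null(p) || nrow(p) == 0L) stop("empty fit result")
  ord <- order(-p$fraction_inside, -p$correlation,
               p$rx, p$ry, p$rz, p$tx, p$ty, p$tz)
  i <- ord[1]
  structure(list(
    rotation_deg = c(rx = p$rx[i], ry = p$ry[i], rz = p$rz[i]),
    quaternion = rotation_quaternion(euler_matrix(p$rx[i], p$ry[i], p$rz[i])),
    translation = c(tx = p$tx[i], ty = p$ty[i], tz = p$tz[i]),
    correlation = p$correlation[i],
    fraction_inside = p$fraction_inside[i],
    cluster = p$cluster[i]
  ), class = "fit_pose")
}

#' @export
print.fit_pose <- function(x, ...) {
  cat(sprintf(
    "<fit_pose> rot (%.1f, %.1f, %.1f) deg, trans (%.1f, %.1f, %.1f) A\n  fraction_inside %.3f, correlation %.3f\n",
    x$rotation_deg[1], x$rotation_deg[2], x$rotation_deg[3],
    x$translation[1], x$translation[2], x$translation[3],
    x$fraction_inside, x$correlation))
  invisible(x)
}

#' @export
print.fit_search <- function(x, ...) {
  cat(sprintf("<fit_search> %d poses, %d clusters; top hit-rate %.1f%%\n",
              nrow(x$poses), nrow(x$clusters), 100 * x$clusters$hit_rate[1]))
  invisible(x)
}

#' Occupancy-versus-correlation scatter of a pose search
#'
#' Fraction of the structure inside the density contour (y) against the
#' correlation of fit (x), one point per evaluated pose, the standard view
#' for picking the fit with the greatest occupation of density.
#'
#' @param x a `fit_search`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fit_search <- function(x, ...) {
  graphics::plot(x$poses$correlation, x$poses$fraction_inside,
                 xlab = "correlation of fit",
                 ylab = "fraction of atoms inside density", ...)
  best <- select_best_fit(x)
  graphics::points(best$correlation, best$fraction_inside, pch = 19)
  invisible(x)
}

#' Write the scored pose table as TSV
#' @param result a `fit_search`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(result, path) {
  utils::write.table(result$poses, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
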