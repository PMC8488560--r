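#' Construct a voxel grid
#'
#' A `voxel_grid` is the package's core container for a 3D scalar density
#' field: a numeric array plus the physical sampling (isotropic voxel size in
#' Angstrom) and the Angstrom offset of voxel `(0,0,0)`.  Map statistics
#' (mean and sigma) are always recomputed from the current data, so they can
#' never go stale after a mutation.
#'
#' @param data 3D numeric array of density values (arbitrary intensity units).
#' @param voxel_size isotropic voxel size in Angstrom (> 0).
#' @param origin length-3 numeric, Angstrom position of voxel `(0,0,0)`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L ||
      !is.finite(voxel_size) || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (Angstrom)")
  if (length(origin) != 3L || !is.numeric(origin) || any(!is.finite(origin)))
    stop("`origin` must be a finite length-3 numeric vector (Angstrom)")
  if (any(is.nan(data)) || any(is.infinite(data)))
    stop("`data` contains NaN or infinite values")
  # NA is permitted: it marks voxels excluded from analysis (e.g. the
  # undetermined voxels of a significance map)
  storage.mode(data) <- "double"
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin)),
    class = "voxel_grid"
  )
}

#' @export
is.voxel_grid <- function(x) inherits(x, "voxel_grid")

#' Grid dimensions
#' @param grid a `voxel_grid`.
#' @return integer vector `(nx, ny, nz)`.
#' @export
grid_dim <- function(grid) dim(grid$data)

#' Map mean and sigma
#'
#' The map mean and the population standard deviation over the whole box.
#' These are the statistics behind sigma-contour levels such as "3 sigma
#' above the mean": the contour threshold is `mean + k * sigma`.
#'
#' @param grid a `voxel_grid`.
#' @return a list with elements `mean` and `sigma` (population sd, divisor N).
#' @export
grid_stats <- function(grid) {
  m <- mean(grid$data, na.rm = TRUE)
  s <- sqrt(mean((grid$data - m)^2, na.rm = TRUE))
  list(mean = m, sigma = s)
}

#' Sigma-contour threshold of a map
#' @param grid a `voxel_grid`.
#' @param sigma_threshold contour level in multiples of sigma above the mean.
#' @return numeric density threshold.
#' @export
contour_level <- function(grid, sigma_threshold = 3) {
  st <- grid_stats(grid)
  st$mean + sigma_threshold * st$sigma
}

#' Test two grids for identical geometry
#'
#' @param a,b `voxel_grid` objects.
#' @param tol relative tolerance on voxel size and absolute (Angstrom)
#'   tolerance on the origin.
#' @return logical.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    abs(a$voxel_size - b$voxel_size) <= tol * max(a$voxel_size, b$voxel_size) &&
    all(abs(a$origin - b$origin) <= tol + tol * abs(a$origin))
}

stop_geometry_mismatch <- function(a, b, what = "grids") {
  stop(sprintf(
    "geometry mismatch between %s: %s @ %.4g A (origin %s) vs %s @ %.4g A (origin %s)",
    what,
    paste(dim(a$data), collapse = "x"), a$voxel_size,
    paste(signif(a$origin, 4), collapse = ","),
    paste(dim(b$data), collapse = "x"), b$voxel_size,
    paste(signif(b$origin, 4), collapse = ",")
  ), call. = FALSE)
}

assert_same_geometry <- function(a, b, what = "grids") {
  if (!same_geometry(a, b)) stop_geometry_mismatch(a, b, what)
  invisible(TRUE)
}

#' Replace the data of a grid, keeping its geometry
#' @param grid a `voxel_grid`.
#' @param data a 3D array with the same dimensions.
#' @return a new `voxel_grid`.
#' @export
grid_with_data <- function(grid, data) {
  if (!identical(dim(data), dim(grid$data)))
    stop("replacement data dimensions do not match the grid")
  voxel_grid(data, grid$voxel_size, grid$origin)
}

#' @export
print.voxel_grid <- function(x, ...) {
  st <- grid_stats(x)
  cat(sprintf(
    "<voxel_grid> %s voxels @ %.3f A/px, origin (%s) A\n  mean %.5g, sigma %.5g, range [%.5g, %.5g]\n",
    paste(dim(x$data), collapse = "x"), x$voxel_size,
    paste(signif(x$origin, 5), collapse = ", "),
    st$mean, st$sigma, min(x$data, na.rm = TRUE), max(x$data, na.rm = TRUE)))
  invisible(x)
}
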