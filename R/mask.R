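# Soft sigma-contour masks in the refinement-mask idiom: binarize at
# mean + k*sigma, extend by a few voxels, soften the edge with a cosine
# fall-off (e.g. "3 sigma, extended 2 px, softened 9 px").

# Offsets (as an integer matrix) within a Euclidean radius r, excluding the
# zero offset when zero = FALSE.
sphere_offsets <- function(r, zero = TRUE) {
  ri <- floor(r)
  g <- expand.grid(dx = -ri:ri, dy = -ri:ri, dz = -ri:ri)
  d2 <- g$dx^2 + g$dy^2 + g$dz^2
  keep <- d2 <= r^2 & (zero | d2 > 0)
  cbind(as.matrix(g[keep, ]), dist = sqrt(d2[keep]))
}

# Shift a logical array by an integer offset, padding with FALSE.
shift_logical <- function(a, o) {
  d <- dim(a)
  out <- array(FALSE, dim = d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    if (o[k] >= 0) {
      if (o[k] >= d[k]) return(out)
      dst[[k]] <- (1 + o[k]):d[k]; src[[k]] <- 1:(d[k] - o[k])
    } else {
      if (-o[k] >= d[k]) return(out)
      dst[[k]] <- 1:(d[k] + o[k]); src[[k]] <- (1 - o[k]):d[k]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Mask specification
#'
#' @param sigma_threshold contour level in multiples of map sigma above the
#'   mean at which the mask is binarized.
#' @param extend_px dilation radius in voxels applied to the binary mask.
#' @param soften_px width in voxels of the cosine soft edge.
#' @return a `mask_spec` list.
#' @export
mask_spec <- function(sigma_threshold = 3, extend_px = 2, soften_px = 9) {
  if (extend_px < 0 || soften_px < 0) stop("extend_px and soften_px must be >= 0")
  structure(list(sigma_threshold = sigma_threshold,
                 extend_px = as.integer(extend_px),
                 soften_px = as.integer(soften_px)),
            class = "mask_spec")
}

#' Build a soft sigma-contour mask
#'
#' Binarizes the map at `mean + sigma_threshold * sigma`, dilates the binary
#' mask by a Euclidean radius of `extend_px` voxels, then applies a cosine
#' fall-off from 1 to 0 over `soften_px` voxels of Euclidean distance from
#' the dilated edge.  All weights lie in `[0, 1]`.  A threshold above the map
#' maximum yields the all-zero mask.
#'
#' @param grid a [voxel_grid()].
#' @param spec a [mask_spec()] (or arguments via `...` forwarded to it).
#' @param ... convenience: `sigma_threshold`, `extend_px`, `soften_px`.
#' @return a [voxel_grid()] of mask weights.
#' @export
make_mask <- function(grid, spec = mask_spec(...), ...) {
  if (!is.voxel_grid(grid)) stop("`grid` must be a voxel_grid")
  thr <- contour_level(grid, spec$sigma_threshold)
  binary <- grid$data >= thr
  if (!any(binary)) return(grid_with_data(grid, array(0, dim = dim(grid$data))))

  if (spec$extend_px > 0) {
    off <- sphere_offsets(spec$extend_px, zero = FALSE)
    dil <- binary
    for (i in seq_len(nrow(off)))
      dil <- dil | shift_logical(binary, off[i, 1:3])
    binary <- dil
  }

  w <- array(as.numeric(binary), dim = dim(grid$data))
  if (spec$soften_px > 0 && !all(binary)) {
    # exact Euclidean distance to the dilated mask, out to soften_px
    dist <- array(Inf, dim = dim(grid$data))
    dist[binary] <- 0
    off <- sphere_offsets(spec$soften_px, zero = FALSE)
    off <- off[order(off[, "dist"]), , drop = FALSE]
    for (i in seq_len(nrow(off))) {
      d <- off[i, "dist"]
      sel <- shift_logical(binary, off[i, 1:3]) & dist > d
      if (any(sel)) dist[sel] <- d
    }
    edge <- !binary & is.finite(dist)
    w[edge] <- 0.5 * (1 + cos(pi * dist[edge] / spec$soften_px))
  }
  grid_with_data(grid, w)
}
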