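#' Fourier shell correlation between two maps
#'
#' Per-shell normalized cross-correlation of the two maps' Fourier
#' coefficients, the standard resolution measure for pairs of independent
#' ("gold standard") half-map reconstructions.  The reported resolution is
#' the frequency at which the curve first crosses below `cutoff_criterion`
#' (default 0.143), with the crossing position linearly interpolated between
#' shells.
#'
#' @param a,b [voxel_grid()] objects of identical geometry.
#' @param mask optional [voxel_grid()] of weights in `[0, 1]` multiplied into
#'   both maps in real space before the transform (e.g. from [make_mask()]).
#' @param cutoff_criterion correlation value defining the resolution cutoff.
#' @return an `fsc_curve`: data.frame with `shell`, `shell_frequency`
#'   (1/Angstrom), `correlation` (NA in shells with zero power), and
#'   `shell_count`; the estimated resolution in Angstrom is in
#'   `attr(, "resolution")` (NA if the curve never crosses the cutoff).
#' @export
fsc <- function(a, b, mask = NULL, cutoff_criterion = 0.143) {
  assert_same_geometry(a, b, "FSC input maps")
  da <- a$data
  db <- b$data
  if (!is.null(mask)) {
    assert_same_geometry(a, mask, "map and FSC mask")
    da <- da * mask$data
    db <- db * mask$data
  }
  d <- dim(da)
  fa <- stats::fft(da)
  fb <- stats::fft(db)
  sh <- fourier_shell_index(d)
  nyq <- nyquist_shell(d)
  keep <- sh <= nyq
  f <- factor(sh[keep], levels = 0:nyq)

  num <- as.numeric(tapply(Re(fa[keep] * Conj(fb[keep])), f, sum))
  pa <- as.numeric(tapply(Mod(fa[keep])^2, f, sum))
  pb <- as.numeric(tapply(Mod(fb[keep])^2, f, sum))
  corr <- ifelse(pa > 0 & pb > 0, num / sqrt(pa * pb), NA_real_)
  corr <- pmin(1, pmax(-1, corr))

  freq <- shell_frequencies(d, a$voxel_size, 0:nyq)
  curve <- data.frame(shell = 0:nyq, shell_frequency = freq,
                      correlation = corr,
                      shell_count = as.integer(table(f)))
  res <- NA_real_
  def <- which(!is.na(corr))
  below <- def[corr[def] < cutoff_criterion & def > 1]
  if (length(below)) {
    i <- below[1]
    # linear interpolation of the crossing between shell i-1 and i
    j <- max(def[def < i])
    c0 <- corr[j]; c1 <- corr[i]
    fr <- if (c0 == c1) freq[i] else
      freq[j] + (c0 - cutoff_criterion) / (c0 - c1) * (freq[i] - freq[j])
    res <- 1 / fr
  }
  attr(curve, "cutoff_criterion") <- cutoff_criterion
  attr(curve, "resolution") <- res
  class(curve) <- c("fsc_curve", "data.frame")
  curve
}

#' @export
print.fsc_curve <- function(x, ...) {
  res <- attr(x, "resolution")
  cat(sprintf("<fsc_curve> %d shells, cutoff %.3f, resolution %s\n",
              nrow(x), attr(x, "cutoff_criterion"),
              if (is.na(res)) "beyond Nyquist (no crossing)"
              else sprintf("%.2f A", res)))
  invisible(x)
}

#' Plot an FSC curve
#' @param x an `fsc_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fsc_curve <- function(x, ...) {
  graphics::plot(x$shell_frequency, x$correlation, type = "l",
                 xlab = "spatial frequency (1/A)", ylab = "FSC",
                 ylim = c(min(0, x$correlation, na.rm = TRUE), 1), ...)
  graphics::abline(h = attr(x, "cutoff_criterion"), lty = 2)
  invisible(x)
}

#' Write a shell table (FSC curve or radial profile) as TSV
#' @param x an `fsc_curve` or `radial_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_shell_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
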