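# Fourier-space machinery shared by the filtering, profile-scaling and FSC
# operations.  Shells are indexed by the integer-rounded Fourier voxel radius
# (rescaled to the largest box dimension for non-cubic grids), the SPIDER-era
# convention: shell s of an N-box grid sits at spatial frequency
# s / (N * voxel_size) in 1/Angstrom, and shell 0 holds only the DC term.
# Every radial operator (low-pass, profile rescaling, B-factor attenuation)
# is constant within a shell, so radial operators commute exactly and act on
# shell-mean amplitudes exactly.  Reported profiles and FSC curves cover
# shells 0..Nyquist; the corner shells beyond Nyquist are carried internally
# so rescaling covers the whole transform.

# Continuous Fourier radius (in voxel-frequency units of the largest
# dimension) for every voxel of an unshifted FFT array.
fourier_radius <- function(d) {
  nmax <- max(d)
  ax <- lapply(d, function(n) {
    f <- 0:(n - 1)
    w <- ifelse(f > n / 2, f - n, f)
    (w * (nmax / n))^2
  })
  sqrt(outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+"))
}

fourier_shell_index <- function(d) {
  s <- as.integer(round(fourier_radius(d)))
  array(s, dim = d)
}

# Number of shells reported: 0 .. Nyquist of the largest dimension.
nyquist_shell <- function(d) as.integer(floor(max(d) / 2))

shell_frequencies <- function(d, voxel_size, shells) shells / (max(d) * voxel_size)

#' Radial amplitude profile of a map
#'
#' Mean Fourier amplitude (modulus of the unnormalized DFT) in integer
#' radius shells from DC to Nyquist.  Matching two maps' radial profiles in
#' reciprocal space removes global amplitude and B-factor-like differences
#' between reconstructions before they are compared voxel-wise.
#'
#' @param grid a [voxel_grid()].
#' @return a `radial_profile`: data.frame with columns `shell`,
#'   `shell_frequency` (1/Angstrom), `mean_amplitude`, `shell_count`, with
#'   the source geometry kept in attributes for compatibility checks.
#' @export
radial_amplitude_profile <- function(grid) {
  d <- dim(grid$data)
  sh <- fourier_shell_index(d)
  amp <- Mod(stats::fft(grid$data))
  smax <- max(sh)
  f <- factor(sh, levels = 0:smax)
  full_amp <- as.numeric(tapply(amp, f, mean))
  full_cnt <- as.integer(table(f))
  nyq <- nyquist_shell(d)
  prof <- data.frame(
    shell = 0:nyq,
    shell_frequency = shell_frequencies(d, grid$voxel_size, 0:nyq),
    mean_amplitude = full_amp[1:(nyq + 1)],
    shell_count = full_cnt[1:(nyq + 1)]
  )
  attr(prof, "dims") <- d
  attr(prof, "voxel_size") <- grid$voxel_size
  attr(prof, "full_mean_amplitude") <- full_amp   # incl. corner shells
  class(prof) <- c("radial_profile", "data.frame")
  prof
}

# Apply a per-voxel Fourier multiplier and return the real part.
apply_fourier_multiplier <- function(grid, mult) {
  ft <- stats::fft(grid$data) * mult
  out <- Re(stats::fft(ft, inverse = TRUE)) / length(ft)
  grid_with_data(grid, out)
}

#' Low-pass Fourier filter
#'
#' Attenuates all Fourier components beyond `cutoff_A` with a raised-cosine
#' edge `edge_width_shells` wide, leaving the pass band (including the DC
#' term, hence the map mean) untouched.
#'
#' @param grid a [voxel_grid()].
#' @param cutoff_A resolution cutoff in Angstrom; must be at or below
#'   Nyquist, i.e. `cutoff_A >= 2 * voxel_size`.
#' @param edge_width_shells width of the raised-cosine roll-off, in Fourier
#'   shells.
#' @return the filtered [voxel_grid()].
#' @export
lowpass_filter <- function(grid, cutoff_A, edge_width_shells = 3) {
  if (!is.voxel_grid(grid)) stop("`grid` must be a voxel_grid")
  if (cutoff_A < 2 * grid$voxel_size)
    stop(sprintf("cutoff %.3g A is beyond Nyquist (%.3g A) for %.3g A voxels",
                 cutoff_A, 2 * grid$voxel_size, grid$voxel_size))
  d <- dim(grid$data)
  r <- fourier_shell_index(d)   # shell-indexed, so radial operators commute
  r_c <- max(d) * grid$voxel_size / cutoff_A   # cutoff radius in shells
  ew <- max(edge_width_shells, 1e-9)
  h <- ifelse(r <= r_c, 1,
              ifelse(r >= r_c + ew, 0,
                     0.5 * (1 + cos(pi * (r - r_c) / ew))))
  apply_fourier_multiplier(grid, h)
}

#' Rescale a map to a reference radial amplitude profile
#'
#' Multiplies every Fourier voxel by `reference_amplitude(s) /
#' target_amplitude(s)` for its integer shell `s` (corner shells beyond
#' Nyquist included), leaving phases untouched, so that the rescaled map's
#' radial profile matches the reference exactly.  Shells whose target
#' amplitude falls below `floor_rel` times the target's DC amplitude are
#' passed through unscaled and flagged in the `"unscaled_shells"` attribute.
#'
#' @param target a [voxel_grid()].
#' @param reference_profile a `radial_profile` from
#'   [radial_amplitude_profile()], computed on a grid of the same geometry.
#' @param target_profile optional `radial_profile` from which the
#'   denominator of the scaling factors is taken.  By default the target's
#'   own profile (so the output profile matches the reference exactly); the
#'   difference pipeline instead passes the profile of the target's
#'   condition mean, so one fixed set of factors is applied identically to
#'   every sub-map of that condition.  With a fixed `target_profile` the
#'   operation is a plain radial multiplier and commutes with the other
#'   radial operators.
#' @param floor_rel relative amplitude floor below which a shell is left
#'   unscaled (avoids division blow-up in empty shells).
#' @return the rescaled [voxel_grid()].
#' @export
scale_to_reference <- function(target, reference_profile,
                               target_profile = NULL, floor_rel = 1e-12) {
  if (!is.voxel_grid(target)) stop("`target` must be a voxel_grid")
  if (!inherits(reference_profile, "radial_profile"))
    stop("`reference_profile` must come from radial_amplitude_profile()")
  d <- dim(target$data)
  pd <- attr(reference_profile, "dims")
  pv <- attr(reference_profile, "voxel_size")
  if (!identical(d, pd) || abs(pv - target$voxel_size) > 1e-6 * pv)
    stop(sprintf(
      "geometry mismatch: profile from %s @ %.4g A, target %s @ %.4g A",
      paste(pd, collapse = "x"), pv, paste(d, collapse = "x"),
      target$voxel_size))

  tgt_prof <- if (is.null(target_profile)) radial_amplitude_profile(target)
              else target_profile
  if (!inherits(tgt_prof, "radial_profile") ||
      !identical(attr(tgt_prof, "dims"), d))
    stop("`target_profile` must be a radial_profile on the target geometry")
  ref_amp <- attr(reference_profile, "full_mean_amplitude")
  tgt_amp <- attr(tgt_prof, "full_mean_amplitude")
  floor_val <- floor_rel * tgt_amp[1]
  usable <- tgt_amp >= floor_val & is.finite(ref_amp)
  factor_per_shell <- ifelse(usable, ref_amp / tgt_amp, 1)

  sh <- fourier_shell_index(d)
  mult <- array(factor_per_shell[sh + 1L], dim = d)
  out <- apply_fourier_multiplier(target, mult)
  attr(out, "unscaled_shells") <- which(!usable) - 1L
  out
}

#' Apply a B-factor-like radial attenuation
#'
#' Multiplies Fourier amplitudes by `exp(-b_factor * s^2 / 4)` where `s` is
#' the spatial frequency (1/Angstrom) of the voxel's integer-rounded Fourier
#' shell; phases and the DC term are preserved.  Used by the synthetic-data
#' generators to emulate a resolution-quality difference between two
#' reconstruction ensembles; the attenuation is constant within each shell,
#' so radial-profile rescaling inverts it exactly.
#'
#' @param grid a [voxel_grid()].
#' @param b_factor attenuation B-factor in Angstrom^2 (>= 0).
#' @return the attenuated [voxel_grid()].
#' @export
apply_radial_attenuation <- function(grid, b_factor) {
  if (b_factor < 0) stop("`b_factor` must be >= 0")
  if (b_factor == 0) return(grid)
  d <- dim(grid$data)
  sh <- fourier_shell_index(d)
  s <- sh / (max(d) * grid$voxel_size)
  apply_fourier_multiplier(grid, exp(-b_factor * s^2 / 4))
}
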