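# Global difference analysis between two reconstruction ensembles:
# per-voxel two-sample Student's t, significance bands, difference maps,
# and the end-to-end pipeline (profile scaling -> low-pass -> ensemble
# statistics -> t/p maps -> classification -> report).

#' Construct a map ensemble
#'
#' An ensemble is a set of n >= 2 independent reconstructions of the same
#' structure on a common grid (e.g. the independent sub-maps produced by
#' splitting a particle stack), the unit of replication for the voxel-wise
#' t-test.
#'
#' @param members list of [voxel_grid()] objects with identical geometry.
#' @param label condition name used in reports.
#' @return a `map_ensemble`.
#' @export
map_ensemble <- function(members, label = "") {
  if (!is.list(members) || length(members) < 2L)
    stop("an ensemble needs at least 2 member maps")
  if (!all(vapply(members, is.voxel_grid, logical(1))))
    stop("all members must be voxel_grid objects")
  for (i in seq_along(members)[-1])
    assert_same_geometry(members[[1]], members[[i]],
                         sprintf("ensemble members 1 and %d", i))
  structure(list(members = members, n = length(members), label = label),
            class = "map_ensemble")
}

#' @export
print.map_ensemble <- function(x, ...) {
  cat(sprintf("<map_ensemble> '%s': %d members, %s voxels @ %.3f A\n",
              x$label, x$n, paste(dim(x$members[[1]]$data), collapse = "x"),
              x$members[[1]]$voxel_size))
  invisible(x)
}

ensemble_map <- function(ens, f) {
  map_ensemble(lapply(ens$members, f), label = ens$label)
}

#' Per-voxel ensemble mean and variance
#'
#' @param ens a [map_ensemble()].
#' @return list with `mean` and `variance` (unbiased, divisor n-1) as
#'   [voxel_grid()] objects.
#' @export
ensemble_stats <- function(ens) {
  if (!inherits(ens, "map_ensemble")) stop("`ens` must be a map_ensemble")
  n <- ens$n
  m <- Reduce(`+`, lapply(ens$members, `[[`, "data")) / n
  v <- Reduce(`+`, lapply(ens$members, function(g) (g$data - m)^2)) / (n - 1)
  list(mean = grid_with_data(ens$members[[1]], m),
       variance = grid_with_data(ens$members[[1]], v))
}

#' Plain difference map
#'
#' Voxel-wise `B - A`; inputs are expected to be already profile-scaled and
#' filtered condition means.
#'
#' @param mean_b,mean_a [voxel_grid()] objects of identical geometry.
#' @return a [voxel_grid()].
#' @export
difference_map <- function(mean_b, mean_a) {
  assert_same_geometry(mean_b, mean_a, "difference-map inputs")
  grid_with_data(mean_b, mean_b$data - mean_a$data)
}

#' Difference-pipeline configuration
#'
#' Defaults mirror the conventions for whole-assembly comparisons: an 11 A
#' low-pass cutoff (use 12 A for smaller sub-volumes such as vertex hubs),
#' significance bands at P < 0.05, P < 0.0005 and P < 0.0001, two-tailed
#' probabilities, and amplitude scaling anchored on condition A (the
#' ligand-free condition, so the ligand-bearing maps are rescaled to its
#' profile).
#'
#' @param lowpass_A low-pass filter cutoff in Angstrom.
#' @param thresholds strictly decreasing probability cutoffs defining the
#'   significance bands (most stringent band last).
#' @param tails `"two"` or `"one"`; one-tailed tests for density gain in B.
#' @param variance_floor voxels whose pooled variance falls below
#'   `variance_floor` times the spatial mean pooled variance are labeled
#'   undetermined and excluded from classification (solvent-type voxels).
#' @param welch use Welch's t (per-voxel Welch-Satterthwaite df) instead of
#'   the pooled-variance Student's t.
#' @param scaling enable reciprocal-space radial amplitude-profile scaling.
#' @param scaling_reference which condition (`"A"` or `"B"`) anchors the
#'   scaling profile.
#' @param edge_width_shells raised-cosine edge width of the low-pass filter.
#' @param mask optional [mask_spec()] restricting the analysis (applied to
#'   classification; voxels with mask weight < 0.5 become undetermined).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(lowpass_A = 11,
                            thresholds = c(0.05, 0.0005, 0.0001),
                            tails = c("two", "one"),
                            variance_floor = 1e-9,
                            welch = FALSE,
                            scaling = TRUE,
                            scaling_reference = c("A", "B"),
                            edge_width_shells = 3,
                            mask = NULL) {
  tails <- match.arg(tails)
  scaling_reference <- match.arg(scaling_reference)
  if (any(diff(thresholds) >= 0))
    stop("`thresholds` must be strictly decreasing")
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("`thresholds` must lie in (0, 1)")
  structure(list(lowpass_A = lowpass_A, thresholds = thresholds,
                 tails = tails, variance_floor = variance_floor,
                 welch = welch, scaling = scaling,
                 scaling_reference = scaling_reference,
                 edge_width_shells = edge_width_shells, mask = mask),
            class = "pipeline_config")
}

#' Per-voxel two-sample t and p maps
#'
#' Pooled-variance two-sample Student's t per voxel, with
#' `df = n_A + n_B - 2` (or Welch's t with per-voxel df when
#' `config$welch`).  The sign convention follows `mean_A - mean_B`: extra
#' density in condition B gives negative t.  Voxels whose pooled variance
#' falls below the variance floor are labeled undetermined and get NA t/p.
#'
#' @param ens_a,ens_b [map_ensemble()] objects on a common grid.
#' @param config a [pipeline_config()].
#' @return a `significance_map`: list with [voxel_grid()]s `t` and `p`,
#'   scalar `df` (pooled) or df grid (Welch), integer class array `classes`
#'   (-1 undetermined, 0 not significant, k = band k), `thresholds`,
#'   `undetermined` logical array, and member counts `n_a`, `n_b`.
#' @export
voxel_t_map <- function(ens_a, ens_b, config = pipeline_config()) {
  if (!inherits(ens_a, "map_ensemble") || !inherits(ens_b, "map_ensemble"))
    stop("inputs must be map_ensemble objects")
  assert_same_geometry(ens_a$members[[1]], ens_b$members[[1]],
                       "condition A and condition B")
  na <- ens_a$n; nb <- ens_b$n
  sa <- ensemble_stats(ens_a)
  sb <- ensemble_stats(ens_b)
  ma <- sa$mean$data; mb <- sb$mean$data
  va <- sa$variance$data; vb <- sb$variance$data

  if (config$welch) {
    sem2 <- va / na + vb / nb
    df <- sem2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    pooled <- (va + vb) / 2
  } else {
    df <- na + nb - 2L
    pooled <- ((na - 1) * va + (nb - 1) * vb) / df
    sem2 <- pooled * (1 / na + 1 / nb)
  }
  undet <- pooled < config$variance_floor * mean(pooled)
  tval <- (ma - mb) / sqrt(sem2)
  tval[undet] <- NA_real_
  p <- if (config$tails == "two") 2 * stats::pt(-abs(tval), df)
       else stats::pt(tval, df)   # one-tailed: density gain in B
  g1 <- ens_a$members[[1]]
  classes <- classify_significance(p, config$thresholds, undet)
  structure(list(
    t = grid_with_data(g1, array(tval, dim = dim(g1$data))),
    p = grid_with_data(g1, array(ifelse(is.na(p), 1, p), dim = dim(g1$data))),
    df = df,
    classes = classes,
    thresholds = config$thresholds,
    undetermined = undet,
    n_a = na, n_b = nb, tails = config$tails
  ), class = "significance_map")
}

#' Classify per-voxel probabilities into significance bands
#'
#' Each determined voxel is assigned the most stringent band whose cutoff
#' its p falls strictly below; band 3 (default P < 0.0001) is the "direct
#' density difference" band interpreted as ligand density.
#'
#' @param p numeric array of per-voxel probabilities (NA allowed).
#' @param thresholds strictly decreasing probability cutoffs.
#' @param undetermined optional logical array of voxels to exclude.
#' @return integer array: -1 undetermined, 0 not significant, k for band k.
#' @export
classify_significance <- function(p, thresholds = c(0.05, 0.0005, 0.0001),
                                  undetermined = NULL) {
  if (any(diff(thresholds) >= 0))
    stop("`thresholds` must be strictly decreasing")
  cls <- array(0L, dim = if (is.null(dim(p))) length(p) else dim(p))
  for (k in seq_along(thresholds))
    cls[!is.na(p) & p < thresholds[k]] <- k
  cls[is.na(p)] <- -1L
  if (!is.null(undetermined)) cls[undetermined] <- -1L
  cls
}

#' @export
print.significance_map <- function(x, ...) {
  counts <- band_counts(x)
  cat(sprintf("<significance_map> n=%d vs %d, df=%s, %s-tailed\n",
              x$n_a, x$n_b,
              if (length(x$df) == 1) format(x$df) else "per-voxel (Welch)",
              x$tails))
  for (k in seq_along(x$thresholds))
    cat(sprintf("  band %d (p < %g): %d voxels\n", k, x$thresholds[k],
                counts[[paste0("band", k)]]))
  cat(sprintf("  undetermined: %d voxels\n", counts$undetermined))
  invisible(x)
}

band_counts <- function(sig) {
  cls <- sig$classes
  out <- list(undetermined = sum(cls == -1L),
              not_significant = sum(cls == 0L),
              determined = sum(cls >= 0L))
  for (k in seq_along(sig$thresholds))
    out[[paste0("band", k)]] <- sum(cls >= k)  # bands are nested
  out
}

#' Run the full global difference pipeline
#'
#' Stages, in order: (1) the scaling profile is computed from the plain mean
#' of the reference condition's unfiltered members; (2) every member of the
#' other condition is rescaled to that profile; (3) all members of both
#' conditions are low-pass filtered at `config$lowpass_A`; (4) per-voxel
#' ensemble mean/variance; (5) t and p maps; (6) significance
#' classification; (7) a run report with member counts, df, band voxel
#' counts and the expected false-positive voxel count in band 1 under the
#' null.
#'
#' @param ens_a,ens_b [map_ensemble()] objects (condition A is typically the
#'   ligand-free reference, B the ligand-bearing condition).
#' @param config a [pipeline_config()].
#' @return a `diff_result`: list with `difference` (mean_B - mean_A),
#'   `mean_a`, `mean_b` (processed condition means), `sig` (the
#'   `significance_map`), `report` (data.frame) and `config`.
#' @export
run_difference_pipeline <- function(ens_a, ens_b, config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) stop("`config` must be a pipeline_config")
  assert_same_geometry(ens_a$members[[1]], ens_b$members[[1]],
                       "condition A and condition B")

  if (config$scaling) {
    # one scaling profile per condition: factors computed from the two
    # unfiltered condition means, applied identically to every sub-map of
    # the non-reference condition
    ref <- if (config$scaling_reference == "A") ens_a else ens_b
    oth <- if (config$scaling_reference == "A") ens_b else ens_a
    ref_profile <- radial_amplitude_profile(ensemble_stats(ref)$mean)
    oth_profile <- radial_amplitude_profile(ensemble_stats(oth)$mean)
    oth <- ensemble_map(oth, function(g)
      scale_to_reference(g, ref_profile, target_profile = oth_profile))
    if (config$scaling_reference == "A") ens_b <- oth else ens_a <- oth
  }

  ens_a <- ensemble_map(ens_a, function(g)
    lowpass_filter(g, config$lowpass_A, config$edge_width_shells))
  ens_b <- ensemble_map(ens_b, function(g)
    lowpass_filter(g, config$lowpass_A, config$edge_width_shells))

  sig <- voxel_t_map(ens_a, ens_b, config)
  if (!is.null(config$mask)) {
    w <- make_mask(ensemble_stats(ens_a)$mean, config$mask)
    sig$undetermined <- sig$undetermined | (w$data < 0.5)
    sig$classes <- classify_significance(sig$p$data, sig$thresholds,
                                         sig$undetermined)
  }

  mean_a <- ensemble_stats(ens_a)$mean
  mean_b <- ensemble_stats(ens_b)$mean
  diff <- difference_map(mean_b, mean_a)

  counts <- band_counts(sig)
  report <- data.frame(
    metric = c("n_A", "n_B", "df", "lowpass_A", "tails", "scaling",
               "voxels_total", "voxels_determined", "voxels_undetermined",
               paste0("band", seq_along(sig$thresholds), "_p<",
                      sig$thresholds, "_voxels"),
               "expected_false_positives_band1"),
    value = c(sig$n_a, sig$n_b,
              if (length(sig$df) == 1) sig$df else NA,
              config$lowpass_A, config$tails, config$scaling,
              length(sig$classes), counts$determined, counts$undetermined,
              unlist(counts[paste0("band", seq_along(sig$thresholds))]),
              sig$thresholds[1] * counts$determined),
    stringsAsFactors = FALSE
  )
  structure(list(difference = diff, mean_a = mean_a, mean_b = mean_b,
                 sig = sig, report = report, config = config),
            class = "diff_result")
}

#' Fraction of determined voxels in a significance band
#' @param sig a `significance_map` (or `diff_result`).
#' @param band band index (1 = least stringent).  Bands are nested: a voxel
#'   in band 3 also counts in bands 1 and 2.
#' @return numeric fraction.
#' @export
band_fraction <- function(sig, band = 1) {
  if (inherits(sig, "diff_result")) sig <- sig$sig
  counts <- band_counts(sig)
  counts[[paste0("band", band)]] / counts$determined
}

#' @export
print.diff_result <- function(x, ...) {
  cat("<diff_result>\n")
  print(x$sig)
  invisible(x)
}
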