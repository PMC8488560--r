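---
title: "Attributing density in cryo-EM reconstructions: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing density in cryo-EM reconstructions: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cryodiff answers a recurring question in intermediate-resolution cryo-EM:
when a binding partner (an "adaptor" or other ligand) is added to a large
assembly and the resulting reconstruction shows extra, poorly resolved
density, which parts of that density are really attributable to the ligand,
and which are noise or conformational response?  The package provides three
coordinated tools: a voxel-wise statistical difference pipeline between
ensembles of independent reconstructions, rigid-body fit scoring of atomic
models against density, and computational alanine scanning of the resulting
interface model.  Everything can be exercised end to end on synthetic data
with known ground truth.

```{r setup}
library(cryodiff)
```

## The voxel-wise difference model

The unit of replication is a *map ensemble*: $n \ge 2$ independent
reconstructions of the same structure on a common grid, such as the sub-maps
obtained by splitting a particle stack evenly by micrograph.  For two
conditions A (reference, e.g. assembly alone) and B (assembly plus ligand)
with $n_A$ and $n_B$ members, every voxel $v$ carries a two-sample pooled
Student's $t$:

$$ t(v) = \frac{\bar{x}_A(v) - \bar{x}_B(v)}
               {s_p(v)\sqrt{\tfrac{1}{n_A} + \tfrac{1}{n_B}}},
\qquad
s_p^2(v) = \frac{(n_A-1)s_A^2(v) + (n_B-1)s_B^2(v)}{n_A + n_B - 2}, $$

with $\nu = n_A + n_B - 2$ degrees of freedom.  Extra density in B therefore
gives *negative* $t$, while the plain difference map is reported as
$\bar{x}_B - \bar{x}_A$ so that ligand density is positive there.  Two-tailed
probabilities are the default (a conformational change can move density in
either direction); a one-tailed option and Welch's unequal-variance
statistic (per-voxel Satterthwaite df) are available in the configuration
but off by default, since the pooled form with its single df is the
classical map-comparison convention and the member maps of a condition share
one reconstruction protocol.

Probabilities are classified into nested significance bands, by default
$P<0.05$, $P<0.0005$ and $P<0.0001$; the most stringent band is the one
interpreted as direct ligand density, the weaker bands as conformational
response.  No multiple-testing correction is applied — the per-voxel raw
$P$ convention — but the run report states the expected number of
false-positive voxels in band 1 under the null so the reader can judge the
band counts against it.

Voxels whose pooled variance falls below `variance_floor` (relative to the
spatially averaged pooled variance, default $10^{-9}$) are labeled
*undetermined* and excluded rather than assigned $t = \pm\infty$; this
catches flat solvent padding and masked regions.

### Reciprocal-space amplitude scaling

Two reconstructions of the same structure routinely differ in their radial
amplitude falloff (B-factor-like attenuation from defocus sampling, particle
numbers, or refinement quality).  Left uncorrected, this produces broad
false "differences".  The pipeline therefore computes one radial amplitude
profile per condition from the *unfiltered condition means*, forms per-shell
scaling factors `reference_amplitude(s) / target_amplitude(s)`, and applies
that single fixed factor set to every member of the non-reference condition.
The reference is condition A by default (the ligand-free condition anchors
the scale).  Factors are never recomputed per member: one profile per
condition keeps members exchangeable and the correction strictly radial.

All radial operators in the package — the low-pass filter, the profile
scaling, and the synthetic B-factor attenuation — are constant within each
integer-rounded Fourier shell (shell $s$ of an $N$-box at frequency
$s/(N\,\Delta)$ for voxel size $\Delta$, corner shells beyond Nyquist
included).  This shell-indexed convention means radial operators commute
exactly and act on shell-mean amplitudes exactly, which in turn makes the
scaling an exact inverse of a shell-wise attenuation; the cost is a
filter edge quantized to shells, irrelevant at these band widths.  Shells
whose target amplitude falls below $10^{-12}$ of the DC amplitude are passed
through unscaled (flagged on the result) to avoid dividing by empty shells.

### Pipeline order and defaults

Stages run in a fixed order: scaling profiles from unfiltered means →
rescale the non-reference members → low-pass filter all members → ensemble
mean/variance → $t$/$P$ maps → classification → report.  Because the
operators commute, scale-then-filter equals filter-then-scale for the maps;
the profiles are nonetheless always estimated on unfiltered means so that
the factors do not depend on the filter choice.

The low-pass cutoff defaults to 11 Å, the convention for whole-assembly
comparisons at this resolution range; 12 Å is the matching choice for
smaller sub-volumes (vertex hubs).  The filter edge is a raised cosine three
shells wide — the band edge shape is a free choice at these scales, and a
soft edge avoids ringing.  The display contour convention throughout is
$\text{mean} + 3\sigma$, with $\sigma$ computed over the whole box unless a
mask is supplied.

## What the synthetic generator emulates

`make_ground_truth()` builds a deterministic pseudo-atomic "cage fragment":
three arcs of Gaussian blobs (σ = 5 Å) converging near the box centre, a
cartoon of three curved legs meeting at a vertex, normalized to unit peak on
a 48³ grid at 2 Å/voxel.  `make_ensemble()` then draws members as ground
truth plus i.i.d. white Gaussian noise, optionally adding a planted
spherical "ligand" blob to one condition and/or degrading every member with
a shell-wise attenuation $\exp(-Bs^2/4)$.

Chosen study conditions, fixed once:

* **Grid 48³ at 2 Å** — larger than $10^5$ analyzable voxels for stable
  fraction estimates, small enough for sub-second transforms.
* **Noise σ = 0.02** of the ground-truth peak (peak SNR 50 per member).
  Reconstruction sub-maps agree almost perfectly at low frequency
  (half-map FSC near 1), so per-member noise is small relative to the
  structure; this is the regime in which a systematic amplitude distortion
  is visible against the noise floor, as it is in real comparisons.
* **Planted ligand: Gaussian blob, σ = 5 Å, peak $= 5\sigma/\sqrt{n}$** —
  five times the per-voxel noise SD of a 4-member condition mean.  The blob
  width (FWHM ≈ 12 Å) passes the 11 Å low-pass essentially intact, and its
  half-maximum mask defines "ligand voxels" for recovery statistics.
* **Distortion B = 100 Å²** — at the 11 Å band edge this attenuates
  amplitudes by ≈ 19%, a realistic inter-reconstruction quality difference.

White noise is deliberate: it makes the null calibration exact (each voxel's
$t$ is exactly Student-$t$) and the quantile–quantile check clean.  Real
reconstruction noise is colored and masked, reconstructions need alignment
onto a common grid, and solvent regions are flattened — none of which the
generator reproduces.  Passing tests therefore demonstrate the statistical
machinery (calibration, scaling correction, band logic) and not robustness
to registration error or correlated noise; the low-pass filter does impose
strong spatial correlation, so the band-fraction checks already operate on
correlated fields with the marginal calibration intact.

## Fit scoring

`simulate_density()` renders an atomic model as a sum of isotropic Gaussians
with FWHM equal to the nominal resolution and amplitude proportional to
atomic number — the standard simple kernel when the true point-spread is
unknown.  Two scores describe a rigid-body fit:

* **fraction inside** — the fraction of atoms whose trilinearly interpolated
  map value reaches the $3\sigma$ display contour ("occupancy" of density).
  Atoms outside the grid count as outside, so edge poses stay comparable.
* **correlation of fit** — Pearson correlation, about the mean, between
  simulated and experimental density over the map's $3\sigma$ region (or a
  supplied mask).  The normalization and region of the historical
  fitting-software score are not published; masked about-mean Pearson is
  this package's documented choice.

`rigid_body_search()` evaluates both scores on an exhaustive local grid —
by default ±10° in 2° steps per rotation axis about the ligand centroid and
±10 Å in 1 Å steps per translation axis, the classic local-refinement
window.  Exhaustive enumeration replaces stochastic pose search: it is
deterministic, its resolution is the step size by construction, and at
local-refinement scale it is affordable (axes can be restricted for quick
scans; a full 6-D grid at default steps is $11^3 \times 21^3 \approx 12$
million poses and is not the intended use).  Poses are merged greedily, in
descending occupancy order, into clusters within one step per degree of
freedom of the cluster exemplar; each cluster's *hit-rate* is its share of
all evaluated poses.  The best fit is the pose with the greatest occupancy,
ties broken by correlation and then by deterministic lexicographic order, so
selection is invariant to evaluation order.

## Interface energetics and the alanine scan

The energy function is an explicitly generic pairwise model, configured in
`energy_model()`: Coulomb with distance-dependent dielectric
$\varepsilon(r) = 4r$ (giving $E \propto q_iq_j/4r^2$, with
$k = 1389.35$ kJ mol⁻¹ Å e⁻²), a 12-6 steric term with well depth
0.25 kJ/mol at contact distance $r_i + r_j$, and an 8 Å cutoff, summed over
receptor–ligand pairs only.  Formal charges sit on side-chain termini (Lys
NZ +1, Arg guanidinium +1/3 each, Asp/Glu carboxylate −1/2 each).  Absolute
ΔΔG values from this model are *not* comparable to any published forcefield
numbers — the machinery around the energy is the point:

* **alanine_scan**: for each residue on one side, side-chain atoms beyond
  Cβ are deleted (backbone and Cβ keep their coordinates; no
  re-minimization, single-point convention) and
  $\Delta\Delta G = E_\text{truncated} - E_\text{wild-type}$, so a residue
  whose contacts stabilize the interface scores positive.  Gly/Ala are 0 by
  construction; Pro is scanned by the same rule with a warning.
* **hotspot_report**: hot spots at ΔΔG ≥ 5 kJ/mol (inclusive), constellation
  candidates at ΔΔG > 3 kJ/mol (strict) — the two published thresholds.
* **constellation_scan**: a residue group truncated *simultaneously* gives
  the constellation ΔΔG; cooperativity = constellation ΔΔG − Σ individual
  ΔΔGs, exactly, by construction.  Negative cooperativity flags redundant
  (mutually substitutable) contact networks; a singleton's cooperativity is
  identically zero.
* **salt_bridges**: basic side-chain nitrogens (Lys NZ, Arg NE/NH1/NH2)
  against acidic side-chain oxygens (Asp OD1/OD2, Glu OE1/OE2) across the
  interface, reported per residue pair at minimum atom distance ≤ 4 Å.

Residues are keyed by (chain, residue number) and constellation members are
written chain-prefixed ("B804"), matching the labeling convention of
published interface tables.

## Numerical choices and degenerate inputs

* MRC2014 mode 2 (float32), axis order 1,2,3, little-endian; voxel size from
  CELLA/MX–MZ.  Anisotropic voxels are rejected (relative tolerance 10⁻³),
  never silently resampled.  NA voxels (undetermined) are written as 0 with
  a warning since MRC has no missing-value code.
* FSC curves report shells to Nyquist; shells with zero power in either map
  are NA.  The resolution is the linearly interpolated first crossing below
  the criterion (default 0.143); a curve that never crosses reports NA.
* Masks: binarize at mean + kσ, Euclidean dilation by `extend_px`, cosine
  fall-off over `soften_px` of exact Euclidean distance from the dilated
  edge.  A threshold above the maximum yields the empty mask.
* `voxel_t_map` requires n ≥ 2 per condition and identical geometry;
  mismatches are rejected naming both geometries.
* Generators restore the caller's RNG state; equal seeds give bit-identical
  output.

## Worked example

A null comparison (no ligand, independent noise only) should put about 5% of
voxels in the weakest band and none of the structure in the strongest:

```{r null-example, eval = FALSE}
a <- make_ensemble(n = 4, seed = 11, label = "clathrin-only")
b <- make_ensemble(n = 4, seed = 12, label = "clathrin+ligand")
res <- run_difference_pipeline(a$ensemble, b$ensemble)
band_fraction(res, 1)   # ~0.05 under the null
res$report
```

Planting ligand density in condition B and rerunning moves essentially all
ligand-mask voxels into the strong bands while the background stays at the
nominal rate; `scripts/acceptance.R` in the source repository reruns exactly
these analyses from scratch.

## Known limitations

* Inputs are assumed reconstructed, aligned, and on a common grid; no
  registration, CTF handling, sharpening, or symmetry operations.
* The per-voxel test is marginal: band fractions on filtered maps are
  averages over spatially correlated voxels, so their run-to-run spread is
  larger than a binomial count would suggest.
* The energy model ranks residues within one structure under one parameter
  set; it does not predict absolute binding energies.
* Exhaustive search is local by design — it refines a placement, it does not
  find one globally.
* Problem sizes used in the tests (48³ ensembles, reduced search axes,
  ~140-atom toy complexes) were chosen to make every statistical property
  measurable in seconds; they are surrogates, and quantities that require
  experimental data (true map resolutions, real hit-rates, published ΔΔG
  magnitudes) are out of reach by construction.
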