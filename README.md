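# cryodiff

Statistical attribution of density in cryo-EM reconstructions: where, in a
map of a large assembly plus a binding partner, is the density that really
belongs to the partner?

At intermediate resolution (9–20 Å), a bound adaptor or ligand often shows
up only as weak, ambiguous extra density.  cryodiff implements the
three-stage analysis used to localize such a partner:

1. **Voxel-wise significance mapping** between two *ensembles* of
   independent reconstructions (condition A: assembly alone; condition B:
   assembly + ligand).  Per voxel, a pooled two-sample Student's *t* with
   df = n_A + n_B − 2 classifies differences into nested significance bands
   (default P < 0.05, P < 0.0005, P < 0.0001; the most stringent band is
   read as direct ligand density).  Before testing, the two conditions are
   matched in reciprocal space: per-shell radial amplitude-profile scaling
   removes B-factor-like quality differences that would otherwise create
   false differences, and an 11 Å low-pass (12 Å for sub-volumes) restricts
   the comparison to the trustworthy band.
2. **Rigid-body fit scoring** of an atomic model into density, on the two
   axes of the classic occupancy-versus-correlation plot: *fraction of
   atoms inside the 3σ contour* and *masked Pearson correlation of fit*,
   with exhaustive local pose search (±10° / 2°, ±10 Å / 1 Å), pose
   clustering, per-cluster hit-rates, and best-fit selection by greatest
   density occupancy.
3. **Interface energetics** of the resulting model: computational alanine
   scanning (side-chain truncation beyond Cβ, fixed coordinates),
   hot-spot thresholding (ΔΔG ≥ 5 kJ/mol), constellation analysis of
   residue groups (candidates at ΔΔG > 3 kJ/mol) with
   *cooperativity = constellation ΔΔG − Σ individual ΔΔGs*, and
   salt-bridge detection (basic N / acidic O pairs ≤ 4 Å).

Seeded synthetic-data generators (reconstruction ensembles with known
ground truth, planted ligand blobs, B-factor distortions, toy two-chain
charged complexes) make the whole pipeline testable without experimental
data.  Maps are MRC2014, models are PDB (via bio3d), tables are TSV.

## Worked example

Two synthetic conditions, four member maps each (48³ voxels, 2 Å/voxel),
with a weak ligand blob (peak five times the noise SD of the condition
mean) planted in condition B:

```r
library(cryodiff)
a <- make_ensemble(n = 4, seed = 11, label = "assembly-only")
b <- make_ensemble(n = 4, seed = 12, ligand = list(peak = 0.05),
                   label = "assembly+ligand")
res <- run_difference_pipeline(a$ensemble, b$ensemble)
res
#> <diff_result>
#> <significance_map> n=4 vs 4, df=6, two-tailed
#>   band 1 (p < 0.05): 5917 voxels
#>   band 2 (p < 0.0005): 250 voxels
#>   band 3 (p < 0.0001): 133 voxels
#>   undetermined: 0 voxels
```

The run report puts those counts in context: with 110,592 analyzable voxels
the null expectation for band 1 is ~5530 false-positive voxels, so its
5917 are mostly noise — but bands 2 and 3 are far above their null
expectations (55 and 11), and they sit where the ligand was planted:

```r
inside <- b$ligand_mask$data > 0.5
mean(res$sig$classes[inside] >= 2)
#> [1] 0.8823529
```

88% of the planted-ligand voxels reach P < 0.0005, while the background
stays at the nominal rate.  `write_map()` exports the difference, t, p and
class maps for display; the same pipeline is available from the shell via
`inst/cli/cryodiff diffsig --a a1.mrc,a2.mrc,... --b ... --out dir`.

## Package layout

* `R/` — voxel grids and MRC I/O, Fourier shell machinery (filtering,
  profiles, scaling, FSC), masks, the difference pipeline, fit scoring,
  interface energetics, synthetic generators, CLI commands
* `vignettes/density-attribution.Rmd` — the model, its assumptions, the
  chosen study conditions, and known limitations
* `tests/testthat/` — unit, property and end-to-end tests with independent
  brute-force oracles
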