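# snapref

Scaling, merging and post-refinement for snapshot ("still") serial
crystallography data in which **every reflection is partially recorded**.

In serial femtosecond crystallography each crystal yields one still
diffraction pattern in a random orientation and is destroyed by the pulse,
so the classic rotation-method partiality corrections are unavailable and
there are no fully recorded reference reflections anywhere in the dataset.
`snapref` implements the *method of scaled partials with post-refinement*:

* **Partiality model.** Each reflection is a sphere of radius *r* around
  its reciprocal lattice point; the beam's top-hat bandwidth and
  convergence generate a nest of Ewald spheres, and the partiality *p* is
  the volume fraction of the sphere between the two limiting surfaces,
  computed from the clamped signed radial distances r_high and r_low via
  the cap fraction f(t) = (r−t)²(2r+t)/4r³. A Lorentz factor
  L ∝ 1/(r_low − r_high) accounts for the growth of the excited volume with
  scattering angle, and each partial measurement scales up as
  I_full = I_partial / (p·L).
* **Scaling and merging.** Full intensities per unique hkl are means of
  I_partial/(p·L·G_j) over symmetry equivalents and patterns (p < 0.1
  rejected), with per-pattern scales G_j from the linear-cost iterative
  scheme: merge with equal scales, fit each pattern to the merged set,
  re-merge, repeat.
* **Post-refinement.** The nine Cartesian reciprocal-basis components of
  each pattern are refined by Gauss–Newton least squares against the
  current merged estimates (analytic dp/dv, Bricogne-rescaled normal
  equations, SVD with 10⁻⁶ eigenvalue filtering — exactly one eigenvalue is
  eliminated per solve, the beam-axis rotation redundancy), then the whole
  dataset is re-scaled and re-merged, iteratively.
* **Simulator.** A snapshot simulator reproduces the reference study
  conditions (rhombohedral a = 144.2 Å, α = 113.78° crystal, 8 keV /
  0.05% bandwidth / 1 mrad convergence beam, 76.8 mm detector at 50 mm,
  synthetic Wilson-distributed reference intensities), so the entire method
  runs with no external data.

## Worked example

```r
library(snapref)

cfg <- simulationConfig(nPatterns = 300, seed = 101)   # reference conditions
ds  <- simulateDataset(cfg)
round(partialityStatistics(ds), 4)
#>       mean        max          n
#>     0.2478     0.7690 467856.0000

run <- runCycles(ds, nCycles = 3)                      # scale, merge, refine
round(rFactorHistory(run), 4)
#> cycle0 cycle1 cycle2 cycle3
#> 0.3551 0.2910 0.2758 0.2715

ref <- referenceIntensities(ds)
round(overallRFactor(mergeBaseline(ds, "punit"), ref), 4)    # p = 1 baseline
#> [1] 0.6966
round(overallRFactor(mergeBaseline(ds, "noscale"), ref), 4)  # no scaling
#> [1] 0.3643
```

The simulated dataset has mean partiality 0.248 and maximum 0.769 — the
beam/detector geometry makes the reflection count peak at the detector-edge
resolution (2.41 Å) where the nest of Ewald spheres is thickest relative to
the reflection spheres. The R-factor against the generating intensities
falls monotonically with refinement cycles (0.355 → 0.272); treating all
reflections as fully recorded (`punit`) more than doubles it, and skipping
the scaling step (`noscale`) costs about a point of R even before
refinement. `refinementSummary(run, 1)` shows per-pattern iteration counts,
eliminated eigenvalues and reversion flags; `partialityPairs()` and
`rFactorShells()` provide the observed-vs-calculated partiality and
resolution-shell diagnostics.

A thin command-line front end (`inst/scripts/snapref.R`) exposes
`simulate`, `merge`, `refine` and `evaluate` subcommands over YAML configs
and text reflection files.

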