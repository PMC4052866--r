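---
title: "Partiality modelling and post-refinement for snapshot serial crystallography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partiality modelling and post-refinement for snapshot serial crystallography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snapref)
```

## The problem

In serial femtosecond crystallography (SFX) every crystal contributes a
single still diffraction pattern in a random, unrelated orientation, and the
pulse destroys the crystal before any rotation can be recorded. With a beam
of small but nonzero bandwidth and convergence, essentially every reflection
in every pattern is *partially* recorded: only the fraction of its
reciprocal-space extent that happens to lie inside the excited region
diffracts. The simplest remedy, Monte Carlo merging, averages many raw
partial measurements per unique reflection and relies on the averaging to
wash the partialities out; it needs very large numbers of patterns.

`snapref` implements the alternative: assign each measurement an explicit
partiality from a geometric model, convert each partial intensity to a
full-intensity estimate ("method of scaled partials"), and *post-refine* the
per-pattern diffraction geometry so the partiality estimates become accurate
enough to help. Because no fully recorded reference reflections exist, the
reference is bootstrapped from the data themselves: scale and merge with the
current partialities, refine every pattern against the merged estimates,
re-scale, re-merge and repeat.

## The geometric model

Reciprocal space is handled in nm⁻¹; the beam runs along $+z$ and the Ewald
sphere for wavelength $\lambda$ sits at $(0, 0, -1/\lambda)$. The beam's
top-hat spectrum (full fractional width $\Delta$) and full convergence angle
$\delta$ generate a *nest* of Ewald spheres. For a reflection at scattering
vector $\mathbf{s}$ the package evaluates the four extreme spheres of the
nest (two wavelength limits crossed with two beam tilts of
$\pm\delta/2$, tilting in the plane containing the beam axis and
$\mathbf{s}$ — the in-plane tilt produces the extreme surfaces) and records
the two extreme signed radial excitation distances
$r_\mathrm{high} \le r_\mathrm{low}$. A distance is positive when the
reciprocal lattice point lies inside that limiting sphere; it is negative
when the sphere surface passes closer to the Ewald-sphere centre than the
point.

Each reciprocal lattice point carries a sphere of scattering density of
radius $r$ (a model constant, $5 \times 10^{-3}$ nm⁻¹ by default, small
against the ≈6.45 nm⁻¹ Ewald radius, so the limiting surfaces are locally
flat across it). The partiality is the volume fraction of that sphere
between the two limiting surfaces. With the cap-fraction function
$f(t) = (r-t)^2 (2r+t) / 4r^3$ — the fraction of the sphere volume with
signed radial coordinate at least $t$ — and the distances clamped into
$[-r, +r]$,

$$p = f(\hat r_\mathrm{high}) - f(\hat r_\mathrm{low}), \qquad
L = \frac{k_L}{r_\mathrm{low} - r_\mathrm{high}},$$

where $L$ is the Lorentz factor, computed from the *unclamped* distances so
that it stays independent of $p$. Only "proportional to" is physically
meaningful for $L$; the package fixes $k_L$ to the nest thickness at the
detector-edge resolution of the nominal geometry, so $L = 1$ there. Any
other constant would be absorbed by the overall scale factors.

The full-intensity estimate for one measurement is
$I_\mathrm{full} = I_\mathrm{partial} / (p\,L)$, and the thin-slab limit of
$p\,L$ is constant ($3k_L/4r$), which is exactly the compensation that makes
a low-angle, low-partiality reflection appear as bright as a fully recorded
one at similar angle.

Gradients of $p$ with respect to the nine Cartesian components of the
reciprocal basis $(\mathbf{a}^*, \mathbf{b}^*, \mathbf{c}^*)$ are analytic:
the chain rule runs through the clamped cap fractions (a clamped bound
contributes exactly zero, since $f'(\pm r) = 0$), the Miller index $h$
multiplies the $\mathbf{a}^*$ terms ($k$ and $l$ likewise), and the gradient
of the excitation distance includes the dependence of the tilt plane on
$\mathbf{s}$. $\partial L / \partial v$ is taken as zero: the position of
the point along the slab normal dominates $p$ but barely moves $L$.

## Scaling, merging and post-refinement

Merging uses the plain mean of $I_{ej,\mathrm{partial}} / (p\,L\,G_j)$ over
all symmetry equivalents and patterns, excluding measurements with
$p < 0.1$ (their scale-up factors are explosive); a $1/\sigma^2$-weighted
variant is available behind a flag. Scales $G_j$ come from the linear-cost
iterative scheme: merge with equal scales, fit each pattern's least-squares
ratio $G_j = \sum I_\mathrm{full} \hat I / \sum \hat I^2$ against the merged
table, renormalize to mean 1 (the gauge is otherwise free), re-merge, and
repeat a small number of rounds (3 by default). Cost is linear in the number
of patterns; no all-pairs matrix is ever built.

Post-refinement minimizes, per pattern,
$\sum_e (I_{ej,\mathrm{partial}} / (G_j L_{ej}) - p_{ej} I_\mathrm{full})^2$
over the nine basis components by Gauss–Newton. Reflections enter only if
$I \ge 3\sigma$, $p \ge 0.1$, and their unique reflection has at least one
other scalable measurement anywhere in the dataset; a pattern with no
qualifying reflection is skipped. The normal equations are pre-conditioned
by Bricogne rescaling (diagonal scaled to 1, so small eigenvalues reflect
parameter correlation, not units), solved by SVD with singular values below
$10^{-6}$ of the largest zeroed. One eigenvalue is always eliminated on
generic patterns: rotating the crystal about the beam axis changes no
partiality, so the nine-parameter problem is rank 8. Iteration stops when
the largest partiality change drops below 0.01 or after 10 iterations; a
step that assigns zero partiality to more than a third of the selected
reflections is reverted and ends the refinement of that pattern. Scales are
held fixed during the inner iterations and re-fitted at the next outer
scaling step.

## The simulator

The synthetic datasets reproduce the reference study conditions: 1000
patterns of a rhombohedral crystal with $a = 144.2$ Å,
$\alpha = 113.78°$ (the printed cell of PDB entry 3PQR, space group R32);
8 keV photons (1.5498 Å), 0.05% bandwidth, 1 mrad convergence; a square
76.8 mm detector at 50 mm (edge resolution 2.41 Å, corner 1.93 Å);
reflection-sphere radius $5\times10^{-3}$ nm⁻¹; per-component flat-top
basis errors of at most ±0.1% (a second dataset uses ±1.0%); overall scales
$G \sim N(1, 0.3)$ (redrawn in the rare case of a non-positive draw); and
constant Gaussian noise with standard deviation equal to the mean reference
intensity in the highest of 20 equal-count resolution shells. Negative
noisy intensities are kept — clipping would bias the merged means of weak
reflections.

Two deliberate substitutions keep the generator self-contained:

* **Reference intensities are synthetic.** True structure-factor
  amplitudes of the protein are replaced by draws from an acentric Wilson
  (exponential) distribution whose mean falls off as
  $\exp(-B/2d^2)$ with $B = 25$ Å² and mean 1000 at zero angle —
  typical values for a ~2 Å protein dataset. No statistic the package
  reports depends on the actual protein, only on the intensity
  *distribution*, and this removes every external input.
* **Indexing uses the primitive rhombohedral basis**, not the triple
  hexagonal cell, so every integer index is a real reflection and no
  centring-absence rule is needed (absence handling is out of scope). The
  lattice, reflection density, d-spacings and all partiality statistics are
  identical; Laue-class operator sets for both settings (order 12) are
  provided.

Under these conditions the simulated observations reproduce the published
dataset statistics without any tuning: overall mean partiality ≈ 0.25,
maximum partiality ≈ 0.77, and a reflection-count profile that peaks at the
detector-edge shell and falls steeply into the corner region. These are
emergent properties of the beam/detector geometry — the 0.77 maximum, for
instance, is the centred-slab partiality at the corner-resolution nest
thickness.

What the simulator does *not* emulate: pixel-level images and spot shapes,
indexing ambiguities, FEL spectral jitter, per-crystal variation in
diffraction strength and resolution, and polarization (all out of scope).
Passing tests on these data therefore demonstrate the correctness and
stability of the algorithm under its own model assumptions, not performance
on experimental SFX data.

## Numerical choices and degenerate inputs

* Candidate reflections are enumerated once per dataset from the
  rotation-invariant reciprocal metric (|s| bound at the detector-corner
  resolution) and re-tested per orientation in compiled code.
* The cap-fraction difference is clipped into $[0,1]$ against roundoff;
  both distances clamped to the same bound give exactly $p = 0$.
* $f'(\pm r) = 0$ makes $p$ continuously differentiable across the clamp
  boundary; the min/max over the four nest corners is, however, only
  piecewise smooth, and finite-difference checks must avoid
  corner-degenerate geometries (the analytic gradient takes the one-sided
  value there).
* Zero-diagonal parameters in the normal matrix (all contributing gradients
  zero) are frozen before rescaling; an all-zero matrix yields a zero step
  with every eigenvalue eliminated.
* Patterns with no usable observations keep G = 1 (flagged "unscaled") and
  still contribute to merging; reflections observed only at $p < 0.1$
  simply drop out of the merged table.
* Scale fitting can in principle return a non-positive G on pathological
  noise; such patterns are reset to G = 1 and flagged rather than allowed
  to flip intensity signs.

## Design choices where the design was open

* **Sign of the excitation distance.** We use $e = R - |\mathbf{s} -
  \mathbf{c}|$, positive inside a limiting sphere, which matches the verbal
  convention above; the partiality is invariant under a global sign flip,
  so only reported distances depend on this.
* **Nest extremes from four corners.** The distances are monotone in both
  wavelength and in-plane tilt, so the extremes over the continuous nest
  are attained at the four corners; a dense-sweep oracle confirms this to
  within 1% of the nest thickness.
* **Unit weights** in both merging and least squares (a weighted merge
  exists behind a flag): no weighting scheme is prescribed by the method,
  and unit weights keep the estimator the plain mean the method is defined
  by.
* **Friedel mates merge by default** (the Laue groups include the
  inversion); a `friedel = FALSE` switch keeps anomalous pairs separate.
* **The p < 0.1 rejection applies both in scale fitting and in merging**,
  for consistency of the estimator across stages.
* **Reversion terminates the pattern's refinement** rather than retrying
  with a shorter step — no step-halving is part of the scheme.
* **Fixed scaling rounds** (3) rather than a convergence test: the scheme
  is specified as "iterate a small number of times", and the scale history
  is recorded so users can check |ΔG|.

## What refinement does and does not recover

Post-refinement is judged by what the refined geometry is used for:
partiality estimates and merged-intensity quality. Under the reference
conditions (0.1% basis errors, noiseless), three cycles reduce every
pattern's mean partiality error (0.089 → 0.027 on average) and the overall
R-factor against the generating intensities falls monotonically with
cycles; with noise the orderings R(3 cycles) ≤ R(1) ≤ R(0) ≤ R(p = 1
baseline) and R(0) < R(no scaling) hold, as does the increase of the
observed-vs-calculated partiality correlation after one cycle.

The nine basis components themselves are *not* all determined: beyond the
exact beam-axis rotation null space, the objective has quasi-flat
directions (it constrains each reflection's offset along the local slab
normal), and Gauss–Newton steps drift along them even as the partialities
converge. Parameter-space distance to the generating basis is therefore not
a meaningful quality metric for this problem, and the package reports
partiality and R-factor diagnostics instead.

## Problem sizes used in the tests

The bundled test-suite exercises the full pipeline at 300 simulated
patterns (≈470k observations) for the ordering and rank-deficiency
properties, 200 patterns for the partiality statistics, and small dense
cells (a = 10–30 Å) for exact round-trip and oracle checks; these sizes
preserve every statistic asserted while keeping the default run fast.
`scripts/acceptance.R` regenerates the headline statistics at the full
1000-pattern scale.

## A worked run

```{r example, eval = FALSE}
cfg <- simulationConfig(nPatterns = 300, seed = 101)
ds <- simulateDataset(cfg)
round(partialityStatistics(ds), 4)
#>       mean        max          n
#>     0.2478     0.7690 467856.0000

run <- runCycles(ds, nCycles = 3)
round(rFactorHistory(run), 4)
#> cycle0 cycle1 cycle2 cycle3
#> 0.3551 0.2910 0.2758 0.2715

ref <- referenceIntensities(ds)
round(overallRFactor(mergeBaseline(ds, "punit"), ref), 4)    # p = 1
#> [1] 0.6966
round(overallRFactor(mergeBaseline(ds, "noscale"), ref), 4)  # all G = 1
#> [1] 0.3643
```

## Known limitations

* The partiality profile is the uniform sphere of the model above; Gaussian
  or measured spectral profiles, mosaicity, and Ewald-sphere curvature
  within the reflection sphere are not modelled.
* No polarization correction (irrelevant for the simulator, required for
  experimental data).
* The stream format is a minimal text format for this package's own
  round-tripping, not an interchange format.
* Scaling has a single overall factor per pattern — no per-pattern B factor
  or resolution-dependent scaling.
```
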