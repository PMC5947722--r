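---
title: "Methods: diffuse scattering from crystalline ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diffuse scattering from crystalline ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A crystal is treated as an ensemble of unit-cell (or supercell)
configurations. Writing `f_n(hkl)` for the structure factor of snapshot
`n`,

* the Bragg intensity is the intensity of the *mean* density,
  `I(hkl) = |<f_n>|^2`, and
* the diffuse intensity is the *variance* of the structure factor,
  `D(hkl) = <|f_n|^2> - |<f_n>|^2` (Guinier's equation).

Both are accumulated in a single pass over the snapshot stream as the
running sums of `f` and `|f|^2`; partial accumulators pool exactly
(count-weighted sums of the same moments), so a long stream may be cut
into chunks, processed independently, and merged — the result is
chunk-count invariant to floating-point round-off. The variance uses the
population form (divisor `n`), matching the accumulation identity; the
`(n-1)/n` finite-sample factor only matters when comparing a small-`n`
map against a closed form, and the test suite applies the correction on
the *oracle* side rather than inside the estimator.

Structure factors are computed by direct summation,
`f(hkl) = sum_j occ_j f_j(|s|) exp(2 pi i (h x_j + k y_j + l z_j))`, with
the published four-Gaussian atomic form factors and the convention
`|s| = 1/d` (no `2 pi`). Direct summation is the reference path on
purpose: the toy systems are small, and oracle tests need exactness, not
gridding speed. The hot loop is compiled (explicit real/imaginary
arithmetic; a term-by-term pure-R mirror of the definition cross-checks
it in the tests to 1e-10). No per-atom B smearing is applied inside this
operation — disorder enters only through the ensemble, which is the point
of the method.

### Supercell sampling

A `2 x 2 x 2` supercell has a reciprocal lattice twice as fine: physical
Miller indices at multiples of 1/2. Internally every grid point is an
*integer* index triple of the supercell box plus a per-axis sampling
factor, so half-integers never become floating-point keys; they are
materialized as decimals only in the `h k l I` text format. For a perfect
(undisplaced) tiling the structure factor vanishes at the non-integer
points and equals (number of cells) times the cell value at integer
points — an invariant the tests assert.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `d_min` | 1.6 | Angstrom | resolution cutoff of the reciprocal grid; tests and the pipeline use 3–4 for desk-scale grids |
| `sigma` | 0.3 | Angstrom | per-coordinate displacement SD; typical room-temperature protein scale (B about 7 A^2) |
| `gamma` | 5 | Angstrom | liquid-like correlation length; of the order of a secondary-structure element |
| `rot_sd`, `trans_sd` | 2, 0.1 | degrees, Angstrom | rigid-body amplitudes of the order reported for crystalline protein simulations |
| `switch_prob` | 0.01 | — | per-snapshot probability of a loop flip (symmetric two-state Markov chain) |
| mode-filter kernel, bin | 15 px, 1 ADU | — | neighborhood and histogram resolution of the Bragg-rejection filter |

## What the generator emulates — and what it does not

`sample_ensemble()` produces coordinate stacks with *prescribed
second-moment structure*: i.i.d. Gaussian displacements (an Einstein
crystal), jointly Gaussian displacements with
`cov_ij = sigma^2 exp(-r_ij/gamma)` applied per Cartesian axis
(isotropic; anisotropic coupling is out of scope), per-copy rigid
rotations about uniformly random axes with Gaussian angles, and a
two-state conformational flip of a marked atom subset over an otherwise
Gaussian background. Displacements are drawn in Cartesian Angstrom and
converted back to box-fractional coordinates without wrapping, so
displaced molecules stay intact; diffuse intensities are
translation-phase exact either way. Every generated object owns a named
random stream seeded by the caller and recorded in its metadata, and
never perturbs the caller's RNG.

None of this is molecular dynamics: there are no forces, no solvent, no
time correlation between snapshots, and no attempt to mimic a real fold.
Passing tests therefore demonstrate that the *analysis* — variance
accumulation, decomposition, symmetry handling, image processing,
Patterson transforms, rotation fitting — does what it claims on data
whose ground truth is known exactly; they say nothing about force-field
realism.

## Numerical choices

* **Radial shells.** Isotropic profiles use concentric shells of
  thickness equal to the reciprocal voxel diagonal of the sampled box,
  with the knot at each shell's midpoint. Empty shells are kept and
  flagged.
* **Anisotropic subtraction.** A *natural* cubic interpolating spline
  (zero second derivative at the ends) passes through the shell means;
  points below the first or above the last knot are flagged unmeasured,
  never extrapolated. Fewer than four populated shells is an error.
* **The analysis band.** Two shell classes carry systematic residuals no
  subtraction scheme can remove: (i) the small-angle zone below roughly
  the inverse molecule size (about `d > 15` Angstrom for the toy
  crystals), where the diffuse signal is intrinsically isotropic and the
  anisotropic component is essentially zero-over-zero, and (ii) shells
  cut by the resolution sphere or the grid box, which see only part of
  the sphere. `decomposition_residuals()` flags both; the residual-bias
  check (shell mean of `D'` below 5% of the shell mean `|D'|`) is
  evaluated over complete shells inside the band. With liquid-like maps
  on the tetragonal cell the worst-shell ratio still varies by a factor
  of a few across random toy molecules — cubic-spline interpolation error
  between knots depends on the realized radial profile — so the bound
  holds for typical but not every realization.
* **Symmetrization.** P4/m orbits are the eight images
  `{(h,k,l), (-k,h,l), (-h,-k,l), (k,-h,l)} x {l, -l}`; each point takes
  the mean over the *measured* members of its orbit, unmeasured points
  with measured mates become measured. The operation is idempotent and
  preserves the measured-point mean. Comparisons (`diffuse_compare()`)
  symmetrize both inputs first.
* **Undefined statistics** (fewer than 3 joint points, zero variance,
  static ensembles) propagate as `NA`, never as 0. Negative diffuse
  values from floating-point cancellation are kept, with the variance
  non-negativity bound asserted in tests.
* **Mode filter.** Each pixel takes the representative value (bin lower
  edge + half width) of the most populated bin in its neighborhood; among
  equally populated bins the lowest wins, biasing toward background —
  which is the filter's purpose. Borders use the truncated neighborhood;
  fully masked neighborhoods mask the output. Values are kept floating in
  memory and integerized only on raster write.
* **Geometry.** Flat detector at normal incidence; the combined
  correction divides by the polarization factor (fraction `p` with
  E-field along a stated azimuth; `p = 0.5` reproduces the unpolarized
  `(1 + cos^2 2theta)/2`) times the `cos^3` solid-angle obliquity,
  normalized to 1 at the beam center, in one floating-point pass.
  Integration assigns each pixel to its *nearest* supercell grid point
  (half-way ties round half-up in index space) with count-weighted
  merging across images; image simulation interpolates over the eight
  nearest grid points with weight renormalization over measured corners.
  The synthetic renders place single-pixel Bragg impulses (enough to
  exercise the filter; realistic peak profiles are out of scope) on a
  diffuse pedestal — real detector images always sit on a smooth
  background, and an all-dark synthetic image would make any
  counting-noise bound meaningless at 1-ADU bin resolution.
* **Patterson.** Unmeasured points are zero-filled (fill fraction
  recorded), the input is Friedel-completed by averaging mates, and the
  unnormalized zero-phase DFT is taken on a grid twice the index range
  per axis (even-sized). The origin value equals the completed intensity
  sum. Only the anisotropic component feeds the transforms, so no
  further origin-peak removal is applied.
* **Euler angles.** The z-y-z convention,
  `R = Rz(phi) Ry(theta) Rz(psi)`, fixed and documented; angle-SD
  comparisons are convention-internal. At the gimbal degeneracy
  (`theta ~ 0` or `180`) only one azimuth is determined: `phi` carries
  it, `psi` is set to 0, and the result is flagged. Angle series are
  unwrapped by multiples of 360 degrees before SDs. Note that for
  near-identity rotations the individual azimuths are ill-conditioned
  (only `phi + psi` is stable), which is why the loop-flip demonstrations
  use a quiet background: the two-state geometry then dominates the fit
  and the SD comparison is sharp.
* **Rotation fits.** Kabsch: covariance SVD with determinant correction;
  never a reflection; `rmsd_after <= rmsd_before` by optimality.
  Collinear selections are rejected. A quaternion eigendecomposition
  serves as the independent oracle in the tests.

## Problem sizes

The suite and the acceptance script run desk-scale versions of every
stage: toy asymmetric units of 5–20 atoms (640 atoms in the 2 x 2 x 2
supercell), grids of 1e4–1.5e5 reciprocal points (`d_min` 3–4 Angstrom,
with the single-atom Debye–Waller check at the full 1.6 Angstrom
sphere), ensembles of 200–20000 snapshots, and rotation series of 8–10
images at 512 x 512 pixels. These sizes keep each stage between seconds
and about a minute while leaving every statistical check with clear
Monte-Carlo margins.

## Known limitations

* Only `P1` and `P4/m` Laue handling; only the four P4(1) symmetry
  operators for cell expansion.
* Flat, normally incident detectors; no tilts, no autoindexing (the
  setting matrix is an input).
* The liquid-like model is isotropic and per-axis; no anisotropic
  displacement coupling.
* Form factors cover the light elements plus P, S and Ca; no anomalous
  terms.
* Snapshots are exchangeable draws: nothing in the package models time
  correlation, so "snapshot spacing" is a label, not a physical time.
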