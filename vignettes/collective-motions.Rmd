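---
title: "Collective motions in crystalline protein ensembles: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective motions in crystalline protein ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crystdyn)
```

## The problem

A protein crystal is not a stack of identical molecules. Each copy
fluctuates about the average structure, and the *correlations* between
those fluctuations — within one molecule and across molecular boundaries —
leave a measurable signature: the diffuse X-ray scattering that sits
beneath and between the Bragg peaks. Two simple pictures of these
correlated motions dominate the literature:

* **Liquid-like motions (LLM)**: the crystal behaves as a soft material in
  which the displacement covariance of two atoms decays exponentially with
  their separation, `C(r) = a * exp(-r / gamma)`, characterized by an
  amplitude and a correlation length `gamma`.
* **Rigid-body motions (RBM)**: each molecule moves as a rigid unit —
  small random rotations and translations — producing a covariance that
  depends on atom positions relative to the molecular centroid rather than
  on distance alone.

`crystdyn` implements the analysis chain that distinguishes these
behaviors in a coordinate ensemble of a crystal supercell, and the
diffuse-scattering models that connect them to diffraction data. Because
the analysis itself is purely statistical, the package also provides a
synthetic ensemble generator with *known* LLM/RBM structure, so every
stage can be validated against ground truth without a molecular-dynamics
engine.

## The covariance analysis

Given `F` frames of `N` C-alpha atoms, the pipeline:

1. **Aligns translationally** (`align_translational()`): one rigid
   translation per frame matches the supercell centroid to a reference
   frame. No rotation is applied — a crystal's lattice fixes its
   orientation.
2. **Computes the trace-reduced covariance** (`traced_covariance()`):
   each atom pair's 3x3 Cartesian displacement covariance block is
   replaced by its trace, turning the `3N x 3N` covariance into an
   `N x N` matrix whose diagonal is the per-atom mean squared deviation.
   Normalization is population-style (divide by `F`): this matches the
   ensemble averages in Guinier's equation, and fixing it exactly matters
   for the package's equality tests even though the difference from
   `F - 1` is negligible at thousands of frames.
3. **Sorts pairs by distance** (`pairwise_distances()`): Euclidean
   distances between time-averaged positions, using the minimum-image
   convention whenever a periodic box is present, so the longest distance
   is half the box edge along each axis.
4. **Partitions pairs** (`classify_pairs()`): *intraprotein* pairs lie
   within one chain, *interprotein* pairs cross a chain boundary; the two
   masks partition all off-diagonal pairs exactly. A residue exclusion
   list (default: 5 N-terminal and 8 C-terminal residues, the flexible
   termini of a 149-residue nuclease construct) removes atoms that cannot
   be treated as part of the stable core.
5. **Bins** (`bin_covariance()`): the distance range of the selected
   pairs is divided into 50 even bins; each bin reports the mean
   covariance, a standard error, and the pair count. The bin span is
   re-derived from the selected pairs, so an intra-only analysis re-spans
   its own (shorter) distance range while keeping 50 bins.
6. **Fits** (`fit_exponential()`): unweighted nonlinear least squares of
   `a * exp(-r / gamma) + b` to the bin means with centers in
   `[5, 55.5]` Angstrom by default. The offset `b` absorbs the small
   long-range covariance floor that translational alignment of a periodic
   ensemble produces; without it the exponential fit is visibly poor.
7. **Subtracts model curves** (`subtract_curves()`): an RBM model curve
   computed on the same bin edges can be subtracted bin by bin, errors
   propagated in quadrature, to isolate the residual short-range
   component.

### A caveat about the bin standard errors

The per-bin standard error is the sample standard deviation across pairs
divided by `sqrt(count)` — the convention used for error bars in this
kind of trajectory analysis. It is reproduced deliberately, but it is
*not* an honest standard error of the bin mean: the pair covariances in a
bin are computed from the same frames and are strongly dependent, so the
naive value can understate the true sampling error by an order of
magnitude. The package's own statistical tests therefore derive errors by
frame-block resampling (splitting the ensemble into contiguous blocks,
repeating the analysis per block, and using the scatter of the block
results), both for per-bin checks and for fitted parameters. Users
comparing fitted parameters between ensembles should do the same rather
than trust the asymptotic fit errors.

## The rigid-body motions model

`generate_rbm_ensemble()` reproduces the classic construction: center a
single chain on its centroid, then per frame draw three rotation angles
from `N(0, sd_angle)` and a translation vector from `N(0, sd_trans)`,
apply the rotation first and the translation second. With 5000 frames
(the default in `rbm_covariance_curve()`) the model curve's own noise is
negligible against trajectory curves.

**Euler convention.** The construction samples *extrinsic X-Y-Z
(Tait-Bryan)* angles. This is a deliberate choice: the covariance is a
second-order quantity in the angles, and at second order conventions
differ. For X-Y-Z the small-angle rotation vector is simply the angle
triple, so one shared standard deviation gives an isotropic rotation
distribution and the covariance obeys the closed form

```
C_ij ~ 2 * sigma^2 * (r_i . r_j) + 3 * sd_trans^2,
```

with `r` measured from the centroid and `sigma` in radians. Z-Y-Z-style
conventions concentrate two of the three angles on one axis; their
small-angle rotation vector has covariance `diag(0, sigma^2, 2 sigma^2)`,
which breaks this closed form by terms of the same order as the signal.
Since the isotropic form is both the physically intended model ("the same
width in every direction") and the analytically testable one, X-Y-Z is
used and recorded in the ensemble metadata.

Two consequences worth knowing: a pure translation gives a *flat* curve
at `3 * sd_trans^2` (every atom shares the displacement exactly), and a
pure small rotation gives a curve that is positive at short distance and
negative at the longest intra-chain distances, because `r_i . r_j` is
negative for atoms on opposite sides of the centroid. The superposition
explains why an RBM curve tracks a trajectory's intraprotein covariance
at long range and why subtracting it can reveal a short-range exponential
residual.

## The synthetic crystal generator

`crystal_layout()` builds a periodic supercell of pseudo-protein chains:
one compact self-avoiding random walk (3.8 Angstrom virtual bonds,
confined to a sphere of radius `3 * n^(1/3)` Angstrom — about 16 Angstrom
for 149 residues, the size of a small globular protein) is copied to
centroids that tile the unit cells. All chains are identical copies
because a crystal repeats the same molecule; the package's scope excludes
rotational space-group operators, and identical copies are also what
makes a single-chain RBM model curve exactly comparable to every chain of
the lattice.

`generate_llm_ensemble()` realizes the LLM hypothesis literally as a
Gaussian random field: the per-coordinate covariance between atoms `i`
and `j` is `(a/3) * exp(-r_ij / gamma)`, so the traced covariance equals
`a * exp(-r_ij / gamma)` and the per-atom MSD equals `a`. Distances enter
through the minimum image in the supercell box, making the field
consistent with the periodic boundary. The kernel is factorized by
Cholesky decomposition after adding a `1e-8` Angstrom^2 diagonal jitter.
The minimum-image metric is not guaranteed to produce a positive-definite
exponential kernel: empirically, factorization succeeds comfortably when
the box edge exceeds roughly five correlation lengths and fails as
`gamma` approaches the half-box, in which case the generator raises an
error naming the jitter rather than silently regularizing. The study
conditions (boxes of ~48-127 Angstrom, `gamma` of 5.7-10 Angstrom) are
well inside the safe regime.

`generate_composite_ensemble()` superposes three independent components —
the LLM field, per-chain rigid motions about each chain centroid, and
uncorrelated white noise — so decomposition analyses can be tested
against known ground truth: off-diagonal covariance comes from the LLM
field (all pairs) plus rigid motions (intra-chain pairs only), white
noise contributes `3 * sd^2` to the diagonal alone, and the MSDs add.

**What the generator does not emulate.** Chains are featureless walks
with uniform displacement statistics: no secondary structure, no
side-chain or solvent contribution, no stiffer core versus floppier
termini (exclusion lists are exposed instead), no space-group rotations,
and no force-field physics. Passing tests therefore demonstrate that the
*analysis chain* is correct and that the decomposition logic can recover
known parameters — not that any particular protein behaves this way.

## Diffuse scattering

`guinier_diffuse()` evaluates Guinier's equation on a reciprocal-space
grid: the diffuse intensity is the variance of the structure factor,
`I_d(s) = <|F|^2> - |<F>|^2`. Conventions, fixed throughout the package:
scattering vector `s = (h/a, k/b, l/c)` with `|s| = 1/d`, and phases
`exp(2 pi i h . x_frac)`. Grids (`lattice_spec()`) are indexed in Miller
units of the given cell at `sampling_factor` points per index — 2 (twice
as fine as the Bragg lattice) for maps, 1 (one point per Miller index,
the coarse sampling used when refining models against data) for
refinement. Unit point scatterers are the default; Cromer-Mann
four-Gaussian form factors for common elements are available via
`form_factor_cm()` when realism matters.

The variance can be accumulated **coherently** (pooling all frames) or
**incoherently** (averaging the per-chunk variances of equal contiguous
frame chunks). With population normalization and equal chunks, the pooled
variance equals the mean within-chunk variance plus the variance of the
chunk means, so coherent accumulation dominates incoherent pointwise —
an identity the tests assert exactly. Incoherent accumulation models an
illuminated volume that behaves as independent mosaic domains.

Post-processing follows the standard diffuse workflow:
`symmetrize_laue()` averages symmetry orbits (P4 fourfold about the c
axis; Friedel mates always), `cull_bragg_and_resolution()` applies a
resolution limit (1.6 Angstrom default) and excludes points within 1/4
Miller index of any Bragg position (with optional downsampling to one
point per index by voxel averaging), `anisotropic_component()` removes
the interpolated radial average, and `diffuse_pearson()` compares
lattices over jointly valid points.

### The LLM and rigid-body-translation intensity models

`llm_intensity()` implements the standard closed form

```
I_d(s) = (1 - exp(-4 pi^2 s^2 sigma^2)) * [I_c (*) Gamma_gamma](s),
Gamma_gamma(s) = 8 pi gamma^3 / (1 + 4 pi^2 s^2 gamma^2)^2,
```

where `I_c` is the squared structure factor of the rigid structure and
`Gamma_gamma` is the 3D Fourier transform of `exp(-r/gamma)` (unit
integral). `rbt_intensity()` is the same expression without the
convolution — the whole repeating unit translating rigidly with isotropic
amplitude `sigma`. The two coincide in the large-`gamma` limit, a
consistency the tests verify, along with the cross-module identity that a
rigidly translating ensemble pushed through `guinier_diffuse()`
reproduces `rbt_intensity()` at the generating `sigma`.

**Convolution numerics.** `Gamma_gamma` has heavy `1/s^4` tails, so
truncating it by value retains essentially the whole grid and a direct
sum costs `O(M^2)` per model evaluation. The convolution is therefore
computed as an exact circular convolution via 3D FFT, with offsets taken
minimum-image on the grid and the discrete kernel normalized to unit sum
(conserving total intensity and keeping the delta-kernel limit exact). A
direct-summation reference implementation exists and the test suite
checks the two agree to machine precision on a small grid.

`refine_llm()` fits `gamma` and `sigma` by maximizing the Pearson
correlation between the *anisotropic components* of model and target — a
coarse log-spaced grid search (`gamma` in 2-30 Angstrom, `sigma` in
0.05-1 Angstrom) followed by Nelder-Mead refinement in log-parameter
space. Correlation is scale-free, so a least-squares amplitude is
reported separately. On self-generated targets with 5% multiplicative
noise the refinement recovers both parameters to a few percent.
`llm_msd()` converts a refined `sigma` to the implied mean squared
displacement `3 * sigma^2` (0.50 Angstrom^2 for `sigma = 0.41` Angstrom).

## Problem sizes and reproducibility

The full 32-chain x 149-atom supercell (4768 atoms; a 14304-dimensional
displacement space reduced to a 4768 x 4768 traced matrix) is handled
directly — layout, a short ensemble, and the traced covariance take a few
seconds. The statistical validation analyses are run at deliberately
modest scale chosen so that sampling errors, not compute, set the
precision: ~300-500-atom layouts, 2000-frame LLM fields (where frame-block
errors put parameter recovery within ~1 standard error of truth),
5000-frame RBM model curves, and coarse 17^3 refinement grids. Every
stochastic stage takes an explicit integer seed, and the pipeline derives
all of its component seeds from the single `config$seed`, so identical
configurations produce byte-identical outputs.

## Known limitations

* Orthorhombic-type metrics only (all cell angles 90 degrees); P4 is the
  only non-trivial Laue group implemented.
* The LLM field generator is dense-Cholesky based, `O(N^3)`: practical to
  a few thousand atoms, and restricted to correlation lengths well below
  the half-box by positive definiteness of the minimum-image kernel.
* The exponential fit is unweighted and its asymptotic standard errors
  inherit the dependence problem described above.
* Screw motions, anisotropic TLS tensors, inter-chain coupled rigid
  motions, and normalized correlation-matrix analyses are out of scope.
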