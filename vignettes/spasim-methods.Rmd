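---
title: "Methods: single-particle averaging of two-color SIM volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-particle averaging of two-color SIM volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

A reconstructed 3D-SIM volume of a diffraction-limited two-spot particle
(e.g. a spindle pole body and its satellite) is modelled as the sum of two
3D Gaussians over a constant background,

$$ I(x, y, z) = B + \sum_{k \in \{a, b\}} A_k
  \exp\!\left(-\frac{(x - c_{x,k})^2 + (y - c_{y,k})^2}{2\sigma_{xy}^2}
              -\frac{(z - c_{z,k})^2}{2\sigma_z^2}\right), $$

with all lengths in nm (an integer voxel index names its center;
position = index × spacing). The two spots share $\sigma_{xy}$ and
$\sigma_z$: both are images of point-like objects through the same PSF,
and the shared-width model has four fewer parameters, which stabilizes
fits of dim satellites. Per-spot widths are available via
`fit_dual_spot(..., shared_widths = FALSE)`-style extension points but are
not the default; widths of well-separated structures can instead be read
from the averaged-map profile fits. A constant background per crop is
included because reconstructed SIM volumes carry a nonzero, locally flat
baseline; the model without it biases amplitudes and therefore intensity
ratios.

Assumptions worth stating: the PSF is approximated as an anisotropic
Gaussian (adequate for fitted *centers* and relative widths, not for
absolute deconvolution); the background is locally constant over a crop of
~30 px; chromatic alignment between the two channels has been applied
upstream; and noise is additive Gaussian, which matches reconstructed
(Wiener-filtered) SIM data rather than raw photon counts.

## Detection and its parameters

| parameter | default | unit | why |
|---|---|---|---|
| `blur_sigma` | 1 | px | suppress single-pixel noise before maxima search |
| `threshold_fraction` | 0.15 | — | accept maxima above 15% of the image maximum |
| `min_distance` | 30 | px | one particle per ~1.2 µm neighbourhood (40 nm px) |
| `box` | 30 | px | lateral window for the axial profile |

"Progressively finding maxima" is formalized as greedy acceptance in
descending blurred-intensity order with Euclidean minimum-distance
suppression; ties in value break by (y, x) lexicographic order so the
result is deterministic. The fractional threshold is applied to the
maximum of the *blurred* image — the image in which maxima are found — a
choice the original description leaves open; it is recorded here and
configurable. The axial filter fits a 1D Gaussian to the boxed z-profile
and eliminates particles whose fitted center lies within one slice of
either end; if that fit fails the particle is likewise eliminated
(conservative: truncated particles bias axial centers).

Detection is semi-automated by design: `find_candidates()` proposes,
`detect_particles()` annotates, but pairing mother/distal seeds is the
user's act (the seed CSV), exactly as manual spot picking is in the
original protocol. The `classify_foci()` F-test (dual vs. single fit,
4 extra parameters, p < 0.01, separation gate of one lateral pixel)
replaces visual two-spot counting where automation is wanted.

## Fitting: optimizer and numerical choices

The least-squares problems are solved with `stats::nlminb` (PORT
trust-region quasi-Newton) under box constraints, with an analytic
gradient assembled from the separable structure of the model. Centers are
constrained to seed ± 2 px laterally and initialization ± 2 slices
axially; these guards prevent the dramatic misfits that occur when a dim
satellite's basin of attraction merges with the mother's.

Numerical choices that matter:

* **Initialization.** Background at the crop's lower decile; amplitudes at
  (local 3×3×3 peak − background); σ at 1.2 px lateral / 1 slice axial;
  axial centers at the argmax of the 3×3 z-profile (ties toward the
  smaller slice).
* **Budget.** Up to 1000 iterations at `rel.tol = 1e-10`, parameters
  scaled by their initial magnitudes. A Levenberg–Marquardt code typically
  converges in tens of iterations; the quasi-Newton route needs several
  hundred on the 11-parameter dual model, so the often-quoted cap of 200
  is deliberately not used here.
* **Stall handling.** PORT occasionally reports "false convergence" one
  step short of the optimum; the fit restarts from the stalled point (at
  most twice) and a fit whose residual sum of squares is below
  10⁻⁸ × ΣI² is accepted as numerically exact regardless of the
  diagnostic.
* **Degeneracy.** If both fitted centers collapse within 0.5 px the fit is
  flagged degenerate and excluded downstream; `intensity_ratio()` refuses
  degenerate fits rather than returning ∞.
* **1D profile fits** rescale intensities to unit range first; summed
  z-profiles otherwise carry offsets of ~10⁴ that stall the optimizer.

Monte Carlo uncertainties follow the residual-bootstrap convention: 100
replicates of fitted model + N(0, s²) noise, refit from the original
initialization, SD per parameter. Replicates that fail to converge are
excluded and counted; above 10% failures the estimate is flagged
unreliable. s² = 0 short-circuits to zero SDs.

## Alignment, the plane choice, and probability maps

The published description fixes the two in-plane axes only implicitly:
the x axis is the mother–satellite axis, and the second axis ("pole
axis") is perpendicular to it. Among the planes containing the particle
axis, `spasim` samples the one that also contains the optical z axis
(v = ẑ − (ẑ·u)u, normalized). This is the only choice that makes the
pole axis approximately normal to the nuclear envelope for particles
lying in the imaging plane, and it degrades gracefully with tilt.
Particles whose axis lies within 30° of vertical have no usable pole
direction and are rejected — mirroring the observation that vertically
oriented particles are undetectable as two spots anyway. The choice is
isolated in `extract_aligned_plane()` so alternatives can be swapped.

Planes are sampled by trilinear interpolation at pitch = lateral
voxel / 4 (10 nm for 40 nm voxels) onto a fixed 641 × 641 grid centered
between the fitted spots; out-of-volume samples contribute zero and are
tracked in a coverage grid. Maps are raw **sums** of oriented planes;
normalized views are derived at presentation time.

Orientation decisions (which side is the mother, which way is "up") are
made on **background-subtracted** intensity: the median of in-volume
samples is removed and negatives clamped before computing half-sums and
centroids. On raw intensity the constant background dominates and the
flip decisions degrade to coin tosses, which silently symmetrizes — and
destroys — planted pole-axis offsets. The vertical centroid is taken
within |x| < d/2 + 100 nm to avoid background domination far from the
particle.

Because the fixed-size grid extends ~3 µm beyond any real structure, axis
profiles support two corrections over the plain mean: coverage
normalization (divide by the number of contributing in-volume samples, so
the coverage footprint does not imprint on the profile) and a
perpendicular averaging window (default 300 nm; the vertical profile
additionally windows to the fitted mother–satellite extent + 150 nm).
Averaging metres of pure background into a profile adds noise with no
signal; windowing roughly doubles the signal-to-noise of the pole-axis
peak position. The sub-resolution shifts measured this way (10–30 nm) are
an order of magnitude below the optical resolution, which is the entire
point of averaging.

## Profile decomposition

Average axis profiles are fitted with one or two Gaussians plus a
constant offset. For single-peak x profiles, 30 interpolated pixels are
trimmed at each end before fitting (variable background accumulates
there); the trim is configurable and applies only to that case. For
distributions sitting on a bridge-wide plateau (pore-protein style), an
optional third broad component is added: center fixed at x = 0 and width
parameterized as m × (widest peak σ) with m ≥ 1.5, which prevents the
broad term from collapsing onto a peak. FWHM is reported as
2√(2 ln 2) σ ≈ 2.35 σ and the central-95% width as ≈ 1.665 × FWHM
(printed as 1.7 at two significant figures). Two components whose centers
approach within one pixel are flagged as collapsed.

The bend angle is the deviation from collinearity at the middle landmark:
180° − ∠(mother − middle, distal − middle), computed from the fitted map
peaks (mother and distal at (±d/2, 0) by construction, middle from the
query channel's x and y profile fits). Other angle conventions are
recomputable because the three landmarks are always reported. The ~7°
"natural curvature" prediction sometimes quoted for a 1 µm nucleus
depends on an unstated chord construction and is deliberately not
implemented.

## What the synthetic generator does and does not emulate

`make_scene()` renders point emitters (and uniform line sources,
integrated with ≥ 64 samples) through the anisotropic Gaussian PSF onto a
(2 × 15 × 64 × 64) voxel grid at (125, 40, 40) nm spacing, adds a
constant background (10) and additive Gaussian noise (SD 2 = 2% of the
default mother amplitude 100). Presets encode the canonical geometries:
separation 225 nm, amplitude ratio 1.9, bend 17°, line length 160 nm,
query offsets (12, 15) nm — the scales at which the method was shown to
work. Orientations are uniform in-plane with z-tilt uniform in [0°, 30°];
manual clicking is emulated by ± 1 px uniform seed jitter, which
exercises the ± 2 px fit constraints realistically.

Not emulated: SIM reconstruction artifacts (honeycomb patterns, Wiener
ringing, structured residuals), Poisson photon statistics (available
behind a flag conceptually, but reconstructed SIM data are not
photon-counting), chromatic misalignment, drift, and nuclear-envelope
geometry. A green synthetic test therefore establishes that the
*algorithms* are correct and calibrated at realistic SNR and geometry —
not that reconstruction artifacts cannot bias a real experiment.

Every synthetic quantity is a pure function of (spec, seed): the master
seed derives per-scene seeds, noise streams and click jitter, so full
pipeline runs are bit-reproducible.

## Known limitations

* The axial voxel pitch (125 nm) limits per-particle pole-axis precision
  to ~5 nm; pole-axis conclusions need ensembles (n ≳ 15), which the
  uncertainty reporting makes visible.
* The TIFF layer covers uncompressed ImageJ-style stacks only (uint8/16,
  float32/64) — sufficient for round trips with `tifffile`/ImageJ, not a
  general TIFF implementation.
* Vertical map registration shifts along y only, by design; residual x
  misregistration between maps is not corrected (the x origin is defined
  by each map's own fitted centers).
* The F-test in `classify_foci()` treats interpolated noise as white; at
  very low SNR its nominal p-value is approximate and the separation gate
  does most of the work.
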