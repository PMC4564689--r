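# spasim

Single-particle averaging for two-color 3D structured-illumination
microscopy (SIM) volumes of diffraction-limited particles.

## The problem

Structures such as the budding-yeast spindle pole body (SPB) and its
duplication intermediates (the half-bridge and the satellite) sit below or
near the ~100 nm resolution of 3D-SIM. A single two-color image of one
particle says little; averaging many particles after aligning them into a
common frame turns the ensemble into a *dual-color probability map* whose
peak positions can be localized to a few nanometres — the same idea as
single-particle analysis in cryo-EM, applied to fluorescence volumes.

`spasim` implements that post-processing chain for people who already have
reconstructed two-color SIM z-stacks (or want to validate the method on
synthetic data):

1. **Detection** — sum-project a channel, blur with a 1 px Gaussian and
   greedily accept maxima above 15% of the image maximum that are at least
   30 px apart; reject particles whose 30x30 px z-profile peaks in the
   first or last slice.
2. **Fitting** — model each particle as the sum of two 3D Gaussians over a
   constant background,

   `I(x,y,z) = B + sum_k A_k exp(-(dx^2+dy^2)/2s_xy^2 - dz^2/2s_z^2)`,

   fitted by box-constrained nonlinear least squares with lateral centers
   confined to +/-2 px of the manually picked seeds and axial centers to
   +/-2 slices of their 3x3 z-profile initialization.
3. **Alignment** — identify the mother spot (closest to a fiducial, or the
   brighter one), resample the plane through both centers by trilinear
   interpolation at 4x finer pixels so the mother-satellite axis becomes
   x (mother at -d/2) and the pole axis becomes y, orient by reference
   intensity, and **sum** the planes into a per-channel probability map.
4. **Quantification** — multi-Gaussian fits of average axis profiles
   (FWHM = 2.35 sigma; central-95% width = 1.7 x FWHM), Monte Carlo
   parameter errors from 100 residual-noise refits, 3D separations, bend
   angles, mother/satellite intensity ratios, and 75%-threshold contour
   outlines with vertical map registration.
5. **Synthetic scenes** — a ground-truthed generator (two-spot pairs, bent
   triplets, line-source bridges, single spots) emulating SIM-like volumes
   (40 nm lateral voxels, 125 nm z-step, PSF sigma_xy ~= 50 nm /
   sigma_z ~= 130 nm, additive Gaussian noise), so the whole pipeline is
   testable without microscope data.

## Worked example

```r
library(spasim)

## a reproducible synthetic dataset: 17 two-spot particles,
## 225 nm separation, 1.9 amplitude ratio, 2% noise
ds <- generate_dataset("pair", n_particles = 3, rng_seed = 42)
ds[[1]]$volume
#> <spa_volume 'pair_001'> 2 channel(s) x 15 slice(s) x 64 x 64
#>   voxel size (dz, dy, dx): 125 x 40 x 40 nm
#>   channels: ch0, ch1

fit <- fit_dual_spot(ds[[1]]$volume, ds[[1]]$seed_pair)
fit
#> <spa_dual_fit> converged
#>   mother   : A=101 center=(1164.3, 1205.5, 816.5) nm
#>   distal   : A=53 center=(1219.6, 1417.9, 869.0) nm
#>   sigma_xy = 50.1 nm, sigma_z = 127.4 nm, B = 10, s2 = 4.02
distance_3d(fit$spot_a$center, fit$spot_b$center)  # 225.7 nm
intensity_ratio(fit)                               # 1.91

## the full pipeline: fit -> align -> average -> profile -> report
report <- run_spa(run_config(
  simulate = list(preset = "pair", n_particles = 17),
  reference_channel = 1, query_channel = 0, mc_n = 100, rng_seed = 42))
report
#> <spa_run_report>
#>   particles: 17 used / 17 detected
#>   separation (map fit): 224.4 nm (sd 0.4)
#>   intensity ratio (map fit): 1.92
#>   bend angle: 1.6 deg
```

The separation printed by the map-profile fit (224.4 +/- 0.4 nm, Monte
Carlo SD) recovers the planted 225 nm; the ratio (1.92) recovers the
planted 1.9. The "bend angle" line is only meaningful for three-point
geometries (`preset = "bent_triplet"`), where the query channel holds an
emitter displaced off the mother-satellite axis.

Real data enter through `run_config(volumes = ..., seeds = ...)` with a
TIFF list and a seed CSV (`image_id, fit_channel, reference_channel,
mother_x, mother_y, distal_x, distal_y`, 0-based pixels, mother first). A
thin CLI is installed at `system.file("cli", "spasim", package="spasim")`
with `simulate`, `detect` and `run` subcommands.

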