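# echowss

Wall shear stress (WSS) — the frictional force per unit area that flowing
blood exerts on the vessel wall — shapes endothelial physiology and is
implicated in the focal distribution of atherosclerosis, yet it cannot be
measured directly. `echowss` estimates it from high-frame-rate,
contrast-enhanced B-mode ultrasound: microbubble speckle is tracked by
cross-correlation between consecutive images (ultrasound image
velocimetry, UIV / echoPIV), the vessel wall is tracked in the same
frames, and the near-wall velocity gradient gives the WSS. The package is
aimed at vascular imaging researchers who want a complete, testable
implementation of that chain together with a synthetic phantom that has an
exact analytic ground truth.

## What it computes

* **SVD clutter filtering** — the stack's Casorati matrix (pixels x
  frames) is factorised and split into tissue, blood and noise subspaces;
  the blood band is selected from the spatial similarity of adjacent
  singular vectors.
* **Ensemble-correlation PIV** — multipass interrogation (32 → 16 → 8 px
  windows) with window deformation, incoherent averaging of the
  correlation planes of the per-angle low-resolution image pairs,
   3-point Gaussian sub-pixel peak fitting and normalised-median-test
  outlier rejection; POD truncation denoises the field series.
* **Wall tracking** — tissue/blood augmentation, a narrow-band level set,
  directional peak fitting of the specular wall reflection (half-maximum
  point on the lumen side), boundary classification (upper/lower,
  primary/secondary) and Savitzky–Golay smoothing; scored by the Dice
  coefficient and the mean absolute distance between walls (MADW).
* **WSS / TAWSS / OSI** — the strain-rate tensor
  `ε̇_ij = ∂u_i/∂x_j + ∂u_j/∂x_i` is rotated into wall-oriented
  coordinates by `ε̇′_mn = a_mi a_nj ε̇_ij` with
  `a = [[cosθ, sinθ], [−sinθ, cosθ]]`; along each boundary the tangential
  velocity profile is Savitzky–Golay filtered (relative length
  `n/D = 0.4`) and differenced at the two points closest to the wall with
  a no-slip anchor, so `τ_w = μ_b ε̇′₁₂`. Cycle statistics:
  `TAWSS = (1/T)∫|τ_w|dt` and `OSI = ½(1 − |τ̄|/TAWSS)`.
* **Synthetic phantom** — a straight vessel (diameter pulsating
  2.6→2.8 mm, 200 µm three-layer wall, 15° beam-to-flow angle) with
  microbubble-like scatterers advected by an analytic Womersley /
  Poiseuille solution and rendered through a Gaussian PSF at an effective
  PRF of 4500 Hz (three angles, 1500 fps compounded) — an exact oracle for
  velocity, wall position and WSS.

## Worked example

```r
library(echowss)

# phantom + full measurement chain + scoring against the analytic truth
res <- insilico_validation(seed = 1, n_pairs = 48)
print(res$report)
#> In-silico validation report
#>   velocity waveform error : 0.302 %
#>   WSS waveform error      : 4.747 %
#>   velocity magnitude error: 1.06 +/- 1.37 %
#>   direction error         : 0.69 +/- 1.00 deg
#>   DSC = 0.985, MADW = 44.8 um
```

The report says: over one cardiac cycle, the spatially averaged velocity
waveform recovered by the pipeline deviates from the analytic ground truth
by 0.30 % of its peak; the boundary-averaged WSS waveform by 4.7 % of its
peak (the systolic transient is smoothed by the profile filter — see the
methods vignette); individual vectors are accurate to ~1 % of the peak
speed and ~0.7° in direction; and the tracked lumen overlaps the true one
with Dice coefficient 0.985, the wall sitting on average 45 µm from its
true position (~1.5 axial pixels).

Pieces can be used separately, e.g.

```r
cfg  <- insilico_config(seed = 7)
sq   <- generate_sequence(cfg, frames = 1:40)       # per-angle stacks + truth
filt <- svd_filter(sq$stacks[[1]])                  # tissue/blood split
fld  <- piv_series(lapply(sq$stacks, function(s) svd_filter(s)$blood))
D    <- diameter_waveform(sq$compound, sq$truth$wall$frames[[1]])
```

A thin command-line wrapper with `phantom`, `filter`, `piv`, `wall`,
`validate`/`all` subcommands is installed at `inst/cli/echowss`.

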