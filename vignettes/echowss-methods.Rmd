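---
title: "Measuring wall shear stress with contrast-enhanced ultrasound image velocimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring wall shear stress with contrast-enhanced ultrasound image velocimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Wall shear stress (WSS) is the frictional force per unit area that flowing
blood exerts on the endothelium, `tau_w = mu_b * (near-wall velocity
gradient)`. Its spatial pattern is believed to shape where atherosclerosis
develops, but it cannot be measured directly: it must be derived from (i) a
velocity field resolved close to the wall and (ii) an accurate wall
position, both at high frame rates. `echowss` implements that chain for
high-frame-rate, contrast-enhanced B-mode acquisitions (ultrasound image
velocimetry, UIV / echoPIV): microbubbles make blood speckle trackable, so
2-D velocity fields follow from cross-correlating consecutive images, and
the wall is tracked in the same frames.

The package also contains a synthetic phantom whose flow is analytic, so
every stage of the pipeline can be validated against an exact ground truth.

## The phantom: study conditions and what the generator emulates

A straight vessel of circular cross-section crosses a 128 x 288 px image
(1.2e-4 m/px lateral, 3.0e-5 m/px axial in the desk-scale configuration) at
a 15 degree beam-to-flow angle. The lumen diameter pulsates between 2.6 and
2.8 mm over a 0.33 s cardiac cycle (an 8% excursion typical of the rabbit
thoracic aorta); the wall is 200 um thick and split into three equal layers
(intima, media, adventitia). Blood has density 1044 kg/m^3 and viscosity
4.043e-3 Pa s. Images are formed as if three plane waves were transmitted
per frame at a PRF of 4500 Hz (compounded frame rate 1500 fps): each of the
three per-frame transmissions is rendered from the scatterer state at its
own sub-step time, giving three "low-resolution" stacks for ensemble
correlation.

The flow solver is analytic. In `poiseuille` mode the profile is the
quasi-steady parabola `u(r) = 2 v_mean(t) (1 - (r/R)^2)` with wall shear
rate `4 v_mean / R`. In `womersley` mode (the default) the mean-velocity
waveform is decomposed into >= 8 harmonics and each harmonic is given the
Bessel-function pulsatile-tube solution in a tube of quasi-static radius
`R(t)`; a radial component `v_r = (r/R) dR/dt` carries the fluid with the
moving wall. This replaces a moving-mesh CFD stage and is the reason the
phantom has an *exact* WSS oracle. The complex-argument Bessel functions
are evaluated as power series (accurate for the argument range that occurs
at arterial Womersley numbers, here alpha ~ 3).

The default waveforms are a smooth systolic pulse (mean velocity 0.05 to
~0.47 m/s with a shallow deceleration dip) and a diameter pulse delayed by
~0.07 cycle: values chosen once as representative of rabbit aortic
haemodynamics. Scatterers: microbubble-like points in the lumen at 10 per
resolution cell (the product of the PSF FWHMs, 0.25 x 0.45 mm), wall-layer
scatterers at 30 and background tissue at 3 per cell. Amplitudes follow the
mean +/- SD model (tissue +/-2.5/0.01, intima 0/1, media +/-2.5/0.01,
adventitia 0/0.01, microbubble +/-1.4/0.01); the "+/-" is drawn as a random
sign per scatterer, except the media whose contributions sum coherently so
that the wall produces the specular reflection the tracking relies on.
Rendering stamps a separable Gaussian PSF at each (continuous) scatterer
position and takes the envelope; scatterers advect at the PRF (three
sub-steps per frame) and washed-out bubbles are replenished per 5% x 5%
image sub-region. A single seed fans out into sub-streams for placement,
amplitudes and noise, so identical seeds give bit-identical data.

What the phantom does *not* emulate: RF-domain propagation and
beamforming, nonlinear bubble response, attenuation or shadowing,
out-of-plane motion, non-rigid wall mechanics, and clutter sources other
than static-plus-pulsating tissue. Passing the in-silico validation
therefore demonstrates the correctness of the algorithmic chain under
idealised speckle statistics, not robustness to everything an in-vivo
acquisition can produce.

## Clutter filtering and POD

Each per-angle stack is unfolded into a Casorati matrix (pixels x frames)
and factorised by SVD. Tissue occupies the leading, mutually similar
spatial singular vectors; blood and noise follow. The low cut is placed
where the Pearson correlation between adjacent `|U|` vectors first drops
below 0.2, with a fallback at the valley of that curve — needed because
blood vectors share the lumen footprint and plateau near 0.5 similarity,
so an absolute threshold alone can fail. The correlation curve is used
unsmoothed: a 3-point moving mean delays the crossing by one component
when the transition is abrupt. The default high cut keeps 90% of the
post-low-cut energy; the pipeline itself leaves the high cut open
(`noise_energy = 1`) because the renderer is low-noise and an energy cut
removes pair-specific speckle detail (which collapsed first-pair
velocities during development) rather than noise.

Velocity-field series are denoised by POD of the concatenated (u, v) state
vectors. `pod_filter` defaults to 95% retained energy; the pipeline uses
99% because at 95% the 48-sample series collapsed to a single mode, which
erases the Womersley phase lead of the near-wall flow and doubles the WSS
waveform error. Masked grid points stay masked; vectors rejected by
validation keep their median/POD replacement but remain flagged invalid.

## PIV

Interrogation windows start at 32 x 32 px and halve for three passes
(32 -> 16 -> 8), each pass warping the second frame of every pair by the
bilinearly interpolated predictor field. Correlation planes of the three
per-angle pairs are averaged (incoherent ensemble correlation) before peak
detection. Numerical choices that matter:

* Correlation is computed zero-padded (linear, not circular) and divided
  by the per-lag overlap count. The circular form's triangular wraparound
  weighting biases broad-speckle peaks toward zero lag — with the
  phantom's 3.5 px axial speckle this was a 30% axial underestimate. The
  overlap correction is capped at 4x and the peak search restricted to the
  quarter-window rule, since extreme lags have little support.
* Sub-pixel refinement is an independent 3-point Gaussian fit per axis,
  falling back to a parabolic fit for non-positive neighbours; border
  peaks return the integer lag flagged.
* Spurious vectors are removed by the normalised median test (3 x 3
  neighbourhood, threshold 2.0, regularisation 0.1 px) and replaced by the
  neighbour median, flagged as interpolated.
* Vectors are reported strictly valid only where the final window fits
  inside the tracked lumen: windows straddling the wall are weighted
  toward the bright moving interior and overestimate near-wall speed. The
  WSS profile deliberately keeps the full field (see below).

## Wall tracking

The compound stack is split into tissue and blood components, each
moving-averaged over 10 frames, normalised by its maximum (a numerically
empty blood component stays on the tissue scale instead) and subtracted:
lumen strongly negative, wall strongly positive. A narrow-band level set
(two-region mean-separation speed with curvature weight 0.3, band
half-width 3 px, periodic distance reinitialisation) tracks the lumen,
each frame initialised from the previous mask; convergence is judged on
the net mask change per reinitialisation cycle because the front moves in
sub-pixel steps. The first-frame mask comes from Otsu-thresholding the
mean blood image (the phantom counterpart of a manually drawn mask).

Boundaries are extracted column-wise per labelled lumen component (upper =
anterior, lower = posterior; largest component = primary vessel) — the
module targets near-horizontal vessels, where this gives ordered chains
directly. Directional peak fitting then walks each outward normal on the
time-averaged tissue image, finds the first local maximum above half the
profile maximum, and places the wall where the profile crosses the
half-maximum measured from the foot of the peak's lumen-side flank
(sub-pixel, and allowed to move back inside the mask; the search starts
from the lumen side so an overshooting mask cannot hide the peak). Points
without a qualifying peak are dropped as flagged fallbacks. Chains are
resampled to uniform arc length and smoothed with a Savitzky-Golay filter
(window 21, order 2); the final segmentation mask is rebuilt by filling
between the refined chains.

A known limitation: with a 250 um axial PSF and the specular media layer
centred 100 um outside the lumen, the half-maximum point sits ~30 um
inside the true wall (DSC 0.985, mean absolute wall distance ~45 um on the
desk-scale phantom). This bias is inherent to the half-maximum convention
at this resolution and feeds directly into the WSS level (below).

## WSS, TAWSS and OSI

At each wall point the velocity is sampled along the inward normal (step =
axial pixel spacing, depth = local radius), rotated into the wall-oriented
frame by the tangent angle, and filtered by a third-order Savitzky-Golay
filter of relative length `n / D = 0.4`. The shear rate is the finite
difference of the two closest filtered samples with zero velocity imposed
at the wall point (no-slip anchor); grid-masked samples next to the wall
are filled by a no-slip-consistent cubic fitted through the anchor; shear
values are median-filtered (width 5) along the boundary, and
`tau_w = mu_b * shear`. The full-field strain-rate tensor
(`e_ij = du_i/dx_j + du_j/dx_i`, no 1/2 factor) and its rotation
`e'_mn = a_mi a_nj e_ij` are available for map-style analyses and share
the same convention. TAWSS is the trapezoidal cycle average of `|tau|`;
`OSI = 0.5 (1 - |mean tau| / TAWSS)` is clipped to [0, 0.5] with
zero-TAWSS points defined as 0 and flagged.

Two systematic effects bound the accuracy of the WSS waveform at desk
scale. First, even fed the exact analytic field on the PIV grid, the
`n = 0.4 D` filter plus anchored two-point rule under-estimates during the
systolic rise and over-estimates during deceleration (the thin transient
Stokes layer is smoothed), a ~2.5% normalised mean error floor for the
default waveform. Second, the ~30 um inward wall bias inflates the
anchored chord. Together the pipeline reaches ~4-5% WSS waveform error on
the desk-scale run, against 0.3% for the velocity waveform.

## Validation experiment and problem sizes

`insilico_validation(seed, n_pairs = 48)` generates one cycle of the
pulsating phantom, renders 48 frame pairs spread evenly over the cycle
(advection runs continuously at the PRF; only the analysed frames are
rendered), runs the full chain and reports: the normalised mean error
(mean absolute deviation / reference maximum) of the spatially averaged
velocity and boundary-averaged WSS waveforms, point-by-point velocity
magnitude errors (percent of the global true maximum) and direction errors
(vectors above a 5%-of-peak magnitude floor), and DSC / MADW of the final
masks against the true lumen. These problem sizes — 128 x 288 px, 48 of
the ~495 frame pairs of a cycle — were chosen so a complete validation
runs in a few minutes on one CPU; the spatially averaged waveforms are
insensitive to analysing more pairs.

The diameter waveform can be recovered independently by 1-D
cross-correlation of axial wall profiles at 10 positions; for sparsely
sampled stacks the drift-free first-frame reference is preferable to the
cumulative consecutive-frame form.

## Degenerate inputs and tie-breaks

Zero-variance interrogation windows flag their correlation plane invalid
rather than erroring; a fully rejected field only warns. Lumen scatterers
crossing the wall abort advection (they indicate a bug, and are never
clamped). An all-zero stack cannot be augmented. Boundaries shorter than
the smoothing window return unfiltered, flagged. `dice` of two empty masks
is 1; `madw` of empty contours errors. OSI of an identically zero series
is 0 with a degenerate flag.
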