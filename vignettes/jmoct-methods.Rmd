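---
title: "Phase-consistent computational refocusing of Jones-matrix PS-OCT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-consistent computational refocusing of Jones-matrix PS-OCT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(jmoct)
```

## The measurement model

Jones-matrix PS-OCT acquires four complex tomograms in a single raster scan:
two multiplexed input polarization states times two detection channels. Per
voxel they form the *cumulative measured Jones matrix*

$$J_m(x, y, z) = J_{out}\, J_s(x, y, z)\, J_{in},$$

where $J_{in}$ and $J_{out}$ are fixed (unknown) system matrices and $J_s$ is
the round-trip Jones matrix of the sample down to depth $z$. The polarization
effect of a depth slab $[z_1, z_2]$ is isolated by the similarity
construction

$$J_l = J_m(z_2)\, J_m(z_1)^{-1},$$

whose eigenvalues equal those of the sample's local round-trip matrix: the
unknown system matrices conjugate away. The *local phase retardation*
$\delta$ is the absolute phase difference of the two eigenvalues of $J_l$,
wrapped into $[0, \pi]$ (retardation is defined only up to conjugate
eigenvalue ordering), and birefringence follows as

$$b = \frac{\delta}{2 k_0 Z_d}, \qquad k_0 = \frac{2\pi}{\lambda_c},$$

with $Z_d$ the slab thickness. The factor 2 accounts for the round trip:
a slab of birefringence $b$ adds one-way retardation $k_0 b Z_d$ and the
echo passes it twice. The default window is 8 depth pixels, i.e.
$8 \times 7.24 = 57.9\ \mu m$ at the default depth pitch.
`birefringence_map()` slides this window through the volume.

All depth windows are half-open in pixels, $[z, z + Z_{d,px})$, and depth
index 1 is the shallowest plane.

### Birefringence reliability

The reference reconstruction this package follows uses a maximum a
posteriori birefringence estimator whose internals live outside our scope;
here the eigenvalue estimator is direct, and the *reliability* channel is an
explicit heuristic in $[0,1]$: the eigenvector separation
$1 - |\langle v_1, v_2\rangle|$ (0 when $J_l$ is defective and the
retardation undefined, 1 for orthogonal eigenstates), multiplied by a signal
weight $S/(S + \text{noise floor})$. It plays the same pipeline role
(saturation channel of the pseudo-colour composite, masking) without claiming
to reproduce the MAP estimator's statistics.

## Computational refocusing

An en face plane at signed defocus $z_d$ (positive = deeper than the focus)
is refocused by the phase-only spatial-frequency filter

$$H^{-1}(f_x, f_y; z_d) = \exp\left[-i \pi \lambda_c z_d (f_x^2 + f_y^2)\right]$$

applied between a forward and inverse 2-D FFT (`propagate_enface()`, Eq.
sign `-1`; the simulator's forward defocus uses the exact conjugate, sign
`+1`). Frequencies are the unshifted DFT grid in cycles/$\mu m$ implied by
the lateral pitches. Because the filter has unit modulus, the padded
transform pair conserves energy exactly.

**Zero padding.** Refocusing blurs the artificially sharp edge of the finite
en face field; without padding that blur wraps to the opposite edge of the
frame (circular convolution). Each plane is therefore zero-padded by 50
pixels on all four sides before the FFT and the pad is truncated afterwards.
The pad absorbs the aliasing exactly as long as the blur extent
$\approx \lambda_c |z_d| f_{max}$ stays below the pad width. A consequence
worth knowing: pixels within one blur extent of the *frame* edge can never be
exactly refocused, because energy blurred outward across the frame boundary
was never recorded. Quantitative evaluations in the tests exclude a 16-pixel
frame margin for this reason.

### Automatic defocus estimation

Defocus is estimated in three steps.

1. **Bulk phase correction.** Acquisition phase drift multiplies each frame
   (slow-axis position) by a piston phase that destroys the lateral phase
   coherence refocusing needs. The full smart-integration-path estimator of
   the reference pipeline is out of scope; `bulk_phase_correct()` uses a
   simplified estimator: the piston increment between adjacent frames is the
   phase of their lag-1 complex autocorrelation (summed over the whole
   frame of one reference channel), cumulatively integrated along the slow
   axis. The *same* phase is removed from all four channels, so inter-channel
   phase relations are untouched. The estimator needs laterally correlated
   fields (any real, aperture-limited OCT field is; an idealized full-band
   synthetic field is not). Near the frame edges of synthetic volumes the
   estimate absorbs a small systematic truncated-chirp phase; this is a
   finite-frame artifact, not drift.
2. **Per-depth entropy minimization.** `estimate_defocus_profile()` splits
   the depth axis into blocks (default 50 pixels; smaller for shallow test
   volumes), drops blocks whose mean intensity is less than 5 dB above the
   noise floor, and for each remaining block minimizes the information
   entropy $E = -\sum p_i \ln p_i$, $p_i = I_i / \sum I$, of the refocused
   linear-intensity en face image at the block centre. (The centre plane is
   used rather than a block average so that depth-varying defocus inside a
   block cannot blur the objective.) The search is quasi-Newton (BFGS)
   from $z_d = 0$ with restarts from $\pm z_R$ when the start gradient is
   flat, followed by a golden-section polish to a 1 nm step tolerance.
   Natural logarithm; the base only rescales the objective. The entropy is
   computed on the directly normalized intensity, not a histogram.
3. **Linear fit and DOF extrapolation.** The per-block estimates are fitted
   with a straight line $z_d(z)$ by least squares, excluding estimates that
   the fit itself predicts to lie inside the depth-of-focus band
   $|z_d| < z_R$ (located iteratively: fit all, exclude, refit). Inside the
   band the quadratic phase is too weak for reliable estimation, so the line
   is extrapolated there. The DOF half-width default is the Rayleigh range
   $z_R = \pi w_0^2 / \lambda_c$ with $w_0 = \text{FWHM}/\sqrt{2 \ln 2}$.

All four channels are then refocused with the same fitted $z_d(z)$
(`refocus_volume()`), which keeps the channels phase-consistent — the
property that the polarimetric reconstruction depends on.

Entropy-based autofocus needs *structured* intensity. A hypothetical sample
whose scatterer field is i.i.d. circular Gaussian in every voxel produces
fully developed speckle whose statistics are invariant under the (unitary)
defocus filter — the entropy carries no defocus information at all. Real
samples (particle phantoms, foam, muscle) are structured, and the simulator
reflects that (see below).

## Polarimetric contrasts

`jones_to_stokes()` forms, per input state, $S_0 = |E_1|^2 + |E_2|^2$,
$S_1 = |E_1|^2 - |E_2|^2$, $S_2 = 2\,\mathrm{Re}(E_1 E_2^*)$,
$S_3 = -2\,\mathrm{Im}(E_1 E_2^*)$ from the two detection channels.

**DOPU.** `compute_dopu()` averages each Stokes component over a 3x3 en
face kernel (the en face plane matches the refocusing geometry), takes the
norm of the averaged $(S_1, S_2, S_3)$ normalized by the averaged $S_0$, and
combines the two input states by $S_0$-weighted summation. Additive detector
noise biases DOPU low; the correction subtracts the known noise contribution
from the averaged $S_0$ ($2\sigma^2$ for two detection channels) and the
noise-induced bias $(2\sigma^2 S_0 + 2\sigma^4)/N$ from each squared
kernel-mean component, clamping negatives to zero. The noise variance
$\sigma^2$ per channel is an input: the simulator records it; for measured
data it comes from a noise-floor measurement. Corrected values can
transiently exceed 1 and are clamped to $[0,1]$; the pre-clamp value is kept
for diagnostics.

**Pseudo-colour composites.** Birefringence: HSV with hue linear in $b$
over a configurable window (default $[0, 8\times10^{-3}]$, matching the
magnitude scale on which tissue birefringence is usually plotted) across
two thirds of the hue circle, saturation = reliability, value = log
intensity clipped to a dB window. DOPU: a perceptually ordered red-to-yellow
ramp (high DOPU red, low DOPU yellow), converted to HSL with the saturation
replaced by normalized log intensity, so low-intensity pixels render gray.
Both mappings are deterministic and every export records its windows in a
JSON sidecar.

## The synthetic phantom

`phantom_model()` / `simulate_jones_volume()` generate JM-OCT volumes with
exact ground truth:

* **Scatterers**: per voxel, Bernoulli(density) occupancy times a circular
  complex Gaussian amplitude. Density 1 reproduces fully developed speckle
  (intensity contrast 1); sparse densities emulate particle phantoms. The
  bundled presets use density 1 with region-wise amplitude contrast for
  tissue-like samples ("foam", "muscle") and sparse density 0.04 for the
  particle suspension ("scattering").
* **Sample polarization**: layered linear retarders. Each voxel's one-way
  layer matrix is $R(\theta)\,\mathrm{diag}(e^{+i k_0 b \Delta z/2},
  e^{-i k_0 b \Delta z / 2})\,R(-\theta)$ — eigenphase *difference*
  $k_0 b \Delta z$ one way — and the round trip closes by reciprocity,
  $J_s = P^T P$, so the accumulated round-trip retardation of a uniform
  region is $2 k_0 b z$ and $b = \delta/(2 k_0 Z_d)$ inverts it exactly.
* **System matrices**: fixed non-trivial unitaries $J_{in}$, $J_{out}$.
* **Defocus**: every en face plane of every channel is forward-filtered with
  the exact conjugate of the refocusing filter at $z_d(z) = z - z_{focus}$.
  $z_d$ is *optical* defocus; no refractive-index scaling is applied, and
  simulator and engine share the sign convention (that internal consistency
  is the testable contract). Optionally (`confocal = TRUE`) the spectrum is
  also apodized by the Gaussian round-trip beam envelope
  $\exp[-(\pi w_0 f)^2/2]$, which band-limits the field like a real
  confocal PSF and gives the fields the lateral correlation the bulk-phase
  estimator relies on.
* **Noise**: additive circular complex Gaussian noise per channel, drawn
  from a separate seed so repeated "acquisitions" share scatterers but not
  noise; the variance is recorded as the volume's noise floor. `snr_db`
  chooses the variance relative to the realized mean signal intensity.

Because the forward defocus is exactly the conjugate of the refocusing
filter, the engine's inverse is exact (up to frame-edge truncation), which
isolates estimator and artifact testing from forward-model mismatch. The
deliberate consequence: behaviours that originate in *real* model mismatch
are not reproduced. In particular, the systematic departure of per-depth
defocus estimates from the fitted line *inside* the DOF band that is seen on
measured phantom data does not arise here — with a model-matched filter the
entropy minimum stays at the true defocus at every depth, and our per-depth
estimates remain on the line inside the DOF to within fractions of a
micrometre. The DOF-band exclusion and extrapolation machinery is exercised
and tested regardless. What passing tests show about real data is therefore:
the pipeline mechanics (phase bookkeeping, inversion, estimation, masking,
statistics) are correct; they do not certify robustness to aberrations,
multiple scattering, or confocal-gating model error, none of which the
generator emulates.

### Presets

| preset | pitch ($\mu m$) | structure | $b$ values | confocal |
|---|---|---|---|---|
| `foam` | 5.86 (3 mm / 512) | extruded polygonal walls (thresholded smooth field), two axis populations | walls $2.5\times10^{-3}$, matrix $2\times10^{-4}$ | off |
| `muscle` | 3.90625 (2 mm / 512) | multi-scale anisotropic fibers along x | fibers $2\times10^{-3}$ / $1.5\times10^{-3}$, matrix $3\times10^{-4}$ | off |
| `scattering` | 2.93 (1.5 mm / 512) | uniform sparse particles | 0 | on |

Preset birefringence values are plausible defaults of order $10^{-3}$
(the scale on which tissue birefringence is reported); no calibrated
ground-truth phantom exists to pin them down. The muscle fiber field is
deliberately broadband (mixture of two anisotropic correlation scales): a
strictly periodic fiber pattern would make the mean DOPU *recover* once the
defocus blur exceeds the period — averaging over whole periods returns the
mean state — which is an artifact of periodicity, not a property of tissue.

The `scattering` preset pairs the printed particle-phantom geometry (2.93
$\mu m$ pitch) with a 7 $\mu m$ FWHM lateral resolution ($z_R \approx 85\
\mu m$) so that both the DOF band and a wide linear defocus range fit inside
the simulated depth span at practical volume sizes; an 18 $\mu m$ system
would need a 4 mm deep volume for the same study.

## Defocus-induced polarization artifacts

Defocus mixes neighbouring pixels' complex fields. Where the polarization
state varies laterally, the mixed local Jones matrix is no longer a pure
retarder: its eigenvalue phase difference inflates (apparent birefringence
up) and the kernel-averaged Stokes vector shortens (DOPU down). Two
protocol details matter and are fixed in the analysis tools:

* The evaluation depth must lie *under* birefringent structure: at the very
  surface all A-lines still share the input polarization state and no
  artifact can form. The experiments evaluate ~230 $\mu m$ deep (33 depth
  pixels), comparable to the evaluation depth used on real muscle.
* The defocus sweep (`defocus_sweep()`) applies each additional defocus to
  the computationally in-focus volume (the x-axis zero is the refocused
  state), recomputes the full contrast chain at every step — including the
  DOPU noise correction — and masks pixels below 5 dB above the noise
  floor. Means are reported per defocus value; monotonicity is asserted
  separately for each sign of defocus, treating jitter below 1% of a curve's
  dynamic range as ties (the curves saturate once the blur exceeds the
  structure scale).

The four-condition experiment (`four_condition_experiment()`) acquires the
same numerical sample twice (same scatterers, independent noise), once
physically defocused and once in focus at the evaluation depth, then
computationally refocuses the former and defocuses the latter by the same
amount. Region statistics use equal-size square regions (15x15 pixels by
default), so the grand mean (mean of region means) equals the pooled pixel
mean; the spread across region means gives the error bars, and paired
t-tests (`stats::t.test`, with explicit degenerate-case reports) compare all
condition pairs. Refocusing here uses the generator's known defocus line
rather than the entropy estimator: the experiment quantifies the artifact,
and the estimator's own accuracy is validated separately. With zero applied
defocus the design is a null experiment; across many seeds the pairwise
rejection rate is checked to be consistent with the nominal $\alpha = 0.05$
(a calibrated test still rejects ~5% of true nulls, so "no significant
differences" is asserted as a rate, not as zero rejections).

## Numerical choices and degenerate inputs

* 2x2 inversion is explicit (adjugate over determinant); pixels with
  $|\det J_m(z_1)| < 10^{-6} \times$ the plane median are masked invalid
  rather than inverted, and an all-singular plane returns an empty validity
  mask with a warning.
* Near-defective $J_l$ (eigenvalue separation below $10^{-12}$ of the
  eigenvalue scale) reports $\delta = 0$ with reliability 0.
* The entropy of an all-zero image is an error, as is a negative intensity.
* The BFGS search uses a parameter scale of 100 $\mu m$; the final
  golden-section polish runs on a $\pm 5\ \mu m$ bracket with 1 nm ($10^{-3}
  \mu m$) tolerance.
* `fit_defocus_linear()` refuses fewer than 2 usable points and instructs
  the caller to widen the volume or supply a manual line
  (`manual_defocus_profile()`).
* DOPU kernel means are computed with a summed-area table; only
  full-kernel interior pixels are valid.
* Paired t-tests with zero-variance differences return explicit degenerate
  reports ($t=0, p=1$ for identical samples) instead of erroring.
* The zero-defocus filter is short-circuited to the identity so that a
  "no-op" propagation is bit-exact.

## Problem sizes

The bundled tests and the acceptance script run, by design, on scaled-down
versions of the study geometries: en face fields of 128-256 pixels
(vs 512 in the reference measurements), depth spans of 16-128 pixels, 2-20
seeds per stochastic check. These sizes were chosen so the full validation
suite reruns from scratch in minutes on a single CPU while every behaviour
remains in the regime the larger geometry would probe (blur extents well
below the pad width, DOF band well inside the depth span, thousands of
pixels per masked mean).

## Known limitations

* The bulk-phase estimator is a simplified stand-in for the
  smart-integration-path algorithm: per-frame piston only (no per-A-line
  structure), first-order lag-1 estimation, and it inherits a small
  frame-edge systematic on finite synthetic fields.
* The reliability channel is a heuristic, not the MAP estimator's
  reliability.
* No aberrations beyond defocus, no multiple scattering, no depth-dependent
  sensitivity roll-off, no sample motion: the generator validates the
  pipeline, not its robustness to effects it does not model.
* Optic-axis orientation and diattenuation imaging are out of scope.
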