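---
title: "Phase-based computational adaptive optics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-based computational adaptive optics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Refractive-index structure inside a biological specimen distorts the
wavefront of the emitted light, so the point spread function (PSF) of a 3D
wide-field fluorescence microscope departs from its design shape: spherical
aberration (SA) stretches and skews the axial response, coma and astigmatism
deform it laterally. Hardware adaptive optics measures the wavefront and
cancels it with a deformable element. `phicao` reproduces the sensor-less
variant of that procedure entirely in software, after acquisition: it
*measures* the aberration directly from an ordinary 3D stack and then
*removes* it by deconvolution with the matching aberrated transfer function.

The key observation the method rests on: in 3D frequency space the
aberration information travels almost entirely in the **phase** of the
optical transfer function (OTF), the phase transfer function (PTF), while
the 3D amplitude (MTF) changes comparatively little. Scanning trial PTFs
over an image and scoring the result with a sharpness metric therefore
emulates what a sensor-less AO loop does with a deformable mirror.

## Wavefront and pupil model

The pupil function is a hard-edged disk in the back aperture,

$$P(u,v) = \mathbb{1}\left[u^2+v^2 < (\mathrm{NA}/\lambda)^2\right],$$

with $u,v$ spatial frequencies in cycles/nm. Aberrations enter as optical
path difference (OPD) surfaces $W(u,v)$ in nm, multiplied on as
$\exp\!\left(i \tfrac{2\pi}{\lambda} W\right)$:

* **Defocus and spherical aberration** follow the Gibson–Lanni picture:
  both are OPDs accumulated across the immersion layer. Defocus varies the
  layer thickness, $W_d(z) = z\,(\sqrt{n^2-\lambda^2 k_r^2} - n)$; SA
  mismatches its refractive index,
  $W_{sa}(\Delta n_1) = t\,[\sqrt{(n+\Delta n_1)^2-\lambda^2 k_r^2} -
  \sqrt{n^2-\lambda^2 k_r^2}]$ (piston removed). The immersion thickness
  $t$ sets the lever arm between the mismatch $\Delta n_1$ and the
  wavefront magnitude; it defaults to 150 µm, a typical oil-immersion
  working distance consistent with the correction-collar scale of such
  objectives, and is configurable (`immersion_thickness`).
* **Coma** $\alpha_u(\rho^2)\rho_u + \alpha_v(\rho^2)\rho_v$ and
  **astigmatism** $\tfrac12\alpha_g \rho_u^2$ (plus its 45°-rotated
  partner) are polynomials in pupil coordinates normalized to the pupil
  edge, with coefficients in wavelength units.
* **Zernike modes** use Wyant single-index ordering with non-normalized
  polynomials ($R_n^m(1)=1$) and coefficients in wavelength units; `z8` is
  primary spherical, `z4`/`z5` primary astigmatism, `z6`/`z7` primary coma.
* **Tilt** is a pure linear phase whose magnitude is the lateral image
  displacement in nm; the 1/2 prefactor sometimes quoted for tilt terms is
  absorbed so that a `tilt_x` of 100 nm displaces the PSF by exactly
  100 nm, which is the convention the shift calibration relies on.

PSFs are built by the 2D-inverse-transform route: for every section the
defocused pupil is inverse transformed, squared, and the stack of sections
is cropped centrally to the configured shape. OTFs are 3D Fourier
transforms of the centered PSF, stored as amplitude (MTF) and phase (PTF)
with DC at the grid center; internal transforms use corner (FFT) order.
The pupil grid must hold the pupil circle in less than half its width
(checked at configuration time) and is at least 256×256 pixels — smaller
grids alias the wrapped pupil replicas into the passband.

### Shift calibration

Every aberration mode drags a displacement along with its shape: SA moves
the focal plane, coma translates the spot. If uncompensated, the sharpness
search would partly chase that displacement. `calibrate_mode_shifts()`
generates uncompensated PSFs at ±1 initial step of a mode, interpolates the
peak position quadratically, and fits a line through the displacements;
compensating defocus/tilt terms are then folded into every generated pupil
(measurement trials, correction kernels, phantom PSFs alike). Calibrations
are cached per mode and configuration.

## Measurement: phase-only deconvolution plus a sharpness search

A trial aberration $(\psi,\alpha)$ yields a trial PTF $\phi'$. The stack
spectrum $D$ is phase-only deconvolved,

$$D' = D \,\frac{A\,e^{-i\phi'}}{A^2 + w^2},$$

inside the system's frequency support box (zero outside), where $A$ is the
unit-peak ideal MTF and $w = 0.22$. Two properties matter: the amplitude
factor does not depend on the trial, so scanning a mode changes only the
phase content; and the filter is rescaled to exactly unit DC gain, so
**total image intensity is conserved** for any trial — brightness is a
fair score across trials.

*Why this regularized form:* a literal complex denominator
$A e^{i\phi'}+w^2$ can nearly vanish wherever $A \approx w^2$ and
$\phi' \approx \pi$, so the metric grows without bound at large trial
magnitudes instead of peaking; a real denominator $A + w^2$ amplifies
signal-free frequencies by $1/w^2 \approx 20\times$, which buries the
metric under Poisson noise. The conjugate-Wiener form keeps the exact
noiseless argmax at the injected magnitude and remains on-truth down to
peak SNR ≈ 16 in our simulations.

The deconvolved image is passed through a cone bandpass before scoring.
The passband condition is scale-invariant in $|k|$:
$(4\pi/\chi)\,(|k_l|\sin\theta - |k_s|\cos\theta) \ge |k|$ with
$\theta=\asin(\mathrm{NA}/n)$ and $\chi = 1.8$; it admits the DC voxel,
excludes the missing-cone directions around the axial axis, and passes the
lateral wedge where the wide-field OTF carries signal.

The score is the penalized intensity variance

$$v = \mathrm{Var}\{x^2 : x \ge 0\} - \gamma\,\mathrm{Var}\{x^2 : x < 0\},
\qquad \gamma = 10,$$

over the voxels of the filtered image: sharpening concentrates intensity
(raising the first term), over-correction rings negative (raising the
penalty).

**Sampling plan.** Each mode is scanned at five initial magnitudes
symmetric about the running estimate (steps: $\Delta n_1 = 0.01$ for SA,
0.125 λ for coma/astigmatism, 0.5 λ for Zernike coefficients), refined by
typically two extra points bracketing the running maximum at ±step/2, then
±step/4. A polynomial is fitted through the five samples nearest the peak
and its argmax, restricted to the sampled interval, is the estimate. A
fifth-order fit through five points is underdetermined, so the effective
degree is `min(fit_order, points − 1)` (quartic interpolation); with fewer
than five usable samples the scan falls back to the discrete argmax with a
warning. Measurement cycles repeat the scan over all modes about the
accumulated estimate (order: SA, coma, astigmatism, Zernike ascending)
until the update falls below 2% of a step, and a trace whose update RMS
grows for two consecutive cycles is declared divergent, reverting to the
last good cycle. Raw stacks get a border-median background subtraction
(clipped at zero) first; a DC-dominated spectrum destabilizes the metric.

## Correction

The measured spec builds the aberrated OTF
$O'' = A'' e^{i\phi''}$ and the stack is deconvolved with

$$D'' = D\,\frac{A\,e^{-i\phi''}}{A'' + w^2}, \qquad w = 0.01,$$

inside the support box — the aberrated amplitude and phase are removed and
the ideal MTF is re-imposed. Negative output values are retained. The
correction kernel optionally carries the **B′ amplitude model**: when the
sample index differs from design, Fresnel reflection at the interface
lowers the field amplitude while wavefront compression raises it toward
the pupil periphery. B′ is implemented as the mean s/p Fresnel amplitude
transmission times the compression apodization
$\sqrt{n\cos\theta_i/(n_s\cos\theta_s)}$. The sample-side mismatch
$\Delta n_2$ it needs is not measured directly: it is chosen so that the
SA wavefront of an emitter at a fixed 5 µm depth best matches (least
squares over the pupil, piston and defocus removed) the measured
immersion-side $\Delta n_1$ wavefront, searched over ±0.1.

Deconvolution can only redistribute captured photons.
`intensity_recovery_curve()` quantifies this: a point source with SA is
sampled at a given number of Nyquist-spaced sections around its brightest
plane (all other sections zero), corrected with the true spec, and the
corrected peak is reported against the fully sampled aberration-free peak.
Alternative protocol readings were examined and rejected: deconvolving the
few-section volume on its own small axial grid is numerically degenerate
(the unit-DC normalization of a 3-slice OTF is meaningless), and using the
sparsely sampled PSF as the kernel recovers almost nothing.

## 3D structured illumination

Three-beam 3D-SIM is modeled with an excitation pupil of three Gaussian
spots (σ = 0.4 pupil pixels): a central beam and side beams at
$\pm\,b\,k_{frac}\,\mathrm{NA}/\lambda$, phase-stepped by $\pm 2\pi s/5$
over five pattern phases. The spot positions are rounded onto the image
frequency lattice so that order separation and band shifting are exact
array operations. The illumination intensity is evaluated directly on the
image grid from the sparse spot table (a few dozen coherent plane waves),
which is both faster and free of cropping artifacts; the 3D-SIM PSF is the
product of this profile with the aberrated detection PSF, sharing one
aberration spec between illumination and detection. Raw data are simulated
with the physically correct forward model — object × illumination,
convolved with the detection PSF — so the separated order spectra carry
laterally shifted object content, which is what gives SIM its resolution
gain.

Aberrations are measured from raw SIM stacks by two routes:

* **Pseudo-wide-field**: summing all phases and rotations washes out the
  pattern and the wide-field machinery applies unchanged.
* **Modulation amplitude**: after 5-phase order separation, the complex
  correlation of $D_0(k)\,O_m(k+\mu_m)$ with $D_m(k+\mu_m)\,O_0(k)$
  estimates the modulation amplitude $c_m e^{i\varphi_m}$ of order $m$;
  its squared modulus is the objective. Trial aberrations enter only
  through the phase of the order OTFs (ideal amplitudes, trial PTF), so
  the objective peaks when the trial matches the aberration that generated
  the data. The same sampling machinery as in wide-field drives the scan;
  laterally asymmetric modes use the illumination angle most perpendicular
  to their asymmetry axis. The depth estimate is relative to the
  theoretical order-OTF model and is well below 1 even for matched beam
  weights (the forward model and the product-PSF OTF differ by the
  object's axial structure); the metric uses its variation, not its
  absolute value.

A minimal generalized-Wiener recombination (`reconstruct_sim()`) shifts
every band (m = −2…2, negative bands by conjugate reflection) to its true
frequency position, weights it by its conjugate order OTF, sums over bands
and angles, divides by the summed power plus $w^2$ (default 0.02) and
applies a triangular apodization out to the extended support. It exists to
exercise the metric end to end — uniform objects reconstruct flat, bead
pairs below the wide-field limit resolve — not to compete with production
SIM reconstruction (no pattern-vector refinement, no measured OTFs, no
multi-channel handling).

## Subregional correction

Sample-induced aberrations vary across a field of view. Aberrations are
measured in user-chosen boxes; for correction every voxel is assigned to
the nearest region (Euclidean distance to the region's bounding box, voxel
units by default, ties to the lowest id), each region is corrected inside
the smallest FFT-friendly enclosing cuboid padded with surrounding stack
content, and only the voxels owned by a region are copied back — a hard
partition with no blending. The default padding of 12 voxels per side
keeps the windowed deconvolution within a couple of percent RMS of the
full-field result; deviations shrink as cubes grow because both
computations differ only through their periodic FFT windows. For SIM,
small regions cannot support a pattern-vector estimate, so each region's
spec drives a full-image reconstruction and the masks only gate where it
contributes.

## Synthetic data

All test inputs are generated in code: point sources and axial two-point
pairs (delta objects convolved with the optionally aberrated PSF, peak
normalized to 100), random bead fields, and fiber phantoms — fifty
quadratic Bézier tubes of radius 180 nm with control points uniform in the
volume, rasterized by voxel-center distance against a densely sampled
curve, axially decimated 3:1, then convolved with the theoretical PSF.
Noise follows the additive-Poisson-background convention: the stack is
peak-normalized to 100 and Poisson counts of mean $\mu=(100/\mathrm{SNR})^2$
are added, so "peak SNR" is peak over background standard deviation
($100/\sqrt{\mu}$). The signal itself is *not* shot-noise resampled by
default, matching that convention exactly; a `mode = "shot"` flag provides
the physical alternative. All generators are bit-reproducible under a
fixed seed.

What the generators do *not* emulate: real camera effects (read noise,
gain, offset), refractive-index structure that varies within the volume
(aberrations here are constant per stack or per region), pattern-vector
jitter in SIM, or sample motion. Passing tests therefore demonstrate the
estimator's correctness and noise behavior under the stated image
formation model, not performance on arbitrary real-world acquisitions.

## Numerical choices and problem sizes

* All internal math is double precision; file output is 32-bit float TIFF
  or MRC mode 2.
* Frequency grids live DC-centered for inspection and corner-ordered
  inside transforms; PSF cropping is central, never wrap-around.
* The frequency support box uses the incoherent limits
  $k_{lat} < 2\mathrm{NA}/\lambda$, $k_{ax} < n(1-\cos\theta)/\lambda$.
* The accuracy-study protocol used throughout the deeper tests is NA 1.42,
  λ 528 nm, n 1.515, 128³ voxels of 267×92×92 nm, pupil 512² — full-scale
  measurements (two-point Strehl, single-mode recovery, sectioning
  recovery) run there. Bench-scale properties (metric shape, conservation
  laws, SIM behavior) run on 32×64×64 grids with a 256² pupil, where the
  same machinery is 20–50× faster; single-mode recovery there is within a
  few percent, and the noise floor of the metric is correspondingly
  higher.
* The measurement convergence tolerance is 2% of an initial step; the
  divergence guard needs two consecutive growing update-RMS cycles.

## Known limitations

* The aberration model is scalar; vectorial high-NA effects and
  polarization are out of scope (B′ is the only amplitude correction).
* SA is parametrized by an immersion-side index mismatch at a fixed
  immersion thickness; depth-dependent SA inside the sample is only
  captured through subregional measurement.
* Image-boundary truncation violates the shift-invariant model; regions
  should be chosen away from hard object truncations.
* The SIM reconstruction is deliberately minimal (see above).
* Quantities that depend on the absolute SA-per-mismatch scaling (for
  example the sectioning-recovery percentages) inherit the uncertainty of
  the immersion-thickness default.
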