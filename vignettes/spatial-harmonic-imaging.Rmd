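---
title: "Spatial harmonic imaging: model, retrieval and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial harmonic imaging: model, retrieval and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shir)
```

## The measurement model

A two-dimensional periodic absorbing mask (inverted Hartmann mask)
placed in a divergent X-ray beam imprints a mesh intensity pattern of
projected period $d$ detector pixels on the recorded image. Because the
pattern is periodic, the 2-D discrete Fourier transform of the image
concentrates into a lattice of harmonic peaks at multiples of the
fundamental frequency $1/d$ along both axes. Writing the inverse
transform of the band-limited window around the order-$(m,n)$ peak as

$$I_{m,n}(x,y) = I_0(x,y)\, D_{m,n}(x,y)\, e^{i\psi_{m,n}(x,y)},$$

the transmitted intensity $I_0$, the modulation amplitude $D_{m,n}$ and
the phase $\psi_{m,n}$ respond to three different sample properties:

* **Absorption** attenuates $I_0$ by Beer–Lambert,
  $I_0 \mapsto I_0\, e^{-\mu d_s}$ with $\mu$ the linear attenuation
  coefficient and $d_s$ the thickness (we write the product as the
  *optical thickness* `mu_d` throughout the package, dimensionless).
* **Refraction** displaces the beamlets laterally by $\delta$ pixels,
  which by the Fourier shift theorem appears as a phase
  $\psi = 2\pi\delta/d$ in the first-order harmonic along the
  displacement direction.
* **Sub-resolution scatter** blurs the pattern and reduces its
  visibility, attenuating $D_{m,n}$ for $(m,n)\neq(0,0)$ while leaving
  the fundamental untouched.

Dividing each sample harmonic pixel-wise by the matching reference
(mask-only) harmonic removes the mask and illumination structure; the
fundamental has no modulation ($D_{0,0}=1$, $\psi_{0,0}=0$), so the
three channels separate as the familiar log-modulus / visibility-ratio /
argument formulas implemented in `absorption()`, `scattering()` and
`dpc()`. Because the mask is periodic along both axes, horizontal
$(\pm1,0)$ and vertical $(0,\pm1)$ channels exist separately and are
averaged into bidirectional maps; the diagonal orders $(\pm1,\pm1)$
carry second-order contributions retrieved with the same formulas.

## Processing pipeline and its assumptions

The pipeline is: crop to a persisted ROI → flat-field correction
$(I-D)/(B-D)$ → forward FFT → harmonic peak detection (reference only)
→ band-limited extraction of all nine orders → reference correction →
contrast formulas → optional phase unwrapping → export.

Assumptions worth making explicit:

* **Stationary mask.** Reference and sample images must see the mask in
  the same position; residual rigid drift appears as a constant phase
  offset which the reference division removes, and sub-bin drift as a
  linear phase ramp which it also removes. This is why integer-bin peak
  centers suffice (no sub-bin interpolation is attempted).
* **Harmonic separation.** The band limit is the floor of half the
  measured inter-peak spacing, i.e. the window edge sits at the midpoint
  between adjacent harmonics, and the same limit is propagated to all
  orders so every harmonic image has the same $(2b+1)^2$ size. The
  projected period must satisfy $d \ge 3$ pixels (Nyquist); both the
  simulator and the peak detector enforce this gate and refuse
  sub-Nyquist input.
* **Resolution trade.** All contrast maps live on the
  $(2b+1)\times(2b+1)$ grid of the extraction window — the method trades
  spatial resolution for simultaneous multicontrast readout.

### Peak detection

The fundamental spacing is found by a magnitude-maximum search along
each frequency axis (restricted to a ±2-bin neighborhood of the
position predicted from `expected_period_px` when the user supplies it);
the remaining peaks are then *snapped* to the magnitude maximum within
±2 bins of their predicted lattice position. This residual-displacement
compensation absorbs the small peak shifts that finite source size,
pixel sampling and mask/detector misalignment introduce in practice.
Every accepted peak must exceed `noise_rel` (default 0.005) times the
zero-frequency magnitude — the noise floor is exposed as a parameter
because no universal criterion exists. Metadata (centers, band limit,
period) is detected once per measurement on the reference and reused
verbatim for the sample image and for every CT angle, which both saves
time and guarantees that sample and reference harmonics occupy
corresponding frequency windows.

### Conventions

Spectra are stored centered (zero frequency at `floor(n/2)`, 0-based).
Harmonic labels follow a displacement-sign convention: $(+1,0)$ denotes
the harmonic whose phase *grows positive* when the pattern moves toward
+x; with the $e^{-i2\pi}$ DFT convention of `stats::fft` this is the
bin at negative column frequency. Which member of a symmetric peak pair
carries the $+$ label is pure convention; this choice makes retrieved
phase maps directly interpretable as signed displacements.

### Numerical choices and degenerate inputs

* Flat-field denominators at or below `eps` (default
  $10^{-6}\max(B)$), saturated pixels at the 16-bit ceiling, and
  reference-harmonic moduli below `guard` (default $10^{-3}$ of the
  maximum) are *masked invalid* and set to 0 rather than clipped or left
  as NaN — NaNs would poison entire spectra through the FFT.
* All accumulation is double precision regardless of storage type.
* Phase maps are principal-value in $(-\pi,\pi]$. Unwrapping defaults
  to `"none"`; a row-wise cumulative (Itoh) method and a quality-guided
  2-D region-growing method ship with the package, and further
  algorithms can be registered at run time (`register_unwrap_method()`).
  Every method must preserve values modulo $2\pi$.
* The optional Hann window in `forward_spectrum()` is for ROIs with
  strong edge discontinuities; it is off by default because the
  reference division already cancels common leakage.

## Geometry and CT preparation

With the mask in the beam, reconstruction can treat the system as an
imaginary setup with an *effective pixel size*: the detector pitch
scaled by the ratio of the sample and optic distances, oriented with the
larger distance in the numerator (for the validated optic-upstream
configuration, $p \cdot D_2/D_1$; `effective_pixel_size()` documents why
this orientation — the inverse ratio would shrink the pitch, which
contradicts the worked configuration the convention is pinned to). The
detector pitch demagnified to the sample plane, $p \cdot D_2/D_{sd}$, is
provided separately.

Divergent-beam projections are rebinned to a parallel grid with the
closed-form small-divergence remap
$t = u D_2 / \sqrt{D_{sd}^2+u^2+v^2}$ (inverted exactly, resampled
bilinearly). At realistic geometries the displacement is a small
fraction of a pixel, so the remap's mean-square effect on a
unit-normalized projection is tiny — which is precisely the argument for
treating such data as parallel-beam. The operation records provenance
and refuses to run twice. Reconstruction is classical Ram-Lak filtered
backprojection with the rotation center as the only geometric input;
quality is scored with NRMSE (range-normalized), PSNR, mean SSIM (7×7
uniform window, standard stabilizing constants on the reference range)
and NMI from a 256-bin joint histogram — definitions chosen to match the
common defaults of standard image-metric libraries, and cross-checked
against one during development.

The projection-count study decimates angles to evenly spaced subsets
that always include the first angle (the subset rule is otherwise
unconstrained) and scores each reconstruction against the full-count
one.

## The synthetic forward model

`render_frames()` emulates the acquisition: dark frames (offset plus
read noise), bright frames (unmodulated beam), reference frames (mask
pattern) and sample frames built in the physically ordered sequence
warp → attenuate → blur → detect:

1. the mask pattern is evaluated analytically at locally displaced
   coordinates (refraction as a displacement field — adequate because
   the retrieval senses exactly pattern displacement, not the wavefront
   itself);
2. multiplied by $e^{-\mu d_s}$;
3. convolved with a Gaussian of width $\sigma(x,y)$ (small-angle scatter
   as visibility loss), implemented piecewise-constant per region so the
   cost stays at one FFT per distinct $\sigma$;
4. passed through the detector model: flat-field gain (default a gentle
   parabolic vignette, so the correction has real structure to remove),
   fixed-pattern dark offset, Poisson shot noise at the configured
   photon scale, Gaussian read noise. Identical seeds give bit-identical
   frames and files.

The pillar pattern is the separable product of two square waves with
duty cycle 0.5 and a Gaussian *edge softness* of 0.5 px by default. The
softness emulates the penumbral blur of a finite focal spot (real
mask-based setups deliberately run large spots for flux) and keeps the
sampled pattern effectively band-limited, so sub-pixel displacements and
blurs behave on the grid as they would in the continuum; with hard
edges, spectral tails beyond Nyquist alias onto the harmonics and the
zero-clamp of the detector distorts small-$\sigma$ blurs. Under this
model the scattering channel obeys $S = 2\pi^2\sigma^2/d^2$ exactly at
the first order (the Gaussian transfer function evaluated at $1/d$),
which is what parameter-recovery tests compare against. Residual
deviations at $\sigma \lesssim 0.5$ px (a few percent) and the few-mrad
phase floor for *fractional* sub-pixel shifts both stem from the same
surviving alias terms and are documented in the tests.

Default study conditions: 512×512 frames with a period-8 mask — scaled
down from the multi-megapixel detector format of real setups, with the
period chosen a little above typical projected periods (4–5 px) so that
one frame still spans 64 periods; photon scale $10^4$ at bright level
with offset 100 ADU, read noise 2 ADU (conventional lab-detector
magnitudes; published setups rarely state theirs); one frame per
category by default, since single-shot operation is the method's selling
point, with repeats available for averaging studies.

`simulate_ct()` line-integrates a voxel phantom slice-wise (parallel
rays at the sample plane) at evenly spaced angles over $[0°, 180°)$,
renders frames per angle against one shared reference, and writes a
ready-to-process project; scatter widths add in variance along the ray,
so the $\sigma^2$ density is integrated and square-rooted.

### What the simulator does not model

Fresnel propagation and wave-optical edge effects, polychromatic
spectra, detector PSF and charge sharing, source-size penumbra beyond
the Gaussian edge softness, scatter kernels other than Gaussian, and
hexagonal mask lattices. Passing tests therefore demonstrate the
*processing chain* is correct under the stated forward model — they do
not validate the physics approximations against a real beamline.

## Test problem sizes

The suite runs phantom recoveries at 256² (512² for the end-to-end
acceptance checks), CT round trips at 64–96 voxels with 40–48 angles,
and the projection-count study on a 129² phantom with 180 angles —
sizes chosen so the full suite completes in well under a minute while
every check still operates in the asymptotic regime it probes (many mask
periods per frame, band limits ≥ 8 bins).

## Known limitations

* Integer-bin peak centers mean a deliberately non-compensated sub-bin
  mask drift between reference and sample leaves a linear phase ramp in
  P (removed only if common to both).
* The quality-guided unwrapper is O(n² log n)-ish with a plain-vector
  frontier; fine for harmonic-sized maps, slow for megapixel maps.
* `effective_pixel_size()` is an empirical convention, not derived
  optics; interoperability with other tools' geometry files is not
  attempted.
* The CT path assumes the harmonic-filtered projections are parallel
  (the rebinning MSE justifies this at long source distances); no FDK,
  no iterative reconstruction.
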