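# shir — spatial harmonic X-ray imaging in R

Single-shot multicontrast X-ray imaging with a two-dimensional periodic
mask (an inverted Hartmann mask: a regular array of absorbing pillars on
a transparent substrate). The mask imprints a mesh intensity pattern on
the beam; the sample then

* **attenuates** the pattern (absorption),
* **displaces** it laterally through refraction, and
* **de-modulates** it through sub-resolution small-angle scatter,

and each effect is read out from a different harmonic of the recorded
image's 2-D Fourier spectrum — all from one exposure. `shir` is aimed at
lab users of such mask-based setups who need the processing side: it
takes raw 16-bit TIFF frame stacks (dark / bright / reference / sample),
performs flat-field correction, locates the harmonic lattice
automatically, and retrieves the three contrast channels, plus the
computed-tomography preparation around them. A seeded synthetic forward
simulator stands in for the beamline so the entire pipeline runs (and is
tested) offline.

## The retrieval in brief

Each harmonic image, obtained by cutting a band-limited window around
the Fourier peak of order (m, n) and inverse-transforming, factors as

    I_{m,n}(x,y) = I_0(x,y) · D_{m,n}(x,y) · exp[i ψ_{m,n}(x,y)]

with `I_0` the transmitted intensity, `D` the modulation (visibility)
amplitude and `ψ` the phase. Dividing the sample harmonics by the
reference (mask-only) harmonics isolates the sample, giving

* absorption `A = −ln |I^S_{0,0} / I^R_{0,0}|` (= optical thickness µ·d
  for a pure absorber, by Beer–Lambert);
* scattering (dark-field)
  `S_{m,n} = −ln [ (|I^S_{m,n}|/|I^S_{0,0}|) / (|I^R_{m,n}|/|I^R_{0,0}|) ]`,
  the log visibility loss, which cancels plain absorption exactly;
* differential phase `P_{m,n} = arg [ I^S_{m,n} / I^R_{m,n} ]`,
  proportional to the lateral beamlet displacement along the (m, n)
  direction.

First-order harmonics (±1, 0) and (0, ±1) give the horizontal and
vertical channels (averaged into bidirectional maps); the diagonals
(±1, ±1) carry the second-order contributions. The projected mask
period `d` on the detector must satisfy `d ≥ 3` pixels (Nyquist).

For CT, projections are optionally rebinned from the divergent-beam to a
parallel geometry, organised per angle and per harmonic, reconstructed
with Ram-Lak filtered backprojection, and scored with NRMSE / PSNR /
MSSIM / NMI against a reference reconstruction.

## Worked example

```r
library(shir)

# Simulate a measurement: 512x512 frames, mask period 8 px, a disk
# sample with optical thickness mu*d = 0.7 -- then retrieve.
cfg  <- sim_config(shape = c(512L, 512L), photons = 1e4, seed = 1)
mask <- mask_spec(period = 8)
ph   <- phantom_disk(c(512L, 512L), mu_d = 0.7)
fr   <- render_frames(mask, ph, cfg)

dark   <- average_stack(fr$dark)
bright <- average_stack(fr$bright)
ref    <- flat_field(average_stack(fr$reference), dark, bright)
smp    <- flat_field(average_stack(fr$sample),    dark, bright)

cs <- retrieve_contrasts(ref, smp)
cs
#> <shi_contrasts> 65 x 65 maps, period 8.00 px, band_limit 32
#>   absorption mean 0.1371; bidirectional S mean 7.29e-05; P mean 0.0003985 rad

w <- nrow(cs$absorption$map)
mean(cs$absorption$map[disk_mask(c(w, w), c(0.5, 0.5), 0.2)])
#> [1] 0.7008745
```

The contrast maps are 65×65 because each harmonic is extracted through a
band-limited window of half-width 32 bins (half the inter-harmonic
spacing 512/8 = 64): the retrieval trades resolution for the three
simultaneous contrast channels. At the default photon budget the disk
interior recovers the ground truth µ·d = 0.7 to about 0.1 %, while the
scattering and phase channels stay quiet.

A thin command-line front end is installed with the package
(`inst/cli/shi`): `shi simulate`, `shi process`, `shi ct-prep`,
`shi reconstruct`, `shi metrics`.

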