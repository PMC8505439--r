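# VortexPSF

Orientation-resolved 3D single-molecule localization microscopy with a
vortex phase mask.

Inserting a spiral phase plate (topological charge 1, the same component
used for STED depletion beams) in the emission-path Fourier plane of a
standard fluorescence microscope turns each single-molecule spot into a
compact "vortex PSF" whose shape encodes, in a single 2D camera frame, the
emitter's 3D position, its dipole orientation, and how rigidly it is held.
This package is for microscopists and single-molecule biophysicists who
want to fit such data — or to explore, in simulation, what the approach can
deliver before modifying a microscope.

It implements:

* a fully vectorial dipole image-formation model with supercritical-angle
  fluorescence, Fresnel transmission through the sample stack, Zernike
  aberrations and the vortex phase;
* Poisson maximum-likelihood fitting of the eight parameters
  Θ = (x, y, z, N, b, φ, θ, g2) per ROI, with Cramér–Rao lower bounds
  (CRLB), the standard stopping rules (30 iterations, 10⁻⁶ relative
  log-likelihood tolerance) and acceptance filters (3-pixel center cut,
  normalized χ² in [0.75, 3]);
* field-dependent aberration calibration: Zernike retrieval from bead
  through-focus stacks and Nodal-Aberration-Theory maps of the 12
  coefficients across the field of view;
* a frame-to-table pipeline (photon conversion, detection, fitting,
  linking at 3× the localization uncertainty, fine drift correction from
  DNA-strand splines);
* orientation analyses along strands: wobble-cone conversion
  g2 = cos α (1 + cos α)/2, smoothing-spline strand axes, azimuth relative
  to the local strand tangent, and 6.5-nm-binned autocorrelation for
  periodicity detection;
* seeded synthetic-data generators and CRLB/MLE benchmarks.

## The model in brief

The expected photon count in pixel k of an ROI is

```
mu_k = N [ (1 - g2)/3 * Hfree + g2/3 * Hfixed(phi, theta) ]_k + b
```

where `Hfree` is the freely rotating dipole PSF, `Hfixed` the fixed-dipole
PSF at the mean orientation, and the mixture is normalized to unit mass
over the entire image plane, so `N` is the number of photons captured into
the NA (of which about 0.48 land inside the 15 × 15 fitting ROI for the
default optics: NA 1.45, λ = 597.5 nm, 65 nm pixels, water / coverslip /
oil = 1.33 / 1.523 / 1.518). Precision is quantified by the CRLB of the
Poisson likelihood; the maximum-likelihood estimator attains it to within a
few tens of percent under the reference conditions (4000 signal photons, 10
background photons per pixel).

## Worked example

Simulate one vortex-PSF spot at the reference photon budget and fit it:

```r
library(VortexPSF)

cfg <- opticalConfig()            # NA 1.45, 597.5 nm, 65 nm px, 15x15 ROI
pb  <- buildPupil(cfg)
truth <- emitterParams(x = 20, y = -30, z = 0, N = 4000, b = 10,
                       phi = 70, theta = 60, g2 = 0.75)
roi <- simulateRoi(truth, pb, seed = 7)

fit <- fitMLE(roi, pb)
round(fit$theta, 2)
#>       x       y       z       N       b     phi   theta      g2
#>    9.78  -31.77  -26.83 3898.46   10.43   67.02   61.10    0.70
round(fit$crlb, 2)
#>      x      y      z      N      b    phi  theta     g2
#>   5.90   6.50  28.37 213.14   0.40   4.79   2.86   0.07
fit$chi2          # 0.88  -> inside the [0.75, 3] acceptance window
fit$rejectedReason  # "none"
g2ToConeAngle(fit$theta[["g2"]])  # 38.6 deg wobble-cone half-angle
```

Every estimate sits within about one CRLB of the truth: ~6 nm laterally,
~28 nm axially, ~5° in azimuth, ~3° in polar angle, 0.07 in g2 — the
single-image, single-channel orientation-plus-3D readout the vortex PSF is
designed for. `processStack()` runs the same fit over whole frame stacks,
`linkLocalizations()` merges repeated detections, and `strandReport()`
summarizes orientation statistics along a DNA strand.

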