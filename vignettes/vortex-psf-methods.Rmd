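---
title: "The vortex-PSF model and estimator: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The vortex-PSF model and estimator: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The imaging model

A rotationally constrained fluorophore is modeled as an oscillating electric
dipole with mean axis (φ, θ) and a degree of orientational constraint
g2 ∈ [0, 1]. The expected photon count in pixel k is

    μ_k = N [ (1 − g2)/3 · Hfree + g2/3 · Hfixed(φ, θ) ]_k + b,

a weighted sum of the freely rotating dipole PSF and the fixed-dipole PSF at
the equilibrium orientation, plus a flat background b (photons/pixel). The
second-moment parameter g2 summarizes the orientational constraint
irrespective of its microscopic form (cone, harmonic well, ...): g2 = 0 is a
free rotor, g2 = 1 a rigid dipole.

**Normalization contract.** Hfree and Hfixed are each normalized to
integrate to 3 over the entire image plane, for every orientation and
defocus, so the bracketed mixture integrates to exactly 1 and N counts the
photons captured into the NA and spread over the whole field of view (not
just the fitted ROI). The full-plane integrals are evaluated in closed form
in the pupil (Parseval), not on a finite image grid, so the contract holds
exactly even though the supercritical-angle tails of the PSF extend over
many micrometers. A consequence worth knowing: summing a finite rendering of
the mixture never reaches 1 exactly — a 101 × 101-pixel grid at 65 nm pixels
captures about 0.96 of the mass, and the 15 × 15 fitting ROI about 0.48
(this in-ROI fraction is what links N to the photons a spot detector sees).

## The vectorial pupil

Image formation is fully vectorial. On a Cartesian pupil grid (default
64 × 64 samples across the unit disk, with a one-sample anti-aliased rim),
each point carries a 2 × 3 complex matrix coupling the dipole components
(x, y, z) into the two transverse field components on the camera:

* s/p polarization decomposition with Fresnel transmission through the
  medium / coverslip / immersion stack (defaults 1.33 / 1.523 / 1.518,
  NA 1.45, λ = 597.5 nm). The transmission is evaluated for the reversed
  wave (immersion → medium), which by reciprocity gives the collection-path
  coupling and retains the supercritical-angle enhancement at the critical
  angle instead of letting it vanish.
* supercritical-angle fluorescence (SAF): pupil radii beyond n_medium/NA
  couple to the evanescent near-field of an emitter close to the coverslip.
  There the medium-side axial wavevector is complex; its imaginary part
  produces the exponential z-decay of SAF and is part of both the defocus
  factor and the (z-dependent) normalization integrals.
* radial amplitude weighting A(ρ) = 1/(cos θ_imm · sqrt(cos θ_med)): the
  aplanatic collection apodization combined with flux-normalized interface
  transmission. The 1/sqrt(cos θ_med) factor carries the integrable
  near-singularity of the back-focal-plane intensity at the critical angle
  for a surface emitter. This radiometric convention is validated against
  the in-ROI capture fractions of the mixture (≈0.48 for both the vortex
  and the standard PSF at 15 × 15 pixels) and the Cramér–Rao precision
  levels it implies; the naive 1/sqrt(cos θ_imm) weighting concentrates the
  PSF far too strongly (capture ≈0.72) and is inconsistent with the
  precision this PSF family is known to deliver.
* phase: the vortex ramp (topological charge ±1; charge 0 gives the
  unengineered PSF), orthonormal Zernike aberrations (Noll modes 5–16,
  coefficients in mλ = 10⁻³ wavelength RMS), the emitter defocus
  exp(i k_z,med z) and the stage defocus exp(−i k_z,imm z_stage). The two
  defocus terms oppose in sign: raising the emitter into the medium and
  raising the stage shift focus in opposite directions.

Pupil-to-image propagation uses an explicit complex DFT (matrix products
with the kernel exp(i k NA u·r)), which allows arbitrary image sampling
without zero-padding. Pixel values are integrals over the pixel area,
approximated by 3× subpixel oversampling and binning; the oversampling
factor is a configuration knob. Model derivatives with respect to all eight
parameters are analytic (the x/y/z derivatives are extra DFTs of the
gradient-weighted pupil; N, b, g2 are linear; the angles differentiate the
dipole vector and the orientation-dependent normalization), and the test
suite pins them to central finite differences at relative error < 10⁻³.

## Coordinate and angle conventions

Images are (row = y, col = x); positions are nm relative to the ROI center;
z > 0 points from the coverslip into the medium. A dipole axis is antipodally
symmetric, so estimates are reported on the canonical hemisphere
θ ∈ [0°, 180°), φ ∈ [0°, 180°), applying (θ, φ) → (180° − θ, φ + 180°) as
needed after convergence.

# Estimation

Each ROI is fitted by maximizing the Poisson log-likelihood with damped
Fisher scoring (Levenberg-style multiplicative damping on the Fisher
matrix). N and b are fitted on a log scale and g2 through a logistic
transform, which enforces their ranges without active-set logic; x, y, z
and the angles are unconstrained. Iteration stops when the relative change
of successive log-likelihood values drops below 10⁻⁶, or after 30
iterations (fits hitting the cap are flagged and rejected). Because the
vortex PSF retains weak near-symmetries in orientation, fitting starts from
an orientation grid of 6 azimuths × 3 polar angles (plus the first-pass
orientation): all starts are screened by their initial likelihood — cheap,
since the field components do not depend on the dipole vector — and the two
best are refined to convergence, keeping the better final likelihood.

First-pass estimates: background from the median of the ROI border ring
(which slightly overestimates b because it includes PSF tails — harmless,
since b is refitted), lateral position from the background-subtracted
centroid (the vortex PSF's local maximum is off-center, the centroid is
not), and N from the background-corrected ROI sum divided by the in-ROI
capture fraction; orientation multi-start as above with g2 starting at 0.75.

Accepted localizations must converge, lie within 3 pixels of the ROI
center, and have a normalized chi-squared — the per-pixel mean of
(n_k − μ_k)²/μ_k over all K pixels, without a degrees-of-freedom
correction — inside [0.75, 3]. The per-pixel convention (rather than K − 8)
was chosen because the acceptance band is stated for a statistic that
concentrates at 1; with K = 225 pixels the difference between the two
conventions is ~4%, well inside the band.

Per-parameter uncertainties are the Cramér–Rao lower bounds from the
analytic Poisson Fisher matrix at the estimate. Structurally
non-identifiable parameters are reported as `Inf` rather than failing: the
azimuth of an on-axis dipole (θ = 0), and both angles of a fully free
dipole (g2 = 0), have exactly zero Fisher rows, which are dropped before
inversion.

# Field-dependent aberrations

Bead through-focus stacks are fitted jointly over all slices as freely
rotating dipoles, with position, a focus offset, one shared photon count
per slice, background, and the 12 Zernike coefficients as free parameters
(shared N keeps the parameter count at 17; per-slice intensities would add
little information for synthetic stacks with stable excitation). Aberration
derivatives are analytic phase derivatives; the normalization is
coefficient-independent because the Zernike phase is real.

The field dependence of the coefficients follows Nodal Aberration Theory:
writing the field position as h = (x + i y)/R_fov (normalized so |h| = 1 at
the FOV corner radius, for conditioning), the astigmatism pair is a complex
quadratic c0 + c1 h + c2 h², the coma pair a complex linear b0 + b1 h, and
the remaining modes real quadratics in (hx, hy). These forms produce the
characteristic zero loci: up to two astigmatism nodes (roots of the
quadratic) and one coma node. Fitting is weighted linear least squares in
the complex representation; collinear bead layouts are rejected with an
error naming the unconstrainable terms. Refitting the map to its own
noiseless evaluations reproduces it to machine precision (tested).

# Pipeline

Frames are converted from camera ADU to photons as (ADU − offset)/gain,
clamped at zero. Candidates are pixels above the frame median plus 10
photons, grouped by connected components after a radius-3 dilation — the
dilation merges the lobes of one donut-shaped spot, which the dark ring
otherwise splits into several components. With that merging, a 2-pixel
component floor no longer rejects shot noise (two isolated noise pixels
within the dilation radius would form a component), so a candidate must
contain at least 4 original super-threshold pixels. Each candidate is cut
to a 15 × 15 ROI at its local intensity centroid; when an aberration map is
supplied it is evaluated at the ROI's field position and the fit uses the
corresponding pupil (cached, rounded to 0.1 mλ).

Linking is greedy and frame-to-frame (no gap frames): two accepted
localizations in consecutive frames link when every difference in x, y, z,
φ and θ is below 3× the larger of the two uncertainties, with the azimuth
compared wrap-aware on the hemisphere; g2 and the photon count are not part
of the criterion. Linked records merge by inverse-variance weighting.

Fine drift correction consumes per-strand perpendicular residuals: per
frame bin, the per-strand mean deviations from the strand spline are
projected through the strand normals and solved for a common (dx, dy) by
weighted least squares. At least two distinctly oriented strands are
required; near-parallel strands trigger a warning because the drift
component along their common axis is unconstrained. Coarse drift correction
is consumed as an external (frame, dx, dy) table and is out of scope here.

# Strand analyses

**Wobble cone.** The uniform wobble-in-cone model gives
g2 = cos α (1 + cos α)/2 for cone half-angle α, inverted in closed form.
The anchors g2 = 0.4 ↔ α ≈ 58° and g2 = 0.86 ↔ α ≈ 25.4° pin the
convention. Note that under this mapping g2 = 0.8 corresponds to α = 30.6°,
not 29°; the mapping is kept as the single consistent convention of the
package.

**Strand axis.** Localizations are rotated onto their principal axis and a
smoothing spline of transverse against longitudinal coordinate is fitted.
The smoothing parameter p ∈ (0, 1] interpolates between the least-squares
line (p → 0) and interpolation (p → 1); the default p = 0.1. Internally the
curvature penalty is (1 − p)/p per observation on the unit-normalized
abscissa — stated explicitly so other implementations can match the
behavior, since smoothing-spline parameter conventions differ between
ecosystems. Tangents come from central finite differences on the densely
sampled curve; spline ends are unpenalized and should not be trusted within
roughly 10% of the strand length.

**Relative azimuth.** For each localization the nearest curve sample is
found (ties broken by smaller arc length) and Δφ = φ − tangent angle is
wrapped into [0°, 180°). The signed perpendicular distance feeds the
line-width FWHM (computed on records with 35° ≤ θ ≤ 145°, where the azimuth
and position estimates are well conditioned) and the fine drift correction.

**Periodicity.** Arc-length positions of an orientation subset are binned
at 6.5 nm, the bin counts mean-subtracted, and the normalized
autocorrelation computed. Peaks are local maxima whose prominence over the
adjacent valleys exceeds 2× the noise level (the MAD of the
autocorrelation around its running-median trend). A period is reported only
when at least three peaks align with an equidistant comb through the origin
(regression of peak positions on their harmonic index, residuals within
1.5 bins or 10%), and is flagged unreliable when the data span fewer than
three periods. On uniform strands the false-positive rate of this rule is
below 5% (tested over seeded replicates).

# Synthetic data and benchmark conditions

The generator reproduces the reference simulation conditions: 4000 signal
photons captured into the NA, 10 background photons per pixel, positions
uniform over ±1 pixel, orientations uniform on the sphere via φ = π u,
θ = arccos(1 − 2u), emitters at the coverslip (z = 0) unless swept, Poisson
noise only (readout noise neglected). Strand layouts draw azimuths at a
configurable offset from the local tangent with wrapped two-sided
exponential noise (whose MAD equals the requested value by construction),
g2 from a truncated normal, and optionally cluster positions periodically
for plectoneme-like fixtures.

Benchmarks run 300 instances per condition rather than the 10⁴ of a
full-scale study; at 300 the Monte-Carlo error of a mean CRLB is ~2% and of
an error standard deviation ~4%, adequate for the ±10% and ±30% bands being
checked. One master seed expands into per-instance seeds; identical inputs
and seeds give byte-identical outputs.

**Efficiency evaluation.** Estimator spread and bias are compared with the
mean CRLB on accepted fits within the polar band 20° < θ < 160°. The band
matches where the azimuth is well conditioned: the azimuth CRLB diverges
toward the poles, so the unrestricted mean of per-instance bounds is
dominated by a few near-axis draws and no finite ensemble spread can be
expected to track it. Standardized errors (error divided by the
per-instance bound) are also reported and are the more stable diagnostic.

# Known limitations

* For emitters exactly at the coverslip the likelihood has a long, curved
  ridge coupling z, N and b (defocus asymmetry is minimal and the SAF decay
  trades against intensity). The MLE consequently shows a small systematic
  photon-count bias (~2% of N, about 0.35× its CRLB in our ensembles) and
  heavy-tailed N errors for near-axis orientations. This is a property of
  the model at z = 0, not of the optimizer: the bias persists across
  starting points and tolerances.
* The axial precision of freely rotating emitters at the coverslip is
  extremely sensitive to the supercritical radial weighting; under this
  package's convention the free-dipole axial bound at z = 0 is ~85 nm,
  recovering to ~25 nm within 100 nm of defocus.
* The synthetic generator draws independent emitters with flat background
  and exact Poisson statistics; it does not emulate sCMOS read-noise maps,
  overlapping emitters, sample autofluorescence gradients, or dipole
  excitation-polarization selection. Passing benchmarks therefore
  demonstrate internal consistency of model and estimator, not robustness
  to these real-data effects; the aberration-map machinery addresses the
  dominant real-data systematic (field-dependent aberrations) explicitly.
* Localization tables are read and written as CSV only.
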