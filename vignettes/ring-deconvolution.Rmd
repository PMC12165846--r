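---
title: "Ring deconvolution: models, numerics and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ring deconvolution: models, numerics and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ringdeconv)
```

This vignette is the package's own account of the science it
implements: the imaging model, the numerical choices behind each
component, what the synthetic validation study does and does not show,
and the known limitations.

## The imaging model

A linear imaging system maps an object `g` to an image `f` through the
superposition of point spread functions,
`f(x,y) = ∬ g(u,v) h(x,y;u,v) du dv`.  Classical deconvolution assumes
space invariance (`h` depends only on `x−u`, `y−v`), reducing imaging
to one 2D convolution.  `ringdeconv` targets the much larger class of
*revolution-invariant* systems: optics symmetric about their axis, where
the PSF at field radius `r` and angle `θ` is the rotation by `θ` of the
PSF at `(r, 0)`.  Writing images in polar coordinates about the optical
center, the superposition becomes a radial integral of 1D circular
convolutions over the angle ("ring convolution"), and by the 1D
convolution theorem each ring is a product in the angular Fourier
domain.  The forward model therefore needs only one radial line of PSFs
and costs `O(N³ log N)`; the brute-force superposition, which the
package also implements as the `true_blur()` oracle, costs `O(N⁴)`.

The radial PSF line itself is generated from the five primary Seidel
aberrations.  The pupil wavefront is the classical fourth-order
polynomial

`W(ρ,φ) = w_sph ρ⁴ + w_coma H ρ³cos(φ−θ) + w_ast H²ρ²cos²(φ−θ) +
 w_fc H²ρ² + w_dist H³ρcos(φ−θ)`,

with `H = r/r_max` the normalized field height (`H = 1` at the corner
of the field of view) and all coefficients in waves.  The PSF is
`|F⁻¹{exp(i2πW)}|²` on a padded pupil grid.  Rotating the field angle is
done exactly inside the polynomial, never by resampling rendered
images.

## Numerical design choices

**Pupil sampling.** The pupil disc spans half the padded grid
(`pupil_fill = 0.5`, pad factor 2).  The PSF *intensity* spectrum is the
autocorrelation of the pupil, i.e. twice its support; at fill 0.5 the
intensity is exactly band-limited on the grid.  We measured the
alternative (disc inscribed in the grid, a ~2 px diffraction core)
to alias the intensity: rotation-equivariance errors of rendered PSFs
dropped from 5–45% to below ~1% for moderate aberrations after the
change, and the ring-vs-oracle forward error fell from several percent
to ~0.1%.  The cost is a ~5 px diffraction-limited core.  Residual
equivariance error (up to a few percent) remains for multi-wave
coefficient sets whose pupil phase gradient approaches the sampling
limit at the disc edge; the test suite checks the median and tail of
that distribution separately.

**PSF normalization.** PSFs are scaled to unit energy *at the pupil*
(a Parseval constant), not to unit sum over the cropped image.
Re-normalizing each crop makes the effective PSF depend on how much of
its pattern leaves the field of view — a function of field angle at the
FoV edge — which silently breaks revolution invariance and caps the
achievable agreement between ring convolution and the brute-force
oracle at a few percent.  With energy normalization the in-image sum is
at most 1 (edge sources lose flux physically, like vignetting) and the
forward model matches the oracle to ~0.1% relative L2 at 64×64.
`normalize = "sum"` remains available for space-invariant kernels.

**Kernel-bank canvas.** The radial PSF line is rendered at `θ = 0`,
which exits an `N×N` image for radii beyond `N/2`.  The bank is
therefore rendered on an enlarged square canvas covering the field disc
plus half an image of margin (`canvas = "field"`), so outer-radius PSFs
are represented without clipping.

**Polar grids.** Defaults: radial spacing ~1 px out to the image
half-diagonal; angular count the next FFT-friendly (5-smooth) multiple
of 4 above `2π·r_max`, so the outermost ring is not angularly
undersampled.  Both transform directions use separable Catmull–Rom
cubic interpolation (bilinear is available as an option): cubic
round-trip error is ~0.2–0.8% on band-limited images versus ~2.3% for
bilinear, and the bilinear low-pass bias does not vanish under polar
grid refinement.  Both directions are materialized as sparse matrices,
which makes the adjoints exact by construction — the inner-product test
holds to machine precision, and gates the deconvolution solver.

**Radial quadrature.** Ring `j` carries weight `r_j Δr Δφ`; the center
sample carries `Δr²Δφ/8`, the area of the central half-pixel disc per
angular step.  An optional flat-field normalization (divide by the
response to an all-ones object) is available but off by default: with
energy-normalized PSFs the flat response's edge dimming is physical and
dividing it out over-corrects.  It is still the right tool for
idealized unit-sum kernel banks (e.g. the impulse-bank identity test)
and restores exact flux preservation for flat objects.

**Banded angular spectra.** The polar transform of the PSF at radius
`r_j` has support only in rings near `r_j`.  The operator detects each
PSF's radial band (threshold far below the interpolation error floor)
and transforms/mixes only those rings, which keeps the measured runtime
scaling of `ring_convolve` near its `N³ log N` theory (log–log slope
~2.9–3.1 over N = 32…256) while the brute-force oracle scales with
slope ~4.

**Solvers.** Ring/sheet deconvolution minimizes
`‖f − A g‖² + λ·TV(g)` (anisotropic TV, default `λ = 1e-4`, images
normalized to [0, 1]).  Pure least squares (no TV, no nonnegativity) is
a convex quadratic and dispatches to conjugate gradients on the normal
equations; the regularized/projected problem uses accelerated projected
gradient descent (FISTA) with the step set by power iteration of
`2AᵀA`.  We initially used adaptive-moment (Adam-style) updates
throughout, but their pixel-diagonal preconditioning cannot address
frequency-space conditioning: on bead volumes Adam gained ~1 dB in 150
iterations where FISTA gains ~4 dB in 200.  The 5-parameter Seidel fit
and the 1-parameter blind search keep Adam, where it works well.  The
solver returns the best iterate seen (accelerated schemes are not
monotone) and stops on a relative loss change below `tol`.

**Seidel fitting.** The calibration image is modelled *jointly* as the
sum of all detected/known sources' rendered PSFs plus a constant
background; per-source amplitudes and the background are linear and
solved in closed form every iteration.  Joint modelling is essential at
multi-wave aberrations, where PSF footprints (~30 px) overlap any
realistic source spacing on a 64×64 frame and per-source crops are
hopelessly contaminated.  The coefficient gradient is computed
analytically through the pupil function (chain rule through
`|F⁻¹{e^{2πiW}}|²`), verified against finite differences to ~1e-5.
Because the problem is nonconvex with a ~50% failure rate from naive
starts, the fit first probes a coarse 3-level lattice over the
coefficient box with closed-form amplitudes (~250 cheap evaluations)
and starts the optimizer from the best cell, followed by an
aberration-free start; on uniform 0–3 wave draws this recovers
coefficients to ~1e-3 waves from a single noiseless 10-source image.

**Source positions and distortion.** `fit_seidel` renders model PSFs at
the *nominal* source positions carried by the `calibration_image`.
When positions come from peak detection, the distortion coefficient is
nearly unidentifiable — its only effect is a field-dependent
displacement, indistinguishable from the unknown true positions (coma
also displaces the peak, by `~4 w_coma H` px at this pupil scale, but
coma reshapes the PSF strongly and remains identifiable).  The
synthetic generator returns ground-truth nominal positions and the
validation study uses them; for detection-only calibration the
`freeze_distortion` flag pins distortion at 0, mirroring how such fits
behave on real single-image data.

**Optical center.** Estimated as the maximizer of the correlation
between the image and its 180°-rotated copy, computed for all centers
at once by an FFT autoconvolution.  On sparse bead images the estimate
is reliable once ~25+ sources let the self-pair peak dominate
accidental pairings; below that, supply the center explicitly.

**Blind spherical search.** Renders a trial center PSF, deconvolves,
and maximizes the total absolute image gradient.  Under a least-squares
inner solver this surrogate rewards over-deconvolution ringing; under
Richardson–Lucy (60 multiplicative updates) it is best behaved, so RL
is the default inner solver.  The landscape is plateaued below the true
coefficient, so the search probes a coarse 0.25-wave grid before
refining with finite-difference adaptive-moment steps.  Even so the
surrogate localizes the coefficient only to roughly ±0.5 waves on our
synthetic scenes — an honest limitation of sharpness maximization,
reported as measured by the validation study.

## The light-sheet analogue

In light-sheet microscopy the detection optics are space-invariant but
the illumination sheet thickens away from its waist, so the 3D PSF
varies along one axis only.  Sheet convolution integrates 2D
convolutions of object slices over that axis, at `O(N⁴ log N)` versus
`O(N⁶)` for an unconstrained spatially varying 3D blur; the package
implements it with circular convolutions in the invariant plane and
direct (clipped) summation along the sheet axis, plus the exact
adjoint and the brute-force voxel-superposition oracle.

The PSF model multiplies a space-invariant detection PSF by a Gaussian
axial envelope with Gaussian-beam spread `σ(u) = α√(1+(βu)²)`; the
product is deliberately not renormalized, so flux falls away from the
waist as it does physically.  The default detection PSF is a
scalar-diffraction defocus stack whose depth of field exceeds typical
sheet thicknesses (defocus rate 0.08 waves/voxel) — the regime in which
light-sheet optical sectioning is meaningful; with an axially sharp
detection PSF the sheet envelope would be invisible in the axial
profile and axial-resolution comparisons would be degenerate.  Any
measured 3D PSF can be supplied instead, and a measured
`axial_psf_set` can replace the parametric model entirely (convex
interpolation between the two nearest measured positions, clamped at
the ends).  `(α, β)` are fitted to a bead volume by box-constrained
quasi-Newton least squares with per-bead amplitude/background solved in
closed form, on an energy-scaled objective.

## What the validation study shows — and does not

All validation inputs are produced by the seeded synthetic-data module:
procedural test scenes (filaments, discs, point scatterers), scattered
point-source calibration frames with amplitudes in [0.5, 1], Gaussian
noise specified as `10·log10(mean signal power / noise variance)` dB
(so −20 dB means noise power 100× the mean signal power), Poisson shot
noise at a photon scale, and 3D bead volumes.  Coefficients are drawn
uniformly over 0–3 waves per coefficient (or from a jittered grid), the
range that spans near-perfect to heavily aberrated systems.

The study sizes are chosen for a single-CPU desk run: 64×64 images for
forward/inverse comparisons (the oracle dominates at `O(N⁴)`),
N = 32…256 for scaling measurements, 50 seeded calibration trials with
10 sources each, volumes up to 64×40×28 for the sheet study.

Passing these tests demonstrates internal consistency of the
implementation (theorem-level equivalences to 1e-10, exact adjoints,
oracle agreement to ~0.1%, parameter recovery to ~1e-3 waves) and the
qualitative orderings the method predicts (standard convolution
degrades with off-axis aberration while ring convolution does not;
ring deconvolution wins most in the outer field; sheet deconvolution
homogenizes axial resolution when inversion is noise-limited).  It does
*not* demonstrate performance on real detector data: procedural scenes
lack the texture statistics of natural samples, the noise models ignore
read-noise structure and hot pixels (a median-based pre-filter is
available but not simulated), the pupil model omits apodization,
vectorial/high-NA effects and chromatic dispersion, and calibration
accuracy on real beads depends on bead size and mounting, which the
point-source generator idealizes away.

Three measured limits are worth naming explicitly.  First, at −20 dB
SNR with 10 sources on a 64×64 frame, the coefficient likelihood is
noise-dominated: fits reach lower loss than the true coefficients, so
regenerated PSFs settle around 20–50% relative error rather than under
20% — an estimation-variance limit, not an optimizer failure (the
fitted PSFs are still far closer to the truth than the raw noisy data).
Second, ring and standard deconvolution of the *same* space-invariant
data agree to ~3%, not arbitrarily closely: the two operators treat the
image boundary differently (field-disc clipping versus circular wrap)
and inversion amplifies the difference.  Third, the blind sharpness
search is a coarse tool (±0.5 waves); treat its output as an
initialization, not a calibration.

## Degenerate inputs and edge behavior

Out-of-field radii error; non-finite coefficients error; all-zero
images detect no sources (empty table) and refuse center estimation;
Richardson–Lucy refuses negative input; Poisson noise refuses negative
intensities; the FWHM measurement returns `NA` with a warning when a
half-maximum crossing is not bracketed (bead at the volume edge);
the blind search clamps its coefficient to the configured interval with
a warning.  Polar samples outside the image, and Cartesian pixels
outside the sampled disc, are zero.  Ties in source detection resolve
to the brighter peak, with a warning.
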