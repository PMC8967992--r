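---
title: "Methods: simulating and quantifying NPC organization in 3D-SIM-like volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying NPC organization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters and numerical choices behind
`npcorg`. The package treats the quantitation of nuclear pore complexes
(NPCs) in small spherical nuclei as a closed loop: a generative model of the
imaging experiment with exact ground truth, and a measurement pipeline whose
accuracy is characterized against that truth.

## The generative model

A nucleus is a sphere of radius $r$ (600–1800 nm covers the biologically
relevant range, from spores to arrested cells; surface areas
$4\pi r^2 \approx 4.5\text{–}40.7\ \mu m^2$). NPCs are point emitters on the
sphere, placed uniformly at random by rejection sampling with a minimum
centre-to-centre distance of 100 nm — roughly the physical footprint of one
pore, and the only spatial correlation the null model imposes. The sampler
fails explicitly (naming the count achieved) after $10^4$ rejected attempts
for a point rather than silently relaxing the spacing; the `sim_config()`
constructor additionally rejects configurations whose spacing discs would
cover more than half the sphere, which random sequential packing cannot
reliably reach.

Each emitter is rendered as an anisotropic 3D Gaussian with FWHM 100 nm in
x–y and 300 nm in z (the scale of a structured-illumination point response),
evaluated at voxel centres on a 40 nm / 125 nm (x–y / z) grid. Throughout
the package FWHM $= 2.355 \times$ SD; the constant is pinned once and every
Gaussian fit reports widths through it. The grid is auto-sized to the sphere
diameter plus a 3×(axial FWHM) margin per side and each Gaussian is
evaluated on a ±4.5 SD window, so truncation error is well below 1% of the
emitter mass (the rendered photon sum is tested against the closed-form
Gaussian integral at 1%).

The camera model is
$$ I = g \cdot \mathrm{Poisson}(E) + \mathcal{N}(0, \sigma_r^2), $$
with expected photons $E$ (peak 100 per emitter), gain $g = 20$ and read
noise $\sigma_r = 40$ intensity units. Photon units imply shot noise, so
Poisson sampling defaults on, with a flag to disable it; the calibration
results are insensitive to the choice because read noise and spot crowding
dominate. All emitters share one peak intensity — no brightness distribution
is modelled.

The optional second channel carries the spindle pole body (SPB) landmark
pair: two brighter Gaussians 180 nm apart, placed in the top polar cap with
the pair axis tangent to the sphere and random in-plane orientation. The cap
is sized so both landmarks project at least 400 nm inside the projected
nucleus edge, which makes the downstream edge filter pass by construction
and fixes a top-down viewing geometry. The mother SPB is rendered brighter
(daughter fraction 0.7 by default, an interphase-like ratio); landmark peak
intensity defaults to 4× the NPC peak. Neither value is critical: the pair
fit estimates amplitudes jointly.

What the generator deliberately does **not** emulate: SIM reconstruction
artifacts (stripes, haloing, Wiener ringing), NPC clustering into rings,
anaphase-bridge geometries, photobleaching, or drift. Tests passing on this
substrate therefore demonstrate correctness of the measurement chain under
the stated noise model, not robustness to reconstruction artifacts or
non-random NPC arrangements in real data.

## Measurement pipeline

**Segmentation.** Nuclei are found in the maximum-intensity projection by
local mean thresholding (window ≈ 2× a typical nucleus diameter, default
5000 nm, clamped to the image; offset defaulting to 3×MAD of the
projection, robust to the sparse bright foreground), followed by
morphological closing with a disc of ~450 nm (bridging the gaps between
punctate NE signal), hole filling, connected components and an area filter
(≥ 0.5 µm²). Touching nuclei are not watershed-split; instead ROI polygon
edits can add or remove masks, mirroring a semi-automated curation workflow.

**Detection.** "Track max, not mask": repeatedly take the brightest
remaining voxel, record it, and zero an ellipsoidal spheroid of 8 px
(320 nm) lateral diameter and 5 slices (625 nm) axial extent centred on it,
until the next maximum falls below 25% of the *original* image maximum. The
stop threshold is computed once, on the cropped nucleus, before any
masking — recomputing it per iteration would never terminate cleanly.
Coordinates are voxel centres (no sub-voxel refinement), matching the
voxel-based procedure. A traced consequence of these exact rules, frozen in
the tests: two equal emitters merge into one detection only below ~2 px
separation; at 3 px the masked peak leaves an above-threshold shoulder just
outside the ellipsoid and is still counted.

**NE surface.** The convex hull of the detected 3D positions models the NE.
Because occasional detections sit off the envelope (noise, cytoplasmic
signal), up to 10% of points may be removed before the final hull if
removal increases the fraction of points on the hull surface. A point is
"on the surface" if it is a hull vertex or within 20 nm (half a pixel) of a
facet. Removing a strictly interior point never changes the facets and
always raises the fraction, so the greedy loop reduces to removing the
deepest off-surface points (ties by lowest index) up to the cap — the tests
verify equivalence with exhaustive subset search on small inputs. The hull
itself is an incremental insertion algorithm written in R (validated against
a brute-force facet-enumeration oracle and analytic sphere bounds); for
interior points the distance to the hull equals the minimum facet-plane
distance, which is what the depth ordering uses. Per-nucleus density is
count / hull surface area; the count includes points the optimizer removed
(they are detections, just not surface-model support), with a
`count_retained_only` flag for the alternative convention.

**Calibration.** Detection undercounts as spots crowd and the inscribed
hull slightly underestimates the sphere, so measured density is biased low
in a density-dependent way. `run_density_calibration()` quantifies this over
radii 1.0/1.25/1.5 µm × densities 4–7 NPCs/µm², 20 nuclei per condition
(240 simulated nuclei, a problem size chosen to keep the whole suite at
desk scale while the per-condition means are stable); the acceptance test
asserts the error stays within 30% everywhere and grows with density.

**SPA-SIM.** The SPB pair is fitted jointly as two 3D Gaussians with shared
widths and baseline on a subvolume around the seeds; failures (divergence,
centre swap relative to the seeds, collapse below half a pixel) are flagged,
never returned as numbers. Accepted nuclei (edge filter ≥ 400 nm) are
realigned so the mother→daughter axis lies along +x with the midpoint at
the frame centre (lateral bilinear interpolation; z untouched). The average
map is built from z-slab sum projections (±300 nm around the fitted pair's
z-plane) rather than full-z sums: the pair sits on top of the nucleus, and
a full-z projection of a spherical shell adds the bottom hemisphere and a
limb-brightened rim that depress the normalized centre of the profile even
for randomly placed NPCs. The mean map is averaged with its x-axis mirror
(the y direction carries no biological sign), and displayed — never
quantified — with a 25%-of-maximum threshold.

The axis profile averages a 12 px band across the pair, is lightly
boxcar-smoothed (3 samples = 120 nm; rendered photon counts are noisier
than reconstructed SIM data, and the smoothing inflates a 200 nm dip by
under 10%), extends ±300 nm (covering both SPBs at ±90 nm plus flanking
NE), and is normalized to its maximum. Exclusion is called when the profile
value *at the SPB positions* falls below 0.8 — the threshold is anchored to
what the random-NPC null yields there (~0.85–0.91 at 100 nuclei in the
acceptance runs). For excluded profiles the zone size is the FWHM of an
inverted Gaussian plus constant baseline fitted on the central window, with
a 95% CI propagated from the fit covariance of the SD (a bootstrap over
nuclei would be the heavier alternative; the asymptotic CI is what the
fitting convention supplies).

**Proximal/distal intensities.** Foci are split by 3D distance < 100 nm to
either fitted SPB centre; normalized intensities are compared with a
two-sided Wilcoxon rank-sum test (normal approximation with tie
correction). Empty groups yield flagged, missing statistics. The test's
type-I error is verified at 0.05 ± 0.03 under a constructed null.

**Nucleolar profiles.** Per nucleus, the marker profile is boxcar-smoothed
(default 5 samples; the width is not critical and is configurable),
thresholded at half its maximum, and the *midpoint of the above-threshold
run* — robust to plateaus, unlike the argmax — defines position 0. Nup
profiles are normalized by their mean over the arc outside the marker run
dilated by 2 samples (the reference region must not touch the transition),
resampled onto a common grid (spacing = the native sample spacing) with
circular wrap-around for closed traces, and averaged. The headline quantity
is the mean normalized Nup intensity at position 0. On noise-free
constructions this recovers the built-in reduction exactly; with 10%
noise, 50 scenes recover reductions of 0/0.2/0.5 within three standard
errors.

**Staging.** Septation dominates (G1/S); binucleate cells ≥ 11 µm are late
mitosis; mononucleate cells split at 9.5 and 11 µm. Binucleate cells under
11 µm have no published rule and return `"unclassified"` rather than a
guess. SPB bands are [0, 0.5), [0.5, 0.8), [0.8, ∞): only the 0.8 boundary
is stated as inclusive by the source convention; the others are half-open
for exhaustiveness.

## Numerical and interface choices

* Physical quantities are nm everywhere; voxel centres sit at
  $(i - 0.5)\cdot$pitch with the volume corner at the origin, and all
  conversions go through two helpers.
* Volumes are stored (y, x, z); TIFF output is 32-bit with an affine
  offset/scale and the voxel calibration recorded in a JSON sidecar, since
  baseline TIFF writing cannot carry arbitrary tags. CSV outputs carry
  `#`-commented headers with the JSON-encoded run configuration and its
  hash.
* Every stochastic entry point takes a seed; condition grids derive
  per-image seeds from a master seed, so identical seeds give bit-identical
  outputs (tested).
* 1D Gaussian fits use Levenberg–Marquardt with non-negativity bounds on
  amplitude and SD. A start centre sitting exactly on a symmetric grid
  point can produce a singular initial Jacobian; the fitter retries with
  the start nudged a third of a sample off-centre. Non-convergence is a
  flagged state, excluded from averages, never an NA silently propagated.

## Known limitations

* The hull is convex by construction; invaginated or flattened NE shapes
  would be over-smoothed and their surface area underestimated.
* Detection reports voxel centres; quantization (±20 nm laterally, ±62 nm
  axially) is visible in the hull's on-surface tolerance and in co-detection
  at very small radii.
* The SPA averages are 2D slab projections; a full 3D average is available
  behind `average_maps()`'s input flexibility but the profile machinery is
  2D.
* The simulation null carries discrete-punctum noise: with 100 nuclei the
  axis profile fluctuates by several percent per sample, which is exactly
  why the exclusion call is anchored at 0.8 rather than 1.
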