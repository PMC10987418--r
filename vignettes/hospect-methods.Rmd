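---
title: "Scatter correction and dosimetry for Ho-166 SPECT: models and methods"
author: "hospect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scatter correction and dosimetry for Ho-166 SPECT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hospect)
```

# The problem

Holmium-166 microspheres are used in transarterial radioembolization of
liver tumours. Unlike pure gamma emitters, ¹⁶⁶Ho (half-life 26.8 h) pairs a
low-abundance 80.6 keV imaging photon with a high-energy 1379 keV photon and
an intense beta continuum. On a gamma camera this produces an unusually
complex spectrum in the 60–130 keV range: roughly half of the counts in the
main 80.6 keV acquisition window are *not* primary photopeak events but
high-energy gamma rays that scattered down in energy (or punched through the
collimator septa), plus a small bremsstrahlung tail. Because post-treatment
dose maps are computed from reconstructed SPECT activity, the choice of
scatter correction propagates directly into patient dosimetry.

`hospect` implements the full phantom arm of such a study as a reusable,
testable pipeline:

1. a digital Jaszczak-style sphere phantom (`buildJaszczak()`),
2. a parametric multi-energy-window acquisition simulator
   (`forwardProject()`, `synthesizeAcquisition()`),
3. dual- and triple-energy-window scatter correction (`dewCorrect()`,
   `tewCorrect()`),
4. OSEM reconstruction with attenuation correction (`osemReconstruct()`),
5. contrast-recovery and contrast-to-noise scoring with sigmoid curve fits
   (`crc()`, `cnr()`, `fitSigmoid()`), and
6. local-dose-deposition compartment dosimetry with paired statistics
   (`lddDoseMap()`, `compartmentStats()`, `pairedTTest()`).

# The phantom

The digital phantom reproduces a Jaszczak Pro-NM cylinder: inner diameter
206 mm, inner height 186 mm, 7 mm PMMA wall, with six fillable spheres of
inner diameter 9.9–31.3 mm (2 mm walls) on a ring in one transverse plane.
Defaults put 29 MBq in the 31.5 ml of sphere volume and 312 MBq in the
6200 ml background, an 18:1 concentration ratio and 341 MBq total.

Voxelization is by voxel-centre membership: simple, unambiguous, and
convergent — at 1 mm voxels the voxelized volume of the larger regions
agrees with the closed-form volume within 2 % (the 9.9–12.4 mm spheres need
finer grids because of their surface-to-volume ratio; the test suite asserts
the 2 % bound on a refined sub-phantom containing the 19.8 and 31.3 mm
spheres). Activity arrays store concentration (MBq/ml); totals are always
derived. The axial position of the sphere plane is not constrained by the
phantom's published dimensions; we centre it at mid-height. Sphere ring
radius defaults to 60 mm, which keeps all six spheres inside the cylinder
with clearance.

Attenuation maps assign water to the fillable compartments, PMMA
(1.19 g/ml) to the walls and zero to air, interpolating embedded standard
mass-attenuation tables log-log over 50–150 keV (water at the 80.6 keV
photopeak: 0.183 cm⁻¹).

# The acquisition simulator

The simulator is *parametric*, not a photon-transport code. The published
Monte-Carlo spectrum decomposition quantifies four components per
acquisition window (photopeak + its associated scatter, high-energy
scattered gammas, X-ray peak, bremsstrahlung), and all downstream analyses
depend only on window-integrated quantities, so the component fractions are
configuration — `spectrumComponentModel()` — with the published
decomposition as default (W2: 48.3 % photopeak(+scatter), 48.7 %
high-energy scatter, 3 % bremsstrahlung; W4: 96.9 % high-energy scatter).
Published rows carry rounding, so each row is renormalized to sum to 1.

The projector is an attenuated parallel-beam line integral with a
distance-dependent Gaussian PSF, FWHM(d) = 4 mm + 0.55 mm/cm · d by
default — a plausible medium-energy-collimator resolution model, chosen once
and configurable because the published resolution curves cannot be read as
numeric ground truth. Acquisition defaults follow the clinical protocol: 120
projections, 30 s each, 360°, 128×128 matrix, 300 mm orbit radius.

Spatially, each component is the primary projection convolved with a
component-specific kernel:

* photopeak + associated scatter: 60 % unscattered (identity) + 40 % blurred
  with 2× the system FWHM;
* high-energy downscatter: blurred with 10× the system FWHM — these photons
  cross collimator septa almost freely, so their contamination is nearly
  structureless;
* X-ray peak and bremsstrahlung: broad Gaussians (6× and 8×).

Blur kernels are renormalized per projection so detector-edge truncation
does not destroy counts — component totals are model inputs. Per-window
total rates relative to W2 are not pinned down by the published
decomposition; defaults (W1 0.30, W3 0.25, W4 0.25) were chosen once as
realistic for 6/12/6/12 keV windows on this spectrum and are not revisited.
With these rates the side-window (TEW) scatter estimate slightly exceeds the
true injected W2 scatter, while the W4 (DEW, k = 1) estimate recovers only
about half of it, reproducing the study's qualitative finding that DEW
behaves like no correction while TEW approaches the scatter-free reference.

Counting noise is independent Poisson per pixel *per component*, so realized
component tallies sum exactly to the total simulated counts, and the
tallies provide exact ground truth for scatter-estimation accuracy tests.
Decay (26.8 h half-life) is applied per projection on a contiguous schedule;
the rotation convention (counter-clockwise, projection 1 at 0°) is recorded
in every sidecar. All randomness flows through one integer seed; draws occur
window by window (W1..W4), component by component, pixels in array order.
The camera stores W1+W3 as a single image on hardware limited to three
concurrent windows; `combineSideWindows()` reproduces that summation, and
sum-then-store is assumed equivalent to store-then-sum (Poisson counts are
additive).

What the simulator does **not** emulate: energy-resolution blurring of
individual photons, collimator hole patterns, septal-penetration
microphysics, dead time (total activity stays below 400 MBq by
construction), and patient anatomy. Passing the ordering tests therefore
shows that the *pipeline* behaves like the study's phantom arm under a
faithful spectral model — not that the simulator predicts any specific
camera's absolute counts.

# Scatter correction

Both corrections act in projection space, before reconstruction, as in the
clinical protocol:

* **DEW**: `out = W2 − k·W4`, k = 1 by default (the established value for
  ¹⁶⁶Ho); k is kept configurable for sensitivity analyses.
* **TEW**: trapezoidal estimate
  `scatter = pLow·wMain/(2·wLow) + pHigh·wMain/(2·wHigh)`. With the
  protocol's 6/12/6 keV widths the factors are exactly 1 and the estimate
  reduces bit-exactly to direct subtraction of the summed side windows —
  the arithmetic is written in that factored form so the equivalence is
  exact in floating point, not just analytically.

Negative pixels after subtraction are clamped to zero by default (OSEM
requires non-negative data; the vendor's handling is unpublished); a
no-clamp mode is kept for analysis.

# Reconstruction

OSEM with the protocol's 10 iterations × 8 subsets. The projector pair is
rotation-based: the in-plane rotation is a sparse linear operator built in
the *splatting* (transpose-interpolation) form, so voxel mass is conserved
exactly, and the backprojector is the literal matrix transpose — adjointness
holds to machine precision, which the tests assert at 1e-6. Attenuation is a
fixed diagonal factor accumulated along the rays of the rotated mu map
(half-voxel self-attenuation convention); the optional PSF is a per-depth
symmetric Gaussian convolution and therefore self-adjoint. Subsets take
every 8th angle (each spans the orbit) and are visited in
maximal-angular-spacing order; initialization is a uniform positive cylinder
filling the field of view; `epsilon = 1e-12` stabilizes the update ratio.
With one subset the algorithm is plain MLEM.

The Butterworth post-filter (cutoff 0.25 cycles/pixel, order 1.5, gain
`1/sqrt(1+(f/fc)^(2n))` on radial frequency) is applied for visualization
only; CRC, CNR and dose are computed on unfiltered volumes by default, with
a configuration switch (`butterworth$applyBeforeMetrics`) for sensitivity
studies, since the original protocol does not state which volumes the
metrics used.

No claim of equivalence with any vendor's OSEM is made — only
protocol-parameter equivalence (10 it / 8 subsets, Butterworth 0.25/1.5).

# Image-quality metrics

Sphere VOIs are the labelled sphere voxels eroded by one voxel by default
(avoiding partial-volume border voxels); the background VOI is a 25 mm
radius cylinder about the phantom axis in the sphere-centre plane, 40 mm
high by default (the protocol fixes only the radius; the height is
configurable and logged). CRC follows the double-ratio definition
(measured/true sphere concentration over measured/true background
concentration), CNR uses the sample (n−1) standard deviation of the
background VOI — the population/sample choice is not specified in the
source; both are asserted scale-invariant. CRC curves are plotted against
sphere diameter / FWHM with the FWHM taken from the PSF model at the orbit
radius (30 cm), i.e. the acquisition distance. The sigmoid
`S(x) = 1/(1+exp(−b(x−c))) − d` is fitted by bounded Levenberg–Marquardt
least squares (b > 0, c > 0, d ∈ [0,1], start (1, 2, 0)) with the plateau
fixed at a = 1, because contrast recovery tends to 1 for large spheres.

# Dosimetry and statistics

The local-dose-deposition model assigns each voxel a share of the total
deposited energy proportional to its reconstructed counts:
`dose = A·κ·(counts/total)·1000/mass`. Only the *relative* count
distribution matters, so camera calibration cancels — the same relative
normalization to administered activity implied by compartmental dosimetry
tools. The energy coefficient κ defaults to 15.87 J/GBq (the standard
locally deposited energy per administered GBq of ¹⁶⁶Ho, fully decayed); it
is configuration, documented here, since the source never prints it. Tissue
density defaults to 1.0 g/ml (phantom water) with 1.06 g/ml as the liver
option. DVH criteria follow the clinical endpoints: tumour fraction
≥ 150 Gy and non-tumoral-liver fraction in [0, 50) Gy — the interval is
taken half-open, the source stating "between 0 and 50 Gy" without an
endpoint convention. Fractions are mass-weighted (equal-mass voxels reduce
to voxel counting). Activity planning is linear in the target dose with the
lung limits (30 Gy single, 50 Gy cumulative) flagged, never silently capped.

The paired t-test is implemented from its closed form
(`t = mean(d)/(sd(d)/√n)`, df = n−1, two-sided p) because it is part of the
analysis contract; the test suite cross-checks it against both numerical
integration of the t density and `t.test()`. The degenerate all-differences-
zero case is defined as t = 0, p = 1.

Patient data are unavailable by design, so the published patient-level dose
tables are not reproducible at the desk. In their place the pipeline
asserts a *consistency* property: over ≥ 10 simulated replicates of the
phantom study, the paired DEW-vs-TEW mean tumour-dose difference is nonzero
with a consistent sign across seeds.

# Numerical and testing choices

* Problem sizes in the test suite are scaled to the structure they probe:
  window arithmetic and dosimetry run on toy arrays; projector and OSEM
  properties on a 64³ grid at 4 mm with 64 projections (8 subsets must
  divide the projection count, so 64 rather than 60 angles are used at this
  scale); the figure-level ordering study on 64³ with 48 projections; the
  replicate dosimetry study on 40³ at 6.5 mm with the four largest spheres,
  which remain resolvable at that voxel size.
* Configuration files are YAML; volumes are NIfTI with JSON sidecars;
  tables are CSV. Every artifact records its seed, parameters and an MD5
  hash of upstream inputs.
* The spectrum model draws with `rmultinom`; a fixed seed makes the whole
  simulation bit-reproducible, and the RNG state of the caller is always
  restored.

# Known limitations

* The projector is parallel-beam with an isotropic in-plane grid; detector
  and volume grids must match (no fan/cone geometries, no sub-pixel
  detector offsets).
* The spectrum model is window-integrated: it cannot express spatial
  variation of the scatter fractions across the object, which the study
  itself names as the fundamental limitation of window-based corrections.
* Voxel-centre membership biases small-structure volumes at coarse grids;
  use ≤ 1 mm voxels (or analytic volumes, which the region table always
  carries) when sub-percent volume accuracy matters.
* The dose model deposits all energy locally; no dose-point-kernel
  convolution, registration, or partial-volume recovery is provided.
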