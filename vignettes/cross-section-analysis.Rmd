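---
title: "Cross-section analysis of scattering from disoriented fibrils"
author: "fibrilSAXS authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-section analysis of scattering from disoriented fibrils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilSAXS)
```

## The problem

Amyloid fibrils and similar cross-β assemblies are, at small-angle
resolution, very long rods of roughly uniform cross-section. When such
fibrils are disoriented — tumbling in solution, or frozen at random
orientations inside a fixed-tissue matrix — the measured small-angle
scattering is an isotropic average, and the conventional solution-SAXS
toolkit fits it poorly: the pair distribution function of a rod of
indeterminate length has no well-defined maximum dimension, and everything
about the estimate becomes hostage to the smallest measurable angle.

The way out, implemented here, uses two facts about fibrils with a short
axial repeat. First, when the repeat is below roughly 30 Å (4.7 Å for the
cross-β stack), the whole small-angle region of the fiber diffraction
pattern is equatorial: the first layer plane sits at $q = 2\pi/4.7 \approx
1.34\ \mathrm{Å^{-1}}$, far outside the SAXS regime, so the isotropic
intensity can be converted back to equatorial intensity $I_e(q)$ by a
geometric disorientation correction that is, away from the smallest angles,
proportional to $q$. Second, equatorial intensity depends only on the
*cross-section* of the fibril: it supports a cross-section pair distribution
function $P_c(r)$ — a histogram of interatomic distances projected onto the
plane perpendicular to the fibril axis — and a cross-section correlation
function $a_c(r) = P_c(r)/r$, both independent of fibril length. For a
compact cross-section of uniform density, $a_c$ falls to zero at the
diameter.

The correlation function, rather than the PDF, is the working quantity
because the extra factor of $q$ in its transform suppresses exactly the
low-$q$ errors that dominate data from fibrils in a matrix.

## Transform conventions

With $q = 4\pi\sin(\theta)/\lambda$ (so a Bragg spacing $d$ appears at
$q = 2\pi/d$), the package uses the transform pair

$$P_s(r) = \frac{r^2}{2\pi^2}\int q^2 I(q)\,\frac{\sin qr}{qr}\,dq,
\qquad I(q) = 4\pi\int P_s(r)\,\frac{\sin qr}{qr}\,dr$$

in spherical geometry and

$$P_c(r) = \frac{r}{2\pi}\int q\,I_e(q)\,J_0(qr)\,dq,
\qquad I_e(q) = 2\pi\int P_c(r)\,J_0(qr)\,dr$$

in cross-section geometry, with $a_s = P_s/r^2$ and $a_c = P_c/r$.
Normalization conventions for these transforms differ between texts by
constants; ours are pinned down not against printed curves but against
independent oracles — Monte-Carlo histograms of (projected) pair distances
in the model bodies — which the test suite runs routinely. Integrals are
evaluated by the trapezoid rule on the measured grid with no extrapolation
to $q = 0$; insensitivity to missing low-$q$ data is a design goal, not an
accident.

## Forward models

`cylinderAmplitude()` implements the Fourier transform of a solid cylinder
of radius $R$ and length $h$,
$F(q_x, Z) = V\,[2 J_1(q_x R)/(q_x R)]\,\mathrm{sinc}(Z h/2)$, whose
equatorial slice is the Airy circular-aperture pattern.
`isotropicCylinderIntensity()` averages $|F|^2$ over orientations by
Gauss–Legendre quadrature in $\cos\phi$ (default order 256; the integrand is
smooth, the result deterministic, and doubling the order moves nothing at
the 0.1% level). `debyeIntensity()` evaluates the Debye formula over an
`AtomSet` with $q$-independent form factors — adequate at SAXS resolution,
where shape dominates — switching to a 0.1 Å distance histogram (compiled
code) above 5000 atoms. `stackedModelFromLayer()` builds cross-β stacks and
reports length as *layers × spacing*, the axial-repeat bookkeeping under
which 30 layers at 4.7 Å are a 141 Å fibril; note this counts repeats, not
the 29-interval coordinate span.

## The indirect transform and its defaults

`iftFit()` expands $P(r)$ in cubic B-splines on $[0, d_{\max}]$ (default 30
basis functions) and solves a weighted, second-difference-penalized linear
least-squares problem against the measured intensity through the
geometry-appropriate kernel. Choices that matter:

* **Boundary conditions.** $P(0) = P(d_{\max}) = 0$ is enforced by omitting
  the boundary splines. This is not cosmetic: the penalty's null space
  contains linear $P(r)$ — a constant $a_c$ — which band-limited data cannot
  reject, and without the end constraint the recovered diameter is biased
  upward by ~10 Å even on exact input.
* **$d_{\max}$.** Default is the lower-bound convention $2\pi/q_{\min}$,
  appropriate when correlations longer than the measurable window may exist
  (fibrils in a matrix). For a particle of known bounded cross-section a
  tighter, explicit $d_{\max}$ resolves better: the worked analyses use
  200 Å for single fibrils and 600 Å for the gel packing.
* **Weighting.** $1/\sigma^2$ when the profile carries measured
  uncertainties. A flat $\sigma$ (or one that is flat up to the $q$ factor
  of the equatorial correction) carries no information; then the fit assumes
  counting-like variance proportional to intensity, which stops the
  decades-spanning low-$q$ region from dominating.
* **Smoothness weight.** When not given, the weight is chosen
  deterministically from 10 log-spaced candidates as the *smoothest solution
  whose weighted residual stays within 5% of the best achievable* (with an
  absolute floor of $10^{-4}$ of the data norm, i.e. 1% rms, below which
  residual differences are treated as meaningless). We tried the classical
  L-curve maximum-curvature corner first; with noiseless model data the
  residual is dominated by an irreducible floor — the small-$q$ error of the
  proportional-$q$ correction — the L-curve has no corner, and the corner
  estimate drifts to the over-smoothed end. The plateau rule is stable for
  both noiseless and Poisson-noised inputs.
* **Normalization anchor.** $a(0)$ is obtained by extrapolating through the
  three smallest $r$ points at or above the band-limit resolution
  $\pi/q_{\max}$; grid points below the resolution contain only ringing.

`crossSectionAnalysis()` chains the correction, the fit, the conversion to
$a_c$ and the zero-crossing search. On intensity simulated for cylinders to
$q = 0.3\ \mathrm{Å^{-1}}$ it returns crossings of 67.5 Å ($R = 35$ Å) and
54.9 Å ($R = 28$ Å) — inside the ±3 Å band that the band-limited transform
allows around the true diameters, with the small deficit coming from the
proportional-$q$ approximation near $q_{\min}$ (the same approximation that
makes the 300 Å and 1000 Å cylinders differ slightly).

## Scan-grid processing

A scanning-microdiffraction experiment yields one azimuthally averaged
profile per raster cell; `ScanGrid` stores them as a
`SummarizedExperiment` (rows = $q$ points, columns = cells). A raster
specified by extent counts cells inclusively per axis: a 300 × 400 µm²
region at 5 µm steps is a 61 × 81 = 4941-pattern grid.

`crossbetaHeatmap()` integrates, per cell, the intensity above a *local
linear baseline* in a ±0.03 Å⁻¹ window around $q = 1.337\ \mathrm{Å^{-1}}$.
The baseline anchor at the window edges makes the map exactly invariant to
any $q$-linear diffuse background, so only the sharp cross-β excess — the
fibril signature — drives lesion detection. `selectBackgroundCells()` picks
the `n = 5` lowest-map cells in a 3–10-step annulus around a candidate
lesion (ties broken by distance, then row-major index: deterministic), and
`subtractBackground()` removes non-fibrillar scattering by the two-reference
formula $I = (I_l - I_b) - a\,(I_t - I_b)$, with the substrate term $I_b$
unscaled and $a$ given in closed form by least squares over
$1.6 < q < 2.0\ \mathrm{Å^{-1}}$, where fibrillar scattering is weak. On
noiseless input the recovery of $a$ is exact to machine precision; the
annulus radii and the unweighted fit are package conventions.

## What the generators emulate — and what they do not

The `synthgen` functions produce every fixture the tests use, at the study
conditions rather than convenient ones:

* `genProfile()` draws Poisson counts at a given exposure (Gaussian limit
  above $10^7$ mean counts), seeded and bit-reproducible, never touching the
  caller's RNG state.
* `genTissueProfile()` is a smooth diffuse curve — a low-$q$ power-law term
  plus a broad disordered-matter band near 1.4 Å⁻¹ — deliberately
  featureless (below 1% against a local smooth fit) across the 1.6–2.0 Å⁻¹
  background window. It is a fixture convention, not a tissue model.
* `genScan()` composes substrate (smooth curve plus sharp mica-like
  spikes), tissue scaled by a smooth density field, and — inside planted
  plaque disks — a fibril curve (solid cylinder, $R = 35$ Å) plus a Gaussian
  cross-β peak at 1.337 Å⁻¹ ($\sigma_q = 0.01\ \mathrm{Å^{-1}}$; the width
  is a convention, the reflection being described only as sharp). Lesion
  tissue is 1.3× denser than its surroundings, which is what the
  subtraction's $a$ should recover.
* `genPacking2D()` models the concentrated-gel cross-section: sequential
  random insertion with a hard core, then a deterministic soft-repulsion
  relaxation (pairs closer than a repulsion range push apart; 150 sweeps)
  with the range bisected until the mean nearest-neighbor distance is
  within 2% of the 275 Å target. The relaxation is essential, not
  decorative: insertion alone leaves a broad, upward-skewed first
  coordination shell, and the interparticle peak of $a_c$ — which reflects
  the whole first shell, smeared by the 180 Å particle autocorrelation —
  lands some 45 Å above the nearest-neighbor mean. Mutually repelling
  particles, the physical situation in the gel, sharpen the shell so that
  the peak tracks the spacing (278–286 Å across seeds here, against a
  hexagonal-lattice control at 270 Å).
* `interferenceEquatorialIntensity()` uses the oriented-parallel-rod
  approximation $I_e = |F_{eq}|^2 S(q)$ with
  $S(q) = 1 + (2/N)\sum_{j<k} J_0(q\,d_{jk})$ — a 2D cross-section problem
  with no orientational averaging of $S$, matching the highly oriented gel.

What passing tests on these fixtures do **not** show: real tissue has
unknown diffuse scattering, fibril–matrix cross-terms that no subtraction
removes (they are, in fact, part of what the cross-section correlation of
an embedded fibril *measures*), partial orientation, and detector artifacts
beyond static masks. The synthetic scans validate the machinery, not the
biology.

## Numerical choices and degenerate inputs

Removable singularities ($\mathrm{sinc}$, $2J_1(x)/x$, the $i = j$ Debye
terms, $q \to 0$) are evaluated by their limits. Zero intensity transforms
to zero; an all-masked detector image, an empty merge overlap, a fit window
with fewer than $2 n_{\mathrm{basis}}$ points, a tissue reference equal to
the substrate in the fit window, and an annulus with fewer than `n` cells
are all errors with named causes rather than silent NaNs. Ill-conditioned
IFT normal equations are reported with the condition number. The zero-
crossing search interpolates linearly and, for correlations that decay
without crossing, falls back to the largest radius below 2% of $a(0)$.

## Problem sizes

The test suite and the acceptance script run simulations at the sizes the
analyses need, chosen once: 300-point profiles to $q = 0.3\ \mathrm{Å^{-1}}$
for cylinder pipelines, a ≥10⁴-point volume-weighted lattice for the Debye
cross-check, 2000-point Monte-Carlo disks (≈2 × 10⁶ pairs) for the
projected-distance oracle, 21 × 21 rasters with 420-point profiles for the
end-to-end scans, and 200-particle packings over 5 seeds for the gel
analysis.

## Known limitations

The proportional-$q$ correction is the paper-standard approximation, not
the exact disorientation integral; its small-$q$ error is the dominant
systematic in the diameter estimates and is why the 300 Å cylinder reads a
few Å lower than the 1000 Å one. Only $q$-independent form factors are
built in. Helical selection rules, layer-line modelling for repeats beyond
30 Å, excluded-volume/hydration corrections, polydispersity deconvolution
and information-theoretic channel analysis are out of scope.
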