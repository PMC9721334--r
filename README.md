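# fibrilSAXS

Cross-section analysis of small-angle X-ray scattering from disoriented
fibrils — amyloid and other cross-β assemblies tumbling in solution or
frozen at random orientations inside fixed tissue.

For structural biologists and beamline users working with scanning
microdiffraction of tissue sections or solution SAXS of fibrils, the package
provides the full chain from forward models to maps and cross-section size
estimates:

* **Forward calculators** — the solid-cylinder transform
  `F(q_x, Z) = V · [2J₁(q_x R)/(q_x R)] · sinc(Zh/2)`, orientational
  averages, the Debye formula `I(q) = Σᵢⱼ fᵢfⱼ sin(q rᵢⱼ)/(q rᵢⱼ)` over
  atomic models (PDB input), and stacked cross-β layer models.
* **Equatorial recovery** — for fibrils with axial repeat < 30 Å the
  small-angle intensity is entirely equatorial, and `I_e(q) ≈ q · I(q)`
  recovers it from the isotropic average (with a validity check against the
  first layer plane at `q = 2π/repeat`).
* **Cross-section functions** — the cross-section pair distribution
  function `P_c(r) = (r/2π) ∫ q I_e(q) J₀(qr) dq` and correlation function
  `a_c(r) = P_c(r)/r`, independent of fibril length, by direct quadrature
  or by a regularized indirect Fourier transform (cubic B-splines,
  second-difference penalty, `d_max = 2π/q_min` lower-bound rule for
  embedded fibrils). For a compact cross-section, the first zero crossing
  of `a_c` estimates the fibril diameter.
* **Scan-grid processing** — substrate-peak masking, azimuthal averaging,
  SAXS/WAXS merging, beam-monitor normalization, cross-β heat maps
  (baseline-anchored intensity at `q ≃ 1.34 Å⁻¹`, the 4.7 Å spacing) for
  locating plaques and tangles, and the two-reference background
  subtraction `I = (I_l − I_b) − a(I_t − I_b)` with `a` fitted over
  `1.6 < q < 2.0 Å⁻¹`.
* **Synthetic data** — seeded generators for noisy profiles, tissue-like
  diffuse curves, plaque-bearing scan rasters with ground truth, and 2D
  liquid-like packings of parallel cylinders with interparticle
  interference `I_e = |F_eq|² S(q)`, `S(q) = 1 + (2/N) Σ J₀(q d_jk)`.

Core containers are S4: `SaxsProfile`, `RealSpaceFunction`, `CylinderSpec`,
`AtomSet`, `ScanGrid` (a `SummarizedExperiment` of profiles), `HeatMap`,
`BackgroundModel`.

## Worked example

Simulate isotropic scattering from randomly oriented solid cylinders of
radius 35 Å and length 1000 Å, recover the equatorial intensity, and
estimate the diameter from the cross-section correlation function:

```r
library(fibrilSAXS)

q       <- seq(0.004, 0.3, length.out = 300)          # 1/Angstrom
cyl     <- CylinderSpec(radius = 35, length = 1000)   # Angstrom
profile <- isotropicCylinderIntensity(q, cyl)

res <- crossSectionAnalysis(profile, dMax = 200)
res$correlation
#> RealSpaceFunction (cross_section correlation): 512 points, r in [0, 200] Ang, normalized
round(res$diameter, 1)
#> [1] 67.5
```

The crossing at 67.5 Å estimates the 70 Å diameter; the small deficit is
the documented cost of the proportional-`q` correction and the finite
`q`-window (band limit `π/q_max ≈ 10 Å`). The attribution of small-angle
intensity to the equator is legitimate here because the cross-β repeat puts
the first layer plane far beyond the data:

```r
checkEquatorialValidity(4.7, qMax = 0.3)
#> $verdict
#> [1] "valid"
#> $firstLayerQ
#> [1] 1.336848
```

A command-line front end covering simulation, cross-section analysis and
scan processing is installed at
`system.file("scripts", "fibrilsaxs", package = "fibrilSAXS")`; e.g.

```sh
fibrilsaxs simulate cylinder --radius 35 --length 1000 --out cyl.dat
fibrilsaxs xsection --in cyl.dat --dmax 200 --out-prefix cyl
```

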