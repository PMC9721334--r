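test_that("spherical PDF by direct quadrature matches distance-based oracles", {
  q <- seq(0.01, 3, length.out = 400)
  r <- seq(0.5, 20, length.out = 200)

  ## zero intensity transforms to zero
  z <- pdfSphericalDirect(SaxsProfile(q, rep(0, length(q))), r)
  expect_equal(fnValues(z), rep(0, length(r)))
  expect_equal(z@geometry, "spherical"); expect_equal(z@kind, "pdf")

  ## two points 10 Ang apart: P_s peaks at the interatomic distance
  two <- debyeIntensity(AtomSet(rbind(c(0, 0, 0), c(0, 0, 10))), q)
  ps <- pdfSphericalDirect(two, r)
  expect_lt(abs(rValues(ps)[which.max(fnValues(ps))] - 10), 1)

  ## solid cylinder: the spherical correlation extends to about the length
  q2 <- saxsQGrid()
  pcyl <- isotropicCylinderIntensity(q2, CylinderSpec(35, 300))
  ps2 <- pdfSphericalDirect(pcyl, seq(2, 450, length.out = 300))
  as2 <- correlationFromPDF(ps2, anchorMin = pi / 0.3)
  rr <- rValues(as2); vv <- fnValues(as2)
  expect_true(all(vv[rr < 250] > 0))
  expect_lt(max(abs(vv[rr > 330])), 0.01)
  ## solid-body correlation decreases monotonically inside the particle
  expect_true(all(diff(vv[rr >= 12 & rr <= 290]) < 1e-6))

  expect_error(pdfSphericalDirect(SaxsProfile(c(0, 0.1), c(1, 1)), r), "above 0")
})

test_that("cross-section PDF matches the Monte-Carlo projected-distance oracle", {
  q <- seq(0.002, 1.2, length.out = 800)
  Ie <- SaxsProfile(q, airyEquatorial(q, 35), equatorial = TRUE)

  ## support ends at the diameter (70 Ang) up to truncation ripple
  r <- seq(0.5, 120, length.out = 240)
  pc <- pdfCrossSectionDirect(Ie, r)
  v <- fnValues(pc) / max(fnValues(pc))
  expect_lt(max(abs(v[r > 75])), 0.02)

  ## the r-weighted histogram of projected pair distances in the disk
  h <- diskPairDistanceHist(R = 35, nPoints = 2000, breaks = seq(0, 70.01, 1),
                            seed = 101)
  pc2 <- pdfCrossSectionDirect(Ie, h$mids)
  a <- fnValues(pc2) / max(fnValues(pc2))
  b <- h$density / max(h$density)
  sel <- h$mids >= 5 & h$mids <= 65
  expect_lt(max(abs(a - b)[sel]), 0.05)

  ## zero in, zero out; and the equatorial flag is policed
  expect_equal(fnValues(pdfCrossSectionDirect(
    SaxsProfile(q, rep(0, length(q)), equatorial = TRUE), r)), rep(0, length(r)))
  expect_error(pdfCrossSectionDirect(SaxsProfile(q, rep(1, length(q))), r),
               "equatorial")
})

test_that("PDF and correlation operators are linear in the intensity", {
  q <- saxsQGrid(150)
  p <- isotropicCylinderIntensity(q, CylinderSpec(30, 500))
  p3 <- SaxsProfile(q, 3 * intensities(p))
  r <- seq(1, 150, length.out = 100)
  expect_equal(fnValues(pdfSphericalDirect(p3, r)),
               3 * fnValues(pdfSphericalDirect(p, r)))
  e1 <- equatorialFromIsotropic(p); e3 <- equatorialFromIsotropic(p3)
  expect_equal(fnValues(pdfCrossSectionDirect(e3, r)),
               3 * fnValues(pdfCrossSectionDirect(e1, r)))
})

test_that("correlation functions divide out the geometric weight", {
  r <- seq(0, 1, length.out = 101)
  pc <- RealSpaceFunction(r, r, geometry = "cross_section", kind = "pdf")
  ac <- correlationFromPDF(pc, normalize = FALSE)
  expect_equal(fnValues(ac), rep(1, 101))
  expect_equal(ac@kind, "correlation")

  acn <- correlationFromPDF(pc, normalize = TRUE)
  expect_equal(fnValues(acn), rep(1, 101))
  expect_true(acn@normalized)

  ps <- RealSpaceFunction(r, 5 * r^2, geometry = "spherical", kind = "pdf")
  expect_equal(fnValues(correlationFromPDF(ps, normalize = FALSE)), rep(5, 101))

  expect_error(correlationFromPDF(ac), "pdf")
})

test_that("indirect transform honours the automatic d_max rule", {
  q <- seq(0.02, 0.5, length.out = 200)
  prof <- SaxsProfile(q, airyEquatorial(q, 20), equatorial = TRUE)
  fit <- iftFit(prof, IFTConfig(dMax = NA, nBasis = 20, geometry = "cross_section"))
  expect_equal(fit@metadata$dMax, 2 * pi / 0.02, tolerance = 1e-12)
  expect_equal(fit@metadata$dMax, 314.159, tolerance = 1e-5)
})

test_that("indirect transform recovers a known two-Gaussian PDF from its forward model", {
  dMax <- 120
  r <- seq(0, dMax, length.out = 1024)
  wr <- diff(r)[1]

  ## cross-section geometry
  P <- exp(-(r - 35)^2 / (2 * 8^2)) + 0.6 * exp(-(r - 70)^2 / (2 * 10^2))
  q <- seq(0.004, 0.5, length.out = 400)
  K <- 2 * pi * outer(q, r, function(qq, rr) besselJ(qq * rr, 0))
  I <- as.vector(K %*% (P * wr))
  fit <- iftFit(SaxsProfile(q, I, equatorial = TRUE),
                IFTConfig(dMax = dMax, nBasis = 30, geometry = "cross_section"))
  Pf <- approx(rValues(fit), fnValues(fit), xout = r)$y
  expect_lt(max(abs(Pf - P)) / max(P), 0.02)

  ## spherical geometry
  P2 <- exp(-(r - 40)^2 / (2 * 9^2))
  K2 <- 4 * pi * outer(q, r, function(qq, rr) {
    x <- qq * rr; ifelse(x == 0, 1, sin(x) / x)
  })
  I2 <- as.vector(K2 %*% (P2 * wr))
  fit2 <- iftFit(SaxsProfile(q, I2),
                 IFTConfig(dMax = dMax, nBasis = 30, geometry = "spherical"))
  Pf2 <- approx(rValues(fit2), fnValues(fit2), xout = r)$y
  expect_lt(max(abs(Pf2 - P2)) / max(P2), 0.02)

  ## preconditions
  expect_error(iftFit(SaxsProfile(q[1:30], I[1:30], equatorial = TRUE),
                      IFTConfig(dMax = dMax, nBasis = 30,
                                geometry = "cross_section")),
               "2\\*nBasis")
  expect_error(IFTConfig(smoothness = -1), "smoothness")
  expect_error(iftFit(SaxsProfile(q, I), IFTConfig(geometry = "cross_section")),
               "equatorial")
})

test_that("first zero crossing is located by interpolation with a decay fallback", {
  r <- seq(0, 100, length.out = 501)
  lin <- RealSpaceFunction(r, 1 - r / 70, geometry = "cross_section",
                           kind = "correlation", normalized = TRUE)
  expect_equal(firstZeroCrossing(lin), 70, tolerance = 1e-10)

  cosfn <- RealSpaceFunction(r, cos(pi * r / 100), geometry = "cross_section",
                             kind = "correlation", normalized = TRUE)
  expect_equal(firstZeroCrossing(cosfn), 50, tolerance = 1e-6)

  ## no crossing: report where the function has decayed below 2% of a(0)
  dec <- RealSpaceFunction(r, exp(-r / 10), geometry = "cross_section",
                           kind = "correlation", normalized = TRUE)
  expect_equal(firstZeroCrossing(dec), max(r[exp(-r / 10) < 0.02]))

  flat <- RealSpaceFunction(r, rep(1, 501), geometry = "cross_section",
                            kind = "correlation", normalized = TRUE)
  expect_error(firstZeroCrossing(flat), "never")

  unnorm <- RealSpaceFunction(r, 1 - r / 70, geometry = "cross_section",
                              kind = "correlation", normalized = FALSE)
  expect_error(firstZeroCrossing(unnorm), "normalized")
})

test_that("restricting the q window broadens but does not move the diameter estimate much", {
  q <- saxsQGrid()
  p <- isotropicCylinderIntensity(q, CylinderSpec(35, 1000))
  full <- crossSectionAnalysis(p, dMax = 200)
  half <- crossSectionAnalysis(p, dMax = 200, qMax = 0.15)
  expect_lt(abs(half$diameter - full$diameter) / full$diameter, 0.10)
})

test_that("cylinder length barely affects the cross-section correlation", {
  q <- saxsQGrid()
  r <- seq(1, 120, length.out = 300)
  acOf <- function(h) {
    pe <- equatorialFromIsotropic(isotropicCylinderIntensity(q, CylinderSpec(35, h)))
    fnValues(correlationFromPDF(pdfCrossSectionDirect(pe, r), anchorMin = pi / 0.3))
  }
  expect_lt(max(abs(acOf(300) - acOf(1000))), 0.05)
})
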