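## Small detector-geometry fixture used throughout.
testGeometry <- function() {
  DetectorGeometry(beamCenter = c(64.5, 64.5), pixelSize = 0.172,
                   distance = 300, wavelength = 1.0)
}

renderImage <- function(I0, geom = testGeometry(), npx = 128) {
  img <- matrix(0, npx, npx)
  px <- col(img) - geom@beamCenter[1]
  py <- row(img) - geom@beamCenter[2]
  rad <- sqrt(px^2 + py^2) * geom@pixelSize
  qmap <- (4 * pi / geom@wavelength) * sin(atan2(rad, geom@distance) / 2)
  img[] <- I0(qmap)
  img
}

test_that("substrate-peak masking flags regions and is the identity without regions", {
  img <- matrix(1, 64, 64)
  expect_identical(maskSubstratePeaks(img), img)
  m <- maskSubstratePeaks(img, list(c(10, 12, 20, 22)))
  expect_true(all(is.na(m[10:12, 20:22])))
  expect_equal(sum(is.na(m)), 9)
  expect_error(maskSubstratePeaks(img, list(c(60, 70, 1, 5))), "bounds")
  ## fully masked image fails downstream, not silently
  full <- maskSubstratePeaks(img, list(c(1, 64, 1, 64)))
  expect_error(circularAverage(full, testGeometry()), "masked")
})

test_that("circular averaging recovers radial profiles and ignores masked pixels", {
  geom <- testGeometry()

  ## uniform image: every bin equals the constant
  u <- circularAverage(matrix(7, 128, 128), geom, nBins = 40)
  expect_equal(intensities(u), rep(7, length(qValues(u))))
  expect_equal(sigmas(u), rep(0, length(qValues(u))))

  ## render-then-average round trip
  I0 <- function(q) exp(-q^2 / 0.02) + 0.1
  img <- renderImage(I0, geom)
  prof <- circularAverage(img, geom, nBins = 60)
  rel <- (intensities(prof) - I0(qValues(prof))) / I0(qValues(prof))
  expect_lt(sqrt(mean(rel^2)), 0.01)

  ## masking injected spikes restores the average of the clean image under
  ## the same mask (azimuthally uniform, so also close to the unmasked one)
  regions <- list(c(30, 32, 80, 82), c(90, 91, 15, 17), c(60, 62, 110, 112))
  spiked <- img
  for (rg in regions) spiked[rg[1]:rg[2], rg[3]:rg[4]] <- 100 * max(img)
  cleanMasked <- circularAverage(maskSubstratePeaks(img, regions), geom, 60)
  spikeMasked <- circularAverage(maskSubstratePeaks(spiked, regions), geom, 60)
  expect_equal(intensities(spikeMasked), intensities(cleanMasked))
  expect_lt(max(abs(intensities(spikeMasked) - intensities(prof)) /
                intensities(prof)), 0.02)

  ## masking a wedge leaves an azimuthally uniform expectation unchanged
  wedge <- circularAverage(maskSubstratePeaks(img, list(c(1, 40, 1, 40))), geom, 60)
  sharedQ <- qValues(wedge) %in% qValues(prof)
  expect_lt(max(abs(intensities(wedge) - I0(qValues(wedge))) / I0(qValues(wedge))),
            0.02)
})

test_that("SAXS/WAXS merging finds the scale and splices at the overlap midpoint", {
  qs <- seq(0.01, 0.5, by = 0.005)
  qw <- seq(0.3, 2.5, by = 0.01)
  shape <- function(q) 10 * exp(-q) + 1
  saxs <- SaxsProfile(qs, shape(qs))
  waxs <- SaxsProfile(qw, 2 * shape(qw))
  m <- mergeProfiles(saxs, waxs, overlap = c(0.32, 0.48))
  ## scale and splice continuity up to the interpolation used on the overlap
  expect_equal(m@metadata$waxsScale, 0.5, tolerance = 1e-4)
  expect_equal(intensities(m), shape(qValues(m)), tolerance = 1e-4)
  expect_true(all(diff(qValues(m)) > 0))

  ## round trip with seeded noise: merged curve matches the original model
  sn <- genProfile(saxs, exposure = 2e4, seed = 4)
  wn <- genProfile(SaxsProfile(qw, 2 * shape(qw)), exposure = 2e4, seed = 5)
  mn <- mergeProfiles(sn, wn, overlap = c(0.32, 0.48))
  expect_lt(max(abs(intensities(mn) - shape(qValues(mn))) /
                pmax(sigmas(mn), 1e-9)), 6)

  expect_error(mergeProfiles(saxs, SaxsProfile(c(3, 4), c(1, 1)), c(0.3, 0.5)),
               "overlap")
})

test_that("beam-monitor normalization divides and inverts exactly", {
  p <- SaxsProfile(c(0.1, 0.2), c(4, 8), c(1, 2))
  expect_equal(intensities(normalizeBeam(p, 1)), c(4, 8))
  h <- normalizeBeam(p, 2)
  expect_equal(intensities(h), c(2, 4))
  expect_equal(sigmas(h), c(0.5, 1))
  back <- normalizeBeam(h, 1 / 2)
  expect_equal(intensities(back), intensities(p))
  expect_error(normalizeBeam(p, 0), "monitor")
})

test_that("cross-beta heat maps isolate the sharp 4.7 Angstrom excess", {
  q <- seq(0.8, 2.0, length.out = 240)
  base <- 2 + 0.5 * q
  peak <- function(h) base + h * exp(-(q - 1.337)^2 / (2 * 0.01^2))
  nx <- 7; ny <- 5
  I <- sapply(seq_len(nx * ny), function(j) peak(0))
  scanFlat <- ScanGrid(q, I, nx = nx, ny = ny)
  expect_equal(max(heatValues(crossbetaHeatmap(scanFlat))), 0, tolerance = 1e-9)

  ## one cell with a peak lights up; a q-linear baseline change does not
  I2 <- I; I2[, cellIndex(scanFlat, 4, 3)] <- peak(5)
  scan2 <- ScanGrid(q, I2, nx = nx, ny = ny)
  hv <- heatValues(crossbetaHeatmap(scan2))
  expect_equal(unname(which(hv == max(hv), arr.ind = TRUE)[1, ]), c(4, 3))
  I3 <- I2 + outer(3 + 10 * q, rep(1, nx * ny))
  hv3 <- heatValues(crossbetaHeatmap(ScanGrid(q, I3, nx = nx, ny = ny)))
  expect_equal(hv3, hv, tolerance = 1e-9)

  expect_error(crossbetaHeatmap(scanFlat, qCenter = 3), "window")
})

test_that("a 61 x 81 raster holds 4941 patterns", {
  q <- seq(1.0, 2.0, length.out = 101)
  scan <- ScanGrid(q, matrix(0, 101, 61 * 81), nx = 61, ny = 81, step = 5)
  expect_equal(ncol(scan), 4941)
  expect_equal(length(heatValues(crossbetaHeatmap(scan))), 4941)
  expect_equal(unname(gridDims(scan)), c(61L, 81L))
})

test_that("two-reference background subtraction solves for the scale exactly", {
  q <- seq(0.1, 2.1, length.out = 300)
  Ib <- 1 + 0.2 * sin(3 * q)
  It <- Ib + 4 * exp(-q / 2)
  Il <- Ib + 2 * (It - Ib)
  res <- subtractBackground(SaxsProfile(q, Il), SaxsProfile(q, It),
                            SaxsProfile(q, Ib))
  expect_equal(res$model@a, 2, tolerance = 1e-12)
  expect_lt(res$model@residual, 1e-12)
  expect_equal(intensities(res$profile), rep(0, 300), tolerance = 1e-12)

  ## lesion identical to bare substrate: a = 0 and nothing remains
  res0 <- subtractBackground(SaxsProfile(q, Ib), SaxsProfile(q, It),
                             SaxsProfile(q, Ib))
  expect_equal(res0$model@a, 0)
  expect_equal(intensities(res0$profile), rep(0, 300))

  expect_error(subtractBackground(SaxsProfile(q, Il), SaxsProfile(q, Ib),
                                  SaxsProfile(q, Ib)), "undefined")
})

test_that("background selection avoids the lesion and is deterministic under ties", {
  nx <- 15; ny <- 15
  q <- seq(0.5, 2.0, length.out = 50)
  I <- matrix(1, 50, nx * ny)
  scan <- ScanGrid(q, I, nx = nx, ny = ny)
  map <- HeatMap(matrix(0, nx, ny))

  sel <- selectBackgroundCells(scan, map, c(8, 8), n = 5)
  cells <- sel@metadata$cells
  d <- sqrt((cells[, "ix"] - 8)^2 + (cells[, "iy"] - 8)^2)
  expect_true(all(d >= 3 & d <= 10))
  ## uniform map: ties broken by distance, then row-major index
  expect_equal(unname(cells[1, ]), c(8, 5))   # first cell at distance 3
  expect_equal(intensities(sel), rep(1, 50))

  expect_error(selectBackgroundCells(scan, map, c(8, 8), n = 1000), "annulus")
  expect_error(selectBackgroundCells(scan, map, c(99, 8)), "outside")
})

test_that("a synthetic scan is located, background-subtracted and sized end to end", {
  gen <- genScan(syntheticScanSpec(seed = 5))
  scan <- gen$scan
  truth <- gen$truth
  map <- crossbetaHeatmap(scan)
  hv <- heatValues(map)

  ## localization: the heat map peaks inside the planted plaque and plaque
  ## cells are far above background cells
  amax <- which(hv == max(hv), arr.ind = TRUE)[1, ]
  expect_true(truth$plaqueMask[amax[1], amax[2]])
  expect_gt(median(hv[truth$plaqueMask]), 5 * max(median(hv[!truth$plaqueMask]), 1e-9))

  ## background cells avoid the plaque
  tissue <- selectBackgroundCells(scan, map, c(11, 11), n = 5)
  expect_false(any(truth$plaqueMask[tissue@metadata$cells]))

  ## the fitted tissue scale recovers the planted density contrast
  res <- subtractBackground(profileAt(scan, 11, 11), tissue,
                            truth$substrateProfile)
  expect_equal(res$model@a, 1.30, tolerance = 0.01)

  ## subtracted curve matches the injected fibril profile within noise
  fib <- intensities(truth$fibrilProfile)
  dev <- (intensities(res$profile) - fib) / pmax(sigmas(res$profile), 1e-9)
  expect_lt(stats::quantile(abs(dev), 0.99), 6)

  ## diameter of the planted fibril recovered within 10%
  sel <- qValues(res$profile) <= 0.3
  ps <- SaxsProfile(qValues(res$profile)[sel],
                    pmax(intensities(res$profile)[sel], 0),
                    sigmas(res$profile)[sel])
  est <- crossSectionAnalysis(ps, dMax = 200)
  expect_lt(abs(est$diameter - 70) / 70, 0.10)
})
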