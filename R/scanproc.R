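#' Mask substrate peaks in a detector image
#'
#' Flags pixel regions (e.g. sharp mica reflections) as invalid by setting
#' them to NA; all other pixels are unchanged. Downstream azimuthal averaging
#' ignores NA pixels.
#'
#' @param image numeric matrix of detector counts.
#' @param peakRegions list of regions, each \code{c(rowMin, rowMax, colMin,
#'   colMax)} in 1-based pixel indices.
#' @return the masked image matrix.
#' @export
maskSubstratePeaks <- function(image, peakRegions = list()) {
  stopifnot(is.matrix(image))
  for (reg in peakRegions) {
    if (length(reg) != 4L) stop("each region must be c(rowMin, rowMax, colMin, colMax)")
    if (reg[1] < 1 || reg[2] > nrow(image) || reg[3] < 1 || reg[4] > ncol(image) ||
        reg[1] > reg[2] || reg[3] > reg[4])
      stop("region [", paste(reg, collapse = ", "), "] out of image bounds")
    image[reg[1]:reg[2], reg[3]:reg[4]] <- NA_real_
  }
  image
}

#' Azimuthal (circular) average of a detector image
#'
#' Bins unmasked pixels by momentum transfer, computed from the detector
#' geometry as \code{q = (4*pi/lambda) * sin(atan2(radius_mm, distance)/2)},
#' and returns the per-bin mean intensity with the standard error of the mean
#' as uncertainty. Bins are uniform in q between the image's q extremes;
#' empty bins are dropped.
#'
#' @param image numeric matrix (NA = masked).
#' @param geometry a \linkS4class{DetectorGeometry}.
#' @param nBins number of q bins.
#' @return a \linkS4class{SaxsProfile}.
#' @export
circularAverage <- function(image, geometry, nBins = 200) {
  stopifnot(is.matrix(image), is(geometry, "DetectorGeometry"))
  ok <- is.finite(image)
  if (!any(ok)) stop("all pixels are masked; nothing to average")
  px <- col(image) - geometry@beamCenter[1]
  py <- row(image) - geometry@beamCenter[2]
  rad <- sqrt(px^2 + py^2) * geometry@pixelSize
  qmap <- (4 * pi / geometry@wavelength) * sin(atan2(rad, geometry@distance) / 2)
  qv <- qmap[ok]
  iv <- image[ok]
  edges <- seq(min(qv), max(qv), length.out = nBins + 1)
  bin <- pmin(nBins, pmax(1L, findInterval(qv, edges, rightmost.closed = TRUE)))
  n <- tabulate(bin, nBins)
  msum <- vapply(split(iv, factor(bin, levels = seq_len(nBins))), sum, numeric(1))
  mean <- ifelse(n > 0, msum / n, NA_real_)
  ssq <- vapply(split(iv^2, factor(bin, levels = seq_len(nBins))), sum, numeric(1))
  varv <- ifelse(n > 1, pmax(0, (ssq - n * mean^2) / (n - 1)), 0)
  sem <- ifelse(n > 0, sqrt(varv / pmax(1, n)), NA_real_)
  qc <- (edges[-1] + edges[-(nBins + 1)]) / 2
  keep <- n > 0
  SaxsProfile(qc[keep], mean[keep], sem[keep],
              metadata = list(nPixels = n[keep]))
}

#' Merge SAXS and WAXS profiles
#'
#' Scales the WAXS curve onto the SAXS curve by the least-squares scalar over
#' the overlap window, then splices: SAXS points below the overlap midpoint,
#' scaled WAXS points above. Uncertainties are carried through (WAXS sigma
#' scaled by the same factor).
#'
#' @param saxs,waxs \linkS4class{SaxsProfile}s with overlapping q ranges.
#' @param overlap length-2 q window used for scaling (1/Angstrom).
#' @return a merged \linkS4class{SaxsProfile}; the fitted scale is recorded
#'   in its metadata as \code{waxsScale}.
#' @export
mergeProfiles <- function(saxs, waxs, overlap) {
  stopifnot(is(saxs, "SaxsProfile"), is(waxs, "SaxsProfile"))
  qs <- qValues(saxs); qw <- qValues(waxs)
  selS <- qs >= overlap[1] & qs <= overlap[2]
  inW <- qw >= overlap[1] & qw <= overlap[2]
  if (!any(selS) || !any(inW))
    stop("empty overlap window: SAXS covers [", min(qs), ", ", max(qs),
         "], WAXS covers [", min(qw), ", ", max(qw), "]")
  wI <- stats::approx(qw, intensities(waxs), xout = qs[selS], rule = 1)$y
  ok <- is.finite(wI)
  if (!any(ok)) stop("overlap window not covered by both detectors")
  c0 <- sum(intensities(saxs)[selS][ok] * wI[ok]) / sum(wI[ok]^2)
  mid <- mean(overlap)
  keepS <- qs < mid
  keepW <- qw >= mid
  q <- c(qs[keepS], qw[keepW])
  I <- c(intensities(saxs)[keepS], c0 * intensities(waxs)[keepW])
  s <- c(sigmas(saxs)[keepS], c0 * sigmas(waxs)[keepW])
  o <- order(q)
  SaxsProfile(q[o], I[o], s[o], metadata = list(waxsScale = c0, overlap = overlap))
}

#' Normalize a profile by a beam-monitor reading
#'
#' Divides intensity and uncertainty by the monitor value, correcting for
#' shot-to-shot fluctuations in incident beam intensity.
#'
#' @param profile a \linkS4class{SaxsProfile}.
#' @param monitor positive scalar monitor reading.
#' @return the normalized \linkS4class{SaxsProfile}.
#' @export
normalizeBeam <- function(profile, monitor) {
  stopifnot(is(profile, "SaxsProfile"))
  if (!is.finite(monitor) || monitor <= 0) stop("monitor must be > 0")
  SaxsProfile(qValues(profile), intensities(profile) / monitor,
              sigmas(profile) / monitor, equatorial = isEquatorial(profile),
              metadata = profile@metadata)
}

#' Cross-beta heat map of a scan grid
#'
#' For every scan cell, integrates the intensity above a local linear
#' baseline over a narrow window around the cross-beta reflection (default
#' q = 1.337 1/Angstrom, the 4.7 Angstrom axial spacing). The baseline is the
#' straight line through the window's edge points, so any q-linear diffuse
#' background cancels and only the sharp cross-beta excess drives the map;
#' negative integrals are clipped to zero. High map values locate pathological
#' fibrillar deposits (plaques, neurofibrillary tangles).
#'
#' @param scan a \linkS4class{ScanGrid}.
#' @param qCenter,qHalfWidth integration window (1/Angstrom).
#' @return a \linkS4class{HeatMap} with one value per cell.
#' @export
crossbetaHeatmap <- function(scan, qCenter = 1.337, qHalfWidth = 0.03) {
  stopifnot(is(scan, "ScanGrid"))
  q <- qValues(scan)
  lo <- qCenter - qHalfWidth
  hi <- qCenter + qHalfWidth
  sel <- which(q >= lo & q <= hi)
  if (length(sel) < 3 || lo < min(q) || hi > max(q))
    stop("integration window [", lo, ", ", hi, "] outside the measured q grid")
  qi <- q[sel]
  I <- intensities(scan)[sel, , drop = FALSE]
  i1 <- 1L; i2 <- length(sel)
  slope <- (I[i2, ] - I[i1, ]) / (qi[i2] - qi[i1])
  base <- outer(qi - qi[i1], slope) + rep(I[i1, ], each = length(qi))
  w <- .trapzWeights(qi)
  vals <- pmax(0, as.vector(crossprod(I - base, w)))
  dims <- gridDims(scan)
  HeatMap(matrix(vals, nrow = dims["nx"], ncol = dims["ny"]),
          qCenter = qCenter, qHalfWidth = qHalfWidth)
}

#' Two-reference background subtraction
#'
#' Removes non-fibrillar scattering from a lesion profile using a proximal
#' tissue profile and a bare-substrate profile:
#' \deqn{I = (I_l - I_b) - a (I_t - I_b),}
#' where the dimensionless scale a is chosen to minimize the squared
#' difference between lesion and scaled tissue over \code{fitRange} (default
#' 1.6 < q < 2.0 1/Angstrom, where fibrillar scattering is weak). The
#' substrate term needs no scaling because the substrate contribution is the
#' same under lesion and tissue. a has the closed form
#' ratio of inner products of the two excess curves over the fit window.
#' Uncertainties are propagated in quadrature.
#'
#' @param lesion,tissue,substrate \linkS4class{SaxsProfile}s on a common q
#'   grid.
#' @param fitRange length-2 q window for the scale fit (1/Angstrom).
#' @return list with \code{profile} (the subtracted \linkS4class{SaxsProfile})
#'   and \code{model} (a \linkS4class{BackgroundModel}).
#' @export
subtractBackground <- function(lesion, tissue, substrate,
                               fitRange = c(1.6, 2.0)) {
  stopifnot(is(lesion, "SaxsProfile"), is(tissue, "SaxsProfile"),
            is(substrate, "SaxsProfile"))
  q <- qValues(lesion)
  if (!isTRUE(all.equal(q, qValues(tissue))) ||
      !isTRUE(all.equal(q, qValues(substrate))))
    stop("lesion, tissue and substrate must share one q grid")
  sel <- q >= fitRange[1] & q <= fitRange[2]
  if (!any(sel)) stop("fit range contains no q points")
  le <- intensities(lesion) - intensities(substrate)
  te <- intensities(tissue) - intensities(substrate)
  denom <- sum(te[sel]^2)
  if (denom <= 0)
    stop("tissue minus substrate is zero over the fit range; scale undefined")
  a <- sum(le[sel] * te[sel]) / denom
  out <- le - a * te
  sig <- sqrt(sigmas(lesion)^2 + sigmas(substrate)^2 +
              a^2 * (sigmas(tissue)^2 + sigmas(substrate)^2))
  rms <- sqrt(mean(out[sel]^2))
  list(
    profile = SaxsProfile(q, out, sig,
                          metadata = list(backgroundScale = a, fitRange = fitRange)),
    model = BackgroundModel(a = a, fitRange = fitRange, residual = rms)
  )
}

#' Select and average background cells near a lesion
#'
#' Picks the \code{n} cells with the lowest heat-map values inside an annulus
#' of 3 to 10 grid steps (Euclidean, in cell units) around the lesion cell —
#' regions adjacent to, but outside, the deposit — and returns their averaged
#' profile for use as the tissue reference in
#' \code{\link{subtractBackground}}. Ties are broken by distance, then by
#' row-major cell index, so the selection is deterministic.
#'
#' @param scan a \linkS4class{ScanGrid}.
#' @param map the matching \linkS4class{HeatMap}.
#' @param lesionCell length-2 integer vector \code{c(ix, iy)}.
#' @param n number of background cells to average (default 5).
#' @param annulus length-2 distance bounds in grid steps.
#' @return the averaged \linkS4class{SaxsProfile}; selected cells are listed
#'   in its metadata as \code{cells} (a matrix of ix, iy).
#' @export
selectBackgroundCells <- function(scan, map, lesionCell, n = 5,
                                  annulus = c(3, 10)) {
  stopifnot(is(scan, "ScanGrid"), is(map, "HeatMap"))
  if (n < 1) stop("n must be >= 1")
  dims <- gridDims(scan)
  if (lesionCell[1] < 1 || lesionCell[1] > dims["nx"] ||
      lesionCell[2] < 1 || lesionCell[2] > dims["ny"])
    stop("lesion cell outside the grid")
  cd <- colData(scan)
  d <- sqrt((cd$ix - lesionCell[1])^2 + (cd$iy - lesionCell[2])^2)
  cand <- which(d >= annulus[1] & d <= annulus[2])
  if (length(cand) < n)
    stop("annulus contains only ", length(cand), " cells; need ", n)
  heat <- heatValues(map)[cbind(cd$ix[cand], cd$iy[cand])]
  o <- order(heat, d[cand], cand)
  pick <- cand[o[seq_len(n)]]
  I <- intensities(scan)[, pick, drop = FALSE]
  S <- sigmas(scan)[, pick, drop = FALSE]
  SaxsProfile(qValues(scan), rowMeans(I), sqrt(rowSums(S^2)) / n,
              metadata = list(cells = cbind(ix = cd$ix[pick], iy = cd$iy[pick])))
}
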