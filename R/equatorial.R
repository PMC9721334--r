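#' Recover equatorial intensity from isotropic scattering
#'
#' For randomly oriented long fibrils with a short axial repeat, the
#' small-angle intensity is entirely equatorial and the equatorial curve can
#' be recovered from the isotropic average by a geometric disorientation
#' correction that, except at very small q, is proportional to q:
#' \eqn{I_e(q) = q \, I(q)}. Below \code{qFloor} (default 1.5 times the
#' smallest measured q), where the proportional approximation breaks down,
#' the corrected curve is continued linearly from its value at \code{qFloor}
#' down to 0 at q = 0. Uncertainties are scaled by the same per-point factor.
#'
#' @param profile a \linkS4class{SaxsProfile} of isotropic intensity with all
#'   q > 0.
#' @param qFloor smallest q treated exactly (1/Angstrom); default
#'   \code{1.5 * min(q)}.
#' @return a \linkS4class{SaxsProfile} flagged as equatorial.
#' @examples
#' p <- SaxsProfile(seq(0.01, 0.3, 0.01), rep(1, 30))
#' qe <- equatorialFromIsotropic(p)  # I_e(q) = q away from the floor
#' @export
equatorialFromIsotropic <- function(profile, qFloor = NULL) {
  stopifnot(is(profile, "SaxsProfile"))
  q <- qValues(profile)
  if (q[1] <= 0) stop("q values must be > 0")
  if (is.null(qFloor)) qFloor <- 1.5 * q[1]
  if (qFloor < 0) stop("qFloor must be >= 0")
  I <- intensities(profile)
  s <- sigmas(profile)
  Ie <- q * I
  se <- q * s
  below <- q < qFloor
  if (any(below) && any(!below)) {
    i0 <- which(!below)[1]
    ## linear continuation through the origin: I_e(q) = (q / q0) * I_e(q0)
    Ie[below] <- q[below] / q[i0] * Ie[i0]
    se[below] <- q[below] / q[i0] * se[i0]
  }
  SaxsProfile(q, Ie, se, equatorial = TRUE,
              metadata = c(profile@metadata,
                           list(correction = "proportional_q", qFloor = qFloor)))
}

#' Validity of the equatorial attribution
#'
#' Small-angle intensity from disoriented fibrils can be attributed entirely
#' to the equator only when the first layer plane, at
#' \code{firstLayerQ = 2*pi/axialRepeat}, lies beyond the measured q range
#' and the axial repeat is comfortably short (< 30 Angstrom); for repeats in
#' 25-30 Angstrom the attribution is borderline, and for longer repeats
#' disorientation mixes equatorial and layer-plane intensity. A cross-beta
#' repeat of 4.7 Angstrom puts the first layer plane at q = 1.337 1/Angstrom,
#' far outside the SAXS regime.
#'
#' @param axialRepeat fibril axial repeat (Angstrom, > 0).
#' @param qMax largest q used in the analysis (1/Angstrom).
#' @return list with \code{verdict} ("valid", "boundary" or "invalid") and
#'   \code{firstLayerQ} (1/Angstrom).
#' @export
checkEquatorialValidity <- function(axialRepeat, qMax) {
  if (axialRepeat <= 0) stop("axialRepeat must be > 0")
  firstLayerQ <- 2 * pi / axialRepeat
  verdict <- if (axialRepeat >= 25 && axialRepeat <= 30) {
    "boundary"
  } else if (firstLayerQ > qMax && axialRepeat < 30) {
    "valid"
  } else {
    warning("axial repeat ", axialRepeat,
            " Ang: layer-plane intensity mixes into the measured range")
    "invalid"
  }
  list(verdict = verdict, firstLayerQ = firstLayerQ)
}

#' Cross-section correlation analysis of an isotropic profile
#'
#' Convenience pipeline behind the fibril-diameter analysis: apply the
#' proportional-to-q equatorial correction (unless the profile is already
#' flagged equatorial), fit the cross-section PDF by the indirect Fourier
#' transform, convert to the normalized cross-section correlation function
#' and locate its first zero crossing, which estimates the fibril diameter
#' for a compact cross-section.
#'
#' @param profile a \linkS4class{SaxsProfile}.
#' @param dMax maximum cross-section vector length for the IFT (Angstrom);
#'   \code{NA} for the automatic \code{2*pi/qMin} rule.
#' @param nBasis,smoothness passed to \code{\link{IFTConfig}}.
#' @param qMin,qMax fit window; defaults to the full measured range.
#' @param qFloor passed to \code{\link{equatorialFromIsotropic}}.
#' @param rMinSearch ignore crossings below this radius (Angstrom).
#' @return list with elements \code{pdf}, \code{correlation} (both
#'   \linkS4class{RealSpaceFunction}) and \code{diameter} (Angstrom).
#' @export
crossSectionAnalysis <- function(profile, dMax = NA, nBasis = 30,
                                 smoothness = NA, qMin = NULL, qMax = NULL,
                                 qFloor = NULL, rMinSearch = 5) {
  stopifnot(is(profile, "SaxsProfile"))
  eq <- if (isEquatorial(profile)) profile
        else equatorialFromIsotropic(profile, qFloor = qFloor)
  q <- qValues(eq)
  cfg <- IFTConfig(dMax = dMax, nBasis = nBasis, smoothness = smoothness,
                   qMin = if (is.null(qMin)) q[1] else qMin,
                   qMax = if (is.null(qMax)) q[length(q)] else qMax,
                   geometry = "cross_section")
  pdf <- iftFit(eq, cfg)
  ## anchor the a(0) extrapolation at the band-limit resolution so that
  ## sub-resolution ringing of the fitted PDF cannot corrupt the scale
  ac <- correlationFromPDF(pdf, normalize = TRUE, anchorMin = pi / cfg@qMax)
  list(pdf = pdf, correlation = ac,
       diameter = firstZeroCrossing(ac, rMinSearch = rMinSearch))
}
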