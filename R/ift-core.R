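#' Spherical pair distribution function by direct quadrature
#'
#' Computes the r^2-weighted histogram of interatomic vector lengths from an
#' isotropic intensity curve,
#' \deqn{P_s(r) = \frac{r^2}{2\pi^2} \int q^2 I(q) \frac{\sin(qr)}{qr}\, dq,}
#' integrated by the trapezoid rule over the measured q window only (no
#' extrapolation to q = 0; the correlation-function analysis is deliberately
#' insensitive to missing low-q data). With a finite q window a band-limited
#' transform shows truncation ripple: a warning is raised when
#' \code{max(q) * max(r)} is small enough that ripple will dominate.
#'
#' @param profile a \linkS4class{SaxsProfile} of isotropic intensity,
#'   \code{min(q) > 0}.
#' @param r positive, increasing real-space grid (Angstrom).
#' @return a \linkS4class{RealSpaceFunction} (spherical pdf).
#' @export
pdfSphericalDirect <- function(profile, r) {
  stopifnot(is(profile, "SaxsProfile"))
  q <- qValues(profile)
  if (q[1] <= 0) stop("q grid must start above 0")
  if (any(r <= 0)) stop("r grid must be positive")
  if (max(q) * min(diff(c(0, r))) > pi)
    warning("r grid coarser than the band limit pi/q_max; expect aliasing")
  w <- .trapzWeights(q)
  I <- intensities(profile)
  K <- outer(r, q, function(rr, qq) .sinc(qq * rr))      # n_r x n_q
  vals <- (r^2 / (2 * pi^2)) * as.vector(K %*% (w * q^2 * I))
  RealSpaceFunction(r, vals, geometry = "spherical", kind = "pdf",
                    metadata = list(qWindow = range(q)))
}

#' Cross-section pair distribution function by direct quadrature
#'
#' Computes the histogram of interatomic distances projected onto the plane
#' perpendicular to the fibril axis from equatorial intensity,
#' \deqn{P_c(r) = \frac{r}{2\pi} \int q\, I_e(q)\, J_0(qr)\, dq,}
#' by the trapezoid rule over the measured window. The input must carry the
#' equatorial flag (see \code{\link{equatorialFromIsotropic}}); the result is
#' independent of fibril length.
#'
#' @param profile a \linkS4class{SaxsProfile} flagged as equatorial.
#' @param r positive, increasing real-space grid (Angstrom).
#' @return a \linkS4class{RealSpaceFunction} (cross-section pdf).
#' @export
pdfCrossSectionDirect <- function(profile, r) {
  stopifnot(is(profile, "SaxsProfile"))
  if (!isEquatorial(profile))
    stop("input must be equatorial intensity; apply equatorialFromIsotropic() first")
  q <- qValues(profile)
  if (q[1] <= 0) stop("q grid must start above 0")
  if (any(r <= 0)) stop("r grid must be positive")
  w <- .trapzWeights(q)
  I <- intensities(profile)
  K <- outer(r, q, function(rr, qq) besselJ(qq * rr, 0))
  vals <- (r / (2 * pi)) * as.vector(K %*% (w * q * I))
  RealSpaceFunction(r, vals, geometry = "cross_section", kind = "pdf",
                    metadata = list(qWindow = range(q)))
}

#' Correlation function from a pair distribution function
#'
#' Divides out the geometric weight of the PDF: \eqn{a_s(r) = P_s(r)/r^2} in
#' spherical geometry, \eqn{a_c(r) = P_c(r)/r} in cross-section geometry. The
#' correlation function is the probability (relative to the mean density) of
#' finding scattering material at distance r from an arbitrary occupied
#' point; it may be negative where local density falls below the average of
#' the scattering volume. An r = 0 point, when present on the grid, is filled
#' by polynomial extrapolation (quadratic for spherical, linear for
#' cross-section) through the three smallest positive-r points; when the PDF
#' comes from band-limited data, \code{anchorMin} should be set to the
#' real-space resolution (about \code{pi/q_max}) so the extrapolation is not
#' taken from sub-resolution ringing.
#'
#' @param pdf a \linkS4class{RealSpaceFunction} of kind "pdf".
#' @param normalize logical; scale so a(0) = 1 (a(0) taken from the
#'   extrapolated value).
#' @param anchorMin extrapolate a(0) from the three smallest r points at or
#'   above this radius (Angstrom; default 0, i.e. the smallest grid points).
#' @return a \linkS4class{RealSpaceFunction} of kind "correlation".
#' @export
correlationFromPDF <- function(pdf, normalize = TRUE, anchorMin = 0) {
  stopifnot(is(pdf, "RealSpaceFunction"))
  if (pdf@kind != "pdf") stop("input must be of kind 'pdf'")
  r <- rValues(pdf)
  v <- fnValues(pdf)
  pw <- if (pdf@geometry == "spherical") 2 else 1
  a <- ifelse(r > 0, v / r^pw, NA_real_)
  pos <- which(r > 0 & r >= anchorMin)[1:3]
  if (any(is.na(pos))) stop("anchorMin leaves fewer than three r points")
  deg <- if (pdf@geometry == "spherical") 2 else 1
  fit <- stats::lm(y ~ stats::poly(x, deg, raw = TRUE),
                   data = data.frame(x = r[pos], y = a[pos]))
  a0 <- unname(stats::predict(fit, newdata = data.frame(x = 0)))
  a[r == 0] <- a0
  if (normalize) {
    if (a0 == 0) stop("cannot normalize: extrapolated a(0) is zero")
    a <- a / a0
  }
  RealSpaceFunction(r, a, geometry = pdf@geometry, kind = "correlation",
                    normalized = isTRUE(normalize),
                    metadata = c(pdf@metadata, list(a0 = a0)))
}

## Clamped cubic B-spline basis on [0, dMax] evaluated at x: nBasis columns.
.bsplineBasis <- function(x, dMax, nBasis) {
  if (nBasis < 4) stop("nBasis must be >= 4")
  inner <- if (nBasis > 4) seq(0, dMax, length.out = nBasis - 2)[seq(2, nBasis - 3)] else numeric(0)
  knots <- c(rep(0, 4), inner, rep(dMax, 4))
  splines::splineDesign(knots, x, ord = 4, outer.ok = TRUE)
}

## Forward design matrix mapping B-spline P(r) coefficients to intensity on q.
## Spherical: I(q) = 4*pi * int P(r) sinc(qr) dr
## Cross-section: I_e(q) = 2*pi * int P(r) J0(qr) dr
## The boundary splines are dropped, imposing P(0) = P(dMax) = 0: a pair
## distribution vanishes at zero distance and, by the choice of dMax, at the
## maximum vector length. Without the dMax constraint the smoothness
## penalty's null space (linear P, i.e. constant cross-section correlation)
## is unconstrained by band-limited data and biases the recovered extent.
.iftDesign <- function(q, dMax, nBasis, geometry, nR = 1024L) {
  r <- seq(0, dMax, length.out = nR)
  Bfull <- .bsplineBasis(r, dMax, nBasis + 2L)
  B <- Bfull[, 2:(nBasis + 1L), drop = FALSE]   # nR x nBasis free functions
  wr <- .trapzWeights(r)
  K <- if (geometry == "spherical") {
    4 * pi * outer(q, r, function(qq, rr) .sinc(qq * rr))
  } else {
    2 * pi * outer(q, r, function(qq, rr) besselJ(qq * rr, 0))
  }
  list(A = K %*% (wr * B), r = r, B = B)
}

#' Indirect Fourier transform of a scattering profile
#'
#' Fits a pair distribution function represented as a sum of cubic B-spline
#' basis functions on [0, d_max] to the measured intensity through the
#' geometry-appropriate forward kernel (a sinc kernel for isotropic data, a
#' \eqn{J_0} Hankel kernel for equatorial data), by linear least squares
#' weighted by 1/sigma^2 with a second-difference smoothness penalty on the
#' basis coefficients. When \code{dMax} is \code{NA} (automatic) the maximum
#' vector length is set to \code{2*pi/qMin}: for particles embedded in a
#' matrix, correlations longer than the smallest measurable angle cannot be
#' constrained and the fitted function is a lower bound on the true
#' correlations. When \code{smoothness} is \code{NA} the weight is chosen
#' as the largest of 10 log-spaced candidates whose weighted residual stays
#' within 5 percent of the smallest achievable — the smoothest solution
#' consistent with the data, a deterministic rule. The fitted function obeys
#' P(0) = P(dMax) = 0 (the boundary splines are omitted), as a pair
#' distribution must.
#'
#' @param profile a \linkS4class{SaxsProfile}; must be equatorial when
#'   \code{config@geometry == "cross_section"}.
#' @param config an \linkS4class{IFTConfig}.
#' @return a \linkS4class{RealSpaceFunction} of kind "pdf" evaluated on 512
#'   uniform r points, with fit diagnostics (coefficients, lambda, condition
#'   number, chi-square) in its metadata.
#' @examples
#' cyl <- CylinderSpec(35, 1000)
#' p <- isotropicCylinderIntensity(seq(0.004, 0.3, length.out = 300), cyl)
#' pe <- equatorialFromIsotropic(p)
#' fit <- iftFit(pe, IFTConfig(dMax = 200, geometry = "cross_section"))
#' @export
iftFit <- function(profile, config) {
  stopifnot(is(profile, "SaxsProfile"), is(config, "IFTConfig"))
  if (config@geometry == "cross_section" && !isEquatorial(profile))
    stop("cross-section IFT requires equatorial intensity")
  q <- qValues(profile)
  sel <- q >= config@qMin & q <= config@qMax
  if (sum(sel) < 2 * config@nBasis)
    stop("need at least 2*nBasis q points inside the fit window")
  q <- q[sel]
  y <- intensities(profile)[sel]
  sig <- sigmas(profile)[sel]
  sig[sig <= 0] <- min(sig[sig > 0], 1)
  dMax <- if (is.na(config@dMax)) 2 * pi / q[1] else config@dMax
  nb <- as.integer(config@nBasis)

  des <- .iftDesign(q, dMax, nb, config@geometry)
  A <- des$A
  ## Weighting: 1/sigma^2 when the profile carries measured uncertainties.
  ## A flat sigma (the uninformative default), or one that is flat up to the
  ## q factor applied by the equatorial correction, carries no information;
  ## in that case assume counting-like variance proportional to intensity,
  ## which keeps the decades-spanning low-q region from dominating the fit.
  flat <- function(v) diff(range(v)) <= 1e-12 * max(abs(v))
  W <- if (flat(sig) || flat(sig / q)) {
    1 / pmax(abs(y), max(abs(y)) * 1e-8)
  } else {
    1 / sig^2
  }
  D <- diff(diag(nb), differences = 2)          # second differences
  AtWA <- crossprod(A * sqrt(W))
  AtWy <- crossprod(A, W * y)
  DtD <- crossprod(D)
  lamRef <- sum(diag(AtWA)) / max(sum(diag(DtD)), .Machine$double.eps)

  solveFor <- function(lam) {
    M <- AtWA + lam * DtD
    co <- tryCatch(solve(M, AtWy), error = function(e)
      stop("normal equations singular (condition number ~ ", format(kappa(M)),
           "); increase smoothness or reduce nBasis"))
    as.vector(co)
  }

  if (is.na(config@smoothness)) {
    ## Sweep 10 log-spaced weights and keep the smoothest solution whose
    ## weighted residual is within 5% of the best achievable: past that point
    ## extra roughness only chases the residual floor (noise, or the
    ## small-q error of the proportional-q correction), not signal.
    lams <- lamRef * 10^seq(-7, 2, length.out = 10)
    res <- vapply(lams, function(l) {
      co <- solveFor(l)
      sum(W * (y - A %*% co)^2)
    }, numeric(1))
    ## absolute floor: a weighted misfit below 1e-4 of the data norm (1% rms)
    ## is already noise-level, so residual differences down there must not
    ## drive the solution toward roughness
    tol <- max(1.05 * min(res), 1e-4 * sum(W * y^2))
    lambda <- lams[max(which(res <= tol))]
  } else {
    lambda <- config@smoothness
  }

  coefs <- solveFor(lambda)
  M <- AtWA + lambda * DtD
  cond <- kappa(M, exact = FALSE)
  fitI <- as.vector(A %*% coefs)
  chi2 <- sum(W * (y - fitI)^2) / max(1, length(y) - nb)

  rOut <- seq(0, dMax, length.out = 512L)
  Bout <- .bsplineBasis(rOut, dMax, nb + 2L)[, 2:(nb + 1L), drop = FALSE]
  vals <- as.vector(Bout %*% coefs)
  RealSpaceFunction(rOut, vals, geometry = config@geometry, kind = "pdf",
    metadata = list(dMax = dMax, nBasis = nb, lambda = lambda,
                    condition = cond, chi2 = chi2, qWindow = range(q),
                    coefficients = coefs))
}

#' First zero crossing of a correlation function
#'
#' The smallest r beyond \code{rMinSearch} where the linearly interpolated
#' correlation crosses from positive to nonpositive values; for a compact
#' particle of uniform density this estimates the maximum cross-section (or
#' full) extent, e.g. the diameter for a_c of a solid cylinder. If the
#' function never crosses zero, the largest r where it has decayed below
#' 2 percent of a(0) is returned instead; if it never falls that low the
#' search fails.
#'
#' @param fn a normalized \linkS4class{RealSpaceFunction} of kind
#'   "correlation".
#' @param rMinSearch ignore crossings at or below this radius (Angstrom).
#' @return crossing radius (Angstrom).
#' @export
firstZeroCrossing <- function(fn, rMinSearch = 0) {
  stopifnot(is(fn, "RealSpaceFunction"))
  if (fn@kind != "correlation") stop("input must be of kind 'correlation'")
  if (!fn@normalized) stop("correlation must be normalized (a(0) = 1)")
  r <- rValues(fn)
  v <- fnValues(fn)
  sel <- which(r > rMinSearch)
  for (i in sel[sel < length(r)]) {
    if (v[i] > 0 && v[i + 1] <= 0) {
      ## linear interpolation to the crossing
      return(r[i] + (r[i + 1] - r[i]) * v[i] / (v[i] - v[i + 1]))
    }
  }
  low <- sel[v[sel] < 0.02]
  if (length(low) == 0)
    stop("correlation never crosses zero nor decays below 2% of a(0)")
  r[max(low)]
}
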