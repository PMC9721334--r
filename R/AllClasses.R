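#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
NULL

## Momentum-transfer convention used throughout: q = 4*pi*sin(theta)/lambda,
## so a Bragg spacing d corresponds to q = 2*pi/d.  All q in 1/Angstrom, all
## real-space distances in Angstrom.

#' SaxsProfile: a one-dimensional scattering curve
#'
#' Container for a circularly averaged scattering profile: a strictly
#' increasing momentum-transfer grid \code{q} (1/Angstrom), intensities and
#' per-point uncertainties. The \code{equatorial} flag records whether the
#' curve represents equatorial (cross-section) intensity \eqn{I_e(q)} rather
#' than isotropically averaged intensity.
#'
#' @slot q numeric, strictly increasing, all \eqn{\ge 0} (1/Angstrom).
#' @slot intensity numeric, same length as \code{q}, finite.
#' @slot sigma numeric, nonnegative uncertainties (default 1 per point).
#' @slot equatorial logical scalar; TRUE for equatorial intensity.
#' @slot metadata list of free-form provenance entries.
#'
#' @examples
#' p <- SaxsProfile(q = seq(0.01, 0.3, 0.01), intensity = rep(1, 30))
#' qValues(p)[1:3]
#' @export
setClass("SaxsProfile",
  representation(
    q = "numeric",
    intensity = "numeric",
    sigma = "numeric",
    equatorial = "logical",
    metadata = "list"
  ),
  prototype(equatorial = FALSE, metadata = list())
)

setValidity("SaxsProfile", function(object) {
  msg <- NULL
  n <- length(object@q)
  if (n < 1L) msg <- c(msg, "empty q grid")
  if (length(object@intensity) != n) msg <- c(msg, "intensity length != q length")
  if (length(object@sigma) != n) msg <- c(msg, "sigma length != q length")
  if (any(object@q < 0)) msg <- c(msg, "q values must be >= 0")
  if (n > 1L && any(diff(object@q) <= 0)) msg <- c(msg, "q must be strictly increasing")
  if (any(!is.finite(object@intensity))) msg <- c(msg, "intensities must be finite")
  if (any(object@sigma < 0, na.rm = TRUE)) msg <- c(msg, "sigma must be nonnegative")
  if (length(object@equatorial) != 1L) msg <- c(msg, "equatorial must be a scalar flag")
  if (is.null(msg)) TRUE else msg
})

#' @param q,intensity,sigma numeric vectors of equal length.
#' @param equatorial logical; is this equatorial intensity?
#' @param metadata list of provenance entries.
#' @rdname SaxsProfile-class
#' @export
SaxsProfile <- function(q, intensity, sigma = rep(1, length(q)),
                        equatorial = FALSE, metadata = list()) {
  new("SaxsProfile",
    q = as.numeric(q), intensity = as.numeric(intensity),
    sigma = as.numeric(sigma), equatorial = isTRUE(equatorial),
    metadata = metadata
  )
}

#' RealSpaceFunction: P(r) or a(r) on an r grid
#'
#' A real-space pair distribution function (kind \code{"pdf"}) or correlation
#' function (kind \code{"correlation"}) in either \code{"spherical"} geometry
#' (all interatomic vectors, r^2-weighted) or \code{"cross_section"} geometry
#' (vectors projected onto the plane perpendicular to the fibril axis,
#' r-weighted).
#'
#' @slot r increasing nonnegative grid (Angstrom).
#' @slot values numeric, same length as r.
#' @slot geometry "spherical" or "cross_section".
#' @slot kind "pdf" or "correlation".
#' @slot normalized logical; TRUE when a correlation has been scaled to a(0)=1.
#' @slot metadata list (fit diagnostics, q window, d_max, ...).
#' @export
setClass("RealSpaceFunction",
  representation(
    r = "numeric",
    values = "numeric",
    geometry = "character",
    kind = "character",
    normalized = "logical",
    metadata = "list"
  ),
  prototype(normalized = FALSE, metadata = list())
)

setValidity("RealSpaceFunction", function(object) {
  msg <- NULL
  n <- length(object@r)
  if (n < 2L) msg <- c(msg, "need at least two r points")
  if (length(object@values) != n) msg <- c(msg, "values length != r length")
  if (any(object@r < 0)) msg <- c(msg, "r must be >= 0")
  if (n > 1L && any(diff(object@r) <= 0)) msg <- c(msg, "r must be strictly increasing")
  if (!object@geometry %in% c("spherical", "cross_section"))
    msg <- c(msg, "geometry must be 'spherical' or 'cross_section'")
  if (!object@kind %in% c("pdf", "correlation"))
    msg <- c(msg, "kind must be 'pdf' or 'correlation'")
  if (is.null(msg)) TRUE else msg
})

#' @param r,values numeric vectors of equal length.
#' @param geometry "spherical" or "cross_section".
#' @param kind "pdf" or "correlation".
#' @param normalized logical.
#' @param metadata list.
#' @rdname RealSpaceFunction-class
#' @export
RealSpaceFunction <- function(r, values, geometry = c("spherical", "cross_section"),
                              kind = c("pdf", "correlation"),
                              normalized = FALSE, metadata = list()) {
  new("RealSpaceFunction",
    r = as.numeric(r), values = as.numeric(values),
    geometry = match.arg(geometry), kind = match.arg(kind),
    normalized = isTRUE(normalized), metadata = metadata
  )
}

#' CylinderSpec: a solid-cylinder scattering model
#'
#' Radius and length of a solid cylinder of uniform scattering-length-density
#' contrast, the low-resolution stand-in for a fibril.
#'
#' @slot radius cylinder radius (Angstrom), > 0.
#' @slot length cylinder length (Angstrom), > 0.
#' @slot contrast scattering-length density difference (arbitrary units).
#' @export
setClass("CylinderSpec",
  representation(radius = "numeric", length = "numeric", contrast = "numeric"),
  prototype(contrast = 1)
)

setValidity("CylinderSpec", function(object) {
  msg <- NULL
  if (length(object@radius) != 1L || !is.finite(object@radius) || object@radius <= 0)
    msg <- c(msg, "radius must be a single positive number")
  if (length(object@length) != 1L || !is.finite(object@length) || object@length <= 0)
    msg <- c(msg, "length must be a single positive number")
  if (length(object@contrast) != 1L || !is.finite(object@contrast))
    msg <- c(msg, "contrast must be a single finite number")
  if (is.null(msg)) TRUE else msg
})

#' @param radius,length,contrast see slots.
#' @rdname CylinderSpec-class
#' @export
CylinderSpec <- function(radius, length, contrast = 1) {
  new("CylinderSpec", radius = as.numeric(radius), length = as.numeric(length),
      contrast = as.numeric(contrast))
}

#' AtomSet: point scatterers with form factors
#'
#' Atomic (or pseudo-atomic) coordinates with per-atom scattering factors
#' f_i, taken q-independent by default. Scattering depends only on the
#' pairwise distances r_ij and the f_i.
#'
#' @slot coords n x 3 numeric matrix of positions (Angstrom).
#' @slot f numeric vector of per-atom scattering factors.
#' @export
setClass("AtomSet", representation(coords = "matrix", f = "numeric"))

setValidity("AtomSet", function(object) {
  msg <- NULL
  if (!is.numeric(object@coords) || ncol(object@coords) != 3L)
    msg <- c(msg, "coords must be an n x 3 numeric matrix")
  if (nrow(object@coords) < 1L) msg <- c(msg, "need at least one atom")
  if (any(!is.finite(object@coords))) msg <- c(msg, "coordinates must be finite")
  if (length(object@f) != nrow(object@coords))
    msg <- c(msg, "one form factor per atom required")
  if (any(!is.finite(object@f))) msg <- c(msg, "form factors must be finite")
  if (is.null(msg)) TRUE else msg
})

#' @param coords n x 3 matrix of coordinates (Angstrom).
#' @param f per-atom scattering factors (default 1).
#' @rdname AtomSet-class
#' @export
AtomSet <- function(coords, f = rep(1, nrow(coords))) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  new("AtomSet", coords = coords, f = as.numeric(f))
}

#' IFTConfig: settings for the indirect Fourier transform
#'
#' @slot dMax maximum vector length of the real-space model (Angstrom);
#'   \code{NA} means automatic, \code{dMax = 2*pi/qMin}, the lower-bound
#'   convention for correlations whose true extent is not measurable.
#' @slot nBasis number of cubic B-spline basis functions (>= 4).
#' @slot smoothness second-difference regularization weight; \code{NA} selects
#'   it by a deterministic L-curve corner search.
#' @slot qMin,qMax fit window (1/Angstrom).
#' @slot geometry "spherical" or "cross_section".
#' @export
setClass("IFTConfig",
  representation(
    dMax = "numeric", nBasis = "numeric", smoothness = "numeric",
    qMin = "numeric", qMax = "numeric", geometry = "character"
  )
)

setValidity("IFTConfig", function(object) {
  msg <- NULL
  if (!is.na(object@dMax) && object@dMax <= 0) msg <- c(msg, "dMax must be > 0 when set")
  if (object@nBasis < 4) msg <- c(msg, "nBasis must be >= 4")
  if (!is.na(object@smoothness) && object@smoothness < 0)
    msg <- c(msg, "smoothness must be >= 0")
  if (object@qMin >= object@qMax) msg <- c(msg, "qMin must be < qMax")
  if (!object@geometry %in% c("spherical", "cross_section"))
    msg <- c(msg, "geometry must be 'spherical' or 'cross_section'")
  if (is.null(msg)) TRUE else msg
})

#' @param dMax,nBasis,smoothness,qMin,qMax,geometry see slots.
#' @rdname IFTConfig-class
#' @export
IFTConfig <- function(dMax = NA_real_, nBasis = 30, smoothness = NA_real_,
                      qMin = 0, qMax = Inf,
                      geometry = c("cross_section", "spherical")) {
  new("IFTConfig", dMax = as.numeric(dMax), nBasis = as.numeric(nBasis),
      smoothness = as.numeric(smoothness), qMin = as.numeric(qMin),
      qMax = as.numeric(qMax), geometry = match.arg(geometry))
}

#' DetectorGeometry: 2D detector geometry for azimuthal averaging
#'
#' Maps detector pixels to momentum transfer through
#' \code{q = (4*pi/lambda) * sin(atan2(radius_mm, distance)/2)}.
#'
#' @slot beamCenter length-2 pixel coordinates (x, y) of the direct beam.
#' @slot pixelSize pixel size (mm).
#' @slot distance sample-to-detector distance (mm).
#' @slot wavelength X-ray wavelength (Angstrom).
#' @export
setClass("DetectorGeometry",
  representation(beamCenter = "numeric", pixelSize = "numeric",
                 distance = "numeric", wavelength = "numeric")
)

setValidity("DetectorGeometry", function(object) {
  msg <- NULL
  if (length(object@beamCenter) != 2L) msg <- c(msg, "beamCenter must have length 2")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@distance <= 0) msg <- c(msg, "distance must be > 0")
  if (object@wavelength <= 0) msg <- c(msg, "wavelength must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' @param beamCenter,pixelSize,distance,wavelength see slots.
#' @rdname DetectorGeometry-class
#' @export
DetectorGeometry <- function(beamCenter, pixelSize, distance, wavelength) {
  new("DetectorGeometry", beamCenter = as.numeric(beamCenter),
      pixelSize = as.numeric(pixelSize), distance = as.numeric(distance),
      wavelength = as.numeric(wavelength))
}

#' ScanGrid: a raster of scattering profiles
#'
#' A scanning-microdiffraction raster: one circularly averaged profile per
#' grid cell, all sharing a common q grid. Extends
#' \linkS4class{SummarizedExperiment}: rows are q points, columns are scan
#' cells; assays \code{"intensity"} and \code{"sigma"}; \code{colData} holds
#' the integer cell indices \code{ix}, \code{iy} and stage positions \code{x},
#' \code{y} (micrometre). Grid dimensions \code{nx}, \code{ny} and the step
#' size (micrometre) are in \code{metadata()}.
#'
#' @export
setClass("ScanGrid", contains = "SummarizedExperiment")

setValidity("ScanGrid", function(object) {
  msg <- NULL
  if (!all(c("intensity", "sigma") %in% names(assays(object))))
    msg <- c(msg, "assays 'intensity' and 'sigma' required")
  md <- metadata(object)
  if (!all(c("nx", "ny", "step", "q") %in% names(md)))
    msg <- c(msg, "metadata must contain nx, ny, step, q")
  cd <- colData(object)
  if (!all(c("ix", "iy", "x", "y") %in% names(cd)))
    msg <- c(msg, "colData must contain ix, iy, x, y")
  if (is.null(msg)) {
    if (ncol(object) != md$nx * md$ny)
      msg <- c(msg, "number of cells must equal nx * ny")
    if (length(md$q) != nrow(object))
      msg <- c(msg, "metadata q must match the number of rows")
  }
  if (is.null(msg)) TRUE else msg
})

#' @param q common momentum-transfer grid (1/Angstrom).
#' @param intensity,sigma matrices, \code{length(q)} rows and \code{nx*ny}
#'   columns; cells ordered with \code{ix} varying fastest.
#' @param nx,ny grid dimensions (cells per axis).
#' @param step scan step (micrometre).
#' @param origin stage position of cell (1, 1), micrometre.
#' @rdname ScanGrid-class
#' @export
ScanGrid <- function(q, intensity, sigma = NULL, nx, ny, step = 5,
                     origin = c(0, 0)) {
  intensity <- as.matrix(intensity)
  if (is.null(sigma)) sigma <- matrix(1, nrow(intensity), ncol(intensity))
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  cd <- DataFrame(ix = ix, iy = iy,
                  x = origin[1] + (ix - 1) * step,
                  y = origin[2] + (iy - 1) * step)
  se <- SummarizedExperiment(
    assays = SimpleList(intensity = intensity, sigma = as.matrix(sigma)),
    colData = cd,
    metadata = list(nx = as.integer(nx), ny = as.integer(ny),
                    step = as.numeric(step), q = as.numeric(q))
  )
  new("ScanGrid", se)
}

#' BackgroundModel: fitted tissue-subtraction scale factor
#'
#' Result of the two-reference subtraction
#' \code{I = (I_l - I_b) - a (I_t - I_b)}: the scale factor \code{a} chosen to
#' minimize the lesion-minus-background residual over \code{fitRange}
#' (default 1.6 < q < 2.0 1/Angstrom, where fibrillar scattering is weak), and
#' the rms residual achieved there.
#'
#' @slot a dimensionless tissue scale factor.
#' @slot fitRange length-2 q window (1/Angstrom).
#' @slot residual rms residual of the subtracted intensity in the fit range.
#' @export
setClass("BackgroundModel",
  representation(a = "numeric", fitRange = "numeric", residual = "numeric")
)

setValidity("BackgroundModel", function(object) {
  msg <- NULL
  if (!is.finite(object@a)) msg <- c(msg, "a must be finite")
  if (length(object@fitRange) != 2L || object@fitRange[1] >= object@fitRange[2])
    msg <- c(msg, "fitRange must be (q_lo, q_hi) with q_lo < q_hi")
  if (is.null(msg)) TRUE else msg
})

#' @param a,fitRange,residual see slots.
#' @rdname BackgroundModel-class
#' @export
BackgroundModel <- function(a, fitRange = c(1.6, 2.0), residual = NA_real_) {
  new("BackgroundModel", a = as.numeric(a), fitRange = as.numeric(fitRange),
      residual = as.numeric(residual))
}

#' HeatMap: per-cell cross-beta peak intensity
#'
#' Baseline-subtracted integrated intensity in a narrow window around the
#' cross-beta reflection, one nonnegative value per scan cell.
#'
#' @slot values nx x ny matrix of nonnegative intensities (row = ix, col = iy).
#' @slot qCenter,qHalfWidth integration window (1/Angstrom).
#' @export
setClass("HeatMap",
  representation(values = "matrix", qCenter = "numeric", qHalfWidth = "numeric")
)

setValidity("HeatMap", function(object) {
  msg <- NULL
  if (any(object@values < 0, na.rm = TRUE)) msg <- c(msg, "values must be nonnegative")
  if (object@qHalfWidth <= 0) msg <- c(msg, "qHalfWidth must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' @param values,qCenter,qHalfWidth see slots.
#' @rdname HeatMap-class
#' @export
HeatMap <- function(values, qCenter = 1.337, qHalfWidth = 0.03) {
  new("HeatMap", values = as.matrix(values), qCenter = as.numeric(qCenter),
      qHalfWidth = as.numeric(qHalfWidth))
}
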