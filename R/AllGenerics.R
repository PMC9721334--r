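#' Accessors
#'
#' Small accessor generics for the scattering containers: \code{qValues} and
#' \code{intensities}/\code{sigmas} for profiles and scan grids,
#' \code{isEquatorial} for the equatorial flag, \code{rValues} and
#' \code{fnValues} for real-space functions, \code{gridDims}/\code{stepSize}
#' for scan rasters and \code{heatValues} for heat maps.
#'
#' @param x an object of the appropriate class.
#' @return the corresponding slot contents.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("qValues", function(x) standardGeneric("qValues"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("sigmas", function(x) standardGeneric("sigmas"))
#' @rdname accessors
#' @export
setGeneric("isEquatorial", function(x) standardGeneric("isEquatorial"))
#' @rdname accessors
#' @export
setGeneric("rValues", function(x) standardGeneric("rValues"))
#' @rdname accessors
#' @export
setGeneric("fnValues", function(x) standardGeneric("fnValues"))
#' @rdname accessors
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))
#' @rdname accessors
#' @export
setGeneric("stepSize", function(x) standardGeneric("stepSize"))
#' @rdname accessors
#' @export
setGeneric("heatValues", function(x) standardGeneric("heatValues"))

#' @rdname accessors
setMethod("qValues", "SaxsProfile", function(x) x@q)
#' @rdname accessors
setMethod("intensities", "SaxsProfile", function(x) x@intensity)
#' @rdname accessors
setMethod("sigmas", "SaxsProfile", function(x) x@sigma)
#' @rdname accessors
setMethod("isEquatorial", "SaxsProfile", function(x) x@equatorial)

#' @rdname accessors
setMethod("rValues", "RealSpaceFunction", function(x) x@r)
#' @rdname accessors
setMethod("fnValues", "RealSpaceFunction", function(x) x@values)

#' @rdname accessors
setMethod("qValues", "ScanGrid", function(x) metadata(x)$q)
#' @rdname accessors
setMethod("intensities", "ScanGrid", function(x) assay(x, "intensity"))
#' @rdname accessors
setMethod("sigmas", "ScanGrid", function(x) assay(x, "sigma"))
#' @rdname accessors
setMethod("gridDims", "ScanGrid",
          function(x) c(nx = metadata(x)$nx, ny = metadata(x)$ny))
#' @rdname accessors
setMethod("stepSize", "ScanGrid", function(x) metadata(x)$step)

#' @rdname accessors
setMethod("heatValues", "HeatMap", function(x) x@values)

#' Extract one cell's profile from a scan grid
#'
#' @param scan a \linkS4class{ScanGrid}.
#' @param ix,iy 1-based cell indices along the fast (x) and slow (y) axis.
#' @return a \linkS4class{SaxsProfile}.
#' @export
profileAt <- function(scan, ix, iy) {
  dims <- gridDims(scan)
  if (ix < 1 || ix > dims["nx"] || iy < 1 || iy > dims["ny"])
    stop("cell (", ix, ", ", iy, ") outside the ", dims["nx"], " x ",
         dims["ny"], " grid")
  j <- cellIndex(scan, ix, iy)
  SaxsProfile(qValues(scan), intensities(scan)[, j], sigmas(scan)[, j],
              metadata = list(ix = ix, iy = iy))
}

#' Column index of a scan cell
#'
#' Cells are stored with \code{ix} varying fastest.
#' @inheritParams profileAt
#' @return integer column index into the assay matrices.
#' @export
cellIndex <- function(scan, ix, iy) {
  as.integer((iy - 1) * gridDims(scan)["nx"] + ix)
}

setMethod("show", "SaxsProfile", function(object) {
  cat("SaxsProfile: ", length(object@q), " points, q in [",
      format(min(object@q), digits = 4), ", ",
      format(max(object@q), digits = 4), "] 1/Ang",
      if (object@equatorial) " [equatorial]", "\n", sep = "")
})

setMethod("show", "RealSpaceFunction", function(object) {
  cat("RealSpaceFunction (", object@geometry, " ", object@kind, "): ",
      length(object@r), " points, r in [",
      format(min(object@r), digits = 4), ", ",
      format(max(object@r), digits = 4), "] Ang",
      if (object@normalized) ", normalized", "\n", sep = "")
})

setMethod("show", "CylinderSpec", function(object) {
  cat("CylinderSpec: radius ", object@radius, " Ang, length ", object@length,
      " Ang, contrast ", object@contrast, "\n", sep = "")
})

setMethod("show", "AtomSet", function(object) {
  cat("AtomSet:", nrow(object@coords), "atoms\n")
})

setMethod("show", "BackgroundModel", function(object) {
  cat("BackgroundModel: a = ", format(object@a, digits = 6),
      ", fit range ", object@fitRange[1], "-", object@fitRange[2],
      " 1/Ang, rms residual ", format(object@residual, digits = 4),
      "\n", sep = "")
})

setMethod("show", "HeatMap", function(object) {
  cat("HeatMap: ", nrow(object@values), " x ", ncol(object@values),
      " cells, window ", object@qCenter, " +/- ", object@qHalfWidth,
      " 1/Ang\n", sep = "")
})
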