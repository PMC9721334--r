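## Plain-text I/O. Profiles are 3-column ASCII (q, I, sigma) with '#'-prefixed
## header lines of the form "# key: value"; real-space functions are 2-column
## (r, value) with the geometry, kind and fit window recorded in the header.

.writeHeader <- function(con, fields) {
  writeLines(paste0("# ", names(fields), ": ",
                    vapply(fields, function(v) paste(format(v, digits = 15),
                                                     collapse = " "),
                           character(1))), con)
}

.readHeader <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^#\\s*([^:]+):\\s*(.*)$", hdr))
  out <- list()
  for (m in kv) if (length(m) == 3) out[[trimws(m[2])]] <- trimws(m[3])
  out
}

#' Write a profile to a 3-column ASCII file
#'
#' Columns are q (1/Angstrom), intensity and sigma, preceded by a
#' \code{#}-prefixed header that records the equatorial flag and any metadata
#' entries with scalar values (tool provenance included).
#'
#' @param profile a \linkS4class{SaxsProfile}.
#' @param path output file path.
#' @param extra named list of extra header fields.
#' @export
writeProfile <- function(profile, path, extra = list()) {
  stopifnot(is(profile, "SaxsProfile"))
  con <- file(path, "w")
  on.exit(close(con))
  md <- Filter(function(v) is.atomic(v) && length(v) <= 4, profile@metadata)
  .writeHeader(con, c(list(format = "fibrilSAXS profile",
                           version = as.character(utils::packageVersion("fibrilSAXS")),
                           equatorial = profile@equatorial,
                           columns = "q intensity sigma"),
                      md, extra))
  utils::write.table(
    data.frame(q = qValues(profile), I = intensities(profile), s = sigmas(profile)),
    con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a profile from a 3-column ASCII file
#'
#' Accepts 2- or 3-column files (sigma defaults to 1); \code{#} lines are
#' parsed as header fields and the equatorial flag is restored.
#'
#' @param path input file path.
#' @return a \linkS4class{SaxsProfile}.
#' @export
readProfile <- function(path) {
  hdr <- .readHeader(path)
  tab <- utils::read.table(path, comment.char = "#")
  if (ncol(tab) < 2) stop("profile file needs at least q and intensity columns")
  sigma <- if (ncol(tab) >= 3) tab[[3]] else rep(1, nrow(tab))
  SaxsProfile(tab[[1]], tab[[2]], sigma,
              equatorial = identical(tolower(hdr$equatorial), "true"),
              metadata = hdr)
}

#' Write a real-space function to a 2-column ASCII file
#'
#' @param fn a \linkS4class{RealSpaceFunction}.
#' @param path output file path.
#' @param extra named list of extra header fields.
#' @export
writeRealSpaceFunction <- function(fn, path, extra = list()) {
  stopifnot(is(fn, "RealSpaceFunction"))
  con <- file(path, "w")
  on.exit(close(con))
  md <- Filter(function(v) is.atomic(v) && length(v) <= 4, fn@metadata)
  .writeHeader(con, c(list(format = "fibrilSAXS realspace",
                           version = as.character(utils::packageVersion("fibrilSAXS")),
                           geometry = fn@geometry, kind = fn@kind,
                           normalized = fn@normalized,
                           columns = "r value"),
                      md, extra))
  utils::write.table(data.frame(r = rValues(fn), v = fnValues(fn)),
                     con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a real-space function written by \code{writeRealSpaceFunction}
#'
#' @param path input file path.
#' @return a \linkS4class{RealSpaceFunction}.
#' @export
readRealSpaceFunction <- function(path) {
  hdr <- .readHeader(path)
  tab <- utils::read.table(path, comment.char = "#")
  RealSpaceFunction(tab[[1]], tab[[2]],
                    geometry = hdr$geometry %||% "spherical",
                    kind = hdr$kind %||% "pdf",
                    normalized = identical(tolower(hdr$normalized), "true"),
                    metadata = hdr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a heat map as a CSV matrix
#'
#' One row per iy, one column per ix; the integration window is recorded in
#' \code{#} header lines.
#'
#' @param map a \linkS4class{HeatMap}.
#' @param path output file path.
#' @export
writeHeatMap <- function(map, path) {
  stopifnot(is(map, "HeatMap"))
  con <- file(path, "w")
  on.exit(close(con))
  .writeHeader(con, list(format = "fibrilSAXS heatmap",
                         qCenter = map@qCenter, qHalfWidth = map@qHalfWidth))
  utils::write.table(t(heatValues(map)), con, row.names = FALSE,
                     col.names = FALSE, sep = ",")
  invisible(path)
}

#' Read a heat map CSV written by \code{writeHeatMap}
#'
#' @param path input file path.
#' @return a \linkS4class{HeatMap}.
#' @export
readHeatMap <- function(path) {
  hdr <- .readHeader(path)
  m <- as.matrix(utils::read.table(path, comment.char = "#", sep = ","))
  HeatMap(t(unname(m)),
          qCenter = as.numeric(hdr$qCenter %||% 1.337),
          qHalfWidth = as.numeric(hdr$qHalfWidth %||% 0.03))
}

#' Write a scan grid as a directory of per-cell profiles
#'
#' Creates \code{dir/manifest.txt} recording the raster dimensions and step,
#' plus one 3-column profile file \code{cell_<iy>_<ix>.dat} per cell.
#'
#' @param scan a \linkS4class{ScanGrid}.
#' @param dir output directory (created if missing).
#' @export
writeScanGrid <- function(scan, dir) {
  stopifnot(is(scan, "ScanGrid"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dims <- gridDims(scan)
  con <- file(file.path(dir, "manifest.txt"), "w")
  .writeHeader(con, list(format = "fibrilSAXS scangrid",
                         nx = dims["nx"], ny = dims["ny"],
                         step = stepSize(scan)))
  close(con)
  cd <- colData(scan)
  for (j in seq_len(ncol(scan))) {
    writeProfile(profileAt(scan, cd$ix[j], cd$iy[j]),
                 file.path(dir, sprintf("cell_%03d_%03d.dat", cd$iy[j], cd$ix[j])))
  }
  invisible(dir)
}

#' Read a scan grid directory written by \code{writeScanGrid}
#'
#' @param dir directory containing \code{manifest.txt} and cell files.
#' @return a \linkS4class{ScanGrid}.
#' @export
readScanGrid <- function(dir) {
  man <- .readHeader(file.path(dir, "manifest.txt"))
  nx <- as.integer(man$nx); ny <- as.integer(man$ny)
  step <- as.numeric(man$step)
  q <- NULL
  I <- S <- NULL
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    f <- file.path(dir, sprintf("cell_%03d_%03d.dat", iy, ix))
    if (!file.exists(f))
      stop("scan grid malformed: missing cell (", ix, ", ", iy, ") [", f, "]")
    p <- readProfile(f)
    if (is.null(q)) {
      q <- qValues(p)
      I <- matrix(NA_real_, length(q), nx * ny)
      S <- matrix(NA_real_, length(q), nx * ny)
    } else if (length(qValues(p)) != length(q) || any(qValues(p) != q)) {
      stop("scan grid malformed: cell (", ix, ", ", iy,
           ") is not on the common q grid")
    }
    j <- (iy - 1) * nx + ix
    I[, j] <- intensities(p)
    S[, j] <- sigmas(p)
  }
  ScanGrid(q, I, S, nx = nx, ny = ny, step = step)
}
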