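#' Poisson-noised realization of a model intensity
#'
#' Draws per-point photon counts from a Poisson law with mean
#' \code{exposure * I} and returns counts/exposure with uncertainty
#' \code{sqrt(counts)/exposure} (a count of at least 1 is used for the
#' uncertainty so zero-count points keep a finite sigma). Above a mean of
#' 1e7 counts the Poisson draw switches to its Gaussian limit to avoid
#' integer overflow; the two are indistinguishable at that level. The RNG
#' state of the caller is left untouched; the same seed always reproduces
#' the same realization.
#'
#' @param model a \linkS4class{SaxsProfile} of nonnegative model intensity.
#' @param exposure effective exposure (counts per intensity unit), > 0.
#' @param seed integer seed.
#' @return a noisy \linkS4class{SaxsProfile}.
#' @export
genProfile <- function(model, exposure, seed = 0) {
  stopifnot(is(model, "SaxsProfile"))
  if (exposure <= 0) stop("exposure must be > 0")
  I <- intensities(model)
  if (any(I < 0)) stop("model intensity must be nonnegative")
  lam <- exposure * I
  counts <- .withSeed(seed, {
    big <- lam > 1e7
    out <- numeric(length(lam))
    if (any(!big)) out[!big] <- stats::rpois(sum(!big), lam[!big])
    if (any(big)) out[big] <- round(stats::rnorm(sum(big), lam[big], sqrt(lam[big])))
    out
  })
  SaxsProfile(qValues(model), counts / exposure,
              sqrt(pmax(counts, 1)) / exposure,
              equatorial = isEquatorial(model),
              metadata = c(model@metadata, list(exposure = exposure, seed = seed)))
}

#' Smooth diffuse tissue scattering curve
#'
#' A deterministic stand-in for the diffuse scattering of fixed, dehydrated
#' tissue: a low-q power-law term plus a broad disordered-matter band near
#' q = 1.4 1/Angstrom. The curve has no sharp features; in particular it is
#' featureless across the 1.6-2.0 1/Angstrom background-fit window, which is
#' what makes that window usable for the tissue scale fit. The
#' parameterization is a fixture convention, not a model of real tissue.
#'
#' @param q momentum-transfer grid (1/Angstrom).
#' @param amplitude overall scale (>= 0).
#' @param params list of curve parameters: \code{powerScale}, \code{q0} and
#'   \code{powerExp} for the low-q term
#'   \code{powerScale * (q0/(q0+q))^powerExp}; \code{bumpScale},
#'   \code{bumpCenter}, \code{bumpWidth} for the broad band.
#' @return a \linkS4class{SaxsProfile}.
#' @export
genTissueProfile <- function(q, amplitude = 1,
                             params = list(powerScale = 30, q0 = 0.05,
                                           powerExp = 3, bumpScale = 5,
                                           bumpCenter = 1.4, bumpWidth = 0.35)) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  p <- params
  I <- amplitude * (p$powerScale * (p$q0 / (p$q0 + q))^p$powerExp +
                    p$bumpScale * exp(-(q - p$bumpCenter)^2 / (2 * p$bumpWidth^2)))
  SaxsProfile(q, I, metadata = list(model = "tissue_diffuse", amplitude = amplitude))
}

#' Specification of a synthetic scanning-microdiffraction experiment
#'
#' Bundles the parameters of a synthetic scan grid: raster dimensions and
#' step, plaque (lesion) disks, the fibril model inside the plaques (a solid
#' cylinder plus a sharp cross-beta Gaussian peak at q = 1.337 1/Angstrom),
#' the tissue density inside vs outside plaques, substrate spikes standing in
#' for mica reflections, exposure and seed.
#'
#' @param nx,ny grid dimensions (cells).
#' @param step scan step (micrometre).
#' @param q common q grid; defaults to a grid dense at low q (for
#'   cross-section analysis) and extending past 2.0 (for the background fit).
#' @param plaqueCenters matrix of plaque centers, columns ix, iy.
#' @param plaqueRadii plaque radii (cells).
#' @param fibril a \linkS4class{CylinderSpec} for the fibril form factor.
#' @param fibrilAmp amplitude of the fibril SAXS curve (I(0) scaled to this).
#' @param peakHeight height of the cross-beta peak above the diffuse curve.
#' @param peakWidth Gaussian sigma of the cross-beta peak (1/Angstrom).
#' @param tissueAmp tissue diffuse amplitude outside plaques.
#' @param plaqueTissueScale factor on tissue density inside plaques (lesions
#'   are typically somewhat denser than adjacent tissue).
#' @param substrateAmp substrate diffuse amplitude.
#' @param spikePositions q positions of sharp substrate peaks (1/Angstrom).
#' @param exposure counts per intensity unit for the Poisson noise.
#' @param seed integer seed.
#' @return a list of class "SyntheticScanSpec".
#' @export
syntheticScanSpec <- function(nx = 21, ny = 21, step = 5,
                              q = c(seq(0.005, 0.3, length.out = 160),
                                    seq(0.305, 2.1, length.out = 260)),
                              plaqueCenters = matrix(c(11, 11), ncol = 2),
                              plaqueRadii = 4,
                              fibril = CylinderSpec(35, 1000),
                              fibrilAmp = 60,
                              peakHeight = 12,
                              peakWidth = 0.01,
                              tissueAmp = 1,
                              plaqueTissueScale = 1.3,
                              substrateAmp = 0.5,
                              spikePositions = c(0.62, 0.95, 1.48),
                              exposure = 2000,
                              seed = 0) {
  plaqueCenters <- matrix(plaqueCenters, ncol = 2)
  if (any(plaqueCenters[, 1] < 1) || any(plaqueCenters[, 1] > nx) ||
      any(plaqueCenters[, 2] < 1) || any(plaqueCenters[, 2] > ny))
    stop("plaque centers must lie inside the grid")
  if (fibrilAmp < 0 || peakHeight < 0 || tissueAmp < 0 || substrateAmp < 0)
    stop("amplitudes must be nonnegative")
  structure(list(nx = nx, ny = ny, step = step, q = q,
                 plaqueCenters = plaqueCenters,
                 plaqueRadii = rep(plaqueRadii, length.out = nrow(plaqueCenters)),
                 fibril = fibril, fibrilAmp = fibrilAmp,
                 peakHeight = peakHeight, peakWidth = peakWidth,
                 tissueAmp = tissueAmp, plaqueTissueScale = plaqueTissueScale,
                 substrateAmp = substrateAmp, spikePositions = spikePositions,
                 exposure = exposure, seed = seed),
            class = "SyntheticScanSpec")
}

#' Generate a synthetic scan grid with ground truth
#'
#' Builds the per-cell profiles of a synthetic scanning experiment: every
#' cell receives substrate scattering (smooth curve plus sharp spikes) and
#' tissue diffuse scattering scaled by a local density; cells inside a
#' plaque disk additionally receive the fibril curve (isotropic solid
#' cylinder intensity, normalized to \code{fibrilAmp} at its first q point)
#' and the sharp cross-beta Gaussian at 1.337 1/Angstrom, with tissue density
#' raised by \code{plaqueTissueScale}. Each cell is Poisson-noised with a
#' cell-specific seed derived from the spec seed, so the whole grid is
#' bit-reproducible.
#'
#' @param spec a spec from \code{\link{syntheticScanSpec}}.
#' @return list with \code{scan} (\linkS4class{ScanGrid}) and \code{truth}, a
#'   list holding the plaque mask (nx x ny logical), the tissue density
#'   matrix, the clean fibril-only profile (\linkS4class{SaxsProfile}), the
#'   clean substrate and unit-tissue profiles, and the tissue scale inside
#'   plaques.
#' @export
genScan <- function(spec) {
  stopifnot(inherits(spec, "SyntheticScanSpec"))
  q <- spec$q
  ## component curves
  substrate <- spec$substrateAmp *
    (0.6 + 0.4 * exp(-q / 0.8) +
     Reduce(`+`, lapply(spec$spikePositions,
                        function(p) 8 * exp(-(q - p)^2 / (2 * 0.006^2))),
            accumulate = FALSE))
  tissueUnit <- intensities(genTissueProfile(q, amplitude = 1))
  fib <- intensities(isotropicCylinderIntensity(q, spec$fibril))
  fibCurve <- spec$fibrilAmp * fib / fib[1] +
    spec$peakHeight * exp(-(q - 1.337)^2 / (2 * spec$peakWidth^2))

  nx <- spec$nx; ny <- spec$ny
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  plaque <- rep(FALSE, nx * ny)
  for (k in seq_len(nrow(spec$plaqueCenters))) {
    d <- sqrt((ix - spec$plaqueCenters[k, 1])^2 + (iy - spec$plaqueCenters[k, 2])^2)
    plaque <- plaque | (d <= spec$plaqueRadii[k])
  }
  ## smooth deterministic tissue-density variation across the raster
  density <- 1 + 0.08 * sin(2 * pi * ix / nx) * cos(2 * pi * iy / ny)
  density <- density * ifelse(plaque, spec$plaqueTissueScale, 1)

  Imat <- matrix(0, length(q), nx * ny)
  Smat <- matrix(0, length(q), nx * ny)
  for (j in seq_len(nx * ny)) {
    model <- substrate + spec$tissueAmp * density[j] * tissueUnit +
      if (plaque[j]) fibCurve else 0
    noisy <- genProfile(SaxsProfile(q, model), spec$exposure,
                        seed = spec$seed * 100003L + j)
    Imat[, j] <- intensities(noisy)
    Smat[, j] <- sigmas(noisy)
  }
  scan <- ScanGrid(q, Imat, Smat, nx = nx, ny = ny, step = spec$step)
  list(scan = scan,
       truth = list(plaqueMask = matrix(plaque, nx, ny),
                    density = matrix(density, nx, ny),
                    fibrilProfile = SaxsProfile(q, fibCurve),
                    substrateProfile = SaxsProfile(q, substrate),
                    tissueUnitProfile = SaxsProfile(q, tissueUnit),
                    plaqueTissueScale = spec$plaqueTissueScale))
}

#' Specification of a 2D liquid-like packing
#'
#' Parameters of a hard-core random packing of parallel cylinders seen in
#' cross-section: particle count, box side, minimum center-to-center
#' distance, and optionally a target mean nearest-neighbor distance to which
#' the hard core is tuned.
#'
#' @param nParticles number of centers (>= 1).
#' @param box box side length (Angstrom).
#' @param hardCore minimum center distance (Angstrom).
#' @param targetNN desired mean nearest-neighbor distance (Angstrom), or NA
#'   to use \code{hardCore} as given.
#' @param seed integer seed.
#' @return a list of class "PackingSpec".
#' @export
packingSpec <- function(nParticles = 200, box = 3650, hardCore = 150,
                        targetNN = 275, seed = 0) {
  if (nParticles < 1) stop("nParticles must be >= 1")
  if (!is.na(targetNN) && (hardCore > targetNN || targetNN >= box))
    stop("need hardCore <= targetNN < box")
  structure(list(nParticles = nParticles, box = box, hardCore = hardCore,
                 targetNN = targetNN, seed = seed),
            class = "PackingSpec")
}

## One sequential hard-core insertion run. Returns centers or NULL if the
## requested density cannot be packed.
.insertPacking <- function(n, box, hc, seed, maxAttempts = 400L * n) {
  .withSeed(seed, {
    pts <- matrix(NA_real_, n, 2)
    placed <- 0L
    attempts <- 0L
    hc2 <- hc^2
    while (placed < n && attempts < maxAttempts) {
      cand <- stats::runif(2, 0, box)
      attempts <- attempts + 1L
      if (placed == 0L ||
          min((pts[seq_len(placed), 1] - cand[1])^2 +
              (pts[seq_len(placed), 2] - cand[2])^2) >= hc2) {
        placed <- placed + 1L
        pts[placed, ] <- cand
      }
    }
    if (placed < n) NULL else pts
  })
}

.meanNN <- function(pts) {
  D <- as.matrix(stats::dist(pts))
  diag(D) <- Inf
  mean(apply(D, 1, min))
}

## Deterministic soft-repulsion relaxation: every pair closer than d0 pushes
## apart in proportion to its overlap, particles clamped to the box. Emulates
## the mutual repulsion that makes a concentrated gel a partially ordered,
## liquid-like packing; pure sequential insertion alone leaves too broad a
## first coordination shell. Monotonically opens small distances, so a hard
## core established at insertion is preserved.
.relaxPacking <- function(pts, box, d0, nIter = 150L, step = 0.45) {
  n <- nrow(pts)
  for (it in seq_len(nIter)) {
    D <- as.matrix(stats::dist(pts))
    moved <- pts
    for (i in seq_len(n)) {
      nb <- which(D[i, ] > 0 & D[i, ] < d0)
      if (length(nb)) {
        dir <- (matrix(pts[i, ], length(nb), 2, byrow = TRUE) -
                pts[nb, , drop = FALSE]) / D[i, nb]
        push <- colSums(dir * (d0 - D[i, nb]))
        moved[i, ] <- pts[i, ] + step * push / max(1, length(nb))
      }
    }
    moved[, 1] <- pmin(pmax(moved[, 1], 0), box)
    moved[, 2] <- pmin(pmax(moved[, 2], 0), box)
    pts <- moved
  }
  pts
}

#' Generate a 2D liquid-like packing of cylinder centers
#'
#' Sequential random insertion with hard-core rejection in a square box,
#' followed (when \code{targetNN} is set) by a deterministic soft-repulsion
#' relaxation that emulates the mutual repulsion of particles in a
#' concentrated gel: pairs closer than a repulsion range push apart until
#' the packing is partially ordered and liquid-like, with a sharp first
#' coordination shell. The repulsion range is tuned by bisection until the
#' realized mean nearest-neighbor distance is within 2 percent of
#' \code{targetNN}. Without a target, the raw seeded insertion at
#' \code{hardCore} is returned. A density feasibility check
#' (\code{n * pi * (hc/2)^2 < 0.5 * box^2}) rejects impossible requests.
#' All steps are bit-reproducible given (spec, seed).
#'
#' @param spec a \code{\link{packingSpec}}.
#' @return list with \code{centers} (n x 2 matrix, Angstrom),
#'   \code{hardCore} (the insertion hard core), \code{repulsionRange} (the
#'   tuned relaxation range, NA when no relaxation ran) and \code{meanNN}
#'   (realized mean nearest-neighbor distance).
#' @export
genPacking2D <- function(spec) {
  stopifnot(inherits(spec, "PackingSpec"))
  n <- spec$nParticles
  box <- spec$box
  feasible <- function(hc) n * pi * (hc / 2)^2 < 0.5 * box^2
  if (!feasible(spec$hardCore))
    stop("requested density infeasible: n*pi*(hardCore/2)^2 must be < 0.5*box^2")
  if (n == 1L) {
    pts <- .withSeed(spec$seed, matrix(stats::runif(2, 0, box), 1, 2))
    return(list(centers = pts, hardCore = spec$hardCore,
                repulsionRange = NA_real_, meanNN = NA_real_))
  }
  pts0 <- .insertPacking(n, box, spec$hardCore, spec$seed)
  if (is.null(pts0)) stop("packing failed at the requested hard core")
  if (is.na(spec$targetNN)) {
    return(list(centers = pts0, hardCore = spec$hardCore,
                repulsionRange = NA_real_, meanNN = .meanNN(pts0)))
  }
  target <- spec$targetNN
  lo <- 0.9 * target
  hi <- 1.2 * target
  best <- NULL
  for (it in seq_len(12)) {
    d0 <- (lo + hi) / 2
    pts <- .relaxPacking(pts0, box, d0)
    m <- .meanNN(pts)
    if (is.null(best) || abs(m - target) < abs(best$meanNN - target))
      best <- list(centers = pts, hardCore = spec$hardCore,
                   repulsionRange = d0, meanNN = m)
    if (abs(m - target) <= 0.02 * target) break
    if (m < target) lo <- d0 else hi <- d0
  }
  if (abs(best$meanNN - target) > 0.02 * target)
    warning("relaxation ended with mean NN ", round(best$meanNN, 1),
            " vs target ", target,
            "; the box may be too small or too large for this spacing")
  best
}

#' Equatorial intensity of parallel cylinders with interference
#'
#' Oriented-parallel-rod model of a concentrated gel: the equatorial
#' intensity is the single-cylinder equatorial form factor modulated by the
#' 2D structure factor of the center positions,
#' \deqn{I_e(q) = |F_{eq}(q)|^2 \Big(1 + \frac{2}{N}\sum_{j<k} J_0(q\, d_{jk})\Big),}
#' with \eqn{F_{eq}} the infinite-cylinder equatorial amplitude (per unit
#' length). S(q) tends to 1 at large q and in the dilute limit, where the
#' intensity reduces to the isolated-particle form factor.
#'
#' @param centers n x 2 matrix of cylinder centers (Angstrom).
#' @param cyl a \linkS4class{CylinderSpec} (its radius and contrast are used;
#'   the equatorial amplitude is taken per unit length).
#' @param q momentum-transfer grid (1/Angstrom).
#' @return a \linkS4class{SaxsProfile} flagged equatorial, with the structure
#'   factor stored in its metadata as \code{structureFactor}.
#' @export
interferenceEquatorialIntensity <- function(centers, cyl, q) {
  stopifnot(is(cyl, "CylinderSpec"))
  centers <- matrix(centers, ncol = 2)
  n <- nrow(centers)
  if (n < 1) stop("need at least one center")
  Feq <- cyl@contrast * pi * cyl@radius^2 * .jinc(q * cyl@radius)
  S <- rep(1, length(q))
  if (n > 1) {
    d <- as.vector(stats::dist(centers))
    ## chunk the q x pairs Bessel evaluation to bound memory
    csize <- max(1L, floor(5e6 / length(d)))
    for (i0 in seq(1L, length(q), by = csize)) {
      ii <- i0:min(length(q), i0 + csize - 1L)
      S[ii] <- 1 + (2 / n) * as.vector(
        matrix(besselJ(outer(q[ii], d), 0), nrow = length(ii)) %*% rep(1, length(d)))
    }
  }
  SaxsProfile(q, Feq^2 * S, equatorial = TRUE,
              metadata = list(structureFactor = S, nParticles = n))
}
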