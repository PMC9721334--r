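## Shared oracle constructions, independent of the code paths they check.

## Volume-weighted cylindrical quadrature lattice: rings x angle x z with
## cell-volume form factors. A deterministic point model of a solid cylinder
## for the Debye-formula cross-check of the orientational average.
cylinderLattice <- function(R, h, sp) {
  nr <- max(3L, round(R / sp)); dr <- R / nr
  nz <- max(3L, round(h / sp)); dz <- h / nz
  pts <- NULL; w <- NULL
  for (k in seq_len(nr)) {
    rr <- (k - 0.5) * dr
    nphi <- max(6L, round(2 * pi * rr / dr))
    phi <- 2 * pi * (seq_len(nphi) - 0.5) / nphi
    pts <- rbind(pts, cbind(rr * cos(phi), rr * sin(phi)))
    w <- c(w, rep(((k * dr)^2 - ((k - 1) * dr)^2) * pi / nphi, nphi))
  }
  zs <- (seq_len(nz) - 0.5) * dz
  AtomSet(cbind(pts[rep(seq_len(nrow(pts)), nz), ], rep(zs, each = nrow(pts))),
          rep(w, nz) * dz)
}

## Exact equatorial intensity of an infinite cylinder (per unit length,
## unit contrast): the Airy pattern squared.
airyEquatorial <- function(q, R) {
  x <- q * R
  j <- ifelse(x == 0, 1, 2 * besselJ(x, 1) / x)
  (pi * R^2 * j)^2
}

## Monte-Carlo histogram of pairwise distances between points uniform in a
## disk of radius R: the projected-distance oracle for the cross-section PDF.
diskPairDistanceHist <- function(R, nPoints, breaks, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  rr <- R * sqrt(runif(nPoints)); th <- runif(nPoints, 0, 2 * pi)
  d <- as.vector(dist(cbind(rr * cos(th), rr * sin(th))))
  hist(d, breaks = breaks, plot = FALSE)
}

## First positive root of J1 by scanning and bisection (no closed form used).
besselJ1FirstRoot <- function() {
  xs <- seq(0.1, 5, by = 0.1)
  s <- besselJ(xs, 1)
  i <- which(s[-1] * s[-length(s)] < 0)[1]
  lo <- xs[i]; hi <- xs[i + 1]
  for (k in 1:80) {
    mid <- (lo + hi) / 2
    if (besselJ(lo, 1) * besselJ(mid, 1) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

## Standard q grid used by the cylinder pipelines in the tests.
saxsQGrid <- function(n = 300) seq(0.004, 0.3, length.out = n)

## Location of the first positive local maximum of a correlation function
## beyond rMin (linear grid assumed).
firstPositiveMaxBeyond <- function(fn, rMin) {
  r <- rValues(fn); v <- fnValues(fn)
  sel <- which(r > rMin & r < max(r))
  i <- sel[which(diff(sign(diff(v[sel]))) == -2) + 1]
  r[i][v[i] > 0][1]
}
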