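## Internal numerical helpers.

## sin(x)/x with the removable singularity evaluated at its limit.
.sinc <- function(x) {
  out <- rep(1, length(x))
  nz <- x != 0
  out[nz] <- sin(x[nz]) / x[nz]
  out
}

## 2*J1(x)/x with the removable singularity evaluated at its limit.
.jinc <- function(x) {
  out <- rep(1, length(x))
  nz <- x != 0
  out[nz] <- 2 * besselJ(x[nz], 1) / x[nz]
  out
}

## Trapezoid rule on an arbitrary grid; also returns weights when asked so the
## same quadrature can be folded into design matrices.
.trapzWeights <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least two points for quadrature")
  dx <- diff(x)
  w <- numeric(n)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2L) w[2:(n - 1)] <- (dx[-1] + dx[-(n - 1)]) / 2
  w
}

.trapz <- function(x, y) sum(.trapzWeights(x) * y)

## Run `expr` with a local RNG state seeded at `seed`, restoring the caller's
## state afterwards so generators never perturb user code.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}
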