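#' @keywords internal
"_PACKAGE"

## Shared small helpers: seeded evaluation, seed splitting, rotations,
## numeric validation. Nothing here is exported.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic seed-splitting: derive sub-seed `i` from a master seed.
# Affine map modulo a Mersenne prime keeps results in 32-bit integer range.
split_seed <- function(seed, i) {
  m <- 2147483647
  as.integer((as.numeric(seed) %% m * 48271 + as.numeric(i) * 16807) %% m)
}

# Rotation about z by theta (radians).
rot_z <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

rot_x <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3)
}

rot_y <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3)
}

# z-y-z Euler rotation used to orient rigid bodies.
euler_zyz <- function(a, b, g) rot_z(a) %*% rot_y(b) %*% rot_z(g)

stopifnot_finite <- function(x, what = "value") {
  if (!all(is.finite(x))) stop(sprintf("non-finite %s encountered", what))
  invisible(x)
}

# sin(x)/x with the x -> 0 limit.
sinc <- function(x) {
  out <- rep(1, length(x))
  nz <- abs(x) > 1e-12
  out[nz] <- sin(x[nz]) / x[nz]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
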