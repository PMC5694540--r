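# internal helpers shared across modules

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# row-wise cross product for n x 3 matrices
cross3_rows <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

row_norms <- function(m) sqrt(rowSums(m^2))

unit_rows <- function(m) {
  n <- row_norms(m)
  n[n == 0] <- 1
  m / n
}

rot_z <- function(theta_rad) {
  ct <- cos(theta_rad); st <- sin(theta_rad)
  matrix(c(ct, st, 0, -st, ct, 0, 0, 0, 1), 3L, 3L)
}

# Evaluate a function under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# central differences with periodic wrap-around, for cyclic samples
periodic_gradient <- function(x, dt) {
  n <- length(x)
  (x[c(2:n, 1L)] - x[c(n, 1:(n - 1L))]) / (2 * dt)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
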