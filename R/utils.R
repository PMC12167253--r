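#' @keywords internal
"_PACKAGE"

# Numerical helpers shared across modules. All geometry is planar, in mm.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Signed angle (radians) from vector a to vector b, in (-pi, pi].
signed_angle <- function(a, b) {
  atan2(a[1] * b[2] - a[2] * b[1], a[1] * b[1] + a[2] * b[2])
}

rotate2 <- function(v, theta) {
  c(cos(theta) * v[1] - sin(theta) * v[2],
    sin(theta) * v[1] + cos(theta) * v[2])
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) c(0, 0) else v / n
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All generator-style ops funnel through this so
# they are pure functions of (args, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("parameter `%s` must be a single positive number", name),
         call. = FALSE)
  }
  invisible(x)
}

# Fixed-width numeric formatting used by the text file formats so that
# write -> read -> write is byte-identical.
fmt_num <- function(x, digits = 6L) {
  formatC(x, format = "f", digits = digits)
}
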