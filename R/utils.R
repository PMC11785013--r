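#' @importFrom rlang %||% abort warn
#' @importFrom stats rnorm sd var integrate setNames
#' @importFrom utils head tail
NULL

# Coordinate matrix (N x 3) from a structure tibble or a matrix.
coords <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    return(unname(x))
  }
  stopifnot(all(c("x", "y", "z") %in% names(x)))
  unname(cbind(x$x, x$y, x$z))
}

# Replace the coordinates of a structure tibble.
set_coords <- function(structure, xyz) {
  stopifnot(nrow(structure) == nrow(xyz), ncol(xyz) == 3)
  structure$x <- xyz[, 1]
  structure$y <- xyz[, 2]
  structure$z <- xyz[, 3]
  structure
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotation matrix about a unit axis (Euler-Rodrigues form), angle in radians.
rotation_about_axis <- function(axis, angle) {
  u <- unit(axis)
  c0 <- cos(angle)
  s0 <- sin(angle)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) * c0 + s0 * K + (1 - c0) * (u %o% u)
}

# Wrap an angle difference into (-pi, pi].
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  ifelse(y <= -pi, y + 2 * pi, y)
}

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

# Deterministic content hash (md5 of a canonical text rendering).
content_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  txt <- paste(utils::capture.output(str(x, digits.d = 12, list.len = 1e6,
                                         vec.len = 1e6)), collapse = "\n")
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}

# Canonical unordered pair key used for exclusion bookkeeping.
pair_key <- function(i, j) {
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  paste(lo, hi, sep = "-")
}
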