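# Internal geometry and RNG helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("zero-length vector cannot be normalized")
  v / n
}

# Euclidean distances between one point and the rows of a matrix
dist_to <- function(p, xyz) {
  xyz <- matrix(xyz, ncol = 3L)
  sqrt((xyz[, 1] - p[1])^2 + (xyz[, 2] - p[2])^2 + (xyz[, 3] - p[3])^2)
}

# Rodrigues rotation of points (rows of xyz) about the axis through `origin`
# with direction `axis`, by `theta` radians.
rotate_about_axis <- function(xyz, origin, axis, theta) {
  k <- unitv(axis)
  xyz <- sweep(matrix(xyz, ncol = 3L), 2, origin)
  ct <- cos(theta); st <- sin(theta)
  kx <- xyz %*% t(matrix(c(0, -k[3], k[2],
                           k[3], 0, -k[1],
                           -k[2], k[1], 0), 3, 3, byrow = TRUE))
  kdot <- drop(xyz %*% k)
  out <- xyz * ct + kx * st + outer(kdot, k) * (1 - ct)
  sweep(out, 2, origin, `+`)
}

# Signed dihedral angle (degrees, in (-180, 180]) for points p1-p2-p3-p4.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Minimal angular difference to 0 degrees, folding the periodic domain.
angle_dev <- function(theta) {
  d <- abs(((theta + 180) %% 360) - 180)
  d
}

# Numerically stable log(mean(exp(x))).
log_mean_exp <- function(x) {
  stopifnot(length(x) >= 1L)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

# kcal/(mol K); CODATA value rounded as conventional in biophysics.
GAS_CONSTANT_KCAL <- 1.98720e-3
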