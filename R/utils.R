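#' @importFrom rlang abort warn inform .data %||%
#' @importFrom stats cor rnorm runif sd quantile median coef fitted setNames
#' @importFrom utils head tail
NULL

# internal: degrees <-> radians
deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# map angles (degrees) into [-90, 90): fiber orientations are axial (mod 180)
wrap_axial <- function(a) {
  a <- a %% 180
  ifelse(a >= 90, a - 180, a)
}

# normalize a vector to unit length
unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) abort("cannot normalize a zero vector")
  v / n
}

# pad a 2- or 3-vector (x, y[, z]) to length 3 with zeros
as_xyz <- function(v, what = "vector") {
  if (!is.numeric(v) || !(length(v) %in% c(2L, 3L))) {
    abort(sprintf("`%s` must be a numeric vector of length 2 or 3 (x, y[, z])", what))
  }
  out <- c(v, 0, 0)[1:3]
  names(out) <- c("x", "y", "z")
  out
}

# run code with a fixed RNG seed without disturbing the global stream
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Otsu threshold on raw intensities (rescales to [0,1] for EBImage::otsu)
auto_threshold <- function(x) {
  x <- x[is.finite(x)]
  rng <- range(x, finite = TRUE)
  if (diff(rng) == 0) abort("cannot auto-threshold a constant image")
  xn <- (x - rng[1]) / diff(rng)
  thr01 <- EBImage::otsu(matrix(xn, nrow = 1L), range = c(0, 1))
  rng[1] + thr01 * diff(rng)
}

# bilinear sampling of matrix `m` (dims [d1, d2]) at fractional 1-based
# coordinates (i, j); coordinates are clamped to the valid domain
bilinear_sample <- function(m, i, j) {
  d1 <- nrow(m); d2 <- ncol(m)
  i <- pmin(pmax(i, 1), d1)
  j <- pmin(pmax(j, 1), d2)
  i0 <- pmin(floor(i), d1 - 1L); j0 <- pmin(floor(j), d2 - 1L)
  if (d1 == 1L) i0 <- rep(1L, length(i))
  if (d2 == 1L) j0 <- rep(1L, length(j))
  fi <- i - i0; fj <- j - j0
  i1 <- pmin(i0 + 1L, d1); j1 <- pmin(j0 + 1L, d2)
  m[cbind(i0, j0)] * (1 - fi) * (1 - fj) +
    m[cbind(i1, j0)] * fi * (1 - fj) +
    m[cbind(i0, j1)] * (1 - fi) * fj +
    m[cbind(i1, j1)] * fi * fj
}

# 1D Gaussian kernel, truncated at +-ceiling(4*sigma), normalized
gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}
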