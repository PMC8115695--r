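# Collagen fiber orientation analysis: per-pixel orientation from the
# structure tensor, orientation histograms, Gaussian-fit FWHM, and the
# degree of alignment d = (FWHM_max - FWHM) / FWHM_max.

#' Extract fiber orientations from an image region
#'
#' Per-pixel orientation from the structure tensor: image gradients (central
#' differences) are smoothed into the tensor components
#' `Jxx, Jxy, Jyy` with a Gaussian window; the fiber direction is the minor
#' eigenvector of the tensor (perpendicular to the dominant gradient).
#' Orientations are axial, wrapped to `[-90, 90)` degrees, measured from
#' the +x (column) axis toward the +y (row) axis. Pixels are retained when
#' their tensor coherence `(l1 - l2)/(l1 + l2)` exceeds
#' `coherence_threshold` and their gradient energy is above a small
#' fraction of the region maximum; the coherence is returned as a
#' per-sample weight.
#'
#' @param image `Y x X` numeric matrix.
#' @param smoothing_sigma Gaussian window of the tensor smoothing, pixels
#'   (default 1).
#' @param gradient_sigma Gaussian pre-smoothing of the image before
#'   differentiation, pixels (default 1); sharpens the angular response of
#'   the estimator on pixel-discretized, noisy fibers.
#' @param coherence_threshold Minimum coherence to retain a pixel
#'   (default 0.2).
#' @param energy_floor Fraction of the maximum gradient energy below which
#'   pixels are discarded (default 0.02).
#' @return A tibble: `angle_deg` in `[-90, 90)`, `coherence`.
#' @export
extract_angles <- function(image, smoothing_sigma = 1, gradient_sigma = 1,
                           coherence_threshold = 0.2, energy_floor = 0.02) {
  stopifnot(is.matrix(image))
  if (min(dim(image)) < ceiling(4 * smoothing_sigma) + 3) {
    abort("region smaller than the tensor smoothing window")
  }
  if (diff(range(image)) == 0) abort("no gradient information: constant image")
  if (gradient_sigma > 0) image <- EBImage::gblur(image, gradient_sigma)
  # central-difference gradients; image is [y, x]
  kx <- matrix(c(-0.5, 0, 0.5), 1, 3)  # d/dx (along columns)
  gx <- EBImage::filter2(image, kx, boundary = "replicate")
  gy <- EBImage::filter2(image, t(kx), boundary = "replicate")
  jxx <- EBImage::gblur(gx * gx, sigma = smoothing_sigma)
  jyy <- EBImage::gblur(gy * gy, sigma = smoothing_sigma)
  jxy <- EBImage::gblur(gx * gy, sigma = smoothing_sigma)
  energy <- jxx + jyy
  if (max(energy) <= 0) abort("no gradient information: constant image")
  coherence <- sqrt((jxx - jyy)^2 + 4 * jxy^2) / (energy + 1e-12)
  # dominant gradient orientation, then +90 deg for the fiber direction
  grad_angle <- 0.5 * atan2(2 * jxy, jxx - jyy)
  fiber_angle <- wrap_axial(rad2deg(grad_angle) + 90)
  # trim the border where replicate-padding biases the gradients
  b <- ceiling(2 * smoothing_sigma) + 1L
  interior <- matrix(FALSE, nrow(image), ncol(image))
  interior[(b + 1):(nrow(image) - b), (b + 1):(ncol(image) - b)] <- TRUE
  keep <- interior & coherence >= coherence_threshold &
    energy >= energy_floor * max(energy)
  if (!any(keep)) abort("no pixels passed the coherence/energy filters")
  tibble::tibble(angle_deg = fiber_angle[keep], coherence = coherence[keep])
}

#' Orientation histogram over [-90, 90)
#'
#' @param angles A tibble from [extract_angles()], or a numeric vector of
#'   angles in degrees (wrapped axially).
#' @param bin_width Bin width, degrees (default 5; must divide 180).
#' @param weighted If `TRUE` (default) and coherence weights are available,
#'   counts are coherence-weighted.
#' @return A tibble of class `orientation_histogram`: `angle_mid` (bin
#'   centre), `count`; attribute `n` holds the number of samples.
#' @export
orientation_histogram <- function(angles, bin_width = 5, weighted = TRUE) {
  if (is.numeric(angles)) angles <- tibble::tibble(angle_deg = angles)
  stopifnot(180 %% bin_width == 0)
  a <- wrap_axial(angles$angle_deg)
  w <- if (weighted && "coherence" %in% names(angles)) angles$coherence else
    rep(1, length(a))
  edges <- seq(-90, 90, by = bin_width)
  bin <- pmin(floor((a + 90) / bin_width) + 1L, length(edges) - 1L)
  cnt <- vapply(seq_len(length(edges) - 1L),
                function(i) sum(w[bin == i]), numeric(1))
  out <- tibble::tibble(angle_mid = head(edges, -1) + bin_width / 2,
                        count = cnt)
  attr(out, "n") <- length(a)
  attr(out, "bin_width") <- bin_width
  class(out) <- c("orientation_histogram", class(out))
  out
}

#' Fit a Gaussian to an orientation histogram and return its FWHM
#'
#' The histogram is circularly re-centred (its mode shifted to 0°, bins
#' wrapped modulo 180°) to avoid wrap-around artifacts, then a Gaussian
#' `A exp(-(phi - mu)^2 / (2 sigma^2))`, wrapped onto the 180° orientation
#' domain (±180° replicas), is fitted by Levenberg-Marquardt least
#' squares. The fitted width is corrected for bin broadening (Sheppard) and
#' reported as `FWHM = 2 sqrt(2 ln 2) sigma`. A fitted width wider than
#' the 180° domain is clipped to 180° and flagged.
#'
#' @param hist An [orientation_histogram()], or anything accepted by it
#'   (angles are histogrammed with defaults first).
#' @param offset If `TRUE`, add a free constant baseline to the model.
#'   Off by default: the wrapped replicas already describe an isotropic
#'   background, and a free baseline is degenerate with them for wide
#'   distributions.
#' @return An object of class `fwhm_fit`: list with `fwhm_deg`,
#'   `sigma_deg`, `mu_deg` (mode position in original coordinates),
#'   `amplitude`, `offset`, `r_squared`, `clipped`, `n_bins`, `fit` (the
#'   `nls` object), `hist`. Supports [generics::tidy()] /
#'   [generics::glance()] and `autoplot()`.
#' @export
fit_fwhm <- function(hist, offset = FALSE) {
  if (!inherits(hist, "orientation_histogram")) {
    hist <- orientation_histogram(hist)
  }
  if (sum(hist$count > 0) < 5) abort("need at least 5 non-empty bins")
  bw <- attr(hist, "bin_width") %||% diff(hist$angle_mid[1:2])
  mode_angle <- hist$angle_mid[which.max(hist$count)]
  phi <- wrap_axial(hist$angle_mid - mode_angle)
  df <- tibble::tibble(phi = phi, y = hist$count)
  a0 <- max(df$y) - min(df$y)
  s0 <- max(bw, sqrt(sum(df$y * df$phi^2) / sum(df$y)) / 2)
  # Gaussian wrapped onto the 180 degree orientation domain: without the
  # +-180 degree replicas the tails of wide distributions leak out of the
  # window and sigma is biased low
  model <- if (offset) {
    y ~ A * (exp(-(phi - mu)^2 / (2 * sigma^2)) +
               exp(-(phi - mu - 180)^2 / (2 * sigma^2)) +
               exp(-(phi - mu + 180)^2 / (2 * sigma^2))) + c0
  } else {
    y ~ A * (exp(-(phi - mu)^2 / (2 * sigma^2)) +
               exp(-(phi - mu - 180)^2 / (2 * sigma^2)) +
               exp(-(phi - mu + 180)^2 / (2 * sigma^2)))
  }
  start <- list(A = a0, mu = 0, sigma = s0)
  lower <- c(A = 0, mu = -90, sigma = 1e-3)
  upper <- c(A = Inf, mu = 90, sigma = 1e4)
  if (offset) {
    start$c0 <- min(df$y)
    lower <- c(lower, c0 = 0); upper <- c(upper, c0 = Inf)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(model, data = df, start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) abort(sprintf("Gaussian fit failed: %s", conditionMessage(e))))
  p <- coef(fit)
  # Sheppard's correction: binning broadens the fitted width by bw^2/12
  sigma_hat <- sqrt(max(p[["sigma"]]^2 - bw^2 / 12, (bw / 10)^2))
  fwhm <- 2 * sqrt(2 * log(2)) * sigma_hat
  clipped <- fwhm > 180
  if (clipped) {
    warn("fitted FWHM wider than the 180 degree domain; clipped to 180")
    fwhm <- 180
  }
  ss_res <- sum((df$y - fitted(fit))^2)
  ss_tot <- sum((df$y - mean(df$y))^2)
  structure(list(
    fwhm_deg = fwhm,
    sigma_deg = sigma_hat,
    mu_deg = wrap_axial(mode_angle + p[["mu"]]),
    amplitude = p[["A"]], offset = if (offset) p[["c0"]] else 0,
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    clipped = clipped, n_bins = nrow(df),
    fit = fit, hist = hist
  ), class = "fwhm_fit")
}

#' @export
print.fwhm_fit <- function(x, ...) {
  cat(sprintf("<fwhm_fit: FWHM = %.2f deg (sigma = %.2f, mode at %.1f deg)%s>\n",
              x$fwhm_deg, x$sigma_deg, x$mu_deg,
              if (x$clipped) ", clipped" else ""))
  invisible(x)
}

#' Degree of alignment
#'
#' `d = (FWHM_max - FWHM) / FWHM_max`, where `FWHM_max` is the maximal FWHM
#' measured across all analyzed conditions (regions, treatments, ...). The
#' least-aligned condition thus has `d = 0`; a perfectly aligned texture
#' approaches `d = 1`.
#'
#' @param fwhm_deg Fitted FWHM of the condition, degrees; may be an
#'   `fwhm_fit`.
#' @param fwhm_max_deg The maximal FWHM over all conditions, degrees.
#' @return `d`, dimensionless in `[0, 1]`.
#' @examples
#' degree_of_alignment(23.5, 94)
#' @export
degree_of_alignment <- function(fwhm_deg, fwhm_max_deg) {
  if (inherits(fwhm_deg, "fwhm_fit")) fwhm_deg <- fwhm_deg$fwhm_deg
  if (fwhm_deg <= 0) abort("`fwhm_deg` must be positive")
  if (fwhm_deg > fwhm_max_deg) {
    abort("`fwhm_deg` exceeds `fwhm_max_deg`; FWHM_max must be the maximum over all conditions")
  }
  (fwhm_max_deg - fwhm_deg) / fwhm_max_deg
}

#' Fiber alignment across image regions
#'
#' Runs [extract_angles()], [orientation_histogram()] and [fit_fwhm()] per
#' region, sets `FWHM_max` to the maximal fitted FWHM across the supplied
#' regions (the "all conditions" set), and computes the degree of alignment
#' for each.
#'
#' @param image `Y x X` matrix.
#' @param regions Named list of regions; each region is either a logical
#'   mask matrix matching `image`, or a bounding box
#'   `c(y0, y1, x0, x1)` (1-based, inclusive).
#' @param bin_width Histogram bin width, degrees.
#' @param ... Passed to [extract_angles()].
#' @return A tibble of class `alignment_result`: `region`, `n`, `fwhm_deg`,
#'   `fwhm_max_deg`, `d`.
#' @export
alignment_by_region <- function(image, regions, bin_width = 5, ...) {
  stopifnot(is.list(regions), length(regions) >= 1,
            !is.null(names(regions)))
  if (length(regions) == 1L) {
    warn("single region supplied: d = 0 by construction (FWHM_max = FWHM)")
  }
  fits <- purrr::imap(regions, function(rg, nm) {
    sub <- if (is.matrix(rg) && is.logical(rg)) {
      # crop to the mask bounding box; pixels outside the mask keep their
      # values (the tensor window needs contiguous intensities)
      ij <- which(rg, arr.ind = TRUE)
      image[min(ij[, 1]):max(ij[, 1]), min(ij[, 2]):max(ij[, 2])]
    } else {
      image[rg[1]:rg[2], rg[3]:rg[4]]
    }
    ang <- extract_angles(sub, ...)
    list(fit = fit_fwhm(orientation_histogram(ang, bin_width = bin_width)),
         n = nrow(ang))
  })
  fwhm <- purrr::map_dbl(fits, ~ .x$fit$fwhm_deg)
  fwhm_max <- max(fwhm)
  out <- tibble::tibble(
    region = names(regions),
    n = purrr::map_int(fits, "n"),
    fwhm_deg = unname(fwhm),
    fwhm_max_deg = fwhm_max,
    d = purrr::map_dbl(unname(fwhm), degree_of_alignment, fwhm_max_deg = fwhm_max))
  attr(out, "fits") <- purrr::map(fits, "fit")
  class(out) <- c("alignment_result", class(out))
  out
}
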