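#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted orientation-histogram Gaussian
#'
#' @param x An `fwhm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per fitted term (`estimate`, `std.error`,
#'   `statistic`, `p.value`).
#' @export
tidy.fwhm_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1],
                 std.error = s[, 2], statistic = s[, 3], p.value = s[, 4])
}

#' @rdname tidy.fwhm_fit
#' @return `glance()`: a one-row tibble with `fwhm_deg`, `sigma_deg`,
#'   `mu_deg`, `r_squared`, `n_bins`, `clipped`.
#' @export
glance.fwhm_fit <- function(x, ...) {
  tibble::tibble(fwhm_deg = x$fwhm_deg, sigma_deg = x$sigma_deg,
                 mu_deg = x$mu_deg, r_squared = x$r_squared,
                 n_bins = x$n_bins, clipped = x$clipped)
}

#' Tidy a cell-ECM coupling result
#'
#' @param x A `coupling_result` from [couple_cell_ecm()].
#' @param ... Unused.
#' @return `tidy()`: the lag scan as a plain tibble; `glance()`: one row
#'   with `peak_lag`, `peak_correlation`, `n`, `method`.
#' @export
tidy.coupling_result <- function(x, ...) {
  tibble::tibble(lag = x$lag, correlation = x$correlation)
}

#' @rdname tidy.coupling_result
#' @export
glance.coupling_result <- function(x, ...) {
  tibble::tibble(peak_lag = attr(x, "peak_lag"),
                 peak_correlation = attr(x, "peak_correlation"),
                 n = attr(x, "n"), method = attr(x, "method"))
}
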