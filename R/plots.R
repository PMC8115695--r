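# ggplot2 figures for each result type.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col geom_step
#'   geom_errorbar geom_hline geom_vline labs theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot a cumulative near-field displacement series
#'
#' @param series A tibble from [cumulative_displacement()].
#' @return A ggplot.
#' @export
plot_cumulative_displacement <- function(series) {
  ggplot(series, aes(x = .data$time_min, y = .data$cum_um)) +
    geom_line(color = "#b2182b") +
    geom_point(size = 0.8, color = "#b2182b") +
    labs(x = "time (min)", y = "cumulative displacement toward tip (µm)") +
    theme_minimal()
}

#' Plot the angular anisotropy profile
#'
#' @param profile A tibble from [angular_profile()].
#' @return A ggplot.
#' @export
plot_angular_profile <- function(profile) {
  ggplot(profile, aes(x = .data$theta_mid, y = .data$s_mean)) +
    geom_errorbar(aes(ymin = .data$s_mean - .data$s_sd,
                      ymax = .data$s_mean + .data$s_sd), width = 3) +
    geom_point() + geom_line() +
    labs(x = "angle to branch axis θ (deg)",
         y = "mean toward-tip displacement (µm/step)") +
    theme_minimal()
}

#' Plot a distance-stripe displacement profile
#'
#' @param profile A tibble from [stripe_profile()]; per-frame profiles are
#'   drawn as one line per frame.
#' @return A ggplot.
#' @export
plot_stripe_profile <- function(profile) {
  p <- ggplot(profile,
              aes(x = (.data$r_lo + .data$r_hi) / 2, y = .data$s_mean))
  if ("frame" %in% names(profile)) {
    p <- p + geom_line(aes(group = .data$frame, color = .data$frame))
  } else {
    p <- p + geom_col()
  }
  p + labs(x = "distance to tip (µm)",
           y = "mean toward-tip displacement (µm/step)",
           color = "frame") +
    theme_minimal()
}

#' @export
autoplot.orientation_histogram <- function(object, ...) {
  ggplot(object, aes(x = .data$angle_mid, y = .data$count)) +
    geom_col(width = diff(object$angle_mid[1:2]) * 0.9, fill = "grey40") +
    labs(x = "fiber angle (deg)", y = "weighted count") +
    theme_minimal()
}

#' @export
autoplot.fwhm_fit <- function(object, ...) {
  h <- object$hist
  grid <- tibble::tibble(angle_mid = seq(-90, 90, by = 0.5))
  mu <- object$mu_deg
  phi <- wrap_axial(grid$angle_mid - mu)
  grid$fit <- object$amplitude *
    (exp(-phi^2 / (2 * object$sigma_deg^2)) +
       exp(-(phi - 180)^2 / (2 * object$sigma_deg^2)) +
       exp(-(phi + 180)^2 / (2 * object$sigma_deg^2))) + object$offset
  autoplot(h) +
    geom_line(data = grid, aes(x = .data$angle_mid, y = .data$fit),
              color = "#b2182b", linewidth = 0.8) +
    labs(subtitle = sprintf("FWHM = %.1f deg", object$fwhm_deg))
}

#' @export
autoplot.motion_phases <- function(object, ...) {
  ggplot(object, aes(x = .data$frame)) +
    geom_col(aes(y = .data$v_par_mean, fill = .data$label), width = 0.9) +
    geom_line(aes(y = .data$phi), linetype = 2) +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    labs(x = "frame", y = "mean parallel velocity (µm/min) / Φ",
         fill = "phase") +
    theme_minimal()
}

#' @export
autoplot.coupling_result <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$lag, y = .data$correlation)) +
    geom_col(width = 0.8) +
    geom_vline(xintercept = attr(object, "peak_lag"),
               linetype = 2, color = "#b2182b") +
    labs(x = "lag (frames; ECM relative to cells)",
         y = "correlation of v_par with -s") +
    theme_minimal()
}

#' @export
autoplot.drift_series <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("dz", "dy", "dx"),
                              names_to = "axis", values_to = "shift")
  ggplot(long, aes(x = .data$frame, y = .data$shift, color = .data$axis)) +
    geom_step() +
    labs(x = "frame", y = "cumulative shift (voxels)") +
    theme_minimal()
}
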