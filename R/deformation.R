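# ECM deformation statistics around a branch tip: geometric projection of
# bead steps, near-field cumulative displacement, angular anisotropy
# profile, 100-µm distance stripes, and contraction/relaxation labeling.
#
# Sign convention, fixed package-wide: `s` is the component of a bead step
# toward the branch tip, in µm; positive s = contraction toward the branch,
# negative s = relaxation away from it.

#' Project bead steps into the branch reference frame
#'
#' For every displacement step, computes the distance `r_um` from the step's
#' starting position to the tip, the angle `theta_deg` (in `[0, 180]`)
#' between the tip-to-bead vector and the branch axis, and the signed scalar
#' `s_um`, the component of the step pointing from the bead toward the tip.
#'
#' @param displacements A tibble from [track_displacements()].
#' @param geometry A [branch_geometry()].
#' @return The input tibble with columns `r_um`, `theta_deg`, `s_um` added,
#'   classed `displacement_samples`.
#' @export
project_samples <- function(displacements, geometry) {
  stopifnot(inherits(geometry, "branch_geometry"))
  tip <- geometry$tip; ax <- geometry$axis
  dx <- displacements$x_um - tip["x"]
  dy <- displacements$y_um - tip["y"]
  dz <- displacements$z_um - tip["z"]
  r <- sqrt(dx^2 + dy^2 + dz^2)
  ct <- ifelse(r > 0, (dx * ax["x"] + dy * ax["y"] + dz * ax["z"]) / r, 1)
  # unit vector bead -> tip is -(dx,dy,dz)/r; s = step . (bead -> tip)
  s <- ifelse(r > 0,
              -(displacements$du_x * dx + displacements$du_y * dy +
                  displacements$du_z * dz) / r,
              0)
  out <- dplyr::mutate(tibble::as_tibble(displacements),
                       r_um = unname(r),
                       theta_deg = unname(rad2deg(acos(pmin(pmax(ct, -1), 1)))),
                       s_um = unname(s))
  class(out) <- c("displacement_samples", class(out))
  out
}

# near-field membership: within the near-field radius and in front of the
# tip plane (theta <= 90 deg)
in_near_field <- function(samples, geometry) {
  samples$r_um <= geometry$near_field_um & samples$theta_deg <= 90
}

#' Per-frame mean toward-tip displacement in the near field
#'
#' @param samples A tibble from [project_samples()].
#' @param geometry A [branch_geometry()].
#' @param frame_interval Minutes per frame for the time stamp.
#' @return A tibble: `frame`, `time_min`, `s_mean` (µm per step), `n`.
#' @export
frame_mean_displacement <- function(samples, geometry, frame_interval = 10) {
  samples |>
    dplyr::filter(in_near_field(samples, geometry)) |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(s_mean = mean(.data$s_um), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(time_min = (.data$frame - 1) * frame_interval,
                  .after = "frame")
}

#' Cumulative near-field bead displacement over time
#'
#' Per bead, the running sum of its toward-tip steps `s`; the series value
#' at each time is the mean over near-field beads. A bead that leaves the
#' near field is frozen at its exit value and keeps contributing that value
#' (its accumulated deformation is retained, but no further motion is
#' attributed to it); the number of frozen beads is reported via attribute
#' `n_frozen`. The series starts at 0 at the movie start.
#'
#' @param samples A tibble from [project_samples()].
#' @param geometry A [branch_geometry()].
#' @param frame_interval Minutes per frame.
#' @return A tibble of class `cumulative_series`: `frame`, `time_min`,
#'   `cum_um` (mean cumulative toward-tip displacement, µm), `n_active`.
#' @export
cumulative_displacement <- function(samples, geometry, frame_interval = 10) {
  nf <- in_near_field(samples, geometry)
  ids <- unique(samples$track_id[nf])
  if (!length(ids)) abort("empty near field: no beads within the near-field region")
  frames <- sort(unique(samples$frame))
  f0 <- min(frames) - 1L                    # movie start: zero displacement

  pb <- samples |>
    dplyr::filter(.data$track_id %in% ids) |>
    dplyr::arrange(.data$track_id, .data$frame)
  pb$inside <- in_near_field(pb, geometry)
  per_bead <- pb |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(
      # frozen from the first step taken outside the near field onwards
      frozen = cumsum(!.data$inside) > 0,
      step = ifelse(.data$frozen, 0, .data$s_um),
      cum = cumsum(.data$step)
    ) |>
    dplyr::ungroup()

  # carry each bead's last value forward across frames it has no sample in
  grid <- tidyr::expand_grid(track_id = ids, frame = c(f0, frames))
  filled <- grid |>
    dplyr::left_join(per_bead[, c("track_id", "frame", "cum", "frozen")],
                     by = c("track_id", "frame")) |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(cum = dplyr::if_else(.data$frame == f0, 0, .data$cum)) |>
    tidyr::fill("cum", .direction = "down") |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$cum))

  out <- filled |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(cum_um = mean(.data$cum), n_active = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(time_min = (.data$frame - 1L) * frame_interval,
                  .after = "frame")
  attr(out, "n_frozen") <- length(unique(per_bead$track_id[per_bead$frozen]))
  class(out) <- c("cumulative_series", class(out))
  out
}

#' Angular anisotropy profile of the deformation
#'
#' Bins displacement samples by angle `theta` to the branch axis and
#' averages the toward-tip component `s` per bin; the deformation of a
#' tip-driven field decreases with increasing angle.
#'
#' @param samples A tibble from [project_samples()].
#' @param bin_width Angular bin width, degrees (default 15).
#' @param max_r Optional maximum distance `r_um` to include, µm.
#' @return A tibble: `theta_lo`, `theta_hi`, `theta_mid`, `s_mean`, `s_sd`,
#'   `n`.
#' @export
angular_profile <- function(samples, bin_width = 15, max_r = Inf) {
  samples |>
    dplyr::filter(.data$r_um <= max_r) |>
    dplyr::mutate(bin = pmin(floor(.data$theta_deg / bin_width),
                             ceiling(180 / bin_width) - 1)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(s_mean = mean(.data$s_um), s_sd = sd(.data$s_um),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(theta_lo = .data$bin * bin_width,
                  theta_hi = (.data$bin + 1) * bin_width,
                  theta_mid = .data$theta_lo + bin_width / 2) |>
    dplyr::select("theta_lo", "theta_hi", "theta_mid",
                  "s_mean", "s_sd", "n")
}

#' Distance-stripe profile of the deformation
#'
#' Segments the ECM in front of the branch (`theta <= 90` degrees) into
#' stripes of `stripe_width` µm by distance to the tip and averages the
#' toward-tip displacement per stripe and frame. Stripes with no sample are
#' reported as `NA` with `n = 0` (missing, not zero).
#'
#' @param samples A tibble from [project_samples()].
#' @param geometry A [branch_geometry()].
#' @param stripe_width Stripe width, µm (default 100).
#' @param per_frame If `FALSE`, average over all frames per stripe instead.
#' @return A tibble of class `stripe_profile`: `stripe`, `r_lo`, `r_hi`
#'   (+ `frame` when `per_frame`), `s_mean`, `n`.
#' @export
stripe_profile <- function(samples, geometry, stripe_width = 100,
                           per_frame = TRUE) {
  stopifnot(stripe_width > 0)
  fwd <- dplyr::filter(samples, .data$theta_deg <= 90)
  n_stripes <- if (nrow(fwd)) ceiling(max(fwd$r_um) / stripe_width) else 0L
  base <- tibble::tibble(stripe = seq_len(max(n_stripes, 0L))) |>
    dplyr::mutate(r_lo = (.data$stripe - 1) * stripe_width,
                  r_hi = .data$stripe * stripe_width)
  fwd <- dplyr::mutate(fwd, stripe = floor(.data$r_um / stripe_width) + 1L)
  grp <- if (per_frame) c("stripe", "frame") else "stripe"
  agg <- fwd |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(s_mean = mean(.data$s_um), n = dplyr::n(),
                     .groups = "drop")
  full <- if (per_frame) {
    tidyr::expand_grid(base, frame = sort(unique(samples$frame)))
  } else base
  out <- full |>
    dplyr::left_join(agg, by = grp) |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L))
  class(out) <- c("stripe_profile", class(out))
  out
}

#' Label ECM motion phases as contraction or relaxation
#'
#' Labels each frame of a mean-displacement series: `"contraction"` when
#' the near-field mean toward-tip step is positive, `"relaxation"` when
#' negative, and `"neutral"` when its magnitude is below `noise_floor`.
#'
#' @param series A tibble with columns `frame` and `s_mean`, e.g. from
#'   [frame_mean_displacement()].
#' @param noise_floor Magnitude below which motion is called neutral, µm.
#'   The recommended calibration is twice the median per-frame `|s|` of a
#'   matched zero-field scene (localization noise); default 0.
#' @return The input with a `phase` column added.
#' @export
label_phases_ecm <- function(series, noise_floor = 0) {
  stopifnot(nrow(series) >= 1, "s_mean" %in% names(series))
  dplyr::mutate(tibble::as_tibble(series),
                phase = dplyr::case_when(
                  abs(.data$s_mean) <= noise_floor ~ "neutral",
                  .data$s_mean > 0 ~ "contraction",
                  TRUE ~ "relaxation"))
}

#' Displacement change after a perturbation event
#'
#' The signed change of a cumulative-displacement series after an event
#' frame (e.g. actin disruption or matrix ablation):
#' `value(end) - value(event_frame)`. Negative values mean relaxation —
#' beads retracting opposite to the initial deformation field.
#'
#' @param series A tibble from [cumulative_displacement()].
#' @param event_frame Frame index of the event; must lie within the series.
#' @return A single number, µm.
#' @export
relaxation_delta <- function(series, event_frame) {
  stopifnot(all(c("frame", "cum_um") %in% names(series)))
  if (!event_frame %in% series$frame) {
    abort("`event_frame` must be a frame of the series")
  }
  series$cum_um[which.max(series$frame)] -
    series$cum_um[series$frame == event_frame]
}
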