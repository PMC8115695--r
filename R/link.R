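# Track linking: mutual nearest-neighbour matching between consecutive
# frames within a link radius, keeping only chains that persist over at
# least three consecutive frames.

# mutual nearest-neighbour matches between two position matrices (um);
# returns an integer vector: for each row of p1 the matched row of p2 or NA
mutual_nn_match <- function(p1, p2, radius) {
  n1 <- nrow(p1); n2 <- nrow(p2)
  if (n1 == 0L || n2 == 0L) return(rep(NA_integer_, n1))
  dm <- outer(rowSums(p1^2), rep(1, n2)) +
    outer(rep(1, n1), rowSums(p2^2)) - 2 * p1 %*% t(p2)
  dm[dm < 0] <- 0
  dm <- sqrt(dm)
  nn12 <- apply(dm, 1, which.min)
  nn21 <- apply(dm, 2, which.min)
  match <- rep(NA_integer_, n1)
  for (i in seq_len(n1)) {
    j <- nn12[i]
    if (nn21[j] == i && dm[i, j] <= radius) match[i] <- j
  }
  match
}

#' Link per-frame detections into bead tracks
#'
#' Matches coordinates across consecutive frames by mutual nearest-neighbour
#' assignment within `link_radius`, then emits a track wherever matches hold
#' over at least `min_length` (default 3) consecutive frames. There is no
#' gap closing: a missed detection terminates the track. No detection ever
#' belongs to two tracks.
#'
#' @param detections A tibble with columns `frame`, `x_um`, `y_um`, `z_um`
#'   (and optionally `intensity`), e.g. from [detect_beads_stack()].
#' @param link_radius Maximum per-step displacement, µm (default 10, a
#'   generous bound for ECM tracers at 10-minute frame intervals).
#' @param min_length Minimum track length in frames (default 3, the
#'   three-consecutive-images rule).
#' @return A tibble of class `bead_tracks`: `track_id`, `frame`, `x_um`,
#'   `y_um`, `z_um` (+ `intensity` if present), ordered by track and frame.
#'   The number of detections left unlinked is available as attribute
#'   `n_unlinked`.
#' @export
link_tracks <- function(detections, link_radius = 10, min_length = 3) {
  stopifnot(all(c("frame", "x_um", "y_um", "z_um") %in% names(detections)))
  detections <- dplyr::arrange(tibble::as_tibble(detections),
                               .data$frame, .data$x_um)
  frames <- sort(unique(detections$frame))
  by_frame <- split(seq_len(nrow(detections)), detections$frame)

  # successor pointer (row index in `detections`) for every detection
  succ <- rep(NA_integer_, nrow(detections))
  for (fi in seq_along(frames)[-length(frames)]) {
    f <- frames[fi]; fn <- frames[fi + 1]
    if (fn != f + 1L) next                       # only consecutive frames link
    i1 <- by_frame[[as.character(f)]]
    i2 <- by_frame[[as.character(fn)]]
    m <- mutual_nn_match(as.matrix(detections[i1, c("x_um", "y_um", "z_um")]),
                         as.matrix(detections[i2, c("x_um", "y_um", "z_um")]),
                         link_radius)
    succ[i1[!is.na(m)]] <- i2[m[!is.na(m)]]
  }

  has_pred <- rep(FALSE, nrow(detections))
  has_pred[succ[!is.na(succ)]] <- TRUE
  starts <- which(!has_pred)
  out <- vector("list", length(starts))
  tid <- 0L
  used <- 0L
  for (s in starts) {
    chain <- s
    while (!is.na(succ[chain[length(chain)]])) {
      chain <- c(chain, succ[chain[length(chain)]])
    }
    if (length(chain) >= min_length) {
      tid <- tid + 1L
      out[[tid]] <- dplyr::mutate(detections[chain, ], track_id = tid,
                                  .before = 1)
      used <- used + length(chain)
    }
  }
  res <- if (tid > 0) dplyr::bind_rows(out[seq_len(tid)]) else
    dplyr::mutate(detections[0, ], track_id = integer(), .before = 1)
  n_unlinked <- nrow(detections) - used
  if (n_unlinked > 0) {
    inform(sprintf("link_tracks: %d detection(s) not part of any track", n_unlinked))
  }
  attr(res, "n_unlinked") <- n_unlinked
  class(res) <- c("bead_tracks", class(res))
  res
}

#' Per-step displacements of bead tracks
#'
#' Finite differences of consecutive track positions. Each step is stamped
#' with the *arrival* frame (the displacement is realized at the later of
#' the two frames) and with the starting position, which downstream
#' geometry projections use as the material point of the step.
#'
#' @param tracks A tibble from [link_tracks()] (columns `track_id`, `frame`,
#'   `x_um`, `y_um`, `z_um`).
#' @param frame_interval Minutes per frame, used for the `time_min` stamp
#'   (default 10).
#' @return A tibble: `track_id`, `frame`, `time_min`, `x_um`, `y_um`,
#'   `z_um` (step start position), `du_x`, `du_y`, `du_z` (step vector, µm).
#' @export
track_displacements <- function(tracks, frame_interval = 10) {
  stopifnot(all(c("track_id", "frame", "x_um", "y_um", "z_um") %in% names(tracks)))
  tracks |>
    tibble::as_tibble() |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(
      du_x = .data$x_um - dplyr::lag(.data$x_um),
      du_y = .data$y_um - dplyr::lag(.data$y_um),
      du_z = .data$z_um - dplyr::lag(.data$z_um),
      x_um = dplyr::lag(.data$x_um),
      y_um = dplyr::lag(.data$y_um),
      z_um = dplyr::lag(.data$z_um)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$du_x)) |>
    dplyr::mutate(time_min = (.data$frame - 1) * frame_interval) |>
    dplyr::select("track_id", "frame", "time_min",
                  "x_um", "y_um", "z_um", "du_x", "du_y", "du_z")
}
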