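#' Time-lapse image stack
#'
#' The universal image container of the package: a `T x Z x Y x X` intensity
#' array with physical calibration. All physical positions in the package are
#' expressed in micrometres, with the centre of voxel `(i, j, k)` (0-based
#' indices along z, y, x) at `(i, j, k) * voxel_size`. Time is in minutes,
#' frame `f` at `(f - 1) * frame_interval`.
#'
#' @param data Numeric array. Either `T x Z x Y x X`, or `T x Y x X` (a
#'   single-slice movie, promoted to `Z = 1`).
#' @param voxel_size Numeric length-3 voxel size `(z, y, x)` in µm, or a
#'   single number used for all three axes.
#' @param frame_interval Time between consecutive frames, minutes.
#' @param channel Channel label (e.g. `"beads"`, `"nuclei"`, `"collagen"`).
#'
#' @return An object of class `timelapse_stack`: a list with elements
#'   `data`, `voxel_size`, `frame_interval`, `channel`.
#' @examples
#' a <- array(rnorm(5 * 1 * 16 * 16), c(5, 1, 16, 16))
#' s <- timelapse_stack(a, voxel_size = c(2, 0.5, 0.5), frame_interval = 10)
#' n_frames(s)
#' @export
timelapse_stack <- function(data, voxel_size = 1, frame_interval = 10,
                            channel = "beads") {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L))) {
    abort("`data` must be a T x Z x Y x X (or T x Y x X) array")
  }
  if (length(dim(data)) == 3L) {
    d <- dim(data)
    data <- array(data, c(d[1], 1L, d[2], d[3]))
  }
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    abort("`voxel_size` must be positive, length 3 (z, y, x) or length 1")
  }
  if (frame_interval <= 0) abort("`frame_interval` must be positive")
  structure(
    list(
      data = data,
      voxel_size = setNames(as.numeric(voxel_size), c("z", "y", "x")),
      frame_interval = as.numeric(frame_interval),
      channel = channel
    ),
    class = "timelapse_stack"
  )
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<timelapse_stack: %d frame(s), %d x %d x %d voxels (z,y,x), voxel %s um, dt %g min, channel '%s'>\n",
    d[1], d[2], d[3], d[4],
    paste(signif(x$voxel_size, 3), collapse = " x "),
    x$frame_interval, x$channel
  ))
  invisible(x)
}

#' @rdname timelapse_stack
#' @param stack A `timelapse_stack`.
#' @export
n_frames <- function(stack) dim(stack$data)[1]

#' Extract one frame of a stack as a Z x Y x X array
#'
#' @param stack A [timelapse_stack()].
#' @param frame Frame index (1-based).
#' @return A `Z x Y x X` numeric array.
#' @export
get_frame <- function(stack, frame) {
  stopifnot(frame >= 1, frame <= n_frames(stack))
  d <- dim(stack$data)
  array(stack$data[frame, , , ], d[2:4])
}

#' Maximum-intensity projection along z
#'
#' Collapses each frame to a 2D `Y x X` image; used for 2D optical flow.
#'
#' @param stack A [timelapse_stack()].
#' @return A list of `Y x X` matrices, one per frame.
#' @export
max_project <- function(stack) {
  purrr::map(seq_len(n_frames(stack)), function(f) {
    fr <- get_frame(stack, f)
    if (dim(fr)[1] == 1L) matrix(fr[1, , ], dim(fr)[2], dim(fr)[3])
    else apply(fr, c(2, 3), function(v) {
      m <- suppressWarnings(max(v, na.rm = TRUE))
      if (is.finite(m)) m else NA_real_
    })
  })
}

#' Read / write a time-lapse stack as multi-page TIFF
#'
#' Pages are ordered frame-major, slice-minor (`T` blocks of `Z` pages).
#' Calibration (`voxel_size`, `frame_interval`, dimensions, channel) lives in
#' a JSON sidecar `<path>.json` because baseline TIFF has no standard slot
#' for time and z calibration.
#'
#' @param stack A [timelapse_stack()]. Intensities are rescaled to `[0, 1]`
#'   for storage; the scale factor is kept in the sidecar and undone on read.
#' @param path Output/input TIFF file path.
#' @return `write_stack_tiff()` returns `path` invisibly; `read_stack_tiff()`
#'   returns a [timelapse_stack()].
#' @export
write_stack_tiff <- function(stack, path) {
  d <- dim(stack$data)
  lo <- min(stack$data); hi <- max(stack$data)
  scale <- if (hi > lo) hi - lo else 1
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (f in seq_len(d[1])) for (z in seq_len(d[2])) {
    pages[[k]] <- (matrix(stack$data[f, z, , ], d[3], d[4]) - lo) / scale
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(
    n_frames = d[1], n_z = d[2], n_y = d[3], n_x = d[4],
    voxel_size = as.list(stack$voxel_size),
    frame_interval = stack$frame_interval,
    channel = stack$channel,
    intensity_offset = lo, intensity_scale = scale
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- c(meta$n_frames, meta$n_z, meta$n_y, meta$n_x)
  a <- array(0, d)
  k <- 1L
  for (f in seq_len(d[1])) for (z in seq_len(d[2])) {
    a[f, z, , ] <- pages[[k]] * meta$intensity_scale + meta$intensity_offset
    k <- k + 1L
  }
  timelapse_stack(a,
                  voxel_size = unlist(meta$voxel_size)[c("z", "y", "x")],
                  frame_interval = meta$frame_interval,
                  channel = meta$channel)
}
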