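# Global stage-drift correction by correlation maximization: for every
# consecutive frame pair the integer (z, y, x) shift maximizing normalized
# cross-correlation on the overlap is found by exhaustive search in a window,
# then chained into cumulative shifts relative to frame 1.

# normalized cross-correlation between frame `a` and frame `b` shifted by
# integer (dz, dy, dx); computed on the overlapping region only
ncc_at_shift <- function(a, b, dz, dy, dx) {
  d <- dim(a)
  az <- max(1, 1 + dz):min(d[1], d[1] + dz)
  ay <- max(1, 1 + dy):min(d[2], d[2] + dy)
  ax <- max(1, 1 + dx):min(d[3], d[3] + dx)
  if (!length(az) || !length(ay) || !length(ax)) return(NA_real_)
  va <- as.vector(a[az, ay, ax, drop = FALSE])
  vb <- as.vector(b[az - dz, ay - dy, ax - dx, drop = FALSE])
  ok <- is.finite(va) & is.finite(vb)      # sentinel voxels are excluded
  if (sum(ok) < 9) return(NA_real_)
  va <- va[ok]; vb <- vb[ok]
  if (sd(va) == 0 || sd(vb) == 0) return(NA_real_)
  cor(va, vb)
}

# full correlation landscape over the search window for one frame pair;
# returns the best shift with ties broken toward the smaller magnitude
best_shift <- function(a, b, max_shift) {
  d <- dim(a)
  wz <- if (d[1] == 1L) 0L else -min(max_shift[1], d[1] - 1L):min(max_shift[1], d[1] - 1L)
  wy <- -max_shift[2]:max_shift[2]
  wx <- -max_shift[3]:max_shift[3]
  grid <- expand.grid(dz = wz, dy = wy, dx = wx)
  cc <- vapply(seq_len(nrow(grid)), function(i) {
    ncc_at_shift(a, b, grid$dz[i], grid$dy[i], grid$dx[i])
  }, numeric(1))
  mag <- grid$dz^2 + grid$dy^2 + grid$dx^2
  ord <- order(-cc, mag, abs(grid$dz), abs(grid$dy), abs(grid$dx),
               na.last = TRUE)
  best <- ord[1]
  # tie handling: among scores within 1e-12 of the top, smallest magnitude
  top <- cc[best]
  tied <- which(!is.na(cc) & cc >= top - 1e-12)
  if (length(tied) > 1L) best <- tied[order(mag[tied], abs(grid$dz[tied]),
                                            abs(grid$dy[tied]),
                                            abs(grid$dx[tied]))][1]
  list(shift = c(grid$dz[best], grid$dy[best], grid$dx[best]),
       correlation = cc[best], grid = grid, cc = cc,
       window = list(wz = wz, wy = wy, wx = wx))
}

# 1D quadratic subpixel refinement around an interior peak
refine_axis <- function(cm, c0, cp) {
  den <- cm - 2 * c0 + cp
  if (!is.finite(den) || den >= 0) return(0)
  max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
}

#' Estimate global drift by correlation maximization
#'
#' For each consecutive frame pair, finds the integer shift in
#' `[-max_shift, max_shift]^3` that maximizes the normalized
#' cross-correlation of the overlapping region (exhaustive stepwise search;
#' ties broken toward the smaller-magnitude shift). Cumulative sums give the
#' shift of every frame relative to frame 1. Optionally refines each peak to
#' subvoxel precision by separable quadratic interpolation.
#'
#' Chaining consecutive pairs mirrors how drift accumulates during
#' acquisition but lets estimation error random-walk over long movies; for
#' rigid stage drift over tens of frames this is negligible compared to one
#' voxel.
#'
#' @param stack A [timelapse_stack()] with at least 2 frames.
#' @param max_shift Search half-width in voxels (scalar or `(z, y, x)`).
#'   The z window is additionally clamped to the stack depth.
#' @param subvoxel If `TRUE`, add quadratic subvoxel refinement.
#' @return A tibble of class `drift_series` with one row per frame:
#'   `frame`, `dz`, `dy`, `dx` (cumulative shift in voxels relative to frame
#'   1; first row zero) and `correlation` (peak NCC of the step into this
#'   frame; `NA` for frame 1).
#' @examples
#' a <- array(0, c(2, 1, 32, 32)); a[, , 10:14, 10:14] <- 1
#' s <- timelapse_stack(a)
#' estimate_drift(s, max_shift = 3)
#' @export
estimate_drift <- function(stack, max_shift = 10, subvoxel = FALSE) {
  stopifnot(inherits(stack, "timelapse_stack"))
  nt <- n_frames(stack)
  if (nt < 2) abort("drift estimation needs at least 2 frames")
  if (length(max_shift) == 1L) max_shift <- rep(max_shift, 3L)
  if (any(max_shift < 1)) abort("`max_shift` must be >= 1")
  max_shift <- as.integer(max_shift)

  steps <- matrix(0, nt, 3L)
  corrs <- rep(NA_real_, nt)
  prev <- get_frame(stack, 1)
  if (sd(prev, na.rm = TRUE) == 0) {
    abort("uninformative frame: frame 1 has zero variance")
  }
  for (f in 2:nt) {
    cur <- get_frame(stack, f)
    if (sd(cur, na.rm = TRUE) == 0) {
      abort(sprintf("uninformative frame: frame %d has zero variance", f))
    }
    # shift of the current frame's content relative to the previous frame:
    # maximize cor(cur[i], prev[i - d]) so a scene moved by +d reports +d
    bs <- best_shift(cur, prev, max_shift)
    sh <- as.numeric(bs$shift)
    on_edge <- (length(bs$window$wz) > 1 && abs(sh[1]) == max(bs$window$wz)) ||
      abs(sh[2]) == max_shift[2] || abs(sh[3]) == max_shift[3]
    if (on_edge) {
      warn(sprintf("drift peak on search boundary at frame %d: max_shift may be too small", f))
    } else if (subvoxel) {
      g <- bs$grid; cc <- bs$cc
      pick <- function(dz, dy, dx) {
        i <- which(g$dz == dz & g$dy == dy & g$dx == dx)
        if (length(i)) cc[i] else NA_real_
      }
      c0 <- bs$correlation
      if (length(bs$window$wz) > 1) {
        sh[1] <- sh[1] + refine_axis(pick(sh[1] - 1, sh[2], sh[3]), c0,
                                     pick(sh[1] + 1, sh[2], sh[3]))
      }
      sh[2] <- sh[2] + refine_axis(pick(bs$shift[1], sh[2] - 1, sh[3]), c0,
                                   pick(bs$shift[1], sh[2] + 1, sh[3]))
      sh[3] <- sh[3] + refine_axis(pick(bs$shift[1], bs$shift[2], sh[3] - 1), c0,
                                   pick(bs$shift[1], bs$shift[2], sh[3] + 1))
    }
    steps[f, ] <- sh
    corrs[f] <- bs$correlation
    prev <- cur
  }
  cum <- apply(steps, 2, cumsum)
  out <- tibble::tibble(frame = seq_len(nt),
                        dz = cum[, 1], dy = cum[, 2], dx = cum[, 3],
                        correlation = corrs)
  class(out) <- c("drift_series", class(out))
  out
}

#' Undo estimated drift by integer translation
#'
#' Translates every frame by minus its cumulative shift. Voxels that fall
#' outside the field of view are filled with `fill` and recorded in a
#' validity mask.
#'
#' @param stack A [timelapse_stack()].
#' @param drift A drift series from [estimate_drift()] (subvoxel shifts are
#'   rounded to the nearest voxel for translation).
#' @param fill Sentinel value for out-of-field voxels (default `NA`, which
#'   downstream operations — drift re-estimation, bead detection — treat as
#'   missing rather than as intensity 0).
#' @return A list with `stack` (corrected [timelapse_stack()]) and `mask`
#'   (logical `T x Z x Y x X` array, `TRUE` where voxels are valid in every
#'   sense: came from inside the field of view).
#' @export
apply_drift <- function(stack, drift, fill = NA_real_) {
  stopifnot(inherits(stack, "timelapse_stack"))
  nt <- n_frames(stack)
  if (nrow(drift) != nt) abort("drift series length must equal the number of frames")
  d <- dim(stack$data)[2:4]
  out <- stack$data
  mask <- array(TRUE, dim(stack$data))
  sh <- round(cbind(drift$dz, drift$dy, drift$dx))
  for (f in seq_len(nt)) {
    s <- sh[f, ]
    if (all(s == 0)) next
    src <- get_frame(stack, f)
    dst <- array(fill, d)
    ok <- array(FALSE, d)
    # destination voxel i gets source voxel i + s (shift by -s)
    zi <- max(1, 1 - s[1]):min(d[1], d[1] - s[1])
    yi <- max(1, 1 - s[2]):min(d[2], d[2] - s[2])
    xi <- max(1, 1 - s[3]):min(d[3], d[3] - s[3])
    if (length(zi) && length(yi) && length(xi)) {
      dst[zi, yi, xi] <- src[zi + s[1], yi + s[2], xi + s[3], drop = FALSE]
      ok[zi, yi, xi] <- TRUE
    }
    out[f, , , ] <- dst
    mask[f, , , ] <- ok
  }
  corrected <- stack
  corrected$data <- out
  list(stack = corrected, mask = mask)
}
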