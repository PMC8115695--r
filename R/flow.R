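# Dense optical flow of the nuclei channel (polynomial-expansion /
# Farneback-family), branch-axis velocity decomposition, collective-motion
# phase segmentation, and cell-ECM coupling correlation.

# --- polynomial expansion -------------------------------------------------
# Approximate the image locally by f(x + d) ~ d' A d + b' d + c using
# weighted least squares over a Gaussian applicability window. Because the
# applicability is spatially constant, the normal-equation matrix G is the
# same at every pixel and the six projection images are plain correlations.

poly_expansion <- function(f, n = 7, sigma = 1.5) {
  off <- -n:n
  w1 <- exp(-off^2 / (2 * sigma^2))
  W <- outer(w1, w1)                       # [dy, dx]
  BX <- outer(rep(1, length(off)), off)    # x (column) offset
  BY <- outer(off, rep(1, length(off)))    # y (row) offset
  basis <- list(B1 = BX^0, BX = BX, BY = BY,
                BXX = BX^2, BYY = BY^2, BXY = BX * BY)
  G <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    G[i, j] <- sum(W * basis[[i]] * basis[[j]])
  }
  Ginv <- solve(G)
  # correlation = convolution with the doubly flipped kernel
  flip <- function(k) k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k))), drop = FALSE]
  v <- purrr::map(basis, function(b) {
    EBImage::filter2(f, flip(W * b), boundary = "replicate")
  })
  r <- purrr::map(1:6, function(k) {
    Reduce(`+`, purrr::map(1:6, function(j) Ginv[k, j] * v[[j]]))
  })
  list(a11 = r[[4]], a12 = r[[6]] / 2, a22 = r[[5]], b1 = r[[2]], b2 = r[[3]])
}

# bilinearly sample every expansion coefficient at (x + dx, y + dy)
warp_expansion <- function(e, dx, dy) {
  ny <- nrow(e$a11); nx <- ncol(e$a11)
  ii <- matrix(rep(seq_len(ny), nx), ny, nx) + dy
  jj <- matrix(rep(seq_len(nx), each = ny), ny, nx) + dx
  purrr::map(e, function(m) {
    matrix(bilinear_sample(m, as.vector(ii), as.vector(jj)), ny, nx)
  })
}

# one resolution level of displacement estimation with warping iterations
flow_level <- function(e1, e2_img, d, winsize, iters, poly_n, poly_sigma) {
  e2 <- poly_expansion(e2_img, poly_n, poly_sigma)
  smooth_sigma <- winsize / 4
  for (it in seq_len(iters)) {
    e2w <- warp_expansion(e2, d$dx, d$dy)
    a11 <- (e1$a11 + e2w$a11) / 2
    a12 <- (e1$a12 + e2w$a12) / 2
    a22 <- (e1$a22 + e2w$a22) / 2
    db1 <- -0.5 * (e2w$b1 - e1$b1) + a11 * d$dx + a12 * d$dy
    db2 <- -0.5 * (e2w$b2 - e1$b2) + a12 * d$dx + a22 * d$dy
    # Gaussian-aggregated normal equations of A d = db, solved per pixel
    m11 <- EBImage::gblur(a11 * a11 + a12 * a12, smooth_sigma)
    m12 <- EBImage::gblur(a11 * a12 + a12 * a22, smooth_sigma)
    m22 <- EBImage::gblur(a12 * a12 + a22 * a22, smooth_sigma)
    h1 <- EBImage::gblur(a11 * db1 + a12 * db2, smooth_sigma)
    h2 <- EBImage::gblur(a12 * db1 + a22 * db2, smooth_sigma)
    det <- m11 * m22 - m12^2
    det[abs(det) < 1e-12] <- 1e-12
    d <- list(dx = (m22 * h1 - m12 * h2) / det,
              dy = (m11 * h2 - m12 * h1) / det)
  }
  d
}

# full pyramidal flow between two frames; returns pixels/frame displacement
farneback_flow <- function(f1, f2, levels = 3, winsize = 15, iters = 3,
                           poly_n = 7, poly_sigma = 1.5) {
  stopifnot(all(dim(f1) == dim(f2)))
  pyr1 <- list(f1); pyr2 <- list(f2)
  # the next level must still accommodate the expansion and integration
  # kernels, else it is skipped
  min_size <- 2 * max(2 * poly_n + 1, 2 * ceiling(3 * winsize / 4) + 1)
  for (l in seq_len(levels - 1)) {
    top1 <- pyr1[[l]]
    if (min(dim(top1)) < min_size) break
    shrink <- function(m) {
      EBImage::resize(EBImage::gblur(m, 1),
                      w = max(8, round(nrow(m) / 2)),
                      h = max(8, round(ncol(m) / 2)))
    }
    pyr1[[l + 1]] <- shrink(pyr1[[l]])
    pyr2[[l + 1]] <- shrink(pyr2[[l]])
  }
  nl <- length(pyr1)
  d <- list(dx = matrix(0, nrow(pyr1[[nl]]), ncol(pyr1[[nl]])),
            dy = matrix(0, nrow(pyr1[[nl]]), ncol(pyr1[[nl]])))
  for (l in rev(seq_len(nl))) {
    if (l < nl) {
      up <- function(m, ny, nx) 2 * EBImage::resize(m, w = ny, h = nx)
      ny <- nrow(pyr1[[l]]); nx <- ncol(pyr1[[l]])
      d <- list(dx = up(d$dx, ny, nx), dy = up(d$dy, ny, nx))
    }
    e1 <- poly_expansion(pyr1[[l]], poly_n, poly_sigma)
    d <- flow_level(e1, pyr2[[l]], d, winsize, iters, poly_n, poly_sigma)
  }
  d
}

#' Dense optical flow of a nuclei movie
#'
#' Computes a dense 2D velocity field for every consecutive frame pair of
#' the (max-projected) nuclei channel with a pyramidal polynomial-expansion
#' flow of the Farneback family: each image is locally approximated by a
#' quadratic polynomial over a Gaussian applicability window, and
#' displacements solve the induced linear relation between the two
#' expansions, aggregated over a Gaussian integration window, with warping
#' iterations at each pyramid level. Velocities are returned in µm/min.
#'
#' @param stack A [timelapse_stack()] (nuclei channel; z is max-projected),
#'   or a list of `Y x X` matrices.
#' @param levels Pyramid levels (default 3).
#' @param winsize Integration window, pixels (default 15).
#' @param iters Warping iterations per level (default 3).
#' @param poly_n Polynomial expansion window half-width, pixels (default 7).
#' @param poly_sigma Applicability Gaussian s.d., pixels (default 1.5).
#' @param voxel_size,frame_interval Calibration; taken from the stack when
#'   one is supplied.
#' @return An object of class `velocity_field`: list with `vx`, `vy`
#'   (arrays `(T-1) x Y x X`, µm/min; pair `i` spans frames `i -> i+1`),
#'   `pixel_size` (µm, `(y, x)`), `frame_interval` (min).
#' @export
compute_flow <- function(stack, levels = 3, winsize = 15, iters = 3,
                         poly_n = 7, poly_sigma = 1.5,
                         voxel_size = c(1, 1), frame_interval = 10) {
  if (inherits(stack, "timelapse_stack")) {
    voxel_size <- stack$voxel_size[c("y", "x")]
    frame_interval <- stack$frame_interval
    frames <- max_project(stack)
  } else {
    frames <- stack
    if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 2L)
  }
  nt <- length(frames)
  if (nt < 2) abort("optical flow needs at least 2 frames")
  ny <- nrow(frames[[1]]); nx <- ncol(frames[[1]])
  vx <- array(0, c(nt - 1, ny, nx))
  vy <- array(0, c(nt - 1, ny, nx))
  for (i in seq_len(nt - 1)) {
    f1 <- frames[[i]]; f2 <- frames[[i + 1]]
    # sentinel (out-of-field) pixels carry the frame median
    f1[!is.finite(f1)] <- median(f1, na.rm = TRUE)
    f2[!is.finite(f2)] <- median(f2, na.rm = TRUE)
    if (sd(f1) == 0 || sd(f2) == 0) {
      warn(sprintf("blank frame in pair %d: returning zero flow", i))
      next
    }
    d <- farneback_flow(f1, f2, levels, winsize, iters, poly_n, poly_sigma)
    vx[i, , ] <- d$dx * voxel_size[[2]] / frame_interval
    vy[i, , ] <- d$dy * voxel_size[[1]] / frame_interval
  }
  structure(list(vx = vx, vy = vy,
                 pixel_size = setNames(as.numeric(voxel_size), c("y", "x")),
                 frame_interval = frame_interval),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- dim(x$vx)
  cat(sprintf("<velocity_field: %d frame pair(s), %d x %d px, um/min>\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Decompose a velocity field along the branch axis
#'
#' Projects every in-plane velocity vector onto the branch axis
#' (`v_par`, positive = outward) and its 90°-rotated normal (`v_orth`).
#' The decomposition is exactly invertible:
#' `v = v_par * axis + v_orth * axis_perp`.
#'
#' @param field A [compute_flow()] result.
#' @param geometry A [branch_geometry()]; only the in-plane (x, y) part of
#'   the axis is used (renormalized).
#' @param mask Optional logical `Y x X` matrix restricting the output to a
#'   branch region.
#' @return A tibble: `pair`, `frame` (arrival frame of the pair), `y`, `x`
#'   (pixel indices), `v_x`, `v_y`, `v_par`, `v_orth` (µm/min).
#' @export
decompose_velocity <- function(field, geometry, mask = NULL) {
  stopifnot(inherits(field, "velocity_field"),
            inherits(geometry, "branch_geometry"))
  ax <- unit_vector(geometry$axis[c("x", "y")])
  perp <- c(-ax[2], ax[1])
  d <- dim(field$vx)
  if (is.null(mask)) mask <- matrix(TRUE, d[2], d[3])
  stopifnot(all(dim(mask) == d[2:3]))
  keep <- which(mask)
  yy <- ((keep - 1L) %% d[2]) + 1L
  xx <- ((keep - 1L) %/% d[2]) + 1L
  purrr::map_dfr(seq_len(d[1]), function(i) {
    vxm <- matrix(field$vx[i, , ], d[2], d[3])
    vym <- matrix(field$vy[i, , ], d[2], d[3])
    vx <- vxm[keep]; vyv <- vym[keep]
    tibble::tibble(pair = i, frame = i + 1L, y = yy, x = xx,
                   v_x = vx, v_y = vyv,
                   v_par = vx * ax[1] + vyv * ax[2],
                   v_orth = vx * perp[1] + vyv * perp[2])
  })
}

#' Segment collective-motion phases
#'
#' Per frame, the direction-consensus order parameter
#' `Phi = |mean(sign(v_par))|` over the branch region summarizes how
#' uniformly cells move along the axis. Frames with `Phi >= phi_threshold`
#' are collective (outward or inward by the sign of the mean `v_par`);
#' others are uncoordinated.
#'
#' @param vpar A tibble with columns `frame` and `v_par` (one row per pixel
#'   or cell sample), e.g. from [decompose_velocity()].
#' @param phi_threshold Consensus threshold in `[0, 1]` (default 0.5).
#' @return A tibble of class `motion_phases`: `frame`, `phi`, `v_par_mean`,
#'   `label` in `{collective_outward, collective_inward, uncoordinated}`.
#' @seealso [phase_intervals()] to merge consecutive same-label frames.
#' @export
segment_phases <- function(vpar, phi_threshold = 0.5) {
  stopifnot(all(c("frame", "v_par") %in% names(vpar)), nrow(vpar) >= 1)
  out <- vpar |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(phi = abs(mean(sign(.data$v_par))),
                     v_par_mean = mean(.data$v_par), .groups = "drop") |>
    dplyr::mutate(label = dplyr::case_when(
      .data$phi >= phi_threshold & .data$v_par_mean > 0 ~ "collective_outward",
      .data$phi >= phi_threshold & .data$v_par_mean < 0 ~ "collective_inward",
      TRUE ~ "uncoordinated"))
  class(out) <- c("motion_phases", class(out))
  out
}

#' Merge per-frame phase labels into intervals
#'
#' @param phases A tibble from [segment_phases()].
#' @return A tibble: `start_frame`, `end_frame`, `label`, `mean_phi`.
#' @export
phase_intervals <- function(phases) {
  phases |>
    dplyr::arrange(.data$frame) |>
    dplyr::mutate(run = cumsum(.data$label != dplyr::lag(.data$label,
                                                         default = dplyr::first(.data$label))) ) |>
    dplyr::group_by(.data$run, .data$label) |>
    dplyr::summarise(start_frame = min(.data$frame),
                     end_frame = max(.data$frame),
                     mean_phi = mean(.data$phi), .groups = "drop") |>
    dplyr::select("start_frame", "end_frame", "label", "mean_phi")
}

#' Cell-ECM coupling correlation with lag scan
#'
#' Correlates the branch-mean parallel cell velocity `v_par(t)` with the
#' *negated* near-field ECM toward-tip displacement `-s(t + lag)`: outward
#' cell motion pairs with ECM relaxation, inward motion with contraction,
#' so a positive coefficient means cells and matrix move synchronously in
#' the paired sense. Positive lags mean the ECM follows the cells.
#'
#' @param cell_series A tibble with `frame` and `v_par_mean` (e.g. from
#'   [segment_phases()]), or a plain numeric vector.
#' @param ecm_series A tibble with `frame` and `s_mean` (e.g. from
#'   [frame_mean_displacement()]), or a plain numeric vector aligned with
#'   `cell_series`.
#' @param max_lag Maximum lag scanned, frames (default 5).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A tibble of class `coupling_result`: `lag`, `correlation`, with
#'   attributes `peak_lag`, `peak_correlation`, `n`, `method`. Supports
#'   [generics::glance()] and `autoplot()`.
#' @export
couple_cell_ecm <- function(cell_series, ecm_series, max_lag = 5,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  v <- if (is.numeric(cell_series)) {
    tibble::tibble(frame = seq_along(cell_series), v_par_mean = cell_series)
  } else dplyr::select(tibble::as_tibble(cell_series), "frame", "v_par_mean")
  s <- if (is.numeric(ecm_series)) {
    tibble::tibble(frame = seq_along(ecm_series), s_mean = ecm_series)
  } else dplyr::select(tibble::as_tibble(ecm_series), "frame", "s_mean")
  joined <- dplyr::inner_join(v, s, by = "frame") |> dplyr::arrange(.data$frame)
  if (nrow(joined) < 3) abort("need at least 3 aligned time points")
  if (sd(joined$v_par_mean) == 0 || sd(joined$s_mean) == 0) {
    warn("constant series: coupling correlation undefined")
    out <- tibble::tibble(lag = integer(), correlation = numeric())
    attr(out, "peak_lag") <- NA_integer_
    attr(out, "peak_correlation") <- NA_real_
    attr(out, "n") <- nrow(joined); attr(out, "method") <- method
    class(out) <- c("coupling_result", class(out))
    return(out)
  }
  nt <- nrow(joined)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(l) {
    iv <- seq_len(nt)
    is <- iv + l
    ok <- is >= 1 & is <= nt
    if (sum(ok) < 3) return(NA_real_)
    a <- joined$v_par_mean[iv[ok]]
    b <- -joined$s_mean[is[ok]]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b, method = method)
  }, numeric(1))
  out <- tibble::tibble(lag = lags, correlation = cc)
  best <- which.max(cc)
  attr(out, "peak_lag") <- lags[best]
  attr(out, "peak_correlation") <- cc[best]
  attr(out, "n") <- nt
  attr(out, "method") <- method
  class(out) <- c("coupling_result", class(out))
  out
}
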