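# Synthetic scene generation: image stacks and point sets with known ground
# truth, emulating the statistical structure of organoid branch time lapses
# (tracer beads advected by a tip-centred field, oriented fiber textures,
# nuclei moving in collective phases, global stage drift).

# render Gaussian spots into a Z x Y x X array; positions in continuous
# 0-based voxel coordinates (z, y, x); sigma in voxels
render_spots <- function(dim_zyx, pos_vox, sigma, amplitude) {
  img <- array(0, dim_zyx)
  if (nrow(pos_vox) == 0L) return(img)
  r <- ceiling(4 * sigma)
  thin_z <- dim_zyx[1] == 1L
  for (b in seq_len(nrow(pos_vox))) {
    vz <- pos_vox[b, 1]; vy <- pos_vox[b, 2]; vx <- pos_vox[b, 3]
    win <- function(v, n) {
      lo <- max(1L, floor(v + 1 - r)); hi <- min(n, ceiling(v + 1 + r))
      if (lo > hi) integer(0) else lo:hi
    }
    zi <- if (thin_z) 1L else win(vz, dim_zyx[1])
    yi <- win(vy, dim_zyx[2])
    xi <- win(vx, dim_zyx[3])
    if (!length(zi) || !length(yi) || !length(xi)) next   # spot off-field
    wz <- if (thin_z) 1 else exp(-((zi - 1) - vz)^2 / (2 * sigma^2))
    wy <- exp(-((yi - 1) - vy)^2 / (2 * sigma^2))
    wx <- exp(-((xi - 1) - vx)^2 / (2 * sigma^2))
    img[zi, yi, xi] <- img[zi, yi, xi] +
      as.vector(amplitude * outer(outer(wz, wy), wx))
  }
  img
}

#' Simulate a tracer-bead scene with full ground truth
#'
#' Places beads uniformly at random in the image volume, advects them
#' frame-to-frame with the increments of the reference displacement field
#' ([make_displacement_field()]) so that deformation history accumulates as
#' it does for real tracers, renders each frame as Gaussian spots plus
#' additive Gaussian noise, and optionally superposes a global stage drift.
#' Ground-truth tracks are recorded in µm before rendering, so they carry no
#' discretization error.
#'
#' @param params A [field_params()]; `tip`/`axis` are in µm in image
#'   coordinates.
#' @param n_frames Number of frames (>= 1).
#' @param image_dim Image size as `(z, y, x)` voxel counts; `z = 1` gives a
#'   fast single-slice scene.
#' @param voxel_size Voxel size `(z, y, x)` µm (scalar recycled).
#' @param frame_interval Minutes between frames (default 10).
#' @param n_beads Number of beads (>= 0).
#' @param psf_sigma Gaussian spot width, voxels.
#' @param bead_intensity Peak spot intensity (a.u.).
#' @param noise_sigma Additive Gaussian noise s.d.; SNR is
#'   `bead_intensity / noise_sigma`.
#' @param drift Optional `n_frames x 3` matrix of cumulative stage shifts
#'   `(z, y, x)` in voxels, first row zero. `NULL` means no drift.
#' @param min_spacing Optional minimum pairwise bead spacing in µm, enforced
#'   at placement by dart throwing (useful for detectability-controlled
#'   scenes).
#' @param seed Integer; fixes all randomness (same seed, bit-identical scene).
#' @return An object of class `synthetic_scene`: list with `stack`
#'   ([timelapse_stack()]), `true_tracks` (tibble: `track_id`, `frame`,
#'   `x_um`, `y_um`, `z_um`, `exited`), `true_drift` (tibble: `frame`, `dz`,
#'   `dy`, `dx` voxels), `field` (the params), `psf_sigma`, `noise_sigma`.
#' @examples
#' fp <- field_params(2, 60, 2, 60, 0.5, tip = c(10, 32), axis = c(1, 0))
#' sc <- simulate_bead_scene(fp, n_frames = 4, image_dim = c(1, 64, 64),
#'                           n_beads = 15, seed = 1)
#' @export
simulate_bead_scene <- function(params,
                                n_frames = 12,
                                image_dim = c(1, 128, 128),
                                voxel_size = 1,
                                frame_interval = 10,
                                n_beads = 100,
                                psf_sigma = 1.5,
                                bead_intensity = 1,
                                noise_sigma = 0.1,
                                drift = NULL,
                                min_spacing = NULL,
                                seed = 1) {
  stopifnot(inherits(params, "field_params"), n_beads >= 0, n_frames >= 1)
  image_dim <- as.integer(image_dim)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  extent <- (image_dim - 1) * voxel_size          # physical extent (z,y,x) um
  if (!is.null(drift)) {
    drift <- as.matrix(drift)
    stopifnot(nrow(drift) == n_frames, ncol(drift) == 3L)
    if (any(drift[1, ] != 0)) abort("drift series must start at zero")
  } else {
    drift <- matrix(0, n_frames, 3L)
  }
  u <- make_displacement_field(params)

  with_seed(seed, {
    # initial positions, uniform in the volume (um, x/y/z order internally)
    draw <- function(n) cbind(
      x = runif(n, 0, extent[3]),
      y = runif(n, 0, extent[2]),
      z = if (image_dim[1] == 1L) rep(0, n) else runif(n, 0, extent[1]))
    if (is.null(min_spacing) || n_beads < 2) {
      pos <- draw(n_beads)
    } else {
      pos <- draw(1)
      tries <- 0L
      while (nrow(pos) < n_beads) {
        cand <- draw(1)
        if (min(sqrt(rowSums(sweep(pos, 2, cand)^2))) >= min_spacing) {
          pos <- rbind(pos, cand)
        }
        tries <- tries + 1L
        if (tries > 500L * n_beads) {
          abort("could not place beads at the requested `min_spacing`")
        }
      }
    }
    if (n_beads >= 2) {
      dmat <- as.matrix(stats::dist(pos))
      diag(dmat) <- Inf
      nn <- apply(dmat, 1, min)
      if (mean(nn) < 2 * psf_sigma * mean(voxel_size[2:3])) {
        abort("bead density too high: mean nearest-neighbour spacing < 2 * psf_sigma")
      }
    }

    tracks <- vector("list", n_frames)
    p <- pos
    for (f in seq_len(n_frames)) {
      if (f > 1) {
        t1 <- (f - 2) * frame_interval
        t2 <- (f - 1) * frame_interval
        if (n_beads > 0) p <- p + (u(p, t2) - u(p, t1))
      }
      exited <- p[, "x"] < 0 | p[, "x"] > extent[3] |
        p[, "y"] < 0 | p[, "y"] > extent[2] |
        (if (image_dim[1] > 1L) p[, "z"] < 0 | p[, "z"] > extent[1] else FALSE)
      tracks[[f]] <- tibble::tibble(
        track_id = seq_len(n_beads), frame = f,
        x_um = p[, "x"], y_um = p[, "y"], z_um = p[, "z"],
        exited = as.logical(exited))
    }
    true_tracks <- dplyr::bind_rows(tracks)

    a <- array(0, c(n_frames, image_dim))
    for (f in seq_len(n_frames)) {
      tf <- tracks[[f]]
      pos_vox <- cbind(tf$z_um / voxel_size[1] + drift[f, 1],
                       tf$y_um / voxel_size[2] + drift[f, 2],
                       tf$x_um / voxel_size[3] + drift[f, 3])
      fr <- render_spots(image_dim, pos_vox, psf_sigma, bead_intensity)
      a[f, , , ] <- fr + rnorm(length(fr), sd = noise_sigma)
    }
  })

  structure(list(
    stack = timelapse_stack(a, voxel_size = voxel_size,
                            frame_interval = frame_interval, channel = "beads"),
    true_tracks = true_tracks,
    true_drift = tibble::tibble(frame = seq_len(n_frames),
                                dz = drift[, 1], dy = drift[, 2], dx = drift[, 3]),
    field = params, psf_sigma = psf_sigma, noise_sigma = noise_sigma
  ), class = "synthetic_scene")
}

#' Simulate an oriented fiber texture
#'
#' Renders straight line segments whose angles are drawn from a wrapped
#' normal distribution (axial, modulo 180°). Small `sigma_deg` gives a
#' strongly aligned texture; `sigma_deg` of 60° or more is indistinguishable
#' from isotropic. Angles are measured from the +x (column) axis toward the
#' +y (row) axis.
#'
#' Defaults render long fibers (a sizeable fraction of the field of view,
#' as collagen fibers are at high magnification) at a coverage where
#' individual fibers remain resolvable; short stubby segments would
#' contaminate per-pixel orientation statistics with end-cap pixels, and
#' heavy overlap would narrow them by orientation mixing.
#'
#' @param mean_angle_deg Mean fiber angle, degrees.
#' @param sigma_deg Angular spread (wrapped normal s.d.), degrees, >= 0.
#' @param n_fibers Number of segments.
#' @param image_dim Image size `(y, x)` pixels.
#' @param fiber_length Segment length, pixels.
#' @param line_width Gaussian cross-profile s.d., pixels.
#' @param noise_sigma Additive Gaussian noise s.d.
#' @param seed Integer seed; same seed gives an identical image.
#' @return List with `image` (`Y x X` matrix), `angles_deg` (drawn angles,
#'   wrapped to `[-90, 90)`), and `true_orientation` (list with
#'   `mean_angle_deg`, `sigma_deg`).
#' @examples
#' tx <- simulate_fiber_texture(30, 10, n_fibers = 200,
#'                              image_dim = c(128, 128), seed = 1)
#' @export
simulate_fiber_texture <- function(mean_angle_deg, sigma_deg, n_fibers = 500,
                                   image_dim = c(640, 640), fiber_length = 100,
                                   line_width = 1, noise_sigma = 0.02,
                                   seed = 1) {
  stopifnot(sigma_deg >= 0, n_fibers >= 0)
  ny <- image_dim[1]; nx <- image_dim[2]
  with_seed(seed, {
    ang <- wrap_axial(rnorm(n_fibers, mean_angle_deg, sigma_deg))
    cx <- runif(n_fibers, 1, nx)
    cy <- runif(n_fibers, 1, ny)
    img <- matrix(0, ny, nx)
    if (n_fibers > 0) {
      s <- seq(-fiber_length / 2, fiber_length / 2, by = 0.4)
      px <- as.vector(outer(cos(deg2rad(ang)), s) + cx)  # n_fibers x |s|
      py <- as.vector(outer(sin(deg2rad(ang)), s) + cy)
      off <- as.matrix(expand.grid(oy = -2:2, ox = -2:2))
      idx_all <- integer(0); w_all <- numeric(0)
      for (k in seq_len(nrow(off))) {
        iy <- round(py) + off[k, 1]
        ix <- round(px) + off[k, 2]
        keep <- iy >= 1 & iy <= ny & ix >= 1 & ix <= nx
        if (!any(keep)) next
        w <- exp(-((iy[keep] - py[keep])^2 + (ix[keep] - px[keep])^2) /
                   (2 * line_width^2))
        idx_all <- c(idx_all, (ix[keep] - 1L) * ny + iy[keep])
        w_all <- c(w_all, w)
      }
      if (length(idx_all)) {
        acc <- rowsum(w_all, idx_all)
        img[as.integer(rownames(acc))] <- acc[, 1]
      }
    }
    img <- img + rnorm(length(img), sd = noise_sigma)
  })
  list(image = img, angles_deg = ang,
       true_orientation = list(mean_angle_deg = mean_angle_deg,
                               sigma_deg = sigma_deg))
}

#' Simulate nuclei moving in collective and uncoordinated phases
#'
#' Point nuclei move along (or against) the branch axis during "collective"
#' intervals — all cells share the signed axis velocity plus optional
#' jitter — and with i.i.d. random per-cell velocities (uniform direction,
#' the same speed) during "uncoordinated" intervals. The per-frame step
#' takes the phase of the arrival frame, so velocity labels align with
#' optical-flow frame pairs. Optionally renders the nuclei as Gaussian blobs
#' into a single-slice stack for flow estimation.
#'
#' @param phases Tibble/data.frame with columns `start_frame`, `end_frame`,
#'   `label` (`"collective"` or `"uncoordinated"`), `speed_um_min`, and
#'   `direction` (+1 outward, -1 inward; ignored for uncoordinated).
#'   Intervals must tile `1..n_frames` without overlap.
#' @param geometry A [branch_geometry()]; only the in-plane axis is used.
#' @param n_cells Number of nuclei.
#' @param jitter Per-step isotropic positional noise s.d., µm.
#' @param image_dim Image size `(y, x)` pixels.
#' @param voxel_size Pixel size `(y, x)` µm (scalar recycled).
#' @param frame_interval Minutes per frame.
#' @param nucleus_sigma Blob width, pixels.
#' @param noise_sigma Additive image noise s.d.
#' @param render If `TRUE`, also return a rendered [timelapse_stack()].
#' @param seed Integer seed.
#' @return List with `trajectories` (tibble: `cell_id`, `frame`, `x_um`,
#'   `y_um`), `phase_frames` (tibble: `frame`, `label`, `direction`),
#'   `phases` (the input, normalized), and `stack` (or `NULL`).
#' @examples
#' ph <- tibble::tibble(start_frame = c(1, 5), end_frame = c(4, 8),
#'                      label = c("collective", "uncoordinated"),
#'                      speed_um_min = 1, direction = c(1, 1))
#' geo <- branch_geometry(c(0, 32), c(1, 0))
#' nm <- simulate_nuclei_motion(ph, geo, n_cells = 20, render = FALSE, seed = 1)
#' @export
simulate_nuclei_motion <- function(phases, geometry, n_cells = 60,
                                   jitter = 0, image_dim = c(128, 128),
                                   voxel_size = 1, frame_interval = 10,
                                   nucleus_sigma = 2.5, noise_sigma = 0.02,
                                   render = TRUE, seed = 1) {
  stopifnot(inherits(geometry, "branch_geometry"))
  phases <- tibble::as_tibble(phases)
  if (nrow(phases) == 0L || max(phases$end_frame) < 1) {
    return(list(trajectories = tibble::tibble(cell_id = integer(),
                                              frame = integer(),
                                              x_um = numeric(), y_um = numeric()),
                phase_frames = tibble::tibble(frame = integer(),
                                              label = character(),
                                              direction = numeric()),
                phases = phases, stack = NULL))
  }
  phases <- dplyr::arrange(phases, .data$start_frame)
  if (phases$start_frame[1] != 1L ||
      any(phases$start_frame[-1] != head(phases$end_frame, -1) + 1L)) {
    abort("`phases` must tile frames 1..n without gaps or overlap")
  }
  n_frames <- max(phases$end_frame)
  phase_of_frame <- integer(n_frames)
  for (i in seq_len(nrow(phases))) {
    phase_of_frame[phases$start_frame[i]:phases$end_frame[i]] <- i
  }
  ax <- unit_vector(geometry$axis[c("x", "y")])
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 2L)
  extent <- (image_dim - 1) * voxel_size          # (y, x) um

  with_seed(seed, {
    margin <- 0.1 * extent
    pos <- cbind(x = runif(n_cells, margin[2], extent[2] - margin[2]),
                 y = runif(n_cells, margin[1], extent[1] - margin[1]))
    # per-cell random velocity for each uncoordinated phase, drawn up front
    rand_v <- vector("list", nrow(phases))
    for (i in seq_len(nrow(phases))) {
      if (phases$label[i] == "uncoordinated") {
        th <- runif(n_cells, 0, 2 * pi)
        rand_v[[i]] <- phases$speed_um_min[i] * cbind(x = cos(th), y = sin(th))
      }
    }
    traj <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      if (f > 1) {
        i <- phase_of_frame[f]
        v <- if (phases$label[i] == "collective") {
          matrix(rep(phases$direction[i] * phases$speed_um_min[i] * ax,
                     each = n_cells), ncol = 2L,
                 dimnames = list(NULL, c("x", "y")))
        } else {
          rand_v[[i]]
        }
        pos <- pos + v * frame_interval
        if (jitter > 0) pos <- pos + matrix(rnorm(2 * n_cells, sd = jitter),
                                            ncol = 2L)
      }
      traj[[f]] <- tibble::tibble(cell_id = seq_len(n_cells), frame = f,
                                  x_um = pos[, "x"], y_um = pos[, "y"])
    }
    trajectories <- dplyr::bind_rows(traj)

    stack <- NULL
    if (render) {
      a <- array(0, c(n_frames, 1L, image_dim))
      for (f in seq_len(n_frames)) {
        tf <- traj[[f]]
        pos_vox <- cbind(0, tf$y_um / voxel_size[1], tf$x_um / voxel_size[2])
        fr <- render_spots(c(1L, image_dim), pos_vox, nucleus_sigma, 1)
        a[f, , , ] <- fr + rnorm(length(fr), sd = noise_sigma)
      }
      stack <- timelapse_stack(a, voxel_size = c(1, voxel_size),
                               frame_interval = frame_interval,
                               channel = "nuclei")
    }
  })

  list(trajectories = trajectories,
       phase_frames = tibble::tibble(
         frame = seq_len(n_frames),
         label = ifelse(phases$label[phase_of_frame] == "collective",
                        ifelse(phases$direction[phase_of_frame] > 0,
                               "collective_outward", "collective_inward"),
                        "uncoordinated"),
         direction = phases$direction[phase_of_frame]),
       phases = phases, stack = stack)
}
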