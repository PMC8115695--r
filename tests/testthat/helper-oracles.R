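# Shared fixtures and independent oracles used across tests.

# smooth random 3D array (z, y, x) with spatial structure, fixed seed
textured_volume <- function(dim_zyx, seed = 1, blur = 2) {
  withr::with_seed(seed, {
    a <- array(runif(prod(dim_zyx)), dim_zyx)
    for (z in seq_len(dim_zyx[1])) {
      a[z, , ] <- as.matrix(EBImage::gblur(matrix(a[z, , ], dim_zyx[2], dim_zyx[3]), blur))
    }
    a
  })
}

# build a wrap-free translated frame pair: frame 2 is frame 1 with content
# moved by `shift` = (dz, dy, dx) voxels, both cropped from one big volume
translated_pair <- function(dim_zyx, shift, seed = 1) {
  m <- max(abs(shift)) + 1L
  big <- textured_volume(dim_zyx + 2L * m, seed = seed)
  i0 <- m + 1L
  zr <- i0:(i0 + dim_zyx[1] - 1L)
  yr <- i0:(i0 + dim_zyx[2] - 1L)
  xr <- i0:(i0 + dim_zyx[3] - 1L)
  a <- big[zr, yr, xr, drop = FALSE]
  b <- big[zr - shift[1], yr - shift[2], xr - shift[3], drop = FALSE]
  stack_data <- array(0, c(2L, dim_zyx))
  stack_data[1, , , ] <- a
  stack_data[2, , , ] <- b
  timelapse_stack(stack_data)
}

# independent brute-force NCC drift oracle: plain nested loops
oracle_best_shift <- function(a, b, w) {
  d <- dim(a)
  best <- NULL; best_cc <- -Inf
  for (dz in (if (d[1] == 1L) 0L else -w:w)) for (dy in -w:w) for (dx in -w:w) {
    az <- max(1, 1 + dz):min(d[1], d[1] + dz)
    ay <- max(1, 1 + dy):min(d[2], d[2] + dy)
    ax <- max(1, 1 + dx):min(d[3], d[3] + dx)
    va <- as.vector(b[az, ay, ax, drop = FALSE])
    vb <- as.vector(a[az - dz, ay - dy, ax - dx, drop = FALSE])
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) next
    cc <- stats::cor(va, vb)
    if (cc > best_cc + 1e-12) { best_cc <- cc; best <- c(dz, dy, dx) }
  }
  list(shift = best, cc = best_cc)
}

# brute-force globally optimal one-to-one assignment between two point sets
# (minimum total distance over all permutations; small n only)
oracle_assignment <- function(p1, p2, radius) {
  n <- nrow(p1)
  stopifnot(n == nrow(p2), n <= 7)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(n))) {
    dists <- sqrt(rowSums((p1 - p2[p, , drop = FALSE])^2))
    if (any(dists > radius)) next
    cost <- sum(dists)
    if (cost < best_cost) { best_cost <- cost; best <- p }
  }
  best
}

# match detections to ground-truth positions by mutual nearest neighbour
# within a tolerance; returns counts for precision/recall
match_detections <- function(det, truth, tol = 1.5) {
  if (nrow(det) == 0L) {
    return(list(tp = 0L, fp = 0L, fn = nrow(truth), dists = numeric()))
  }
  dm <- sqrt(outer(det$x_um, truth$x_um, "-")^2 +
               outer(det$y_um, truth$y_um, "-")^2 +
               outer(det$z_um, truth$z_um, "-")^2)
  used_t <- rep(FALSE, nrow(truth)); used_d <- rep(FALSE, nrow(det))
  dists <- numeric()
  repeat {
    dm2 <- dm; dm2[used_d, ] <- Inf; dm2[, used_t] <- Inf
    i <- which.min(dm2)
    if (!length(i) || !is.finite(dm2[i])) break
    di <- ((i - 1) %% nrow(det)) + 1; ti <- ((i - 1) %/% nrow(det)) + 1
    if (dm2[i] > tol) break
    used_d[di] <- TRUE; used_t[ti] <- TRUE
    dists <- c(dists, dm2[i])
  }
  list(tp = sum(used_d), fp = sum(!used_d), fn = sum(!used_t), dists = dists)
}

# reference study-condition field used by several tests
reference_field <- function(rho = 0.5, k = 2, amplitude = 3,
                            decay_length = 80, tip = c(0, 64),
                            axis = c(1, 0)) {
  field_params(amplitude, decay_length, k, period = 60,
               plastic_fraction = rho, tip = tip, axis = axis)
}

# bead tracks laid on a ring around the tip, advected by the exact field
# (no rendering, no localization error): the analytic input for angular
# and stripe statistics
ring_tracks <- function(params, r, theta_deg, n_frames = 7,
                        frame_interval = 10) {
  u <- make_displacement_field(params)
  ax <- params$axis[c("x", "y")]
  perp <- c(-ax[2], ax[1])
  th <- branchmech:::deg2rad(theta_deg)
  pos0 <- cbind(
    x = params$tip["x"] + r * (cos(th) * ax[1] + sin(th) * perp[1]),
    y = params$tip["y"] + r * (cos(th) * ax[2] + sin(th) * perp[2]),
    z = 0)
  p <- pos0
  out <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    if (f > 1) {
      t1 <- (f - 2) * frame_interval; t2 <- (f - 1) * frame_interval
      p <- p + (u(p, t2) - u(p, t1))
    }
    out[[f]] <- tibble::tibble(track_id = seq_along(theta_deg), frame = f,
                               x_um = p[, 1], y_um = p[, 2], z_um = p[, 3])
  }
  dplyr::bind_rows(out)
}
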