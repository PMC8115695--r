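# Synthetic-scene generator: field closed forms, determinism, ground-truth
# integrity.

test_that("displacement field matches its closed form", {
  fp <- field_params(4, 100, 2, 60, 1, tip = c(0, 50), axis = c(1, 0))
  u <- make_displacement_field(fp)
  # at the tip, t = P, rho = 1: all factors unity
  expect_equal(sqrt(sum(u(c(0, 50), 60)^2)), 4)
  # theta = 90 deg: zero for any k > 0
  expect_equal(sqrt(sum(u(c(0, 150), 30)^2)), 0)
  # direction points from the bead toward the tip
  uu <- u(c(80, 50), 30)
  expect_true(uu[1] < 0)
  expect_equal(uu[2], 0)
  # radial decay
  m1 <- sqrt(sum(u(c(50, 50), 30)^2))
  m2 <- sqrt(sum(u(c(150, 50), 30)^2))
  expect_equal(m2 / m1, exp(-100 / 100), tolerance = 1e-12)
})

test_that("time profile: rho=0 vanishes at period boundaries, peaks mid-period", {
  fp <- field_params(1, 100, 0, 60, 0, tip = c(0, 0), axis = c(1, 0))
  tt <- seq(0, 180, by = 0.1)
  g <- field_time_profile(tt, fp)
  # dense-grid evaluation against the closed form
  expect_equal(g, 0.5 * (1 - cos(2 * pi * tt / 60)), tolerance = 1e-12)
  expect_equal(g[tt %in% c(0, 60, 120, 180)], rep(0, 4))
  expect_equal(max(g[tt <= 60]), 1, tolerance = 1e-9)
  expect_equal(tt[tt <= 60][which.max(g[tt <= 60])], 30, tolerance = 0.1)
  # plastic ramp: g(mP) = m * rho
  fp5 <- field_params(1, 100, 0, 60, 0.5, tip = c(0, 0), axis = c(1, 0))
  expect_equal(field_time_profile(c(60, 120, 180), fp5), c(0.5, 1.0, 1.5))
})

test_that("ground-truth displacement equals field increments exactly", {
  fp <- reference_field()
  sc <- simulate_bead_scene(fp, n_frames = 4, image_dim = c(1, 64, 64),
                            n_beads = 12, seed = 3)
  u <- make_displacement_field(fp)
  t1 <- dplyr::filter(sc$true_tracks, frame == 2)
  t0 <- dplyr::filter(sc$true_tracks, frame == 1)
  p0 <- as.matrix(t0[, c("x_um", "y_um", "z_um")])
  step <- u(p0, 10) - u(p0, 0)
  expect_equal(t1$x_um - t0$x_um, step[, 1], tolerance = 1e-12)
  expect_equal(t1$y_um - t0$y_um, step[, 2], tolerance = 1e-12)
})

test_that("cumulative ground-truth displacement over m periods is m * rho * field", {
  fp <- reference_field(rho = 0.5)
  u <- make_displacement_field(fp)
  # a bead held fixed in the record accumulates u(x, t) exactly; advected
  # beads deviate only through the (small) motion of their base point
  sc <- simulate_bead_scene(fp, n_frames = 19, image_dim = c(1, 128, 128),
                            n_beads = 25, noise_sigma = 0, seed = 4)
  tr <- sc$true_tracks
  p0 <- as.matrix(dplyr::filter(tr, frame == 1)[, c("x_um", "y_um", "z_um")])
  one_period <- sqrt(rowSums(u(p0, 60)^2))        # includes g(P) = rho
  last <- dplyr::filter(tr, frame == 19)
  total <- sqrt((last$x_um - p0[, 1])^2 + (last$y_um - p0[, 2])^2)
  # 19 frames x 10 min = 3 periods
  expect_equal(total, 3 * one_period, tolerance = 0.05)
  # strictly increasing across period starts (frames 1, 7, 13, 19)
  b1 <- dplyr::filter(tr, track_id == which.max(one_period))
  d_at <- function(f) {
    r <- dplyr::filter(b1, frame == f)
    sqrt((r$x_um - b1$x_um[1])^2 + (r$y_um - b1$y_um[1])^2)
  }
  expect_true(d_at(7) > d_at(1) && d_at(13) > d_at(7) && d_at(19) > d_at(13))
})

test_that("scene generation is deterministic and honours edge cases", {
  fp <- reference_field()
  s1 <- simulate_bead_scene(fp, n_frames = 3, image_dim = c(1, 48, 48),
                            n_beads = 8, seed = 11)
  s2 <- simulate_bead_scene(fp, n_frames = 3, image_dim = c(1, 48, 48),
                            n_beads = 8, seed = 11)
  expect_identical(s1$stack$data, s2$stack$data)
  expect_identical(s1$true_tracks, s2$true_tracks)

  # n_beads = 0: pure noise, empty tracks
  s0 <- simulate_bead_scene(fp, n_frames = 2, image_dim = c(1, 32, 32),
                            n_beads = 0, seed = 1)
  expect_equal(nrow(s0$true_tracks), 0)
  expect_true(sd(s0$stack$data) > 0)

  # A = 0, no drift: constant tracks
  fp0 <- field_params(0, 100, 2, 60, 0.5, tip = c(0, 24), axis = c(1, 0))
  sc0 <- simulate_bead_scene(fp0, n_frames = 4, image_dim = c(1, 48, 48),
                             n_beads = 6, seed = 2)
  spread <- sc0$true_tracks |>
    dplyr::group_by(track_id) |>
    dplyr::summarise(dx = diff(range(x_um)), dy = diff(range(y_um)))
  expect_equal(max(spread$dx, spread$dy), 0)

  # overdense scene is rejected
  expect_error(
    simulate_bead_scene(fp, n_frames = 2, image_dim = c(1, 16, 16),
                        n_beads = 60, psf_sigma = 2, seed = 1),
    "density")
})

test_that("fiber texture generator is deterministic with controlled order", {
  t1 <- simulate_fiber_texture(30, 0, n_fibers = 60, image_dim = c(96, 96),
                               fiber_length = 30, seed = 5)
  t2 <- simulate_fiber_texture(30, 0, n_fibers = 60, image_dim = c(96, 96),
                               fiber_length = 30, seed = 5)
  expect_identical(t1$image, t2$image)
  # sigma = 0: every drawn angle equals the mean
  expect_true(all(t1$angles_deg == 30))
  # large sigma: angle histogram uniform (chi-square on drawn angles)
  t3 <- simulate_fiber_texture(0, 80, n_fibers = 4000,
                               image_dim = c(64, 64), fiber_length = 10,
                               seed = 6)
  cnt <- table(cut(t3$angles_deg, breaks = seq(-90, 90, by = 15)))
  expect_gt(stats::chisq.test(cnt)$p.value, 0.01)
})

test_that("nuclei motion generator follows its phase schedule", {
  ph <- tibble::tibble(start_frame = c(1, 4), end_frame = c(3, 6),
                       label = c("collective", "uncoordinated"),
                       speed_um_min = 1, direction = c(1, 1))
  geo <- branch_geometry(c(0, 32), c(1, 0))
  nm <- simulate_nuclei_motion(ph, geo, n_cells = 10, jitter = 0,
                               image_dim = c(64, 64), render = FALSE,
                               seed = 7)
  # collective outward at 1 um/min with dt = 10 min: +10 um per step in x
  st <- nm$trajectories |>
    dplyr::arrange(cell_id, frame) |>
    dplyr::group_by(cell_id) |>
    dplyr::mutate(dx = x_um - dplyr::lag(x_um), dy = y_um - dplyr::lag(y_um)) |>
    dplyr::filter(frame %in% 2:3)
  expect_equal(st$dx, rep(10, nrow(st)))
  expect_equal(st$dy, rep(0, nrow(st)))
  expect_equal(nm$phase_frames$label[1:3], rep("collective_outward", 3))
  expect_equal(nm$phase_frames$label[4:6], rep("uncoordinated", 3))
  # determinism and empty movie
  nm2 <- simulate_nuclei_motion(ph, geo, n_cells = 10, jitter = 0,
                                image_dim = c(64, 64), render = FALSE,
                                seed = 7)
  expect_identical(nm$trajectories, nm2$trajectories)
  empty <- simulate_nuclei_motion(ph[0, ], geo, render = FALSE, seed = 1)
  expect_equal(nrow(empty$trajectories), 0)
  # overlapping phases are rejected
  bad <- tibble::tibble(start_frame = c(1, 3), end_frame = c(3, 6),
                        label = c("collective", "uncoordinated"),
                        speed_um_min = 1, direction = 1)
  expect_error(simulate_nuclei_motion(bad, geo, render = FALSE), "tile")
})
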