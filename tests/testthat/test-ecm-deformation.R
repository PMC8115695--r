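# ECM deformation statistics: projection geometry, cumulative series,
# angular and stripe profiles, phase labels, relaxation delta.

make_samples <- function(disp_tbl, geometry) {
  project_samples(disp_tbl, geometry)
}

test_that("projection geometry honours the sign convention", {
  geo <- branch_geometry(c(0, 0), c(1, 0))
  # bead on the axis ahead of the tip, step pointing at the tip
  d1 <- tibble::tibble(track_id = 1, frame = 2, time_min = 10,
                       x_um = 50, y_um = 0, z_um = 0,
                       du_x = -2, du_y = 0, du_z = 0)
  s1 <- project_samples(d1, geo)
  expect_equal(s1$theta_deg, 0)
  expect_equal(s1$r_um, 50)
  expect_equal(s1$s_um, 2)                 # toward the tip: positive
  # step perpendicular to the tip->bead direction: s = 0
  d2 <- dplyr::mutate(d1, du_x = 0, du_y = 3)
  expect_equal(project_samples(d2, geo)$s_um, 0)
  # step away from the tip: negative (relaxation)
  d3 <- dplyr::mutate(d1, du_x = 2)
  expect_equal(project_samples(d3, geo)$s_um, -2)
  # bead perpendicular to the axis: theta = 90
  d4 <- dplyr::mutate(d1, x_um = 0, y_um = 30)
  expect_equal(project_samples(d4, geo)$theta_deg, 90)
})

test_that("every sample lands in exactly one stripe and one angular bin", {
  fp <- reference_field()
  tr <- ring_tracks(fp, r = rep(c(40, 80, 150, 260), each = 18),
                    theta_deg = rep(seq(5, 175, 10), times = 4),
                    n_frames = 4)
  geo <- branch_geometry(c(0, 64), c(1, 0))
  disp <- track_displacements(tr)
  smp <- project_samples(disp, geo)
  ap <- angular_profile(smp, 15)
  expect_equal(sum(ap$n), nrow(smp))
  sp <- stripe_profile(smp, geo, 100)
  fwd <- sum(smp$theta_deg <= 90)
  expect_equal(sum(sp$n), fwd)
})

test_that("cumulative displacement is n * delta for constant steps", {
  geo <- branch_geometry(c(0, 0), c(1, 0), near_field_um = 300)
  delta <- 0.25
  disp <- tidyr::expand_grid(track_id = 1:3, frame = 2:6) |>
    dplyr::mutate(time_min = (frame - 1) * 10,
                  x_um = 50, y_um = 0, z_um = 0,
                  du_x = -delta, du_y = 0, du_z = 0)
  cum <- cumulative_displacement(project_samples(disp, geo), geo)
  expect_equal(cum$cum_um, delta * (0:5))
  expect_equal(cum$time_min, 10 * (0:5))
  expect_equal(cum$cum_um[1], 0)
})

test_that("zero field gives a flat zero series; empty near field errors", {
  geo <- branch_geometry(c(0, 0), c(1, 0), near_field_um = 300)
  disp <- tidyr::expand_grid(track_id = 1:2, frame = 2:4) |>
    dplyr::mutate(time_min = (frame - 1) * 10, x_um = 40, y_um = 10,
                  z_um = 0, du_x = 0, du_y = 0, du_z = 0)
  cum <- cumulative_displacement(project_samples(disp, geo), geo)
  expect_equal(cum$cum_um, rep(0, 4))
  geo_far <- branch_geometry(c(-1000, 0), c(-1, 0), near_field_um = 10)
  expect_error(
    cumulative_displacement(project_samples(disp, geo_far), geo_far),
    "empty near field")
})

test_that("plastic synthetic field reproduces the closed-form ramp", {
  fp <- reference_field(rho = 0.5, k = 2, amplitude = 3, decay_length = 80)
  geo <- branch_geometry(c(0, 64), c(1, 0), near_field_um = 120)
  sc <- simulate_bead_scene(fp, n_frames = 19, image_dim = c(1, 128, 128),
                            n_beads = 40, noise_sigma = 0, seed = 5)
  disp <- track_displacements(sc$true_tracks)
  smp <- project_samples(disp, geo)
  cum <- cumulative_displacement(smp, geo)
  u <- make_displacement_field(fp)
  nf_ids <- unique(smp$track_id[branchmech:::in_near_field(smp, geo)])
  p0 <- sc$true_tracks |>
    dplyr::filter(frame == 1, track_id %in% nf_ids)
  per_period <- mean(sqrt(rowSums(
    u(as.matrix(p0[, c("x_um", "y_um", "z_um")]), 60)^2)))
  # three periods of net plastic gain (truth tracks: only advection error)
  expect_equal(cum$cum_um[cum$frame == 19], 3 * per_period, tolerance = 0.05)
  # increasing between period starts (frames 1, 7, 13, 19)
  ps <- cum$cum_um[cum$frame %in% c(1, 7, 13, 19)]
  expect_true(all(diff(ps) > 0))
})

test_that("angular profile is strictly decreasing for k > 0 and flat for k = 0", {
  geo <- branch_geometry(c(0, 64), c(1, 0))
  for (k in c(1, 2, 4)) {
    fp <- reference_field(rho = 1, k = k)
    tr <- ring_tracks(fp, r = 60, theta_deg = seq(2.5, 177.5, by = 5),
                      n_frames = 3)
    smp <- project_samples(track_displacements(tr), geo)
    ap <- angular_profile(smp, 15)
    fwd <- ap$s_mean[ap$theta_hi <= 90]
    expect_true(all(diff(fwd) < 0), info = sprintf("k = %d", k))
  }
  fp0 <- reference_field(rho = 1, k = 0)
  tr0 <- ring_tracks(fp0, r = 60, theta_deg = seq(2.5, 87.5, by = 5),
                     n_frames = 3)
  ap0 <- angular_profile(project_samples(track_displacements(tr0), geo), 15)
  expect_lt(diff(range(ap0$s_mean)) / mean(ap0$s_mean), 0.02)
})

test_that("stripe means follow the analytic exponential decay", {
  fp <- reference_field(rho = 1, k = 0, amplitude = 2, decay_length = 150)
  geo <- branch_geometry(c(0, 64), c(1, 0))
  tr <- ring_tracks(fp, r = rep(c(50, 150, 250, 350), each = 7),
                    theta_deg = rep(seq(10, 70, 10), times = 4),
                    n_frames = 3)
  smp <- project_samples(track_displacements(tr), geo)
  sp <- stripe_profile(smp, geo, 100, per_frame = FALSE)
  expect_true(all(diff(sp$s_mean) < 0))
  # ratio between consecutive stripes: exp(-100 / lambda) up to advection
  expect_equal(sp$s_mean[2] / sp$s_mean[1], exp(-100 / 150), tolerance = 0.02)
  # single bead in one stripe; other stripes flagged empty, not zero
  one <- tibble::tibble(track_id = 1, frame = 2, time_min = 10,
                        x_um = 150, y_um = 64, z_um = 0,
                        du_x = -2, du_y = 0, du_z = 0)
  sp1 <- stripe_profile(project_samples(one, geo), geo, 100,
                        per_frame = FALSE)
  expect_equal(sp1$s_mean[sp1$stripe == 2], 2)
  expect_true(is.na(sp1$s_mean[sp1$stripe == 1]))
  expect_equal(sp1$n[sp1$stripe == 1], 0L)
})

test_that("phase labels follow the sign of the mean displacement", {
  ser <- tibble::tibble(frame = 1:6,
                        s_mean = c(0.5, 0.2, -0.3, -0.1, 0.005, 0))
  lab <- label_phases_ecm(ser, noise_floor = 0.01)
  expect_equal(lab$phase, c("contraction", "contraction", "relaxation",
                            "relaxation", "neutral", "neutral"))
  expect_equal(label_phases_ecm(ser)$phase[5], "contraction")
  # periodic field, rho = 0: alternating labels with the field period
  fp <- reference_field(rho = 0, k = 0)
  geo <- branch_geometry(c(0, 64), c(1, 0))
  tr <- ring_tracks(fp, r = rep(60, 12), theta_deg = seq(5, 60, 5),
                    n_frames = 13)
  fm <- frame_mean_displacement(project_samples(track_displacements(tr), geo),
                                geo)
  lab2 <- label_phases_ecm(fm, noise_floor = 1e-9)
  # period 60 min = 6 frames: contraction while g rises (t in (0, 30)),
  # relaxation while it falls (t in (30, 60)), contraction again after
  expect_equal(lab2$phase[lab2$frame %in% 2:4], rep("contraction", 3))
  expect_equal(lab2$phase[lab2$frame %in% 5:7], rep("relaxation", 3))
  expect_equal(lab2$phase[lab2$frame %in% 8:10], rep("contraction", 3))
})

test_that("relaxation delta quantifies the post-event change", {
  ser <- tibble::tibble(frame = 1:10, time_min = 10 * (0:9),
                        cum_um = c(0, 1, 2, 3, 4, 5, 3.5, 2.5, 2, 2))
  expect_equal(relaxation_delta(ser, 6), -3)
  expect_equal(relaxation_delta(ser, 10), 0)
  flat <- tibble::tibble(frame = 1:5, cum_um = c(0, 1, 2, 2, 2))
  expect_equal(relaxation_delta(flat, 3), 0)
  expect_error(relaxation_delta(ser, 12), "event_frame")
  # constructed reversal: field reversed by fraction phi after the event
  phi <- 0.4
  cum <- c(seq(0, 2, length.out = 6), 2 - phi * 2 * seq(0.25, 1, 0.25))
  ser2 <- tibble::tibble(frame = 1:10, cum_um = cum)
  expect_equal(relaxation_delta(ser2, 6), -phi * 2)
})

test_that("beads leaving the near field are frozen at exit", {
  geo <- branch_geometry(c(0, 0), c(1, 0), near_field_um = 100)
  # bead 1 stays at r = 50; bead 2 starts inside then exits to r = 150
  disp <- dplyr::bind_rows(
    tibble::tibble(track_id = 1, frame = 2:5, x_um = 50, y_um = 0, z_um = 0,
                   du_x = -1, du_y = 0, du_z = 0),
    tibble::tibble(track_id = 2, frame = 2:5,
                   x_um = c(90, 150, 150, 150), y_um = 0, z_um = 0,
                   du_x = -1, du_y = 0, du_z = 0)) |>
    dplyr::mutate(time_min = (frame - 1) * 10)
  cum <- cumulative_displacement(project_samples(disp, geo), geo)
  # bead 2 contributes its first step only, frozen at 1 um afterwards
  expect_equal(cum$cum_um, c(0, 1, 1.5, 2, 2.5))
  expect_equal(attr(cum, "n_frozen"), 1L)
})
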