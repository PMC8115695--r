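# Optical flow, velocity decomposition, phase segmentation, coupling.

textured_frame <- function(n = 128, seed = 1) {
  withr::with_seed(seed,
    as.matrix(EBImage::gblur(matrix(runif((n + 32)^2), n + 32, n + 32), 2)))
}

test_that("static movies give zero flow", {
  f <- textured_frame(64)[1:64, 1:64]
  fl <- compute_flow(list(f, f), voxel_size = 1, frame_interval = 10)
  expect_lt(max(abs(fl$vx)), 1e-6)
  expect_lt(max(abs(fl$vy)), 1e-6)
})

test_that("uniform translation speed is recovered within 10 percent", {
  big <- textured_frame(128, seed = 2)
  f1 <- big[17:144, 17:144]
  f2 <- big[17:144, (17:144) - 3]          # content moves +3 px in x
  fl <- compute_flow(list(f1, f2), voxel_size = 1, frame_interval = 10)
  inner <- 20:108
  expect_equal(median(fl$vx[1, inner, inner]), 0.3, tolerance = 0.1 * 0.3)
  expect_lt(abs(median(fl$vy[1, inner, inner])), 0.03)
  # antisymmetry: reversed pair gives the opposite flow
  fl2 <- compute_flow(list(f2, f1), voxel_size = 1, frame_interval = 10)
  expect_equal(median(fl2$vx[1, inner, inner]), -0.3, tolerance = 0.15 * 0.3)
})

test_that("units chain: voxel size and frame interval scale velocities", {
  big <- textured_frame(96, seed = 3)
  f1 <- big[9:104, 9:104]; f2 <- big[9:104, (9:104) - 2]
  fl <- compute_flow(list(f1, f2), voxel_size = c(1, 0.5), frame_interval = 5)
  inner <- 20:76
  # 2 px * 0.5 um/px / 5 min = 0.2 um/min
  expect_equal(median(fl$vx[1, inner, inner]), 0.2, tolerance = 0.02)
})

test_that("blank frames yield zero flow with a warning", {
  f <- textured_frame(64)[1:64, 1:64]
  expect_warning(
    fl <- compute_flow(list(f, matrix(0, 64, 64)), voxel_size = 1),
    "blank frame")
  expect_equal(max(abs(fl$vx)), 0)
})

test_that("axis decomposition is exact and invertible", {
  geo <- branch_geometry(c(0, 0), c(1, 1))   # axis at 45 degrees
  ax <- branchmech:::unit_vector(c(1, 1))
  vf <- structure(list(
    vx = array(rnorm(2 * 8 * 8), c(2, 8, 8)),
    vy = array(rnorm(2 * 8 * 8), c(2, 8, 8)),
    pixel_size = c(y = 1, x = 1), frame_interval = 10),
    class = "velocity_field")
  dec <- decompose_velocity(vf, geo)
  # reconstruction to machine precision
  expect_equal(dec$v_par * ax[1] + dec$v_orth * -ax[2], dec$v_x,
               tolerance = 1e-12)
  expect_equal(dec$v_par * ax[2] + dec$v_orth * ax[1], dec$v_y,
               tolerance = 1e-12)
  expect_equal(dec$v_par^2 + dec$v_orth^2, dec$v_x^2 + dec$v_y^2,
               tolerance = 1e-12)
  # pure axis-parallel motion: v_par = |v|, v_orth = 0
  vf2 <- vf
  vf2$vx[] <- 2 * ax[1]; vf2$vy[] <- 2 * ax[2]
  dec2 <- decompose_velocity(vf2, geo)
  expect_equal(dec2$v_par, rep(2, nrow(dec2)), tolerance = 1e-12)
  expect_equal(max(abs(dec2$v_orth)), 0, tolerance = 1e-12)
  # motion at 90 degrees to the axis: v_par = 0
  vf3 <- vf
  vf3$vx[] <- -ax[2]; vf3$vy[] <- ax[1]
  expect_equal(max(abs(decompose_velocity(vf3, geo)$v_par)), 0,
               tolerance = 1e-12)
})

test_that("flow on a rendered collective scene recovers the cell speed", {
  ph <- tibble::tibble(start_frame = c(1, 4), end_frame = c(3, 6),
                       label = "collective", speed_um_min = 1,
                       direction = c(1, -1))
  geo <- branch_geometry(c(0, 64), c(1, 0))
  nm <- simulate_nuclei_motion(ph, geo, n_cells = 60, jitter = 0,
                               image_dim = c(128, 128), seed = 21)
  fl <- compute_flow(nm$stack)
  dec <- decompose_velocity(fl, geo)
  mean_vpar <- dec |>
    dplyr::group_by(frame) |>
    dplyr::summarise(v = mean(v_par))
  # outward phase steps (frames 2-3): +1 um/min; inward (frames 5-6): -1
  expect_equal(mean_vpar$v[mean_vpar$frame %in% 2:3], c(1, 1),
               tolerance = 0.15)
  expect_equal(mean_vpar$v[mean_vpar$frame %in% 5:6], c(-1, -1),
               tolerance = 0.15)
})

test_that("phase segmentation recovers the schedule exactly from clean velocities", {
  ph <- tibble::tibble(start_frame = c(1, 4, 8), end_frame = c(3, 7, 10),
                       label = c("collective", "uncoordinated", "collective"),
                       speed_um_min = 1, direction = c(1, 1, -1))
  geo <- branch_geometry(c(0, 64), c(1, 0))
  nm <- simulate_nuclei_motion(ph, geo, n_cells = 40, jitter = 0,
                               image_dim = c(512, 512), render = FALSE,
                               seed = 22)
  # per-cell parallel velocities straight from the jitter-free trajectories
  vpar <- nm$trajectories |>
    dplyr::arrange(cell_id, frame) |>
    dplyr::group_by(cell_id) |>
    dplyr::mutate(v_par = (x_um - dplyr::lag(x_um)) / 10) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(v_par))
  phases <- segment_phases(vpar, phi_threshold = 0.5)
  truth <- nm$phase_frames$label[-1]
  expect_equal(phases$label, truth)
  expect_equal(phases$phi[phases$frame %in% 2:3], c(1, 1))
  iv <- phase_intervals(phases)
  expect_equal(nrow(iv), 3)
  expect_equal(iv$start_frame, c(2, 4, 8))
  # random directions on a large mask: phi near zero
  rnd <- tibble::tibble(frame = 1,
                        v_par = withr::with_seed(5, sample(c(-1, 1), 4000,
                                                           replace = TRUE)))
  expect_lt(segment_phases(rnd)$phi, 0.1)
  expect_equal(segment_phases(rnd)$label, "uncoordinated")
})

test_that("coupling is +1 at lag 0 for exactly paired series", {
  v <- sin(seq(0, 6 * pi, length.out = 40))
  s <- -0.7 * v
  cp <- couple_cell_ecm(v, s, max_lag = 4)
  expect_equal(attr(cp, "peak_lag"), 0)
  expect_equal(attr(cp, "peak_correlation"), 1, tolerance = 1e-12)
})

test_that("a constructed delay shifts the coupling peak to lag 1", {
  withr::with_seed(31, {
    v <- as.numeric(stats::filter(rnorm(60), rep(1 / 3, 3), sides = 1))
  })
  v[is.na(v)] <- 0
  s <- c(0, -v[-60])            # ECM follows the cells one frame later
  cp <- couple_cell_ecm(v, s, max_lag = 4)
  expect_equal(attr(cp, "peak_lag"), 1)
  expect_gt(attr(cp, "peak_correlation"), 0.9)
})

test_that("independent series stay inside a permutation null band", {
  withr::with_seed(32, {
    v <- rnorm(80); s <- rnorm(80)
    cp <- couple_cell_ecm(v, s, max_lag = 3)
    null_q <- quantile(replicate(500, abs(cor(sample(v), s))), 0.99)
  })
  expect_lt(abs(attr(cp, "peak_correlation")), null_q + 0.1)
})

test_that("constant series are flagged as undefined coupling", {
  expect_warning(cp <- couple_cell_ecm(rep(1, 10), rnorm(10)), "constant")
  expect_true(is.na(attr(cp, "peak_correlation")))
})
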