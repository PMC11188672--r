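test_that("angle trajectory has the metronome-implied period and exact endpoints", {
  ph <- phantom_config()
  for (bpm in c(45, 100)) {
    # mocap rate chosen so the full-cycle period (2.667 s / 1.2 s) is an
    # integer number of samples and periodicity can be checked exactly
    rate <- if (bpm == 45) 90 else 100
    ses <- session_config(bpm = bpm, trial_duration_s = 30, mocap_rate_hz = rate,
                          beat_jitter_sd_s = 0, angle_jitter_sd_deg = 0)
    tr <- generate_angle_trajectory(ses, ph)
    period <- 2 * 60 / bpm  # plantarflexion on every second beat
    lag <- as.integer(round(period * rate))
    expect_equal(lag / rate, period, tolerance = 1e-12)
    n <- nrow(tr)
    expect_lt(max(abs(tr$theta_deg[seq_len(n - lag) + lag] -
                        tr$theta_deg[seq_len(n - lag)])), 1e-9)
    expect_equal(min(tr$theta_deg), ph$theta_neutral_deg, tolerance = 1e-12)
    expect_equal(max(tr$theta_deg), ph$theta_plantar_deg, tolerance = 1e-12)
  }
  expect_error(generate_angle_trajectory(
    session_config(trial_duration_s = 1e-9), ph), NA)
  expect_error(session_config(trial_duration_s = -1), "positive")
  expect_error(session_config(bpm = 0), "positive")
})

test_that("angle trajectory is smooth with dense sampling near the reversals", {
  ph <- phantom_config()
  ses <- session_config(trial_duration_s = 60, beat_jitter_sd_s = 0,
                        angle_jitter_sd_deg = 0)
  tr <- generate_angle_trajectory(ses, ph)
  # raised cosine: slope ~ 0 at extremes, so equal-width angle windows near
  # the extremes collect far more samples than one at mid-range
  lo <- sum(tr$theta_deg <= 115)
  mid <- sum(tr$theta_deg >= 134 & tr$theta_deg <= 136)
  hi <- sum(tr$theta_deg >= 155)
  expect_gt(lo, 2 * mid)
  expect_gt(hi, 2 * mid)
  # slope bounded by the raised-cosine maximum
  amp <- (ph$theta_plantar_deg - ph$theta_neutral_deg) / 2
  max_slope <- 2 * amp * pi / (2 * 60 / ses$bpm) * (2 / 2)  # A*pi/T_half
  emp <- max(abs(diff(tr$theta_deg))) * ses$mocap_rate_hz
  expect_lt(emp, max_slope * 1.01)
})

test_that("marker synthesis inverts the ankle-angle computation to 1e-9 deg", {
  for (theta in c(0.5, 45, 90, 113, 130, 157, 179.5)) {
    mk <- angle_to_markers(theta)
    expect_lt(abs(compute_ankle_angle(mk) - theta), 1e-9)
  }
  # under arbitrary rigid transforms too
  set.seed(11)
  for (i in 1:10) {
    th <- runif(1, 5, 175)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); ang <- runif(1, 0, 2 * pi)
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
    mk <- angle_to_markers(th, rotation = R, translation = rnorm(3, 0, 100))
    expect_lt(abs(compute_ankle_angle(mk) - th), 1e-9)
  }
  expect_error(marker_geometry(shank_length_mm = 0), "degenerate")
  expect_error(angle_to_markers(185), "between 0 and 180")
  # segment lengths constant over time
  mk <- angle_to_markers(seq(100, 160, by = 5))
  shank <- sqrt((mk$epicondyle_lat_x - mk$malleolus_lat_x)^2 +
                (mk$epicondyle_lat_y - mk$malleolus_lat_y)^2 +
                (mk$epicondyle_lat_z - mk$malleolus_lat_z)^2)
  foot <- sqrt((mk$metatarsal5_x - mk$malleolus_lat_x)^2 +
               (mk$metatarsal5_y - mk$malleolus_lat_y)^2 +
               (mk$metatarsal5_z - mk$malleolus_lat_z)^2)
  expect_lt(diff(range(shank)), 1e-9)
  expect_lt(diff(range(foot)), 1e-9)
})

test_that("muscle length interpolates linearly between the endpoint lengths", {
  ph <- phantom_config(L_neutral_mm = 200, L_plantar_mm = 222.4)
  expect_equal(muscle_length_at(ph$theta_neutral_deg, ph), 200)
  expect_equal(muscle_length_at(ph$theta_plantar_deg, ph), 222.4)
  expect_equal(muscle_length_at((113 + 157) / 2, ph), 211.2)
  # clamped outside the endpoint angles
  expect_equal(muscle_length_at(90, ph), 200)
  expect_equal(muscle_length_at(170, ph), 222.4)
})

test_that("the analytic CSA profile integrates to the phantom volume at every angle", {
  for (shape in c("spindle", "ellipsoid")) {
    ph <- phantom_config(shape = shape)
    for (th in seq(113, 157, length.out = 50)) {
      L <- muscle_length_at(th, ph)
      v <- integrate(Vectorize(function(x) csa_at(ph, th, x)), 0, L,
                     subdivisions = 1000, rel.tol = 1e-8)$value
      expect_lt(abs(v / ph$volume_mm3 - 1), 0.005)
    }
  }
})

test_that("the CSA peak sits at the configured, length-interpolated position", {
  ph <- phantom_config()
  s <- seq(0.01, 0.99, by = 1e-4)
  for (th in c(113, 135, 157)) {
    L <- muscle_length_at(th, ph)
    u <- (L - ph$L_neutral_mm) / (ph$L_plantar_mm - ph$L_neutral_mm)
    p_true <- ph$csa_peak_frac_short +
      u * (ph$csa_peak_frac_long - ph$csa_peak_frac_short)
    p_emp <- s[which.max(csa_at(ph, th, s * L))]
    expect_lt(abs(p_emp - p_true), 2e-4)
  }
})

test_that("rendered cross-sections match the analytic ellipse area", {
  # mid-muscle slice of a pure-ellipsoid configuration with a = b
  ph <- phantom_config(shape = "ellipsoid", aspect_ratio = 1, noise_sd = 0,
                       image_px = c(64, 64))
  L <- muscle_length_at(113, ph)
  img <- render_cross_section(ph, 113, L / 2)
  a_true <- csa_at(ph, 113, L / 2)
  r_px <- sqrt(a_true / pi) / ph$pixel_mm
  boundary_px <- 2 * pi * r_px
  expect_lt(abs(sum(img) * ph$pixel_mm^2 - a_true), boundary_px * ph$pixel_mm^2)
  # beyond the muscle end: background only
  expect_identical(sum(render_cross_section(ph, 113, L + 5)), 0)
  expect_identical(sum(render_cross_section(ph, 113, -3)), 0)
  # noise is seeded through the caller's RNG
  set.seed(5); n1 <- render_cross_section(ph, 113, L / 2, noise_sd = 0.05)
  set.seed(5); n2 <- render_cross_section(ph, 113, L / 2, noise_sd = 0.05)
  expect_identical(n1, n2)
})

test_that("simulated sessions have the documented file layout and frame spacing", {
  ph <- phantom_config()
  ses <- session_config(trial_duration_s = 10, n_trials = 2, seed = 3)
  us <- simulate_session(ses, ph, dir = file.path(tempdir(), "lay1"))
  expect_length(us$trial_dirs, 2)
  for (td in us$trial_dirs) {
    expect_true(all(file.exists(file.path(td, c("frames.tif", "encoder.csv",
                                                "markers.csv", "truth.csv")))))
  }
  enc <- read.csv(file.path(us$trial_dirs[1], "encoder.csv"))
  expect_named(enc, c("t_s", "axis1_mm", "axis2_mm", "axis3_mm", "frame_idx"))
  # |dpos| = probe_speed / frame_rate except at sweep turnarounds
  dpos <- abs(diff(enc$axis2_mm))
  nominal <- ses$probe_speed_mm_s / ses$frame_rate_hz
  interior <- dpos[abs(dpos - nominal) < 1e-6]
  expect_gt(length(interior) / length(dpos), 0.95)
  expect_true(all(dpos <= nominal + 1e-9))
  # frames count = duration * rate + 1
  expect_equal(nrow(enc), 10 * 30 + 1)
  # markers at the mocap rate
  mk <- read.csv(file.path(us$trial_dirs[1], "markers.csv"))
  expect_equal(nrow(mk), 10 * 100 + 1)
  expect_equal(ncol(mk), 1 + 6 * 3)
})

test_that("simulation is deterministic for a fixed seed, and differs across seeds", {
  ph <- phantom_config(image_px = c(16, 16))
  ses <- session_config(trial_duration_s = 3, n_trials = 1, seed = 42)
  a <- simulate_session(ses, ph, dir = file.path(tempdir(), "det_a"))
  b <- simulate_session(ses, ph, dir = file.path(tempdir(), "det_b"))
  for (f in c("encoder.csv", "markers.csv", "truth.csv", "frames.tif")) {
    expect_identical(readBin(file.path(a$trial_dirs[1], f), "raw", 1e6),
                     readBin(file.path(b$trial_dirs[1], f), "raw", 1e6),
                     info = f)
  }
  ses2 <- session_config(trial_duration_s = 3, n_trials = 1, seed = 43)
  c3 <- simulate_session(ses2, ph, dir = file.path(tempdir(), "det_c"))
  expect_false(identical(readBin(file.path(a$trial_dirs[1], "frames.tif"), "raw", 1e6),
                         readBin(file.path(c3$trial_dirs[1], "frames.tif"), "raw", 1e6)))
})

test_that("sessions round-trip through disk in both frame formats", {
  ph <- phantom_config(image_px = c(16, 16))
  ses <- session_config(trial_duration_s = 2, n_trials = 1, seed = 9)
  for (fmt in c("tiff", "nifti")) {
    us <- simulate_session(ses, ph, dir = file.path(tempdir(), paste0("rt_", fmt)),
                           format = fmt)
    us2 <- read_session(us$dir)
    expect_equal(us2$session$bpm, ses$bpm)
    expect_equal(us2$muscle_origin_mm, us$muscle_origin_mm)
    tr <- sonogate:::load_trial_(us2, 1)
    expect_length(tr$images, 2 * 30 + 1)
    expect_equal(dim(tr$images[[1]]), c(16, 16))
  }
})

test_that("the ground-truth table matches the rendered content", {
  ph <- phantom_config()
  ses <- session_config(trial_duration_s = 8, n_trials = 1, seed = 77)
  us <- simulate_session(ses, ph, dir = file.path(tempdir(), "truthchk"))
  tr <- sonogate:::load_trial_(us, 1)
  truth <- tr$truth
  # recorded CSA equals the analytic CSA at the recorded angle/position
  i <- which(truth$csa_mm2 > 50)[1:20]
  for (k in i) {
    expect_equal(truth$csa_mm2[k],
                 csa_at(ph, truth$theta_deg[k],
                        truth$scan_pos_mm[k] - us$muscle_origin_mm,
                        active = truth$slope_deg_s[k] < 0),
                 tolerance = 1e-9)
  }
  # frames with substantial true CSA contain foreground; empty truth, none
  fg <- vapply(tr$images, function(m) sum(m > 0.5), numeric(1))
  expect_true(all(fg[truth$csa_mm2 > 50] > 10))
  expect_true(all(fg[truth$csa_mm2 == 0] < 3))
})

test_that("the active-bulging hook scales CSA only on active half-cycles", {
  ph <- phantom_config(active_csa_scale = 1.15)
  expect_equal(csa_at(ph, 130, 100, active = TRUE) /
               csa_at(ph, 130, 100, active = FALSE), 1.15, tolerance = 1e-12)
  ph0 <- phantom_config()
  expect_equal(csa_at(ph0, 130, 100, active = TRUE),
               csa_at(ph0, 130, 100, active = FALSE))
})

test_that("phantom configuration invariants are enforced", {
  expect_error(phantom_config(volume_mm3 = -1))
  expect_error(phantom_config(csa_peak_frac_short = 0), "between 0 and 1")
  expect_error(phantom_config(csa_peak_frac_long = 1), "between 0 and 1")
  expect_error(phantom_config(L_neutral_mm = 220, L_plantar_mm = 210), "exceed")
  expect_error(phantom_config(theta_neutral_deg = 160, theta_plantar_deg = 150),
               "exceed")
})
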