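# Shared fixtures. The full-scale pipeline fixture (two velocities, 2 x 150 s
# sub-trials each, 64 x 64 px frames, default phantom) is expensive (~2 min),
# so it is built once on first use and cached for the whole test run.

.fixture_env <- new.env(parent = emptyenv())

pipeline_fixture <- function() {
  if (!is.null(.fixture_env$result)) return(.fixture_env$result)
  ph <- phantom_config()
  slow <- simulate_session(
    session_config(bpm = 45, trial_duration_s = 150, n_trials = 2, seed = 20),
    ph, dir = file.path(tempdir(), "fix_slow"))
  fast <- simulate_session(
    session_config(bpm = 100, trial_duration_s = 150, n_trials = 2, seed = 1020),
    ph, dir = file.path(tempdir(), "fix_fast"))
  res <- run_gated_pipeline(slow, fast)
  .fixture_env$result <- list(result = res, phantom = ph,
                              slow = slow, fast = fast)
  .fixture_env$result
}

# A closed n-vertex ellipse contour record as produced by segment_slices.
make_ellipse_contour <- function(a, b, z, n = 96, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  v <- cbind(center[1] + a * cos(th), center[2] + b * sin(th))
  cen <- sonogate:::polygon_centroid_(v)
  list(slice = NA_integer_, vertices = v, z_mm = z,
       area_mm2 = sonogate:::polygon_area_(v),
       centroid_mm = c(cen[1], cen[2], z))
}

make_contour_set <- function(contours, pixel_mm = 1) {
  structure(list(contours = contours, pixel_mm = pixel_mm),
            class = "contour_set")
}

# Minimal synced_frames object for binning tests (tiny placeholder images).
make_synced <- function(theta, direction, scan_pos, pixel_mm = 1,
                        images = NULL, t = seq_along(theta) / 30,
                        trial_id = 1L) {
  n <- length(theta)
  if (is.null(images)) images <- replicate(n, matrix(0, 2, 2), simplify = FALSE)
  structure(list(
    table = data.frame(frame_idx = seq_len(n), t = t, scan_pos_mm = scan_pos,
                       vert_pos_mm = 0, theta_deg = theta,
                       direction = direction, trial_id = trial_id),
    images = images, pixel_mm = pixel_mm), class = "synced_frames")
}

# Minimal bin_stack for merge / inclusion tests.
make_stack <- function(positions, images = NULL, theta = 130,
                       direction = "active", velocity = "slow") {
  n <- length(positions)
  if (is.null(images)) images <- replicate(n, matrix(0, 2, 2), simplify = FALSE)
  structure(list(theta_center_deg = theta, direction = direction,
                 velocity = velocity, positions_mm = positions,
                 vert_pos_mm = rep(0, n), images = images,
                 frame_idx = seq_len(n), pixel_mm = 1, n_raw = n,
                 merged = FALSE, accepted = NA, rejection_reason = "none"),
            class = "bin_stack")
}
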