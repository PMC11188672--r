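#' Deforming-muscle phantom configuration
#'
#' Defines a constant-volume, spindle-shaped muscle whose length tracks the
#' ankle joint angle. Cross-sections are ellipses whose semi-axes follow a
#' piecewise-quadratic longitudinal profile peaking at a configurable fraction
#' of muscle length; the profile integrates to `volume_mm3` at every length,
#' so muscle volume is conserved across the motion by construction.
#'
#' The length--angle map is linear between the neutral and plantarflexed
#' endpoint angles (clamped outside), and the fractional position of the peak
#' cross-sectional area (CSA) is interpolated linearly in length between
#' `csa_peak_frac_short` (at `L_neutral_mm`) and `csa_peak_frac_long` (at
#' `L_plantar_mm`). The defaults reproduce a tibialis-anterior-like muscle:
#' 89 cm^3 volume, 11.2% elongation from 113 deg (neutral, shortest) to
#' 157 deg (plantarflexed, longest), and a CSA peak sitting at 55% of the
#' reference length L0 when shortest and 60% of L0 when longest.
#'
#' @param volume_mm3 Muscle volume in mm^3, constant across the motion.
#' @param L_neutral_mm,L_plantar_mm Muscle length (mm) at the neutral and
#'   plantarflexed endpoint angles; `L_plantar_mm > L_neutral_mm`.
#' @param theta_neutral_deg,theta_plantar_deg Endpoint ankle angles (deg);
#'   `theta_plantar_deg > theta_neutral_deg`.
#' @param csa_peak_frac_short,csa_peak_frac_long Fractional position (0-1,
#'   proximal = 0) of the maximum CSA along the *current* muscle length, at the
#'   shortest and longest length respectively. The default long value
#'   `0.60 / 1.112` places the peak at 60% of L0 for the default 11.2%
#'   elongation.
#' @param aspect_ratio Ellipse semi-axis ratio a/b of the cross-sections.
#' @param pixel_mm In-plane pixel size (mm) of rendered frames.
#' @param noise_sd Standard deviation of additive Gaussian image noise
#'   (images are on a 0-1 intensity scale).
#' @param image_px Rendered frame size, `c(rows, cols)` pixels.
#' @param shape `"spindle"` (default) or `"ellipsoid"`. The ellipsoid shape is
#'   an exact ellipsoid of revolution-like body (semi-axes `a`, `b`, `L/2`)
#'   used by the geometry oracles; its CSA peak is fixed at midlength.
#' @param active_csa_scale Optional CSA scale factor applied on active
#'   (dorsiflexion) half-cycles only, emulating activation-dependent bulging.
#'   Default 1 (no asymmetry).
#' @return An object of class `phantom_config`.
#' @seealso [session_config()], [simulate_session()], [csa_at()]
#' @export
phantom_config <- function(volume_mm3 = 89000,
                           L_neutral_mm = 200,
                           L_plantar_mm = 222.4,
                           theta_neutral_deg = 113,
                           theta_plantar_deg = 157,
                           csa_peak_frac_short = 0.55,
                           csa_peak_frac_long = 0.60 / 1.112,
                           aspect_ratio = 1.5,
                           pixel_mm = 1.0,
                           noise_sd = 0.05,
                           image_px = c(64, 64),
                           shape = c("spindle", "ellipsoid"),
                           active_csa_scale = 1.0) {
  shape <- match.arg(shape)
  stopifnot(volume_mm3 > 0, aspect_ratio > 0, pixel_mm > 0, noise_sd >= 0,
            length(image_px) == 2, all(image_px >= 8), active_csa_scale > 0)
  if (!(csa_peak_frac_short > 0 && csa_peak_frac_short < 1 &&
        csa_peak_frac_long > 0 && csa_peak_frac_long < 1))
    stop("csa_peak_frac_* must lie strictly between 0 and 1", call. = FALSE)
  if (!(L_plantar_mm > L_neutral_mm))
    stop("L_plantar_mm must exceed L_neutral_mm", call. = FALSE)
  if (!(theta_plantar_deg > theta_neutral_deg))
    stop("theta_plantar_deg must exceed theta_neutral_deg", call. = FALSE)
  structure(list(volume_mm3 = volume_mm3,
                 L_neutral_mm = L_neutral_mm, L_plantar_mm = L_plantar_mm,
                 theta_neutral_deg = theta_neutral_deg,
                 theta_plantar_deg = theta_plantar_deg,
                 csa_peak_frac_short = csa_peak_frac_short,
                 csa_peak_frac_long = csa_peak_frac_long,
                 aspect_ratio = aspect_ratio, pixel_mm = pixel_mm,
                 noise_sd = noise_sd, image_px = as.integer(image_px),
                 shape = shape, active_csa_scale = active_csa_scale),
            class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("<phantom_config>\n")
  cat(sprintf("  %s muscle, V = %.1f cm^3, L = %.1f -> %.1f mm over theta %g -> %g deg\n",
              x$shape, x$volume_mm3 / 1000, x$L_neutral_mm, x$L_plantar_mm,
              x$theta_neutral_deg, x$theta_plantar_deg))
  cat(sprintf("  CSA peak frac %.3f (short) -> %.3f (long), a/b = %g\n",
              x$csa_peak_frac_short, x$csa_peak_frac_long, x$aspect_ratio))
  cat(sprintf("  frames %d x %d px at %g mm/px, noise sd %g\n",
              x$image_px[1], x$image_px[2], x$pixel_mm, x$noise_sd))
  invisible(x)
}

#' Acquisition-session configuration
#'
#' Describes one simulated acquisition at one metronome velocity: the foot
#' oscillates between the phantom's endpoint angles ("plantarflexion on every
#' second beat"), while the probe sweeps back and forth along the scan axis as
#' a triangle wave. The full movement cycle therefore spans two beats,
#' i.e. `2 * 60 / bpm` seconds.
#'
#' Human timing is not metronome-perfect, so per-beat timing jitter
#' (`beat_jitter_sd_s`) and per-beat endpoint-angle jitter
#' (`angle_jitter_sd_deg`) are applied by default; set both to 0 for an
#' idealised trajectory that hits the endpoint angles exactly.
#'
#' @param bpm Metronome rate in beats/min (45 = slow, 100 = fast in the
#'   reference protocol; any positive value is accepted).
#' @param probe_speed_mm_s Probe sweep speed along the scan axis (mm/s).
#' @param frame_rate_hz Ultrasound frame rate (Hz).
#' @param mocap_rate_hz Motion-capture marker rate (Hz).
#' @param trial_duration_s Duration of one sub-trial (s).
#' @param n_trials Number of sub-trials per velocity.
#' @param sweep_extent_mm Scan-path length (mm). The default 231.7 mm covers
#'   the default phantom with margin and makes the probe round-trip period
#'   jointly incommensurate with both reference metronome periods (the
#'   per-cycle probe step is far from every small-denominator rational
#'   fraction of the round trip), so frame positions within an angle bin --
#'   in particular the reversal dwells that feed the extreme bins --
#'   decorrelate across sweeps instead of aliasing onto a position lattice.
#' @param seed Integer random seed; drives trajectory jitter and image noise.
#' @param beat_jitter_sd_s SD of the i.i.d. per-beat timing error (s). Human
#'   metronome tracking is good but not perfect; the default 0.04 s is typical
#'   tapping variability and also decorrelates the movement cycle from the
#'   probe sweep.
#' @param angle_jitter_sd_deg SD of an optional per-beat endpoint-angle error
#'   (deg). Default 0: the trajectory reaches the endpoint angles exactly, so
#'   the angle-bin population at the movement reversals is dense and the
#'   available ROM equals the configured endpoints. Non-zero values emulate
#'   amplitude variability; note that they create marginal bins beyond the
#'   nominal endpoints that are occupied only by rare over-shoot dwells, which
#'   is useful for exercising the inclusion criteria but makes ROM-end
#'   morphometry coverage-limited.
#' @return An object of class `session_config`.
#' @export
session_config <- function(bpm = 45,
                           probe_speed_mm_s = 20,
                           frame_rate_hz = 30,
                           mocap_rate_hz = 100,
                           trial_duration_s = 135,
                           n_trials = 4,
                           sweep_extent_mm = 231.7,
                           seed = 1L,
                           beat_jitter_sd_s = 0.04,
                           angle_jitter_sd_deg = 0) {
  if (!(bpm > 0 && probe_speed_mm_s > 0 && frame_rate_hz > 0 &&
        mocap_rate_hz > 0 && sweep_extent_mm > 0))
    stop("all rates, speeds and extents must be positive", call. = FALSE)
  if (!(trial_duration_s > 0))
    stop("trial_duration_s must be positive", call. = FALSE)
  if (!(n_trials >= 1)) stop("n_trials must be >= 1", call. = FALSE)
  structure(list(bpm = bpm, probe_speed_mm_s = probe_speed_mm_s,
                 frame_rate_hz = frame_rate_hz, mocap_rate_hz = mocap_rate_hz,
                 trial_duration_s = trial_duration_s, n_trials = as.integer(n_trials),
                 sweep_extent_mm = sweep_extent_mm, seed = as.integer(seed),
                 beat_jitter_sd_s = beat_jitter_sd_s,
                 angle_jitter_sd_deg = angle_jitter_sd_deg),
            class = "session_config")
}

#' @export
print.session_config <- function(x, ...) {
  cat("<session_config>\n")
  cat(sprintf("  %g bpm (cycle %.3f s), %d x %g s trials, probe %g mm/s over %g mm\n",
              x$bpm, 2 * 60 / x$bpm, x$n_trials, x$trial_duration_s,
              x$probe_speed_mm_s, x$sweep_extent_mm))
  cat(sprintf("  frames %g Hz, mocap %g Hz, seed %d\n",
              x$frame_rate_hz, x$mocap_rate_hz, x$seed))
  invisible(x)
}

#' Muscle length at a given ankle angle
#'
#' Linear interpolation between the neutral and plantarflexed lengths; angles
#' outside the endpoint range are clamped.
#'
#' @param theta_deg Ankle angle(s) in degrees.
#' @param phantom A [phantom_config()].
#' @return Muscle length(s) in mm.
#' @export
muscle_length_at <- function(theta_deg, phantom) {
  stopifnot(inherits(phantom, "phantom_config"))
  th <- clamp_(theta_deg, phantom$theta_neutral_deg, phantom$theta_plantar_deg)
  u <- (th - phantom$theta_neutral_deg) /
    (phantom$theta_plantar_deg - phantom$theta_neutral_deg)
  phantom$L_neutral_mm + u * (phantom$L_plantar_mm - phantom$L_neutral_mm)
}

# Fractional CSA-peak position at muscle length L (linear in L).
peak_frac_at_ <- function(phantom, L) {
  if (phantom$shape == "ellipsoid") return(rep(0.5, length(L)))
  u <- (L - phantom$L_neutral_mm) / (phantom$L_plantar_mm - phantom$L_neutral_mm)
  phantom$csa_peak_frac_short +
    clamp_(u, 0, 1) * (phantom$csa_peak_frac_long - phantom$csa_peak_frac_short)
}

# Dimensionless semi-axis profile q(s) in [0,1], peak value 1 at s = p.
# Spindle: two parabolic arcs, zero at the ends, C1 at the peak; the integral
# of q^2 over [0,1] is 8/15 for every p, which makes volume independent of the
# peak position. Ellipsoid: q = sqrt(4 s (1-s)), integral of q^2 is 2/3.
axis_profile_ <- function(s, p, shape) {
  if (shape == "ellipsoid") return(sqrt(pmax(0, 4 * s * (1 - s))))
  side <- ifelse(s <= p, p, 1 - p)
  pmax(0, 1 - ((s - p) / side)^2)
}

# Peak semi-axes (a, b) at muscle length L such that the CSA profile
# integrates to the phantom volume.
peak_axes_ <- function(phantom, L, active = FALSE) {
  ab <- if (phantom$shape == "ellipsoid") {
    3 * phantom$volume_mm3 / (2 * pi * L)
  } else {
    15 * phantom$volume_mm3 / (8 * pi * L)
  }
  scale <- if (active) phantom$active_csa_scale else 1
  ab <- ab * scale
  b <- sqrt(ab / phantom$aspect_ratio)
  c(a = phantom$aspect_ratio * b, b = b)
}

#' Analytic cross-sectional area of the phantom
#'
#' CSA of the phantom at angle `theta_deg` and axial position `axial_pos_mm`
#' measured from the proximal muscle end. Returns 0 outside the muscle.
#'
#' @inheritParams muscle_length_at
#' @param axial_pos_mm Position(s) along the muscle from the proximal end (mm).
#' @param active Logical; apply the active-bulging CSA scale factor.
#' @return CSA in mm^2.
#' @export
csa_at <- function(phantom, theta_deg, axial_pos_mm, active = FALSE) {
  stopifnot(inherits(phantom, "phantom_config"), length(theta_deg) == 1)
  L <- muscle_length_at(theta_deg, phantom)
  s <- axial_pos_mm / L
  ax <- peak_axes_(phantom, L, active)
  q <- axis_profile_(s, peak_frac_at_(phantom, L), phantom$shape)
  out <- pi * ax["a"] * ax["b"] * q^2
  out[s < 0 | s > 1] <- 0
  unname(out)
}

#' Render one synthetic cross-sectional frame
#'
#' Draws the phantom's elliptical cross-section as a bright disc on a dark
#' background with a one-pixel anti-aliased edge (pixel value = approximate
#' coverage fraction), then adds Gaussian noise from the *current* RNG state
#' and clips to the 0-1 intensity range. Positions outside the muscle yield a
#' background-only (noise) image.
#'
#' @inheritParams csa_at
#' @param image_px,pixel_mm,noise_sd Overrides for the phantom's frame raster.
#' @return A numeric matrix `image_px[1] x image_px[2]` with values in 0-1.
#' @export
render_cross_section <- function(phantom, theta_deg, axial_pos_mm,
                                 image_px = phantom$image_px,
                                 pixel_mm = phantom$pixel_mm,
                                 noise_sd = phantom$noise_sd,
                                 active = FALSE) {
  stopifnot(inherits(phantom, "phantom_config"))
  nr <- image_px[1]; nc <- image_px[2]
  L <- muscle_length_at(theta_deg, phantom)
  s <- axial_pos_mm / L
  img <- matrix(0, nr, nc)
  if (s >= 0 && s <= 1) {
    ax <- peak_axes_(phantom, L, active)
    q <- axis_profile_(s, peak_frac_at_(phantom, L), phantom$shape)
    a <- ax["a"] * q; b <- ax["b"] * q
    if (a > pixel_mm / 4 && b > pixel_mm / 4) {
      # pixel-centre coordinates, image centred on the muscle axis
      u <- (seq_len(nc) - (nc + 1) / 2) * pixel_mm
      v <- (seq_len(nr) - (nr + 1) / 2) * pixel_mm
      U <- matrix(u, nr, nc, byrow = TRUE)
      V <- matrix(v, nr, nc)
      f <- sqrt((U / a)^2 + (V / b)^2)
      denom <- sqrt((U / a^2)^2 + (V / b^2)^2)
      d <- ifelse(denom > 0, (f - 1) * f / denom, -min(a, b))  # signed distance, mm
      img <- clamp_(0.5 - d / pixel_mm, 0, 1)
    }
  }
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
  clamp_(img, 0, 1)
}

# Piecewise raised-cosine angle trajectory as a closure; all jitter is drawn
# from the current RNG state. Returns list(theta = function(t), slope = f(t)).
make_angle_fun_ <- function(session, phantom) {
  half <- 60 / session$bpm
  dur <- session$trial_duration_s
  n_beats <- ceiling(dur / half) + 2L
  tb <- (0:n_beats) * half
  if (session$beat_jitter_sd_s > 0 && n_beats >= 1) {
    tb[-1] <- tb[-1] + stats::rnorm(n_beats, 0, session$beat_jitter_sd_s)
    tb <- cummax(tb + seq_along(tb) * 1e-9)  # keep strictly increasing
  }
  ends <- ifelse((0:n_beats) %% 2 == 0, phantom$theta_neutral_deg,
                 phantom$theta_plantar_deg)
  if (session$angle_jitter_sd_deg > 0) {
    ends <- ends + stats::rnorm(n_beats + 1L, 0, session$angle_jitter_sd_deg)
  }
  theta <- function(t) {
    i <- pmin(pmax(findInterval(t, tb), 1L), n_beats)
    u <- (t - tb[i]) / (tb[i + 1L] - tb[i])
    ends[i] + (ends[i + 1L] - ends[i]) * (1 - cos(pi * clamp_(u, 0, 1))) / 2
  }
  slope <- function(t) {
    i <- pmin(pmax(findInterval(t, tb), 1L), n_beats)
    dt <- tb[i + 1L] - tb[i]
    u <- (t - tb[i]) / dt
    (ends[i + 1L] - ends[i]) * pi * sin(pi * clamp_(u, 0, 1)) / (2 * dt)
  }
  list(theta = theta, slope = slope, beats = tb, endpoints = ends)
}

#' Generate the ankle-angle trajectory of one sub-trial
#'
#' Smooth periodic angle curve at the motion-capture rate: a raised cosine
#' between per-beat endpoint angles, so the angular velocity is zero at the
#' movement reversals and maximal at mid-range (more frames accumulate near
#' the extremes, as in human cyclic movement). With jitter disabled the curve
#' oscillates exactly between the phantom's endpoint angles with full-cycle
#' period `2 * 60 / bpm` seconds. Deterministic for a fixed `session$seed`.
#'
#' @param session A [session_config()].
#' @param phantom A [phantom_config()].
#' @return A data frame with columns `t` (s) and `theta_deg`, plus attributes
#'   `beats` (jittered beat times) and `slope_deg_s`.
#' @export
generate_angle_trajectory <- function(session, phantom) {
  stopifnot(inherits(session, "session_config"), inherits(phantom, "phantom_config"))
  if (!(session$trial_duration_s > 0))
    stop("invalid config: non-positive trial duration", call. = FALSE)
  af <- with_seed_(session$seed, make_angle_fun_(session, phantom))
  t <- seq(0, session$trial_duration_s, by = 1 / session$mocap_rate_hz)
  out <- data.frame(t = t, theta_deg = af$theta(t))
  attr(out, "beats") <- af$beats
  attr(out, "slope_deg_s") <- af$slope(t)
  out
}

#' Leg marker-set geometry
#'
#' Constant segment lengths and medio-lateral marker offsets used to
#' synthesise marker trajectories from an ankle angle.
#'
#' @param shank_length_mm Lateral epicondyle to lateral malleolus distance.
#' @param foot_length_mm Lateral malleolus to fifth metatarsal distance.
#' @param knee_width_mm,ankle_width_mm,foot_width_mm Medio-lateral separation
#'   of the medial/first-ray markers from their lateral counterparts.
#' @return An object of class `marker_geometry`.
#' @export
marker_geometry <- function(shank_length_mm = 400, foot_length_mm = 150,
                            knee_width_mm = 90, ankle_width_mm = 70,
                            foot_width_mm = 70) {
  if (shank_length_mm <= 0 || foot_length_mm <= 0)
    stop("degenerate geometry: segment lengths must be positive", call. = FALSE)
  structure(list(shank_length_mm = shank_length_mm, foot_length_mm = foot_length_mm,
                 knee_width_mm = knee_width_mm, ankle_width_mm = ankle_width_mm,
                 foot_width_mm = foot_width_mm),
            class = "marker_geometry")
}

MARKER_NAMES <- c("epicondyle_lat", "epicondyle_med", "malleolus_lat",
                  "malleolus_med", "metatarsal1", "metatarsal5")

#' Synthesise marker positions for given ankle angles
#'
#' Inverse of [compute_ankle_angle()]: places the shank markers at fixed
#' positions and rotates the foot markers about the malleolus in the sagittal
#' plane so that the angle between the epicondyle-to-malleolus and
#' malleolus-to-metatarsal vectors equals `theta_deg`. An optional rigid-body
#' transform is applied to all markers (the recovered angle is invariant
#' under it).
#'
#' @param theta_deg Ankle angle(s) in degrees, strictly between 0 and 180.
#' @param geometry A [marker_geometry()].
#' @param rotation 3x3 rotation matrix applied to all markers.
#' @param translation Length-3 translation (mm) applied to all markers.
#' @return A data frame with one row per angle and columns `<marker>_x`,
#'   `<marker>_y`, `<marker>_z` (mm) for the six markers.
#' @export
angle_to_markers <- function(theta_deg, geometry = marker_geometry(),
                             rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(geometry, "marker_geometry"))
  if (any(theta_deg <= 0 | theta_deg >= 180))
    stop("theta_deg must lie strictly between 0 and 180", call. = FALSE)
  th <- theta_deg * pi / 180
  base <- list(
    epicondyle_lat = cbind(0, 0, rep(geometry$shank_length_mm, length(th))),
    malleolus_lat  = cbind(0, 0, rep(0, length(th))),
    metatarsal5    = cbind(geometry$foot_length_mm * sin(th), 0,
                           -geometry$foot_length_mm * cos(th)))
  base$epicondyle_med <- base$epicondyle_lat + rep(c(0, geometry$knee_width_mm, 0), each = length(th))
  base$malleolus_med  <- base$malleolus_lat + rep(c(0, geometry$ankle_width_mm, 0), each = length(th))
  base$metatarsal1    <- base$metatarsal5 + rep(c(0, geometry$foot_width_mm, 0), each = length(th))
  out <- data.frame(row.names = seq_along(th))
  for (m in MARKER_NAMES) {
    p <- base[[m]] %*% t(rotation)
    p <- sweep(p, 2, translation, "+")
    out[[paste0(m, "_x")]] <- p[, 1]
    out[[paste0(m, "_y")]] <- p[, 2]
    out[[paste0(m, "_z")]] <- p[, 3]
  }
  out
}

#' Simulate a full acquisition session
#'
#' Writes `n_trials` sub-trials to disk: rendered frame streams (multi-page
#' TIFF or NIfTI), per-frame encoder positions (CSV), marker trajectories at
#' the motion-capture rate (CSV) and a per-frame ground-truth table (CSV),
#' plus a JSON sidecar echoing both configurations. The probe position along
#' the scan axis is a triangle wave at `probe_speed_mm_s`; the muscle's
#' proximal end is fixed and its distal end tracks the angle-dependent length.
#' Deterministic for a fixed `session$seed`.
#'
#' @param session A [session_config()].
#' @param phantom A [phantom_config()].
#' @param dir Output directory (created if needed).
#' @param format `"tiff"` (multi-page, 8-bit) or `"nifti"`.
#' @return An object of class `us_session`: paths, configs, and the muscle's
#'   proximal-end scan coordinate `muscle_origin_mm`.
#' @export
simulate_session <- function(session, phantom, dir = tempfile("us_session_"),
                             format = c("tiff", "nifti")) {
  stopifnot(inherits(session, "session_config"), inherits(phantom, "phantom_config"))
  format <- match.arg(format)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create session directory: ", dir, call. = FALSE)
  origin <- (session$sweep_extent_mm - phantom$L_plantar_mm) / 2
  trial_dirs <- character(session$n_trials)
  for (k in seq_len(session$n_trials)) {
    td <- file.path(dir, sprintf("trial_%02d", k))
    if (!dir.exists(td) && !dir.create(td))
      stop("cannot create trial directory: ", td, call. = FALSE)
    trial_dirs[k] <- td
    tr_seed <- (as.numeric(session$seed) * 2654435761 + k) %% 2147483647
    with_seed_(tr_seed, {
      af <- make_angle_fun_(session, phantom)
      # markers at mocap rate
      tm <- seq(0, session$trial_duration_s, by = 1 / session$mocap_rate_hz)
      mk <- angle_to_markers(af$theta(tm))
      utils::write.csv(cbind(t_s = tm, mk), file.path(td, "markers.csv"),
                       row.names = FALSE)
      # frames + encoder at frame rate
      tf <- seq(0, session$trial_duration_s, by = 1 / session$frame_rate_hz)
      theta_f <- af$theta(tf)
      slope_f <- af$slope(tf)
      # the sweep and the metronome are started asynchronously, so each
      # sub-trial begins at a random phase of the probe's back-and-forth path
      probe_phase <- stats::runif(1, 0, 2 * session$sweep_extent_mm /
                                    session$probe_speed_mm_s)
      pos <- triangle_wave_(tf + probe_phase, session$sweep_extent_mm,
                            session$probe_speed_mm_s)
      enc <- data.frame(t_s = tf, axis1_mm = 0, axis2_mm = pos, axis3_mm = 0,
                        frame_idx = seq_along(tf))
      utils::write.csv(enc, file.path(td, "encoder.csv"), row.names = FALSE)
      L_f <- muscle_length_at(theta_f, phantom)
      s_f <- (pos - origin) / L_f
      active_f <- slope_f < 0
      imgs <- vector("list", length(tf))
      for (i in seq_along(tf)) {
        imgs[[i]] <- render_cross_section(phantom, theta_f[i], pos[i] - origin,
                                          active = active_f[i])
      }
      if (format == "tiff") {
        ok <- tiff::writeTIFF(imgs, file.path(td, "frames.tif"),
                              bits.per.sample = 8L, compression = "LZW")
        if (!identical(ok, length(imgs)) && !isTRUE(ok > 0))
          stop("failed to write frames to ", file.path(td, "frames.tif"), call. = FALSE)
      } else {
        arr <- array(unlist(imgs), dim = c(dim(imgs[[1]]), length(imgs)))
        RNifti::writeNifti(RNifti::asNifti(arr, pixdim = c(phantom$pixel_mm,
                                                           phantom$pixel_mm, 1)),
                           file.path(td, "frames.nii.gz"))
      }
      dir_true <- ifelse(slope_f < 0, "active",
                         ifelse(slope_f > 0, "passive", "excluded"))
      truth <- data.frame(frame_idx = seq_along(tf), t_s = tf,
                          theta_deg = theta_f, slope_deg_s = slope_f,
                          direction = dir_true, scan_pos_mm = pos,
                          s_frac = s_f, L_mm = L_f,
                          csa_mm2 = vapply(seq_along(tf), function(i)
                            csa_at(phantom, theta_f[i], pos[i] - origin,
                                   active = active_f[i]), numeric(1)))
      utils::write.csv(truth, file.path(td, "truth.csv"), row.names = FALSE)
    })
  }
  meta <- list(session = unclass(session), phantom = unclass(phantom),
               muscle_origin_mm = origin, format = format,
               trial_dirs = basename(trial_dirs))
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(dir = dir, trial_dirs = trial_dirs, session = session,
                 phantom = phantom, muscle_origin_mm = origin, format = format),
            class = "us_session")
}

#' @export
print.us_session <- function(x, ...) {
  cat("<us_session>\n")
  cat(sprintf("  %d trial(s) of %g s at %g bpm in %s\n",
              x$session$n_trials, x$session$trial_duration_s, x$session$bpm, x$dir))
  invisible(x)
}

#' Reload a simulated session from disk
#'
#' @param dir Directory previously written by [simulate_session()].
#' @return A `us_session` object.
#' @export
read_session <- function(dir) {
  sj <- file.path(dir, "session.json")
  if (!file.exists(sj)) stop("no session.json found in ", dir, call. = FALSE)
  meta <- jsonlite::read_json(sj, simplifyVector = TRUE)
  ses <- do.call(session_config, meta$session[names(formals(session_config))])
  ph <- do.call(phantom_config, meta$phantom[names(formals(phantom_config))])
  structure(list(dir = dir, trial_dirs = file.path(dir, meta$trial_dirs),
                 session = ses, phantom = ph,
                 muscle_origin_mm = meta$muscle_origin_mm, format = meta$format),
            class = "us_session")
}

# Load one trial's frames and tables into memory.
load_trial_ <- function(us, k) {
  td <- us$trial_dirs[k]
  imgs <- if (us$format == "tiff") {
    tiff::readTIFF(file.path(td, "frames.tif"), all = TRUE)
  } else {
    arr <- RNifti::readNifti(file.path(td, "frames.nii.gz"))
    lapply(seq_len(dim(arr)[3]), function(i) arr[, , i])
  }
  list(images = imgs,
       encoder = utils::read.csv(file.path(td, "encoder.csv")),
       markers = utils::read.csv(file.path(td, "markers.csv")),
       truth = utils::read.csv(file.path(td, "truth.csv")))
}
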