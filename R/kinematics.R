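#' Compute the ankle joint angle from markers
#'
#' The ankle angle is the angle between the vector from the lateral knee
#' epicondyle to the lateral malleolus and the vector from the lateral
#' malleolus to the fifth metatarsal. Only the three lateral-chain markers are
#' used; medial markers, when present, are validated for finiteness but do not
#' enter the angle. The result is invariant under any rigid rotation or
#' translation applied to all markers.
#'
#' @param markers Either a data frame with columns `epicondyle_lat_x/_y/_z`,
#'   `malleolus_lat_*`, `metatarsal5_*` (one angle per row), or a named list
#'   of length-3 numeric marker positions.
#' @return Ankle angle(s) in degrees, in `[0, 180]`.
#' @export
compute_ankle_angle <- function(markers) {
  get3 <- function(name) {
    if (is.data.frame(markers)) {
      cols <- paste0(name, c("_x", "_y", "_z"))
      if (!all(cols %in% names(markers)))
        stop("missing marker data: ", name, call. = FALSE)
      as.matrix(markers[, cols])
    } else {
      p <- markers[[name]]
      if (is.null(p)) stop("missing marker data: ", name, call. = FALSE)
      matrix(as.numeric(p), nrow = 1)
    }
  }
  epi <- get3("epicondyle_lat"); mal <- get3("malleolus_lat"); met <- get3("metatarsal5")
  if (!all(is.finite(epi)) || !all(is.finite(mal)) || !all(is.finite(met)))
    stop("missing marker data: non-finite marker coordinates", call. = FALSE)
  v1 <- mal - epi
  v2 <- met - mal
  n1 <- sqrt(rowSums(v1^2)); n2 <- sqrt(rowSums(v2^2))
  if (any(n1 < 1e-9) || any(n2 < 1e-9))
    stop("degenerate geometry: zero-length segment vector", call. = FALSE)
  cosang <- clamp_(rowSums(v1 * v2) / (n1 * n2), -1, 1)
  acos(cosang) * 180 / pi
}

#' Resample a channel to the ultrasound frame times
#'
#' Linear interpolation (default) or previous-sample hold of an arbitrary-rate
#' channel at the frame timestamps. Frame times may extend past the channel
#' support by at most one channel sample period (edge values are held there);
#' anything further is an error.
#'
#' @param t Channel sample times (s), strictly increasing.
#' @param x Channel values, same length as `t`.
#' @param frame_times Target times (s).
#' @param method `"linear"` or `"hold"` (previous-sample hold).
#' @return Values at `frame_times`.
#' @export
resample_to_frame_rate <- function(t, x, frame_times, method = c("linear", "hold")) {
  method <- match.arg(method)
  if (length(t) == 0 || length(x) == 0) stop("empty channel", call. = FALSE)
  stopifnot(length(t) == length(x))
  period <- if (length(t) > 1) stats::median(diff(t)) else Inf
  if (any(frame_times < t[1] - period | frame_times > t[length(t)] + period))
    stop("out-of-range: frame time outside channel support by more than one sample period",
         call. = FALSE)
  if (method == "linear") {
    stats::approx(t, x, xout = frame_times, rule = 2)$y
  } else {
    stats::approx(t, x, xout = frame_times, method = "constant", f = 0, rule = 2)$y
  }
}

#' Label movement direction from the angle curve
#'
#' The angle series is smoothed with a centred moving average, the slope is
#' estimated by central differences (in deg/frame), and each sample is
#' labelled `active` (dorsiflexion, negative slope), `passive`
#' (plantarflexion, positive slope) or `excluded` when the slope magnitude is
#' within the dead-band `slope_eps`. The dead-band keeps jitter at movement
#' reversals from flip-flopping between directions.
#'
#' @param theta_deg Ankle angle series at the frame rate (>= 3 samples).
#' @param window Moving-average window in frames (odd; default 5).
#' @param slope_eps Dead-band half-width in deg/frame (default 0.05).
#' @return Character vector of labels, one per sample.
#' @export
label_direction <- function(theta_deg, window = 5L, slope_eps = 0.05) {
  n <- length(theta_deg)
  if (n < 3) stop("need at least 3 samples to label direction", call. = FALSE)
  window <- max(1L, as.integer(window))
  sm <- as.numeric(stats::filter(theta_deg, rep(1 / window, window), sides = 2))
  # shrink the window near the edges instead of dropping samples
  half <- window %/% 2L
  for (i in which(is.na(sm))) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    sm[i] <- mean(theta_deg[lo:hi])
  }
  slope <- numeric(n)
  slope[2:(n - 1)] <- (sm[3:n] - sm[1:(n - 2)]) / 2
  slope[1] <- sm[2] - sm[1]
  slope[n] <- sm[n] - sm[n - 1]
  ifelse(slope < -slope_eps, "active",
         ifelse(slope > slope_eps, "passive", "excluded"))
}

#' Synchronise one trial to the ultrasound frame rate
#'
#' Computes the ankle angle from the marker stream, resamples it to the frame
#' timestamps from the encoder table, and labels the movement direction,
#' yielding one angle and one direction per frame.
#'
#' @param trial A list with elements `images` (list of matrices), `encoder`
#'   (data frame with `t_s`, `axis2_mm`, `axis3_mm`, `frame_idx`) and
#'   `markers` (data frame with `t_s` and marker columns), as produced by the
#'   session simulator's per-trial files.
#' @param pixel_mm In-plane pixel size of the frames (mm).
#' @param trial_id Identifier stored with every frame.
#' @param window,slope_eps Passed to [label_direction()].
#' @return An object of class `synced_frames`: `$table` (one row per frame:
#'   `frame_idx`, `t`, `scan_pos_mm`, `vert_pos_mm`, `theta_deg`, `direction`,
#'   `trial_id`) and `$images`.
#' @export
sync_trial <- function(trial, pixel_mm, trial_id = 1L, window = 5L, slope_eps = 0.05) {
  enc <- trial$encoder
  theta_m <- compute_ankle_angle(trial$markers)
  theta_f <- resample_to_frame_rate(trial$markers$t_s, theta_m, enc$t_s)
  tab <- data.frame(frame_idx = enc$frame_idx, t = enc$t_s,
                    scan_pos_mm = enc$axis2_mm, vert_pos_mm = enc$axis3_mm,
                    theta_deg = theta_f,
                    direction = label_direction(theta_f, window, slope_eps),
                    trial_id = trial_id)
  structure(list(table = tab, images = trial$images, pixel_mm = pixel_mm),
            class = "synced_frames")
}

#' Stitch synchronised sub-trials into one stream
#'
#' Concatenates the frame tables and images of several sub-trials. Each
#' trial's times are shifted so the stitched time axis is monotone (one frame
#' period after the end of the previous trial); no frame is dropped and
#' `trial_id` is retained.
#'
#' @param trials List of `synced_frames` objects sharing the same pixel size.
#' @return A single `synced_frames` object.
#' @export
stitch_trials <- function(trials) {
  stopifnot(length(trials) >= 1)
  px <- vapply(trials, function(x) x$pixel_mm, numeric(1))
  if (any(abs(px - px[1]) > 1e-12))
    stop("incompatible trials: pixel sizes differ", call. = FALSE)
  if (length(trials) == 1) return(trials[[1]])
  tabs <- lapply(trials, function(x) x$table)
  offset <- 0
  for (i in seq_along(tabs)) {
    dtf <- stats::median(diff(tabs[[i]]$t))
    tabs[[i]]$t <- tabs[[i]]$t + offset
    offset <- max(tabs[[i]]$t) + dtf
  }
  tab <- do.call(rbind, tabs)
  tab$frame_idx <- seq_len(nrow(tab))
  structure(list(table = tab, images = do.call(c, lapply(trials, `[[`, "images")),
                 pixel_mm = px[1]),
            class = "synced_frames")
}

#' Synchronise and stitch a whole session
#'
#' Convenience wrapper: loads each sub-trial of a simulated (or identically
#' laid-out) session, synchronises it with [sync_trial()] and stitches the
#' results with [stitch_trials()].
#'
#' @param us A `us_session` object or a session directory path.
#' @param window,slope_eps Passed to [label_direction()].
#' @return A `synced_frames` object covering the whole session.
#' @export
sync_session <- function(us, window = 5L, slope_eps = 0.05) {
  if (is.character(us)) us <- read_session(us)
  stopifnot(inherits(us, "us_session"))
  trials <- lapply(seq_along(us$trial_dirs), function(k) {
    sync_trial(load_trial_(us, k), pixel_mm = us$phantom$pixel_mm,
               trial_id = k, window = window, slope_eps = slope_eps)
  })
  stitch_trials(trials)
}

#' @export
print.synced_frames <- function(x, ...) {
  tab <- x$table
  cat(sprintf("<synced_frames> %d frames, %d trial(s), %.1f s, theta %.1f-%.1f deg\n",
              nrow(tab), length(unique(tab$trial_id)), diff(range(tab$t)),
              min(tab$theta_deg), max(tab$theta_deg)))
  print(table(tab$direction))
  invisible(x)
}

#' Read a TRC marker file
#'
#' Minimal reader for the tab-separated TRC motion-capture format: parses the
#' header to recover marker names and returns a wide data frame in the same
#' layout the session simulator writes (`t_s` plus `<marker>_x/_y/_z`).
#'
#' @param path Path to a `.trc` file.
#' @return A data frame with `t_s` and three coordinate columns per marker.
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6) stop("not a TRC file: ", path, call. = FALSE)
  hdr <- strsplit(lines[4], "\t")[[1]]
  marker_names <- hdr[seq(3, length(hdr))]
  marker_names <- marker_names[nzchar(trimws(marker_names))]
  dat <- utils::read.table(text = lines[-(1:5)], sep = "\t", header = FALSE,
                           fill = TRUE)
  dat <- dat[stats::complete.cases(dat[, 1:2]), , drop = FALSE]
  out <- data.frame(t_s = dat[[2]])
  for (i in seq_along(marker_names)) {
    base <- 2 + (i - 1) * 3
    nm <- trimws(marker_names[i])
    out[[paste0(nm, "_x")]] <- dat[[base + 1]]
    out[[paste0(nm, "_y")]] <- dat[[base + 2]]
    out[[paste0(nm, "_z")]] <- dat[[base + 3]]
  }
  out
}
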