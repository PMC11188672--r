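#' Acquisition arithmetic helpers
#'
#' The nominal spacing between consecutive frames along the scan axis is the
#' probe speed divided by the frame rate; its reciprocal (per cm) is the
#' number of images collected per centimetre of sweep. The total session
#' duration is the sub-trial duration times the number of sub-trials.
#'
#' @param session A [session_config()].
#' @return Spacing in mm, a frame count per cm, or a duration in seconds.
#' @export
nominal_frame_spacing <- function(session) {
  stopifnot(inherits(session, "session_config"))
  session$probe_speed_mm_s / session$frame_rate_hz
}

#' @rdname nominal_frame_spacing
#' @export
frames_per_cm <- function(session) {
  stopifnot(inherits(session, "session_config"))
  10 * session$frame_rate_hz / session$probe_speed_mm_s
}

#' @rdname nominal_frame_spacing
#' @export
session_duration <- function(session) {
  stopifnot(inherits(session, "session_config"))
  session$n_trials * session$trial_duration_s
}

# Morphometry of one accepted cell stack.
cell_morphometry_ <- function(stack, frame_spacing_mm, n_slices, pca_weights) {
  sstack <- build_slice_stack(stack)
  contours <- segment_slices(sstack, mode = "threshold", n_slices = n_slices)
  vol <- interpolate_surface(contours,
                             voxel_mm = c(sstack$pixel_mm, sstack$pixel_mm,
                                          frame_spacing_mm))
  aligned <- weighted_pca_align(vol, weights = pca_weights)
  list(volume_mm3 = compute_volume(aligned),
       length_mm = compute_length(contours),
       profile = compute_csa_profile(aligned),
       contour_csa = compute_csa_profile(contours),
       n_contours = length(contours$contours))
}

#' Run the full gating-reconstruction-morphometry pipeline
#'
#' From two acquisition sessions (one per metronome velocity) to the
#' 4-condition x 11-ROM-point morphometry table: synchronises and stitches
#' the sub-trials, gates frames into 1-degree angle bins split by movement
#' direction, merges near-duplicate positions and applies the inclusion
#' criteria, computes the combined range of motion and selects bin stacks at
#' 10%-of-ROM increments, reconstructs each cell by contour lofting, aligns
#' it by weighted PCA and computes volume, length and the CSA profile, then
#' normalises to the reference length L0 and localises the maximum CSA by
#' quadratic fitting.
#'
#' @param slow,fast `us_session` objects (or session directories) acquired at
#'   the slow and fast metronome rate.
#' @param n_slices Segmented slices per reconstruction (default 17).
#' @param min_frames,max_gap_mm Inclusion criteria
#'   (see [apply_inclusion_criteria()]).
#' @param merge_dist_mm Merge threshold (see [merge_close_frames()]).
#' @param window,slope_eps Direction labelling (see [label_direction()]).
#' @param pca_weights PCA weighting (see [weighted_pca_align()]).
#' @param fallback_deg Bin substitution window (see [select_rom_stacks()]).
#' @param verbose Print progress.
#' @return An object of class `rom_morphometry`: `$cells` (one row per
#'   condition x ROM% with volume, length, L0, normalised length and volume,
#'   max CSA and its %L0 position, fit quality and flags), `$profiles`
#'   (normalised CSA profiles per cell, from the aligned voxel volume),
#'   `$contour_profiles` (polygon areas at the segmented stations, an
#'   independent route to the same quantity), `$rom`, `$slopes` (per-condition
#'   regression of max CSA on length) and `$params`.
#' @export
run_gated_pipeline <- function(slow, fast, n_slices = 17L, min_frames = 40,
                               max_gap_mm = 25, merge_dist_mm = 0.8,
                               window = 5L, slope_eps = 0.05,
                               pca_weights = "uniform", fallback_deg = 2L,
                               verbose = FALSE) {
  sessions <- list(slow = slow, fast = fast)
  bins <- list()
  spacing <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  for (v in names(sessions)) {
    us <- sessions[[v]]
    if (is.character(us)) us <- read_session(us)
    stopifnot(inherits(us, "us_session"))
    spacing[[v]] <- nominal_frame_spacing(us$session)
    say("[%s] syncing %d trial(s)", v, length(us$trial_dirs))
    synced <- sync_session(us, window = window, slope_eps = slope_eps)
    say("[%s] gating %d frames", v, nrow(synced$table))
    bv <- assign_bins(synced, velocity = v)
    rm(synced)
    bv <- lapply(bv, merge_close_frames, merge_dist_mm = merge_dist_mm)
    bv <- lapply(bv, apply_inclusion_criteria, min_frames = min_frames,
                 max_gap_mm = max_gap_mm)
    say("[%s] %d/%d bins accepted", v,
        sum(vapply(bv, function(b) isTRUE(b$accepted), logical(1))), length(bv))
    bins <- c(bins, bv)
  }
  rom <- compute_rom(bins)
  cells_sel <- select_rom_stacks(rom, bins, fallback_deg = fallback_deg)
  rm(bins)
  man <- cells_sel$manifest
  say("ROM %g-%g deg; %d/%d cells filled", rom$theta_min_deg, rom$theta_max_deg,
      sum(!man$missing), nrow(man))
  res <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    if (man$missing[i]) next
    v <- sub("_(active|passive)$", "", man$condition[i])
    res[[i]] <- cell_morphometry_(cells_sel$stacks[[i]], spacing[[v]],
                                  n_slices, pca_weights)
    cells_sel$stacks[i] <- list(NULL)  # free the images as we go
    say("cell %d/%d: %s %d%% -> V = %.1f cm^3, L = %.1f mm", i, nrow(man),
        man$condition[i], man$rom_pct[i], res[[i]]$volume_mm3 / 1000,
        res[[i]]$length_mm)
  }
  cells <- man
  cells$volume_mm3 <- vapply(res, function(r) r$volume_mm3 %||% NA_real_, numeric(1))
  cells$length_mm <- vapply(res, function(r) r$length_mm %||% NA_real_, numeric(1))
  profiles <- lapply(res, function(r) r$profile)
  contour_profiles <- lapply(res, function(r) r$contour_csa)
  cells <- normalize_lengths(cells, profiles)
  profiles <- attr(cells, "profiles")
  attr(cells, "profiles") <- NULL
  # per-condition volume normalisation
  cells$volume_norm <- NA_real_
  for (cn in unique(cells$condition)) {
    sel <- cells$condition == cn
    cells$volume_norm[sel] <- cells$volume_mm3[sel] /
      mean(cells$volume_mm3[sel], na.rm = TRUE)
  }
  # maximum CSA via quadratic smoothing on the %L0-scaled profile
  cells$max_csa_mm2 <- NA_real_
  cells$max_csa_pos_pct_L0 <- NA_real_
  cells$fit_r <- NA_real_
  cells$fit_fallback <- NA
  for (i in seq_len(nrow(cells))) {
    p <- profiles[[i]]
    if (is.null(p) || nrow(p) < 5) next
    fit <- fit_max_csa(p[, c("pos_pct_L0", "csa_mm2")])
    cells$max_csa_mm2[i] <- fit$max_csa
    cells$max_csa_pos_pct_L0[i] <- fit$max_pos
    cells$fit_r[i] <- fit$fit_r
    cells$fit_fallback[i] <- fit$fallback
  }
  slopes <- regress_max_csa_vs_length(cells[is.finite(cells$max_csa_mm2), ])
  structure(list(cells = cells, profiles = profiles,
                 contour_profiles = contour_profiles, rom = rom, slopes = slopes,
                 params = list(n_slices = n_slices, min_frames = min_frames,
                               max_gap_mm = max_gap_mm,
                               merge_dist_mm = merge_dist_mm,
                               frame_spacing_mm = spacing,
                               pca_weights = pca_weights)),
            class = "rom_morphometry")
}

#' @export
print.rom_morphometry <- function(x, ...) {
  cat("<rom_morphometry>\n")
  cat(sprintf("  ROM %g-%g deg, %d cells (%d substituted, %d missing)\n",
              x$rom$theta_min_deg, x$rom$theta_max_deg, nrow(x$cells),
              sum(x$cells$substituted), sum(x$cells$missing)))
  cols <- c("condition", "rom_pct", "bin_used", "volume_mm3", "length_mm",
            "length_pct_L0", "max_csa_mm2", "max_csa_pos_pct_L0", "fit_r")
  print(x$cells[, cols], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Summarise a pipeline result
#'
#' Reports, per condition: the maximum pairwise difference of normalised
#' volume across the 11 ROM cells (in % of the condition mean), the measured
#' elongation (length at 100% ROM as % of L0), the maximum-CSA position at
#' the shortest and longest length, the regression slope of max CSA on
#' length, and the mean quadratic-fit correlation.
#'
#' @param object A `rom_morphometry`.
#' @param ... Unused.
#' @return A data frame, one row per condition, of class
#'   `summary.rom_morphometry`.
#' @export
summary.rom_morphometry <- function(object, ...) {
  cells <- object$cells
  out <- lapply(unique(cells$condition), function(cn) {
    d <- cells[cells$condition == cn & !cells$missing, ]
    v <- d$volume_norm[is.finite(d$volume_norm)]
    data.frame(condition = cn,
               n_cells = nrow(d),
               volume_spread_pct = 100 * (max(v) - min(v)),
               elongation_pct_L0 = d$length_pct_L0[d$rom_pct == 100][1],
               peak_pos_0_pct_L0 = d$max_csa_pos_pct_L0[d$rom_pct == 0][1],
               peak_pos_100_pct_L0 = d$max_csa_pos_pct_L0[d$rom_pct == 100][1],
               csa_slope = object$slopes$slope[object$slopes$condition == cn],
               mean_fit_r = mean(d$fit_r, na.rm = TRUE))
  })
  structure(do.call(rbind, out), class = c("summary.rom_morphometry", "data.frame"))
}

#' @export
print.summary.rom_morphometry <- function(x, ...) {
  cat("Per-condition pipeline summary\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot CSA profiles or maximum-CSA trends of a pipeline result
#'
#' `type = "profiles"` draws the normalised CSA over %L0 for every ROM cell,
#' one panel per condition, colour-graded from the shortest (red) to the
#' longest (blue) muscle. `type = "max_csa"` plots the maximum CSA against
#' normalised length per condition with its regression line and the
#' constant-volume ellipsoid prediction. `type = "volume"` plots normalised
#' volume across ROM.
#'
#' @param x A `rom_morphometry`.
#' @param type One of `"profiles"`, `"max_csa"`, `"volume"`.
#' @param ... Passed to the underlying plot calls.
#' @export
plot.rom_morphometry <- function(x, type = c("profiles", "max_csa", "volume"), ...) {
  type <- match.arg(type)
  cells <- x$cells
  conds <- unique(cells$condition)
  if (type == "profiles") {
    op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op), add = TRUE)
    for (cn in conds) {
      sel <- which(cells$condition == cn & !cells$missing)
      xlim <- range(unlist(lapply(x$profiles[sel], function(p) p$pos_pct_L0)))
      ylim <- range(unlist(lapply(x$profiles[sel], function(p) p$csa_norm)))
      graphics::plot(NA, xlim = xlim, ylim = ylim, xlab = "position (% L0)",
                     ylab = "normalised CSA", main = cn, ...)
      cols <- grDevices::colorRampPalette(c("red", "blue"))(length(sel))
      for (j in seq_along(sel)) {
        p <- x$profiles[[sel[j]]]
        graphics::lines(p$pos_pct_L0, p$csa_norm, col = cols[j])
      }
    }
  } else if (type == "max_csa") {
    graphics::plot(cells$length_pct_L0, cells$max_csa_mm2,
                   col = as.integer(factor(cells$condition, levels = conds)),
                   pch = 19, xlab = "muscle length (% L0)",
                   ylab = "max CSA (mm^2)", ...)
    for (k in seq_along(conds)) {
      s <- x$slopes[x$slopes$condition == conds[k], ]
      graphics::abline(s$intercept, s$slope, col = k)
    }
    d <- cells[is.finite(cells$length_mm) & is.finite(cells$volume_mm3), ]
    lx <- seq(min(d$length_pct_L0), max(d$length_pct_L0), length.out = 50)
    Vbar <- mean(d$volume_mm3)
    Lbar0 <- mean(d$L0_mm)
    graphics::lines(lx, ellipsoid_csa(Vbar, lx / 100 * Lbar0), lty = 2)
    graphics::legend("topright", legend = c(conds, "ellipsoid"),
                     col = c(seq_along(conds), 1),
                     lty = c(rep(1, length(conds)), 2), cex = 0.8)
  } else {
    graphics::plot(cells$rom_pct, cells$volume_norm,
                   col = as.integer(factor(cells$condition, levels = conds)),
                   pch = 19, xlab = "ROM (%)", ylab = "normalised volume", ...)
    graphics::abline(h = 1, lty = 3)
    graphics::legend("topright", legend = conds, col = seq_along(conds),
                     pch = 19, cex = 0.8)
  }
  invisible(x)
}

#' Write the morphometry results table
#'
#' One CSV row per (condition, ROM%) cell with volume, length, L0, normalised
#' length, maximum CSA, its position, fit quality and flags.
#'
#' @param result A `rom_morphometry`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_morphometry_csv <- function(result, path) {
  stopifnot(inherits(result, "rom_morphometry"))
  utils::write.csv(result$cells, path, row.names = FALSE)
  invisible(path)
}
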