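#' Assign synchronised frames to 1-degree angle bins per direction
#'
#' Each non-excluded frame with angle theta goes to the unique integer-degree
#' bin `c` with `c - 0.5 <= theta < c + 0.5` for its movement direction;
#' excluded (dead-band) frames are dropped. Frames are partitioned: none is
#' duplicated and none assigned twice.
#'
#' @param synced A `synced_frames` object (see [sync_session()]).
#' @param velocity Velocity label attached to every resulting stack
#'   (e.g. `"slow"` or `"fast"`).
#' @return A list of `bin_stack` objects keyed `"<velocity>:<direction>:<bin>"`,
#'   each holding the bin's frames ordered by scan-axis position.
#' @export
assign_bins <- function(synced, velocity = "slow") {
  stopifnot(inherits(synced, "synced_frames"))
  tab <- synced$table
  keep <- tab$direction != "excluded"
  tab <- tab[keep, , drop = FALSE]
  centers <- floor(tab$theta_deg + 0.5)  # c - 0.5 <= theta < c + 0.5
  key <- paste(velocity, tab$direction, centers, sep = ":")
  out <- list()
  for (k in unique(key)) {
    sel <- which(key == k)
    ord <- sel[order(tab$scan_pos_mm[sel])]
    rows <- tab[ord, , drop = FALSE]
    out[[k]] <- structure(list(
      theta_center_deg = centers[ord][1],
      direction = rows$direction[1],
      velocity = velocity,
      positions_mm = rows$scan_pos_mm,
      vert_pos_mm = rows$vert_pos_mm,
      images = synced$images[rows$frame_idx],
      frame_idx = rows$frame_idx,
      pixel_mm = synced$pixel_mm,
      n_raw = length(ord),
      merged = FALSE,
      accepted = NA,
      rejection_reason = "none"), class = "bin_stack")
  }
  out[order(names(out))]
}

#' @export
print.bin_stack <- function(x, ...) {
  cat(sprintf("<bin_stack> %s %s %d deg: %d frame(s) over %.1f-%.1f mm%s\n",
              x$velocity, x$direction, x$theta_center_deg, length(x$positions_mm),
              min(x$positions_mm), max(x$positions_mm),
              if (isTRUE(x$accepted)) ", accepted"
              else if (isFALSE(x$accepted)) paste0(", rejected (", x$rejection_reason, ")")
              else ""))
  invisible(x)
}

#' Merge near-duplicate frames within a bin stack
#'
#' Greedy closest-pair-first pass over the position-sorted stack: while any
#' adjacent pair of frames is closer than `merge_dist_mm`, the closest pair is
#' replaced by the pixelwise mean image at the mean position, repeating to
#' convergence. The output positions are pairwise at least `merge_dist_mm`
#' apart; the operation is idempotent.
#'
#' @param stack A `bin_stack` (positions sorted ascending).
#' @param merge_dist_mm Merge distance threshold in mm (default 0.8).
#' @return The merged `bin_stack`.
#' @export
merge_close_frames <- function(stack, merge_dist_mm = 0.8) {
  stopifnot(inherits(stack, "bin_stack"))
  pos <- stack$positions_mm
  imgs <- stack$images
  vert <- stack$vert_pos_mm
  if (length(pos) >= 2) {
    repeat {
      gaps <- diff(pos)
      i <- which.min(gaps)
      if (length(gaps) == 0 || gaps[i] >= merge_dist_mm) break
      imgs[[i]] <- (imgs[[i]] + imgs[[i + 1]]) / 2
      pos[i] <- (pos[i] + pos[i + 1]) / 2
      vert[i] <- (vert[i] + vert[i + 1]) / 2
      imgs[[i + 1]] <- NULL
      pos <- pos[-(i + 1)]
      vert <- vert[-(i + 1)]
      if (length(pos) < 2) break
    }
  }
  stack$positions_mm <- pos
  stack$vert_pos_mm <- vert
  stack$images <- imgs
  stack$frame_idx <- NULL  # merged frames no longer map 1:1 to source frames
  stack$merged <- TRUE
  stack
}

#' Apply the stack inclusion criteria
#'
#' A merged stack is accepted iff it holds at least `min_frames` images and
#' the maximum consecutive-position gap is strictly less than `max_gap_mm`.
#' The frame-count criterion is checked first and determines
#' `rejection_reason` (`"too_few_frames"` before `"gap_too_large"`).
#'
#' @param stack A merged, position-sorted `bin_stack`.
#' @param min_frames Minimum number of images (default 40).
#' @param max_gap_mm Maximum allowed gap between consecutive images, exclusive
#'   bound (default 25).
#' @return The `bin_stack` with `accepted` and `rejection_reason` set.
#' @export
apply_inclusion_criteria <- function(stack, min_frames = 40, max_gap_mm = 25) {
  stopifnot(inherits(stack, "bin_stack"))
  n <- length(stack$positions_mm)
  if (n < min_frames) {
    stack$accepted <- FALSE
    stack$rejection_reason <- "too_few_frames"
  } else if (n >= 2 && max(diff(stack$positions_mm)) >= max_gap_mm) {
    stack$accepted <- FALSE
    stack$rejection_reason <- "gap_too_large"
  } else {
    stack$accepted <- TRUE
    stack$rejection_reason <- "none"
  }
  stack
}

condition_of_ <- function(stack) paste(stack$velocity, stack$direction, sep = "_")

ALL_CONDITIONS <- c("slow_active", "slow_passive", "fast_active", "fast_passive")

# Nearest integer bin centre for a grid angle, ties broken towards theta_min.
grid_bin_ <- function(theta) ceiling(theta - 0.5)

#' Compute the usable range of motion across conditions
#'
#' For each condition (velocity x direction) the minimum and maximum accepted
#' bin centre is determined; the combined ROM runs from the largest of the
#' per-condition minima to the smallest of the per-condition maxima, so every
#' condition can be reconstructed over an identical angle range. The
#' 0,10,...,100% grid maps each percentage to an angle and to its nearest
#' integer bin centre (ties towards the ROM minimum).
#'
#' @param bins List of `bin_stack`s that have been through
#'   [apply_inclusion_criteria()].
#' @param conditions Conditions that must all be present (default the four
#'   velocity x direction combinations).
#' @param per_velocity If `TRUE`, compute a separate ROM for each velocity
#'   instead of one combined ROM (returned as a list).
#' @return An object of class `rom_definition`: `theta_min_deg`,
#'   `theta_max_deg`, `per_condition` ranges, and `grid` (percent, angle, bin).
#' @export
compute_rom <- function(bins, conditions = ALL_CONDITIONS, per_velocity = FALSE) {
  acc <- Filter(function(b) isTRUE(b$accepted), bins)
  cond <- vapply(acc, condition_of_, character(1))
  if (per_velocity) {
    vels <- unique(sub("_(active|passive)$", "", conditions))
    out <- lapply(vels, function(v) {
      compute_rom(bins, conditions = grep(paste0("^", v, "_"), conditions, value = TRUE))
    })
    names(out) <- vels
    return(out)
  }
  ranges <- lapply(conditions, function(cn) {
    th <- vapply(acc[cond == cn], `[[`, numeric(1), "theta_center_deg")
    if (length(th) == 0)
      stop("insufficient data: no accepted bins for condition ", cn, call. = FALSE)
    range(th)
  })
  per_condition <- data.frame(condition = conditions,
                              theta_min = vapply(ranges, `[`, numeric(1), 1),
                              theta_max = vapply(ranges, `[`, numeric(1), 2))
  tmin <- max(per_condition$theta_min)
  tmax <- min(per_condition$theta_max)
  if (!(tmin < tmax))
    stop("insufficient data: combined ROM is empty", call. = FALSE)
  pct <- seq(0, 100, by = 10)
  theta <- tmin + pct / 100 * (tmax - tmin)
  structure(list(theta_min_deg = tmin, theta_max_deg = tmax,
                 per_condition = per_condition,
                 grid = data.frame(rom_pct = pct, theta_deg = theta,
                                   bin = grid_bin_(theta))),
            class = "rom_definition")
}

#' @export
print.rom_definition <- function(x, ...) {
  cat(sprintf("<rom_definition> combined ROM %g-%g deg\n",
              x$theta_min_deg, x$theta_max_deg))
  print(x$per_condition, row.names = FALSE)
  invisible(x)
}

#' Select the bin stacks at 10%-of-ROM increments
#'
#' For each condition and each of the 11 ROM grid points, returns the accepted
#' stack at the mapped bin centre. If that bin is not accepted for the
#' condition, the nearest accepted bin within +/- `fallback_deg` degrees is
#' substituted (ties towards the ROM minimum) and flagged; otherwise the cell
#' is marked missing. 0% of ROM corresponds to the shortest muscle length.
#'
#' @param rom A `rom_definition`.
#' @param bins List of `bin_stack`s with acceptance flags.
#' @param conditions Conditions to fill (default all four).
#' @param fallback_deg Substitution search half-width in degrees (default 2).
#' @return An object of class `rom_cells`: `$manifest` (data frame with one
#'   row per condition x ROM%) and `$stacks` (list parallel to the manifest;
#'   `NULL` for missing cells).
#' @export
select_rom_stacks <- function(rom, bins, conditions = ALL_CONDITIONS,
                              fallback_deg = 2L) {
  stopifnot(inherits(rom, "rom_definition"))
  cond <- vapply(bins, condition_of_, character(1))
  centers <- vapply(bins, `[[`, numeric(1), "theta_center_deg")
  ok <- vapply(bins, function(b) isTRUE(b$accepted), logical(1))
  offsets <- as.vector(rbind(-seq_len(fallback_deg), seq_len(fallback_deg)))
  manifest <- list(); stacks <- list(); i <- 0L
  for (cn in conditions) {
    for (g in seq_len(nrow(rom$grid))) {
      i <- i + 1L
      target <- rom$grid$bin[g]
      hit <- which(cond == cn & centers == target & ok)
      sub <- FALSE; used <- NA_real_
      if (length(hit) == 0) {
        for (off in c(0L, offsets)) {
          hit <- which(cond == cn & centers == target + off & ok)
          if (length(hit) > 0) { sub <- off != 0L; break }
        }
      }
      if (length(hit) > 0) used <- centers[hit[1]]
      manifest[[i]] <- data.frame(condition = cn, rom_pct = rom$grid$rom_pct[g],
                                  theta_deg = rom$grid$theta_deg[g],
                                  bin = target, bin_used = used,
                                  substituted = sub, missing = length(hit) == 0,
                                  n_frames = if (length(hit) > 0)
                                    length(bins[[hit[1]]]$positions_mm) else 0L)
      stacks[[i]] <- if (length(hit) > 0) bins[[hit[1]]] else NULL
    }
  }
  structure(list(manifest = do.call(rbind, manifest), stacks = stacks, rom = rom),
            class = "rom_cells")
}

#' @export
print.rom_cells <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<rom_cells> %d cells (%d filled, %d substituted, %d missing)\n",
              nrow(m), sum(!m$missing), sum(m$substituted), sum(m$missing)))
  invisible(x)
}

#' Write the per-cell manifest and ROM report
#'
#' Exports the cell manifest (bin key, positions, acceptance, substitution
#' flags) as JSON and the ROM definition as JSON alongside it.
#'
#' @param cells A `rom_cells` object.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_cell_manifest <- function(cells, dir) {
  stopifnot(inherits(cells, "rom_cells"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir, call. = FALSE)
  cell_list <- lapply(seq_len(nrow(cells$manifest)), function(i) {
    row <- as.list(cells$manifest[i, ])
    st <- cells$stacks[[i]]
    if (!is.null(st)) row$positions_mm <- st$positions_mm
    row
  })
  p1 <- file.path(dir, "cells.json")
  p2 <- file.path(dir, "rom.json")
  jsonlite::write_json(cell_list, p1, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(list(theta_min_deg = cells$rom$theta_min_deg,
                            theta_max_deg = cells$rom$theta_max_deg,
                            per_condition = cells$rom$per_condition,
                            grid = cells$rom$grid),
                       p2, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(p1, p2))
}
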