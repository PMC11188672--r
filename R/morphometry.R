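#' Align a voxel volume to its principal axes
#'
#' Computes the (optionally weighted) principal component axes of the
#' foreground voxel cloud and rotates the volume so the first principal axis
#' becomes the longitudinal coordinate, with the sign fixed so the proximal
#' end (smaller scan coordinate) keeps the smaller longitudinal coordinate.
#' Weights are uniform by default; the `"slice"` option normalises by
#' per-slice voxel count so each axial station contributes equally regardless
#' of its cross-sectional area.
#'
#' The rotated voxel centres are re-binned onto a new grid with the same
#' voxel sizes; the aligned array stores per-voxel source counts, so total
#' mass (and hence [compute_volume()]) is preserved exactly.
#'
#' @param volume A `voxel_volume`.
#' @param weights `"uniform"` or `"slice"`.
#' @return An object of class `aligned_volume`: numeric `array` of source
#'   counts, `voxel_mm`, `origin_mm`, the `rotation` matrix (columns =
#'   principal axes) and the weighted `center`.
#' @export
weighted_pca_align <- function(volume, weights = c("uniform", "slice")) {
  stopifnot(inherits(volume, "voxel_volume"))
  weights <- match.arg(weights)
  idx <- which(volume$array, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty volume", call. = FALSE)
  X <- sweep((idx - 1), 2, volume$voxel_mm, "*")
  X <- sweep(X, 2, volume$origin_mm, "+")
  w <- if (weights == "slice") {
    cnt <- tabulate(idx[, 3], nbins = dim(volume$array)[3])
    1 / cnt[idx[, 3]]
  } else rep(1, nrow(idx))
  w <- w / sum(w)
  mu <- colSums(X * w)
  Xc <- sweep(X, 2, mu)
  S <- crossprod(Xc * sqrt(w))
  ev <- eigen(S, symmetric = TRUE)
  if (ev$values[3] / max(ev$values[1], 1e-300) < 1e-12 || nrow(unique(X)) < 4)
    stop("degenerate voxel set: foreground is not three-dimensional", call. = FALSE)
  R <- ev$vectors
  # proximal (small scan coordinate) maps to the small longitudinal coordinate
  if (sum(Xc[, 3] * (Xc %*% R[, 1])) < 0) R[, 1] <- -R[, 1]
  if (det(R) < 0) R[, 3] <- -R[, 3]
  Xr <- Xc %*% R
  # bin each principal axis at the source spacing of the original axis it is
  # closest to, so the re-binned grid pitch matches the source sampling and
  # the axial profile does not beat against the slice spacing
  src_axis <- apply(abs(R), 2, which.max)
  if (anyDuplicated(src_axis)) src_axis <- c(3L, 1L, 2L)  # PC1 ~ scan axis
  d <- volume$voxel_mm[src_axis]
  lo <- apply(Xr, 2, min)
  ii <- floor(sweep(sweep(Xr, 2, lo), 2, d, "/") + 0.5) + 1
  dims <- apply(ii, 2, max)
  lin <- ii[, 1] + dims[1] * (ii[, 2] - 1) + dims[1] * dims[2] * (ii[, 3] - 1)
  counts <- tabulate(lin, nbins = prod(dims))
  # aligned axes ordered (long, trans1, trans2) -> store longitudinal last to
  # keep the slice convention array[, , k]
  arr <- array(counts, dim = dims)
  arr <- aperm(arr, c(2, 3, 1))
  structure(list(array = arr, voxel_mm = d[c(2, 3, 1)],
                 origin_mm = lo[c(2, 3, 1)], rotation = R, center = mu,
                 n_source = nrow(idx)),
            class = "aligned_volume")
}

#' @export
print.aligned_volume <- function(x, ...) {
  d <- dim(x$array)
  cat(sprintf("<aligned_volume> %d x %d x %d grid, V = %.1f cm^3\n",
              d[1], d[2], d[3], compute_volume(x) / 1000))
  invisible(x)
}

#' Muscle volume of a voxel volume
#'
#' Volume is the number of segmented voxels multiplied by the voxel
#' resolution in each dimension. For aligned volumes (which store per-voxel
#' source counts) the total count is used, so alignment never changes the
#' volume.
#'
#' @param volume A `voxel_volume` or `aligned_volume`.
#' @return Volume in mm^3.
#' @export
compute_volume <- function(volume) {
  if (inherits(volume, "aligned_volume")) {
    sum(volume$array) * prod(volume$voxel_mm)
  } else if (inherits(volume, "voxel_volume")) {
    sum(volume$array) * prod(volume$voxel_mm)
  } else stop("expected a voxel_volume or aligned_volume", call. = FALSE)
}

#' Muscle length from segmented contours
#'
#' Euclidean distance between the centroids of the first and the last
#' segmented slice (the most proximal and most distal segmented stations).
#'
#' @param contours A `contour_set` with at least 2 contours.
#' @return Length in mm.
#' @export
compute_length <- function(contours) {
  stopifnot(inherits(contours, "contour_set"))
  cts <- contours$contours
  if (length(cts) < 2) stop("need at least 2 contours", call. = FALSE)
  z <- vapply(cts, `[[`, numeric(1), "z_mm")
  c1 <- cts[[which.min(z)]]$centroid_mm
  c2 <- cts[[which.max(z)]]$centroid_mm
  sqrt(sum((c2 - c1)^2))
}

#' Cross-sectional-area profile
#'
#' Per axial slice, the CSA is the foreground pixel count multiplied by the
#' in-plane pixel area. Works on raw voxel volumes, PCA-aligned volumes
#' (where fractional source counts are summed) and contour sets (polygon
#' areas at the segmented stations).
#'
#' @param x A `voxel_volume`, `aligned_volume` or `contour_set`.
#' @return A data frame with `pos_mm` (axial position on the object's
#'   longitudinal axis) and `csa_mm2`, restricted to slices with positive CSA.
#' @export
compute_csa_profile <- function(x) UseMethod("compute_csa_profile")

#' @export
compute_csa_profile.voxel_volume <- function(x) {
  d <- x$voxel_mm
  csa <- apply(x$array, 3, sum) * d[1] * d[2]
  pos <- x$origin_mm[3] + (seq_len(dim(x$array)[3]) - 1) * d[3]
  out <- data.frame(pos_mm = pos, csa_mm2 = csa)
  out[out$csa_mm2 > 0, , drop = FALSE]
}

#' @export
compute_csa_profile.aligned_volume <- compute_csa_profile.voxel_volume

#' @export
compute_csa_profile.contour_set <- function(x) {
  z <- vapply(x$contours, `[[`, numeric(1), "z_mm")
  a <- abs(vapply(x$contours, `[[`, numeric(1), "area_mm2"))
  out <- data.frame(pos_mm = z, csa_mm2 = a)
  out[order(out$pos_mm), , drop = FALSE]
}

#' Normalise lengths and CSA to the reference length L0
#'
#' The shortest muscle length -- the 0%-of-ROM cell of each condition -- is
#' defined as 100% of the reference length L0; all lengths of that condition
#' are expressed as a percentage of it. When per-cell CSA profiles are
#' supplied, axial positions are rescaled to %L0 (measured from each cell's
#' proximal end) and CSA values are divided by the condition's grand-mean CSA
#' over all slices and ROM cells.
#'
#' @param cells Data frame with one row per (condition, ROM%) holding at
#'   least `condition`, `rom_pct` and `length_mm`.
#' @param profiles Optional list (parallel to `cells` rows) of CSA-profile
#'   data frames with `pos_mm` and `csa_mm2`.
#' @return `cells` with `L0_mm` and `length_pct_L0` added; if `profiles` was
#'   given, the result carries the normalised profiles (columns `pos_pct_L0`,
#'   `csa_norm` added) as attribute `"profiles"`.
#' @export
normalize_lengths <- function(cells, profiles = NULL) {
  stopifnot(is.data.frame(cells), all(c("condition", "rom_pct", "length_mm") %in% names(cells)))
  cells$L0_mm <- NA_real_
  for (cn in unique(cells$condition)) {
    sel <- cells$condition == cn
    i0 <- which(sel & cells$rom_pct == 0)
    if (length(i0) == 0 || is.na(cells$length_mm[i0[1]]))
      stop("missing 0%-ROM cell for condition ", cn, call. = FALSE)
    cells$L0_mm[sel] <- cells$length_mm[i0[1]]
  }
  cells$length_pct_L0 <- 100 * cells$length_mm / cells$L0_mm
  if (!is.null(profiles)) {
    stopifnot(length(profiles) == nrow(cells))
    for (cn in unique(cells$condition)) {
      sel <- which(cells$condition == cn)
      grand <- mean(unlist(lapply(profiles[sel], function(p) p$csa_mm2)))
      for (i in sel) {
        p <- profiles[[i]]
        if (is.null(p) || nrow(p) == 0) next
        p$pos_pct_L0 <- 100 * (p$pos_mm - min(p$pos_mm)) / cells$L0_mm[i]
        p$csa_norm <- p$csa_mm2 / grand
        profiles[[i]] <- p
      }
    }
    attr(cells, "profiles") <- profiles
  }
  cells
}

#' Locate the maximum CSA by quadratic smoothing
#'
#' Fits a least-squares second-degree polynomial to the CSA profile over the
#' central 80% of its positional extent (excluding the tendon tails, which
#' would bias a global quadratic) and takes the parabola's vertex as the
#' position and value of the maximum CSA. The fit quality is the Pearson
#' correlation between fitted and observed CSA over the fit window. If the
#' fitted parabola opens upwards or its vertex falls outside the window, the
#' result is flagged and falls back to the argmax of the observed profile.
#'
#' @param profile Data frame with a position column and a CSA column (first
#'   two columns are used; typically `pos_pct_L0` and `csa_norm` or `pos_mm`
#'   and `csa_mm2`). At least 5 points.
#' @param window_frac Central fraction of the positional extent used for the
#'   fit (default 0.8).
#' @return A list: `max_csa`, `max_pos`, `fit_r`, `fallback` (logical),
#'   `coefficients` of the quadratic, and the fit `window`.
#' @export
fit_max_csa <- function(profile, window_frac = 0.8) {
  stopifnot(is.data.frame(profile), ncol(profile) >= 2)
  x <- profile[[1]]; y <- profile[[2]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5) stop("need at least 5 profile points", call. = FALSE)
  r <- range(x)
  pad <- (1 - window_frac) / 2 * diff(r)
  win <- c(r[1] + pad, r[2] - pad)
  inw <- x >= win[1] & x <= win[2]
  if (sum(inw) < 5) { inw <- rep(TRUE, length(x)); win <- r }
  fit <- stats::lm(y[inw] ~ x[inw] + I(x[inw]^2))
  b <- unname(stats::coef(fit))
  fit_r <- suppressWarnings(stats::cor(stats::fitted(fit), y[inw]))
  fallback <- FALSE
  if (!is.finite(b[3]) || b[3] >= 0) {
    fallback <- TRUE
  } else {
    vx <- -b[2] / (2 * b[3])
    if (vx < win[1] || vx > win[2]) fallback <- TRUE
  }
  if (fallback) {
    i <- which.max(y)
    list(max_csa = y[i], max_pos = x[i], fit_r = fit_r, fallback = TRUE,
         coefficients = b, window = win)
  } else {
    list(max_csa = b[1] + b[2] * vx + b[3] * vx^2, max_pos = vx, fit_r = fit_r,
         fallback = FALSE, coefficients = b, window = win)
  }
}

#' Ellipsoid muscle model
#'
#' An ellipsoid with semi-axes `a`, `b`, `c` is a highly simplified muscle
#' shape: its volume is `V = 4/3 pi a b c`, its longitudinal semi-axis is
#' half the muscle length (`c = L/2`), and its maximum cross-section is
#' `CSA = pi a b`. Under constant volume these combine to
#' `CSA = (3/4) V / c = (3/2) V / L`, which [ellipsoid_csa()] evaluates.
#'
#' @param a_mm,b_mm,c_mm Semi-axes in mm, all positive.
#' @return For `ellipsoid_model()`: a list with the semi-axes and `V_mm3`.
#' @export
ellipsoid_model <- function(a_mm, b_mm, c_mm) {
  if (any(c(a_mm, b_mm, c_mm) <= 0)) stop("semi-axes must be positive", call. = FALSE)
  structure(list(a_mm = a_mm, b_mm = b_mm, c_mm = c_mm,
                 V_mm3 = 4 / 3 * pi * a_mm * b_mm * c_mm),
            class = "ellipsoid_model")
}

#' @rdname ellipsoid_model
#' @param V_mm3 Muscle volume in mm^3 (assumed constant across the motion).
#' @param L_muscle_mm Muscle length in mm at the angle interval of interest.
#' @return For `ellipsoid_csa()`: the predicted maximum CSA in mm^2.
#' @export
ellipsoid_csa <- function(V_mm3, L_muscle_mm) {
  if (any(V_mm3 <= 0) || any(L_muscle_mm <= 0))
    stop("volume and length must be positive", call. = FALSE)
  c_ax <- L_muscle_mm / 2
  (3 / 4) * V_mm3 / c_ax
}

#' Per-condition regression of maximum CSA on muscle length
#'
#' Ordinary least squares of the maximum CSA against normalised muscle length
#' for each condition; the slopes feed the ANCOVA slope comparison.
#'
#' @param cells Data frame with columns `condition`, a length column and a
#'   CSA column.
#' @param x,y Names of the length and CSA columns.
#' @return Data frame with one row per condition: `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
regress_max_csa_vs_length <- function(cells, x = "length_pct_L0", y = "max_csa_mm2") {
  stopifnot(is.data.frame(cells), all(c("condition", x, y) %in% names(cells)))
  out <- lapply(unique(cells$condition), function(cn) {
    d <- cells[cells$condition == cn & is.finite(cells[[x]]) & is.finite(cells[[y]]), ]
    if (nrow(d) < 3) stop("need at least 3 points per condition", call. = FALSE)
    if (stats::sd(d[[x]]) < 1e-12)
      stop("rank-deficient regression for condition ", cn, call. = FALSE)
    fit <- stats::lm(d[[y]] ~ d[[x]])
    tss <- sum((d[[y]] - mean(d[[y]]))^2)
    r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
    data.frame(condition = cn, slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = r2, n = nrow(d))
  })
  do.call(rbind, out)
}
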