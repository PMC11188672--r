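#' Position a bin stack's frames in 3D
#'
#' Places each frame of an accepted bin stack at its scan-axis encoder
#' position with its vertical-axis offset. This device sweeps along a single
#' straight axis, so all image planes are parallel with a fixed normal along
#' the scan axis; the in-plane axes are identical across slices. In-plane
#' coordinates are in mm with the image centre at `(0, vert_pos_mm)`.
#'
#' @param stack An accepted `bin_stack`.
#' @param pixel_mm In-plane pixel size (mm); defaults to the stack's own.
#' @return An object of class `slice_stack`: `images`, `positions_mm` (scan
#'   axis), `vert_pos_mm`, `pixel_mm`.
#' @export
build_slice_stack <- function(stack, pixel_mm = stack$pixel_mm) {
  stopifnot(inherits(stack, "bin_stack"))
  if (is.null(stack$positions_mm) || anyNA(stack$positions_mm))
    stop("missing position for one or more frames", call. = FALSE)
  structure(list(images = stack$images,
                 positions_mm = stack$positions_mm,
                 vert_pos_mm = stack$vert_pos_mm %||% rep(0, length(stack$positions_mm)),
                 pixel_mm = pixel_mm,
                 provenance = paste(stack$velocity, stack$direction,
                                    stack$theta_center_deg, sep = ":")),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  cat(sprintf("<slice_stack> %d slices spanning %.1f mm, %g mm/px\n",
              length(x$images), diff(range(x$positions_mm)), x$pixel_mm))
  invisible(x)
}

# In-plane mm coordinates of pixel centres for slice i of a stack.
plane_coords_ <- function(sstack, i) {
  d <- dim(sstack$images[[i]])
  list(u = (seq_len(d[2]) - (d[2] + 1) / 2) * sstack$pixel_mm,
       v = (seq_len(d[1]) - (d[1] + 1) / 2) * sstack$pixel_mm + sstack$vert_pos_mm[i])
}

# Extract the muscle boundary of one slice as a closed CCW polygon (mm),
# using sub-pixel contour tracing at the given threshold. Returns NULL when
# no usable ring exists.
trace_contour_ <- function(img, thr, u, v, n_vertices) {
  rings <- grDevices::contourLines(x = v, y = u, z = img, levels = thr)
  if (length(rings) == 0) return(NULL)
  best <- NULL; best_area <- 0
  for (r in rings) {
    if (length(r$x) < 4) next
    closed <- abs(r$x[1] - r$x[length(r$x)]) < 1e-9 &&
      abs(r$y[1] - r$y[length(r$y)]) < 1e-9
    verts <- cbind(r$y, r$x)  # (u, v)
    if (closed) verts <- verts[-nrow(verts), , drop = FALSE]
    a <- abs(polygon_area_(verts))
    if (a > best_area) { best <- verts; best_area <- a }
  }
  if (is.null(best) || best_area < 1e-6) return(NULL)
  out <- resample_closed_(orient_ccw_(best), n_vertices)
  # image noise can leave sub-pixel wiggles that self-cross after resampling;
  # a light circular moving average removes them with negligible area change
  for (k in 1:3) {
    if (is_simple_polygon_(out)) return(out)
    n <- nrow(out)
    prev <- out[c(n, seq_len(n - 1L)), ]
    nxt <- out[c(seq_len(n)[-1L], 1L), ]
    out <- (prev + out + nxt) / 3
  }
  if (!is_simple_polygon_(out)) return(NULL)
  out
}

#' Segment the muscle on a subset of slices
#'
#' Selects `n_slices` approximately equidistant slices between (and always
#' including) the first and last slices containing foreground, then extracts
#' one closed muscle contour per selected slice.
#'
#' In `"threshold"` mode (synthetic phantom images) a global Otsu threshold is
#' computed over the stack, the largest connected component defines the
#' muscle, and its boundary is traced at sub-pixel resolution. In `"import"`
#' mode user-supplied polylines (e.g. manual outlines) are validated
#' (closed, simple) and resampled.
#'
#' @param sstack A `slice_stack`.
#' @param mode `"threshold"` or `"import"`.
#' @param n_slices Number of slices to segment (15-20 in the reference
#'   protocol; default 17).
#' @param contours For `"import"` mode: a list of `list(slice, vertices)`
#'   where `vertices` is an n x 2 matrix of in-plane mm coordinates.
#' @param n_vertices Vertex count of the resampled output contours.
#' @param min_foreground_px Minimum number of above-threshold pixels for a
#'   slice to count as foreground (default 4).
#' @return An object of class `contour_set`: per slice the closed polyline
#'   (mm), scan position, area (mm^2) and 3D centroid.
#' @export
segment_slices <- function(sstack, mode = c("threshold", "import"),
                           n_slices = 17L, contours = NULL, n_vertices = 96L,
                           min_foreground_px = 4L) {
  stopifnot(inherits(sstack, "slice_stack"))
  mode <- match.arg(mode)
  if (n_slices < 2) stop("n_slices must be at least 2", call. = FALSE)
  if (mode == "import") {
    if (is.null(contours) || length(contours) < 2)
      stop("import mode requires at least 2 contours", call. = FALSE)
    out <- lapply(contours, function(ct) {
      verts <- as.matrix(ct$vertices)
      if (nrow(verts) >= 2 &&
          sqrt(sum((verts[1, ] - verts[nrow(verts), ])^2)) < 1e-9)
        verts <- verts[-nrow(verts), , drop = FALSE]
      if (nrow(verts) < 3) stop("imported contour has fewer than 3 vertices",
                                call. = FALSE)
      if (!is_simple_polygon_(verts))
        stop("imported contour is self-intersecting", call. = FALSE)
      verts <- resample_closed_(orient_ccw_(verts), max(n_vertices, 64L))
      z <- sstack$positions_mm[ct$slice]
      cen <- polygon_centroid_(verts)
      list(slice = ct$slice, vertices = verts, z_mm = z,
           area_mm2 = polygon_area_(verts),
           centroid_mm = c(cen[1], cen[2], z))
    })
    return(structure(list(contours = out, pixel_mm = sstack$pixel_mm),
                     class = "contour_set"))
  }
  imgs <- sstack$images
  all_px <- do.call(cbind, imgs)
  thr <- EBImage::otsu(EBImage::Image(all_px), range = c(0, 1))
  # contour level at the midpoint of the two class means: for an image whose
  # edge is an intensity ramp between background and foreground this is the
  # unbiased half-maximum boundary, where Otsu's level itself sits slightly
  # inside the ramp
  level <- (mean(all_px[all_px <= thr]) + mean(all_px[all_px > thr])) / 2
  fg_count <- vapply(imgs, function(m) sum(m > thr), numeric(1))
  fg <- which(fg_count >= min_foreground_px)
  if (length(fg) < 2)
    stop("segmentation failure: fewer than 2 foreground slices", call. = FALSE)
  # approximately equidistant stations drawn from the foreground slices,
  # always including the first and last (noise can push individual tip
  # frames below threshold, so selection is restricted to usable slices)
  sel <- fg[unique(round(seq(1, length(fg),
                             length.out = min(n_slices, length(fg)))))]
  out <- vector("list", length(sel))
  for (j in seq_along(sel)) {
    i <- sel[j]
    if (fg_count[i] < min_foreground_px)
      stop("segmentation failure: empty foreground on selected slice ", i,
           call. = FALSE)
    # largest connected component defines the muscle region
    lab <- EBImage::bwlabel(imgs[[i]] > thr)
    tab <- tabulate(lab[lab > 0])
    main_label <- which.max(tab)
    pc <- plane_coords_(sstack, i)
    verts <- trace_contour_(imgs[[i]], level, pc$u, pc$v, n_vertices)
    if (is.null(verts))
      stop("segmentation failure: no closed contour on selected slice ", i,
           call. = FALSE)
    # confirm the traced ring encloses the main component's centre of mass
    idx <- which(lab == main_label, arr.ind = TRUE)
    com <- c(pc$u[round(mean(idx[, 2]))], pc$v[round(mean(idx[, 1]))])
    if (!mgcv::in.out(rbind(verts, verts[1, ]), matrix(com, 1, 2)))
      warning("traced contour does not enclose the largest component on slice ", i)
    cen <- polygon_centroid_(verts)
    out[[j]] <- list(slice = i, vertices = verts, z_mm = sstack$positions_mm[i],
                     area_mm2 = polygon_area_(verts),
                     centroid_mm = c(cen[1], cen[2], sstack$positions_mm[i]))
  }
  structure(list(contours = out, threshold = thr, contour_level = level,
                 pixel_mm = sstack$pixel_mm),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  z <- vapply(x$contours, `[[`, numeric(1), "z_mm")
  a <- vapply(x$contours, `[[`, numeric(1), "area_mm2")
  cat(sprintf("<contour_set> %d contours over %.1f mm, CSA %.1f-%.1f mm^2\n",
              length(z), diff(range(z)), min(a), max(a)))
  invisible(x)
}

# Align contour j's vertex ordering to contour ref by the circular shift
# minimising the summed squared vertex distance (minimal-twist correspondence).
align_start_ <- function(verts, ref) {
  n <- nrow(verts)
  ss <- vapply(seq_len(n), function(k) {
    idx <- ((seq_len(n) - 1 + (k - 1)) %% n) + 1
    sum((verts[idx, ] - ref)^2)
  }, numeric(1))
  k <- which.min(ss)
  idx <- ((seq_len(n) - 1 + (k - 1)) %% n) + 1
  verts[idx, , drop = FALSE]
}

#' Interpolate a closed surface between contours and voxelize it
#'
#' Replaces the proprietary surface interpolation of freehand-3D-ultrasound
#' packages with a documented contour-lofting voxelizer: all contours are
#' resampled to a common vertex count with matched starting vertices
#' (minimal-twist correspondence), corresponding vertices are linearly
#' interpolated between adjacent segmented slices at the axial voxel spacing,
#' the two ends are capped by shrinking the end contours onto their centroids
#' over one axial voxel spacing, and each axial plane is filled by
#' point-in-polygon rasterisation.
#'
#' @param contours A `contour_set` with at least 2 contours at distinct
#'   positions.
#' @param voxel_mm Voxel size `c(dx, dy, dz)` in mm. Defaults to the in-plane
#'   pixel size in all three dimensions; the pipeline passes the nominal
#'   frame spacing (probe speed / frame rate) as the axial spacing `dz`.
#' @param margin_vox In-plane margin around the contour bounding box, voxels.
#' @return An object of class `voxel_volume`: logical `array`, `voxel_mm`,
#'   `origin_mm` (centre of voxel `[1,1,1]`), and a triangulated `mesh`
#'   (`vertices`, `faces`) of the lofted surface.
#' @export
interpolate_surface <- function(contours, voxel_mm = NULL, margin_vox = 2L) {
  stopifnot(inherits(contours, "contour_set"))
  cts <- contours$contours
  if (length(cts) < 2) stop("need at least 2 contours", call. = FALSE)
  z <- vapply(cts, `[[`, numeric(1), "z_mm")
  ord <- order(z)
  cts <- cts[ord]; z <- z[ord]
  if (diff(range(z)) < 1e-9)
    stop("degenerate contour set: all contours at the same position", call. = FALSE)
  nv <- nrow(cts[[1]]$vertices)
  polys <- lapply(cts, function(ct) {
    v <- orient_ccw_(as.matrix(ct$vertices))
    if (!is_simple_polygon_(v)) stop("self-intersecting contour", call. = FALSE)
    if (nrow(v) != nv) v <- resample_closed_(v, nv)
    v
  })
  for (j in seq_along(polys)[-1]) polys[[j]] <- align_start_(polys[[j]], polys[[j - 1]])
  px <- contours$pixel_mm %||% 1
  if (is.null(voxel_mm)) voxel_mm <- c(px, px, px)
  dx <- voxel_mm[1]; dy <- voxel_mm[2]; dz <- voxel_mm[3]
  allv <- do.call(rbind, polys)
  # in-plane grid snapped to voxel multiples so rigid translations of the
  # contours translate, not reshape, the raster
  ux <- seq(floor(min(allv[, 1]) / dx) * dx - margin_vox * dx,
            ceiling(max(allv[, 1]) / dx) * dx + margin_vox * dx, by = dx)
  vy <- seq(floor(min(allv[, 2]) / dy) * dy - margin_vox * dy,
            ceiling(max(allv[, 2]) / dy) * dy + margin_vox * dy, by = dy)
  cen_first <- polygon_centroid_(polys[[1]])
  cen_last <- polygon_centroid_(polys[[length(polys)]])
  # axial planes at voxel centres straddling the contour span: the interior
  # planes tile [z_first, z_last] exactly, the two outermost planes sample the
  # end caps at half shrinkage
  zgrid <- seq(z[1] - dz / 2, z[length(z)] + dz / 2, by = dz)
  arr <- array(FALSE, dim = c(length(ux), length(vy), length(zgrid)))
  grid_pts <- cbind(rep(ux, times = length(vy)), rep(vy, each = length(ux)))
  poly_at_ <- function(zq) {
    if (zq <= z[1]) {             # proximal cap: shrink to centroid over dz
      w <- clamp_((z[1] - zq) / dz, 0, 1)
      sweep(polys[[1]], 2, cen_first, "-") * (1 - w) +
        matrix(cen_first, nv, 2, byrow = TRUE)
    } else if (zq >= z[length(z)]) {  # distal cap
      w <- clamp_((zq - z[length(z)]) / dz, 0, 1)
      sweep(polys[[length(polys)]], 2, cen_last, "-") * (1 - w) +
        matrix(cen_last, nv, 2, byrow = TRUE)
    } else {
      i <- findInterval(zq, z, rightmost.closed = TRUE)
      w <- (zq - z[i]) / (z[i + 1] - z[i])
      polys[[i]] * (1 - w) + polys[[i + 1]] * w
    }
  }
  for (g in seq_along(zgrid)) {
    pg <- poly_at_(zgrid[g])
    if (abs(polygon_area_(pg)) < (dx * dy) / 4) next
    # restrict the test to the polygon's bounding box
    selx <- which(ux >= min(pg[, 1]) - dx & ux <= max(pg[, 1]) + dx)
    sely <- which(vy >= min(pg[, 2]) - dy & vy <= max(pg[, 2]) + dy)
    if (length(selx) == 0 || length(sely) == 0) next
    pts <- cbind(rep(ux[selx], times = length(sely)),
                 rep(vy[sely], each = length(selx)))
    inside <- mgcv::in.out(rbind(pg, pg[1, ]), pts)
    arr[selx, sely, g] <- arr[selx, sely, g] | matrix(inside, length(selx))
  }
  mesh <- loft_mesh_(polys, z, cen_first, cen_last, dz)
  structure(list(array = arr, voxel_mm = voxel_mm,
                 origin_mm = c(ux[1], vy[1], zgrid[1]),
                 mesh = mesh, provenance = NULL),
            class = "voxel_volume")
}

# Triangulated surface of the lofted contours with centroid-fan end caps.
loft_mesh_ <- function(polys, z, cen_first, cen_last, dz) {
  nv <- nrow(polys[[1]])
  verts <- do.call(rbind, lapply(seq_along(polys), function(i)
    cbind(polys[[i]], z[i])))
  faces <- list()
  for (i in seq_len(length(polys) - 1)) {
    b0 <- (i - 1) * nv
    for (k in seq_len(nv)) {
      k2 <- if (k == nv) 1L else k + 1L
      faces[[length(faces) + 1L]] <- c(b0 + k, b0 + k2, b0 + nv + k)
      faces[[length(faces) + 1L]] <- c(b0 + k2, b0 + nv + k2, b0 + nv + k)
    }
  }
  apex1 <- nrow(verts) + 1L
  apex2 <- nrow(verts) + 2L
  verts <- rbind(verts, c(cen_first, z[1] - dz), c(cen_last, z[length(z)] + dz))
  for (k in seq_len(nv)) {
    k2 <- if (k == nv) 1L else k + 1L
    faces[[length(faces) + 1L]] <- c(k2, k, apex1)
    b0 <- (length(polys) - 1) * nv
    faces[[length(faces) + 1L]] <- c(b0 + k, b0 + k2, apex2)
  }
  list(vertices = verts, faces = do.call(rbind, faces))
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$array)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels of %g x %g x %g mm, V = %.1f cm^3\n",
              d[1], d[2], d[3], x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3],
              compute_volume(x) / 1000))
  invisible(x)
}

#' Export a slice stack in the Stradwin text dialect
#'
#' Writes a text `.sw` file (one `IM` record per frame: pixel scale in x and
#' y, 3D position, orientation quaternion) and the image payload as a raw
#' 8-bit binary sidecar with the same base name and extension `.sxi`. Planes
#' are parallel in this device, so every record carries the identity
#' quaternion; the full pose fields are retained for freehand data. The
#' format round-trips losslessly through [read_stradwin()] up to 8-bit image
#' quantisation.
#'
#' @param sstack A `slice_stack`.
#' @param path Output path for the `.sw` file.
#' @return Invisibly, the two paths written.
#' @export
export_stradwin <- function(sstack, path) {
  stopifnot(inherits(sstack, "slice_stack"))
  n <- length(sstack$images)
  d <- dim(sstack$images[[1]])
  sxi <- sub("\\.sw$", ".sxi", path)
  if (identical(sxi, path)) sxi <- paste0(path, ".sxi")
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write ", path, call. = FALSE)
  on.exit(close(con), add = TRUE)
  writeLines(c("SW_DIALECT 1",
               sprintf("RES_BUF_FRAMES %d", n),
               sprintf("RES_BUF_WIDTH %d", d[2]),
               sprintf("RES_BUF_HEIGHT %d", d[1]),
               sprintf("RES_XSCALE %.9f", sstack$pixel_mm),
               sprintf("RES_YSCALE %.9f", sstack$pixel_mm)), con)
  for (i in seq_len(n)) {
    writeLines(sprintf("IM %d %.9f %.9f %.9f %.9f %.9f %.9f %.9f %.9f %.9f",
                       i, sstack$pixel_mm, sstack$pixel_mm,
                       0, sstack$vert_pos_mm[i], sstack$positions_mm[i],
                       1, 0, 0, 0), con)
  }
  raw_px <- as.raw(round(clamp_(unlist(sstack$images), 0, 1) * 255))
  bcon <- file(sxi, "wb")
  writeBin(raw_px, bcon)
  close(bcon)
  invisible(c(path, sxi))
}

#' Read a Stradwin-dialect file pair
#'
#' @param path Path to a `.sw` file written by [export_stradwin()].
#' @return A `slice_stack`.
#' @export
read_stradwin <- function(path) {
  lines <- readLines(path)
  grab <- function(key) as.numeric(sub(paste0("^", key, " "), "",
                                       grep(paste0("^", key, " "), lines, value = TRUE)[1]))
  n <- as.integer(grab("RES_BUF_FRAMES"))
  w <- as.integer(grab("RES_BUF_WIDTH"))
  h <- as.integer(grab("RES_BUF_HEIGHT"))
  xs <- grab("RES_XSCALE")
  im_lines <- grep("^IM ", lines, value = TRUE)
  rec <- do.call(rbind, lapply(strsplit(im_lines, " +"), function(p) as.numeric(p[-1])))
  sxi <- sub("\\.sw$", ".sxi", path)
  if (identical(sxi, path)) sxi <- paste0(path, ".sxi")
  bcon <- file(sxi, "rb")
  raw_px <- readBin(bcon, "raw", n = n * w * h)
  close(bcon)
  vals <- as.numeric(raw_px) / 255
  imgs <- lapply(seq_len(n), function(i)
    matrix(vals[((i - 1) * w * h + 1):(i * w * h)], h, w))
  structure(list(images = imgs, positions_mm = rec[, 6], vert_pos_mm = rec[, 5],
                 pixel_mm = xs, provenance = basename(path)),
            class = "slice_stack")
}

#' Export a lofted surface as ASCII STL or PLY
#'
#' @param volume A `voxel_volume` carrying a `mesh`, or a mesh list with
#'   `vertices` (n x 3) and `faces` (m x 3, 1-based).
#' @param path Output file; the format follows `format`.
#' @param format `"stl"` or `"ply"`.
#' @return Invisibly, `path`.
#' @export
write_surface <- function(volume, path, format = c("stl", "ply")) {
  format <- match.arg(format)
  mesh <- if (inherits(volume, "voxel_volume")) volume$mesh else volume
  if (is.null(mesh)) stop("no mesh available", call. = FALSE)
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  if (format == "stl") {
    writeLines("solid muscle", con)
    for (i in seq_len(nrow(f))) {
      tri <- v[f[i, ], , drop = FALSE]
      nrm <- c(crossprod_(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ]))
      nn <- sqrt(sum(nrm^2)); if (nn > 0) nrm <- nrm / nn
      writeLines(c(sprintf("  facet normal %g %g %g", nrm[1], nrm[2], nrm[3]),
                   "    outer loop",
                   sprintf("      vertex %g %g %g", tri[, 1], tri[, 2], tri[, 3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid muscle", con)
  } else {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%g %g %g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  }
  invisible(path)
}

crossprod_ <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                               a[3] * b[1] - a[1] * b[3],
                               a[1] * b[2] - a[2] * b[1])

#' Write a voxel volume as NIfTI
#'
#' @param volume A `voxel_volume`.
#' @param path Output `.nii` or `.nii.gz` path.
#' @return Invisibly, `path`.
#' @export
write_volume_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  arr <- volume$array * 1.0
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- volume$voxel_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
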