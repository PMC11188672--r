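ellipsoid_mask_ <- function(a, b, c_ax, voxel = 1, rot = diag(3), pad = 3) {
  # lab-frame extent of a body-frame ellipsoid sampled via p_body = g %*% rot
  ext <- sqrt(rowSums((rot %*% diag(c(a, b, c_ax)))^2)) + pad
  xs <- seq(-ext[1], ext[1], by = voxel)
  ys <- seq(-ext[2], ext[2], by = voxel)
  zs <- seq(-ext[3], ext[3], by = voxel)
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  p <- g %*% rot  # body-frame coordinates
  inside <- (p[, 1] / a)^2 + (p[, 2] / b)^2 + (p[, 3] / c_ax)^2 <= 1
  structure(list(array = array(inside, dim = c(length(xs), length(ys), length(zs))),
                 voxel_mm = rep(voxel, 3),
                 origin_mm = c(xs[1], ys[1], zs[1])),
            class = "voxel_volume")
}

test_that("volume is voxel count times voxel resolution", {
  v <- structure(list(array = array(c(rep(TRUE, 3), rep(FALSE, 5)), c(2, 2, 2)),
                      voxel_mm = c(0.5, 0.5, 1.0), origin_mm = c(0, 0, 0)),
                 class = "voxel_volume")
  expect_equal(compute_volume(v), 0.75)
  v$array[] <- FALSE
  expect_equal(compute_volume(v), 0)
  # discretised ellipsoid (15, 15, 100) at 1 mm voxels vs the closed form
  e <- ellipsoid_mask_(15, 15, 100)
  expect_lt(abs(compute_volume(e) / (4 / 3 * pi * 15 * 15 * 100) - 1), 0.02)
})

test_that("PCA alignment recovers the longitudinal axis and preserves volume", {
  # axis-aligned ellipsoid: rotation is identity up to axis sign
  e <- ellipsoid_mask_(10, 12, 40)
  al <- weighted_pca_align(e)
  expect_gt(abs(al$rotation[3, 1]), cos(0.5 * pi / 180))
  expect_equal(compute_volume(al), compute_volume(e))
  # rotated 30 deg about a transverse axis: axis recovered within 0.5 deg
  th <- 30 * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  er <- ellipsoid_mask_(10, 12, 40, rot = Rx)
  alr <- weighted_pca_align(er)
  axis_lab <- Rx[, 3]  # body long axis expressed in lab coordinates
  ang <- acos(min(1, abs(sum(alr$rotation[, 1] * axis_lab)))) * 180 / pi
  expect_lt(ang, 0.5)
  expect_equal(compute_volume(alr), compute_volume(er))
  # slice-equalised weights (slabs along the original scan axis) up-weight
  # the thin ends; on a rotated body this is a coarser but still close axis
  alw <- weighted_pca_align(er, weights = "slice")
  angw <- acos(min(1, abs(sum(alw$rotation[, 1] * axis_lab)))) * 180 / pi
  expect_lt(angw, 2)
  expect_equal(compute_volume(alw), compute_volume(er))
  # sphere: any rotation is valid; only volume invariance is asserted
  s <- ellipsoid_mask_(15, 15, 15)
  expect_equal(compute_volume(weighted_pca_align(s)), compute_volume(s))
  # degenerate single-plane voxel set
  flat <- structure(list(array = array(TRUE, c(5, 5, 1)), voxel_mm = c(1, 1, 1),
                         origin_mm = c(0, 0, 0)), class = "voxel_volume")
  expect_error(weighted_pca_align(flat), "degenerate")
})

test_that("length is the distance between the end-slice centroids", {
  ct <- make_contour_set(list(make_ellipse_contour(5, 5, 10),
                              make_ellipse_contour(5, 5, 50),
                              make_ellipse_contour(5, 5, 110)))
  expect_equal(compute_length(ct), 100)
  # 3-4-5-12-13: centroids (3,4,0) and (0,0,12)
  ct2 <- make_contour_set(list(
    make_ellipse_contour(2, 2, 0, center = c(3, 4)),
    make_ellipse_contour(2, 2, 12, center = c(0, 0))))
  expect_equal(compute_length(ct2), 13, tolerance = 1e-9)
  expect_error(compute_length(make_contour_set(list(
    make_ellipse_contour(2, 2, 0)))), "at least 2")
})

test_that("CSA profiles count foreground pixels times pixel area", {
  arr <- array(FALSE, c(20, 20, 3))
  arr[1:10, 1:20, 2] <- TRUE   # 200 pixels
  v <- structure(list(array = arr, voxel_mm = c(0.1, 0.1, 1),
                      origin_mm = c(0, 0, 0)), class = "voxel_volume")
  prof <- compute_csa_profile(v)
  expect_equal(nrow(prof), 1)
  expect_equal(prof$csa_mm2, 2)   # 200 * 0.1 * 0.1
  # profile integral ~ volume for a smooth solid
  e <- ellipsoid_mask_(12, 10, 40, voxel = 0.5)
  pe <- compute_csa_profile(e)
  integral <- sum(pe$csa_mm2) * 0.5
  expect_lt(abs(integral / compute_volume(e) - 1), 1e-9)
  # contour-set method returns polygon areas sorted by position
  ct <- make_contour_set(list(make_ellipse_contour(5, 4, 30),
                              make_ellipse_contour(6, 5, 10)))
  pc <- compute_csa_profile(ct)
  expect_equal(pc$pos_mm, c(10, 30))
  expect_equal(pc$csa_mm2[1], pi * 30, tolerance = 0.01)
})

test_that("phantom mid-slice segmentation matches the analytic CSA within 1%", {
  ph <- phantom_config(noise_sd = 0)
  L <- muscle_length_at(130, ph)
  pos <- seq(5, L - 5, length.out = 40)
  imgs <- lapply(pos, function(p) render_cross_section(ph, 130, p))
  ss <- structure(list(images = imgs, positions_mm = pos,
                       vert_pos_mm = rep(0, 40), pixel_mm = 1),
                  class = "slice_stack")
  ct <- segment_slices(ss, n_slices = 17)
  mid <- which.min(abs(vapply(ct$contours, `[[`, numeric(1), "z_mm") - L / 2))
  a_true <- csa_at(ph, 130, ct$contours[[mid]]$z_mm)
  expect_lt(abs(abs(ct$contours[[mid]]$area_mm2) / a_true - 1), 0.01)
})

test_that("lengths normalise to the 0%-ROM reference L0", {
  cells <- data.frame(condition = "slow_active", rom_pct = c(0, 100),
                      length_mm = c(200, 222.4))
  out <- normalize_lengths(cells)
  expect_equal(out$L0_mm, c(200, 200))
  expect_equal(out$length_pct_L0, c(100, 111.2))
  # a single cell is its own reference
  one <- normalize_lengths(data.frame(condition = "x", rom_pct = 0,
                                      length_mm = 150))
  expect_equal(one$length_pct_L0, 100)
  # missing 0% cell is an error
  expect_error(normalize_lengths(data.frame(condition = "x", rom_pct = 50,
                                            length_mm = 150)), "0%")
  # uniform CSA profile normalises to exactly 1
  prof <- list(data.frame(pos_mm = 0:10, csa_mm2 = rep(4, 11)))
  out2 <- normalize_lengths(data.frame(condition = "x", rom_pct = 0,
                                       length_mm = 100), profiles = prof)
  p <- attr(out2, "profiles")[[1]]
  expect_true(all(p$csa_norm == 1))
  expect_equal(range(p$pos_pct_L0), c(0, 10))
})

test_that("the quadratic fit finds the CSA peak", {
  # exact parabola: vertex and value recovered with r = 1
  x <- seq(10, 100, by = 1)
  prof <- data.frame(pos = x, csa = 100 - (x - 55)^2 / 10)
  fit <- fit_max_csa(prof)
  expect_equal(fit$max_pos, 55, tolerance = 1e-9)
  expect_equal(fit$max_csa, 100, tolerance = 1e-9)
  expect_equal(fit$fit_r, 1, tolerance = 1e-9)
  expect_false(fit$fallback)
  # vertex equals a brute-force dense evaluation of the fitted quadratic
  b <- fit$coefficients
  xx <- seq(fit$window[1], fit$window[2], length.out = 2e5)
  expect_lt(abs(xx[which.max(b[1] + b[2] * xx + b[3] * xx^2)] - fit$max_pos),
            1e-3)  # grid resolution; the vertex itself is closed-form
  # noisy parabola: vertex within 2 of 55, r > 0.95
  set.seed(12)
  noisy <- data.frame(pos = x, csa = 100 - (x - 55)^2 / 10 + rnorm(length(x)))
  fitn <- fit_max_csa(noisy)
  expect_lt(abs(fitn$max_pos - 55), 2)
  expect_gt(fitn$fit_r, 0.95)
  # monotone profile: fallback flagged, argmax of observations returned
  mono <- data.frame(pos = x, csa = x)
  fitm <- fit_max_csa(mono)
  expect_true(fitm$fallback)
  expect_equal(fitm$max_pos, 100)
  expect_error(fit_max_csa(prof[1:4, ]), "at least 5")
})

test_that("ellipsoid model identities hold", {
  m <- ellipsoid_model(1, 1, 1)
  expect_equal(m$V_mm3, 4 * pi / 3)
  # V = 90 000 mm^3, L = 300 mm -> c = 150, CSA = 450 mm^2
  expect_equal(ellipsoid_csa(90000, 300), 450)
  # (3/4) V / c == pi a b whenever V = 4/3 pi a b c, on 100 random ellipsoids
  set.seed(2)
  for (i in 1:100) {
    abc <- runif(3, 0.5, 80)
    V <- 4 / 3 * pi * prod(abc)
    expect_equal(ellipsoid_csa(V, 2 * abc[3]), pi * abc[1] * abc[2],
                 tolerance = 1e-9)
  }
  expect_error(ellipsoid_csa(-1, 10), "positive")
  expect_error(ellipsoid_model(1, 0, 1), "positive")
})

test_that("per-condition regression recovers exact lines", {
  x <- seq(100, 111, by = 1)
  cells <- rbind(
    data.frame(condition = "a", length_pct_L0 = x, max_csa_mm2 = -0.05 * x + 10),
    data.frame(condition = "b", length_pct_L0 = x, max_csa_mm2 = 7))
  out <- regress_max_csa_vs_length(cells)
  expect_equal(out$slope[out$condition == "a"], -0.05, tolerance = 1e-12)
  expect_equal(out$intercept[out$condition == "a"], 10, tolerance = 1e-10)
  expect_equal(out$slope[out$condition == "b"], 0, tolerance = 1e-12)
  expect_error(regress_max_csa_vs_length(
    data.frame(condition = "a", length_pct_L0 = c(1, 1, 1),
               max_csa_mm2 = 1:3)), "rank-deficient")
  expect_error(regress_max_csa_vs_length(cells[1:2, ]), "at least 3")
})
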