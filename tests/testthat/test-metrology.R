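test_that("static rod width and angle match the manufactured geometry", {
  vol <- static_rod()
  w <- apparent_rod_width(vol)
  expect_equal(as.numeric(w), 0.635, tolerance = 0.1 / 0.635)  # +- 1 pixel
  expect_equal(apparent_rod_angle(vol), 26.0, tolerance = 0.5 / 26)
  # the raw AP extent exceeds the perpendicular width by 1/cos(angle)
  expect_gt(attr(w, "ap_extent_cm"), as.numeric(w))
})

test_that("rod measurements are invariant under rigid whole-pixel AP shifts", {
  g <- grid_spec(c(2, 10, 10), in_plane_cm = 0.1, slice_cm = 0.2)
  base <- render_static_volume(rod_phantom(), g)
  moved <- render_static_volume(rod_phantom(), g, ap_offset_cm = 1)
  expect_equal(apparent_rod_angle(moved), apparent_rod_angle(base),
               tolerance = 1e-9)
  expect_equal(as.numeric(apparent_rod_width(moved)),
               as.numeric(apparent_rod_width(base)), tolerance = 1e-9)
})

test_that("symmetric alternating slice perturbations cancel in the axis fit", {
  vol <- static_rod()
  pert <- vol
  ny <- vol$grid$dim[2]
  for (k in seq_len(vol$grid$dim[3])) {
    shift <- if (k %% 2 == 0) 1L else -1L
    sl <- vol$voxels[, , k]
    out <- array(min(sl), dim(sl))
    if (shift > 0) out[, 2:ny] <- sl[, 1:(ny - 1)] else
      out[, 1:(ny - 1)] <- sl[, 2:ny]
    pert$voxels[, , k] <- out
  }
  expect_equal(apparent_rod_angle(pert), apparent_rod_angle(vol),
               tolerance = 0.3 / 26)
})

test_that("raising the object threshold never widens the measurements", {
  vol <- static_rod()
  thresholds <- seq(-700, -250, by = 50)
  # per-slice supra-threshold extents are monotone non-increasing exactly
  exts <- sapply(thresholds, function(th)
    virtual4dct:::slice_profile(vol, th)$extent_y)
  mid <- seq(10, 35)
  expect_true(all(apply(exts[mid, ], 1, function(e) all(diff(e) <= 1e-9))))
  # the reported width follows, up to the wiggle of the re-fitted axis angle
  widths <- vapply(thresholds, function(th)
    as.numeric(apparent_rod_width(vol, measurement_settings(object_threshold_hu = th))),
    numeric(1))
  expect_true(all(diff(widths) <= 0.01))
})

test_that("static width error shrinks with finer in-plane sampling", {
  fine <- render_static_volume(rod_phantom(),
                               grid_spec(c(2, 8, 6), in_plane_cm = 0.05,
                                         slice_cm = 0.2))
  coarse <- render_static_volume(rod_phantom(),
                                 grid_spec(c(2, 8, 6), in_plane_cm = 0.1,
                                           slice_cm = 0.2))
  err <- function(v) abs(as.numeric(apparent_rod_width(v)) - 0.635)
  expect_lt(err(fine), err(coarse))
})

test_that("sphere diameters read true on static renders and respect dilation", {
  sp <- sphere_phantom(diameters_cm = 4, gap_cm = 1)
  g <- grid_spec(c(5, 5, 5), in_plane_cm = 0.1, slice_cm = 0.2)
  vol <- render_static_volume(sp, g)
  d <- sphere_diameters(vol, center_cm = c(0, 0, 0))
  expect_equal(unname(d["ap_cm"]), 4, tolerance = 0.1 / 4)
  expect_equal(unname(d["ap_cm"]), unname(d["lr_cm"]))  # isotropy
  # growing the mask by a one-pixel ring adds two pixels to each diameter
  mask <- vol$voxels >= -650
  shift1 <- function(m, axis, by) {
    out <- array(FALSE, dim(m))
    n <- dim(m)[axis]
    src <- seq_len(n - abs(by))
    if (by > 0) {
      if (axis == 1) out[src + by, , ] <- m[src, , ] else
        out[, src + by, ] <- m[, src, ]
    } else {
      if (axis == 1) out[src, , ] <- m[src + abs(by), , ] else
        out[, src, ] <- m[, src + abs(by), ]
    }
    out
  }
  grown <- mask | shift1(mask, 1, 1) | shift1(mask, 1, -1) |
    shift1(mask, 2, 1) | shift1(mask, 2, -1)
  dil <- image_volume(ifelse(grown, 0, -1000), g)
  d2 <- sphere_diameters(dil, center_cm = c(0, 0, 0),
                         measurement_settings(object_threshold_hu = -500))
  expect_equal(unname(d2 - d), c(0.2, 0.2), tolerance = 1e-9)
})

test_that("auto-threshold contours keep the largest component and invert the sphere formula", {
  g <- grid_spec(c(3, 3, 3), in_plane_cm = 0.1, slice_cm = 0.1)
  vox <- array(-1000, g$dim)
  vox[5:24, 5:24, 5:24] <- 100      # 20^3 block
  vox[28:29, 28:29, 28:29] <- 100   # disconnected fleck
  m <- threshold_contour_metrics(image_volume(vox, g))
  expect_equal(m$volume_cc, 20^3 * 0.001)
  expect_identical(m$n_components, 2L)
  expect_equal(m$equivalent_diameter_cm, (6 * m$volume_cc / pi)^(1 / 3))
  # closed-form anchors for the equivalent diameter
  expect_equal((6 * 33.51 / pi)^(1 / 3), 4.0, tolerance = 1e-3)
  expect_equal((6 * 0.5236 / pi)^(1 / 3), 1.0, tolerance = 1e-3)
  expect_error(threshold_contour_metrics(
    image_volume(array(-1000, g$dim), g)), "contour HU range")
})

test_that("extents and contour volumes agree with brute-force voxel scans", {
  set.seed(42)
  sp <- sphere_phantom(diameters_cm = 2.4, gap_cm = 1)
  g <- grid_spec(c(3.2, 3.2, 3.2), in_plane_cm = 0.1, slice_cm = 0.1)
  vol <- render_static_volume(sp, g)
  vol$voxels <- vol$voxels + array(runif(length(vol$voxels), -30, 30), g$dim)
  prof <- virtual4dct:::slice_profile(vol, -650)
  for (k in c(8, 16, 24))
    expect_equal(prof$extent_y[k], oracle_slice_extent_y(vol, -650, k))
  expect_equal(threshold_contour_metrics(vol)$volume_cc,
               oracle_contour_volume_cc(vol, -500, 2000))
})

test_that("static rods show zero centroid shift beyond the geometric slope", {
  vol <- static_rod()
  # zero up to centroid quantization on the voxel grid
  expect_lt(centroid_shift_fraction(vol, amplitude_cm = 2), 0.01)
  # the geometric per-slice shift itself at 2.5 mm slices is 0.122 cm
  expect_equal(0.25 * tan(26 * pi / 180), 0.122, tolerance = 1e-3)
  prof <- virtual4dct:::slice_profile(static_rod(), -650)
  use <- prof[prof$n > 0, ]
  mid <- seq(5, nrow(use) - 5)
  expect_equal(mean(diff(use$centroid_y[mid])) / 0.2 * 0.25, 0.122,
               tolerance = 0.02)
})

test_that("degenerate inputs raise measurement errors", {
  g <- grid_spec(c(2, 2, 2), in_plane_cm = 0.1, slice_cm = 0.25)
  empty <- image_volume(array(-1000, g$dim), g)
  expect_error(apparent_rod_width(empty), "fewer than 3 slices")
  expect_error(sphere_diameters(empty), "empty mask")
})
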