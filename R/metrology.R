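#' Measurement display and threshold settings
#'
#' The physical measurements were read at a fixed display window/level of
#' 300/-500 HU, which shows the full extent of the rod without saturating the
#' background. For a reproducible surrogate, objects are binarized at the
#' lower window edge (`level - window/2`, -650 HU by default): every voxel
#' rendered above black at those display settings counts as object. The
#' auto-threshold contour range (-500 to 2000 HU) mirrors clinical
#' auto-contouring of solid structures in lung.
#'
#' @param window display window width, HU (> 0).
#' @param level display window center, HU.
#' @param object_threshold_hu binarization threshold; defaults to
#'   `level - window / 2`.
#' @param contour_hu_low,contour_hu_high auto-threshold contour HU range.
#' @return an object of class `measurement_settings`.
#' @export
measurement_settings <- function(window = 300, level = -500,
                                 object_threshold_hu = NULL,
                                 contour_hu_low = -500, contour_hu_high = 2000) {
  if (window <= 0) stop("window must be positive")
  if (contour_hu_low >= contour_hu_high)
    stop("contour_hu_low must be below contour_hu_high")
  structure(list(window = window, level = level,
                 object_threshold_hu = object_threshold_hu %||% (level - window / 2),
                 contour_hu_low = contour_hu_low,
                 contour_hu_high = contour_hu_high),
            class = "measurement_settings")
}

# Per-axial-slice statistics of the supra-threshold mask: AP extent between
# the first and last supra-threshold voxel centers, and the binary centroid.
slice_profile <- function(volume, threshold) {
  g <- volume$grid
  ys <- grid_coords(g, 2)
  xs <- grid_coords(g, 1)
  zs <- grid_coords(g, 3)
  nz <- g$dim[3]
  out <- data.frame(z = zs, n = 0L, extent_y = NA_real_,
                    centroid_y = NA_real_, centroid_x = NA_real_)
  for (k in seq_len(nz)) {
    m <- volume$voxels[, , k] >= threshold
    n <- sum(m)
    if (n == 0L) next
    iy <- which(colSums(m) > 0)
    out$n[k] <- n
    out$extent_y[k] <- ys[max(iy)] - ys[min(iy)]
    wy <- colSums(m); wx <- rowSums(m)
    out$centroid_y[k] <- sum(ys * wy) / n
    out$centroid_x[k] <- sum(xs * wx) / n
  }
  out
}

# Least-squares rod axis through per-slice centroids; returns angle (deg)
# and the slice table restricted to usable slices.
fit_rod_axis <- function(volume, settings) {
  prof <- slice_profile(volume, settings$object_threshold_hu)
  use <- prof[prof$n > 0, , drop = FALSE]
  if (nrow(use) < 3)
    stop("rod not measurable: fewer than 3 slices above threshold")
  fit <- lm(centroid_y ~ z, data = use)
  list(angle_deg = atan(coef(fit)[["z"]]) * 180 / pi, slices = use)
}

#' Apparent rod width
#'
#' Binarizes at the object threshold, measures the AP (y) extent between the
#' first and last supra-threshold voxel centers on each axial slice, fits the
#' rod axis through the per-slice centroids, and reports the mean over the
#' central slices of `extent * cos(fitted angle)` — the width read
#' perpendicular to the rod axis, directly comparable to the manufactured
#' diameter. End slices (where the rod tip truncates the cross-section) are
#' excluded by keeping the central fraction of usable slices.
#'
#' @param volume an [image_volume()] containing the rod.
#' @param settings a [measurement_settings()].
#' @param central_fraction fraction of usable slices retained, centered.
#' @return width in cm, with attributes `ap_extent_cm` (mean raw AP extent)
#'   and `angle_deg` (fitted axis angle).
#' @export
apparent_rod_width <- function(volume, settings = measurement_settings(),
                               central_fraction = 0.7) {
  fit <- fit_rod_axis(volume, settings)
  use <- fit$slices
  m <- nrow(use)
  drop_each <- floor(m * (1 - central_fraction) / 2)
  keep <- seq(drop_each + 1, m - drop_each)
  ext <- mean(use$extent_y[keep])
  width <- ext * cos(fit$angle_deg * pi / 180)
  structure(width, ap_extent_cm = ext, angle_deg = fit$angle_deg)
}

#' Apparent rod angle
#'
#' Angle between the rod and the couch plane, from the least-squares line
#' through the per-slice supra-threshold centroids (AP position vs SI
#' position): `atan(slope)` in degrees. Translation-invariant: rigidly
#' shifting the rod in AP leaves the slope unchanged.
#'
#' @inheritParams apparent_rod_width
#' @return angle in degrees.
#' @export
apparent_rod_angle <- function(volume, settings = measurement_settings()) {
  fit_rod_axis(volume, settings)$angle_deg
}

#' Apparent sphere AP and LR diameters
#'
#' On the axial slice nearest the sphere center, measures the supra-threshold
#' extents along the AP and LR lines through the center (between the first
#' and last supra-threshold voxel centers of the run containing the center).
#' When no center is supplied it is taken as the supra-threshold centroid.
#'
#' @param volume an [image_volume()] (typically cropped to one sphere).
#' @param center_cm optional length-3 sphere center (x, y, z) in cm.
#' @param settings a [measurement_settings()].
#' @return named numeric `c(ap_cm, lr_cm)`.
#' @export
sphere_diameters <- function(volume, center_cm = NULL,
                             settings = measurement_settings()) {
  g <- volume$grid
  mask <- volume$voxels >= settings$object_threshold_hu
  if (!any(mask)) stop("no supra-threshold voxels: empty mask")
  if (is.null(center_cm)) {
    idx <- which(mask, arr.ind = TRUE)
    center_cm <- c(mean(grid_coords(g, 1)[idx[, 1]]),
                   mean(grid_coords(g, 2)[idx[, 2]]),
                   mean(grid_coords(g, 3)[idx[, 3]]))
  }
  near <- function(axis, v) which.min(abs(grid_coords(g, axis) - v))
  ix <- near(1, center_cm[1]); iy <- near(2, center_cm[2]); iz <- near(3, center_cm[3])
  run_extent <- function(profile, coords, at) {
    runs <- rle(profile)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    on <- which(runs$values)
    if (!length(on)) stop("no supra-threshold voxels on the measurement line")
    containing <- on[starts[on] <= at & ends[on] >= at]
    r <- if (length(containing)) containing[1] else
      on[which.min(pmin(abs(starts[on] - at), abs(ends[on] - at)))]
    coords[ends[r]] - coords[starts[r]]
  }
  ap <- run_extent(mask[ix, , iz], grid_coords(g, 2), iy)
  lr <- run_extent(mask[, iy, iz], grid_coords(g, 1), ix)
  c(ap_cm = ap, lr_cm = lr)
}

# Frontier BFS labelling of the largest 6-connected component of a logical
# 3D array; returns the voxel count of the largest component and how many
# components exist.
largest_component <- function(mask) {
  dims <- dim(mask)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  labels <- array(0L, dims)
  remaining <- which(mask)
  sizes <- integer(0)
  lab <- 0L
  while (length(remaining)) {
    lab <- lab + 1L
    frontier <- remaining[1]
    labels[frontier] <- lab
    size <- 0L
    while (length(frontier)) {
      size <- size + length(frontier)
      i0 <- frontier - 1L
      ix <- i0 %% nx
      iy <- (i0 %/% nx) %% ny
      iz <- i0 %/% (nx * ny)
      nb <- c(frontier[ix > 0] - 1L, frontier[ix < nx - 1] + 1L,
              frontier[iy > 0] - nx, frontier[iy < ny - 1] + nx,
              frontier[iz > 0] - nx * ny, frontier[iz < nz - 1] + nx * ny)
      nb <- unique(nb)
      nb <- nb[mask[nb] & labels[nb] == 0L]
      labels[nb] <- lab
      frontier <- nb
    }
    sizes <- c(sizes, size)
    remaining <- remaining[labels[remaining] == 0L]
  }
  list(largest = if (length(sizes)) max(sizes) else 0L,
       n_components = length(sizes))
}

#' Auto-threshold contour volume and equivalent diameter
#'
#' Selects the voxels within the contour HU range, keeps the largest
#' 6-connected component (excluding disconnected artifact flecks, as
#' clinical auto-threshold contouring does), and reports its volume (voxel
#' count times voxel volume) and the equivalent diameter
#' `(6 V / pi)^(1/3)` — the diameter of the sphere of equal volume.
#'
#' @param volume an [image_volume()] (typically cropped to one object).
#' @param settings a [measurement_settings()].
#' @return list with `volume_cc`, `equivalent_diameter_cm`, `n_components`.
#' @export
threshold_contour_metrics <- function(volume, settings = measurement_settings()) {
  mask <- volume$voxels >= settings$contour_hu_low &
    volume$voxels <= settings$contour_hu_high
  if (!any(mask)) stop("no voxels within the contour HU range")
  comp <- largest_component(mask)
  v <- comp$largest * voxel_volume_cc(volume$grid)
  list(volume_cc = v,
       equivalent_diameter_cm = (6 * v / pi)^(1 / 3),
       n_components = comp$n_components)
}

#' Adjacent-slice centroid shift as a fraction of motion amplitude
#'
#' A tilted rod's centroid legitimately advances by
#' `slice_thickness * tan(angle)` per slice; any excess between adjacent
#' slices is motion artifact. Reports the maximum over adjacent usable slice
#' pairs of `max(0, |delta centroid_y| - geometric shift)` divided by the
#' motion amplitude (RoM / 2). Zero for a static rod.
#'
#' @param volume an [image_volume()] containing the rod.
#' @param amplitude_cm motion amplitude (half the range of motion), cm (> 0).
#' @param settings a [measurement_settings()].
#' @param angle_deg the rod's true tilt used for the geometric shift.
#' @return dimensionless fraction.
#' @export
centroid_shift_fraction <- function(volume, amplitude_cm,
                                    settings = measurement_settings(),
                                    angle_deg = 26.0) {
  if (amplitude_cm <= 0) stop("amplitude_cm must be positive")
  prof <- slice_profile(volume, settings$object_threshold_hu)
  use <- prof[prof$n > 0, , drop = FALSE]
  if (nrow(use) < 2) stop("rod not measurable on >= 2 slices")
  adjacent <- which(diff(use$z) <= volume$grid$spacing[3] + 1e-9)
  if (!length(adjacent)) stop("no adjacent usable slice pairs")
  dy <- abs(diff(use$centroid_y))[adjacent]
  geom <- volume$grid$spacing[3] * tan(angle_deg * pi / 180)
  max(pmax(0, dy - geom)) / amplitude_cm
}
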