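#' Voxel grid specification
#'
#' Defines a regular voxel grid with axes x = LR, y = AP (positive anterior),
#' z = SI. Coordinates refer to voxel centers; voxel `[1,1,1]` is centered at
#' `origin`. The grid is built from a requested physical extent centered on
#' `center_cm`; dimensions are rounded to whole voxels.
#'
#' @param extent_cm length-3 physical extent (LR, AP, SI) in cm.
#' @param in_plane_cm in-plane (x and y) voxel size in cm; 0.1 cm is typical
#'   CT in-plane resolution.
#' @param slice_cm slice thickness (z voxel size) in cm.
#' @param center_cm length-3 center of the grid in cm.
#' @return an object of class `grid_spec` with fields `dim`, `spacing`
#'   (dx, dy, dz) and `origin` (center of the first voxel).
#' @export
grid_spec <- function(extent_cm, in_plane_cm = 0.1, slice_cm = 0.25,
                      center_cm = c(0, 0, 0)) {
  if (length(extent_cm) != 3 || any(extent_cm <= 0))
    stop("extent_cm must be three positive lengths (LR, AP, SI)")
  if (in_plane_cm <= 0 || slice_cm <= 0) stop("voxel spacings must be positive")
  spacing <- c(in_plane_cm, in_plane_cm, slice_cm)
  dims <- pmax(1L, as.integer(round(extent_cm / spacing)))
  origin <- center_cm - dims * spacing / 2 + spacing / 2
  structure(list(dim = dims, spacing = spacing, origin = origin),
            class = "grid_spec")
}

#' Voxel-center coordinates along one grid axis
#'
#' @param grid a [grid_spec()].
#' @param axis 1 (LR/x), 2 (AP/y) or 3 (SI/z).
#' @return numeric vector of voxel-center positions in cm.
#' @export
grid_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dim[axis]) - 1) * grid$spacing[axis]
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g cm\n",
              x$dim[1], x$dim[2], x$dim[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Angled rod phantom
#'
#' A rigid cylindrical rod whose axis lies in the AP-SI (y-z) plane, tilted
#' by `angle_deg` from the couch plane so that the rod's AP position changes
#' linearly along SI with slope `tan(angle_deg)`. Manufactured defaults:
#' 6.35 mm (1/4") diameter at 26.0 degrees. HU values are configurable; the
#' defaults (water-equivalent rod in an air-like background) keep the object
#' well separated from background at the fixed measurement window/level.
#'
#' @param diameter_cm rod diameter in cm.
#' @param angle_deg angle between rod axis and couch plane, degrees (0, 90).
#' @param length_cm rod length measured along its axis, cm.
#' @param hu_rod,hu_background Hounsfield units of rod and background.
#' @return an object of class `rod_phantom`.
#' @export
rod_phantom <- function(diameter_cm = 0.635, angle_deg = 26.0,
                        length_cm = 10, hu_rod = 0, hu_background = -800) {
  if (diameter_cm <= 0) stop("diameter_cm must be positive")
  if (angle_deg <= 0 || angle_deg >= 90) stop("angle_deg must lie in (0, 90)")
  if (length_cm <= 0) stop("length_cm must be positive")
  structure(list(diameter_cm = diameter_cm, angle_deg = angle_deg,
                 length_cm = length_cm, hu_object = hu_rod,
                 hu_background = hu_background),
            class = c("rod_phantom", "phantom"))
}

#' Lung-embedded sphere phantom
#'
#' Solid spheres of the given diameters embedded in a lung-equivalent
#' background, arranged along the SI axis with `gap_cm` of background between
#' adjacent sphere surfaces and the chain centered at z = 0. Defaults emulate
#' clay spheres (about +50 HU) in lung-equivalent material (about -700 HU).
#'
#' @param diameters_cm sphere diameters in cm.
#' @param hu_sphere,hu_lung Hounsfield units of spheres and background.
#' @param gap_cm surface-to-surface SI gap between adjacent spheres, cm.
#' @return an object of class `sphere_phantom` with a `centers` matrix
#'   (one row per sphere, columns x, y, z in cm) and `radii_cm`.
#' @export
sphere_phantom <- function(diameters_cm = c(1, 2, 3, 4), hu_sphere = 50,
                           hu_lung = -700, gap_cm = 1.5) {
  if (any(diameters_cm <= 0)) stop("diameters must be positive")
  if (gap_cm <= 0) stop("gap_cm must be positive to prevent overlap")
  r <- diameters_cm / 2
  z <- numeric(length(r))
  for (i in seq_along(r)[-1]) z[i] <- z[i - 1] + r[i - 1] + gap_cm + r[i]
  z <- z - (min(z - r) + max(z + r)) / 2  # center the chain on z = 0
  structure(list(diameters_cm = diameters_cm, radii_cm = r,
                 centers = cbind(x = 0, y = 0, z = z),
                 hu_object = hu_sphere, hu_background = hu_lung),
            class = c("sphere_phantom", "phantom"))
}

# Point-in-phantom test in the phantom's own frame, vectorized over (x, y, z).
phantom_inside <- function(phantom, x, y, z) UseMethod("phantom_inside")

#' @export
phantom_inside.rod_phantom <- function(phantom, x, y, z) {
  a <- phantom$angle_deg * pi / 180
  r2 <- (phantom$diameter_cm / 2)^2
  u <- y * cos(a) - z * sin(a)       # perpendicular offset from the axis
  s <- y * sin(a) + z * cos(a)       # position along the axis
  (x * x + u * u <= r2) & (abs(s) <= phantom$length_cm / 2)
}

#' @export
phantom_inside.sphere_phantom <- function(phantom, x, y, z) {
  inside <- rep(FALSE, length(x))
  for (i in seq_along(phantom$radii_cm)) {
    c_i <- phantom$centers[i, ]
    d2 <- (x - c_i[1])^2 + (y - c_i[2])^2 + (z - c_i[3])^2
    inside <- inside | (d2 <= phantom$radii_cm[i]^2)
  }
  inside
}

#' Rasterize a phantom into a slab of HU slices
#'
#' Each voxel's HU is the occupancy-weighted mix of the object and background
#' HU, with occupancy estimated by supersampling (`supersample` points per
#' axis, 27 subsamples at the default 3). The phantom is rigidly translated
#' by `ap_offset_cm` along +y (anterior) before rasterization, emulating the
#' motion platform.
#'
#' @param phantom a [rod_phantom()] or [sphere_phantom()].
#' @param grid a [grid_spec()] supplying the in-plane geometry and slice
#'   thickness.
#' @param z_start_cm SI position of the slab's first slice boundary (the
#'   first slice is centered at `z_start_cm + slice/2`), cm.
#' @param n_slices number of slices to render.
#' @param ap_offset_cm rigid AP translation of the phantom, cm.
#' @param supersample subsamples per axis for partial-volume occupancy.
#' @return a 3D HU array of dim `c(nx, ny, n_slices)`.
#' @export
render_slab <- function(phantom, grid, z_start_cm, n_slices, ap_offset_cm = 0,
                        supersample = 3L) {
  dzc <- grid$spacing[3]
  zc <- z_start_cm + (seq_len(n_slices) - 0.5) * dzc
  zlim <- c(grid$origin[3] - grid$spacing[3] / 2,
            grid$origin[3] + (grid$dim[3] - 0.5) * grid$spacing[3])
  if (z_start_cm < zlim[1] - 1e-6 || z_start_cm + n_slices * dzc > zlim[2] + 1e-6)
    stop("requested slab lies outside the grid extent")
  xs <- grid_coords(grid, 1)
  ys <- grid_coords(grid, 2)
  nx <- length(xs); ny <- length(ys)
  X <- rep(xs, times = ny * n_slices)
  Y <- rep(rep(ys, each = nx), times = n_slices)
  Z <- rep(zc, each = nx * ny)
  s <- as.integer(supersample)
  if (s < 1L) stop("supersample must be >= 1")
  off <- ((seq_len(s) - 0.5) / s - 0.5)
  occ <- numeric(length(X))
  for (ox in off * grid$spacing[1])
    for (oy in off * grid$spacing[2])
      for (oz in off * dzc)
        occ <- occ + phantom_inside(phantom, X + ox, Y + oy - ap_offset_cm, Z + oz)
  occ <- occ / s^3
  hu <- phantom$hu_background + occ * (phantom$hu_object - phantom$hu_background)
  array(hu, dim = c(nx, ny, n_slices))
}

#' Rasterize a full static phantom volume
#'
#' Renders every slice of the grid at a fixed AP offset (0 by default), the
#' digital analog of a motion-free reference CT. Deterministic: identical
#' specs yield identical voxels.
#'
#' @inheritParams render_slab
#' @param phase_label label stored on the volume.
#' @return an [image_volume()].
#' @export
render_static_volume <- function(phantom, grid, ap_offset_cm = 0,
                                 supersample = 3L, phase_label = "static") {
  vox <- render_slab(phantom, grid,
                     z_start_cm = grid$origin[3] - grid$spacing[3] / 2,
                     n_slices = grid$dim[3],
                     ap_offset_cm = ap_offset_cm, supersample = supersample)
  image_volume(vox, grid, phase_label = phase_label)
}
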