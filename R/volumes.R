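#' A 3D HU image volume
#'
#' The unit of reconstruction and metrology: a 3D array of Hounsfield units
#' on a [grid_spec()], optionally tagged with a phase label ("static", "0%",
#' "MIP", ...).
#'
#' @param voxels 3D numeric array with dimensions matching `grid$dim`.
#' @param grid a [grid_spec()].
#' @param phase_label optional text label.
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(voxels, grid, phase_label = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3)
    stop("voxels must be a 3D array")
  if (!identical(as.integer(dim(voxels)), as.integer(grid$dim)))
    stop("voxel array dimensions do not match the grid")
  if (any(!is.finite(voxels))) stop("HU values must be finite")
  structure(list(voxels = voxels, grid = grid, phase_label = phase_label),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s: %d x %d x %d voxels, HU [%g, %g]\n",
              x$phase_label %||% "(unlabelled)",
              dim(x$voxels)[1], dim(x$voxels)[2], dim(x$voxels)[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Voxel volume of a grid in cubic centimeters
#'
#' @param grid a [grid_spec()].
#' @return scalar cc per voxel.
#' @export
voxel_volume_cc <- function(grid) prod(grid$spacing)

#' Crop an image volume to a physical box
#'
#' Keeps the voxels whose centers fall inside the given coordinate limits
#' (cm); `NULL` limits keep the full axis.
#'
#' @param volume an [image_volume()].
#' @param xlim,ylim,zlim length-2 limits in cm or `NULL`.
#' @return a smaller [image_volume()] on a consistent sub-grid.
#' @export
crop_volume <- function(volume, xlim = NULL, ylim = NULL, zlim = NULL) {
  g <- volume$grid
  keep <- function(axis, lim) {
    co <- grid_coords(g, axis)
    if (is.null(lim)) seq_along(co) else which(co >= lim[1] & co <= lim[2])
  }
  ix <- keep(1, xlim); iy <- keep(2, ylim); iz <- keep(3, zlim)
  if (!length(ix) || !length(iy) || !length(iz))
    stop("crop box contains no voxel centers")
  sub <- volume$voxels[ix, iy, iz, drop = FALSE]
  g2 <- g
  g2$dim <- as.integer(dim(sub))
  g2$origin <- c(grid_coords(g, 1)[ix[1]], grid_coords(g, 2)[iy[1]],
                 grid_coords(g, 3)[iz[1]])
  image_volume(sub, g2, phase_label = volume$phase_label)
}

#' Write / read an image volume as NIfTI
#'
#' Voxel data and spacing round-trip exactly; the world origin is re-centered
#' on read (full qform/sform bookkeeping is out of scope for this package's
#' phantom-frame geometry).
#'
#' @param volume an [image_volume()].
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param phase_label label to attach on read.
#' @return `write_volume()` returns `path` invisibly; `read_volume()` an
#'   [image_volume()].
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$grid$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, phase_label = NULL) {
  img <- RNifti::readNifti(path)
  vox <- as.array(img)
  sp <- RNifti::pixdim(img)[seq_len(3)]
  dims <- dim(vox)
  grid <- structure(list(dim = as.integer(dims), spacing = as.numeric(sp),
                         origin = -dims * sp / 2 + sp / 2),
                    class = "grid_spec")
  image_volume(vox, grid, phase_label = phase_label)
}
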