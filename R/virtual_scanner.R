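#' Cine acquisition parameters from the breathing period
#'
#' Clinical cine protocol rules: the cine time between images is one tenth of
#' the breathing period (so successive images advance the breathing phase by
#' 10%), and the cine duration per couch station is the period plus one
#' second (guaranteeing each station observes at least one full cycle).
#'
#' @param period_s breathing period in seconds.
#' @return list with `cine_interval_s = period_s / 10` and
#'   `cine_duration_s = period_s + 1`.
#' @export
compute_protocol <- function(period_s) {
  if (!is.numeric(period_s) || period_s <= 0) stop("period_s must be positive")
  list(cine_interval_s = period_s / 10, cine_duration_s = period_s + 1)
}

#' Cine-mode acquisition protocol
#'
#' Geometry and timing of a cine 4DCT scan: at each couch station the scanner
#' repeatedly images a slab of `collimation_cm / slice_thickness_cm` slices
#' every `cine_interval_s` for `cine_duration_s`, then moves the couch
#' (taking `station_dead_time_s`). Image formation is an instantaneous
#' geometric snapshot by default; `integration_mode = "windowed"` instead
#' averages the geometry over `integration_window_s` around each timestamp
#' (for sensitivity studies of the scanner's temporal aperture).
#'
#' @param cine_interval_s time between images at one station, seconds.
#' @param cine_duration_s imaging time per station, seconds
#'   (>= `cine_interval_s`).
#' @param slice_thickness_cm reconstructed slice thickness, cm.
#' @param collimation_cm axial beam width per station, cm; must be an integer
#'   multiple of the slice thickness.
#' @param station_dead_time_s couch step time between stations, seconds.
#' @param integration_mode `"snapshot"` or `"windowed"`.
#' @param integration_window_s temporal aperture for windowed mode, seconds.
#' @param n_window_samples sub-snapshots averaged in windowed mode.
#' @return an object of class `cine_protocol`.
#' @export
cine_protocol <- function(cine_interval_s, cine_duration_s,
                          slice_thickness_cm = 0.25, collimation_cm = 2.0,
                          station_dead_time_s = 0.5,
                          integration_mode = c("snapshot", "windowed"),
                          integration_window_s = 0, n_window_samples = 5L) {
  integration_mode <- match.arg(integration_mode)
  if (cine_interval_s <= 0) stop("cine_interval_s must be positive")
  if (cine_duration_s < cine_interval_s)
    stop("cine_duration_s must be >= cine_interval_s")
  k <- collimation_cm / slice_thickness_cm
  if (abs(k - round(k)) > 1e-9)
    stop("collimation_cm must be an integer multiple of slice_thickness_cm")
  if (integration_mode == "windowed" && integration_window_s <= 0)
    stop("windowed integration requires integration_window_s > 0")
  structure(list(cine_interval_s = cine_interval_s,
                 cine_duration_s = cine_duration_s,
                 slice_thickness_cm = slice_thickness_cm,
                 collimation_cm = collimation_cm,
                 slices_per_station = as.integer(round(k)),
                 station_dead_time_s = station_dead_time_s,
                 integration_mode = integration_mode,
                 integration_window_s = integration_window_s,
                 n_window_samples = as.integer(n_window_samples)),
            class = "cine_protocol")
}

#' @rdname cine_protocol
#' @param period_s breathing period used to derive interval and duration via
#'   [compute_protocol()].
#' @param ... passed on to [cine_protocol()].
#' @export
cine_protocol_for_period <- function(period_s, ...) {
  p <- compute_protocol(period_s)
  cine_protocol(p$cine_interval_s, p$cine_duration_s, ...)
}

#' Simulate a cine-mode 4DCT acquisition of a moving phantom
#'
#' Couch stations tile the grid's SI extent in steps of the collimation.
#' Station `k` images during the window starting at
#' `start_time_s + k * (cine_duration_s + station_dead_time_s)`, acquiring
#' `floor(duration / interval) + 1` images at arithmetic timestamps. Each
#' image renders the station's slab with the phantom rigidly displaced by
#' the trace's physical AP value at the image timestamp (snapshot mode), or
#' by the average geometry over the integration window (windowed mode).
#'
#' @param phantom a [rod_phantom()] or [sphere_phantom()].
#' @param trace a [breathing_trace()]; must cover the whole scan (or loop).
#' @param protocol a [cine_protocol()].
#' @param grid a [grid_spec()] whose slice thickness matches the protocol and
#'   whose SI extent is a whole number of stations.
#' @param start_time_s scan start relative to the trace start, seconds. In
#'   the physical procedure scanning began a few cycles in, once the measured
#'   period agreed with the applied one; randomizing this value varies the
#'   breathing phase at which each station starts.
#' @param supersample rasterization subsamples per axis.
#' @return an object of class `cine_acquisition`: a list of images (each with
#'   `station`, `timestamp_s`, `ap_offset_cm` and the HU `slab`), plus the
#'   trace, protocol, grid and station table.
#' @export
acquire <- function(phantom, trace, protocol, grid, start_time_s = 0,
                    supersample = 3L) {
  if (abs(grid$spacing[3] - protocol$slice_thickness_cm) > 1e-9)
    stop("grid slice thickness must match the protocol")
  spst <- protocol$slices_per_station
  if (grid$dim[3] %% spst != 0)
    stop("grid SI extent must be a whole number of couch stations")
  n_st <- grid$dim[3] %/% spst
  n_img <- floor(protocol$cine_duration_s / protocol$cine_interval_s + 1e-9) + 1
  z_edge0 <- grid$origin[3] - grid$spacing[3] / 2
  scan_end <- start_time_s + n_st * (protocol$cine_duration_s +
                                       protocol$station_dead_time_s)
  if (!trace$loop && scan_end > (length(trace$values) - 1) * trace$sample_interval_s)
    stop("trace is shorter than the acquisition and does not loop")
  images <- vector("list", n_st * n_img)
  stations <- data.frame(station = seq_len(n_st),
                         z_start_cm = z_edge0 + (seq_len(n_st) - 1) *
                           protocol$collimation_cm,
                         window_start_s = start_time_s + (seq_len(n_st) - 1) *
                           (protocol$cine_duration_s + protocol$station_dead_time_s))
  idx <- 0L
  for (k in seq_len(n_st)) {
    for (j in seq_len(n_img) - 1L) {
      ts <- stations$window_start_s[k] + j * protocol$cine_interval_s
      ap <- physical_at(trace, ts)
      if (protocol$integration_mode == "snapshot") {
        slab <- render_slab(phantom, grid, stations$z_start_cm[k], spst,
                            ap_offset_cm = ap, supersample = supersample)
      } else {
        w <- protocol$integration_window_s
        tt <- ts + seq(-w / 2, w / 2, length.out = protocol$n_window_samples)
        tt <- pmax(tt, 0)
        acc <- NULL
        for (t1 in tt) {
          s1 <- render_slab(phantom, grid, stations$z_start_cm[k], spst,
                            ap_offset_cm = physical_at(trace, t1),
                            supersample = supersample)
          acc <- if (is.null(acc)) s1 else acc + s1
        }
        slab <- acc / length(tt)
      }
      idx <- idx + 1L
      images[[idx]] <- list(station = k, timestamp_s = ts, ap_offset_cm = ap,
                            slab = slab)
    }
  }
  structure(list(images = images, trace = trace, protocol = protocol,
                 grid = grid, stations = stations, n_stations = n_st,
                 images_per_station = n_img, start_time_s = start_time_s),
            class = "cine_acquisition")
}

#' @export
print.cine_acquisition <- function(x, ...) {
  cat(sprintf("<cine_acquisition> %d stations x %d images (interval %.3g s, duration %.3g s)\n",
              x$n_stations, x$images_per_station,
              x$protocol$cine_interval_s, x$protocol$cine_duration_s))
  invisible(x)
}

#' Acquire a motion-free reference volume
#'
#' The digital analog of the static planning scan: a single artifact-free
#' volume rendered at zero AP offset, typically on a finer (2 mm) slice
#' grid than the cine acquisition.
#'
#' @param phantom a phantom object.
#' @param grid a [grid_spec()] (conventionally with `slice_cm = 0.2`).
#' @param supersample rasterization subsamples per axis.
#' @return an [image_volume()] labelled `"static"`.
#' @export
acquire_static <- function(phantom, grid, supersample = 3L) {
  render_static_volume(phantom, grid, ap_offset_cm = 0,
                       supersample = supersample, phase_label = "static")
}
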