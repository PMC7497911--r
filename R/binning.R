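#' Phase binning configuration
#'
#' @param bin_width_percent phase bin width; 100 must be divisible by it.
#'   The clinical reconstruction used 10% bins (bins at 0%, 10%, ..., 90%).
#' @param missing_bin_policy `"nearest-fill"` assigns the phase-nearest image
#'   to every bin even when its residual exceeds half a bin (mirroring
#'   clinical phase binning, which always produces whole image sets);
#'   `"leave-gap"` instead marks such bins unfilled (NA slab).
#' @return an object of class `binning_config`.
#' @export
binning_config <- function(bin_width_percent = 10,
                           missing_bin_policy = c("nearest-fill", "leave-gap")) {
  missing_bin_policy <- match.arg(missing_bin_policy)
  if (bin_width_percent <= 0 || 100 %% bin_width_percent != 0)
    stop("100 must be divisible by bin_width_percent")
  structure(list(bin_width_percent = bin_width_percent,
                 missing_bin_policy = missing_bin_policy),
            class = "binning_config")
}

#' Assign breathing phases to timestamps
#'
#' RPM-style phase: inhale peaks define 0%, and phase grows piecewise
#' linearly with time to 100% at the next peak (a symmetric sinusoid's trough
#' therefore sits at 50%, the exhale phase). Timestamps before the first or
#' after the last detected peak are extrapolated with the nearest cycle's
#' period, modulo 100. Looping traces have their peak train tiled across
#' loop repetitions.
#'
#' @param trace a [breathing_trace()].
#' @param timestamps_s times in seconds.
#' @param cycles optional precomputed [detect_cycles()] result.
#' @return numeric phases in `[0, 100)`.
#' @export
assign_phase <- function(trace, timestamps_s, cycles = NULL) {
  cyc <- cycles %||% detect_cycles(trace)
  peaks <- cyc$peak_times_s
  periods <- cyc$periods_s
  if (trace$loop) {
    dur <- trace_duration(trace)
    n_rep <- max(0, ceiling((max(timestamps_s) - min(peaks)) / dur))
    reps <- 0:(n_rep + 1)
    seam <- dur - (max(peaks) - min(peaks))  # period across the loop seam
    peaks <- as.vector(outer(peaks, reps * dur, `+`))
    periods <- rep(c(periods, seam), length(reps))[seq_len(length(peaks) - 1)]
  }
  i <- findInterval(timestamps_s, peaks)
  phase <- numeric(length(timestamps_s))
  before <- i == 0
  after <- i >= length(peaks)
  mid <- !before & !after
  if (any(before))
    phase[before] <- (100 * (timestamps_s[before] - peaks[1]) / periods[1]) %% 100
  if (any(after))
    phase[after] <- (100 * (timestamps_s[after] - peaks[length(peaks)]) /
                       periods[length(periods)]) %% 100
  if (any(mid)) {
    im <- i[mid]
    phase[mid] <- 100 * (timestamps_s[mid] - peaks[im]) /
      (peaks[im + 1] - peaks[im])
  }
  phase %% 100
}

# Circular phase distance modulo 100 (phase 98 is 2 away from bin 0).
circular_phase_distance <- function(a, b) {
  d <- abs(a - b) %% 100
  pmin(d, 100 - d)
}

#' Select one image per nominal phase bin at a single couch station
#'
#' For each nominal bin center (0, 10, ..., 90 for 10% bins) the image with
#' the smallest circular phase distance is chosen; ties go to the earlier
#' timestamp. The residual distance is recorded — its maximum over a study is
#' the reconstruction phase error.
#'
#' @param phases image phases in `[0, 100)`.
#' @param timestamps_s image timestamps (for tie-breaking).
#' @param config a [binning_config()].
#' @return data.frame with `bin` (nominal phase), `index` (selected image),
#'   `residual` (circular distance, %), and `filled` (`FALSE` when
#'   `leave-gap` rejected a bin whose best residual exceeds half a bin).
#' @export
bin_station <- function(phases, timestamps_s, config = binning_config()) {
  if (!length(phases)) stop("cannot bin an empty station")
  bins <- seq(0, 100 - config$bin_width_percent, by = config$bin_width_percent)
  ord <- order(timestamps_s)
  out <- lapply(bins, function(b) {
    d <- circular_phase_distance(phases, b)
    best <- ord[which.min(d[ord])]  # earliest timestamp among minima
    data.frame(bin = b, index = best, residual = d[best],
               filled = config$missing_bin_policy == "nearest-fill" ||
                 d[best] <= config$bin_width_percent / 2)
  })
  do.call(rbind, out)
}

#' Assemble a phase-binned study from a cine acquisition
#'
#' Assigns a phase to every image, selects one image per station per nominal
#' bin ([bin_station()]), concatenates the chosen slabs in couch order into
#' one volume per phase, and computes the MIP (voxelwise maximum over
#' phases), Avg (voxelwise mean) and the reconstruction phase error (maximum
#' residual over all stations and bins). No pixel data are interpolated: each
#' station's slab in a phase volume is one acquired image.
#'
#' @param acq a [cine_acquisition()].
#' @param config a [binning_config()].
#' @param cycles optional precomputed [detect_cycles()] of the trace.
#' @return an object of class `phase_binned_study` with `phase_volumes` (a
#'   named list of [image_volume()]s, `"0%"` ... `"90%"`), `mip`, `avg`,
#'   `phase_error_percent` and a `provenance` data.frame (station, bin,
#'   chosen timestamp, phase, residual, ap offset, filled flag).
#' @export
assemble <- function(acq, config = binning_config(), cycles = NULL) {
  ts <- vapply(acq$images, `[[`, numeric(1), "timestamp_s")
  st <- vapply(acq$images, `[[`, integer(1), "station")
  ap <- vapply(acq$images, `[[`, numeric(1), "ap_offset_cm")
  phases <- assign_phase(acq$trace, ts, cycles)
  bins <- seq(0, 100 - config$bin_width_percent, by = config$bin_width_percent)
  g <- acq$grid
  spst <- acq$protocol$slices_per_station
  vols <- lapply(bins, function(b) array(NA_real_, dim = g$dim))
  names(vols) <- paste0(bins, "%")
  prov <- vector("list", acq$n_stations)
  for (k in seq_len(acq$n_stations)) {
    ik <- which(st == k)
    sel <- bin_station(phases[ik], ts[ik], config)
    sel$index <- ik[sel$index]
    zsel <- (k - 1) * spst + seq_len(spst)
    for (r in seq_len(nrow(sel))) {
      if (sel$filled[r])
        vols[[r]][, , zsel] <- acq$images[[sel$index[r]]]$slab
    }
    prov[[k]] <- data.frame(station = k, bin = sel$bin,
                            timestamp_s = ts[sel$index],
                            phase = phases[sel$index],
                            residual = sel$residual,
                            ap_offset_cm = ap[sel$index],
                            filled = sel$filled)
  }
  prov <- do.call(rbind, prov)
  mip <- Reduce(function(a, b) pmax(a, b, na.rm = TRUE), vols)
  acc <- array(0, dim = g$dim); cnt <- array(0, dim = g$dim)
  for (v in vols) {
    ok <- !is.na(v)
    acc[ok] <- acc[ok] + v[ok]
    cnt <- cnt + ok
  }
  avg <- acc / pmax(cnt, 1)
  if (any(cnt == 0)) {  # leave-gap can leave voxels with no filled bin
    bg <- min(mip[is.finite(mip)])
    mip[cnt == 0] <- bg
    avg[cnt == 0] <- bg
  }
  phase_volumes <- Map(function(v, lab) {
    v[is.na(v)] <- min(v, na.rm = TRUE)  # unfilled gaps shown as background
    image_volume(v, g, phase_label = lab)
  }, vols, names(vols))
  structure(list(phase_volumes = phase_volumes,
                 mip = image_volume(mip, g, phase_label = "MIP"),
                 avg = image_volume(avg, g, phase_label = "Avg"),
                 phase_error_percent = max(prov$residual),
                 provenance = prov, grid = g),
            class = "phase_binned_study")
}

#' @export
print.phase_binned_study <- function(x, ...) {
  cat(sprintf("<phase_binned_study> %d phase volumes + MIP + Avg, phase error %.2f%%\n",
              length(x$phase_volumes), x$phase_error_percent))
  invisible(x)
}

#' Write a phase-binned study to disk
#'
#' Serializes the ten phase volumes plus MIP and Avg as NIfTI files and the
#' provenance table (chosen timestamps, residuals, phase error) as JSON.
#'
#' @param study a [assemble()] result.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lab in names(study$phase_volumes))
    write_volume(study$phase_volumes[[lab]],
                 file.path(dir, paste0("phase_", sub("%", "", lab), ".nii.gz")))
  write_volume(study$mip, file.path(dir, "mip.nii.gz"))
  write_volume(study$avg, file.path(dir, "avg.nii.gz"))
  jsonlite::write_json(list(phase_error_percent = study$phase_error_percent,
                            provenance = study$provenance),
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
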