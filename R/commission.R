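#' Recommendation rule configuration
#'
#' @param washout_factor range-of-motion multiple of the object width above
#'   which gradient-phase reconstruction washes the object out (3 by
#'   default: objects whose RoM exceeds three times their width appear
#'   smaller than true size on the gradient phases).
#' @param gradient_phases the transitional phases (%), where the target moves
#'   fastest.
#' @param width_fidelity_tol_frac relative gradient-width error tolerated
#'   when judging a size reliably reconstructed (the package's
#'   operationalization of "reliable"; 20% by default).
#' @return an object of class `recommendation_config`.
#' @export
recommendation_config <- function(washout_factor = 3,
                                  gradient_phases = c(20, 30, 70, 80),
                                  width_fidelity_tol_frac = 0.2) {
  if (washout_factor <= 0) stop("washout_factor must be positive")
  if (width_fidelity_tol_frac < 0) stop("tolerance must be non-negative")
  structure(list(washout_factor = washout_factor,
                 gradient_phases = gradient_phases,
                 width_fidelity_tol_frac = width_fidelity_tol_frac),
            class = "recommendation_config")
}

#' Washout flag for a motion/size combination
#'
#' Flags a setting when the range of motion strictly exceeds
#' `washout_factor` times the object width. For flagged settings the
#' recommendation is to characterize the target's shape and size on the
#' exhale phase and project that contour onto the geometric center of each
#' gradient phase (the geometric center tends to persist in the image because
#' the target dwells there longest), then form the internal target by Boolean
#' union across phases ([build_internal_target()]).
#'
#' @param range_of_motion_cm peak-to-trough motion, cm (> 0).
#' @param object_width_cm true object width, cm (> 0).
#' @param config a [recommendation_config()].
#' @return list with `flagged` (logical) and `recommendation` (text).
#' @export
washout_flag <- function(range_of_motion_cm, object_width_cm,
                         config = recommendation_config()) {
  if (range_of_motion_cm <= 0 || object_width_cm <= 0)
    stop("range of motion and object width must be positive")
  flagged <- range_of_motion_cm > config$washout_factor * object_width_cm
  rec <- if (flagged) {
    paste0("Range of motion (", format(range_of_motion_cm), " cm) exceeds ",
           format(config$washout_factor), "x the object width (",
           format(object_width_cm), " cm): gradient-phase images are ",
           "unreliable. Characterize the target's shape and size on the ",
           "exhale (50%) phase and project it onto the geometric center of ",
           "each gradient phase; define the internal target by Boolean ",
           "union across all phases.")
  } else {
    "Range of motion within the washout threshold: phase images reconstruct the object reliably."
  }
  list(flagged = flagged, recommendation = rec)
}

#' Construct an internal target by Boolean union of translated exhale masks
#'
#' Translates the exhale-phase target mask so that its centroid sits at each
#' per-phase geometric center (nearest-voxel translation, no interpolation)
#' and returns the voxelwise union — the internal target volume (ITV) for
#' planning when gradient-phase shapes cannot be trusted.
#'
#' @param exhale_mask an [image_volume()] whose voxels are 0/1 (or logical).
#' @param per_phase_centroids matrix with one row per phase and columns
#'   x, y, z in cm: the target's geometric center on each phase.
#' @return an [image_volume()] of the 0/1 union mask.
#' @export
build_internal_target <- function(exhale_mask, per_phase_centroids) {
  g <- exhale_mask$grid
  m <- exhale_mask$voxels != 0
  if (!any(m)) stop("exhale mask is empty")
  cen <- as.matrix(per_phase_centroids)
  if (ncol(cen) != 3) stop("per_phase_centroids must have columns x, y, z")
  lo <- g$origin - g$spacing / 2
  hi <- g$origin + (g$dim - 0.5) * g$spacing
  if (any(t(cen) < lo) || any(t(cen) > hi))
    stop("phase centroid outside the grid")
  idx <- which(m, arr.ind = TRUE)
  c0 <- c(mean(grid_coords(g, 1)[idx[, 1]]),
          mean(grid_coords(g, 2)[idx[, 2]]),
          mean(grid_coords(g, 3)[idx[, 3]]))
  un <- array(FALSE, dim = g$dim)
  for (p in seq_len(nrow(cen))) {
    shift <- round((cen[p, ] - c0) / g$spacing)
    moved <- sweep(idx, 2, shift, `+`)
    if (any(moved < 1) || any(t(moved) > g$dim))
      stop("translated mask extends beyond the grid")
    un[moved] <- TRUE
  }
  image_volume(un * 1, g, phase_label = "ITV")
}

#' Commissioning run configuration
#'
#' Study conditions for [run_commissioning()]. Defaults reproduce the
#' commissioning procedure: sinusoids of 3/4/5 s periods crossed with
#' 0.5/1/2/3/4 cm ranges of motion for the rod, plus an irregular
#' patient-like trace applied to both rod and spheres; cine timing derived
#' from the period (period/10 between images, period + 1 duration) for
#' sinusoids and 0.4 s / 5 s for the patient trace; 2.5 mm cine slices with
#' 20 mm collimation and a 2 mm static reference scan.
#'
#' @param periods_s sinusoid periods, seconds.
#' @param roms_cm sinusoid ranges of motion, cm.
#' @param n_repeats seeded repeats per sinusoid setting (each with a fresh
#'   random start phase per scan); cells report the mean over repeats.
#' @param seed run-level RNG seed controlling all start phases and the
#'   patient trace.
#' @param rod a [rod_phantom()].
#' @param spheres a [sphere_phantom()] or `NULL` to skip the sphere study.
#' @param patient a [patient_trace_spec()] or `NULL` to skip patient-trace
#'   scans.
#' @param in_plane_cm in-plane voxel size, cm.
#' @param slice_cm cine slice thickness, cm.
#' @param static_slice_cm static reference slice thickness, cm.
#' @param collimation_cm cine collimation, cm.
#' @param station_dead_time_s couch step time, seconds.
#' @param integration_window_s 0 for snapshot imaging; > 0 averages geometry
#'   over that temporal aperture per image.
#' @param settings a [measurement_settings()].
#' @param binning a [binning_config()].
#' @param recommendation a [recommendation_config()].
#' @param supersample rasterization subsamples per axis.
#' @return an object of class `commissioning_config`.
#' @export
commissioning_config <- function(periods_s = c(3, 4, 5),
                                 roms_cm = c(0.5, 1, 2, 3, 4),
                                 n_repeats = 3L, seed = 1L,
                                 rod = rod_phantom(),
                                 spheres = sphere_phantom(),
                                 patient = patient_trace_spec(),
                                 in_plane_cm = 0.1, slice_cm = 0.25,
                                 static_slice_cm = 0.2, collimation_cm = 2.0,
                                 station_dead_time_s = 0.5,
                                 integration_window_s = 0,
                                 settings = measurement_settings(),
                                 binning = binning_config(),
                                 recommendation = recommendation_config(),
                                 supersample = 3L) {
  structure(list(periods_s = periods_s, roms_cm = roms_cm,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed),
                 rod = rod, spheres = spheres, patient = patient,
                 in_plane_cm = in_plane_cm, slice_cm = slice_cm,
                 static_slice_cm = static_slice_cm,
                 collimation_cm = collimation_cm,
                 station_dead_time_s = station_dead_time_s,
                 integration_window_s = integration_window_s,
                 settings = settings, binning = binning,
                 recommendation = recommendation,
                 supersample = as.integer(supersample)),
            class = "commissioning_config")
}

# Grid sized to hold the rod plus the largest AP motion, SI extent rounded
# up to a whole number of couch stations.
rod_grid <- function(config, slice_cm, max_rom_cm) {
  rod <- config$rod
  a <- rod$angle_deg * pi / 180
  half_ap <- rod$length_cm / 2 * sin(a) + rod$diameter_cm / 2 +
    max_rom_cm / 2 + 0.5
  half_si <- rod$length_cm / 2 * cos(a) + 0.4
  si <- ceiling(2 * half_si / config$collimation_cm) * config$collimation_cm
  lr <- 2 * (rod$diameter_cm / 2 + 0.5)
  grid_spec(c(lr, 2 * half_ap, si), in_plane_cm = config$in_plane_cm,
            slice_cm = slice_cm)
}

sphere_grid <- function(config, slice_cm, max_up_cm, max_down_cm) {
  sp <- config$spheres
  rmax <- max(sp$radii_cm)
  zlo <- min(sp$centers[, 3] - sp$radii_cm)
  zhi <- max(sp$centers[, 3] + sp$radii_cm)
  si <- ceiling((zhi - zlo + 1) / config$collimation_cm) * config$collimation_cm
  ap <- 2 * (rmax + max(max_up_cm, max_down_cm) + 0.5)
  lr <- 2 * (rmax + 0.5)
  grid_spec(c(lr, ap, si), in_plane_cm = config$in_plane_cm,
            slice_cm = slice_cm,
            center_cm = c(0, 0, (zlo + zhi) / 2))
}

# One rod 4DCT scan: acquire, bin, measure width/angle on MIP/Avg and the
# six reporting phases. Returns a one-row-per-label data.frame.
measure_rod_study <- function(study, config) {
  labels <- c("MIP", "Avg", "0%", "20%", "30%", "50%", "70%", "80%")
  vols <- c(list(MIP = study$mip, Avg = study$avg),
            study$phase_volumes[c("0%", "20%", "30%", "50%", "70%", "80%")])
  safely <- function(f) function(v)
    tryCatch(as.numeric(f(v, config$settings)), error = function(e) NA_real_)
  data.frame(label = labels,
             width_cm = vapply(vols, safely(apparent_rod_width), numeric(1)),
             angle_deg = vapply(vols, safely(apparent_rod_angle), numeric(1)))
}

run_rod_scan <- function(config, trace, protocol, grid, start_time_s, cycles) {
  acq <- acquire(config$rod, trace, protocol, grid,
                 start_time_s = start_time_s, supersample = config$supersample)
  study <- assemble(acq, config$binning, cycles = cycles)
  list(metrics = measure_rod_study(study, config),
       phase_error = study$phase_error_percent, study = study)
}

#' Run the full 4DCT commissioning procedure in silico
#'
#' Executes the static reference scan plus every sinusoid period x RoM
#' setting (each repeated `n_repeats` times with seeded random start phases)
#' and the patient-like trace for the rod; and the static scan plus the
#' patient-like trace for the sphere phantom. Builds the report tables
#' (apparent rod width and angle; sphere AP/LR diameters; contoured volumes
#' and equivalent diameters — each over MIP, Avg, inhale, exhale and the
#' gradient-phase mean +- sd), records per-scan reconstruction phase errors,
#' applies the washout rule to every setting, and derives the minimum
#' reliably reconstructed target size.
#'
#' @param config a [commissioning_config()].
#' @return an object of class `commissioning_report`.
#' @export
run_commissioning <- function(config = commissioning_config()) {
  stopifnot(inherits(config, "commissioning_config"))
  with_seed(config$seed, {
    grad <- config$recommendation$gradient_phases
    grad_lab <- paste0(grad, "%")
    max_rom <- max(config$roms_cm,
                   if (!is.null(config$patient))
                     config$patient$max_up_cm + config$patient$max_down_cm else 0)

    ## ---- rod: static reference ------------------------------------------
    g_static <- rod_grid(config, config$static_slice_cm, max_rom)
    rod_static <- acquire_static(config$rod, g_static,
                                 supersample = config$supersample)
    static_width <- as.numeric(apparent_rod_width(rod_static, config$settings))
    static_angle <- apparent_rod_angle(rod_static, config$settings)

    ## ---- rod: 15 sinusoid settings --------------------------------------
    g_cine <- rod_grid(config, config$slice_cm, max_rom)
    n_st <- g_cine$dim[3] %/% (config$collimation_cm / config$slice_cm)
    settings_tab <- expand.grid(rom_cm = config$roms_cm,
                                period_s = config$periods_s)[, c(2, 1)]
    width_rows <- list(); angle_rows <- list(); perr_rows <- list()
    for (i in seq_len(nrow(settings_tab))) {
      T_s <- settings_tab$period_s[i]
      rom <- settings_tab$rom_cm[i]
      protocol <- cine_protocol_for_period(
        T_s, slice_thickness_cm = config$slice_cm,
        collimation_cm = config$collimation_cm,
        station_dead_time_s = config$station_dead_time_s,
        integration_mode = if (config$integration_window_s > 0) "windowed" else "snapshot",
        integration_window_s = config$integration_window_s)
      scan_len <- n_st * (protocol$cine_duration_s + protocol$station_dead_time_s)
      reps <- vector("list", config$n_repeats)
      perr <- numeric(config$n_repeats)
      for (r in seq_len(config$n_repeats)) {
        start <- 3 * T_s + runif(1, 0, T_s)  # post-gate start, random phase
        trace <- make_sinusoid(T_s, rom, duration_s = start + scan_len + 2 * T_s)
        cycles <- detect_cycles(trace)
        if (abs(cycles$mean_period_s - T_s) > 0.1)
          stop("period gate failed: measured period deviates by more than 0.1 s")
        scan <- run_rod_scan(config, trace, protocol, g_cine, start, cycles)
        reps[[r]] <- scan$metrics
        perr[r] <- scan$phase_error
      }
      agg <- reps[[1]]
      if (config$n_repeats > 1)
        for (col in c("width_cm", "angle_deg"))
          agg[[col]] <- rowMeans(sapply(reps, `[[`, col))
      width_rows[[i]] <- summarize_rod_row(agg, "width_cm", T_s, rom, grad_lab)
      angle_rows[[i]] <- summarize_rod_row(agg, "angle_deg", T_s, rom, grad_lab)
      perr_rows[[i]] <- data.frame(scan = sprintf("rod sinusoid T=%gs RoM=%gcm", T_s, rom),
                                   phase_error_percent = max(perr))
    }

    ## ---- rod: patient-like trace ----------------------------------------
    patient_rows <- NULL
    if (!is.null(config$patient)) {
      trace_p <- make_patient_like(config$patient)
      cycles_p <- detect_cycles(trace_p)
      protocol_p <- cine_protocol(
        0.4, 5, slice_thickness_cm = config$slice_cm,
        collimation_cm = config$collimation_cm,
        station_dead_time_s = config$station_dead_time_s,
        integration_mode = if (config$integration_window_s > 0) "windowed" else "snapshot",
        integration_window_s = config$integration_window_s)
      start_p <- 5 + runif(1, 0, cycles_p$mean_period_s)
      scan_p <- run_rod_scan(config, trace_p, protocol_p, g_cine, start_p, cycles_p)
      rom_p <- config$patient$max_up_cm + config$patient$max_down_cm
      width_rows[[length(width_rows) + 1]] <-
        summarize_rod_row(scan_p$metrics, "width_cm", NA, rom_p, grad_lab,
                          setting = "breathing trace")
      angle_rows[[length(angle_rows) + 1]] <-
        summarize_rod_row(scan_p$metrics, "angle_deg", NA, rom_p, grad_lab,
                          setting = "breathing trace")
      perr_rows[[length(perr_rows) + 1]] <-
        data.frame(scan = "rod breathing trace",
                   phase_error_percent = scan_p$phase_error)
    }
    rod_width_table <- do.call(rbind, width_rows)
    rod_angle_table <- do.call(rbind, angle_rows)

    ## ---- spheres: static + patient-like trace ---------------------------
    sphere_diameter_table <- NULL
    sphere_volume_table <- NULL
    if (!is.null(config$spheres) && !is.null(config$patient)) {
      sp <- config$spheres
      trace_p <- make_patient_like(config$patient)
      cycles_p <- detect_cycles(trace_p)
      g_sp_static <- sphere_grid(config, config$static_slice_cm,
                                 config$patient$max_up_cm, config$patient$max_down_cm)
      sp_static <- acquire_static(sp, g_sp_static, supersample = config$supersample)
      g_sp <- sphere_grid(config, config$slice_cm,
                          config$patient$max_up_cm, config$patient$max_down_cm)
      protocol_p <- cine_protocol(
        0.4, 5, slice_thickness_cm = config$slice_cm,
        collimation_cm = config$collimation_cm,
        station_dead_time_s = config$station_dead_time_s)
      start_sp <- 5 + runif(1, 0, cycles_p$mean_period_s)
      acq_sp <- acquire(sp, trace_p, protocol_p, g_sp, start_time_s = start_sp,
                        supersample = config$supersample)
      study_sp <- assemble(acq_sp, config$binning, cycles = cycles_p)
      perr_rows[[length(perr_rows) + 1]] <-
        data.frame(scan = "spheres breathing trace",
                   phase_error_percent = study_sp$phase_error_percent)
      sphere_tabs <- measure_sphere_study(sp, sp_static, study_sp, config, grad_lab)
      sphere_diameter_table <- sphere_tabs$diameters
      sphere_volume_table <- sphere_tabs$volumes
    }

    phase_errors <- do.call(rbind, perr_rows)

    ## ---- flags, minimum size, recommendations ---------------------------
    flag_tab <- rod_width_table[, c("period_s", "rom_cm")]
    flag_tab$object <- "rod"
    flag_tab$object_width_cm <- config$rod$diameter_cm
    if (!is.null(sphere_diameter_table)) {
      rom_p <- config$patient$max_up_cm + config$patient$max_down_cm
      flag_tab <- rbind(flag_tab,
                        data.frame(period_s = NA,
                                   rom_cm = rom_p,
                                   object = paste0("sphere ", config$spheres$diameters_cm, "cm"),
                                   object_width_cm = config$spheres$diameters_cm))
    }
    fl <- lapply(seq_len(nrow(flag_tab)), function(i)
      washout_flag(flag_tab$rom_cm[i], flag_tab$object_width_cm[i],
                   config$recommendation))
    flag_tab$flagged <- vapply(fl, `[[`, logical(1), "flagged")

    report <- structure(list(rod_width_table = rod_width_table,
                             rod_angle_table = rod_angle_table,
                             sphere_diameter_table = sphere_diameter_table,
                             sphere_volume_table = sphere_volume_table,
                             phase_errors = phase_errors,
                             static_rod_width_cm = static_width,
                             static_rod_angle_deg = static_angle,
                             flags = flag_tab,
                             config = config),
                        class = "commissioning_report")
    report$minimum_reliable_size_cm <- minimum_target_size(report,
                                                           config$recommendation)
    report$recommendations <- report_recommendations(report, config)
    report
  })
}

# Aggregate one scan's per-label metrics into a report row with the gradient
# mean +- sd column.
summarize_rod_row <- function(metrics, col, period_s, rom_cm, grad_lab,
                              setting = NULL) {
  v <- function(lab) metrics[[col]][metrics$label == lab]
  gvals <- metrics[[col]][metrics$label %in% grad_lab]
  data.frame(setting = setting %||% sprintf("T=%gs", period_s),
             period_s = period_s, rom_cm = rom_cm,
             mip = v("MIP"), avg = v("Avg"),
             inhale = v("0%"), exhale = v("50%"),
             gradient_mean = mean(gvals, na.rm = TRUE),
             gradient_sd = sd(gvals, na.rm = TRUE))
}

# Sphere metrology over static + reconstructed volumes: AP/LR diameters on
# the central slice, auto-threshold contour volume and equivalent diameter,
# each per sphere per reconstruction label.
measure_sphere_study <- function(sp, sp_static, study, config, grad_lab) {
  labels <- c("Static", "MIP", "Avg", "0%", "20%", "30%", "50%", "70%", "80%")
  vols <- c(list(Static = sp_static, MIP = study$mip, Avg = study$avg),
            study$phase_volumes[c("0%", "20%", "30%", "50%", "70%", "80%")])
  n_sp <- length(sp$radii_cm)
  half_gap <- 0.49 * min(diff(sort(sp$centers[, 3])) -
                           (sp$radii_cm[-n_sp] + sp$radii_cm[-1]))
  rows_d <- list(); rows_v <- list()
  for (i in seq_len(n_sp)) {
    ctr <- sp$centers[i, ]
    zlim <- c(ctr[3] - sp$radii_cm[i] - half_gap, ctr[3] + sp$radii_cm[i] + half_gap)
    per_label <- lapply(vols, function(v) tryCatch({
      sub <- crop_volume(v, zlim = zlim)
      # center from the supra-threshold centroid: motion displaces the
      # sphere, so the static center cannot be assumed
      d <- sphere_diameters(sub, settings = config$settings)
      m <- threshold_contour_metrics(sub, config$settings)
      c(ap = unname(d["ap_cm"]), lr = unname(d["lr_cm"]),
        vol = m$volume_cc, eqd = m$equivalent_diameter_cm)
    }, error = function(e) c(ap = NA_real_, lr = NA_real_,
                             vol = NA_real_, eqd = NA_real_)))
    get <- function(field) vapply(per_label, `[[`, numeric(1), field)
    gmean <- function(x) mean(x[names(vols) %in% grad_lab], na.rm = TRUE)
    gsd <- function(x) sd(x[names(vols) %in% grad_lab], na.rm = TRUE)
    mk_row <- function(x, what) data.frame(
      quantity = what, diameter_cm = sp$diameters_cm[i],
      static = x[["Static"]], mip = x[["MIP"]], avg = x[["Avg"]],
      inhale = x[["0%"]], exhale = x[["50%"]],
      gradient_mean = gmean(x), gradient_sd = gsd(x))
    rows_d[[length(rows_d) + 1]] <- mk_row(get("ap"), "AP diameter (cm)")
    rows_d[[length(rows_d) + 1]] <- mk_row(get("lr"), "LR diameter (cm)")
    rows_v[[length(rows_v) + 1]] <- mk_row(get("vol"), "Volume (cc)")
    rows_v[[length(rows_v) + 1]] <- mk_row(get("eqd"), "Equivalent diameter (cm)")
  }
  list(diameters = do.call(rbind, rows_d), volumes = do.call(rbind, rows_v))
}

#' Minimum reliably reconstructed target size
#'
#' For each tested object width, considers every tested setting whose range
#' of motion does not exceed `washout_factor` times that width, and requires
#' the gradient-phase size estimate to stay within
#' `width_fidelity_tol_frac` of the true width in all of them. Returns the
#' smallest qualifying width (`NA` if none qualifies). This decision rule is
#' the package's operationalization of "reliably reconstructed" and is
#' reported alongside the raw tables, never in place of them.
#'
#' @param report a [run_commissioning()] result (or any list with a
#'   `rod_width_table`, optionally a `sphere_diameter_table`, and a `config`
#'   carrying the phantom specs).
#' @param config a [recommendation_config()].
#' @return smallest reliable width in cm, or `NA_real_`.
#' @export
minimum_target_size <- function(report, config = recommendation_config()) {
  rows <- data.frame(width = numeric(0), rom = numeric(0), gradient = numeric(0))
  if (!is.null(report$rod_width_table)) {
    w <- report$config$rod$diameter_cm
    rows <- rbind(rows, data.frame(width = w,
                                   rom = report$rod_width_table$rom_cm,
                                   gradient = report$rod_width_table$gradient_mean))
  }
  if (!is.null(report$sphere_diameter_table)) {
    ap <- report$sphere_diameter_table[
      report$sphere_diameter_table$quantity == "AP diameter (cm)", ]
    rom_p <- report$config$patient$max_up_cm + report$config$patient$max_down_cm
    rows <- rbind(rows, data.frame(width = ap$diameter_cm, rom = rom_p,
                                   gradient = ap$gradient_mean))
  }
  if (!nrow(rows)) return(NA_real_)
  qualifies <- vapply(sort(unique(rows$width)), function(w) {
    rel <- rows[rows$width == w & rows$rom <= config$washout_factor * w, ]
    if (!nrow(rel)) return(TRUE)  # nothing tested can distort it
    all(abs(rel$gradient - w) / w <= config$width_fidelity_tol_frac)
  }, logical(1))
  ok <- sort(unique(rows$width))[qualifies]
  if (length(ok)) min(ok) else NA_real_
}

report_recommendations <- function(report, config) {
  n_flag <- sum(report$flags$flagged)
  msize <- report$minimum_reliable_size_cm
  c(sprintf("Static reference: apparent rod width %.3f cm, angle %.2f deg.",
            report$static_rod_width_cm, report$static_rod_angle_deg),
    sprintf("Maximum reconstruction phase error across scans: %.2f%%.",
            max(report$phase_errors$phase_error_percent)),
    if (n_flag > 0)
      sprintf(paste0("%d setting(s) exceed the %gx-width washout threshold: for such ",
                     "targets, contour shape and size on the exhale (50%%) phase, ",
                     "project onto each gradient phase's geometric center, and form ",
                     "the internal target by Boolean union across phases."),
              n_flag, config$recommendation$washout_factor)
    else "No setting exceeds the washout threshold.",
    if (is.na(msize))
      "Minimum reliable target size: not determined (no tested size qualifies)."
    else
      sprintf(paste0("Minimum reliable target size (gradient width within %.0f%% of ",
                     "truth for all settings with RoM <= %gx width): %.3f cm."),
              100 * config$recommendation$width_fidelity_tol_frac,
              config$recommendation$washout_factor, msize))
}

#' @export
print.commissioning_report <- function(x, ...) {
  cat("<commissioning_report>\n")
  cat(sprintf("  rod width rows: %d | rod angle rows: %d\n",
              nrow(x$rod_width_table), nrow(x$rod_angle_table)))
  if (!is.null(x$sphere_diameter_table))
    cat(sprintf("  sphere diameter rows: %d | volume rows: %d\n",
                nrow(x$sphere_diameter_table), nrow(x$sphere_volume_table)))
  cat(sprintf("  max phase error: %.2f%% | min reliable size: %s cm\n",
              max(x$phase_errors$phase_error_percent),
              format(x$minimum_reliable_size_cm)))
  for (r in x$recommendations) cat("  -", r, "\n")
  invisible(x)
}

#' Write a commissioning report to disk
#'
#' Emits `report.json` (tables, flags, phase errors, recommendations) and one
#' CSV per table.
#'
#' @param report a [run_commissioning()] result.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("rod_width_table", "rod_angle_table", "sphere_diameter_table",
            "sphere_volume_table", "phase_errors", "flags")
  for (tb in tabs)
    if (!is.null(report[[tb]]))
      write.csv(report[[tb]], file.path(dir, paste0(tb, ".csv")),
                row.names = FALSE)
  payload <- report[c(tabs[!vapply(report[tabs], is.null, logical(1))],
                      "static_rod_width_cm", "static_rod_angle_deg",
                      "minimum_reliable_size_cm", "recommendations")]
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
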