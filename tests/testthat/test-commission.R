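test_that("washout flags trip strictly above the factor-times-width threshold", {
  w <- 0.635
  expect_true(washout_flag(4, w)$flagged)
  expect_false(washout_flag(0.5, w)$flagged)
  expect_false(washout_flag(3 * w, w)$flagged)       # boundary: strict
  expect_true(washout_flag(3 * w + 1e-6, w)$flagged)
  expect_match(washout_flag(4, w)$recommendation, "exhale")
  expect_error(washout_flag(-1, w), "positive")
})

test_that("internal targets are Boolean unions of translated exhale masks", {
  g <- grid_spec(c(3, 6, 3), in_plane_cm = 0.1, slice_cm = 0.1)
  vox <- array(0, g$dim)
  vox[10:20, 20:29, 10:20] <- 1     # 1 cm cube, AP extent 0.9 (centers)
  mask <- image_volume(vox, g)
  same <- build_internal_target(mask, rbind(c(0, -0.55, 0), c(0, -0.55, 0)))
  expect_equal(same$voxels, vox)    # identical centroids reproduce the mask
  # two centroids separated by dy: union AP extent = mask extent + dy
  cen <- rbind(c(0, -0.55, 0), c(0, 0.45, 0))
  un <- build_internal_target(mask, cen)
  ap_extent <- function(v) {
    iy <- which(apply(v$voxels != 0, 2, any))
    grid_coords(v$grid, 2)[max(iy)] - grid_coords(v$grid, 2)[min(iy)]
  }
  expect_equal(ap_extent(un), ap_extent(mask) + 1.0, tolerance = 1e-9)
  expect_gte(sum(un$voxels), sum(vox))
  expect_error(build_internal_target(mask, rbind(c(0, 10, 0))), "outside")
})

test_that("minimum target size applies the gradient-fidelity rule per object", {
  # constructed report: rod washes out at large RoM, spheres hold their size
  report <- list(
    rod_width_table = data.frame(
      rom_cm = c(0.5, 1, 2, 3, 4),
      gradient_mean = c(0.64, 0.58, 0.46, 0.36, 0.29)),
    sphere_diameter_table = data.frame(
      quantity = rep("AP diameter (cm)", 4),
      diameter_cm = c(1, 2, 3, 4),
      gradient_mean = c(1.66, 2.70, 3.41, 4.48)),
    config = list(rod = list(diameter_cm = 0.635),
                  patient = list(max_up_cm = 1.28, max_down_cm = 1.62)))
  cfg <- recommendation_config()
  # rod: only RoM 0.5 and 1 fall below 3 x 0.635 = 1.905 cm; their gradient
  # widths (0.64, 0.58) are within 20% of 0.635, so the rod itself qualifies
  # even though it washes out at larger RoM
  expect_equal(minimum_target_size(report, cfg), 0.635)
  # without the rod, the 1 and 2 cm spheres fail (66% and 35% gradient
  # error at RoM 2.9 cm) and the 3 cm sphere (13.7%) is the smallest pass
  no_rod <- report[c("sphere_diameter_table", "config")]
  expect_equal(minimum_target_size(no_rod, recommendation_config(
    width_fidelity_tol_frac = 0.15)), 3)
  vacuous <- recommendation_config(width_fidelity_tol_frac = 1)
  expect_equal(minimum_target_size(report, vacuous), 0.635)
  nothing <- recommendation_config(width_fidelity_tol_frac = 0)
  expect_true(is.na(minimum_target_size(report, nothing)))
})

test_that("a reduced commissioning run fills every report cell", {
  rep <- run_commissioning(commissioning_config(
    periods_s = 4, roms_cm = c(1, 2), n_repeats = 1, seed = 5,
    rod = rod_phantom(length_cm = 6),
    spheres = sphere_phantom(diameters_cm = c(2, 3), gap_cm = 1.5),
    patient = patient_trace_spec(duration_s = 60, n_cycles = 17, seed = 5)))
  expect_s3_class(rep, "commissioning_report")
  expect_equal(nrow(rep$rod_width_table), 3)   # 2 sinusoid + breathing trace
  expect_false(anyNA(rep$rod_width_table[, c("mip", "avg", "inhale", "exhale",
                                             "gradient_mean")]))
  expect_equal(nrow(rep$rod_angle_table), 3)
  expect_equal(nrow(rep$sphere_diameter_table), 4)  # AP + LR per sphere
  expect_equal(nrow(rep$sphere_volume_table), 4)
  expect_false(anyNA(rep$sphere_diameter_table$gradient_mean))
  expect_true(all(c("rod sinusoid T=4s RoM=1cm", "rod breathing trace",
                    "spheres breathing trace") %in% rep$phase_errors$scan))
  expect_gt(length(rep$recommendations), 2)
  expect_true(any(rep$flags$flagged))  # RoM 2.9 cm vs the 0.635 cm rod
  expect_output(print(rep), "commissioning_report")
  # washout rule wiring: the flagged rows are exactly RoM > 3 x width
  with(rep$flags, expect_equal(flagged, rom_cm > 3 * object_width_cm))
})

test_that("report serialization writes tables and JSON", {
  dir <- withr::local_tempdir()
  rep <- list(rod_width_table = data.frame(rom_cm = 1, mip = 1.3),
              phase_errors = data.frame(scan = "x", phase_error_percent = 3),
              static_rod_width_cm = 0.59, static_rod_angle_deg = 26,
              minimum_reliable_size_cm = 0.635,
              recommendations = "ok")
  class(rep) <- "commissioning_report"
  write_report(rep, dir)
  expect_true(file.exists(file.path(dir, "rod_width_table.csv")))
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(js$static_rod_width_cm, 0.59)
})

test_that("YAML configuration round-trips into a commissioning_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("run:",
               "  periods_s: [3, 5]",
               "  roms_cm: [1, 2]",
               "  n_repeats: 2",
               "  seed: 9",
               "phantom:",
               "  rod: {diameter_cm: 1.0, angle_deg: 30}",
               "  spheres: no",
               "traces:",
               "  patient: {n_cycles: 20, duration_s: 80, seed: 9}",
               "recommendation:",
               "  washout_factor: 2.5"), path)
  cfg <- read_commissioning_config(path)
  expect_equal(cfg$periods_s, c(3, 5))
  expect_equal(cfg$rod$diameter_cm, 1.0)
  expect_null(cfg$spheres)
  expect_equal(cfg$patient$n_cycles, 20)
  expect_equal(cfg$recommendation$washout_factor, 2.5)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("phantom:", "  rod: {diamter_cm: 1.0}"), bad)
  expect_error(read_commissioning_config(bad), "unknown config key")
})
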