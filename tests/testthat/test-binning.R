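test_that("phase assignment anchors inhale peaks at 0% and troughs at 50%", {
  tr <- make_sinusoid(4, 2, duration_s = 30)
  cy <- detect_cycles(tr)
  peaks <- cy$peak_times_s
  expect_true(all(assign_phase(tr, peaks, cy) < 0.2 |
                    assign_phase(tr, peaks, cy) > 99.8))
  troughs <- peaks[-length(peaks)] + cy$periods_s / 2
  expect_equal(assign_phase(tr, troughs, cy), rep(50, length(troughs)),
               tolerance = 0.01)
  # linearity: timestamps advancing by period/10 advance phase by 10%
  ts <- peaks[2] + 0.4 * (0:9)
  dph <- diff(assign_phase(tr, ts, cy)) %% 100
  expect_equal(dph, rep(10, 9), tolerance = 0.1)
})

test_that("bin selection minimizes circular phase distance with earlier-time ties", {
  cfg <- binning_config()
  sel <- bin_station(phases = c(98, 12, 55), timestamps_s = c(0, 1, 2), cfg)
  expect_equal(sel$index[sel$bin == 0], 1)     # 98 is 2 away from 0, 12 is 12
  expect_equal(sel$residual[sel$bin == 0], 2)
  expect_equal(sel$index[sel$bin == 50], 3)
  # ties break to the earlier timestamp: 15 and 5 are both 5 away from 10
  tie <- bin_station(phases = c(15, 5), timestamps_s = c(3, 7), cfg)
  expect_equal(tie$index[tie$bin == 10], 1)
  tie2 <- bin_station(phases = c(15, 5), timestamps_s = c(7, 3), cfg)
  expect_equal(tie2$index[tie2$bin == 10], 2)
  expect_error(bin_station(numeric(0), numeric(0), cfg), "empty")
})

test_that("phases sampled on the bin grid give zero residual; offsets stay within half a bin", {
  cfg <- binning_config()
  exact <- bin_station(phases = seq(0, 90, 10), timestamps_s = 1:10, cfg)
  expect_equal(exact$residual, rep(0, 10))
  off <- bin_station(phases = (seq(0, 90, 10) + 3.7) %% 100,
                     timestamps_s = 1:10, cfg)
  expect_equal(off$residual, rep(3.7, 10), tolerance = 1e-9)
  expect_true(all(off$residual <= 5))
})

test_that("a single image fills every bin under nearest-fill and is flagged under leave-gap", {
  near <- bin_station(phases = 37, timestamps_s = 0, binning_config())
  expect_true(all(near$index == 1) && all(near$filled))
  gap <- bin_station(phases = 37, timestamps_s = 0,
                     binning_config(missing_bin_policy = "leave-gap"))
  expect_identical(sum(gap$filled), 1L)  # only the 40% bin is within 5%
})

test_that("assembled studies preserve acquired pixel data and satisfy MIP/Avg bounds", {
  st <- small_study()$study
  acq <- small_study()$acq
  expect_length(st$phase_volumes, 10)
  # conservation: each station slab in a phase volume is an acquired image
  prov <- st$provenance
  row <- prov[prov$station == 2 & prov$bin == 50, ]
  img <- Filter(function(im) im$station == 2 &&
                  abs(im$timestamp_s - row$timestamp_s) < 1e-9, acq$images)[[1]]
  expect_identical(st$phase_volumes[["50%"]]$voxels[, , 9:16], img$slab)
  # MIP dominates every phase; Avg lies within the voxelwise envelope
  vmin <- Reduce(pmin, lapply(st$phase_volumes, `[[`, "voxels"))
  vmax <- Reduce(pmax, lapply(st$phase_volumes, `[[`, "voxels"))
  for (pv in st$phase_volumes)
    expect_true(all(st$mip$voxels >= pv$voxels - 1e-12))
  expect_true(all(st$avg$voxels >= vmin - 1e-12 &
                    st$avg$voxels <= vmax + 1e-12))
  # 5% bound up to the sub-sample precision of refined peak times
  expect_lte(st$phase_error_percent, 5 + 0.01)
})

test_that("zero motion collapses all phases, MIP and Avg to the static volume", {
  values <- make_sinusoid(4, 1, duration_s = 40)$values
  still <- breathing_trace(values, up_scale_cm = 0, down_scale_cm = 0)
  ph <- rod_phantom(length_cm = 5)
  g <- grid_spec(c(2, 6, 4), in_plane_cm = 0.1, slice_cm = 0.25)
  acq <- acquire(ph, still, cine_protocol_for_period(4), g, start_time_s = 8)
  st <- assemble(acq)
  for (pv in st$phase_volumes) expect_identical(pv$voxels, st$mip$voxels)
  expect_equal(st$avg$voxels, st$mip$voxels, tolerance = 1e-12)
})

test_that("bin width must divide 100", {
  expect_error(binning_config(bin_width_percent = 7), "divisible")
  expect_length(bin_station(1:10 * 7 %% 100, 1:10,
                            binning_config(bin_width_percent = 20))$bin, 5)
})
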