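# Expensive simulation products shared across test files, computed once per
# test session. The commissioning run uses the package defaults (the study
# conditions) under a fixed seed.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache))
    assign(key, expr, envir = .run_cache)
  get(key, envir = .run_cache)
}

# Full default commissioning run: 15 sinusoid settings x 3 repeats plus the
# patient-like trace for the rod, and static + patient-like for the spheres.
full_report <- function() {
  cached("full_report", run_commissioning(commissioning_config(seed = 101L)))
}

# One representative 4DCT study (4 s period, 2 cm RoM) kept with its
# acquisition for voxel-level properties.
small_study <- function() {
  cached("small_study", {
    protocol <- cine_protocol_for_period(4)
    grid <- grid_spec(c(2, 10, 8), in_plane_cm = 0.1, slice_cm = 0.25)
    trace <- make_sinusoid(4, 2, duration_s = 60)
    acq <- acquire(rod_phantom(length_cm = 7), trace, protocol, grid,
                   start_time_s = 13.1)
    list(acq = acq, study = assemble(acq))
  })
}

# Static rod reference at the default metrology geometry (1 mm in-plane,
# 2 mm slices).
static_rod <- function() {
  cached("static_rod", {
    grid <- grid_spec(c(2, 10, 10), in_plane_cm = 0.1, slice_cm = 0.2)
    acquire_static(rod_phantom(), grid)
  })
}
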