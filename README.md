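# virtual4dct

In-silico commissioning of 4DCT phase-binning reconstruction for small moving
targets.

## The problem

Four-dimensional CT (4DCT) images a free-breathing patient by repeatedly
scanning each couch position in cine mode and sorting the images into breathing
*phase* bins (inhale = 0%, exhale = 50%, 10% bins). Phase binning always yields
complete image sets, but moving objects acquire reconstruction artifacts:
apparent widths shrink or grow, angles tilt, and small targets can *wash out*
of the transitional ("gradient") phases entirely. For lung SBRT — small, highly
mobile tumors treated with few high-dose fractions — a geometric miss caused by
an unreliable reconstruction is a serious failure mode, and anterior–posterior
(AP) motion artifacts in particular are rarely characterized during scanner
commissioning.

`virtual4dct` reproduces a physical commissioning procedure entirely in
software, for medical physicists who want to study, teach, or prototype the
procedure before (or alongside) running it on a real scanner:

- **breathing traces** — sinusoids (periods 3/4/5 s, ranges of motion
  0.5–4 cm) and an irregular patient-like generator (153 s loop, 43 cycles,
  +1.28/−1.62 cm excursions, period jitter, stutter/cough bursts), using the
  motion platform's 0–2 displacement encoding at 30 ms steps;
- **digital phantoms** — a 6.35 mm rod angled at 26.0° to the couch, and
  1–4 cm spheres in lung-equivalent material, voxelized with supersampled
  partial-volume occupancy;
- **a virtual cine scanner** — per-couch-station repeated slab imaging
  (2.5 mm slices, 20 mm collimation), cine interval = period/10, cine
  duration = period + 1 s, timestamps tied to the trace;
- **phase binning** — RPM-style peak-to-peak phase assignment, nearest-phase
  image selection per 10% bin, phase-volume assembly, MIP and Avg composites,
  and the reconstruction phase error;
- **artifact metrology** — apparent rod width (perpendicular to the fitted
  axis) and angle, sphere AP/LR diameters, auto-threshold (−500..2000 HU)
  contour volume and equivalent diameter `(6V/π)^{1/3}`, at the fixed
  display settings (window 300 / level −500);
- **commissioning** — the full 15-setting sinusoid study plus the patient
  trace, report tables, washout flagging (range of motion > 3× object
  width), a minimum-reliable-target-size rule, and internal-target
  construction by Boolean union of translated exhale contours.

## Worked example

```r
library(virtual4dct)

# motion-free reference scan of the angled rod (1 mm in-plane, 2 mm slices)
grid_2mm <- grid_spec(c(2, 10, 10), in_plane_cm = 0.1, slice_cm = 0.2)
static <- acquire_static(rod_phantom(), grid_2mm)
round(c(width_cm = as.numeric(apparent_rod_width(static)),
        angle_deg = apparent_rod_angle(static)), 3)
#>  width_cm angle_deg
#>     0.592    25.952

# one 4DCT scan: 4 s sinusoid, 2 cm range of motion
trace <- make_sinusoid(period_s = 4, range_of_motion_cm = 2, duration_s = 60)
protocol <- cine_protocol_for_period(4)   # 0.4 s between images, 5 s per station
grid_4d <- grid_spec(c(2, 10, 10), in_plane_cm = 0.1, slice_cm = 0.25)
acq <- acquire(rod_phantom(), trace, protocol, grid_4d, start_time_s = 13)
study <- assemble(acq)
study
#> <phase_binned_study> 10 phase volumes + MIP + Avg, phase error 5.00%
round(c(inhale = as.numeric(apparent_rod_width(study$phase_volumes[["0%"]])),
        exhale = as.numeric(apparent_rod_width(study$phase_volumes[["50%"]])),
        mip = as.numeric(apparent_rod_width(study$mip)),
        avg = as.numeric(apparent_rod_width(study$avg))), 3)
#> inhale exhale    mip    avg
#>  0.602  0.602  2.370  2.002
```

Reading the numbers: the static scan recovers the manufactured 0.635 cm /
26.0° rod to within one in-plane pixel and half a degree. Under a 2 cm AP
motion the inhale and exhale phases still read the true width (each selected
image is a near-motionless snapshot at a turning point of the cycle), while
the MIP width grows to roughly rod width + range of motion (the envelope of
all rod positions) and the Avg lies in between. The phase error is the
largest distance between any selected image's breathing phase and its
nominal bin — at most half a bin (5%) when each station's cine window covers
a full cycle.

The full procedure is one call:

```r
report <- run_commissioning(commissioning_config(seed = 1))
report$rod_width_table      # 15 sinusoid rows + breathing-trace row
report$recommendations
write_report(report, "commissioning_out")
```

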