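---
title: "Virtual 4DCT commissioning: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual 4DCT commissioning: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virtual4dct)
```

`virtual4dct` simulates, end to end, a procedure for commissioning the
phase-binning reconstruction of a 4DCT system against anterior–posterior (AP)
respiratory motion: known objects (an angled rod, lung-embedded spheres) are
moved with known breathing patterns, imaged with a cine protocol, binned into
phases, and measured; the difference between measured and manufactured
geometry quantifies the reconstruction artifact as a function of breathing
period and range of motion (RoM). This vignette documents the models behind
each stage, the parameters that matter, and the choices made where the design
was genuinely open. It states no result that the package's tests and
acceptance script do not themselves compute.

## Breathing traces

Traces use the motion platform's encoding: scaled values in $[0, 2]$ sampled
every 30 ms, with 0/1/2 the minimum/home/maximum vertical positions and a
hard ±4 cm platform travel limit. Physical displacement is a *piecewise*
linear map about home — value $v \ge 1$ maps to $(v-1)\,u$ and $v < 1$ to
$(v-1)\,d$, with $u$ and $d$ the up/down scales in cm. A single linear factor
cannot map 0/1/2 onto asymmetric excursions such as $-1.62/0/+1.28$ cm while
keeping home at value 1, which is why the map is piecewise; for symmetric
sinusoids $u = d = \mathrm{RoM}/2$ and the map is linear.

Sinusoids are sampled then full-range normalized so every generated trace
attains 0 and 2 exactly, even when the 30 ms grid misses an analytic
extremum (a 5 s period puts peaks between samples).

The irregular generator emulates a recorded lung-SBRT breathing pattern known
only through summary statistics: 153 s loop, 43 cycles, $+1.28$ cm maximum,
$-1.62$ cm minimum (2.90 cm peak-to-trough), varied periods, occasional
stutters. The mechanism: per-cycle periods jittered by ±12% (uniform) and
rescaled to sum exactly to the loop duration; each cycle is a
$P_i \sin^4(\pi s)$ pulse ($s$ the within-cycle fraction, $P_i \sim
U(0.75, 1)$), giving a sharp inhale peak and the long exhale plateau typical
of relaxed breathing; a small slow wander with an integer number of periods
per loop (seam-free); and Poisson-distributed damped-oscillation bursts
(default 2/min, 0.3 cm) placed in the early exhale plateau, where stutters
do not disturb peak detection. Both loop ends sit on the plateau with
near-zero velocity, so the trace tiles seamlessly when an acquisition
outlasts it. The mean period, 153/43 ≈ 3.56 s, is implied by the printed
duration and cycle count rather than stated directly. Because every cycle
has one dominant peak above home by construction, the cycle count is exactly
reproducible for any seed — the suite checks several.

Cycle detection finds local maxima above home (scaled value ≥ 1) separated by
a 1.0 s refractory period (no plausible breath is shorter), then refines each
peak time by parabolic interpolation through its three samples. The
refinement matters downstream: phase assignment divides time between peaks,
and 30 ms peak quantization would otherwise leak ~1% phase error into the
binning residuals.

## Digital phantoms and rasterization

The rod is a cylinder (default 6.35 mm diameter, 10 cm length) whose axis
lies in the AP–SI plane at 26.0° to the couch, so its AP position advances
along SI with slope $\tan 26° \approx 0.488$. The sphere phantom embeds
1–4 cm spheres in lung-equivalent background along SI with 1.5 cm gaps.
Voxel HU is the occupancy-weighted mix of object and background HU, with
occupancy estimated by 3×3×3 supersampling per voxel (27 subsamples);
summed occupancy reproduces closed-form volumes
($\pi r^2 L$, $\tfrac{\pi}{6}d^3$) to well under 2% at the default grids.

HU values are configurable and deliberately unremarkable — rod 0 HU
(water-equivalent plastic) on −800 HU background, clay spheres +50 HU in
−700 HU lung — chosen so the fixed display window/level used for measurement
(300/−500) separates object from background. The commissioning conclusions
are geometric and do not depend on the exact HU; the thresholds derived from
them do (next section). In-plane resolution defaults to 1 mm (typical CT;
not printed in the procedure being emulated), and the suite verifies that
static measurement errors shrink at 0.5 mm.

## Virtual cine scanner

Couch stations tile the SI extent in steps of the collimation (20 mm = eight
2.5 mm slices). Station $k$ images during
$[t_k,\ t_k + \text{duration}]$ with
$t_{k+1} = t_k + \text{duration} + \text{dead time}$, acquiring
$\lfloor \text{duration}/\text{interval} \rfloor + 1$ images at arithmetic
timestamps (13 images for a 4 s period). Interval and duration follow the
clinical cine rules: period/10 — so successive images advance the phase by
one bin — and period + 1 s — so every station sees a full cycle and every
bin is fillable without fallback.

Choices the source procedure leaves open, declared here as defaults:

- **Image formation is an instantaneous snapshot.** The scanner's true
  temporal aperture (gantry rotation) is not specified; a `windowed` mode
  that averages geometry over a configurable aperture exists for sensitivity
  studies. The choice is consequential: snapshots make each selected image
  internally motion-free, so gradient-phase widths stay near the static
  width and the washout seen on real scanners (width collapsing at large
  RoM) appears only in windowed mode. Inhale/exhale fidelity, MIP envelope
  growth, LR invariance, and phase-error behavior are aperture-independent
  and are what the acceptance checks target.
- **Station dead time 0.5 s** (couch step; unprinted). Its main effect is to
  decorrelate the breathing phase at which successive stations start.
- **Scan start**: the physical procedure began scanning once the measured
  period agreed with the applied one within 0.1 s; the simulator verifies
  that gate on the generated trace, then starts each scan a few cycles in at
  a seeded random phase, so station start phases vary realistically across
  repeats.

## Phase binning and reconstruction

Phase is RPM-style: 0% at inhale peaks, growing linearly with time to 100%
at the next peak; a symmetric sinusoid's trough is therefore exactly 50%
(exhale). Timestamps outside the detected peak range extrapolate with the
nearest cycle's period, modulo 100. Per station and nominal bin
(0, 10, …, 90%), the image minimizing *circular* phase distance (phase 98 is
2 from bin 0) is selected, ties to the earlier timestamp — deterministic,
and no pixel data are ever interpolated: every station-slab of a phase
volume is one acquired image. Whether the commercial reconstructor selects
or averages candidate images is unknown; selection is the declared behavior,
isolated behind `assign_phase()`/`bin_station()` so alternatives can be
swapped. Irregular traces can leave bins poorly served at some stations; the
default `nearest-fill` policy mirrors clinical phase binning (whole image
sets, larger residuals), while `leave-gap` marks such bins instead.

The reconstruction phase error is the maximum residual over all stations and
bins. For sinusoids sampled at period/10 it is bounded by half a bin: the
images' phases form a 10%-spaced lattice at a random offset, so the nearest
image to any bin is within 5% (up to the sub-sample precision of the refined
peak times — the suite allows 0.01 percentage points). The MIP is the
voxelwise maximum over the ten phases, the Avg the voxelwise mean; both
inherit the phase volumes' grid.

## Metrology

All measurements binarize at a configurable object threshold defaulting to
the lower display-window edge, level − window/2 = −650 HU: at window/level
300/−500, every pixel rendered above black counts as visible object. The
display settings are given by the procedure; the threshold is this package's
reproducible surrogate for a human reading from the screen.

- **Apparent rod width**: per axial slice, the AP distance between the first
  and last supra-threshold voxel *centers*; the rod axis is fitted by least
  squares through per-slice binary centroids; the width is the mean over the
  central 70% of usable slices of extent × cos(fitted angle) — the reading
  perpendicular to the axis, comparable to the manufactured diameter. The
  center-to-center convention is the one under which an axis-aligned
  cylinder whose surface lands on voxel centers reads its diameter exactly;
  it under-reads the supra-threshold *region* by about one pixel while the
  inclusive −650 HU threshold over-reads the physical surface by a similar
  amount, leaving the static reading within a pixel of truth (the suite pins
  it at 6.35 ± 1 mm). Sub-pixel edge interpolation is deliberately out of
  scope.
- **Apparent rod angle**: arctangent of the centroid-fit slope, in degrees.
  Translation-invariant; alternating ±1-pixel slice perturbations cancel.
- **Sphere diameters**: supra-threshold extents along the AP and LR lines
  through the sphere center on the central axial slice. The center defaults
  to the supra-threshold centroid — under motion the sphere is displaced, so
  a static center cannot be assumed.
- **Auto-threshold contour**: voxels in [−500, 2000] HU, largest 6-connected
  component (disconnected artifact flecks excluded, as clinical
  auto-contouring does), volume = voxel count × voxel volume, equivalent
  diameter $(6V/\pi)^{1/3}$. Counting whole voxels biases the volume high by
  roughly half a voxel of shell; the closed-form comparison in the suite
  therefore uses a 0.25 mm grid, where the bias is under 2%.
- **Centroid shift**: a tilted rod's centroid legitimately advances
  slice-to-slice by thickness × tan(angle) (1.22 mm at 2.5 mm slices); the
  excess over that, as a fraction of motion amplitude, measures
  between-slice misalignment artifact.

A brute-force per-voxel oracle (plain loops, igraph components) cross-checks
extents and contour volumes on small volumes in the test suite.

## Commissioning driver and decision rules

`run_commissioning()` executes: static rod reference (2 mm slices); 15
sinusoid settings (periods 3/4/5 s × RoM 0.5/1/2/3/4 cm), each repeated 3
times with fresh seeded start phases — the physical procedure scanned once
per setting, and the repeats expose start-phase sensitivity that a single
scan hides, with cells reporting the repeat mean; the patient-like trace on
the rod (cine 0.4 s / 5 s, as used for the recorded pattern); and static +
patient-like sphere studies. Tables report MIP, Avg, inhale (0%), exhale
(50%), and the mean ± sd over the four gradient phases (20/30/70/80%).

Decision rules layered on the tables:

- **Washout flag**: RoM strictly greater than 3× object width. At exactly 3×
  the flag stays off (a declared boundary convention). Flagged settings
  carry the planning recommendation: characterize the target's shape and
  size on the exhale phase, project that contour onto each gradient phase's
  geometric center (the center persists in the image, since the target
  dwells there longest), and form the internal target by Boolean union
  across phases — `build_internal_target()` implements the union by
  nearest-voxel translation of the exhale mask, whose AP extent grows by
  exactly the centroid travel.
- **Minimum reliable target size**: the smallest tested width whose
  gradient-phase size estimate stays within 20% of truth across all settings
  with RoM ≤ 3× width. The 20% tolerance and the rule itself are this
  package's operationalization of "reliably reconstructed" — labelled as
  such in the report, never a substitute for the raw tables.

## Problem sizes, determinism, degenerate inputs

Default geometry: 1 mm in-plane, rod grid 2 × 10 × 10 cm (five stations),
sphere grid 5 × 9.2 × 16 cm (eight stations). A full default commissioning
run (45 rod scans + patient rod + spheres) completes in a few minutes on one
core; the acceptance script's rod-only run takes about a minute. All
randomness — trace jitter, bursts, start phases — flows from one run-level
seed through an RNG scope that restores the caller's stream. Degenerate
inputs fail loudly rather than silently: empty masks, rods visible on fewer
than 3 slices, stations with no images, slabs outside the grid, traces that
end before the scan does, values outside the 0–2 encoding, and excursions
beyond the ±4 cm platform limit are all errors with specific messages.

## What passing tests do and do not show

The simulator is a geometry-level model: no photon transport, noise, scatter,
beam hardening, reconstruction kernels, or helical mode; amplitude binning
and registration between phases are out of scope. Agreement with the
emulated procedure is therefore expected for geometric/timing quantities —
protocol arithmetic, static recovery, phase-error bounds, trace statistics,
inhale/exhale width fidelity, MIP envelope growth, LR invariance — and *not*
for quantities driven by scanner physics, such as the absolute gradient-phase
washout widths or HU-dependent contour values of a physical scan, which the
report reproduces qualitatively at best (snapshot mode) or via the windowed
aperture mode (sensitivity studies only). Real patient breathing also drifts
in baseline and amplitude over minutes, which the loop-stationary generator
does not emulate.
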