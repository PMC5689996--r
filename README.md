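# cbctmotion

Motion-induced CT number artifacts in cone-beam CT (CBCT), simulated and
analyzed with a first-order projection-occupancy model.

CBCT on a linac-mounted on-board imager acquires projections over a
rotation lasting many breathing cycles, so a target moving along the
superior–inferior axis is seen at different positions by different
projections. The reconstructed CT numbers smear along the motion axis: the
target elongates, its HU level drops, and for large motion the distribution
splits in two. `cbctmotion` is for medical physicists and imaging
researchers who need to quantify these artifacts in phantom QA, predict them
for given motion parameters, or invert them to estimate motion amplitude
from a blurred scan.

## The model

Reconstruction is treated as an accumulator: each of the `N` projections
deposits a constant increment `ΔCT = CT_S / N` of a voxel's stationary level
into the imaging window (slice, width `w`) containing the voxel at that
projection's time. A window that catches `M ≤ N` projections of a voxel
reaches `CT_M = CT_S · M/N`. Summing over voxels and projection times gives
the mobile profile, and the area under the profile is conserved while the
target stays in view:

    CT_S · w = CT_M · (w + L),

with `L` the elongation. For constant speed `VP` over acquisition time `T`,
`L = VP·T` and the mean level over the broadened support is
`CT_S · w / (w + VP·T)`. For sinusoidal motion `d(t) = A sin(2πft + φ)` the
infinite-`N` limit follows the arcsine occupancy law, giving maximum
elongation `2A`, phase invariance over integer cycle counts, and splitting
exactly when the range of motion `2A` exceeds the target length. The methods
vignette (`vignettes/cbct-motion-model.Rmd`) derives all of this.

## Worked example

Medium phantom target (20 mm gel insert, 700 HU above lung-equivalent
background) moving sinusoidally with amplitude 15 mm at 15 cycles/min during
a 60 s, 1000-projection scan:

```r
library(cbctmotion)

target   <- preset_phantom("medium", center_y0_mm = 50)
grid     <- auto_grid(target, max_excursion_mm = 15)
protocol <- scan_protocol(n_projections = 1000, scan_duration_s = 60)
motion   <- motion_sinusoidal(15, frequency_hz = 0.25)

stationary <- stationary_profile(target, grid, protocol)
mobile     <- simulate_mobile_profile(target, motion, protocol, grid)$profile
profile_metrics(mobile, stationary = stationary, marker_length_mm = 20)
#> $support_extent_mm      52
#> $max_level_hu           398.4
#> $max_positions_mm       45 55
#> $integral_hu_mm         14000
#> $split                  TRUE
#> $elongation_mm          32
#> $level_drop_pct         43.1
#> $estimated_amplitude_mm 16
```

Reading the numbers: the 20 mm target's profile now spans 52 mm (the
5 % support threshold trims the faint extremes of the ideal 20 + 2A =
50 mm span to 52 mm of 2 mm windows); the peak level fell 43 % and sits at
two peaks (45 and 55 mm) around the center — the distribution has split,
as expected since the 30 mm range of motion exceeds the 20 mm length. The
area 14000 HU·mm equals the stationary `700 HU × 20 mm`: conservation
holds. Inverting the support with the known 20 mm marker length recovers the
amplitude within one slice width. Sweep runners (`run_sweep()`), profile
CSV/JSON I/O, synthetic noisy measurements (`generate_measured_profile()`),
PRMS comparison (`prms()`) and a coronal renderer (`render_coronal()`) are
documented in the function reference; `inst/cli/cbctmotion` wraps it all for
shell use.

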