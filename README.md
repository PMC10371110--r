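# fgsim

Simulation and image processing for wearable fluorescence-guided surgery
(FGS) imaging systems.

Head-mounted FGS goggles excite a near-infrared (NIR) fluorophore with a
laser array, image the scene with coaligned visible and NIR cameras
through an emission filter, and overlay the detected fluorescence on the
surgeon's view. Whether such a device is usable comes down to three
quantitative questions that `fgsim` lets you study end to end, on
synthetic scenes with known ground truth:

- **Can ambient NIR be removed in real time?** Pulsing the laser with
  every other frame (trigger period `2T` for frame period `T`) and
  taking the sliding absolute difference `ΔF_n = |F_n − F_{n−1}|`
  removes static room-light background at the full frame rate.
- **Can two viewpoints be coaligned with one calibration?** A projective
  transform `H` (3×3 homography, DLT with Hartley normalization) fitted
  to ≥ 4 matched fiducials at one distance aligns two views of a plane.
  If the viewpoints share an optical center the same `H` is exact at
  *every* distance; if they are separated by a baseline `B`, the
  corrected scene-space error grows as `B·|d/d_cal − 1|` — the parallax
  law that the package both simulates and verifies in closed form.
- **How much fluorophore is detectable?** Per-pixel signal-to-background
  ratio maps normalize background-subtracted intensity by the
  excitation-leak threshold (maximum ON−OFF intensity on a white card),
  so `SBR = 1` marks signal indistinguishable from filter leak; well
  plates with an IR-125 dilution series yield log-log sensitivity curves
  `SBR = 1 + kC/ℓ`.

The simulator (pinhole cameras, Gaussian laser-beam array, scalar
excitation-filter leak/emission-gain channel, Poisson + Gaussian noise,
8-bit quantization) stands in for the hardware; every processing
function also accepts externally supplied images.

## Worked example: does a head-mount survive a distance change?

Calibrate a forehead-mounted imaging camera against an eye-surrogate
camera at 50 cm, then move the target ±10 cm:

```r
library(fgsim)

cam <- default_audit_camera()                      # 410 x 308 px, 1.2 mm/px @ 50 cm
tgt <- planar_target(default_alignment_target())   # 4-fiducial chart
rep <- distance_sweep(mount_geometry("forehead"), d_cal = 500,
                      distances = c(400, 500, 600), tgt, cam)
rep
#> <fgs_alignment_report> forehead geometry, calibrated at 500 mm
#>   calibration residual: 7.32e-14 px
#>   max corrected error: 5.34 mm horizontal, 14 mm vertical
round(rep$records[, c("distance", "raw_h_mm", "raw_v_mm",
                      "corr_h_mm", "corr_v_mm")], 2)
#>   distance raw_h_mm raw_v_mm corr_h_mm corr_v_mm
#> 1      400   -26.52   -69.48      5.34     13.90
#> 2      500   -26.48   -69.52      0.00      0.00
#> 3      600   -26.56   -69.48      5.23     13.97
```

Reading it: the raw overlay offset equals the mount baseline (26.5 mm
horizontal, 69.5 mm vertical — the camera sits above and beside the
eye), calibration cancels it exactly at 50 cm, and at ±10 cm the
residual reappears at `B·|d/d_cal − 1|` = 5.3 / 13.9 mm. Run the same
sweep with `mount_geometry("coaxial")` — a beamsplitter geometry whose
cameras share an optical center — and the corrected error stays ~0.1 mm
at every distance, which is why a coaxial design needs only a single
startup calibration.

Synchronization arithmetic at 30 fps:

```r
make_schedule(30, 0.7)
#> <fgs_schedule> frame 33 ms, trigger 66 ms, on 23.1 ms (duty 0.70)
```

Other entry points: `generate_stream()` / `background_subtract()` for
laser-synchronized streams, `leak_threshold()` / `sbr_map()` /
`overlay()` for quantification and display, `well_sbr()` /
`fit_sensitivity()` for phantom curves, `dual_camera_audit()` for the
NIR/visible sensor pair, `power_from_thermal()` / `coverage_above()` for
illumination analysis, and `run_experiment()` for seeded, reproducible
experiment bundles. A thin CLI lives at `inst/cli/fgsim.R`
(`audit`, `process`, `run`, `illum` subcommands).

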