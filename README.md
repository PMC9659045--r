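# microflow

Quantitative analysis of intravital microcirculation video in R: red-blood-cell
(RBC) flow velocity and vessel diameter from calibrated image sequences, plus
the longitudinal group statistics used to compare treatment groups over time.

Microcirculatory failure — slowing capillary flow, narrowing arterioles — is an
early marker of circulatory shock, and both indices can be measured without
contact from reflectance video: vessels appear dark on brighter tissue (green
light is absorbed by haemoglobin), and moving RBCs are a faint sparse signal on
top. The obstacles are nuisance structure: whole-body motion, static tissue
texture, specular highlights, and the faintness of the RBC signal itself.

## Method

`microflow` implements the processing chain:

1. **Motion correction** — each frame registered to the first by normalized
   cross-correlation over integer shifts (`register_sequence`).
2. **Vessel extraction** — multiscale Hessian vesselness for dark tubes,
   thresholded and cleaned (`enhance_vessels`, `segment_vessels`); a
   patch-based probabilistic predictor can be slotted in, with overlap-average
   stitching (`extract_patches`, `stitch_patches`).
3. **Thinning** — Zhang–Suen skeletonization and branch-free centerline
   tracing with subpixel smoothing (`skeletonize`, `centerline_paths`).
4. **RBC isolation** — robust PCA / principal component pursuit by inexact
   augmented Lagrangian: `min ||L||* + λ||S||₁ s.t. D = L + S`, where `L` is
   the static background and `S` the moving cells (`rpca_decompose`,
   `sparse_video`).
5. **Velocity** — the kymograph (space–time image along a centerline) of the
   sparse video shows oblique streaks; their slope is read from the
   orientation θ′ of the dominant line of the 2-D Fourier spectrum:
   `v = cot θ′ · pixel_size / frame_interval` (`estimate_velocity`).
6. **Diameter** — full width at half maximum of the transverse green-channel
   profile, with the reference level midway between the dip minimum and the
   mean of the two shoulder peaks (`vessel_diameter`); vessels classify as
   capillary (< 20 µm), arteriole/vein (20–100 µm) or out of range.
7. **Statistics** — per-group mean ± SD, range-normalization with centring,
   and per-timepoint paired t-tests against baseline at α = 0.1
   (`group_summary`, `normalize_centralize`, `ttest_vs_baseline`).

A synthetic-video generator with exact ground truth (`render_scene`,
`render_kymograph`, `simulate_cohort`) backs the test suite, so every stage is
validated against known truth. See the methods vignette
(`vignettes/microflow-methods.Rmd`) for the model details and design
decisions.

## Worked example

Render a synthetic scene with a known 25 µm vessel carrying flow at
150 µm/s under ±2 px body-motion jitter, then run the full pipeline:

```r
library(microflow)

sp <- scene_spec(72, 170,
  list(vessel_spec(rbind(c(4, 30), c(165, 30)), width_um = 25,
                   velocity_um_s = 150, rbc_rate = 10)),
  noise_sd = 0.01, jitter_px = 2, n_frames = 150, seed = 42)
rs <- render_scene(sp)
rs$seq
#> image_sequence: 150 frame(s), 72 x 170 px, 3 channel(s), 16-bit
#>   pixel size 0.64 um, frame interval 0.03333 s (30 fps)

cfg <- run_config(pixel_size_um = 0.64, frame_interval_s = 1/30,
                  search_radius_px = 3, vesselness_scales = c(2, 4, 8, 16),
                  diam_half_length_px = 28)
rep <- run_pipeline(rs$seq, cfg)
rep
#> pipeline_report
#>   register   ok (4.89 s)
#>   segment    ok (0.49 s)
#>   thin       ok (0.16 s)
#>   trace      ok (0.08 s)
#>   rpca       ok (12.81 s)
#>   3 vessel measurement(s), 2 warning(s)
#>  vessel_id     quantity     value          units
#>  vessel_03     diameter  25.01826             um
#>  vessel_03 vessel_class        NA arteriole_vein
#>  vessel_03     velocity 150.74656           um/s
#>   warnings: vessel_01: diameter failed (all 3 normals failed ...
```

The planted vessel is recovered at 25.0 µm (truth 25) and 150.7 µm/s (truth
150), classified arteriole/vein — the class whose velocity is estimated. The
two warnings are short spurious centerline fragments from background texture;
they fail the diameter stage gracefully and produce no measurements. The
registration stage undid the planted jitter exactly
(`all(rep$corrected$shifts == -rs$truth$shifts)` is `TRUE`).

A thin CLI over the same functions is installed at `inst/cli/microflow.R`
(`simulate`, `register`, `run`, `stats` subcommands).

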