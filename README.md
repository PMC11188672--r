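# sonogate

Reconstructs 3D skeletal-muscle shape **during cyclic movement** from swept 2D
ultrasound, and measures how the muscle deforms.

A probe on a motorised axis sweeps along the limb while the joint moves
cyclically (paced at 45 or 100 beats/min). No single sweep sees a coherent
muscle — but every frame carries a probe position (axis encoders) and an ankle
joint angle (motion-capture markers: the angle between the lateral-epicondyle
→ lateral-malleolus and malleolus → fifth-metatarsal vectors). Frames are
therefore **gated retrospectively** into 1° angle bins split by movement
direction (dorsiflexion = active, plantarflexion = passive), giving four
conditions (slow/fast × active/passive). Within a bin, images closer than
0.8 mm are merged; a bin is accepted with ≥ 40 images and all gaps < 25 mm.
Accepted stacks at 0, 10, …, 100 % of the usable range of motion (ROM, the
intersection of the four conditions' available angle ranges) are segmented,
lofted into voxel volumes, and measured: volume, length, cross-sectional-area
(CSA) profile, and the position of the maximum CSA (vertex of a quadratic fit
over the central 80 % of the profile).

The reference shape model is a constant-volume ellipsoid: from
V = (4/3)πabc with longitudinal semi-axis c = L/2 and maximal cross-section
πab, constant volume gives

    CSA(L) = (3/4) V / c = (3/2) V / L,

so mean CSA should fall as the muscle lengthens if volume is conserved.

Because validating such a pipeline on humans requires hardware, the package
ships a **deforming-muscle phantom**: a constant-volume spindle whose length
tracks the ankle angle (11.2 % elongation from 113° to 157° by default),
whose CSA peak migrates from 60 % to 55 % of the reference length L0 as the
muscle shortens, and a session simulator (probe sweep, marker kinematics,
rendered cross-sections, per-frame ground truth). Every stage of the pipeline
is tested against this ground truth; statistics (Shapiro–Wilk screening,
repeated-measures ANOVA / Friedman, ANCOVA slope comparison) are tested for
calibration.

Audience: biomechanics / muscle-physiology groups doing 3D (freehand)
ultrasound of muscle during dynamic contraction, and developers of such
pipelines who need a hardware-free test bed.

## Worked example

```r
library(sonogate)

ph <- phantom_config()          # 89 cm^3 spindle, 113°–157°, 11.2% elongation
slow <- simulate_session(session_config(bpm = 45,  trial_duration_s = 150,
                                        n_trials = 2, seed = 1), ph)
fast <- simulate_session(session_config(bpm = 100, trial_duration_s = 150,
                                        n_trials = 2, seed = 2), ph)

res <- run_gated_pipeline(slow, fast)
summary(res)
```

Output from this run (seeds 1/2):

```
Per-condition pipeline summary
    condition n_cells volume_spread_pct elongation_pct_L0 peak_pos_0_pct_L0
  slow_active      11            0.3847             112.4             52.34
 slow_passive      11            0.7759             113.0             51.14
  fast_active      11            1.3813             112.2             52.35
 fast_passive      11            1.1653             110.7             52.50
 peak_pos_100_pct_L0 csa_slope mean_fit_r
               57.97    -6.429     0.9908
               58.17    -5.694     0.9911
               58.06    -4.035     0.9905
               57.32    -5.051     0.9908
```

Reading it: all 4 × 11 ROM cells reconstructed; normalised muscle volume
varies by at most 1.4 % across ROM in every condition (the phantom's volume
is constant — the pipeline recovers that); the muscle at 100 % ROM measures
111–113 % of its shortest length L0 (configured: 111.2 %); the CSA peak sits
more proximally at the shortest length and shifts distally by ~5 %L0 at the
longest (configured shift: 5 %L0; absolute vertex positions carry a known
~3 %L0 proximal bias of the quadratic smoother, which cancels in the shift);
and the fitted max-CSA-vs-length slope is negative in every condition — the
shorter the muscle, the larger its peak cross-section. `plot(res,
type = "profiles")` and `plot(res, type = "max_csa")` draw the CSA curves and
the ellipsoid overlay; `write_morphometry_csv()` exports the cell table.

Lower-level entry points mirror the pipeline stages: `sync_session()` /
`stitch_trials()`, `assign_bins()` / `merge_close_frames()` /
`apply_inclusion_criteria()`, `compute_rom()` / `select_rom_stacks()`,
`segment_slices()` / `interpolate_surface()`, `weighted_pca_align()` /
`compute_volume()` / `compute_csa_profile()` / `fit_max_csa()`, and
`choose_and_run_omnibus()` / `compare_slopes()`. Stacks export to a
documented Stradwin-style text format via `export_stradwin()`; volumes to
NIfTI, meshes to STL/PLY.

See the vignette (`vignettes/gated-3d-ultrasound.Rmd`) for the method
description, the phantom's assumptions, and numerical choices.

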