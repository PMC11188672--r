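---
title: "Gated 3D ultrasound reconstruction of muscle shape during cyclic movement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gated 3D ultrasound reconstruction of muscle shape during cyclic movement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

A 2D ultrasound probe swept along a limb produces a stack of cross-sectional
images from which a 3D muscle volume can be reconstructed -- but only if the
muscle holds still for the duration of the sweep. During cyclic movement
(here: ankle plantar-/dorsiflexion paced by a metronome) no single sweep sees
a coherent muscle. The method implemented by `sonogate` gates frames
*retrospectively*: every frame carries a probe position (from the scanner's
motorised-axis encoders) and an ankle joint angle (from motion-capture
markers), so frames acquired minutes apart at the *same* joint configuration
can be pooled into one coherent slice stack. Binning angles at 1 degree and
splitting by movement direction (dorsiflexion = the imaged dorsiflexor
working, "active"; plantarflexion = "passive") yields, after enough cycles, a
full slice stack per (angle bin, direction). Stacks at 0, 10, ..., 100% of
the usable range of motion (ROM) are reconstructed into voxel volumes, and
muscle volume, length and the cross-sectional-area (CSA) profile are
measured on each.

The ankle angle is the angle between the lateral-epicondyle to
lateral-malleolus vector and the malleolus to fifth-metatarsal vector.
Direction comes from the sign of the angle's slope at each frame, with a
small dead-band (default 0.05 deg/frame on a 5-frame moving average) so that
reversal jitter does not flip labels; dead-band frames are excluded. The
slope estimator and dead-band are configuration knobs
(`label_direction()`), since only the sign rule is inherent to the method.

## Gating rules

Frames with angle $\theta$ enter the unique integer bin $c$ with
$c - 0.5 \le \theta < c + 0.5$ (degrees). Within a bin, images closer than
0.8 mm along the scan axis are merged to their pixelwise mean at the mean
position -- repeatedly, closest pair first, until all gaps are at least
0.8 mm. The greedy closest-pair order makes the merge deterministic and
idempotent given sorted positions. A merged stack is accepted if it holds at
least 40 images and no consecutive gap reaches 25 mm; the count criterion is
evaluated after merging (merged frames count once) and takes precedence in
the rejection reason.

Per condition (velocity x direction), the available angle range is the span
of accepted bins; the combined ROM runs from the largest per-condition
minimum to the smallest per-condition maximum, so all four conditions are
compared over an identical angle range. We combine across both velocities
(not per velocity) because the 44-cell table is meant to be compared
cell-by-cell; a configuration flag restores per-velocity ROM. Fractional
grid angles snap to the nearest integer bin with ties toward the ROM
minimum, and a cell whose bin is not accepted falls back to the nearest
accepted bin within +/-2 degrees (flagged as substituted) before being
declared missing. These two rules are our choices; the gating rules above
are inherent to the method.

## Reconstruction

An accepted stack is a set of parallel planes at encoder positions (this
scanner sweeps a straight axis; the data model carries full per-slice poses
for freehand use, but only parallel planes are voxelized). The muscle is
segmented on 15--20 approximately equidistant slices (default 17), always
including the first and last slices containing foreground. On phantom
images segmentation is automatic: a global Otsu threshold over the stack,
largest connected component, boundary traced at sub-pixel resolution
(`grDevices::contourLines` at the threshold level). Real B-mode images are
segmented manually elsewhere and imported as polylines (`mode = "import"`),
which are validated (closed, simple) and resampled.

The surface between segmented contours is built by lofting: all contours are
resampled to a common vertex count, starting vertices are matched by the
circular shift minimising summed squared vertex distance (minimal twist),
and corresponding vertices are interpolated linearly between adjacent
stations at the axial voxel spacing. The ends are capped by shrinking the
end contours onto their centroids over one axial voxel spacing; this is a
documented bias of at most one frame spacing in length and a fraction of a
percent in volume. Axial sample planes sit at voxel centres straddling the
contour span, so the interior of a lofted solid is tiled exactly. Each plane
is filled by point-in-polygon rasterisation (`mgcv::in.out`) on a grid
snapped to voxel multiples, which makes the voxel volume invariant (to
raster error) under rigid in-plane translation of the contours. Voxel size
defaults to (pixel, pixel, nominal frame spacing = probe speed / frame
rate). A text-dialect `.sw` writer (`export_stradwin()`) exports any stack
for use with external freehand-3D-ultrasound software.

## Morphometry

Volume is segmented-voxel count times voxel resolution. Length is the
Euclidean distance between the centroids of the first and last segmented
slices. CSA per slice is foreground pixel count times pixel area. Before
profiling, the volume is rotated into its principal axes (weighted PCA of
the voxel cloud; uniform weights by default, with a slice-area-equalising
option so each axial station contributes equally -- the weighting in the
literature is not standardised, so both are provided). Rotated voxel
centres are re-binned at the source spacing of the nearest original axis;
the aligned array stores per-voxel source counts, so alignment never changes
the measured volume, and the re-binned pitch matches the source sampling so
the axial profile does not beat against the slice spacing.

The shortest muscle length of each condition -- its 0%-ROM cell -- defines
the reference length $L_0$; lengths and axial positions are expressed in
% of $L_0$, and profile CSA values are normalised by the condition's
grand-mean CSA over all slices and cells (the normalisation baseline for
such curves is a convention; ours is recorded here). The maximum CSA and its
position are read from the vertex of a least-squares quadratic fitted over
the central 80% of the profile extent: the tendon tails are strongly
non-quadratic and would bias a global fit. Fit quality is the Pearson
correlation of fitted versus observed CSA in the window; an upward-opening
parabola or an out-of-window vertex flags a fallback to the observed argmax.

A constant-volume ellipsoid is the reference shape model: with volume
$V = \tfrac{4}{3}\pi a b c$, longitudinal semi-axis $c = L/2$ and maximal
cross-section $\pi a b$, constant volume gives
$\mathrm{CSA}(L) = \tfrac{3}{4} V / c = \tfrac{3}{2} V / L$, a decreasing
function of length that the measured mean CSA should track if the muscle
redistributes its (conserved) volume along its changing length.

Statistics follow the matched-samples battery used for such tables:
Shapiro-Wilk screening per ROM level with an all-levels-must-pass gate (no
multiplicity correction -- the gate rule is configurable), then a one-way
repeated-measures ANOVA for normal data or a Friedman test otherwise, at
$\alpha = 0.05$; slope differences between conditions use an ANCOVA
interaction test with pairwise slope contrasts (via `emmeans`). Tables in
which every subject is constant across levels have no within-subject
variance, which leaves the ANOVA F undefined (0/0); such degenerate tables
are routed to the rank-based Friedman test, which cleanly reports statistic
0 and $p = 1$. No sphericity correction is applied by default.

## The phantom: what it emulates, and what it does not

The phantom is a constant-volume spindle: elliptical cross-sections
(semi-axis ratio $a/b$ = 1.5) whose semi-axes follow two parabolic arcs that
vanish at the muscle ends and peak at a configurable fraction of muscle
length. The squared profile integrates to $8/15$ of peak-CSA x length for
*every* peak position, so scaling the peak axes to
$ab = 15V/(8\pi L)$ conserves volume exactly at every length -- volume
conservation is built in, which is what makes the phantom a ground truth for
the pipeline's conservation measurements rather than a tautology: the
pipeline must *recover* constancy through gating, segmentation, lofting and
counting. A pure-ellipsoid shape option (`shape = "ellipsoid"`) exists for
the geometry oracles. Defaults mimic a tibialis-anterior-like muscle: 89
cm^3, 200 mm neutral length, 11.2% elongation from 113 deg (neutral,
shortest muscle) to 157 deg (plantarflexed, longest), and a CSA peak at 55%
of $L_0$ when shortest, 60% of $L_0$ when longest (the long-length config
value 0.60/1.112 is expressed as a fraction of current length). An optional
CSA scale factor on active half-cycles emulates activation-dependent
bulging (default 1, i.e. off).

The angle trajectory is a raised cosine between per-beat endpoints
("plantarflexion on every second beat"): zero slope at the reversals, so
frames pile up near the extreme angles exactly as paced human movement
produces -- this drives realistic bin occupancy. The waveform between beats
is not prescribed by the protocol; the raised cosine is our choice.
Per-beat timing jitter (default 0.04 s, typical human metronome-tracking
variability) is essential for a *simulator*: it decorrelates the movement
cycle from the probe sweep. For the same reason the default sweep extent
(231.7 mm) was chosen by a small numerical search so that the per-cycle
probe step is far from every small-denominator rational fraction of the
probe round trip for both metronome rates, and each sub-trial starts at a
uniformly random phase of the sweep (sweep and metronome are started
asynchronously in practice). Without these choices, reversal dwells -- the
events that populate the extreme angle bins -- land on a sparse repeating
position lattice, an artifact of perfect periodicity that no real
acquisition exhibits.

Endpoint *amplitude* jitter defaults to 0: the trajectory reaches the
configured endpoint angles exactly, the available ROM equals the configured
range, and the reversal bins are densely covered. With amplitude jitter
enabled, bins just beyond the nominal endpoints are populated only by rare
over-shoot dwells; such bins can pass the inclusion criteria with 40+
images that nevertheless cover the scan axis in a few clusters, and because
the ROM definition extends to the outermost accepted bin, the 0%/100% cells
then measure lengths truncated by wherever frames happened to land. That
regime is real (it is what scan-coverage noise looks like) and the knob
exists to study it, but it is not the regime in which recovery of the
configured elongation is meaningful at desk scale.

Rendering is deliberately minimal: a bright anti-aliased elliptical disc
(pixel value = edge coverage fraction) on a dark background plus additive
Gaussian noise (sd 0.05 on a 0--1 scale), clipped and quantised to 8 bits.
The downstream stages need segmentable geometry with exact ground truth,
not B-mode realism: no speckle, shadowing, anisotropy, probe pressure
deformation, or out-of-plane motion is simulated, and automatic threshold
segmentation is phantom-only. Phantom-based passes therefore validate the
gating/reconstruction/morphometry chain, not in-vivo segmentation quality.

The linear length--angle map is the minimal assumption given only endpoint
lengths, and the linear-in-length interpolation of the CSA-peak position
gives a recoverable ground truth for the proximal-shift measurement.

## Problem sizes and numerical behaviour

The test-suite and acceptance runs simulate two velocities (45 and 100
beats/min) of 2 x 150 s sub-trials each, with 64 x 64 px frames at 1 mm --
about 18 000 frames. These sizes were set from the gating arithmetic: at
30 Hz a 1-degree mid-ROM bin gains roughly 0.22 frames per second per
direction at either metronome rate, so five minutes per velocity yields
~50-65 raw frames per mid bin, comfortably above the 40-frame inclusion
criterion after 0.8 mm merging, whereas two minutes would sit below it (the
reference protocol's nine minutes per velocity exists precisely to fill the
bins). At this scale all 44 cells fill without substitution in most runs.

Two numerical facts are worth knowing when interpreting results. First,
measured lengths are coverage-limited: a cell's length ends at the
outermost *imaged* foreground slice, so each end loses a systematic ~2-4 mm
(where the thinning muscle tip drops below a few pixels) plus wherever the
nearest frame happened to land; at desk scale this leaves per-condition
elongation estimates with roughly +/-1.5 %L0 of noise, which is why
recovery of the configured 11.2% elongation and of the 5 %L0 peak shift is
assessed on the across-condition mean (the corresponding reference
quantities are themselves aggregates). Second, the quadratic-fit vertex on
the phantom's quartic spindle profile is biased proximally by about 3 %L0
within the central-80% window (a property of fitting a parabola to an
asymmetric quartic, present identically at all lengths); the *shift* of the
peak between lengths cancels this bias, the absolute positions do not.
Reported fit correlations of ~0.99 are consistent with a quadratic being a
good but not exact smoother of a spindle profile.

Other numerical choices: Otsu thresholding operates on the whole stack at
once (one global threshold per reconstruction) and defines the foreground
mask; the contour itself is traced on the anti-aliased intensities at the
midpoint of the two class means -- the half-maximum level, which is the
unbiased boundary for a ramp edge, where Otsu's own level sits slightly
inside the ramp -- giving sub-pixel boundaries whose polygon areas match
analytic ellipse areas to well under 1% for radii above 10 pixels; traced
rings that self-cross at sub-pixel scale (a noise artefact) are relaxed by
a light circular moving average before lofting; the point-in-polygon raster is restricted to each polygon's
bounding box; and tie-breaks (grid-angle snapping, substitution search)
always resolve toward the ROM minimum so results are reproducible.

## Limitations

Real B-mode segmentation is out of scope (import manual contours). Only
parallel-plane geometry is voxelized. The phantom's cross-sections are
ellipses and its motion is a single hinge angle; soft-tissue artefacts,
probe-force deformation and marker noise are not modelled. Statistical
reproduction of subject-level significance values is out of scope by
construction -- the tests exercise calibration (type-I error) and large-
effect behaviour instead.

## A minimal session

```{r, eval = FALSE}
library(sonogate)
ph <- phantom_config()
slow <- simulate_session(session_config(bpm = 45, trial_duration_s = 150,
                                        n_trials = 2, seed = 1), ph)
fast <- simulate_session(session_config(bpm = 100, trial_duration_s = 150,
                                        n_trials = 2, seed = 2), ph)
res <- run_gated_pipeline(slow, fast, verbose = TRUE)
summary(res)
plot(res, type = "profiles")
plot(res, type = "max_csa")
```
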