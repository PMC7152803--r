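# strokeangio

Analysis of post-stroke cortical microvasculature from optical coherence
tomography angiography (OCT-A): angiogram construction from repeated
complex B-frames, capillary-orientation statistics referenced to the
ischemic lesion center, longitudinal lesion-area quantification, and
capillary stalling-event metrics — together with a synthetic-data
generator so that every stage can be verified against known ground
truth.

It is written for researchers analysing phase-sensitive OCT angiography
of photothrombotic stroke models (or similar focal lesions), and for
anyone who needs a tested, scriptable replacement for the manual
ImageJ-based workflow those studies typically use.

## The method

**Angiograms.** B-scans are repeated twice per slow-axis position. After
removing the global phase fluctuation (GPF) that bulk sub-pixel motion
imprints on the second repeat — estimated per A-line as the phase of
`sum_z A * Conj(B)`, valid because static tissue dominates the frame —
the decorrelation image is the complex-difference magnitude `|A - B|`:
zero for static tissue, large where moving red blood cells change phase
or amplitude. Volumes are smoothed (3-D Gaussian, sigma 1 px), the
first 60 artifact-free frames of a series are averaged, and an en-face
map is formed by maximum-intensity projection over the focal plane
+/-15 px.

**Orientation.** Vessels are enhanced (tubeness then Frangi filtering),
and each pixel's local orientation `alpha` and coherence come from the
structure tensor. With `beta` the direction (mod pi) from the pixel to
the lesion center, `theta = alpha - beta` wrapped into `[-pi/2, pi/2)`
measures orientation relative to the ischemic center; capillaries with
`|theta| <= pi/12` (+/-15 deg, ~0.26 rad) count as *aligned*. A uniform
network has aligned fraction 1/6; radial reorganization drives it up.

**Lesion.** The avascular lesion is segmented from the en-face map
(smoothing, adaptive threshold, opening, darkest-component selection),
or loaded from a manual mask; areas per depth are normalized by their
day-8 value for longitudinal trajectories.

**Stalling.** Per capillary segment of the skeleton graph, a per-frame
intensity trace is compared with a local background annulus; a frame in
which the segment drops to within 25% of its flowing contrast counts as
one stalling event (volumes are >=10 s apart, so frames are independent
observations). The package reports stalling event density (events per
vascularized area, lesion excluded), stall incidence (fraction of
segments with >=1 event), and the event-count histogram.

## Worked example

```r
library(strokeangio)

# a synthetic cortical scene: 200 capillaries, 75% oriented toward a
# 30-px avascular lesion, plus a 60-frame series with stalling events
spec  <- scene_spec(n_segments = 200, align_fraction = 0.75,
                    lesion_radius_px = 30, seed = 42)
gen   <- generate_scene(spec)
stall <- stall_process_spec(n_frames = 60, stall_prob = 0.05,
                            stall_segment_fraction = 0.25, seed = 43)
r     <- render_angiogram_series(gen$scene, gen$truth, stall, spec)

series <- quality_filter(r$series)      # keep first 60 passing frames
enface <- average_series(series)        # SNR-raising mean image

lesion <- segment_lesion(enface)
lesion$area_px
#> [1] 2884                              # ground truth: 2821 px

oa <- orientation_analysis(enface, lesion_mask = lesion$mask)
oa$distribution$aligned_fraction
#> [1] 0.667                             # 1/6 would be unorganized

mask   <- make_mask(enface, lesion_mask = lesion$mask)
graph  <- build_segment_graph(mask)
traces <- segment_traces(series, graph, vessel_mask = mask)
stall_statistics(traces, graph, mask, lesion = lesion)
#> stall_stats: 74 events, 19 of 97 segments stalled (incidence 0.196),
#>   density 0.00963 events/px^2
```

The aligned fraction 0.667 reflects the 75% radially laid segments
(crossings and endpoints dilute it); the lesion area is recovered within
~2%; and the stalling summary counts each frame-level disappearance of a
segment as one event.

`run_pipeline(default_config(seed = 1), out_dir = "out/")` executes the
whole chain and writes a JSON report, TIFF/CSV intermediates and PNG
figures; `inst/cli/strokeangio.R` exposes `simulate` and `run`
subcommands for shell use.

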