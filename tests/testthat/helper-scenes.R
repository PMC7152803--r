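# Shared fixtures, all generated in code.

# Small crowded scene (crossings allowed), optionally with a lesion.
make_scene <- function(seed = 1, align = 0, lesion = 0, n = 200,
                       noise = 0.02, ...) {
  sp <- scene_spec(n_segments = n, align_fraction = align,
                   lesion_radius_px = lesion, noise_sigma = noise,
                   seed = seed, ...)
  c(generate_scene(sp), list(spec = sp))
}

# Mean en-face image of a rendered series with no stalls.
scene_enface <- function(gen, n_frames = 5, seed = gen$spec$seed) {
  r <- render_angiogram_series(gen$scene, gen$truth,
                               stall_process_spec(n_frames, 0, seed = seed),
                               gen$spec)
  average_series(r$series)
}

# Sparse non-touching scene for segment-level ground-truth checks.
make_separated_scene <- function(seed = 7, n = 40, noise = 0, ...) {
  sp <- scene_spec(n_segments = n, min_separation_px = 2,
                   noise_sigma = noise, seed = seed, ...)
  c(generate_scene(sp), list(spec = sp))
}

# Hand-built segment trace.
toy_trace <- function(intensity, background, id = 1L) {
  structure(list(segment_id = id, intensity = intensity,
                 background = rep_len(background, length(intensity)),
                 n_pixels = 10L),
            class = "segment_trace")
}

# Match graph segments to generator segment ids via the label image.
match_graph_to_truth <- function(graph, scene) {
  vapply(graph$segments, function(s) {
    labs <- scene$label[s$pixels]
    labs <- labs[labs > 0]
    if (length(labs) == 0) return(NA_integer_)
    as.integer(names(sort(table(labs), decreasing = TRUE))[1])
  }, integer(1))
}

# Pixel-weighted aligned fraction of a scene via the full pipeline.
measure_aligned_fraction <- function(align, seed, lesion = 15) {
  gen <- make_scene(seed = seed, align = align, lesion = lesion)
  avg <- scene_enface(gen)
  oa <- orientation_analysis(avg, center_xy = gen$spec$lesion_center_xy)
  oa$distribution$aligned_fraction
}
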