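#' Default pipeline configuration
#'
#' Nested per-stage parameter list covering every stage of the analysis,
#' serializable to YAML. Depth bands default to 230-270, 380-420 and
#' 530-570 um below the cortical surface (40-um bands around the three
#' focal depths 250, 400 and 550 um).
#'
#' @param seed master RNG seed for the run.
#' @return nested list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    depth_bands_um = list(c(230, 270), c(380, 420), c(530, 570)),
    scene = list(
      grid_nx = 128L, grid_ny = 128L, grid_nz = 32L, roi_size_um = 1000,
      n_segments = 200L, align_fraction = 0, lesion_radius_px = 0,
      vessel_radius_px = 1, vessel_intensity = 1,
      background_intensity = 0.1, noise_sigma = 0.02,
      min_separation_px = 0
    ),
    stall = list(n_frames = 60L, stall_prob = 0.05,
                 stall_segment_fraction = 0.25),
    angio = list(gpf_scope = "aline", smooth_sigma = 1,
                 mip_half_band_px = 15L, quality_k = 5, max_kept = 60L),
    enhance = list(tubeness_sigma = 2, frangi_scales = c(1, 1.5, 2),
                   frangi_beta = 0.5, mask_method = "otsu",
                   min_component_px = 10L, min_segment_length_px = 5L),
    orientation = list(grad_sigma = 1, window_sigma = 3, n_bins = 18L,
                       weight = "pixel", coherence_floor = 0),
    lesion = list(smooth_sigma = 5, threshold_frac = 0.35,
                  open_radius = 4L, edge_erode_px = 1L,
                  min_component_px = 100L),
    stalls = list(drop_ratio = 0.25, merge_runs = FALSE,
                  dilate_px = 1, annulus = c(3, 6))
  ), class = "run_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' A run re-executed from its saved configuration and seed reproduces all
#' numeric outputs.
#'
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config(seed = cfg$seed %||% 1L)
  merged <- utils::modifyList(unclass(base), cfg)
  structure(merged, class = "run_config")
}

#' Run the full synthetic analysis pipeline
#'
#' Executes simulate, render, quality-filter, average, enhance, orient,
#' lesion and stall stages in order on a synthetic scene defined by the
#' configuration, and writes a machine-readable JSON report plus figure and
#' table files into `out_dir`. Every stage parameter and the MD5 checksum
#' of every written artifact are logged in the report, so a rerun with the
#' same configuration and seed is byte-reproducible.
#'
#' @param config a `run_config` from [default_config()] or [read_config()].
#' @param out_dir output directory (created if missing).
#' @param figures write PNG figures (orientation rendering, histogram).
#' @return the report, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile(),
                         figures = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logline <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S"), ..., "\n",
        file = log_path, append = TRUE)
  }

  sc <- config$scene
  spec <- scene_spec(
    grid_nx = sc$grid_nx, grid_ny = sc$grid_ny, grid_nz = sc$grid_nz,
    roi_size_um = sc$roi_size_um, n_segments = sc$n_segments,
    align_fraction = sc$align_fraction,
    lesion_radius_px = sc$lesion_radius_px,
    vessel_radius_px = sc$vessel_radius_px,
    vessel_intensity = sc$vessel_intensity,
    background_intensity = sc$background_intensity,
    noise_sigma = sc$noise_sigma,
    min_separation_px = sc$min_separation_px, seed = config$seed
  )

  stage <- function(name, expr) {
    logline("stage", name, "start")
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    logline("stage", name, "done")
    res
  }

  gen <- stage("simulate", generate_scene(spec))
  stall_spec <- stall_process_spec(
    n_frames = config$stall$n_frames, stall_prob = config$stall$stall_prob,
    stall_segment_fraction = config$stall$stall_segment_fraction,
    seed = config$seed + 1L
  )
  rendered <- stage("render",
                    render_angiogram_series(gen$scene, gen$truth,
                                            stall_spec, spec))
  series <- stage("quality",
                  quality_filter(rendered$series,
                                 max_kept = config$angio$max_kept,
                                 k = config$angio$quality_k))
  avg <- stage("average", average_series(series))

  en <- config$enhance
  enhanced <- stage("enhance",
                    enhance_vessels(avg, tubeness_sigma = en$tubeness_sigma,
                                    frangi_scales = en$frangi_scales,
                                    beta = en$frangi_beta))
  lesion <- stage("lesion", {
    if (sc$lesion_radius_px > 0) {
      segment_lesion(avg,
                     smooth_sigma = config$lesion$smooth_sigma,
                     threshold_frac = config$lesion$threshold_frac,
                     open_radius = config$lesion$open_radius,
                     edge_erode_px = config$lesion$edge_erode_px,
                     min_component_px = config$lesion$min_component_px)
    } else NULL
  })
  mask <- stage("mask",
                make_mask(enhanced, method = en$mask_method,
                          min_component_px = en$min_component_px,
                          lesion_mask = if (!is.null(lesion)) lesion$mask))
  graph <- stage("graph",
                 build_segment_graph(mask,
                                     min_length_px = en$min_segment_length_px))

  orient <- stage("orient", {
    st <- structure_tensor_orientation(enhanced,
                                       config$orientation$grad_sigma,
                                       config$orientation$window_sigma)
    center <- if (!is.null(lesion) && lesion$area_px > 0) lesion$center_xy
              else spec$lesion_center_xy
    beta <- synthesize_beta_map(dim(enhanced), center)
    theta <- theta_map(st$alpha, beta)
    dist <- angular_distribution(
      theta, mask, coherence = st$coherence,
      n_bins = config$orientation$n_bins,
      coherence_floor = config$orientation$coherence_floor,
      weight = config$orientation$weight,
      graph = if (config$orientation$weight == "segment") graph
    )
    list(st = st, beta = beta, theta = theta, dist = dist,
         center = center)
  })

  stalls <- stage("stalls", {
    traces <- segment_traces(series, graph, vessel_mask = mask,
                             dilate_px = config$stalls$dilate_px,
                             annulus = config$stalls$annulus)
    stall_statistics(traces, graph, mask, lesion = lesion,
                     drop_ratio = config$stalls$drop_ratio,
                     merge_runs = config$stalls$merge_runs,
                     px_area_um2 = prod(voxel_size_from_spec(spec)[2:3]))
  })

  # artifacts
  write_image_tiff(avg, file.path(out_dir, "enface_mean.tiff"))
  write_image_tiff(enhanced / max(max(enhanced), 1e-12),
                   file.path(out_dir, "enhanced.tiff"))
  write_image_tiff(mask$mask * 1, file.path(out_dir, "mask.tiff"))
  if (!is.null(lesion)) {
    write_image_tiff(lesion$mask * 1, file.path(out_dir, "lesion.tiff"))
  }
  write_distribution_csv(orient$dist,
                         file.path(out_dir, "orientation_histogram.csv"))
  write_segment_csv(graph, file.path(out_dir, "segments.csv"))
  write_ground_truth(rendered$truth,
                     file.path(out_dir, "ground_truth.json"))
  if (figures) {
    grDevices::png(file.path(out_dir, "orientation_hsv.png"),
                   width = spec$grid_nx * 3, height = spec$grid_ny * 3)
    rgb <- render_hsv(orient$theta, orient$st$coherence, enhanced)
    graphics::par(mar = c(0, 0, 0, 0))
    graphics::plot.new()
    graphics::rasterImage(aperm(rgb, c(2, 1, 3)), 0, 0, 1, 1)
    grDevices::dev.off()
    grDevices::png(file.path(out_dir, "orientation_histogram.png"),
                   width = 600, height = 400)
    n <- length(orient$dist$counts)
    mids <- (orient$dist$bin_edges[-1] + orient$dist$bin_edges[-(n + 1)]) / 2
    graphics::barplot(orient$dist$counts / sum(orient$dist$counts),
                      names.arg = signif(mids, 2),
                      xlab = expression(theta ~ "(rad)"),
                      ylab = "fraction of capillary pixels")
    grDevices::dev.off()
  }

  report <- list(
    config = unclass(config),
    n_kept_frames = sum(series$quality_flags),
    aligned_fraction = orient$dist$aligned_fraction,
    orientation_histogram = orient$dist$counts,
    lesion_area_px = if (!is.null(lesion)) lesion$area_px else 0L,
    lesion_center_xy = if (!is.null(lesion)) lesion$center_xy else NULL,
    n_segments = length(graph$segments),
    stall = list(
      n_events = stalls$n_events,
      n_stalled_segments = stalls$n_stalled_segments,
      n_segments_total = stalls$n_segments_total,
      event_density_per_px = stalls$event_density_per_px,
      event_density_per_mm2 = stalls$event_density_per_mm2,
      incidence = stalls$incidence,
      event_count_histogram = as.list(stalls$event_count_histogram)
    )
  )
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!basename(files) %in% c("report.json", "run.log")]
  report$checksums <- as.list(tools::md5sum(files))
  names(report$checksums) <- basename(files)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logline("pipeline complete")
  invisible(report)
}
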