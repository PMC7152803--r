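#' Specification of a synthetic cortical vascular scene
#'
#' Describes the acquisition geometry and scene content for the synthetic
#' data generator: a square region of cortex sampled on a lateral grid,
#' populated with straight capillary segments of controllable orientation
#' relative to an avascular ischemic lesion.
#'
#' The full acquisition geometry of the study this emulates is a
#' 1 mm x 1 mm region sampled as 450 B-frame positions of 500 A-lines each;
#' the generator defaults to a 128 x 128 grid so that complete pipelines run
#' in seconds, and the full-size grid is available by argument.
#'
#' @param grid_nx A-lines per B-frame (fast axis, first image index).
#' @param grid_ny B-frame positions (slow axis, second image index).
#' @param grid_nz axial pixels per A-line.
#' @param roi_size_um lateral extent of the field of view in micrometres
#'   (per axis).
#' @param n_segments number of capillary segments to place.
#' @param align_fraction fraction of segments laid exactly along the local
#'   direction toward the lesion center, in `[0, 1]`. The remainder receive
#'   an orientation offset drawn uniformly on `[-pi/2, pi/2)`.
#' @param lesion_center_xy pixel coordinates `(x, y)` of the lesion center;
#'   default is the grid center.
#' @param lesion_radius_px radius of the avascular disk in pixels
#'   (0 = no lesion).
#' @param vessel_radius_px tube radius in pixels; the default 1 gives
#'   3-pixel-wide tubes, about 6 um at 2 um/px, a realistic capillary
#'   diameter at this sampling.
#' @param vessel_intensity mean dynamic (decorrelation) signal of flowing
#'   vessels, arbitrary units.
#' @param background_intensity parenchyma (noise-floor) signal on rendered
#'   angiograms, same units.
#' @param static_amplitude structural backscatter amplitude of static
#'   tissue in complex B-frames. Static tissue scatters strongly (it only
#'   cancels on the angiogram because repeats are identical), so the
#'   default matches the vessel amplitude; the assumption behind global
#'   phase correction is that this static signal dominates the frame.
#' @param noise_sigma additive noise scale (complex-Gaussian per quadrature
#'   for B-frames, truncated Gaussian for rendered angiograms).
#' @param seg_length_px two-element range of segment lengths in pixels.
#' @param min_separation_px minimum gap (in pixels, beyond the tube radius)
#'   enforced between distinct segments; 0 (default) allows segments to
#'   touch and cross, as real capillary networks do. Positive values give
#'   non-touching tubes, useful for segment-level ground-truth checks.
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(grid_nx = 128L, grid_ny = 128L, grid_nz = 32L,
                       roi_size_um = 1000, n_segments = 200L,
                       align_fraction = 0,
                       lesion_center_xy = NULL, lesion_radius_px = 0,
                       vessel_radius_px = 1, vessel_intensity = 1,
                       background_intensity = 0.1, static_amplitude = 1,
                       noise_sigma = 0.02,
                       seg_length_px = c(10L, 20L),
                       min_separation_px = 0, seed = 1L) {
  stopifnot(
    grid_nx >= 8, grid_ny >= 8, grid_nz >= 4, n_segments >= 1,
    align_fraction >= 0, align_fraction <= 1,
    lesion_radius_px >= 0, vessel_radius_px >= 0,
    noise_sigma >= 0, length(seg_length_px) == 2
  )
  if (is.null(lesion_center_xy)) {
    lesion_center_xy <- c(round(grid_nx / 2), round(grid_ny / 2))
  }
  if (lesion_radius_px > 0) {
    cx <- lesion_center_xy[1]; cy <- lesion_center_xy[2]
    if (cx - lesion_radius_px < 1 || cx + lesion_radius_px > grid_nx ||
        cy - lesion_radius_px < 1 || cy + lesion_radius_px > grid_ny) {
      stop("lesion disk must lie inside the grid")
    }
  }
  if (lesion_radius_px >= max(grid_nx, grid_ny) / 2 &&
      lesion_radius_px^2 * pi >= 0.95 * grid_nx * grid_ny) {
    stop("lesion disk covers (almost) the whole grid: no vascularized area")
  }
  structure(list(
    grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
    grid_nz = as.integer(grid_nz), roi_size_um = roi_size_um,
    n_segments = as.integer(n_segments), align_fraction = align_fraction,
    lesion_center_xy = lesion_center_xy,
    lesion_radius_px = lesion_radius_px,
    vessel_radius_px = vessel_radius_px,
    vessel_intensity = vessel_intensity,
    background_intensity = background_intensity,
    static_amplitude = static_amplitude,
    noise_sigma = noise_sigma,
    seg_length_px = as.integer(seg_length_px),
    min_separation_px = min_separation_px,
    seed = as.integer(seed)
  ), class = "scene_spec")
}

#' Specification of the capillary stalling process
#'
#' @param n_frames length of the angiogram time series (default 60, the
#'   number of motion-artifact-free volumes retained per imaging session).
#' @param stall_prob per-segment, per-frame probability of a stalling event.
#' @param stall_segment_fraction fraction of segments eligible to stall.
#' @param seed integer RNG seed for the stall process.
#' @return object of class `stall_process_spec`.
#' @export
stall_process_spec <- function(n_frames = 60L, stall_prob = 0.05,
                               stall_segment_fraction = 0.25, seed = 1L) {
  stopifnot(
    n_frames >= 1,
    stall_prob >= 0, stall_prob <= 1,
    stall_segment_fraction >= 0, stall_segment_fraction <= 1
  )
  structure(list(
    n_frames = as.integer(n_frames), stall_prob = stall_prob,
    stall_segment_fraction = stall_segment_fraction,
    seed = as.integer(seed)
  ), class = "stall_process_spec")
}

#' Generate a synthetic capillary scene with ground truth
#'
#' Places straight capillary segments on the lateral grid. A fraction
#' `align_fraction` of segments is laid exactly along the direction from the
#' segment midpoint toward the lesion center (orientation offset theta = 0);
#' the rest get theta drawn uniformly on `[-pi/2, pi/2)`. Centerlines are
#' dilated to tubes of radius `vessel_radius_px`; no vessel pixel falls
#' inside the lesion disk.
#'
#' @param spec a [scene_spec()].
#' @return list with components
#'   \describe{
#'     \item{scene}{list: `vessel_mask` (logical nx-by-ny), `label` (integer
#'       nx-by-ny, 0 = background, otherwise segment id of the last segment
#'       painted), `segment_pixels` (per segment, linear pixel indices of its
#'       tube), `lesion_mask`, `spec`.}
#'     \item{truth}{ground truth: `segment_centerlines` (list of n-by-2
#'       integer matrices), `segment_theta` (radians in `[-pi/2, pi/2)`,
#'       orientation relative to the lesion-center direction),
#'       `segment_alpha` (absolute orientation), `lesion_mask`,
#'       `lesion_area_px`, `stall_log` (filled by
#'       [render_angiogram_series()]).}
#'   }
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  nx <- spec$grid_nx; ny <- spec$grid_ny
  cx <- spec$lesion_center_xy[1]; cy <- spec$lesion_center_xy[2]

  xg <- matrix(seq_len(nx), nx, ny)
  yg <- matrix(rep(seq_len(ny), each = nx), nx, ny)
  lesion_mask <- (xg - cx)^2 + (yg - cy)^2 <= spec$lesion_radius_px^2
  if (spec$lesion_radius_px <= 0) lesion_mask[] <- FALSE
  if (all(lesion_mask)) stop("lesion disk covers the whole grid")

  offsets <- disk_offsets(spec$vessel_radius_px)
  sep_off <- if (spec$min_separation_px > 0) {
    disk_offsets(spec$vessel_radius_px + spec$min_separation_px)
  } else offsets

  with_seed(spec$seed, {
    n <- spec$n_segments
    n_aligned <- round(spec$align_fraction * n)
    aligned <- seq_len(n) <= n_aligned   # deterministic partition

    label <- matrix(0L, nx, ny)
    occupied <- matrix(FALSE, nx, ny)    # tube + separation footprint
    vessel_mask <- matrix(FALSE, nx, ny)
    centerlines <- vector("list", n)
    seg_pixels <- vector("list", n)
    theta <- numeric(n)
    alpha <- numeric(n)

    margin <- spec$vessel_radius_px + 1
    placed <- 0L
    for (s in seq_len(n)) {
      len <- stats::runif(1, spec$seg_length_px[1], spec$seg_length_px[2])
      th <- if (aligned[s]) 0 else stats::runif(1, -pi / 2, pi / 2)
      ok <- FALSE
      for (try in seq_len(200L)) {
        mx <- stats::runif(1, 1 + margin, nx - margin)
        my <- stats::runif(1, 1 + margin, ny - margin)
        # midpoint outside the lesion (plus tube clearance); capillaries
        # may abut the rim but their centerline never crosses the disk
        if (spec$lesion_radius_px > 0 &&
            (mx - cx)^2 + (my - cy)^2 <=
              (spec$lesion_radius_px + margin)^2) next
        beta_mid <- atan2(cy - my, cx - mx)       # direction to center, mod pi below
        a <- wrap_orientation(beta_mid + th)
        x0 <- round(mx - len / 2 * cos(a)); x1 <- round(mx + len / 2 * cos(a))
        y0 <- round(my - len / 2 * sin(a)); y1 <- round(my + len / 2 * sin(a))
        if (min(x0, x1) < 1 || max(x0, x1) > nx ||
            min(y0, y1) < 1 || max(y0, y1) > ny) next
        cl <- bresenham_line(x0, y0, x1, y1)
        if (nrow(cl) < 3) next
        if (spec$lesion_radius_px > 0 && any(lesion_mask[cl])) next
        pix <- dilate_coords(cl, offsets, nx, ny)
        pix <- pix[!lesion_mask[pix]]
        if (length(pix) < 3) next
        if (spec$min_separation_px > 0) {
          foot <- dilate_coords(cl, sep_off, nx, ny)
          if (any(occupied[foot])) next
          occupied[foot] <- TRUE
        }
        placed <- placed + 1L
        centerlines[[s]] <- cl
        seg_pixels[[s]] <- pix
        theta[s] <- th
        alpha[s] <- a
        vessel_mask[pix] <- TRUE
        label[pix] <- s
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place segment ", s,
                    ": grid too crowded for the requested separation")
    }

    scene <- list(
      vessel_mask = vessel_mask, label = label,
      segment_pixels = seg_pixels, lesion_mask = lesion_mask, spec = spec
    )
    truth <- list(
      segment_centerlines = centerlines,
      segment_theta = theta,
      segment_alpha = alpha,
      aligned = aligned,
      lesion_mask = lesion_mask,
      lesion_area_px = sum(lesion_mask),
      lesion_center_xy = spec$lesion_center_xy,
      stall_log = NULL
    )
    list(scene = scene, truth = truth)
  })
}

#' Render one repeated complex B-frame pair
#'
#' Simulates the two B-scans acquired back-to-back at one slow-axis
#' position. Static tissue has identical complex amplitude in both repeats
#' (up to additive complex noise); vessel voxels are redrawn independently
#' per repeat (full decorrelation of moving blood). The entire second frame
#' is multiplied by `exp(1i * bulk_phase)`, emulating the global phase
#' fluctuation caused by sub-pixel bulk motion between repeats.
#'
#' Vessels occupy an axial band of half-width `vessel_radius_px` around the
#' focal plane (`grid_nz %/% 2`), i.e. the scene is a thin 3-D slab.
#'
#' @param scene scene component from [generate_scene()].
#' @param position_index slow-axis position (1-based, `<= grid_ny`).
#' @param bulk_phase global phase offset applied to the second repeat
#'   (radians).
#' @param spec the [scene_spec()] used to build the scene.
#' @param seed RNG seed for speckle, decorrelation draws and noise.
#' @return object of class `bframe_pair`: list with complex matrices
#'   `frame_a`, `frame_b` of dim `(grid_nz, grid_nx)` and `position_index`.
#' @export
render_bframe_pair <- function(scene, position_index, bulk_phase = 0,
                               spec = scene$spec, seed = spec$seed) {
  stopifnot(position_index >= 1, position_index <= spec$grid_ny)
  nz <- spec$grid_nz; nx <- spec$grid_nx
  focal_z <- nz %/% 2L
  zr <- max(0L, floor(spec$vessel_radius_px))
  zband <- pmax(1L, focal_z - zr):pmin(nz, focal_z + zr)

  vessel_col <- scene$vessel_mask[, position_index]      # length nx
  vmask <- matrix(FALSE, nz, nx)
  vmask[zband, vessel_col] <- TRUE

  with_seed(seed + 7L * position_index, {
    # static field: amplitude speckle about the structural level, fixed phase
    amp <- (spec$static_amplitude %||% spec$vessel_intensity) *
      (1 + 0.2 * stats::rnorm(nz * nx))
    phs <- stats::runif(nz * nx, -pi, pi)
    static <- matrix(complex(modulus = abs(amp), argument = phs), nz, nx)

    draw_vessels <- function() {
      k <- sum(vmask)
      complex(modulus = spec$vessel_intensity *
                abs(1 + 0.2 * stats::rnorm(k)),
              argument = stats::runif(k, -pi, pi))
    }
    frame_a <- static
    frame_b <- static
    if (any(vmask)) {
      frame_a[vmask] <- draw_vessels()
      frame_b[vmask] <- draw_vessels()
    }
    if (spec$noise_sigma > 0) {
      frame_a <- frame_a + matrix(complex(
        real = stats::rnorm(nz * nx, sd = spec$noise_sigma),
        imaginary = stats::rnorm(nz * nx, sd = spec$noise_sigma)), nz, nx)
      frame_b <- frame_b + matrix(complex(
        real = stats::rnorm(nz * nx, sd = spec$noise_sigma),
        imaginary = stats::rnorm(nz * nx, sd = spec$noise_sigma)), nz, nx)
    }
    frame_b <- frame_b * exp(1i * bulk_phase)
    structure(list(frame_a = frame_a, frame_b = frame_b,
                   position_index = as.integer(position_index)),
              class = "bframe_pair")
  })
}

#' Render a stall-bearing en-face angiogram time series
#'
#' Produces `n_frames` en-face angiogram frames. In each frame, pixels of
#' flowing segments are drawn from the vessel intensity distribution and
#' background pixels from the parenchyma distribution. When a segment
#' stalls in a frame (red-blood-cell flow interrupted), all of its pixels
#' are drawn from the background distribution, so the segment disappears
#' into the parenchyma, as stalled capillaries do on decorrelation
#' angiograms. Stall frames are sampled per eligible segment as independent
#' Bernoulli(`stall_prob`) draws and recorded in the returned ground truth.
#'
#' @param scene,truth output of [generate_scene()].
#' @param stall a [stall_process_spec()].
#' @param spec the [scene_spec()].
#' @return list with
#'   \describe{
#'     \item{series}{an `angiogram_series` of 2-D en-face frames; frame
#'       times assume one 10-s volume per frame.}
#'     \item{truth}{the input truth with `stall_log` filled: per segment an
#'       integer vector of stalled frame indices.}
#'   }
#' @export
render_angiogram_series <- function(scene, truth, stall, spec = scene$spec) {
  stopifnot(inherits(stall, "stall_process_spec"))
  n <- spec$n_segments
  nf <- stall$n_frames
  nx <- spec$grid_nx; ny <- spec$grid_ny

  with_seed(stall$seed, {
    n_elig <- round(stall$stall_segment_fraction * n)
    eligible <- sample.int(n, n_elig)
    stall_log <- vector("list", n)
    for (s in seq_len(n)) stall_log[[s]] <- integer(0)
    if (stall$stall_prob > 0 && n_elig > 0) {
      for (s in eligible) {
        stalled <- which(stats::runif(nf) < stall$stall_prob)
        stall_log[[s]] <- stalled
      }
    }

    frames <- vector("list", nf)
    for (f in seq_len(nf)) {
      img <- matrix(spec$background_intensity, nx, ny)
      for (s in seq_len(n)) {
        if (f %in% stall_log[[s]]) next
        img[scene$segment_pixels[[s]]] <- spec$vessel_intensity
      }
      # stalled segments painted last: every one of their pixels is at
      # background level in that frame, including pixels shared with
      # flowing segments
      for (s in seq_len(n)) {
        if (f %in% stall_log[[s]]) {
          img[scene$segment_pixels[[s]]] <- spec$background_intensity
        }
      }
      if (spec$noise_sigma > 0) {
        img <- img + matrix(stats::rnorm(nx * ny, sd = spec$noise_sigma),
                            nx, ny)
        img[img < 0] <- 0
      }
      frames[[f]] <- img
    }
    truth$stall_log <- stall_log
    truth$eligible_segments <- sort(eligible)
    series <- angiogram_series(frames,
                               frame_times_s = (seq_len(nf) - 1) * 10,
                               voxel_size_um = voxel_size_from_spec(spec))
    list(series = series, truth = truth)
  })
}

#' Reconstruct an angiogram volume from simulated B-frame pairs
#'
#' Convenience wrapper for end-to-end tests: renders a B-frame pair at every
#' slow-axis position (with per-position random bulk phase), applies
#' GPF correction, computes the decorrelation cross-section, and stacks the
#' result into an `angiogram_volume` with axes `(z, x, y)`.
#'
#' @param scene,spec as in [render_bframe_pair()].
#' @param bulk_phase_sd standard deviation of the per-position random bulk
#'   phase (radians).
#' @param seed RNG seed.
#' @param gpf_scope passed to [correct_gpf()].
#' @return an `angiogram_volume`.
#' @export
simulate_volume <- function(scene, spec = scene$spec, bulk_phase_sd = 0.5,
                            seed = spec$seed, gpf_scope = "aline") {
  nz <- spec$grid_nz; nx <- spec$grid_nx; ny <- spec$grid_ny
  phases <- with_seed(seed + 13L,
                      stats::rnorm(ny, sd = bulk_phase_sd))
  vol <- array(0, c(nz, nx, ny))
  for (y in seq_len(ny)) {
    pair <- render_bframe_pair(scene, y, bulk_phase = phases[y],
                               spec = spec, seed = seed)
    pair <- correct_gpf(pair, scope = gpf_scope)
    vol[, , y] <- compute_angiogram(pair)
  }
  angiogram_volume(vol, voxel_size_um = voxel_size_from_spec(spec),
                   focal_z = nz %/% 2L)
}

voxel_size_from_spec <- function(spec) {
  c(axial = 8.3 / 2,
    x = spec$roi_size_um / spec$grid_nx,
    y = spec$roi_size_um / spec$grid_ny)
}
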