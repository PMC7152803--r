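#' Angiogram containers
#'
#' `angiogram_volume()` wraps a non-negative 3-D decorrelation-intensity
#' array with axes `(z, x, y)` (z increases downward from the first axial
#' pixel) plus voxel geometry. `angiogram_series()` wraps an ordered list of
#' frames (3-D volumes or 2-D en-face images) with acquisition times and
#' per-frame quality flags.
#'
#' The default axial sampling is 8.3/2 = 4.15 um per pixel (an axial
#' resolution of 8.3 um spanning 2 pixels on the tomogram).
#'
#' @param data non-negative numeric array, dim `(z, x, y)`.
#' @param voxel_size_um voxel pitch `(axial, lateral x, lateral y)` in um.
#' @param surface_z axial index of the cortical surface (optional).
#' @param focal_z axial index of the focal plane (optional).
#' @return an `angiogram_volume`.
#' @export
angiogram_volume <- function(data, voxel_size_um = c(4.15, 2, 2),
                             surface_z = 1L, focal_z = NULL) {
  stopifnot(length(dim(data)) == 3, all(is.finite(data)), all(data >= 0))
  structure(list(
    data = data, voxel_size_um = voxel_size_um,
    surface_z = as.integer(surface_z),
    focal_z = if (is.null(focal_z)) dim(data)[1] %/% 2L else as.integer(focal_z)
  ), class = "angiogram_volume")
}

#' @rdname angiogram_volume
#' @param frames list of numeric arrays (all the same dimension).
#' @param frame_times_s acquisition start times, strictly increasing.
#' @param quality_flags logical per-frame kept/discarded flags.
#' @export
angiogram_series <- function(frames, frame_times_s = NULL,
                             quality_flags = NULL,
                             voxel_size_um = c(4.15, 2, 2)) {
  stopifnot(is.list(frames), length(frames) >= 1)
  if (is.null(frame_times_s)) frame_times_s <- (seq_along(frames) - 1) * 10
  stopifnot(length(frame_times_s) == length(frames),
            all(diff(frame_times_s) > 0))
  if (is.null(quality_flags)) quality_flags <- rep(TRUE, length(frames))
  structure(list(
    frames = frames, frame_times_s = frame_times_s,
    quality_flags = quality_flags, voxel_size_um = voxel_size_um
  ), class = "angiogram_series")
}

#' @export
length.angiogram_series <- function(x) length(x$frames)

#' Correct global phase fluctuations between repeated B-frames
#'
#' Sub-pixel bulk motion between the two repeats adds a global phase offset
#' to the second frame, which would masquerade as decorrelation everywhere.
#' Under the assumption that dynamic (flowing) tissue occupies only a small
#' fraction of the frame, the offset is estimated from the phase of
#' `sum(frame_a * Conj(frame_b))` — static tissue dominates the sum — and
#' the second frame is rotated back by that phase, driving the static-tissue
#' inter-frame phase difference to zero. Estimation is per A-line by
#' default (robust to line-to-line jitter) or per frame.
#'
#' @param pair a `bframe_pair`.
#' @param scope `"aline"` (one phase per A-line column) or `"frame"` (one
#'   global phase).
#' @return the pair with `frame_b` corrected; the applied phase(s) are
#'   attached as attribute `gpf_phase` (so that `-gpf_phase` estimates the
#'   bulk phase of the input).
#' @export
correct_gpf <- function(pair, scope = c("aline", "frame")) {
  scope <- match.arg(scope)
  stopifnot(inherits(pair, "bframe_pair"))
  a <- pair$frame_a; b <- pair$frame_b
  stopifnot(identical(dim(a), dim(b)))
  if (all(a == 0) && all(b == 0)) stop("degenerate pair: all zeros")
  if (scope == "frame") {
    s <- sum(a * Conj(b))
    phi <- if (Mod(s) == 0) 0 else Arg(s)
    b <- b * exp(1i * phi)
  } else {
    s <- colSums(a * Conj(b))
    phi <- ifelse(Mod(s) == 0, 0, Arg(s))
    if (any(Mod(s) == 0)) {
      message("zero-energy A-line(s): GPF correction phase set to 0 for ",
              sum(Mod(s) == 0), " line(s)")
    }
    b <- b * matrix(exp(1i * phi), nrow(b), ncol(b), byrow = TRUE)
  }
  out <- pair
  out$frame_b <- b
  attr(out, "gpf_phase") <- phi
  out
}

#' Decorrelation angiogram cross-section from a corrected B-frame pair
#'
#' Moving red blood cells change both the phase and the intensity of the
#' backscattered light between repeats, while static tissue (after GPF
#' correction) does not. The per-pixel magnitude of the complex difference
#' `|frame_a - frame_b|` captures both change channels jointly and is zero
#' on static tissue.
#'
#' @param pair a GPF-corrected `bframe_pair`.
#' @param channels `"complex"` (default) for `|a - b|`; `"split"` returns a
#'   list with separate `|d phase|` and `|d intensity|` diagnostic images.
#' @return non-negative matrix over `(z, x)`, or a list of two for
#'   `channels = "split"`.
#' @export
compute_angiogram <- function(pair, channels = c("complex", "split")) {
  channels <- match.arg(channels)
  a <- pair$frame_a; b <- pair$frame_b
  stopifnot(identical(dim(a), dim(b)))
  if (channels == "complex") return(Mod(a - b))
  list(dphase = abs(wrap_angle_pi(Arg(a) - Arg(b))),
       dintensity = abs(Mod(a) - Mod(b)))
}

## wrap into (-pi, pi]
wrap_angle_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Smooth an angiogram volume with an isotropic 3-D Gaussian
#'
#' Standard deviation 1 pixel in all three dimensions (index space), the
#' standard post-processing step for decorrelation volumes. Total intensity
#' is preserved up to boundary effects.
#'
#' @param vol an `angiogram_volume` (or bare 3-D array).
#' @param sigma kernel standard deviation in pixels.
#' @return smoothed object of the same class.
#' @export
smooth_volume <- function(vol, sigma = 1) {
  a <- if (inherits(vol, "angiogram_volume")) vol$data else vol
  stopifnot(length(dim(a)) == 3)
  sm <- gaussian_filter(a, sigma = sigma)
  if (inherits(vol, "angiogram_volume")) {
    vol$data <- sm
    vol
  } else sm
}

#' Average the kept frames of an angiogram series
#'
#' Voxel-wise mean over frames flagged as kept, the SNR-raising
#' preprocessing step before orientation analysis (averaging the 60
#' retained volumes reduces uncorrelated noise by about `sqrt(60)`).
#'
#' @param series an `angiogram_series`.
#' @return mean frame: an `angiogram_volume` for 3-D frames, a matrix for
#'   en-face series.
#' @export
average_series <- function(series) {
  stopifnot(inherits(series, "angiogram_series"))
  kept <- which(series$quality_flags)
  if (length(kept) == 0) stop("no kept frames to average")
  acc <- series$frames[[kept[1]]] * 0
  for (i in kept) acc <- acc + series$frames[[i]]
  avg <- acc / length(kept)
  if (length(dim(avg)) == 3) {
    angiogram_volume(avg, voxel_size_um = series$voxel_size_um)
  } else avg
}

#' En-face maximum intensity projection over a focal depth band
#'
#' Flattens a volume to 2-D by the per-(x, y) maximum over an axial band of
#' `center_z` plus/minus `half_band_px` pixels (inclusive; the default 15
#' gives a 31-slice band around the focal plane).
#'
#' @param vol an `angiogram_volume`.
#' @param center_z axial center of the band (default: the focal plane).
#' @param half_band_px half-width of the band in pixels.
#' @return object of class `enface_map`: list with `image` (nx-by-ny
#'   matrix), `depth_band_px` (half-open `(z_lo, z_hi)`) and
#'   `depth_band_um` (relative to the cortical surface).
#' @export
mip_enface <- function(vol, center_z = NULL, half_band_px = 15L) {
  stopifnot(inherits(vol, "angiogram_volume"))
  if (is.null(center_z)) center_z <- vol$focal_z
  nz <- dim(vol$data)[1]
  z_lo <- center_z - half_band_px
  z_hi_incl <- center_z + half_band_px
  if (z_lo < 1 || z_hi_incl > nz) {
    stop("depth band [", z_lo, ", ", z_hi_incl, "] outside volume (nz = ",
         nz, ")")
  }
  img <- apply(vol$data[z_lo:z_hi_incl, , , drop = FALSE], c(2, 3), max)
  um_per_px <- vol$voxel_size_um[1]
  structure(list(
    image = img,
    depth_band_px = c(z_lo, z_hi_incl + 1L),
    depth_band_um = (c(z_lo, z_hi_incl + 1L) - vol$surface_z) * um_per_px
  ), class = "enface_map")
}

#' Deterministic quality filter for angiogram series
#'
#' Automated stand-in for the manual rejection of motion-corrupted volumes:
#' a frame is discarded when its whole-frame mean intensity deviates from
#' the series median by more than `k` times the series MAD. The first
#' `max_kept` passing frames are retained, preserving order (matching the
#' protocol of keeping the first 60 artifact-free volumes).
#'
#' @param series an `angiogram_series`.
#' @param max_kept maximum number of frames to keep (default 60).
#' @param k MAD multiple for the rejection rule.
#' @param keep_list optional explicit integer vector of frame indices to
#'   keep, overriding the automated rule.
#' @return the series with updated `quality_flags`.
#' @export
quality_filter <- function(series, max_kept = 60L, k = 5, keep_list = NULL) {
  stopifnot(inherits(series, "angiogram_series"))
  n <- length(series$frames)
  if (!is.null(keep_list)) {
    flags <- rep(FALSE, n)
    flags[keep_list] <- TRUE
  } else {
    m <- vapply(series$frames, mean, numeric(1))
    med <- stats::median(m)
    s <- stats::mad(m)
    pass <- if (s == 0) rep(TRUE, n) else abs(m - med) <= k * s
    keep <- which(pass)
    if (length(keep) < max_kept) {
      warning("only ", length(keep), " frames pass the quality rule ",
              "(requested ", max_kept, "); keeping all passing frames")
    }
    keep <- utils::head(keep, max_kept)
    flags <- rep(FALSE, n)
    flags[keep] <- TRUE
  }
  series$quality_flags <- flags
  series
}

#' Acquisition timing implied by the scan geometry
#'
#' With `n_positions` slow-axis positions, each B-scan repeated
#' `n_repeats` times at a fast-axis rate of `fast_rate_hz` B-frames per
#' second, one volumetric scan takes `n_positions * n_repeats /
#' fast_rate_hz` seconds. The study geometry (450 positions, 2 repeats,
#' 90 Hz) gives 10 s per volume and 16.7 min for a 100-volume series.
#'
#' @param n_positions slow-axis B-frame positions per volume.
#' @param n_repeats repeated B-scans per position.
#' @param fast_rate_hz fast-axis B-frame rate in Hz.
#' @param n_volumes number of repeated volumetric scans.
#' @return list with `volume_time_s` and `series_time_min`.
#' @export
acquisition_time <- function(n_positions = 450, n_repeats = 2,
                             fast_rate_hz = 90, n_volumes = 100) {
  volume_time_s <- n_positions * n_repeats / fast_rate_hz
  list(volume_time_s = volume_time_s,
       series_time_min = volume_time_s * n_volumes / 60)
}
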