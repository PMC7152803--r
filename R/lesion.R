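#' Segment the avascular ischemic lesion on an en-face angiogram
#'
#' The photothrombotic lesion appears as a large, dark, vessel-free region.
#' This automated surrogate for manual delineation smooths the en-face map
#' (so inter-capillary gaps are filled by smeared vessel signal while the
#' lesion stays at the parenchyma level), thresholds below an adaptive
#' level, morphologically opens the result, keeps the connected component
#' with the largest integrated darkness and fills its holes.
#'
#' The threshold is `q_lo + threshold_frac * (q_hi - q_lo)` where `q_lo`
#' and `q_hi` are low/high quantiles of the smoothed image, so it adapts to
#' any lesion size instead of assuming a fixed dark-pixel fraction.
#'
#' Because a blurred edge crosses a sub-midpoint threshold slightly
#' outside the true boundary, the final mask is eroded by
#' `edge_erode_px` to remove the smoothing-induced outward bias. A
#' morphological opening (rather than closing) follows thresholding, so
#' thin dark bridges to chance vessel-sparse pockets are cut instead of
#' being annexed into the lesion.
#'
#' @param enface en-face image (matrix or `enface_map`).
#' @param vessel_mask optional `vessel_mask`; when given, vessel pixels are
#'   excluded from the lesion candidate region.
#' @param smooth_sigma Gaussian smoothing scale in pixels.
#' @param threshold_frac position of the threshold between the dark and
#'   bright quantiles, in `(0, 1)`.
#' @param quantiles the `(low, high)` reference quantiles.
#' @param open_radius radius of the morphological opening brush (px).
#' @param edge_erode_px erosion of the final mask compensating the
#'   smoothing-induced outward edge bias.
#' @param min_component_px minimum lesion size; below it an empty mask is
#'   returned with a warning.
#' @param min_mass_frac minimum integrated darkness of the selected
#'   component, as a fraction of image area times the inter-quantile
#'   intensity spread; below it the image is declared lesion-free.
#' @return object of class `lesion_mask`: list with `mask`, `area_px`,
#'   `center_xy` (centroid), `source = "automated"`.
#' @export
segment_lesion <- function(enface, vessel_mask = NULL, smooth_sigma = 5,
                           threshold_frac = 0.35,
                           quantiles = c(0.02, 0.75), open_radius = 4L,
                           edge_erode_px = 1L, min_component_px = 100L,
                           min_mass_frac = 0.03) {
  if (inherits(enface, "enface_map")) enface <- enface$image
  stopifnot(is.matrix(enface))
  sm <- gaussian_filter(enface, smooth_sigma)
  q <- stats::quantile(sm, quantiles, names = FALSE)
  thr <- q[1] + threshold_frac * (q[2] - q[1])
  cand <- sm < thr
  if (!is.null(vessel_mask)) {
    vm <- if (inherits(vessel_mask, "vessel_mask")) vessel_mask$mask else vessel_mask
    cand <- cand & !vm
  }
  empty <- function() {
    warning("no lesion component above minimum size; returning empty mask")
    structure(list(mask = matrix(FALSE, nrow(enface), ncol(enface)),
                   area_px = 0L, center_xy = c(NA_real_, NA_real_),
                   source = "automated", threshold_used = thr),
              class = "lesion_mask")
  }
  if (!any(cand)) return(empty())
  img <- EBImage::Image(cand * 1)
  if (open_radius >= 1) {
    img <- EBImage::opening(img,
                            EBImage::makeBrush(2L * open_radius + 1L, "disc"))
  }
  lab <- EBImage::bwlabel(img)
  labv <- as.integer(lab)
  sizes <- tabulate(labv)
  if (length(sizes) == 0 || max(sizes) < min_component_px) return(empty())
  # pick the component with the largest integrated darkness below the
  # threshold: the lesion core is both large and deep, while chance
  # vessel-sparse pockets are shallow
  depth <- thr - as.vector(sm)
  mass <- tapply(depth[labv > 0], labv[labv > 0], sum)
  mass[sizes[as.integer(names(mass))] < min_component_px] <- -Inf
  big <- as.integer(names(which.max(mass)))
  # "no lesion" guard: a real lesion is both extended and deep, so its
  # integrated darkness is a sizeable fraction of image area x intensity
  # spread; chance vessel-sparse pockets fall an order of magnitude short
  mass_frac <- mass[[as.character(big)]] /
    (length(labv) * max(q[2] - q[1], .Machine$double.eps))
  if (!is.finite(mass_frac) || mass_frac < min_mass_frac) return(empty())
  comp <- EBImage::Image((labv == big) * 1, dim = dim(enface))
  comp <- EBImage::fillHull(comp)
  if (edge_erode_px >= 1) {
    comp <- EBImage::erode(
      comp, EBImage::makeBrush(2L * edge_erode_px + 1L, "disc"))
  }
  mask <- matrix(as.integer(comp) == 1L, nrow(enface), ncol(enface))
  structure(list(mask = mask, area_px = sum(mask),
                 center_xy = mask_centroid(mask),
                 source = "automated", threshold_used = thr),
            class = "lesion_mask")
}

#' Load a manually drawn lesion mask
#'
#' Manual delineation remains the authoritative path (the automated
#' segmentation is a deterministic surrogate); this reads a binary mask
#' image (TIFF) drawn externally.
#'
#' @param path path to a single-page TIFF containing 0/1 (or 0/255) values.
#' @param expected_dim optional `(nx, ny)` to validate against.
#' @return a `lesion_mask` with `source = "manual"`.
#' @export
load_manual_lesion <- function(path, expected_dim = NULL) {
  img <- read_image_tiff(path)
  u <- sort(unique(as.vector(img)))
  if (length(u) > 2) stop("manual lesion mask is not binary")
  mask <- if (max(u) > 0) img == max(u) else img > 0
  if (!is.null(expected_dim) && !identical(dim(mask), as.integer(expected_dim))) {
    stop("manual lesion mask shape ", paste(dim(mask), collapse = "x"),
         " does not match expected ", paste(expected_dim, collapse = "x"))
  }
  structure(list(mask = mask, area_px = sum(mask),
                 center_xy = if (any(mask)) mask_centroid(mask)
                             else c(NA_real_, NA_real_),
                 source = "manual"),
            class = "lesion_mask")
}

#' Longitudinal lesion-area trajectory, normalized to a reference day
#'
#' Normalizes the lesion area at each depth by its value at the reference
#' day (day 8 by default, the first session at which the whole lesion fits
#' in the field of view), and emits the between-depth scatter pairs used to
#' compare lesion extent across cortical depths.
#'
#' @param areas data.frame with columns `day`, `depth_um`, `area_px`.
#' @param reference_day day whose area defines 1.0 per depth.
#' @return object of class `lesion_trajectory`: list with `table` (the
#'   input plus `normalized_area`) and `depth_pairs` (data.frame of
#'   `day`, `depth_lo`, `depth_hi`, `area_lo`, `area_hi` for consecutive
#'   depth pairs).
#' @export
lesion_trajectory <- function(areas, reference_day = 8) {
  stopifnot(all(c("day", "depth_um", "area_px") %in% names(areas)),
            all(areas$area_px >= 0))
  depths <- sort(unique(areas$depth_um))
  out <- areas[order(areas$depth_um, areas$day), , drop = FALSE]
  out$normalized_area <- NA_real_
  for (d in depths) {
    i <- out$depth_um == d
    ref <- out$area_px[i & out$day == reference_day]
    if (length(ref) != 1) {
      stop("reference day ", reference_day, " missing for depth ", d)
    }
    if (ref == 0) {
      warning("reference area is 0 at depth ", d,
              "; normalization undefined")
      next
    }
    out$normalized_area[i] <- out$area_px[i] / ref
  }
  pairs <- NULL
  if (length(depths) >= 2) {
    for (j in seq_len(length(depths) - 1)) {
      lo <- depths[j]; hi <- depths[j + 1]
      a_lo <- out[out$depth_um == lo, c("day", "area_px")]
      a_hi <- out[out$depth_um == hi, c("day", "area_px")]
      m <- merge(a_lo, a_hi, by = "day", suffixes = c("_lo", "_hi"))
      if (nrow(m) > 0) {
        pairs <- rbind(pairs, data.frame(
          day = m$day, depth_lo = lo, depth_hi = hi,
          area_lo = m$area_px_lo, area_hi = m$area_px_hi))
      }
    }
  }
  structure(list(table = out, depth_pairs = pairs,
                 reference_day = reference_day),
            class = "lesion_trajectory")
}
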