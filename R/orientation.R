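#' Local orientation and coherence from the structure tensor
#'
#' The structure tensor is the Gaussian-windowed outer product of the image
#' gradient, `J = G(window_sigma) * [Ix^2, IxIy; IxIy, Iy^2]` with
#' Gaussian-derivative gradients at scale `grad_sigma`. Its minor
#' eigenvector points along coherent structures (a vessel's axis), giving
#' the local orientation `alpha = 0.5 * atan2(-2 Jxy, Jyy - Jxx)` in
#' `[-pi/2, pi/2)` measured from the x axis (first image index; the y axis
#' points down in image convention). Coherence is the normalized eigenvalue
#' contrast `(lmax - lmin) / (lmax + lmin)` in `[0, 1]`, set to 0 where the
#' tensor trace is below `eps` (featureless regions).
#'
#' @param image 2-D numeric matrix (vessel-enhanced en-face angiogram).
#' @param grad_sigma Gaussian-derivative scale for the gradients (px).
#' @param window_sigma Gaussian window for tensor averaging (px).
#' @param eps tensor-trace floor below which coherence is defined as 0.
#' @return list with matrices `alpha` (radians in `[-pi/2, pi/2)`) and
#'   `coherence` (in `[0, 1]`).
#' @export
structure_tensor_orientation <- function(image, grad_sigma = 1,
                                         window_sigma = 3,
                                         eps = 1e-12) {
  stopifnot(is.matrix(image))
  Ix <- gaussian_filter(image, grad_sigma, order = c(1L, 0L))
  Iy <- gaussian_filter(image, grad_sigma, order = c(0L, 1L))
  Jxx <- gaussian_filter(Ix * Ix, window_sigma)
  Jxy <- gaussian_filter(Ix * Iy, window_sigma)
  Jyy <- gaussian_filter(Iy * Iy, window_sigma)
  tr <- Jxx + Jyy
  disc <- sqrt(pmax(0, (Jxx - Jyy)^2 + 4 * Jxy^2))
  coherence <- ifelse(tr < eps, 0, disc / pmax(tr, eps))
  # structure along u = (cos a, sin a) has gradients along (-sin a, cos a):
  # Jyy - Jxx = k cos 2a, -2 Jxy = k sin 2a
  alpha <- wrap_orientation(0.5 * atan2(-2 * Jxy, Jyy - Jxx))
  list(alpha = alpha, coherence = coherence)
}

#' Synthesize the lesion-center orientation map (beta)
#'
#' For each pixel, the orientation (modulo pi) of the line through the
#' pixel and the lesion center: `beta = atan2(cy - py, cx - px)` reduced
#' into `[-pi/2, pi/2)`. Undirected, matching the modulo-pi nature of the
#' structure-tensor orientation, so the map is symmetric under point
#' reflection through the center. A pixel coinciding with the center gets
#' `beta = 0` and is flagged.
#'
#' @param shape integer vector `(nx, ny)`.
#' @param center_xy lesion-center pixel coordinates `(cx, cy)`; may lie
#'   outside the image.
#' @return matrix of orientations in `[-pi/2, pi/2)`; pixels coinciding
#'   with the center are listed in attribute `center_pixels`.
#' @export
synthesize_beta_map <- function(shape, center_xy) {
  nx <- shape[1]; ny <- shape[2]
  px <- matrix(seq_len(nx), nx, ny)
  py <- matrix(rep(seq_len(ny), each = nx), nx, ny)
  dx <- center_xy[1] - px
  dy <- center_xy[2] - py
  beta <- wrap_orientation(atan2(dy, dx))
  at_center <- dx == 0 & dy == 0
  beta[at_center] <- 0
  attr(beta, "center_pixels") <- which(at_center)
  beta
}

#' Orientation relative to the lesion-center direction (theta)
#'
#' `theta = alpha - beta`, wrapped into `[-pi/2, pi/2)`. Theta = 0 means
#' the local structure points along the line toward the ischemic center.
#'
#' @param alpha,beta orientation matrices of equal shape (radians).
#' @return matrix of wrapped differences.
#' @export
theta_map <- function(alpha, beta) {
  stopifnot(identical(dim(alpha), dim(beta)))
  wrap_orientation(alpha - beta)
}

#' Angular distribution of capillary orientation
#'
#' Histogram of theta over vessel pixels and the aligned fraction: the
#' proportion of vessel pixels whose orientation relative to the ischemic
#' center is within `+/- pi/12` (15 degrees, ~0.26 rad), the study's
#' radial-reorganization statistic.
#'
#' Weighting is per pixel by default. With `weight = "segment"` and a
#' [build_segment_graph()] graph, each capillary segment contributes one
#' orientation value, which is the right unit of replication for
#' distribution-level inference: pixels of one segment share a single
#' orientation, and the structure-tensor window additionally couples
#' nearby pixels. The per-segment value is the segment's principal-axis
#' orientation minus the lesion-direction `beta` at the segment (supply
#' `beta`); when `beta` is not given, the coherence-weighted circular mean
#' of the theta map over the segment's skeleton pixels is used instead.
#'
#' @param theta orientation map from [theta_map()].
#' @param mask a `vessel_mask` or logical matrix selecting vessel pixels.
#' @param coherence optional coherence map; pixels below `coherence_floor`
#'   are excluded (and the map weights the segment circular mean).
#' @param n_bins number of histogram bins spanning `[-pi/2, pi/2]`.
#' @param coherence_floor minimum coherence for inclusion (default 0: no
#'   gating).
#' @param weight `"pixel"` or `"segment"`.
#' @param graph `segment_graph`, required for `weight = "segment"`.
#' @param beta optional beta map; with a graph, enables the geometric
#'   per-segment orientation (chain principal axis relative to the
#'   lesion direction), which is free of tensor-window cross-talk
#'   between adjacent capillaries.
#' @return object of class `angular_distribution`: list with `bin_edges`,
#'   `counts`, `aligned_fraction`, `n`, `weight`.
#' @export
angular_distribution <- function(theta, mask, coherence = NULL,
                                 n_bins = 18L, coherence_floor = 0,
                                 weight = c("pixel", "segment"),
                                 graph = NULL, beta = NULL) {
  weight <- match.arg(weight)
  if (inherits(mask, "vessel_mask")) mask <- mask$mask
  stopifnot(identical(dim(theta), dim(mask)))
  sel <- mask
  if (!is.null(coherence) && coherence_floor > 0) {
    sel <- sel & coherence >= coherence_floor
  }
  if (weight == "pixel") {
    vals <- theta[sel]
  } else {
    stopifnot(inherits(graph, "segment_graph"))
    vals <- vapply(graph$segments, function(s) {
      px <- s$pixels
      if (!is.null(beta)) {
        return(wrap_orientation(
          s$orientation - circ_mean_orientation(beta[px])))
      }
      w <- if (is.null(coherence)) rep(1, nrow(px)) else coherence[px]
      if (sum(w) == 0) return(NA_real_)
      t2 <- theta[px]
      wrap_orientation(
        atan2(sum(w * sin(2 * t2)), sum(w * cos(2 * t2))) / 2)
    }, numeric(1))
    vals <- vals[!is.na(vals)]
  }
  if (length(vals) == 0) stop("no vessel pixels selected")
  edges <- seq(-pi / 2, pi / 2, length.out = n_bins + 1)
  counts <- as.integer(table(cut(vals, edges, include.lowest = TRUE)))
  structure(list(
    bin_edges = edges, counts = counts,
    aligned_fraction = mean(abs(vals) <= pi / 12),
    n = length(vals), weight = weight
  ), class = "angular_distribution")
}

## Circular mean of undirected orientations via the double-angle trick.
circ_mean_orientation <- function(x) {
  wrap_orientation(0.5 * atan2(mean(sin(2 * x)), mean(cos(2 * x))))
}

#' HSV rendering of the orientation map
#'
#' Encodes orientation as hue (`(theta + pi/2) / pi`, so -pi/2 and +pi/2
#' wrap to the same point of the color wheel), coherence as saturation and
#' normalized image brightness as value, then converts to RGB.
#'
#' @param theta orientation map (radians in `[-pi/2, pi/2)`).
#' @param coherence coherence map in `[0, 1]`.
#' @param image brightness image (rescaled internally to `[0, 1]`).
#' @return numeric array `nx x ny x 3` of RGB values in `[0, 1]`.
#' @export
render_hsv <- function(theta, coherence, image) {
  stopifnot(identical(dim(theta), dim(coherence)),
            identical(dim(theta), dim(image)))
  rng <- range(image)
  v <- if (diff(rng) == 0) (image > 0) * 1 else (image - rng[1]) / diff(rng)
  h <- (theta + pi / 2) / pi
  h[h >= 1] <- h[h >= 1] - 1
  s <- pmin(pmax(coherence, 0), 1)
  cols <- grDevices::hsv(as.vector(h), as.vector(s), as.vector(v))
  rgb <- grDevices::col2rgb(cols) / 255
  array(c(rgb[1, ], rgb[2, ], rgb[3, ]), c(nrow(theta), ncol(theta), 3))
}

#' Lesion-referenced orientation analysis of an en-face angiogram
#'
#' Convenience wrapper running the full orientation chain: vessel
#' enhancement, structure-tensor orientation/coherence, beta-map synthesis
#' from the lesion center, theta map, vessel mask, and the angular
#' distribution.
#'
#' @param enface en-face image (matrix or `enface_map`).
#' @param center_xy lesion-center pixel coordinates; default: centroid of
#'   `lesion_mask` if given, else the image center.
#' @param lesion_mask optional logical lesion mask (used for the center and
#'   the vascularized-area bookkeeping).
#' @param grad_sigma,window_sigma structure-tensor scales.
#' @param n_bins histogram bins.
#' @param weight,coherence_floor passed to [angular_distribution()].
#' @param ... passed to [enhance_vessels()].
#' @return list with `maps` (alpha, beta, theta, coherence, center_xy),
#'   `mask`, `graph` (when `weight = "segment"`), `distribution`, and the
#'   `enhanced` image.
#' @export
orientation_analysis <- function(enface, center_xy = NULL,
                                 lesion_mask = NULL, grad_sigma = 1,
                                 window_sigma = 3, n_bins = 18L,
                                 weight = "pixel", coherence_floor = 0,
                                 ...) {
  if (inherits(enface, "enface_map")) enface <- enface$image
  if (is.null(center_xy)) {
    center_xy <- if (!is.null(lesion_mask) && any(lesion_mask)) {
      mask_centroid(lesion_mask)
    } else c((nrow(enface) + 1) / 2, (ncol(enface) + 1) / 2)
  }
  enhanced <- enhance_vessels(enface, ...)
  st <- structure_tensor_orientation(enhanced, grad_sigma, window_sigma)
  beta <- synthesize_beta_map(dim(enface), center_xy)
  theta <- theta_map(st$alpha, beta)
  mask <- make_mask(enhanced, lesion_mask = lesion_mask)
  graph <- NULL
  if (weight == "segment") graph <- build_segment_graph(mask)
  dist <- angular_distribution(theta, mask, coherence = st$coherence,
                               n_bins = n_bins,
                               coherence_floor = coherence_floor,
                               weight = weight, graph = graph,
                               beta = beta)
  list(
    maps = list(alpha = st$alpha, beta = beta, theta = theta,
                coherence = st$coherence, center_xy = center_xy),
    mask = mask, graph = graph, distribution = dist, enhanced = enhanced
  )
}

mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}
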