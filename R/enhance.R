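## Scale-normalized 2-D Hessian via Gaussian-derivative filtering.
## Multiplying by sigma^2 makes ridge responses comparable across scales.
hessian2d <- function(image, sigma) {
  list(
    xx = sigma^2 * gaussian_filter(image, sigma, order = c(2L, 0L)),
    xy = sigma^2 * gaussian_filter(image, sigma, order = c(1L, 1L)),
    yy = sigma^2 * gaussian_filter(image, sigma, order = c(0L, 2L))
  )
}

## Eigenvalues of the symmetric 2x2 Hessian field; lo <= hi pointwise.
hessian_eigen <- function(H) {
  tr <- H$xx + H$yy
  disc <- sqrt(pmax(0, (H$xx - H$yy)^2 + 4 * H$xy^2))
  list(lo = (tr - disc) / 2, hi = (tr + disc) / 2)
}

#' Tubeness filter: ridge response from the Hessian
#'
#' A bright tube on a dark background has one strongly negative Hessian
#' eigenvalue (curvature across the tube) and one near zero (along it).
#' The tubeness response is `max(0, -lambda2)` where `lambda2` is the more
#' negative eigenvalue of the scale-normalized Hessian, so flat regions and
#' dark ridges give zero.
#'
#' @param image 2-D non-negative numeric matrix.
#' @param sigma filter scale in pixels (roughly the tube radius).
#' @return non-negative matrix of the same size.
#' @export
tubeness <- function(image, sigma = 2) {
  stopifnot(is.matrix(image))
  ev <- hessian_eigen(hessian2d(image, sigma))
  r <- -ev$lo
  # clamp accumulation noise so flat regions give exactly zero
  r[r < 1e-10 * max(abs(image), .Machine$double.eps)] <- 0
  r
}

#' Frangi vesselness filter
#'
#' Multiscale Hessian vesselness for bright tubes on a dark background.
#' With eigenvalues ordered `|lambda1| <= |lambda2|`, the per-scale
#' response is 0 where `lambda2 > 0` and otherwise
#' `exp(-Rb^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))`, with blobness
#' `Rb = lambda1 / lambda2` and structureness `S = sqrt(lambda1^2 +
#' lambda2^2)`. The output is the maximum over scales and lies in `[0, 1]`.
#'
#' @param image 2-D numeric matrix.
#' @param scales vector of Gaussian scales (pixels).
#' @param beta blobness sensitivity (default 0.5).
#' @param c structureness sensitivity; default `NULL` uses half the maximum
#'   Hessian norm at each scale.
#' @return matrix with values in `[0, 1]`.
#' @export
frangi <- function(image, scales = c(1, 1.5, 2), beta = 0.5, c = NULL) {
  stopifnot(is.matrix(image), length(scales) >= 1)
  out <- matrix(0, nrow(image), ncol(image))
  for (s in scales) {
    ev <- hessian_eigen(hessian2d(image, s))
    # order by magnitude: l1 small, l2 large
    swap <- abs(ev$lo) < abs(ev$hi)
    l1 <- ifelse(swap, ev$lo, ev$hi)
    l2 <- ifelse(swap, ev$hi, ev$lo)
    S <- sqrt(l1^2 + l2^2)
    if (max(S) < 1e-10 * max(abs(image), .Machine$double.eps)) next
    cs <- if (is.null(c)) max(S) / 2 else c
    if (cs == 0) cs <- .Machine$double.eps
    Rb <- ifelse(l2 == 0, 0, l1 / l2)
    V <- exp(-Rb^2 / (2 * beta^2)) * (1 - exp(-S^2 / (2 * cs^2)))
    V[l2 > 0] <- 0
    out <- pmax(out, V)
  }
  out
}

#' Sequential vessel enhancement
#'
#' Applies the tubeness filter then the Frangi filter, the enhancement
#' chain used on en-face angiogram projections before masking and
#' orientation analysis.
#'
#' @param image 2-D matrix (en-face angiogram or [mip_enface()] output).
#' @param tubeness_sigma scale for [tubeness()].
#' @param frangi_scales,beta,c passed to [frangi()].
#' @return enhanced matrix in `[0, 1]`.
#' @export
enhance_vessels <- function(image, tubeness_sigma = 2,
                            frangi_scales = c(1, 1.5, 2), beta = 0.5,
                            c = NULL) {
  if (inherits(image, "enface_map")) image <- image$image
  frangi(tubeness(image, tubeness_sigma), scales = frangi_scales,
         beta = beta, c = c)
}

#' Binary capillary mask from a vessel-enhanced image
#'
#' Thresholds the enhanced image (Otsu by default), removes connected
#' components smaller than `min_component_px`, and reports the vascularized
#' area, i.e. the number of mask-positive pixels outside the lesion when a
#' lesion mask is supplied (the avascular lesion is excluded from
#' area-normalized statistics downstream).
#'
#' @param enhanced 2-D matrix, e.g. from [enhance_vessels()].
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold threshold value for `method = "fixed"`.
#' @param min_component_px minimum connected-component size kept
#'   (8-connectivity).
#' @param lesion_mask optional logical matrix marking lesion pixels.
#' @return object of class `vessel_mask`: list with `mask` (logical),
#'   `threshold_used`, `vascularized_area_px`.
#' @export
make_mask <- function(enhanced, method = c("otsu", "fixed"),
                      threshold = NULL, min_component_px = 10L,
                      lesion_mask = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(enhanced))
  rng <- range(enhanced)
  if (method == "otsu") {
    if (diff(rng) == 0) {
      thr <- rng[1]  # flat image: empty mask below
      mask <- matrix(FALSE, nrow(enhanced), ncol(enhanced))
    } else {
      scaled <- (enhanced - rng[1]) / diff(rng)
      t01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
      thr <- rng[1] + t01 * diff(rng)
      mask <- enhanced > thr
    }
  } else {
    stopifnot(!is.null(threshold))
    thr <- threshold
    mask <- enhanced > thr
  }
  if (any(mask) && min_component_px > 1) {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    sizes <- tabulate(as.integer(lab))
    keep <- which(sizes >= min_component_px)
    mask <- matrix(as.integer(lab) %in% keep, nrow(mask), ncol(mask))
  }
  if (!any(mask)) warning("empty vessel mask")
  area <- if (is.null(lesion_mask)) sum(mask) else sum(mask & !lesion_mask)
  structure(list(mask = mask, threshold_used = thr,
                 vascularized_area_px = area),
            class = "vessel_mask")
}

#' Morphological skeleton (Zhang-Suen thinning)
#'
#' Iteratively peels boundary pixels until only a (mostly) 1-pixel-wide,
#' 8-connected skeleton remains.
#'
#' @param mask logical matrix.
#' @return logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask))
  img <- mask * 1L
  nx <- nrow(img); ny <- ncol(img)
  # pad to avoid border checks
  p <- matrix(0L, nx + 2L, ny + 2L)
  p[2:(nx + 1), 2:(ny + 1)] <- img
  shift <- function(m, dx, dy) {
    m[(2:(nx + 1)) + dx, (2:(ny + 1)) + dy]
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbors P2..P9 clockwise from north (x = row, north = -x)
      P2 <- shift(p, -1L,  0L); P3 <- shift(p, -1L,  1L)
      P4 <- shift(p,  0L,  1L); P5 <- shift(p,  1L,  1L)
      P6 <- shift(p,  1L,  0L); P7 <- shift(p,  1L, -1L)
      P8 <- shift(p,  0L, -1L); P9 <- shift(p, -1L, -1L)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0L & P3 == 1L) + (P3 == 0L & P4 == 1L) +
           (P4 == 0L & P5 == 1L) + (P5 == 0L & P6 == 1L) +
           (P6 == 0L & P7 == 1L) + (P7 == 0L & P8 == 1L) +
           (P8 == 0L & P9 == 1L) + (P9 == 0L & P2 == 1L)
      cur <- p[2:(nx + 1), 2:(ny + 1)]
      if (step == 1) {
        cond <- cur == 1L & B >= 2L & B <= 6L & A == 1L &
          (P2 * P4 * P6 == 0L) & (P4 * P6 * P8 == 0L)
      } else {
        cond <- cur == 1L & B >= 2L & B <= 6L & A == 1L &
          (P2 * P4 * P8 == 0L) & (P2 * P6 * P8 == 0L)
      }
      if (any(cond)) {
        cur[cond] <- 0L
        p[2:(nx + 1), 2:(ny + 1)] <- cur
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p[2:(nx + 1), 2:(ny + 1)] == 1L
}

#' Build the capillary segment graph from a vessel mask
#'
#' Skeletonizes the mask and classifies skeleton pixels by their number of
#' skeleton neighbors (8-connectivity): 1 neighbor = endpoint, 3 or more =
#' junction. Segments are maximal pixel chains between node pixels;
#' segments shorter than `min_length_px` are pruned.
#'
#' @param mask a `vessel_mask` or logical matrix.
#' @param min_length_px minimum segment length kept, in pixels (default 5,
#'   suppressing skeletonization spurs).
#' @return object of class `segment_graph`: list with `segments` (each a
#'   list `id`, `pixels` n-by-2 coordinate matrix, `length_px`,
#'   `orientation` in `[-pi/2, pi/2)`), `nodes` (coordinate matrix with a
#'   `type` column: 1 endpoint, 3 junction), `skeleton` (logical matrix),
#'   and `dim`.
#' @export
build_segment_graph <- function(mask, min_length_px = 5L) {
  if (inherits(mask, "vessel_mask")) mask <- mask$mask
  stopifnot(is.matrix(mask))
  skel <- skeletonize(mask)
  if (!any(skel)) stop("empty skeleton")
  nx <- nrow(skel); ny <- ncol(skel)

  p <- matrix(0L, nx + 2L, ny + 2L)
  p[2:(nx + 1), 2:(ny + 1)] <- skel * 1L
  ncount <- matrix(0L, nx, ny)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    ncount <- ncount + p[(2:(nx + 1)) + dx, (2:(ny + 1)) + dy]
  }
  is_node <- skel & (ncount != 2L)   # endpoints, junctions, isolated pixels
  node_idx <- which(is_node)

  neighbors_of <- function(x, y) {
    res <- matrix(integer(0), 0, 2)
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      xx <- x + dx; yy <- y + dy
      if (xx >= 1 && xx <= nx && yy >= 1 && yy <= ny && skel[xx, yy]) {
        res <- rbind(res, c(xx, yy))
      }
    }
    res
  }

  visited_edge <- matrix(FALSE, nx, ny)  # chain (degree-2) pixels consumed
  segments <- list()
  sid <- 0L

  trace_from <- function(start, nbr) {
    # walk from node pixel `start` through chain pixel `nbr` to next node
    chain <- rbind(start, nbr)
    prev <- start
    cur <- nbr
    while (!is_node[cur[1], cur[2]]) {
      visited_edge[cur[1], cur[2]] <<- TRUE
      nb <- neighbors_of(cur[1], cur[2])
      nxt <- nb[!(nb[, 1] == prev[1] & nb[, 2] == prev[2]), , drop = FALSE]
      if (nrow(nxt) == 0) break            # dead end (shouldn't happen)
      if (nrow(nxt) > 1) {
        # at a chain pixel degree must be 2; pick the one not yet visited
        unv <- nxt[!visited_edge[nxt], , drop = FALSE]
        nxt <- if (nrow(unv) > 0) unv else nxt
      }
      cur <- nxt[1, ]
      chain <- rbind(chain, cur)
      prev <- chain[nrow(chain) - 1, ]
    }
    chain
  }

  for (ni in node_idx) {
    x0 <- ((ni - 1) %% nx) + 1L
    y0 <- ((ni - 1) %/% nx) + 1L
    nb <- neighbors_of(x0, y0)
    for (j in seq_len(nrow(nb))) {
      n1 <- nb[j, ]
      if (is_node[n1[1], n1[2]]) {
        # direct node-node contact: 2-pixel segment, record once
        if (ni < (n1[2] - 1L) * nx + n1[1]) {
          sid <- sid + 1L
          segments[[sid]] <- rbind(c(x0, y0), n1)
        }
        next
      }
      if (visited_edge[n1[1], n1[2]]) next
      chain <- trace_from(c(x0, y0), n1)
      # avoid double-tracing from the far node: mark first chain pixel
      visited_edge[n1[1], n1[2]] <- TRUE
      sid <- sid + 1L
      segments[[sid]] <- chain
    }
  }

  # isolated loops: remaining unvisited degree-2 pixels
  remaining <- which(skel & !is_node & !visited_edge)
  while (length(remaining) > 0) {
    i0 <- remaining[1]
    x0 <- ((i0 - 1) %% nx) + 1L
    y0 <- ((i0 - 1) %/% nx) + 1L
    chain <- matrix(c(x0, y0), 1, 2)
    visited_edge[x0, y0] <- TRUE
    prev <- c(NA_integer_, NA_integer_)
    cur <- c(x0, y0)
    repeat {
      nb <- neighbors_of(cur[1], cur[2])
      nb <- nb[!visited_edge[nb], , drop = FALSE]
      if (nrow(nb) == 0) break
      cur <- nb[1, ]
      visited_edge[cur[1], cur[2]] <- TRUE
      chain <- rbind(chain, cur)
    }
    sid <- sid + 1L
    segments[[sid]] <- chain
    remaining <- which(skel & !is_node & !visited_edge)
  }

  # prune short segments
  keep <- vapply(segments, nrow, integer(1)) >= min_length_px
  segments <- segments[keep]
  if (length(segments) == 0) {
    warning("all segments shorter than min_length_px; graph is empty")
  }

  seg_list <- lapply(seq_along(segments), function(i) {
    px <- segments[[i]]
    dimnames(px) <- list(NULL, c("x", "y"))
    list(id = i, pixels = px, length_px = nrow(px),
         orientation = chain_orientation(px))
  })
  nodes <- if (length(node_idx) > 0) {
    cbind(x = ((node_idx - 1) %% nx) + 1L,
          y = ((node_idx - 1) %/% nx) + 1L,
          type = ncount[node_idx])
  } else matrix(integer(0), 0, 3)
  structure(list(segments = seg_list, nodes = nodes, skeleton = skel,
                 dim = c(nx, ny), min_length_px = min_length_px),
            class = "segment_graph")
}

## Principal-axis orientation of a pixel chain, in [-pi/2, pi/2).
chain_orientation <- function(px) {
  x <- px[, 1] - mean(px[, 1])
  y <- px[, 2] - mean(px[, 2])
  sxx <- sum(x * x); syy <- sum(y * y); sxy <- sum(x * y)
  wrap_orientation(0.5 * atan2(2 * sxy, sxx - syy))
}

#' @export
print.segment_graph <- function(x, ...) {
  cat("segment_graph:", length(x$segments), "segments,",
      nrow(x$nodes), "nodes on a", x$dim[1], "x", x$dim[2], "grid\n")
  invisible(x)
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat("vessel_mask:", sum(x$mask), "positive px (threshold ",
      signif(x$threshold_used, 4), "), vascularized area ",
      x$vascularized_area_px, "px\n")
  invisible(x)
}
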