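#' Wrap an angle into the undirected-orientation range
#'
#' Orientations of line-like structures are defined modulo pi. This helper
#' maps any angle (radians) into `[-pi/2, pi/2)`.
#'
#' @param x numeric vector or array of angles in radians.
#' @return object of the same shape with values in `[-pi/2, pi/2)`.
#' @export
wrap_orientation <- function(x) {
  ((x + pi / 2) %% pi) - pi / 2
}

## 1-D Gaussian (and Gaussian-derivative) kernels, sampled on an integer grid
## of radius ceiling(truncate * sigma). order 0 sums to 1; orders 1 and 2 are
## scaled so that correlation with t and t^2/2 respectively recovers unit
## first/second derivatives on smooth inputs.
gaussian_kernel_1d <- function(sigma, order = 0L, truncate = 4) {
  stopifnot(sigma > 0, order %in% 0:2)
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  t <- seq(-r, r)
  g <- exp(-t^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) {
    k <- t / sigma^2 * g
    return(k / sum(k * t))            # exact unit response to a ramp
  }
  k <- (t^2 - sigma^2) / sigma^4 * g
  k <- k - mean(k)                    # exactly annihilate constants
  k / sum(k * t^2 / 2)                # exact unit response to t^2/2
}

## Correlate (no kernel flip) an array along one axis with replicate padding.
## Works for matrices and 3-D arrays; vectorized over the remaining axes.
correlate_axis <- function(a, k, axis) {
  d <- dim(a)
  n <- d[axis]
  r <- (length(k) - 1L) %/% 2L
  out <- array(0, d)
  base <- seq_len(n)
  for (j in seq_along(k)) {
    if (k[j] == 0) next
    ii <- pmin(pmax(base + (j - r - 1L), 1L), n)
    out <- out + k[j] * slice_axis(a, axis, ii)
  }
  out
}

slice_axis <- function(a, axis, ii) {
  nd <- length(dim(a))
  args <- rep(list(quote(expr = )), nd)
  args[[axis]] <- ii
  do.call(`[`, c(list(a), args, list(drop = FALSE)))
}

## Separable Gaussian (or Gaussian-derivative) filter over every axis of an
## array. `order` is recycled per axis.
gaussian_filter <- function(a, sigma, order = 0L, truncate = 4) {
  d <- dim(a)
  order <- rep_len(order, length(d))
  sigma <- rep_len(sigma, length(d))
  for (ax in seq_along(d)) {
    k <- gaussian_kernel_1d(sigma[ax], order[ax], truncate)
    a <- correlate_axis(a, k, ax)
  }
  a
}

## Integer pixel chain between two endpoints (Bresenham).
bresenham_line <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx - dy
  n <- dx + dy + 1L
  xs <- integer(n); ys <- integer(n)
  x <- as.integer(x0); y <- as.integer(y0)
  i <- 0L
  repeat {
    i <- i + 1L
    xs[i] <- x; ys[i] <- y
    if (x == x1 && y == y1) break
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx)  { err <- err + dx; y <- y + sy }
  }
  cbind(x = xs[seq_len(i)], y = ys[seq_len(i)])
}

## Disk-shaped offset set used to dilate centerlines into tubes. The +0.5
## fudge makes radius-1 a full 3x3 neighborhood, giving tubes of odd width
## 2r+1 like a rasterized circle.
disk_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  keep <- g$dx^2 + g$dy^2 <= (radius + 0.5)^2
  as.matrix(g[keep, , drop = FALSE])
}

## Dilate a set of pixel coordinates by an offset set, clipped to the grid;
## returns unique linear indices into an nx-by-ny matrix.
dilate_coords <- function(coords, offsets, nx, ny) {
  x <- rep(coords[, 1], each = nrow(offsets)) + offsets[, 1]
  y <- rep(coords[, 2], each = nrow(offsets)) + offsets[, 2]
  keep <- x >= 1L & x <= nx & y >= 1L & y <= ny
  unique((y[keep] - 1L) * nx + x[keep])
}

## Run thunk with a private RNG state seeded from `seed`.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
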