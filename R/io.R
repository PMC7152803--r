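#' Read and write images and volumes as TIFF
#'
#' Volumes use axis order `(z, x, y)`: page k of the multi-page TIFF holds
#' the en-face slice at axial index k, stored as an x-by-y matrix. En-face
#' images and masks are single-page TIFFs. Values are written as 32-bit
#' floats; intensities are not rescaled.
#'
#' @param path file path.
#' @return `read_image_tiff`: numeric matrix. `read_volume_tiff`: numeric
#'   3-D array `(z, x, y)`. Writers return the path invisibly.
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  # readTIFF returns row = image row (y), col = x; our convention is [x, y]
  t(img)
}

#' @rdname read_image_tiff
#' @param image numeric matrix `[x, y]`, non-negative.
#' @param normalize divide by the image maximum when values exceed 1
#'   (TIFF samples are stored on `[0, 1]`; angiogram intensities are
#'   arbitrary units, so only relative values are meaningful on disk).
#' @export
write_image_tiff <- function(image, path, normalize = TRUE) {
  stopifnot(all(image >= 0))
  m <- max(image)
  if (normalize && m > 1) image <- image / m
  tiff::writeTIFF(t(image), path, bits.per.sample = 32L,
                  reduce = FALSE)
  invisible(path)
}

#' @rdname read_image_tiff
#' @export
read_volume_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  mats <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    t(p)
  })
  nz <- length(mats)
  nx <- nrow(mats[[1]]); ny <- ncol(mats[[1]])
  vol <- array(0, c(nz, nx, ny))
  for (k in seq_len(nz)) vol[k, , ] <- mats[[k]]
  vol
}

#' @rdname read_image_tiff
#' @param vol numeric 3-D array `(z, x, y)`, non-negative.
#' @export
write_volume_tiff <- function(vol, path, normalize = TRUE) {
  stopifnot(length(dim(vol)) == 3, all(vol >= 0))
  m <- max(vol)
  if (normalize && m > 1) vol <- vol / m
  pages <- lapply(seq_len(dim(vol)[1]), function(k) t(vol[k, , ]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read/write complex B-frame pairs as paired real/imaginary TIFF stacks
#'
#' Each repeat is stored as two real-valued single-page TIFFs (real and
#' imaginary parts). Because TIFF samples live on `[0, 1]`, each component
#' is affinely mapped onto that range and the affine parameters are stored
#' in a JSON sidecar (`<prefix>_scale.json`), so the complex values round
#' trip exactly to 32-bit precision.
#'
#' @param pair a `bframe_pair`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return the file paths (invisibly for the writer).
#' @export
write_bframe_pair <- function(pair, dir, prefix = "bframe") {
  comps <- list(a_re = Re(pair$frame_a), a_im = Im(pair$frame_a),
                b_re = Re(pair$frame_b), b_im = Im(pair$frame_b))
  paths <- file.path(dir, paste0(prefix, "_", names(comps), ".tiff"))
  scales <- list()
  for (i in seq_along(comps)) {
    v <- comps[[i]]
    lo <- min(v); hi <- max(v)
    span <- if (hi > lo) hi - lo else 1
    write_image_tiff((v - lo) / span, paths[i], normalize = FALSE)
    scales[[names(comps)[i]]] <- list(lo = lo, span = span)
  }
  scale_path <- file.path(dir, paste0(prefix, "_scale.json"))
  jsonlite::write_json(c(scales,
                         list(position_index = pair$position_index)),
                       scale_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, scale_path))
}

#' @rdname write_bframe_pair
#' @export
read_bframe_pair <- function(dir, prefix = "bframe") {
  sc <- jsonlite::read_json(file.path(dir, paste0(prefix, "_scale.json")),
                            simplifyVector = TRUE)
  comp <- function(name) {
    v <- read_image_tiff(file.path(dir, paste0(prefix, "_", name, ".tiff")))
    v * sc[[name]][["span"]] + sc[[name]][["lo"]]
  }
  a <- comp("a_re") + 1i * comp("a_im")
  b <- comp("b_re") + 1i * comp("b_im")
  structure(list(frame_a = a, frame_b = b,
                 position_index = as.integer(sc$position_index)),
            class = "bframe_pair")
}

#' Write ground truth of a synthetic scene as JSON
#'
#' Serializes segment orientations, stall log, and lesion geometry (the
#' lesion mask itself is written separately as TIFF when needed).
#'
#' @param truth truth component from [generate_scene()] /
#'   [render_angiogram_series()].
#' @param path output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(
    segment_theta = truth$segment_theta,
    segment_alpha = truth$segment_alpha,
    aligned = truth$aligned,
    lesion_area_px = truth$lesion_area_px,
    lesion_center_xy = truth$lesion_center_xy,
    stall_log = truth$stall_log %||% list()
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an angular distribution as CSV
#'
#' Columns: `bin_lo`, `bin_hi` (radians), `count`, `fraction`.
#'
#' @param dist an `angular_distribution`.
#' @param path output CSV path.
#' @export
write_distribution_csv <- function(dist, path) {
  n <- length(dist$counts)
  df <- data.frame(
    bin_lo = dist$bin_edges[seq_len(n)],
    bin_hi = dist$bin_edges[seq_len(n) + 1],
    count = dist$counts,
    fraction = dist$counts / sum(dist$counts)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the segment table of a graph as CSV
#'
#' Columns: `id`, `length_px`, endpoints, `orientation` (radians).
#'
#' @param graph a `segment_graph`.
#' @param path output CSV path.
#' @export
write_segment_csv <- function(graph, path) {
  df <- do.call(rbind, lapply(graph$segments, function(s) {
    data.frame(id = s$id, length_px = s$length_px,
               x0 = s$pixels[1, 1], y0 = s$pixels[1, 2],
               x1 = s$pixels[nrow(s$pixels), 1],
               y1 = s$pixels[nrow(s$pixels), 2],
               orientation = s$orientation)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
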