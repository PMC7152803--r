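#' Per-segment intensity traces over an angiogram time series
#'
#' For each capillary segment of the graph, computes the per-frame mean
#' angiogram intensity over the segment's pixel chain dilated by
#' `dilate_px`, together with a per-frame local background reference: the
#' mean over a surrounding annulus (radial distance `annulus[1]` to
#' `annulus[2]` from the chain) excluding all vessel pixels. A local
#' reference makes the stall test robust to illumination gradients.
#'
#' @param series an `angiogram_series` of en-face frames (only kept frames
#'   are used).
#' @param graph a `segment_graph`.
#' @param vessel_mask logical matrix (or `vessel_mask`) of all vessel
#'   pixels, excluded from background annuli; defaults to the graph's
#'   skeleton dilated by `annulus[1]`.
#' @param dilate_px dilation radius of the chain for the foreground mean.
#' @param annulus inner/outer radius of the background annulus (px).
#' @return list of `segment_trace` objects: `segment_id`, `intensity`
#'   (per kept frame), `background` (per kept frame), `n_pixels`.
#' @export
segment_traces <- function(series, graph, vessel_mask = NULL,
                           dilate_px = 1, annulus = c(3, 6)) {
  stopifnot(inherits(series, "angiogram_series"),
            inherits(graph, "segment_graph"))
  kept <- which(series$quality_flags)
  frames <- series$frames[kept]
  stopifnot(length(frames) >= 1, length(dim(frames[[1]])) == 2)
  nx <- nrow(frames[[1]]); ny <- ncol(frames[[1]])
  stopifnot(all(graph$dim == c(nx, ny)))

  if (is.null(vessel_mask)) {
    off <- disk_offsets(annulus[1])
    vm <- matrix(FALSE, nx, ny)
    for (s in graph$segments) {
      vm[dilate_coords(s$pixels, off, nx, ny)] <- TRUE
    }
  } else {
    vm <- if (inherits(vessel_mask, "vessel_mask")) vessel_mask$mask
          else vessel_mask
  }

  fg_off <- disk_offsets(dilate_px)
  out_off <- disk_offsets(annulus[2])
  in_off <- disk_offsets(annulus[1] - 1e-9)

  fmat <- vapply(frames, as.vector, numeric(nx * ny))  # (px, frame)

  lapply(graph$segments, function(s) {
    if (any(s$pixels[, 1] < 1 | s$pixels[, 1] > nx |
            s$pixels[, 2] < 1 | s$pixels[, 2] > ny)) {
      stop("segment ", s$id, " has pixels outside the frame")
    }
    fg <- dilate_coords(s$pixels, fg_off, nx, ny)
    ring <- setdiff(dilate_coords(s$pixels, out_off, nx, ny),
                    dilate_coords(s$pixels, in_off, nx, ny))
    ring <- ring[!vm[ring]]
    if (length(ring) == 0) ring <- setdiff(seq_len(nx * ny), which(vm))
    structure(list(
      segment_id = s$id,
      intensity = colMeans(fmat[fg, , drop = FALSE]),
      background = colMeans(fmat[ring, , drop = FALSE]),
      n_pixels = length(fg)
    ), class = "segment_trace")
  })
}

#' Detect stalling events on a segment trace
#'
#' A capillary stalls when red-blood-cell flow is interrupted: the segment
#' disappears on the decorrelation angiogram, its intensity dropping to
#' the background level. A frame is flagged stalled when the segment mean
#' falls to within `drop_ratio` of the background:
#' `intensity <= background + drop_ratio * (median flowing intensity -
#' background)`. The median over all frames stands in for the flowing
#' level (valid while a segment flows in most frames). Because consecutive
#' volumes are at least 10 s apart, each flagged frame is an independent
#' observation and counts as one stalling event; runs of flagged frames
#' are not merged (an optional `merge_runs` collapses a run into one
#' event).
#'
#' @param trace a `segment_trace`.
#' @param drop_ratio fraction of the flowing-minus-background contrast
#'   below which a frame counts as stalled (default 0.25).
#' @param merge_runs if `TRUE`, consecutive stalled frames count as a
#'   single event (off by default).
#' @param min_contrast minimum (median - background) contrast, as a
#'   fraction of background, below which the segment is degenerate.
#' @return list with `stalled` (logical per frame), `n_events`,
#'   `degenerate` (TRUE when the segment never shows flowing contrast and
#'   must be excluded).
#' @export
detect_stalls <- function(trace, drop_ratio = 0.25, merge_runs = FALSE,
                          min_contrast = 0.05) {
  stopifnot(inherits(trace, "segment_trace"),
            length(trace$intensity) >= 2)
  flow <- stats::median(trace$intensity)
  bg <- trace$background
  contrast <- flow - bg
  if (stats::median(contrast) <= min_contrast * max(mean(bg), 1e-12)) {
    return(list(stalled = rep(FALSE, length(trace$intensity)),
                n_events = 0L, degenerate = TRUE))
  }
  thr <- bg + drop_ratio * contrast
  stalled <- trace$intensity <= thr
  n_events <- if (merge_runs) {
    r <- rle(stalled)
    sum(r$values)
  } else sum(stalled)
  list(stalled = stalled, n_events = as.integer(n_events),
       degenerate = FALSE)
}

#' Aggregate stalling statistics over a region of interest
#'
#' Computes the study's three stalling metrics from per-segment detections:
#' \describe{
#'   \item{event density}{total stalling events across the series divided
#'     by the vascularized area (vessel-mask pixels outside the lesion;
#'     the avascular lesion, where almost no capillaries remain, is
#'     excluded).}
#'   \item{stall incidence}{stalled segments / total segments in the ROI.}
#'   \item{event-count histogram}{number of segments per event count
#'     (1, 2, 3, ...).}
#' }
#' Segments lying mostly inside the lesion are excluded from both the
#' event total and the segment counts.
#'
#' @param traces list of `segment_trace` from [segment_traces()].
#' @param graph the `segment_graph`.
#' @param mask the `vessel_mask` used for the vascularized area.
#' @param lesion optional `lesion_mask` (or logical matrix).
#' @param drop_ratio,merge_runs passed to [detect_stalls()].
#' @param lesion_overlap_max maximum fraction of a segment's skeleton
#'   pixels inside the lesion before the segment is excluded.
#' @param px_area_um2 optional pixel area in um^2 to also report density
#'   per mm^2.
#' @return object of class `stall_stats`: list with `n_events`,
#'   `n_stalled_segments`, `n_segments_total`, `vascularized_area_px`,
#'   `event_density_per_px`, `event_density_per_mm2` (if geometry given),
#'   `incidence`, `event_count_histogram` (named integer vector),
#'   `per_segment` (data.frame id/events/degenerate/excluded).
#' @export
stall_statistics <- function(traces, graph, mask, lesion = NULL,
                             drop_ratio = 0.25, merge_runs = FALSE,
                             lesion_overlap_max = 0.5,
                             px_area_um2 = NULL) {
  stopifnot(length(traces) >= 1)
  lm <- NULL
  if (!is.null(lesion)) {
    lm <- if (inherits(lesion, "lesion_mask")) lesion$mask else lesion
  }
  vm <- if (inherits(mask, "vessel_mask")) mask$mask else mask

  seg_ids <- vapply(graph$segments, function(s) s$id, integer(1))
  trace_ids <- vapply(traces, `[[`, integer(1), "segment_id")
  seg_of <- match(trace_ids, seg_ids)
  stopifnot(!anyNA(seg_of))

  excluded <- vapply(seg_of, function(i) {
    if (is.null(lm)) return(FALSE)
    mean(lm[graph$segments[[i]]$pixels]) > lesion_overlap_max
  }, logical(1))

  det <- lapply(traces, detect_stalls, drop_ratio = drop_ratio,
                merge_runs = merge_runs)
  events <- vapply(det, `[[`, integer(1), "n_events")
  degen <- vapply(det, `[[`, logical(1), "degenerate")

  use <- !excluded & !degen
  n_events <- sum(events[use])
  n_total <- sum(!excluded)          # degenerate still counted in ROI total
  n_stalled <- sum(events[use] > 0)

  varea <- if (is.null(lm)) sum(vm) else sum(vm & !lm)
  if (n_total == 0) stop("zero segments in ROI")
  hist_tab <- table(events[use][events[use] > 0])
  hist_vec <- as.integer(hist_tab)
  names(hist_vec) <- names(hist_tab)

  out <- list(
    n_events = n_events,
    n_stalled_segments = n_stalled,
    n_segments_total = n_total,
    vascularized_area_px = varea,
    event_density_per_px = n_events / varea,
    incidence = n_stalled / n_total,
    event_count_histogram = hist_vec,
    per_segment = data.frame(
      segment_id = trace_ids,
      n_events = events, degenerate = degen, excluded = excluded
    )
  )
  if (!is.null(px_area_um2)) {
    out$event_density_per_mm2 <- n_events / (varea * px_area_um2 / 1e6)
  }
  structure(out, class = "stall_stats")
}

#' Compare stalling statistics between two conditions
#'
#' Descriptive baseline-versus-followup comparison: ratios and differences
#' of event density and incidence, and the proportion of stalled segments
#' with exactly one event per condition (the fraction of once-only
#' stallers, which drops when repeated stalling becomes common).
#'
#' @param stats_baseline,stats_followup `stall_stats` objects.
#' @return data.frame with one row per metric: baseline, followup, ratio
#'   (followup / baseline; `NA` when the baseline is 0), difference.
#' @export
compare_conditions <- function(stats_baseline, stats_followup) {
  stopifnot(inherits(stats_baseline, "stall_stats"),
            inherits(stats_followup, "stall_stats"))
  single_frac <- function(s) {
    if (s$n_stalled_segments == 0) return(0)
    one <- s$event_count_histogram[names(s$event_count_histogram) == "1"]
    if (length(one) == 0) 0 else one / s$n_stalled_segments
  }
  metric <- function(name, b, f) {
    ratio <- if (b == 0) {
      if (f == 0) 1 else NA_real_
    } else f / b
    data.frame(metric = name, baseline = b, followup = f,
               ratio = ratio, difference = f - b)
  }
  rbind(
    metric("event_density_per_px",
           stats_baseline$event_density_per_px,
           stats_followup$event_density_per_px),
    metric("incidence", stats_baseline$incidence,
           stats_followup$incidence),
    metric("single_event_fraction",
           as.numeric(single_frac(stats_baseline)),
           as.numeric(single_frac(stats_followup)))
  )
}

#' @export
print.stall_stats <- function(x, ...) {
  cat("stall_stats:", x$n_events, "events,",
      x$n_stalled_segments, "of", x$n_segments_total,
      "segments stalled (incidence",
      signif(x$incidence, 3), "), density",
      signif(x$event_density_per_px, 3), "events/px^2\n")
  invisible(x)
}
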