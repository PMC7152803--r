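test_that("the drop-ratio rule flags the right frames on toy traces", {
  tr <- toy_trace(c(1.0, 0.1, 1.0, 0.1, 1.0), background = 0.1)
  d <- detect_stalls(tr)
  expect_equal(d$n_events, 2L)
  expect_identical(which(d$stalled), c(2L, 4L))

  expect_equal(detect_stalls(toy_trace(rep(1, 10), 0.1))$n_events, 0L)

  # merging runs collapses consecutive stalled frames into one event
  tr2 <- toy_trace(c(1, 0.1, 0.1, 1, 0.1, 1), 0.1)
  expect_equal(detect_stalls(tr2)$n_events, 3L)
  expect_equal(detect_stalls(tr2, merge_runs = TRUE)$n_events, 2L)

  # a segment indistinguishable from background is degenerate
  d3 <- detect_stalls(toy_trace(rep(0.1, 6), 0.1))
  expect_true(d3$degenerate)
  expect_equal(d3$n_events, 0L)
})

test_that("detection matches exhaustive brute-force on random toy traces", {
  set.seed(10)
  for (rep in 1:30) {
    n <- sample(3:10, 1)
    inten <- runif(n, 0, 1.2)
    bg <- runif(n, 0.05, 0.15)
    tr <- toy_trace(inten, 0)
    tr$background <- bg
    d <- detect_stalls(tr, drop_ratio = 0.25)
    # brute force: evaluate the rule frame by frame from first principles
    flow <- median(inten)
    brute <- logical(n)
    for (f in seq_len(n)) {
      brute[f] <- inten[f] <= bg[f] + 0.25 * (flow - bg[f])
    }
    if (d$degenerate) next
    expect_identical(d$stalled, brute)
    expect_equal(d$n_events, sum(brute))
  }
})

test_that("noise-free detection reproduces the generator stall log exactly", {
  gen <- make_separated_scene(seed = 7, n = 40)
  st <- stall_process_spec(60, 0.05, 1, seed = 9)
  r <- render_angiogram_series(gen$scene, gen$truth, st, gen$spec)
  m <- make_mask(average_series(r$series))
  graph <- build_segment_graph(m)
  traces <- segment_traces(r$series, graph, vessel_mask = m)
  ids <- match_graph_to_truth(graph, gen$scene)
  for (i in seq_along(traces)) {
    d <- detect_stalls(traces[[i]])
    expect_identical(which(d$stalled),
                     sort(r$truth$stall_log[[ids[i]]]))
  }
})

test_that("detection stays accurate at noise up to half the contrast", {
  gen <- make_separated_scene(seed = 3, n = 40, noise = 0.45)
  st <- stall_process_spec(60, 0.05, 1, seed = 5)
  r <- render_angiogram_series(gen$scene, gen$truth, st, gen$spec)
  m <- make_mask(average_series(r$series))
  graph <- build_segment_graph(m)
  traces <- segment_traces(r$series, graph, vessel_mask = m)
  ids <- match_graph_to_truth(graph, gen$scene)
  tp <- fp <- fn <- 0
  for (i in seq_along(traces)) {
    flags <- which(detect_stalls(traces[[i]])$stalled)
    truthf <- r$truth$stall_log[[ids[i]]]
    tp <- tp + length(intersect(flags, truthf))
    fp <- fp + length(setdiff(flags, truthf))
    fn <- fn + length(setdiff(truthf, flags))
  }
  f1 <- 2 * tp / (2 * tp + fp + fn)
  expect_gte(f1, 0.95)
})

test_that("stall statistics aggregate hand-enumerable cases correctly", {
  traces <- list(toy_trace(rep(1, 5), 0.1, id = 1L),
                 toy_trace(c(1, 0.1, 1, 0.1, 1), 0.1, id = 2L),
                 toy_trace(rep(1, 5), 0.1, id = 3L))
  fake_graph <- structure(list(
    segments = lapply(1:3, function(i) {
      list(id = i, pixels = cbind(x = 1:5, y = rep(i * 3, 5)),
           length_px = 5L, orientation = 0)
    }), nodes = matrix(integer(0), 0, 3),
    skeleton = matrix(FALSE, 20, 20), dim = c(20L, 20L)),
    class = "segment_graph")
  mask <- matrix(FALSE, 20, 20)
  for (s in fake_graph$segments) mask[s$pixels] <- TRUE

  stats <- stall_statistics(traces, fake_graph, mask)
  expect_equal(stats$n_events, 2)
  expect_equal(stats$n_stalled_segments, 1)
  expect_equal(stats$incidence, 1 / 3)
  expect_identical(stats$event_count_histogram, c("2" = 1L))
  expect_equal(stats$event_density_per_px, 2 / sum(mask))

  # no stalls anywhere
  quiet <- stall_statistics(traces[c(1, 3)], fake_graph, mask)
  expect_equal(quiet$n_events, 0)
  expect_equal(quiet$incidence, 0)
  expect_length(quiet$event_count_histogram, 0)
})

test_that("histogram identity and incidence hold on generator output", {
  gen <- make_separated_scene(seed = 12, n = 40, noise = 0.02)
  st <- stall_process_spec(60, 0.08, 0.5, seed = 2)
  r <- render_angiogram_series(gen$scene, gen$truth, st, gen$spec)
  m <- make_mask(average_series(r$series))
  graph <- build_segment_graph(m)
  traces <- segment_traces(r$series, graph, vessel_mask = m)
  stats <- stall_statistics(traces, graph, m)
  h <- stats$event_count_histogram
  expect_equal(sum(as.integer(names(h)) * h), stats$n_events)
  expect_equal(sum(h), stats$n_stalled_segments)
  expect_lte(stats$n_stalled_segments, stats$n_segments_total)
  # incidence against the closed-form expectation:
  # 20 eligible of 40, P(>=1 stall in 60 frames) = 1 - 0.92^60
  p_any <- 1 - (1 - 0.08)^60
  expect_lt(abs(stats$incidence - 20 * p_any / 40), 3 * sqrt(20 * p_any *
              (1 - p_any)) / 40 + 0.02)
})

test_that("segments inside the lesion are excluded from the statistics", {
  traces <- list(toy_trace(c(1, 0.1, 1, 1), 0.1, id = 1L),
                 toy_trace(c(1, 0.1, 0.1, 1), 0.1, id = 2L))
  fake_graph <- structure(list(
    segments = list(
      list(id = 1L, pixels = cbind(x = 2:6, y = rep(2, 5)),
           length_px = 5L, orientation = 0),
      list(id = 2L, pixels = cbind(x = 2:6, y = rep(10, 5)),
           length_px = 5L, orientation = 0)),
    nodes = matrix(integer(0), 0, 3),
    skeleton = matrix(FALSE, 12, 12), dim = c(12L, 12L)),
    class = "segment_graph")
  mask <- matrix(FALSE, 12, 12)
  mask[2:6, 2] <- TRUE; mask[2:6, 10] <- TRUE
  lesion <- matrix(FALSE, 12, 12)
  lesion[, 8:12] <- TRUE                      # covers segment 2 entirely

  with_lesion <- stall_statistics(traces, fake_graph, mask, lesion = lesion)
  expect_equal(with_lesion$n_events, 1)       # only segment 1 counts
  expect_equal(with_lesion$n_segments_total, 1)
  expect_equal(with_lesion$vascularized_area_px, 5)

  # adding more stalls to the lesion-contained segment changes nothing
  traces2 <- traces
  traces2[[2]] <- toy_trace(c(0.1, 0.1, 0.1, 0.1), 0.1, id = 2L)
  again <- stall_statistics(traces2, fake_graph, mask, lesion = lesion)
  expect_equal(again$n_events, with_lesion$n_events)
  expect_equal(again$vascularized_area_px, with_lesion$vascularized_area_px)
  expect_equal(again$n_segments_total, with_lesion$n_segments_total)
})

test_that("condition comparison reports ratios and single-event fractions", {
  traces <- list(toy_trace(c(1, 0.1, 1, 1), 0.1, id = 1L),
                 toy_trace(rep(1, 4), 0.1, id = 2L))
  fake_graph <- structure(list(
    segments = lapply(1:2, function(i) {
      list(id = i, pixels = cbind(x = 2:6, y = rep(i * 4, 5)),
           length_px = 5L, orientation = 0)
    }), nodes = matrix(integer(0), 0, 3),
    skeleton = matrix(FALSE, 12, 12), dim = c(12L, 12L)),
    class = "segment_graph")
  mask <- matrix(FALSE, 12, 12); mask[2:6, c(4, 8)] <- TRUE
  s1 <- stall_statistics(traces, fake_graph, mask)

  cmp_same <- compare_conditions(s1, s1)
  expect_true(all(cmp_same$ratio == 1))

  quiet <- stall_statistics(list(traces[[2]], toy_trace(rep(1, 4), 0.1, 1L)),
                            fake_graph, mask)
  cmp_empty <- compare_conditions(s1, quiet)
  expect_equal(cmp_empty$ratio[cmp_empty$metric == "event_density_per_px"], 0)
})

test_that("doubling the stall probability doubles the event density", {
  density_at <- function(p, seed) {
    gen <- make_separated_scene(seed = seed, n = 40)
    st <- stall_process_spec(60, p, 1, seed = seed + 50)
    r <- render_angiogram_series(gen$scene, gen$truth, st, gen$spec)
    m <- make_mask(average_series(r$series))
    graph <- build_segment_graph(m)
    traces <- segment_traces(r$series, graph, vessel_mask = m)
    stall_statistics(traces, graph, m)$event_density_per_px
  }
  d1 <- mean(vapply(1:3, function(s) density_at(0.02, s), numeric(1)))
  d2 <- mean(vapply(1:3, function(s) density_at(0.04, s), numeric(1)))
  # expected events 48 vs 96 per run; 3 runs give ~12% Monte-Carlo sd
  expect_lt(abs(d2 / d1 - 2), 0.5)
})
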