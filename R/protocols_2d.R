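#' Planar pacing of a monolayer
#'
#' Applies a line stimulus along one domain edge at cycle length `cl` and
#' flags 1:1 capture per beat at a far-field probe.
#'
#' @param grid an `nram_grid`.
#' @param cl cycle length, ms.
#' @param n_beats number of stimuli.
#' @param edge stimulated edge.
#' @param amplitude,duration stimulus (pA, ms).
#' @param mode tissue mode (see [simulate_tissue()]).
#' @param params parameter set.
#' @param record_frames record full V frames.
#' @param frame_dt frame stride, ms.
#' @param tail_ms extra simulated time after the last stimulus, ms.
#' @param ... passed to [simulate_tissue()].
#' @return `nram_recording` with attribute `beats` (data.frame: beat,
#'   stim_time, captured).
#' @export
planar_pacing <- function(grid, cl = 1000, n_beats = 3, edge = "left",
                          amplitude = 100, duration = 2,
                          mode = "constitutive", params = cell_params(),
                          record_frames = TRUE, frame_dt = 1,
                          tail_ms = min(cl, 500), ...) {
  stim_nodes <- nodes_edge(grid, edge, 5)
  pr <- protocol_spec(pacing_train(10, cl, n_beats, stim_nodes, amplitude,
                                   duration))
  probe <- .far_probe(grid, edge)
  rec <- simulate_tissue(grid, pr, duration = 10 + cl * (n_beats - 1) + tail_ms,
                         mode = mode, params = params, probes = probe,
                         trace_dt = 0.5, frame_dt = frame_dt,
                         record_frames = record_frames, ...)
  stim_times <- 10 + cl * (seq_len(n_beats) - 1)
  beats <- data.frame(beat = seq_len(n_beats), stim_time = stim_times,
                      captured = vapply(stim_times, function(t0) {
                        w <- rec$trace_time >= t0 &
                          rec$trace_time < t0 + min(cl, 400)
                        any(rec$traces[w, 1] > -20)
                      }, TRUE))
  attr(rec, "beats") <- beats
  rec
}

# a probe node deep in the domain opposite the stimulated edge
.far_probe <- function(grid, edge = "left") {
  inside <- which(grid$type == 1L)
  ix <- ((inside - 1) %% grid$nx) + 1
  iy <- ((inside - 1) %/% grid$nx) + 1
  sc <- switch(edge, left = ix, right = -ix, bottom = iy, top = -iy)
  q <- stats::quantile(sc, 0.9)
  cand <- inside[sc >= q]
  cand[which.min(abs(((cand - 1) %/% grid$nx) + 1 - grid$ny / 2))]
}

#' S1-S2 cross-field spiral initiation
#'
#' Applies an S1 line stimulus along the left border, waits until the
#' repolarizing waveback of the S1 wave crosses half the spatial extent of
#' the domain (V falling through `waveback_level` at the mid column), then
#' applies an S2 stimulus over the upper region so that the free end of
#' the S2 wavefront curls into a spiral.
#'
#' @param grid an `nram_grid`.
#' @param duration total simulated time, ms.
#' @param s1_amplitude,s1_duration S1 stimulus (pA, ms).
#' @param s2_amplitude,s2_duration S2 stimulus (pA, ms).
#' @param s2_fraction fraction of the domain (upper rows in y) covered by S2.
#' @param waveback_level repolarization level defining the waveback, mV.
#' @param mode tissue mode.
#' @param params parameter set.
#' @param frame_dt frame stride, ms.
#' @param max_wait_ms give up if the waveback condition is not met, ms.
#' @param ... passed to [simulate_tissue()].
#' @return `nram_recording` of the post-S2 evolution with attributes
#'   `s2_time` (ms, absolute) and `induced` (TRUE when activity persists to
#'   the end of the recording).
#' @export
s1s2_cross_field <- function(grid, duration = 1000,
                             s1_amplitude = 100, s1_duration = 2,
                             s2_amplitude = 100, s2_duration = 2,
                             s2_fraction = 0.37, waveback_level = -60,
                             mode = "constitutive", params = cell_params(),
                             frame_dt = 1, max_wait_ms = 400, ...) {
  s1_nodes <- nodes_rect(grid, 1, 5, 1, grid$ny)
  ## phase 1: S1 and wait for the waveback at the mid column, in chunks
  pr1 <- protocol_spec(stim_event(5, s1_nodes, s1_amplitude, s1_duration))
  midcol <- round(grid$nx / 2)
  mid_nodes <- which(row(grid$type) == midcol & grid$type == 1L)
  probe <- mid_nodes[which.min(abs(((mid_nodes - 1) %/% grid$nx) + 1 - grid$ny / 2))]
  chunk <- 10
  t_abs <- 0
  init <- NULL
  activated <- FALSE
  s2_time <- NA_real_
  rec <- simulate_tissue(grid, pr1, duration = chunk, mode = mode,
                         params = params, probes = probe, trace_dt = 0.5,
                         record_frames = FALSE, init = init, ...)
  init <- rec$final
  t_abs <- chunk
  while (t_abs < max_wait_ms) {
    rec <- simulate_tissue(grid, protocol_spec(), duration = chunk,
                           mode = mode, params = params, probes = probe,
                           trace_dt = 0.5, record_frames = FALSE,
                           init = init, ...)
    v <- rec$traces[, 1]
    if (!activated && any(v > -20)) activated <- TRUE
    if (activated && utils::tail(v, 1) < waveback_level) {
      s2_time <- t_abs + chunk
      init <- rec$final
      t_abs <- s2_time
      break
    }
    init <- rec$final
    t_abs <- t_abs + chunk
  }
  if (is.na(s2_time))
    return(structure(rec, s2_time = NA_real_, induced = FALSE))
  ## phase 2: S2 over the upper region, then free evolution
  y0 <- ceiling(grid$ny * (1 - s2_fraction)) + 1
  s2_nodes <- nodes_rect(grid, 1, grid$nx, y0, grid$ny)
  pr2 <- protocol_spec(stim_event(1, s2_nodes, s2_amplitude, s2_duration))
  rec2 <- simulate_tissue(grid, pr2, duration = duration - t_abs,
                          mode = mode, params = params, probes = probe,
                          trace_dt = 0.5, frame_dt = frame_dt,
                          record_frames = TRUE, init = init, ...)
  last <- rec2$frames[, , dim(rec2$frames)[3]]
  attr(rec2, "s2_time") <- s2_time
  attr(rec2, "induced") <- any(last > -20, na.rm = TRUE)
  rec2
}

#' Burst pacing for reentry induction
#'
#' Applies a rapid train from an edge electrode and reports whether
#' self-sustained activity persists after the last stimulus (at least
#' `sustained_ms` of continued activations at a far-field probe).
#'
#' @param grid an `nram_grid`.
#' @param cl burst cycle length, ms.
#' @param n_stimuli train length.
#' @param edge stimulated edge.
#' @param amplitude,duration stimulus (pA, ms).
#' @param observe_ms observation window after the last stimulus, ms.
#' @param sustained_ms minimum span of post-train activity counted as
#'   induced reentry (about two rotation periods).
#' @param mode tissue mode.
#' @param params parameter set.
#' @param frame_dt frame stride, ms.
#' @param ... passed to [simulate_tissue()].
#' @return `nram_recording` with attribute `induced` (logical).
#' @export
burst_pacing <- function(grid, cl = 80, n_stimuli = 20, edge = "left",
                         amplitude = 100, duration = 2, observe_ms = 500,
                         sustained_ms = 160, mode = "constitutive",
                         params = cell_params(), frame_dt = 2, ...) {
  stim_nodes <- nodes_edge(grid, edge, 5)
  pr <- protocol_spec(pacing_train(10, cl, n_stimuli, stim_nodes, amplitude,
                                   duration))
  t_end_train <- 10 + cl * (n_stimuli - 1) + duration
  probe <- .far_probe(grid, edge)
  rec <- simulate_tissue(grid, pr, duration = t_end_train + observe_ms,
                         mode = mode, params = params, probes = probe,
                         trace_dt = 0.5, frame_dt = frame_dt, ...)
  w <- rec$trace_time > t_end_train + 50   # beyond the last paced response
  v <- rec$traces[w, 1]
  tt <- rec$trace_time[w]
  act <- tt[v > -20]
  attr(rec, "induced") <- length(act) > 0 &&
    (max(act) - min(act)) >= sustained_ms
  rec
}

#' Continue a recording with a drug-block intervention
#'
#' Restarts the simulation from the final state of `rec` with the named
#' current scaled by (1 - `fraction`) at every node from `at_time` onward
#' (relative to the continuation), and appends the requested duration.
#'
#' @param rec an `nram_recording`.
#' @param current blockable current id (see [block_currents()]).
#' @param fraction block fraction in \[0, 1\].
#' @param duration continuation length, ms.
#' @param at_time block onset within the continuation, ms.
#' @param frame_dt frame stride, ms.
#' @param probes probe nodes (default: those of `rec`).
#' @param ... passed to [simulate_tissue()].
#' @return `nram_recording` of the continuation.
#' @export
apply_block <- function(rec, current = "I_KACh", fraction = 1, duration = 1000,
                        at_time = 0, frame_dt = 2, probes = rec$probes, ...) {
  pr <- protocol_spec(block_event(at_time, current, fraction))
  simulate_tissue(rec$grid, pr, duration = duration, mode = rec$mode,
                  params = rec$params, probes = probes, trace_dt = 0.5,
                  frame_dt = frame_dt, init = rec$final, ...)
}

#' Minimum cycle length with 1:1 capture
#'
#' Scans the given cycle lengths in descending order, pacing a strip (or
#' monolayer) from one edge, and returns the smallest cycle length for
#' which each of the last `check_last` stimuli elicits exactly one
#' propagated activation at a far-field probe.
#'
#' @param grid an `nram_grid`.
#' @param cl_grid candidate cycle lengths, ms (scanned descending).
#' @param mode tissue mode (`"blocked"` mimics tertiapin-Q).
#' @param n_beats stimuli per cycle length.
#' @param check_last number of trailing stimuli requiring 1:1 response.
#' @param edge stimulated edge.
#' @param amplitude,duration stimulus (pA, ms).
#' @param params parameter set.
#' @param ... passed to [simulate_tissue()].
#' @return List with `min_cl` (ms; NA when no tested CL captures) and
#'   `table` (data.frame: cl, captured).
#' @export
min_capture_cl <- function(grid, cl_grid, mode = "blocked", n_beats = 8,
                           check_last = 5, edge = "left", amplitude = 100,
                           duration = 2, params = cell_params(), ...) {
  cl_grid <- sort(cl_grid, decreasing = TRUE)
  stim_nodes <- nodes_edge(grid, edge, 5)
  probe <- .far_probe(grid, edge)
  res <- data.frame(cl = cl_grid, captured = NA)
  min_cl <- NA_real_
  for (i in seq_along(cl_grid)) {
    cl <- cl_grid[i]
    pr <- protocol_spec(pacing_train(10, cl, n_beats, stim_nodes, amplitude,
                                     duration))
    rec <- simulate_tissue(grid, pr, duration = 10 + cl * n_beats + 100,
                           mode = mode, params = params, probes = probe,
                           trace_dt = 0.5, record_frames = FALSE, ...)
    v <- rec$traces[, 1]
    tt <- rec$trace_time
    ok <- TRUE
    first_checked <- n_beats - check_last + 1
    for (b in first_checked:n_beats) {
      t0 <- 10 + cl * (b - 1)
      w <- tt >= t0 & tt < t0 + cl
      # one activation: V crosses -20 upward exactly once in the cycle
      if (sum(diff(v[w] > -20) == 1) != 1) { ok <- FALSE; break }
    }
    res$captured[i] <- ok
    if (ok) min_cl <- cl else break
  }
  list(min_cl = min_cl, table = res)
}
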