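#' Discrete Laplacian with no-flux (Neumann) boundaries
#'
#' Five-point stencil on a masked lattice: only neighbours inside the mask
#' contribute `(V_nb - V)` terms, which is the mirror/ghost-node treatment
#' of a zero normal flux at the mask boundary. The discrete divergence
#' theorem holds: the masked sum of the output is zero to rounding error.
#'
#' @param V numeric matrix of potentials; entries outside the mask ignored.
#' @param dx space step, cm (> 0).
#' @param D diffusion coefficient, cm^2/ms.
#' @param mask logical matrix (TRUE inside the tissue).
#' @return Matrix of `D * lap(V)` (mV/ms), zero outside the mask.
#' @export
laplacian_neumann <- function(V, dx, D, mask = NULL) {
  if (dx <= 0) stop("dx must be positive")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(V), ncol(V))
  nx <- nrow(V); ny <- ncol(V)
  Vm <- V
  Vm[!mask] <- 0
  acc <- matrix(0, nx, ny)
  # left neighbour
  nb <- rbind(0, Vm[-nx, ]); in_nb <- rbind(FALSE, mask[-nx, ])
  acc <- acc + ifelse(in_nb, nb - Vm, 0)
  # right neighbour
  nb <- rbind(Vm[-1, ], 0); in_nb <- rbind(mask[-1, ], FALSE)
  acc <- acc + ifelse(in_nb, nb - Vm, 0)
  # down neighbour
  nb <- cbind(0, Vm[, -ny]); in_nb <- cbind(FALSE, mask[, -ny])
  acc <- acc + ifelse(in_nb, nb - Vm, 0)
  # up neighbour
  nb <- cbind(Vm[, -1], 0); in_nb <- cbind(mask[, -1], FALSE)
  acc <- acc + ifelse(in_nb, nb - Vm, 0)
  out <- D / dx^2 * acc
  out[!mask] <- 0
  out
}

## ---- protocol events --------------------------------------------------------

#' Stimulation and block events for tissue protocols
#'
#' `stim_event()` schedules a current injection over a node set;
#' `pacing_train()` expands to `count` stimuli at cycle length `cl`;
#' `block_event()` changes the block fraction of one current at a given
#' time (fraction 1 = complete block, 0 = unblock). Events are combined
#' with [protocol_spec()].
#'
#' @param time event time, ms.
#' @param nodes integer vector of node indices (1-based, column-major), as
#'   returned by [nodes_edge()], [nodes_rect()] or [nodes_disc()].
#' @param amplitude stimulus strength in pA (converted via `C_cell`).
#' @param duration pulse width, ms.
#' @param start time of the first stimulus of a train, ms.
#' @param cl cycle length of the train, ms.
#' @param count number of stimuli.
#' @param current blockable current id (see [block_currents()]).
#' @param fraction block fraction in \[0, 1\].
#' @return An event (or list of events) understood by [protocol_spec()].
#' @name protocol_events
NULL

#' @rdname protocol_events
#' @export
stim_event <- function(time, nodes, amplitude = 100, duration = 2) {
  stopifnot(time >= 0, duration > 0, length(nodes) >= 1)
  structure(list(kind = "stimulus", time = time, nodes = as.integer(nodes),
                 amplitude = amplitude, duration = duration),
            class = "nram_event")
}

#' @rdname protocol_events
#' @export
pacing_train <- function(start, cl, count, nodes, amplitude = 100,
                         duration = 2) {
  lapply(seq_len(count), function(k)
    stim_event(start + (k - 1) * cl, nodes, amplitude, duration))
}

#' @rdname protocol_events
#' @export
block_event <- function(time, current, fraction = 1) {
  if (!current %in% block_currents())
    stop("unknown blockable current: ", current)
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  structure(list(kind = "block", time = time, current = current,
                 fraction = fraction), class = "nram_event")
}

#' Assemble a tissue protocol from events
#'
#' @param ... events from [stim_event()], [pacing_train()] (a list; spliced)
#'   or [block_event()].
#' @return Object of class `nram_protocol` (time-ordered event list).
#' @export
protocol_spec <- function(...) {
  ev <- list(...)
  flat <- list()
  for (e in ev) {
    if (inherits(e, "nram_event")) flat[[length(flat) + 1]] <- e
    else if (is.list(e)) for (x in e) {
      if (!inherits(x, "nram_event")) stop("not an event")
      flat[[length(flat) + 1]] <- x
    } else stop("not an event")
  }
  ord <- order(vapply(flat, `[[`, 0, "time"))
  structure(flat[ord], class = "nram_protocol")
}

## ---- node-set helpers -------------------------------------------------------

#' Node sets for stimulus regions
#'
#' Return 1-based column-major node indices of the grid: a band of columns
#' or rows along one domain edge, a rectangle, or a disc. Only in-mask
#' nodes are returned.
#'
#' @param grid an `nram_grid`.
#' @param edge `"left"`, `"right"`, `"bottom"`, `"top"`.
#' @param width band width in nodes.
#' @param x1,x2,y1,y2 rectangle bounds in node coordinates (inclusive).
#' @param cx,cy,r disc centre and radius in node coordinates.
#' @return Integer vector of node indices.
#' @name node_sets
NULL

#' @rdname node_sets
#' @export
nodes_edge <- function(grid, edge = c("left", "right", "bottom", "top"),
                       width = 5) {
  edge <- match.arg(edge)
  ix <- switch(edge,
               left = seq_len(width), right = grid$nx - seq_len(width) + 1,
               bottom = NULL, top = NULL)
  if (edge %in% c("left", "right")) {
    sel <- which(row(grid$type) %in% ix & grid$type != 0L)
  } else {
    iy <- if (edge == "bottom") seq_len(width) else grid$ny - seq_len(width) + 1
    sel <- which(col(grid$type) %in% iy & grid$type != 0L)
  }
  as.integer(sel)
}

#' @rdname node_sets
#' @export
nodes_rect <- function(grid, x1, x2, y1, y2) {
  sel <- which(row(grid$type) >= x1 & row(grid$type) <= x2 &
                 col(grid$type) >= y1 & col(grid$type) <= y2 & grid$type != 0L)
  as.integer(sel)
}

#' @rdname node_sets
#' @export
nodes_disc <- function(grid, cx, cy, r) {
  sel <- which((row(grid$type) - cx)^2 + (col(grid$type) - cy)^2 <= r^2 &
                 grid$type != 0L)
  as.integer(sel)
}

## ---- tissue simulation ------------------------------------------------------

#' Run a monodomain tissue simulation
#'
#' Advances the 2D monodomain reaction-diffusion system (forward Euler in
#' time, centred five-point Laplacian in space, no-flux boundaries at the
#' mask edge) with the full ionic model at myocyte nodes and passive,
#' gap-junction-coupled myofibroblasts. Per-node conductance multipliers
#' from the grid are applied throughout. Deterministic: identical inputs
#' give identical recordings.
#'
#' @param grid an `nram_grid` from [build_monolayer()].
#' @param protocol an `nram_protocol` (may be empty).
#' @param duration simulated time, ms.
#' @param dt time step, ms; must satisfy the diffusion stability bound.
#' @param mode `"constitutive"` (tissue default), `"blocked"`,
#'   `"single_cell"` or `"carbachol"`.
#' @param params parameter set.
#' @param probes integer node indices recorded at `trace_dt` resolution.
#' @param trace_dt probe sampling interval, ms.
#' @param frame_dt frame stride, ms.
#' @param record_frames record full V frames (memory: nx*ny*frames doubles).
#' @param init per-node initial condition: list with `state`
#'   (24 x n_myocytes matrix) and `V_fb` (fibroblast potentials), e.g. the
#'   `final` element of a previous recording; NULL for the resting state.
#' @param fb_coupled if FALSE, myofibroblasts are uncoupled (G_gap = 0),
#'   acting as inexcitable obstacles.
#' @param euler_gates integrate gates with forward Euler instead of
#'   Rush-Larsen.
#' @return Object of class `nram_recording`: list with `frames` (nx x ny x
#'   n_frames array, if recorded), `frame_time`, `traces` (matrix),
#'   `trace_time`, `probes`, `final` (state for continuation), `grid`,
#'   `duration`, `dt`, `mode`.
#' @export
simulate_tissue <- function(grid, protocol = protocol_spec(), duration,
                            dt = 0.02,
                            mode = c("constitutive", "blocked", "single_cell",
                                     "carbachol"),
                            params = cell_params(), probes = integer(0),
                            trace_dt = 1, frame_dt = 1, record_frames = TRUE,
                            init = NULL, fb_coupled = TRUE,
                            euler_gates = FALSE) {
  mode <- match.arg(mode)
  params <- .mode_params(params, mode)
  nmyo <- sum(grid$type == 1L)
  nfib <- sum(grid$type == 2L)
  if (is.null(init)) {
    st <- matrix(initial_state(params), 24, nmyo)
    vfb <- rep(params$E_fb, nfib)
  } else {
    st <- init$state
    vfb <- init$V_fb
  }
  ss <- Filter(function(e) e$kind == "stimulus", unclass(protocol))
  bb <- Filter(function(e) e$kind == "block", unclass(protocol))
  for (e in c(ss, bb)) if (e$time > duration)
    stop("protocol event at t = ", e$time, " ms lies beyond duration")
  bidx <- match(vapply(bb, `[[`, "", "current"), block_currents()) - 1L
  res <- .cpp_simulate_tissue(
    st, vfb, as.integer(grid$type), grid$nx, grid$ny, grid$mult, params,
    .mode_int(mode), dt, duration, grid$D, grid$dx,
    vapply(ss, `[[`, 0, "time"), vapply(ss, `[[`, 0, "duration"),
    vapply(ss, `[[`, 0, "amplitude") / params$C_cell,
    lapply(ss, function(e) e$nodes - 1L),
    vapply(bb, `[[`, 0, "time"), as.integer(bidx),
    vapply(bb, `[[`, 0, "fraction"),
    as.integer(probes - 1L), trace_dt, frame_dt, record_frames,
    euler_gates, fb_coupled)
  if (length(probes) == 0 && !record_frames)
    warning("no probes and no frames recorded")
  out <- list(frames = res$frames, frame_time = res$frame_time,
              traces = res$traces, trace_time = res$trace_time,
              probes = probes,
              final = list(state = res$final_state, V_fb = res$V_fb),
              grid = grid, duration = duration, dt = dt, mode = mode,
              params = params)
  class(out) <- "nram_recording"
  out
}

#' @export
print.nram_recording <- function(x, ...) {
  cat(sprintf("NRAM tissue recording: %.0f ms on %d x %d grid (mode %s)\n",
              x$duration, x$grid$nx, x$grid$ny, x$mode))
  if (!is.null(x$frames))
    cat(sprintf("  %d frames at %.3g ms stride\n", dim(x$frames)[3],
                x$frame_time[2] - x$frame_time[1]))
  if (length(x$probes))
    cat(sprintf("  %d probe traces at %.3g ms\n", length(x$probes),
                x$trace_time[2] - x$trace_time[1]))
  invisible(x)
}
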