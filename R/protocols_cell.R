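#' Action-potential characteristics of a voltage trace
#'
#' Computes resting membrane potential (pre-stimulus V), amplitude (peak
#' minus RMP), maximum upstroke velocity, take-off potential (V at the
#' dV/dt maximum) and APD50/APD80. APDx is measured from the instant of
#' maximum dV/dt to the crossing of `peak - x% * amplitude` on the
#' repolarizing limb, so the measure is independent of stimulus shape.
#'
#' @param trace an `nram_trace` (or any data.frame with `time` and `V`).
#' @param stim_time onset of the stimulus preceding the analysed beat, ms;
#'   if NULL, the last beat in the trace is detected from the upstroke.
#' @param from start of the analysis window, ms (default: whole trace).
#' @return Object of class `ap_metrics`: list with `RMP`, `peak`,
#'   `amplitude` (mV), `dVdt_max` (mV/ms), `takeoff` (mV), `APD50`,
#'   `APD80` (ms), `t_upstroke` (ms).
#' @examples
#' # a 50 ms square pulse has APD50 = APD80 = 50 ms
#' tr <- data.frame(time = seq(0, 100, 0.1))
#' tr$V <- ifelse(tr$time >= 10 & tr$time < 60, 100, 0)
#' ap_metrics(tr)$APD80
#' @export
ap_metrics <- function(trace, stim_time = NULL, from = NULL) {
  t <- trace$time
  v <- trace$V
  if (!is.null(from)) {
    keep <- t >= from
    t <- t[keep]; v <- v[keep]
  }
  dvdt <- diff(v) / diff(t)
  if (!length(dvdt) || max(v) - min(v) < 5)
    stop("no action-potential upstroke found in trace")
  if (is.null(stim_time)) {
    # last upstroke: final maximal-slope point exceeding 20% of the global max
    thr <- 0.2 * max(dvdt)
    ups <- which(dvdt >= pmax(thr, 1e-9))
    if (!length(ups)) stop("no action-potential upstroke found in trace")
    # split into bursts separated by > 5 ms and keep the last
    brk <- which(diff(t[ups]) > 5)
    first <- if (length(brk)) ups[brk[length(brk)] + 1] else ups[1]
    seg <- first:length(dvdt)
  } else {
    seg <- which(t >= stim_time)
    if (!length(seg)) stop("stim_time beyond trace")
    seg <- seg[seg <= length(dvdt)]
  }
  iup <- seg[which.max(dvdt[seg])]
  rmp_i <- if (is.null(stim_time)) max(1, iup - round(2 / max(diff(t)))) else
    max(which(t < stim_time), 1)
  RMP <- v[rmp_i[length(rmp_i)]]
  after <- iup:length(v)
  ipk <- after[which.max(v[after])]
  peak <- v[ipk]
  amplitude <- peak - RMP
  if (amplitude <= 0) stop("no action-potential upstroke found in trace")
  apd <- function(frac) {
    lvl <- peak - frac * amplitude
    below <- which(v[ipk:length(v)] <= lvl)
    if (!length(below)) return(NA_real_)
    i2 <- ipk + below[1] - 1
    if (i2 > ipk && v[i2 - 1] > lvl && v[i2] < v[i2 - 1]) {
      # linear interpolation of the crossing
      tc <- t[i2 - 1] + (t[i2] - t[i2 - 1]) * (v[i2 - 1] - lvl) / (v[i2 - 1] - v[i2])
    } else tc <- t[i2]
    tc - t[iup]
  }
  out <- list(RMP = RMP, peak = peak, amplitude = amplitude,
              dVdt_max = max(dvdt[seg]), takeoff = v[iup],
              APD50 = apd(0.5), APD80 = apd(0.8), t_upstroke = t[iup])
  class(out) <- "ap_metrics"
  out
}

#' @export
print.ap_metrics <- function(x, ...) {
  cat(sprintf("AP metrics: RMP %.1f mV, amplitude %.2f mV, dV/dt_max %.1f mV/ms\n",
              x$RMP, x$amplitude, x$dVdt_max))
  cat(sprintf("  APD50 %.1f ms, APD80 %.1f ms, take-off %.1f mV\n",
              x$APD50, x$APD80, x$takeoff))
  invisible(x)
}

#' Pace a single cell to steady state
#'
#' Applies a periodic stimulus train (default 7 pA, 5 ms) and returns the
#' recorded trace with per-beat APD80. Steady state is declared when
#' consecutive-beat APD80 differ by less than `ss_tol` (default 1 ms); loss
#' of 1:1 capture is reported in the `captured` column, not raised.
#'
#' @param params parameter set.
#' @param bcl basic cycle length, ms.
#' @param n_beats number of stimuli (>= 1).
#' @param stim_amplitude stimulus strength, pA.
#' @param stim_duration stimulus width, ms.
#' @param mode AP mode (see [simulate_cell()]).
#' @param state initial state (default packaged resting state).
#' @param dt integration step, ms.
#' @param record_dt sampling of the returned trace, ms.
#' @param ss_tol steady-state tolerance on beat-to-beat APD80, ms.
#' @return `nram_trace` with attributes `beats` (data.frame: beat,
#'   stim_time, captured, APD80) and `steady` (logical).
#' @export
pace_cell <- function(params = cell_params(), bcl = 1000, n_beats = 8,
                      stim_amplitude = 7, stim_duration = 5,
                      mode = "single_cell", state = NULL, dt = 0.02,
                      record_dt = 0.05, ss_tol = 1) {
  stopifnot(n_beats >= 1)
  stim <- stim_train(start = 10, cl = bcl, count = n_beats,
                     amplitude = stim_amplitude, duration = stim_duration)
  tr <- simulate_cell(params, duration = 10 + bcl * n_beats, dt = dt,
                      stim = stim, mode = mode, state = state,
                      record_dt = record_dt)
  beats <- data.frame(beat = seq_len(n_beats), stim_time = stim$start,
                      captured = FALSE, APD80 = NA_real_, APD50 = NA_real_)
  for (b in seq_len(n_beats)) {
    w <- tr$time >= stim$start[b] - 5 & tr$time < stim$start[b] + bcl - 5
    seg <- tr[w, ]
    pk <- max(seg$V)
    if (pk > -20) {
      m <- try(ap_metrics(seg, stim_time = stim$start[b]), silent = TRUE)
      if (!inherits(m, "try-error")) {
        beats$captured[b] <- TRUE
        beats$APD80[b] <- m$APD80
        beats$APD50[b] <- m$APD50
      }
    }
  }
  ap <- beats$APD80[beats$captured]
  attr(tr, "beats") <- beats
  attr(tr, "steady") <- length(ap) >= 2 &&
    abs(diff(utils::tail(ap, 2))) < ss_tol
  tr
}

#' Dynamic APD restitution protocol
#'
#' Paces at a descending sequence of cycle lengths, carrying the cell state
#' from one cycle length to the next, and reports the last-beat APD80 per
#' BCL with a 1:1-capture flag.
#'
#' @param params parameter set.
#' @param bcl_list strictly descending cycle lengths, ms.
#' @param beats_per_bcl conditioning beats at each cycle length.
#' @param mode AP mode.
#' @param stim_amplitude,stim_duration stimulus (pA, ms).
#' @param dt integration step, ms.
#' @return data.frame of class `restitution_table`: columns `bcl`, `apd80`,
#'   `captured`. Uncaptured rows carry `NA` APD.
#' @export
dynamic_restitution <- function(params = cell_params(), bcl_list,
                                beats_per_bcl = 20, mode = "single_cell",
                                stim_amplitude = 7, stim_duration = 5,
                                dt = 0.02) {
  if (is.unsorted(rev(bcl_list), strictly = TRUE))
    stop("bcl_list must be strictly descending")
  state <- NULL
  out <- data.frame(bcl = bcl_list, apd80 = NA_real_, captured = FALSE)
  for (i in seq_along(bcl_list)) {
    tr <- pace_cell(params, bcl = bcl_list[i], n_beats = beats_per_bcl,
                    stim_amplitude = stim_amplitude,
                    stim_duration = stim_duration, mode = mode,
                    state = state, dt = dt, record_dt = 0.1)
    state <- attr(tr, "final_state")
    beats <- attr(tr, "beats")
    out$captured[i] <- all(beats$captured)
    if (beats$captured[nrow(beats)])
      out$apd80[i] <- beats$APD80[nrow(beats)]
  }
  class(out) <- c("restitution_table", "data.frame")
  out
}

#' Holding current that clamps the resting potential to a target
#'
#' Returns the constant current that makes `V_target` a stationary point of
#' the membrane equation with all gates at their steady-state values for
#' `V_target` and the Ca2+ subsystem at rest (the current equals the total
#' ionic current at that quasi-steady state, so dV/dt = 0).
#'
#' @param params parameter set.
#' @param V_target target potential, mV (within -120..-40).
#' @param mode AP mode.
#' @return Holding current, pA/pF (negative = hyperpolarizing).
#' @export
holding_current_for <- function(params = cell_params(), V_target,
                                mode = "single_cell") {
  if (V_target < -120 || V_target > -40)
    stop("V_target must lie within -120..-40 mV")
  st <- initial_state(params, V = V_target)
  unname(total_current(st, params, mode)[["I_total"]])
}
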