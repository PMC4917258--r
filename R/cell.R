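#' Integrate the single-cell model
#'
#' Advances the full cell state (membrane potential, 17 gates, Ca2+
#' subsystem) with forward Euler for V, concentrations and RyR states and,
#' by default, Rush-Larsen exponential updates for the Hodgkin-Huxley gates
#' (a pure forward-Euler gate mode is available for fidelity comparison;
#' gates are clamped to \[0, 1\] either way).
#'
#' @param params parameter set ([cell_params()]).
#' @param duration simulated time, ms.
#' @param dt time step, ms (default 0.02).
#' @param stim data.frame with columns `start`, `duration` (ms) and
#'   `amplitude` (pA; converted to pA/pF via `params$C_cell`), or NULL.
#' @param i_hold constant holding current, pA/pF.
#' @param mode AP mode: `"single_cell"`, `"carbachol"`, `"constitutive"`,
#'   `"blocked"`.
#' @param state initial state; defaults to the packaged resting state.
#' @param record_dt sampling interval of the returned trace, ms.
#' @param record_currents if TRUE, attach all currents at the sampled times.
#' @param gate_method `"rush_larsen"` (default) or `"euler"`.
#' @return An object of class `nram_trace`: a data.frame with columns
#'   `time`, `V`, `Ca_i`, `Ca_NSR`, `Ca_JSR`, with the final state in
#'   `attr(, "final_state")` (and a `currents` attribute if requested).
#' @export
simulate_cell <- function(params = cell_params(), duration = 1000, dt = 0.02,
                          stim = NULL, i_hold = 0,
                          mode = c("single_cell", "carbachol", "constitutive",
                                   "blocked"),
                          state = NULL, record_dt = 0.1,
                          record_currents = FALSE,
                          gate_method = c("rush_larsen", "euler")) {
  mode <- match.arg(mode)
  gate_method <- match.arg(gate_method)
  if (dt <= 0) stop("dt must be positive")
  params <- .mode_params(params, mode)
  if (is.null(state)) state <- initial_state(params)
  if (is.null(stim)) stim <- data.frame(start = numeric(0), duration = numeric(0),
                                        amplitude = numeric(0))
  res <- .cpp_simulate_cell(as.numeric(state), params, .mode_int(mode),
                            dt, duration,
                            stim$start, stim$duration,
                            stim$amplitude / params$C_cell, i_hold,
                            record_dt, record_currents,
                            gate_method == "euler")
  tr <- data.frame(time = res$time, V = res$V, Ca_i = res$Ca_i,
                   Ca_NSR = res$Ca_NSR, Ca_JSR = res$Ca_JSR)
  attr(tr, "final_state") <- res$final_state
  if (record_currents) {
    cur <- res$currents
    colnames(cur) <- c("I_Na", "I_CaL", "I_CaT", "I_to", "I_Kur", "I_Kr",
                       "I_Ks", "I_Ksus", "I_K1", "I_KACh", "I_f", "I_NaK",
                       "I_NCX", "I_Nab", "I_Cab", "I_total",
                       "J_up", "J_rel", "J_leak", "J_tr")
    attr(tr, "currents") <- cur
  }
  attr(tr, "dt") <- dt
  attr(tr, "mode") <- mode
  attr(tr, "stim") <- stim
  class(tr) <- c("nram_trace", "data.frame")
  tr
}

#' Advance a single cell by one (or a few) time steps
#'
#' @param state state vector.
#' @param dt time step, ms (> 0).
#' @param I_stim stimulus current, pA/pF.
#' @param params parameter set.
#' @param mode AP mode (see [simulate_cell()]).
#' @param n number of steps to take.
#' @param gate_method `"rush_larsen"` or `"euler"`.
#' @return Updated named state vector.
#' @export
step_cell <- function(state, dt = 0.02, I_stim = 0, params = cell_params(),
                      mode = "single_cell", n = 1,
                      gate_method = c("rush_larsen", "euler")) {
  gate_method <- match.arg(gate_method)
  if (dt <= 0) stop("dt must be positive")
  params <- .mode_params(params, mode)
  stim <- data.frame(start = 0, duration = n * dt, amplitude = 0)
  res <- .cpp_simulate_cell(as.numeric(state), params, .mode_int(mode),
                            dt, n * dt, stim$start, stim$duration,
                            I_stim, 0, n * dt, FALSE,
                            gate_method == "euler")
  res$final_state
}

#' @export
print.nram_trace <- function(x, ...) {
  cat(sprintf("NRAM voltage/Ca trace: %.1f ms at %.3g ms sampling (%d rows)\n",
              max(x$time), x$time[2] - x$time[1], nrow(x)))
  cat(sprintf("  V range [%.1f, %.1f] mV; mode = %s\n",
              min(x$V), max(x$V), attr(x, "mode")))
  invisible(x)
}

#' @export
plot.nram_trace <- function(x, what = c("V", "Ca_i"), ...) {
  what <- match.arg(what)
  ylab <- if (what == "V") "V (mV)" else "[Ca]_i (mM)"
  graphics::plot(x$time, x[[what]], type = "l", xlab = "time (ms)",
                 ylab = ylab, ...)
  invisible(x)
}

#' Construct a periodic stimulus train
#'
#' @param start time of the first stimulus, ms.
#' @param cl cycle length, ms.
#' @param count number of stimuli.
#' @param amplitude stimulus strength, pA (converted by `C_cell`).
#' @param duration pulse width, ms.
#' @return data.frame usable as the `stim` argument of [simulate_cell()].
#' @export
stim_train <- function(start = 10, cl = 1000, count = 1, amplitude = 7,
                       duration = 5) {
  data.frame(start = start + cl * (seq_len(count) - 1),
             duration = duration, amplitude = amplitude)
}
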