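#' Ionic-model parameter set for a neonatal rat atrial cardiomyocyte
#'
#' Constructs the full parameter list of the NRAM ionic model: maximal
#' conductances (nS/pF), fixed intra/extracellular ion concentrations (mM),
#' physical constants, sarcoplasmic-reticulum (SR) calcium-handling constants,
#' buffer totals and dissociation constants, myofibroblast (passive membrane)
#' parameters, and per-current block fractions for drug interventions.
#'
#' The default values reproduce the published single-cell behaviour of the
#' model (resting potential -72 mV, AP amplitude ~133 mV, upstroke velocity
#' ~114 mV/ms, APD80 ~58 ms at 1 Hz) and, in tissue, a planar conduction
#' velocity of ~22 cm/s at D = 0.00012 cm^2/ms. Conductance values that are
#' not fixed by the printed current equations were calibrated once against
#' those observables; see the package vignette for the calibration rationale.
#'
#' Ion concentrations follow the patch-clamp solutions: pipette 8 mM Na+,
#' ~140 mM K+; bath 130 mM Na+, 5.4 mM K+, 1.8 mM Ca2+; T = 295 K.
#'
#' @param ... named overrides of any default parameter (e.g. `G_Na = 10`,
#'   `ACh = 100`, `block = c(I_KACh = 1)`). For `block`, a named vector of
#'   fractions in \[0, 1\] keyed by current id (see [block_currents()]);
#'   unnamed currents keep their current fraction.
#' @return An object of class `nram_params`: a validated named list.
#' @examples
#' p <- cell_params()
#' p$G_Na
#' p_tq <- cell_params(block = c(I_KACh = 1))  # tertiapin-Q
#' @export
cell_params <- function(...) {
  p <- .default_params()
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("all parameter overrides must be named")
    if (anyDuplicated(names(over)))
      stop("duplicated parameter override: ",
           paste(unique(names(over)[duplicated(names(over))]), collapse = ", "))
    for (nm in names(over)) {
      if (nm == "block") {
        b <- over$block
        if (is.null(names(b)) || !all(names(b) %in% block_currents()))
          stop("block must be a named vector keyed by current id; see block_currents()")
        p$block[names(b)] <- unname(b)
      } else {
        if (!nm %in% names(p)) stop("unknown parameter: ", nm)
        p[[nm]] <- over[[nm]]
      }
    }
  }
  validate_params(p)
}

#' Current identifiers that accept a drug-block fraction
#' @return Character vector of the 12 blockable membrane currents.
#' @export
block_currents <- function() {
  c("I_Na", "I_CaL", "I_CaT", "I_to", "I_Ksus", "I_K1",
    "I_KACh", "I_f", "I_NaK", "I_NCX", "I_Nab", "I_Cab")
}

.default_params <- function() {
  block <- stats::setNames(numeric(12), block_currents())
  list(
    ## physical constants
    T = 295,            # K (room temperature, 22 C)
    F = 96.485,         # C/mmol
    Cm = 1,             # uF/cm^2; makes pA/pF numerically equal to uA/cm^2
    C_cell = 1,         # pF; converts printed stimulus pA to pA/pF
    C_cell_phys = 20,   # pF; whole-cell capacitance for Ca flux bookkeeping
    V_cyto_pL = 0.85,   # pL; cytosolic volume for Ca flux bookkeeping
    ## fixed ion concentrations (mM)
    Na_o = 130, Na_i = 8, K_o = 5.4, K_i = 140, Ca_o = 1.8,
    ## acetylcholine (uM); single-cell baseline dose of the fitted IKACh
    ACh = 1,
    ## maximal conductances (nS/pF)
    G_Na = 3.4,
    G_CaL = 0.031,
    G_CaT = 0.189,
    G_to = 0.002,
    G_Kur = 0.008, G_Kr = 0.36, G_Ks = 1.3,
    G_f = 0.021,
    G_Nab = 4.0e-4, G_Cab = 4.43e-4,
    ## composite/scaled K+ currents
    k_Ksus_scale = 0.16,   # net scaling of IKur + IKr + IKs
    gK1_pref = 0.048925,   # composite inward-rectifier prefactor (47.5% of NRVM)
    gK1_scale = 1,
    g_Kleak = 0.01,        # linear K+ leak folded into the composite IK1
    g_KACh_c = 0.37488,    # constitutively active IKACh prefactor (tissue form)
    ## pumps and exchanger
    I_NaK_max = 0.6, Km_Nai = 10, Km_Ko = 1.5,
    k_NCX = 1.55e-5, eta_NCX = 0.35, d_NCX = 1e-4,
    ## room-temperature slowdown of the Na+ gate time constants
    k_tau_Na = 0.9,
    ## Na+ steady-state activation/inactivation (Boltzmann midpoint/slope)
    V_half_m = -54, k_m = 5, V_half_h = -62.1, k_h = 4.5,
    k_tau_h = 2.72, tau_h_min = 0.52, V_tau_h = -50,
    ## funny-current activation midpoint/slope
    V_half_y = -90, k_y = 6.33,
    k_tau_Xs = 1.9,
    ## SR Ca handling (common-pool NSR/JSR scheme)
    V_max_up = 1.1e-3,       # mM/ms SERCA
    Km_up_f = 2.46e-4, Km_up_r = 2.0, H_up = 1.787,
    tau_tr = 2.0,           # ms NSR -> JSR transfer
    k_leak = 2e-6,         # /ms
    k_s_rel = 4,           # /ms RyR release
    ko_Ca = 6.89e-2, ko_m = 0.08, ki_Ca = 5, ki_m = 8e-4,
    K_rel_Ca = 2.06e-4,       # mM; reference Ca of the RyR trigger
    n_RyR = 2,             # Hill steepness of the bulk-Ca RyR trigger
    max_SR = 15, min_SR = 1, EC50_SR = 0.45, h_SR = 2.5,
    ## Ca buffers
    TRPN_tot = 0.035, Km_TRPN = 5e-4,
    CMDN_tot = 0.117, Km_CMDN = 2.38e-3,
    CSQN_tot = 60, Km_CSQN = 0.8,
    ## compartment volumes as fractions of cytosolic volume (JSR = 10% of SR)
    v_NSR = 0.081, v_JSR = 0.009,
    ## Ca-dependent inactivation of ICaL
    K_fCa = 3e-4, tau_fCa = 10,
    tau_g_min = 12,   # ms; depolarized floor of the T-type inactivation tau
    V_half_b = -37, V_half_g = -67,  # T-type activation/inactivation midpoints
    V_half_d = -6, V_half_f = -32,  # L-type activation/inactivation midpoints
    ## myofibroblast (passive) and gap-junctional coupling
    G_fb = 0.016, E_fb = -49.6, C_fb = 6.3, G_gap = 0.5,
    ## drug block fractions
    block = block
  )
}

#' @export
print.nram_params <- function(x, ...) {
  cat("NRAM ionic-model parameters\n")
  cat(sprintf("  G_Na=%.3g G_CaL=%.3g G_CaT=%.3g G_to=%.3g nS/pF\n",
              x$G_Na, x$G_CaL, x$G_CaT, x$G_to))
  cat(sprintf("  [Na]o/[Na]i=%.4g/%.4g  [K]o/[K]i=%.4g/%.4g  [Ca]o=%.4g mM, T=%g K\n",
              x$Na_o, x$Na_i, x$K_o, x$K_i, x$Ca_o, x$T))
  blocked <- x$block[x$block > 0]
  if (length(blocked))
    cat("  block:", paste(sprintf("%s=%.2f", names(blocked), blocked), collapse = ", "), "\n")
  invisible(x)
}

#' Validate an NRAM parameter list
#'
#' Checks positivity of concentrations, non-negativity of conductances,
#' block fractions in \[0, 1\] and the JSR/SR volume ratio (JSR is 10% of
#' the total SR volume).
#'
#' @param p a parameter list as produced by [cell_params()].
#' @return The validated list, classed `nram_params`.
#' @export
validate_params <- function(p) {
  stopifnot(is.list(p))
  need <- names(.default_params())
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("missing parameters: ", paste(miss, collapse = ", "))
  conc <- c("Na_o", "Na_i", "K_o", "K_i", "Ca_o")
  for (nm in conc) if (p[[nm]] <= 0) stop("concentration ", nm, " must be > 0")
  gs <- c("G_Na", "G_CaL", "G_CaT", "G_to", "G_Kur", "G_Kr", "G_Ks", "G_f",
          "G_Nab", "G_Cab", "g_Kleak", "gK1_pref", "g_KACh_c", "G_fb", "G_gap")
  for (nm in gs) if (p[[nm]] < 0) stop("conductance ", nm, " must be >= 0")
  if (any(p$block < 0 | p$block > 1)) stop("block fractions must lie in [0, 1]")
  if (p$ACh < 0) stop("ACh must be >= 0")
  r <- p$v_JSR / (p$v_JSR + p$v_NSR)
  if (abs(r - 0.1) > 1e-6)
    stop("v_JSR/(v_JSR + v_NSR) must equal 0.1 (JSR is 10% of the SR)")
  for (nm in c("V_max_up", "tau_tr", "k_leak", "k_s_rel", "tau_fCa"))
    if (p[[nm]] <= 0 && nm %in% c("tau_tr", "tau_fCa")) stop(nm, " must be > 0")
  class(p) <- "nram_params"
  p
}

#' Resting state of the single-cell model
#'
#' Returns the quiescent steady state reached by the unstimulated model with
#' default parameters (pre-relaxed; membrane potential near -72 mV). The Ca
#' entries are conserved totals: `Ca_tot_i` includes troponin/calmodulin-bound
#' Ca and `Ca_tot_JSR` includes calsequestrin-bound Ca; free concentrations
#' are recovered with [free_calcium()].
#'
#' @param params parameter set; used to place gates at their steady-state
#'   values for the resting potential.
#' @param V resting membrane potential at which gates are initialised.
#' @return Named numeric state vector of length 24.
#' @export
initial_state <- function(params = cell_params(), V = -72.08) {
  k <- gate_kinetics_all(V)
  ca_i <- 2.873e-4
  ca_nsr <- 0.7346
  ca_jsr <- 0.6217
  catot_i <- ca_i + params$TRPN_tot * ca_i / (params$Km_TRPN + ca_i) +
    params$CMDN_tot * ca_i / (params$Km_CMDN + ca_i)
  catot_jsr <- ca_jsr + params$CSQN_tot * ca_jsr / (params$Km_CSQN + ca_jsr)
  st <- c(V = V,
          m = k$x_inf[["m"]], h = k$x_inf[["h"]], j = k$x_inf[["j"]],
          d = k$x_inf[["d"]], f = k$x_inf[["f"]], fCa = 1 / (1 + (ca_i / params$K_fCa)^2),
          b = k$x_inf[["b"]], g = k$x_inf[["g"]],
          r = k$x_inf[["r"]], s = k$x_inf[["s"]], s_slow = k$x_inf[["s_slow"]],
          ua = k$x_inf[["ua"]], ui = k$x_inf[["ui"]],
          Xr = k$x_inf[["Xr"]], Xs1 = k$x_inf[["Xs1"]], Xs2 = k$x_inf[["Xs2"]],
          y = k$x_inf[["y"]],
          Ca_tot_i = catot_i, Ca_NSR = ca_nsr, Ca_tot_JSR = catot_jsr,
          RyR_R = 0.0721, RyR_O = 0.0227, RyR_I = 0.217)
  st
}

#' Free Ca2+ concentrations from the conserved state totals
#'
#' Inverts the rapid-buffer equilibria: the cytosolic total (troponin +
#' calmodulin) by Newton iteration, the junctional-SR total (calsequestrin)
#' in closed form.
#'
#' @param state state vector or matrix (24 x n) as used by the integrators.
#' @param params parameter set.
#' @return Named list with `Ca_i`, `Ca_NSR`, `Ca_JSR` (mM, free).
#' @export
free_calcium <- function(state, params = cell_params()) {
  if (is.matrix(state)) {
    list(Ca_i = .cpp_free_ca(state["Ca_tot_i", ], params, FALSE),
         Ca_NSR = state["Ca_NSR", ],
         Ca_JSR = .cpp_free_ca(state["Ca_tot_JSR", ], params, TRUE))
  } else {
    list(Ca_i = .cpp_free_ca(state[["Ca_tot_i"]], params, FALSE),
         Ca_NSR = state[["Ca_NSR"]],
         Ca_JSR = .cpp_free_ca(state[["Ca_tot_JSR"]], params, TRUE))
  }
}

.mode_int <- function(mode) {
  mode <- match.arg(mode, c("single_cell", "carbachol", "constitutive", "blocked"))
  switch(mode, single_cell = 0L, carbachol = 0L, constitutive = 1L, blocked = 1L)
}

# resolves mode-dependent parameter adjustments (carbachol dose, tertiapin block)
.mode_params <- function(params, mode) {
  if (mode == "carbachol") params$ACh <- 100
  if (mode == "blocked") params$block[["I_KACh"]] <- 1
  params
}
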