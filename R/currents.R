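#' Nernst equilibrium potential
#'
#' @param z ionic valence (integer; 1 for Na+/K+, 2 for Ca2+).
#' @param X_o,X_i extracellular and intracellular concentrations (mM, > 0).
#' @param T temperature in kelvin.
#' @return Equilibrium potential in mV: (RT/zF) ln(X_o/X_i).
#' @examples
#' nernst_potential(1, 5.4, 140, 295)  # E_K, about -82.8 mV
#' @export
nernst_potential <- function(z, X_o, X_i, T = 295) {
  if (any(X_o <= 0) || any(X_i <= 0))
    stop("concentrations must be positive for a Nernst potential")
  (8.314 * T / (z * 96.485)) * log(X_o / X_i)
}

.EK <- function(p) nernst_potential(1, p$K_o, p$K_i, p$T)
.ENa <- function(p) nernst_potential(1, p$Na_o, p$Na_i, p$T)
.ECa <- function(p, Ca_i) nernst_potential(2, p$Ca_o, pmax(Ca_i, 1e-8), p$T)

#' Fast Na+ current
#'
#' Three-gate formulation `I_Na = G_Na m^3 h j (V - E_Na)` with activation
#' gate m and fast/slow inactivation gates h, j.
#'
#' @param V membrane potential, mV.
#' @param m,h,j gate values in \[0, 1\].
#' @param params parameter set.
#' @return Current density, pA/pF (negative = inward).
#' @export
i_na <- function(V, m, h, j, params = cell_params()) {
  params$G_Na * m^3 * h * j * (V - .ENa(params))
}

#' L-type Ca2+ current (GHK driving force)
#'
#' `I_CaL = 4 G_CaL d f fCa (V F^2/RT) ([Ca]_i e^{2VF/RT} - 0.341 [Ca]_o) /
#' (e^{2VF/RT} - 1)`, with Na+/K+ permeability neglected. The removable
#' singularity at V = 0 is evaluated by its analytic limit.
#'
#' @param V membrane potential, mV.
#' @param d,f voltage-dependent activation/inactivation gates.
#' @param fCa Ca-dependent inactivation gate.
#' @param Ca_i free cytosolic Ca2+ (mM, > 0).
#' @param params parameter set.
#' @return Current density, pA/pF.
#' @export
i_cal <- function(V, d, f, fCa, Ca_i, params = cell_params()) {
  if (any(Ca_i <= 0)) stop("Ca_i must be positive")
  p <- params
  RTF <- 8.314 * p$T / p$F
  a <- 2 * V / RTF
  lim <- 0.5 * p$F * (Ca_i - 0.341 * p$Ca_o)
  reg <- (V * p$F / RTF) * (Ca_i * exp(a) - 0.341 * p$Ca_o) / expm1(a)
  4 * p$G_CaL * d * f * fCa * ifelse(abs(a) < 1e-7, lim, reg)
}

#' T-type Ca2+ current
#'
#' `I_CaT = G_CaT b g (V - E_Ca + 106.5)`; zero driving force at
#' V = E_Ca - 106.5 mV.
#'
#' @param V membrane potential, mV.
#' @param b,g activation/inactivation gates.
#' @param Ca_i free cytosolic Ca2+ (mM) defining E_Ca.
#' @param params parameter set.
#' @return Current density, pA/pF.
#' @export
i_cat <- function(V, b, g, Ca_i = 1e-4, params = cell_params()) {
  params$G_CaT * b * g * (V - .ECa(params, Ca_i) + 106.5)
}

#' Transient outward K+ current
#'
#' `I_to = G_to r (0.706 s + 0.294 s_slow)(V - E_K)` with fixed fast/slow
#' inactivation weights.
#'
#' @param V membrane potential, mV.
#' @param r activation gate; `s`, `s_slow` fast and slow inactivation gates.
#' @param s,s_slow inactivation gates.
#' @param params parameter set.
#' @return Current density, pA/pF.
#' @export
i_to <- function(V, r, s, s_slow, params = cell_params()) {
  params$G_to * r * (0.706 * s + 0.294 * s_slow) * (V - .EK(params))
}

#' Sustained outward K+ current
#'
#' Composite `I_Ksus = 0.16 (I_Kur + I_Kr + I_Ks)`: ultra-rapid (gates ua,
#' ui), rapid delayed rectifier (gate Xr with instantaneous rectification)
#' and slow delayed rectifier (gates Xs1, Xs2) components.
#'
#' @param V membrane potential, mV.
#' @param ua,ui,Xr,Xs1,Xs2 gate values.
#' @param params parameter set.
#' @return Named list with the three components and the scaled total
#'   (`I_Ksus`), pA/pF.
#' @export
i_ksus <- function(V, ua, ui, Xr, Xs1, Xs2, params = cell_params()) {
  EK <- .EK(params)
  IKur <- params$G_Kur * ua * ui * (V - EK)
  Rr <- 1 / (1 + exp((V + 10) / 15.4))
  IKr <- params$G_Kr * Xr * Rr * (V - EK)
  IKs <- params$G_Ks * Xs1 * Xs2 * (V - EK)
  list(I_Kur = IKur, I_Kr = IKr, I_Ks = IKs,
       I_Ksus = params$k_Ksus_scale * (IKur + IKr + IKs))
}

#' Composite inward-rectifier K+ current with K+ leak
#'
#' `0.048925 (K_o/(K_o + 210)) (V - E_K - 10)/(1 + exp(0.041 (V - E_K - 10)))
#'  + 0.01 (V - E_K)`. The +10 mV shift reflects the K+ leak contamination of
#' the measured rectifier; the prefactor absorbs the 47.5% scaling relative
#' to a neonatal rat ventricular cell.
#'
#' @param V membrane potential, mV.
#' @param K_o extracellular K+ (mM); defaults to the parameter-set value.
#' @param params parameter set.
#' @return Current density, pA/pF.
#' @export
i_k1bar <- function(V, K_o = NULL, params = cell_params()) {
  p <- params
  if (!is.null(K_o)) p$K_o <- K_o
  EK <- .EK(p)
  dk <- V - EK - 10
  p$gK1_scale * p$gK1_pref * (p$K_o / (p$K_o + 210)) * dk / (1 + exp(0.041 * dk)) +
    p$g_Kleak * (V - EK)
}

#' Acetylcholine-mediated K+ current (single-cell form)
#'
#' Dose-dependent form fitted at \[ACh\] = 1 uM:
#' `I_KACh = 3.5/(1 + 9.13652/[ACh]^0.477811) (0.04 + 0.23/(1 + e^{(V+102)/10}))
#' (V - E_K - 10)`. Monotone increasing in \[ACh\]; zero at V = E_K + 10.
#'
#' @param V membrane potential, mV.
#' @param ACh acetylcholine concentration, uM (>= 0).
#' @param params parameter set.
#' @return Current density, pA/pF.
#' @export
i_kach <- function(V, ACh = 1, params = cell_params()) {
  achp <- ifelse(ACh > 0, ACh^0.477811, 0)
  dose <- 3.5 * achp / (achp + 9.13652)
  dose * (0.04 + 0.23 / (1 + exp((V + 102) / 10))) * (V - .EK(params) - 10)
}

#' Constitutively active acetylcholine-mediated K+ current (tissue form)
#'
#' Agonist-independent form used in monolayers:
#' `I_KACh-c = 0.37488 (0.075 + 0.35/(1 + e^{(V+102)/10})) (V - E_K - 10)`.
#'
#' @param V membrane potential, mV.
#' @param params parameter set.
#' @return Current density, pA/pF.
#' @export
i_kach_c <- function(V, params = cell_params()) {
  params$g_KACh_c * (0.075 + 0.35 / (1 + exp((V + 102) / 10))) *
    (V - .EK(params) - 10)
}

#' Hyperpolarization-activated funny current
#'
#' Mixed Na+/K+ current `I_f = G_f y (0.2 (V - E_Na) + 0.8 (V - E_K))`,
#' activated by hyperpolarization through gate y.
#'
#' @param V membrane potential, mV.
#' @param y activation gate.
#' @param params parameter set.
#' @return Current density, pA/pF.
#' @export
i_f <- function(V, y, params = cell_params()) {
  params$G_f * y * (0.2 * (V - .ENa(params)) + 0.8 * (V - .EK(params)))
}

#' Pump, exchanger and background currents
#'
#' Na+/K+ pump (voltage- and \[K\]o-dependent, saturable in \[Na\]i),
#' Na+/Ca2+ exchanger, and linear Ohmic Na+ and Ca2+ background currents.
#'
#' @param V membrane potential, mV.
#' @param Ca_i free cytosolic Ca2+, mM.
#' @param params parameter set.
#' @return Named list `I_NaK`, `I_NCX`, `I_Nab`, `I_Cab` (pA/pF).
#' @export
pumps_and_backgrounds <- function(V, Ca_i = 1e-4, params = cell_params()) {
  p <- params
  RTF <- 8.314 * p$T / p$F
  sig <- (exp(p$Na_o / 67.3) - 1) / 7
  fNaK <- 1 / (1 + 0.1245 * exp(-0.1 * V / RTF) + 0.0365 * sig * exp(-V / RTF))
  INaK <- p$I_NaK_max * fNaK * (1 / (1 + (p$Km_Nai / p$Na_i)^1.5)) *
    (p$K_o / (p$K_o + p$Km_Ko))
  na3i <- p$Na_i^3; na3o <- p$Na_o^3
  INCX <- p$k_NCX * (na3i * p$Ca_o * exp(p$eta_NCX * V / RTF) -
                       na3o * Ca_i * exp((p$eta_NCX - 1) * V / RTF)) /
    (1 + p$d_NCX * (na3o * Ca_i + na3i * p$Ca_o))
  list(I_NaK = INaK, I_NCX = INCX,
       I_Nab = p$G_Nab * (V - .ENa(p)),
       I_Cab = p$G_Cab * (V - .ECa(p, Ca_i)))
}

#' Sarcoplasmic-reticulum Ca2+ fluxes
#'
#' SERCA uptake (bidirectional, Hill form), RyR release, passive NSR leak
#' and NSR-to-JSR transfer, evaluated from a state vector. Fluxes are
#' expressed in mM/ms of their source compartment (`J_up`, `J_leak`
#' cytosolic; `J_rel`, `J_tr` junctional-SR).
#'
#' @param state state vector (see [initial_state()]); free Ca is recovered
#'   from the conserved totals.
#' @param params parameter set.
#' @return Named list `J_up`, `J_rel`, `J_leak`, `J_tr`.
#' @export
calcium_fluxes <- function(state, params = cell_params()) {
  if (state[["Ca_tot_i"]] < 0 || state[["Ca_NSR"]] < 0 || state[["Ca_tot_JSR"]] < 0)
    stop("negative Ca concentration in state")
  p <- params
  ca <- free_calcium(state, p)
  fwd <- (ca$Ca_i / p$Km_up_f)^p$H_up
  rev <- (ca$Ca_NSR / p$Km_up_r)^p$H_up
  list(J_up = p$V_max_up * (fwd - rev) / (1 + fwd + rev),
       J_rel = p$k_s_rel * state[["RyR_O"]] * (ca$Ca_JSR - ca$Ca_i),
       J_leak = p$k_leak * (ca$Ca_NSR - ca$Ca_i),
       J_tr = (ca$Ca_NSR - ca$Ca_JSR) / p$tau_tr)
}

#' All membrane currents and SR fluxes for a state
#'
#' Evaluates every current of the total ionic current (the compiled
#' evaluator used by the integrators), with the acetylcholine-mediated K+
#' term selected by `mode`: the dose-dependent single-cell form, or the
#' constitutively active tissue form. Drug block fractions in
#' `params$block` scale each current by (1 - fraction).
#'
#' @param state named state vector of length 24.
#' @param params parameter set.
#' @param mode `"single_cell"`, `"carbachol"` (saturating agonist dose),
#'   `"constitutive"` or `"blocked"` (constitutive with full I_KACh block).
#' @return Named numeric vector: all currents (pA/pF), the SR fluxes
#'   (mM/ms) and `I_total`.
#' @export
total_current <- function(state, params = cell_params(),
                          mode = "single_cell") {
  params <- .mode_params(params, match.arg(mode, c("single_cell", "carbachol",
                                                   "constitutive", "blocked")))
  .cpp_currents(as.numeric(state), params, .mode_int(mode))
}

# pure-R cross-check of the compiled current evaluator (used by tests)
total_current_R <- function(state, params = cell_params(), mode = "single_cell") {
  p <- .mode_params(params, mode)
  blk <- p$block
  ca <- free_calcium(state, p)
  V <- state[["V"]]
  cur <- c(
    I_Na = i_na(V, state[["m"]], state[["h"]], state[["j"]], p) * (1 - blk[["I_Na"]]),
    I_CaL = i_cal(V, state[["d"]], state[["f"]], state[["fCa"]],
                  max(ca$Ca_i, 1e-12), p) * (1 - blk[["I_CaL"]]),
    I_CaT = i_cat(V, state[["b"]], state[["g"]], ca$Ca_i, p) * (1 - blk[["I_CaT"]]),
    I_to = i_to(V, state[["r"]], state[["s"]], state[["s_slow"]], p) *
      (1 - blk[["I_to"]])
  )
  ks <- i_ksus(V, state[["ua"]], state[["ui"]], state[["Xr"]],
               state[["Xs1"]], state[["Xs2"]], p)
  cur["I_Ksus"] <- ks$I_Ksus * (1 - blk[["I_Ksus"]])
  cur["I_K1"] <- i_k1bar(V, params = p) * (1 - blk[["I_K1"]])
  kach <- if (.mode_int(mode) == 0) i_kach(V, p$ACh, p) else i_kach_c(V, p)
  cur["I_KACh"] <- kach * (1 - blk[["I_KACh"]])
  cur["I_f"] <- i_f(V, state[["y"]], p) * (1 - blk[["I_f"]])
  pb <- pumps_and_backgrounds(V, ca$Ca_i, p)
  cur["I_NaK"] <- pb$I_NaK * (1 - blk[["I_NaK"]])
  cur["I_NCX"] <- pb$I_NCX * (1 - blk[["I_NCX"]])
  cur["I_Nab"] <- pb$I_Nab * (1 - blk[["I_Nab"]])
  cur["I_Cab"] <- pb$I_Cab * (1 - blk[["I_Cab"]])
  cur["I_total"] <- sum(cur[c("I_Na", "I_CaL", "I_K1", "I_to", "I_CaT", "I_Cab",
                              "I_NCX", "I_NaK", "I_f", "I_Nab", "I_Ksus",
                              "I_KACh")])
  cur
}
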