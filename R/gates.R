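#' Steady-state value and time constant of a gating variable
#'
#' Hodgkin-Huxley gate kinetics of the NRAM model. Activation gates
#' (`m, d, b, r, ua, Xr, Xs1, Xs2`) have steady states increasing in V;
#' inactivation gates (`h, j, f, g, s, s_slow, ui, y`) decrease in V. The
#' fast and slow Na+ inactivation gates `h` and `j` share one steady-state
#' inactivation curve; their time constants differ (fast vs slow recovery).
#' The Na+ time constants carry a room-temperature slowdown factor
#' `k_tau_Na`, and the L-type Ca2+ activation time constant carries a fixed
#' +10 ms correction.
#'
#' The Ca-dependent inactivation gate `fCa` of the L-type current is not a
#' function of voltage; see [i_cal()].
#'
#' @param gate one of `"m","h","j","d","f","b","g","r","s","s_slow",
#'   "ua","ui","Xr","Xs1","Xs2","y"`.
#' @param V membrane potential(s), mV.
#' @param params parameter set (only `k_tau_Na` is used).
#' @return data.frame with columns `V`, `x_inf` (in \[0,1\]) and `tau` (ms, > 0).
#' @export
gate_kinetics <- function(gate, V, params = cell_params()) {
  gates <- c("m", "h", "j", "d", "f", "b", "g", "r", "s", "s_slow",
             "ua", "ui", "Xr", "Xs1", "Xs2", "y")
  if (!is.character(gate) || length(gate) != 1 || !gate %in% gates)
    stop("unknown gate id: ", paste(gate, collapse = ","),
         " (expected one of ", paste(gates, collapse = ", "), ")")
  k <- gate_kinetics_all(V, params)
  if (length(V) == 1)
    data.frame(V = V, x_inf = k$x_inf[[gate]], tau = k$tau[[gate]])
  else
    data.frame(V = V, x_inf = k$x_inf[, gate], tau = k$tau[, gate],
               row.names = NULL)
}

# all 16 voltage-dependent gates at once; V may be a vector.
# Returns list(x_inf = matrix, tau = matrix) with named columns (single V:
# matrices keep drop = FALSE semantics via [1, ]).
gate_kinetics_all <- function(V, params = cell_params()) {
  kt <- params$k_tau_Na
  sig <- function(v) 1 / (1 + exp(v))
  n <- length(V)
  x_inf <- matrix(NA_real_, n, 16)
  tau <- matrix(NA_real_, n, 16)
  colnames(x_inf) <- colnames(tau) <-
    c("m", "h", "j", "d", "f", "b", "g", "r", "s", "s_slow",
      "ua", "ui", "Xr", "Xs1", "Xs2", "y")
  ## fast Na+: activation fit to neonatal atrial data; taus from Luo-Rudy
  ## rates slowed by k_tau_Na for room temperature
  x_inf[, "m"] <- sig(-(V - params$V_half_m) / params$k_m)
  dvm <- V + 47.13
  am <- ifelse(abs(dvm) < 1e-6, 3.2, 0.32 * dvm / (1 - exp(-0.1 * dvm)))
  bm <- 0.08 * exp(-V / 11)
  tau[, "m"] <- kt / (am + bm)
  x_inf[, "h"] <- x_inf[, "j"] <- sig((V - params$V_half_h) / params$k_h)
  tau[, "h"] <- params$k_tau_h * (params$tau_h_min + 9 / (1 + exp((V - params$V_tau_h) / 8)))
  aj <- ifelse(V < -40,
               (-127140 * exp(0.2444 * V) - 3.474e-5 * exp(-0.04391 * V)) *
                 (V + 37.78) / (1 + exp(0.311 * (V + 79.23))), 0)
  bj <- ifelse(V < -40,
               0.1212 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14))),
               0.3 * exp(-2.535e-7 * V) / (1 + exp(-0.1 * (V + 32))))
  tau[, "j"] <- kt / (aj + bj)
  ## L-type Ca2+ (d, f); +10 ms correction on tau_d
  x_inf[, "d"] <- sig(-(V - params$V_half_d) / 6.5)
  ad <- 1.4 / (1 + exp((-35 - V) / 13)) + 0.25
  bd <- 1.4 / (1 + exp((V + 5) / 5))
  gd <- 1 / (1 + exp((50 - V) / 20))
  tau[, "d"] <- 10 + ad * bd + gd
  x_inf[, "f"] <- sig((V - params$V_half_f) / 6)
  tau[, "f"] <- 1125 * exp(-(V + 27)^2 / 240) + 80 + 165 / (1 + exp((25 - V) / 10))
  ## T-type Ca2+ (b, g)
  x_inf[, "b"] <- sig(-(V - params$V_half_b) / 5.5)
  tau[, "b"] <- 1 + 5 / (1 + exp((V + 60) / 10))
  x_inf[, "g"] <- sig((V - params$V_half_g) / 5.5)
  tau[, "g"] <- params$tau_g_min + 32 / (1 + exp((V + 65) / 8))
  ## transient outward (r, s, s_slow)
  x_inf[, "r"] <- sig(-(V + 10.6) / 11.42)
  tau[, "r"] <- 1000 / (45.16 * exp(0.03577 * (V + 50)) + 98.9 * exp(-0.1 * (V + 38)))
  x_inf[, "s"] <- x_inf[, "s_slow"] <- sig((V + 45.3) / 6.8841)
  tau[, "s"] <- 350 * exp(-((V + 70) / 15)^2) + 35
  tau[, "s_slow"] <- 3700 * exp(-((V + 70) / 30)^2) + 35
  ## ultra-rapid K+ (ua, ui)
  x_inf[, "ua"] <- sig(-(V + 22.5) / 7.7)
  tau[, "ua"] <- 0.493 * exp(-0.0629 * V) + 2.058
  x_inf[, "ui"] <- sig((V + 45.2) / 5.7)
  tau[, "ui"] <- 1200 - 170 / (1 + exp((V + 45.2) / 5.7))
  ## rapid delayed rectifier (Xr)
  x_inf[, "Xr"] <- sig(-(V + 15) / 6)
  tau[, "Xr"] <- 50 + 450 * exp(-(V + 30)^2 / 900)
  ## slow delayed rectifier (Xs1, Xs2)
  x_inf[, "Xs1"] <- x_inf[, "Xs2"] <- sig(-(V + 10) / 16)
  tau[, "Xs1"] <- params$k_tau_Xs * (200 + 800 * exp(-(V + 25)^2 / 1600))
  tau[, "Xs2"] <- 4 * tau[, "Xs1"]
  ## funny current (y)
  x_inf[, "y"] <- sig((V - params$V_half_y) / params$k_y)
  tau[, "y"] <- 1000 / (0.11885 * exp((V + 75) / 28.37) +
                          0.56236 * exp(-(V + 75) / 14.19))
  if (n == 1) {
    x_inf <- x_inf[1, ]
    tau <- tau[1, ]
  }
  list(x_inf = x_inf, tau = tau)
}
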