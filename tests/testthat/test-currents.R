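test_that("Nernst potential matches direct evaluation and its symmetries", {
  # identical concentrations give zero
  expect_equal(nernst_potential(1, 5.4, 5.4), 0)
  # E_K for the standard solutions, evaluated independently:
  # (8.314 * 295 / 96485) * ln(5.4/140) V = -82.75 mV
  expect_equal(nernst_potential(1, 5.4, 140, 295), -82.75, tolerance = 1e-3)
  # divalent ion halves the magnitude at the same ratio
  expect_equal(nernst_potential(2, 10, 1), nernst_potential(1, 10, 1) / 2)
  expect_error(nernst_potential(1, -1, 140), "positive")
  expect_error(nernst_potential(1, 5.4, 0), "positive")
})

test_that("each current vanishes at its reversal condition", {
  p <- default_params
  expect_equal(i_na(E_Na, 0.5, 0.5, 0.5, p), 0)
  expect_equal(i_to(E_K, 0.5, 0.5, 0.5, p), 0)
  expect_equal(i_kach(E_K + 10, 1, p), 0)
  expect_equal(i_kach_c(E_K + 10, p), 0)
  # T-type reversal sits 106.5 mV below E_Ca
  ca_i <- 1e-4
  e_ca <- nernst_potential(2, p$Ca_o, ca_i, p$T)
  expect_equal(i_cat(e_ca - 106.5, 1, 1, ca_i, p), 0)
  # GHK bracket zero: [Ca]_i e^{2VF/RT} = 0.341 [Ca]_o
  RTF <- 8.314 * p$T / p$F
  v_rev <- RTF / 2 * log(0.341 * p$Ca_o / ca_i)
  expect_equal(i_cal(v_rev, 1, 1, 1, ca_i, p), 0, tolerance = 1e-10)
  # background currents at their equilibria
  pb <- pumps_and_backgrounds(E_Na, ca_i, p)
  expect_equal(pb$I_Nab, 0)
  pb2 <- pumps_and_backgrounds(e_ca, ca_i, p)
  expect_equal(pb2$I_Cab, 0)
})

test_that("closed gates silence the gated currents", {
  p <- default_params
  expect_equal(i_na(-20, 0, 1, 1, p), 0)
  expect_equal(i_cal(-20, 0, 1, 1, 1e-4, p), 0)
  expect_equal(i_cat(-20, 0, 1, 1e-4, p), 0)
  expect_equal(i_f(-20, 0, p), 0)
  ks <- i_ksus(-20, 0, 0.5, 0, 0, 0, p)
  expect_equal(ks$I_Ksus, 0)
})

test_that("direct substitutions reproduce the closed-form current values", {
  p <- default_params
  # I_Na with open gates, 10 mV above reversal
  expect_equal(i_na(E_Na + 10, 1, 1, 1, p), 10 * p$G_Na)
  # I_to weight ratio between pure-fast and pure-slow inactivation
  r_fast <- i_to(0, 1, 1, 0, p)
  r_slow <- i_to(0, 1, 0, 1, p)
  expect_equal(r_fast / r_slow, 0.706 / 0.294)
  expect_equal(i_to(E_K + 100, 1, 1, 1, p), 100 * p$G_to)
  # I_CaT linearity in the driving force
  ca_i <- 1e-4
  e_ca <- nernst_potential(2, p$Ca_o, ca_i, p$T)
  expect_equal(i_cat(e_ca - 106.5 + 1, 1, 1, ca_i, p), p$G_CaT)
})

test_that("GHK driving force is continuous through V = 0", {
  p <- default_params
  v0 <- i_cal(0, 1, 1, 1, 1e-4, p)
  vp <- i_cal(1e-6, 1, 1, 1, 1e-4, p)
  vm <- i_cal(-1e-6, 1, 1, 1, 1e-4, p)
  expect_true(is.finite(v0))
  expect_equal(v0, vp, tolerance = 1e-6)
  expect_equal(v0, vm, tolerance = 1e-6)
  # analytic limit at V = 0: 2 F G_CaL (Ca_i - 0.341 Ca_o)
  expect_equal(v0, 2 * p$F * p$G_CaL * (1e-4 - 0.341 * p$Ca_o),
               tolerance = 1e-9)
  expect_error(i_cal(0, 1, 1, 1, -1e-4, p), "positive")
})

test_that("the sustained K+ current is the fixed 0.16-scaled component sum", {
  p <- default_params
  ks <- i_ksus(10, 0.7, 0.8, 0.3, 0.2, 0.2, p)
  expect_equal(ks$I_Ksus, 0.16 * (ks$I_Kur + ks$I_Kr + ks$I_Ks))
  p2 <- cell_params(k_Ksus_scale = 1)
  ks2 <- i_ksus(10, 0.7, 0.8, 0.3, 0.2, 0.2, p2)
  expect_equal(ks$I_Ksus, 0.16 * ks2$I_Ksus)
})

test_that("composite inward rectifier follows its printed form", {
  p <- default_params
  # at V = E_K + 10 the rectifier term vanishes; only the leak remains
  expect_equal(i_k1bar(E_K + 10, params = p), 0.01 * 10, tolerance = 1e-12)
  # at V = E_K the leak is zero and the rectifier takes its closed form
  expected <- 0.048925 * (5.4 / (5.4 + 210)) * (-10) / (1 + exp(0.041 * -10))
  expect_equal(i_k1bar(E_K, params = p), expected, tolerance = 1e-12)
  # strong depolarization: rectifier term decays, leaving the linear leak
  v <- 60
  leak_only <- 0.01 * (v - E_K)
  expect_lt(abs(i_k1bar(v, params = p) - leak_only), 0.02)
})

test_that("acetylcholine dose dependence is monotone and saturating", {
  p <- default_params
  v <- -100
  doses <- c(0, 0.01, 0.1, 1, 10, 100)
  vals <- vapply(doses, function(a) i_kach(v, a, p), 0)
  expect_equal(vals[1], 0)           # no agonist, no current
  expect_true(all(diff(abs(vals)) > 0))   # magnitude grows with dose
  # direct evaluation at the fitted dose
  dose <- 3.5 / (1 + 9.13652 / 1^0.477811)
  vfac <- 0.04 + 0.23 / (1 + exp((-100 + 102) / 10))
  expect_equal(i_kach(-100, 1, p), dose * vfac * (-100 - E_K - 10))
})

test_that("constitutively active form is agonist-independent with bounded slope", {
  p1 <- cell_params(ACh = 0)
  p2 <- cell_params(ACh = 50)
  v <- seq(-120, 40, by = 5)
  expect_equal(i_kach_c(v, p1), i_kach_c(v, p2))
  # conductance factor bounds: 0.37488 * [0.075, 0.425]
  f <- i_kach_c(v, p1) / (v - E_K - 10)
  expect_true(all(f > 0.37488 * 0.075 - 1e-9))
  expect_true(all(f < 0.37488 * 0.425 + 1e-9))
  # sigmoid midpoint at -102 mV
  expect_equal(i_kach_c(-102, p1),
               0.37488 * (0.075 + 0.175) * (-102 - E_K - 10))
})

test_that("pump current saturates in substrate and stays non-negative", {
  p <- default_params
  v <- seq(-100, 40, by = 10)
  pb <- pumps_and_backgrounds(v, 1e-4, p)
  expect_true(all(pb$I_NaK >= 0))
  p_lowNa <- cell_params(Na_i = 1e-4)
  pb2 <- pumps_and_backgrounds(-70, 1e-4, p_lowNa)
  expect_lt(pb2$I_NaK, 1e-6)
})

test_that("compiled current evaluator agrees with the plain-R formulas", {
  for (st in random_states(20)) {
    for (mode in c("single_cell", "constitutive")) {
      cxx <- total_current(st, default_params, mode)
      ref <- nram:::total_current_R(st, default_params, mode)
      for (nm in names(ref))
        expect_equal(unname(cxx[[nm]]), unname(ref[[nm]]), tolerance = 1e-10,
                     label = paste(mode, nm))
    }
  }
})

test_that("total current equals the sum of its components", {
  for (st in random_states(10, seed = 7)) {
    cur <- total_current(st, default_params, "constitutive")
    comp <- cur[c("I_Na", "I_CaL", "I_K1", "I_to", "I_CaT", "I_Cab", "I_NCX",
                  "I_NaK", "I_f", "I_Nab", "I_Ksus", "I_KACh")]
    expect_equal(unname(cur[["I_total"]]), sum(comp), tolerance = 1e-12)
  }
})

test_that("block fractions scale currents and full block silences them", {
  st <- probe_state(V = -20)
  p_tq <- cell_params(block = c(I_KACh = 1))
  cur <- total_current(st, p_tq, "constitutive")
  expect_equal(unname(cur[["I_KACh"]]), 0)
  p_half <- cell_params(block = c(I_Na = 0.5))
  cur0 <- total_current(st, default_params, "single_cell")
  cur1 <- total_current(st, p_half, "single_cell")
  expect_equal(unname(cur1[["I_Na"]]), unname(cur0[["I_Na"]]) / 2)
  # the two acetylcholine-current modes differ only in the I_KACh term
  c_sc <- total_current(st, default_params, "single_cell")
  c_ct <- total_current(st, default_params, "constitutive")
  same <- setdiff(names(c_sc), c("I_KACh", "I_total"))
  expect_equal(c_sc[same], c_ct[same])
})
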