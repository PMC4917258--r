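test_that("the packaged resting state is a quiescent fixed point", {
  tr <- simulate_cell(default_params, duration = 2000, record_dt = 1)
  expect_lt(max(abs(tr$V - tr$V[1])), 0.5)
  # no spontaneous beats over a long unstimulated run
  tr2 <- simulate_cell(default_params, duration = 10000, record_dt = 5)
  expect_equal(sum(diff(tr2$V > -30) == 1), 0)
  expect_lt(abs(utils::tail(tr2$V, 1) - tr2$V[1]), 1)
})

test_that("a 7 pA, 5 ms stimulus elicits a full action potential from rest", {
  tr <- simulate_cell(default_params, duration = 300,
                      stim = stim_train(start = 20, amplitude = 7,
                                        duration = 5))
  expect_gt(max(tr$V), 20)          # overshoot
  expect_lt(utils::tail(tr$V, 1), -65)  # returns to rest
  # no stimulus, no AP
  tr0 <- simulate_cell(default_params, duration = 300)
  expect_lt(max(tr0$V) - tr0$V[1], 1)
})

test_that("gates remain within [0,1] along paced trajectories (both schemes)", {
  gate_names <- c("m", "h", "j", "d", "f", "fCa", "b", "g", "r", "s",
                  "s_slow", "ua", "ui", "Xr", "Xs1", "Xs2", "y")
  for (method in c("rush_larsen", "euler")) {
    st <- initial_state(default_params)
    set.seed(31)
    for (k in 1:40) {
      st <- step_cell(st, dt = 0.02, I_stim = runif(1, -5, 40),
                      params = default_params, n = 25, gate_method = method)
      expect_true(all(st[gate_names] >= 0 & st[gate_names] <= 1),
                  label = method)
      expect_true(all(st[c("Ca_tot_i", "Ca_NSR", "Ca_tot_JSR")] >= 0))
    }
  }
})

test_that("closed Ca subsystem conserves total calcium to machine precision", {
  # disable all membrane Ca pathways; only SR fluxes act
  p <- cell_params(block = c(I_CaL = 1, I_CaT = 1, I_Cab = 1, I_NCX = 1))
  st <- initial_state(p)
  st[["Ca_tot_i"]] <- 0.02        # out of equilibrium on purpose
  st[["Ca_NSR"]] <- 1.0
  tot <- function(s)
    s[["Ca_tot_i"]] + s[["Ca_NSR"]] * p$v_NSR + s[["Ca_tot_JSR"]] * p$v_JSR
  t0 <- tot(st)
  st2 <- step_cell(st, dt = 0.02, I_stim = 0, params = p, n = 1000)
  expect_equal(tot(st2), t0, tolerance = 1e-12)
  # and the fluxes moved Ca between compartments meanwhile
  expect_false(isTRUE(all.equal(st2[["Ca_NSR"]], st[["Ca_NSR"]])))
})

test_that("SR flux identities hold at corner states", {
  p <- default_params
  st <- initial_state(p)
  # equal NSR and JSR free Ca => no transfer flux
  ca <- free_calcium(st, p)
  st_eq <- st
  st_eq[["Ca_NSR"]] <- ca$Ca_JSR
  fx <- calcium_fluxes(st_eq, p)
  expect_equal(fx$J_tr, 0, tolerance = 1e-12)
  # empty cytosol: SERCA runs backward only (no forward term)
  st0 <- st
  st0[["Ca_tot_i"]] <- 0
  fx0 <- calcium_fluxes(st0, p)
  expect_lte(fx0$J_up, 0)
  st_neg <- st
  st_neg[["Ca_tot_i"]] <- -1
  expect_error(calcium_fluxes(st_neg, p), "negative")
})

test_that("removing the funny current barely shifts the resting potential", {
  tr1 <- simulate_cell(default_params, duration = 5000, record_dt = 5)
  p0 <- cell_params(block = c(I_f = 1))
  tr0 <- simulate_cell(p0, duration = 5000, record_dt = 5)
  expect_lt(abs(utils::tail(tr1$V, 1) - utils::tail(tr0$V, 1)), 1)
})

test_that("halving the time step leaves APD80 within one percent", {
  run <- function(dt) {
    tr <- pace_cell(default_params, bcl = 500, n_beats = 3, dt = dt,
                    record_dt = 0.02)
    ap_metrics(tr, stim_time = attr(tr, "beats")$stim_time[3])
  }
  m1 <- run(0.02)
  m2 <- run(0.01)
  expect_lt(abs(m1$APD80 - m2$APD80) / m2$APD80, 0.01)
  expect_lt(abs(m1$amplitude - m2$amplitude) / m2$amplitude, 0.01)
})

test_that("Rush-Larsen and Euler gate updates converge to the same AP", {
  mrl <- ap_metrics(simulate_cell(default_params, 300,
                                  stim = stim_train(start = 10),
                                  record_dt = 0.02), stim_time = 10)
  meu <- ap_metrics(simulate_cell(default_params, 300,
                                  stim = stim_train(start = 10),
                                  record_dt = 0.02, gate_method = "euler"),
                    stim_time = 10)
  expect_lt(abs(mrl$APD80 - meu$APD80) / mrl$APD80, 0.02)
  expect_lt(abs(mrl$amplitude - meu$amplitude) / mrl$amplitude, 0.02)
})

test_that("parameter sets round-trip through their text format", {
  p <- cell_params(G_Na = 5.5, block = c(I_KACh = 0.25))
  f <- tempfile(fileext = ".txt")
  write_params(p, f)
  p2 <- read_params(f)
  for (nm in setdiff(names(p), "block"))
    expect_identical(p[[nm]], p2[[nm]], label = nm)
  expect_identical(p$block, p2$block)
  expect_error(read_params(tempfile()), "not found")
  writeLines("nonsense_key = 3", f2 <- tempfile())
  expect_error(read_params(f2), "unknown parameter")
})

test_that("trace CSV export carries the expected columns", {
  tr <- simulate_cell(default_params, duration = 50, record_dt = 1,
                      record_currents = TRUE)
  f <- tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  d <- utils::read.csv(f)
  expect_true(all(c("time_ms", "V_mV", "Ca_i_mM", "I_Na", "I_KACh") %in%
                    names(d)))
  expect_equal(nrow(d), nrow(tr))
})

test_that("frame stacks round-trip through the binary container", {
  fx <- make_fixture("rotor", n = 16, duration = 10)
  f <- tempfile(fileext = ".bin")
  write_frames(fx$frames, fx$times, 0.00625, f)
  back <- read_frames(f)
  expect_equal(back$frames, fx$frames)
  expect_equal(back$times, fx$times)
  expect_equal(back$dx, 0.00625)
})
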