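test_that("AP metrics are exact on constructed waveforms", {
  # 50 ms square pulse: APD50 = APD80 = pulse width
  tr <- data.frame(time = seq(0, 100, 0.1))
  tr$V <- ifelse(tr$time >= 10 & tr$time < 60, 100, 0)
  m <- ap_metrics(tr)
  expect_equal(m$APD50, 50, tolerance = 0.2)
  expect_equal(m$APD80, 50, tolerance = 0.2)
  expect_equal(m$amplitude, 100)
  # triangular repolarization over 100 ms: APD80 = 80, APD50 = 50
  fx <- make_fixture("ap_trace")
  m2 <- ap_metrics(fx)
  expect_equal(m2$APD50, 50, tolerance = 1.1)
  expect_equal(m2$APD80, 80, tolerance = 1.1)
  expect_equal(m2$RMP, -80)
  expect_equal(m2$amplitude, 120)
  expect_lte(m2$APD50, m2$APD80)
  expect_error(ap_metrics(data.frame(time = 0:10, V = rep(-80, 11))),
               "upstroke")
})

test_that("activation map recovers a prescribed linear delay field", {
  n <- 24; nt <- 40
  fr <- array(-80, c(n, n, nt))
  delay <- matrix(rep(seq(2, 25, length.out = n), n), n, n)  # ms per row
  for (k in seq_len(nt))
    fr[, , k] <- ifelse(delay <= k - 1, 0, -80)
  am <- activation_map(fr, threshold = -20, t0 = 0,
                       times = seq(0, nt - 1))
  # recovered within one frame stride
  expect_true(all(abs(am - ceiling(delay)) <= 1))
})

test_that("CV estimator is exact on a uniform-gradient map", {
  n <- 60
  g_ms_per_node <- 0.4
  map <- matrix(rep((seq_len(n) - 1) * g_ms_per_node, 30), n, 30)
  dx <- 0.00625
  cv <- conduction_velocity(map, dx)
  expect_equal(cv, 1000 * dx / g_ms_per_node, tolerance = 1e-9)
  # independent of the chosen margin (plateau test)
  cv2 <- conduction_velocity(map, dx, margin = 0.3)
  expect_equal(cv, cv2, tolerance = 1e-9)
})

test_that("APD map recovers a designed two-region step", {
  n <- 20; times <- seq(0, 200, by = 1)
  fr <- array(-80, c(n, n, length(times)))
  apd_true <- matrix(60, n, n)
  apd_true[1:10, ] <- 90
  for (k in seq_along(times)) {
    t <- times[k]
    v <- matrix(-80, n, n)
    up <- t >= 10 & t < 10 + apd_true
    v[up] <- 40 - 110 * ((t - 10) / apd_true[up])^4  # fast late decay
    fr[, , k] <- v
  }
  am <- apd_map(fr, stim_time = 10, times = times)
  expect_equal(am$dispersion, 30, tolerance = 4)
  expect_true(all(abs(am$apd[1:10, ] - am$apd[11:20, ] - 30) < 6))
})

test_that("tip tracking recovers the circle of a synthetic rotor", {
  fx <- make_fixture("rotor", n = 48, radius_nodes = 6, duration = 100,
                     period = 50)
  traj <- tip_trajectory(fx$frames, iso = -30, times = fx$times, dx = 0.00625)
  expect_gt(nrow(traj), 50)
  # distances from the known centre approximate the prescribed radius
  r <- sqrt((traj$x - fx$centre[1])^2 + (traj$y - fx$centre[2])^2)
  expect_lt(abs(median(r) - fx$radius_nodes), 1.2)
  # core size (max pairwise extent over one rotation) ~ diameter
  cs <- core_size(traj, cycle_ms = 50)
  expect_equal(cs, 2 * fx$radius_nodes * 0.0625, tolerance = 0.35)
})

test_that("a plane wave yields no tip", {
  fx <- make_fixture("plane_wave", n = 32, duration = 40)
  traj <- tip_trajectory(fx$frames, iso = -30, times = fx$times, dx = 0.00625)
  expect_equal(nrow(traj), 0)
})

test_that("dominant period resolves pure and mixed tones", {
  dt <- 1
  t <- seq(0, 4000 - dt, by = dt)
  x <- sin(2 * pi * 12.5 * t / 1000)      # 12.5 Hz -> 80 ms
  dp <- dominant_period(x, dt)
  expect_equal(dp$period_ms, 80, tolerance = 1)
  # two tones: the stronger one wins
  y <- 0.3 * sin(2 * pi * 5 * t / 1000) + sin(2 * pi * 10 * t / 1000)
  expect_equal(dominant_period(y, dt)$period_ms, 100, tolerance = 2)
  y2 <- sin(2 * pi * 5 * t / 1000) + 0.3 * sin(2 * pi * 10 * t / 1000)
  expect_equal(dominant_period(y2, dt)$period_ms, 200, tolerance = 5)
})

test_that("wavelength is the CV-APD product in cm", {
  expect_equal(wavelength(22.2, 40), 0.888)
  expect_equal(wavelength(22.2, 0), 0)
})

test_that("map operations are pure functions of their inputs", {
  fx <- make_fixture("rotor", n = 32, duration = 30)
  a1 <- activation_map(fx$frames, times = fx$times)
  a2 <- activation_map(fx$frames, times = fx$times)
  expect_identical(a1, a2)
  t1 <- tip_trajectory(fx$frames, times = fx$times, dx = 0.00625)
  t2 <- tip_trajectory(fx$frames, times = fx$times, dx = 0.00625)
  expect_identical(t1, t2)
})
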