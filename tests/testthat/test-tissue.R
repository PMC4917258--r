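test_that("Laplacian is zero on uniform fields and matches a hand stencil", {
  mask <- matrix(TRUE, 8, 8)
  V <- matrix(-70, 8, 8)
  L <- laplacian_neumann(V, dx = 0.00625, D = 0.00012, mask)
  expect_true(all(L == 0))
  # single-node delta: hand-computed 5-point values with mirror boundaries
  V2 <- matrix(0, 4, 4)
  V2[2, 2] <- 1
  L2 <- laplacian_neumann(V2, dx = 1, D = 1, matrix(TRUE, 4, 4))
  expect_equal(L2[2, 2], -4)
  expect_equal(L2[1, 2], 1)
  expect_equal(L2[3, 2], 1)
  expect_equal(L2[2, 1], 1)
  expect_equal(L2[2, 3], 1)
  expect_equal(L2[4, 4], 0)
  # delta in a corner: only two in-mask neighbours contribute
  V3 <- matrix(0, 4, 4); V3[1, 1] <- 1
  L3 <- laplacian_neumann(V3, dx = 1, D = 1, matrix(TRUE, 4, 4))
  expect_equal(L3[1, 1], -2)
  expect_error(laplacian_neumann(V2, dx = 0, D = 1), "positive")
})

test_that("no-flux diffusion conserves the masked sum to machine precision", {
  set.seed(2)
  n <- 32
  mask <- matrix(FALSE, n, n)
  cx <- (n + 1) / 2
  mask[(row(mask) - cx)^2 + (col(mask) - cx)^2 <= (n / 2 - 1)^2] <- TRUE
  V <- matrix(runif(n * n, -90, 40), n, n)
  V[!mask] <- 0
  s0 <- sum(V[mask])
  dt <- 0.02
  for (k in 1:10000) {
    V[mask] <- V[mask] + dt * laplacian_neumann(V, 0.00625, 0.00012, mask)[mask]
  }
  expect_equal(sum(V[mask]), s0, tolerance = 1e-10)
  # and the field homogenizes toward the mean
  expect_lt(diff(range(V[mask])), diff(range(runif(10))) * 200)
})

test_that("uniform tissue with no stimulus reproduces the single-cell path", {
  g <- build_monolayer(nx = 3, ny = 3, shape = "square")
  stim_all <- protocol_spec(stim_event(10, which(g$type == 1L), 7, 5))
  rec <- simulate_tissue(g, stim_all, duration = 200, probes = 5,
                         trace_dt = 0.5, record_frames = FALSE)
  tr <- simulate_cell(cell_params(), duration = 200,
                      stim = stim_train(start = 10, amplitude = 7, duration = 5),
                      mode = "constitutive", record_dt = 0.5)
  # diffusion vanishes identically on the uniform field: exact agreement
  expect_equal(rec$traces[, 1], tr$V, tolerance = 1e-9)
})

test_that("resting tissue stays at rest and reruns are bit-identical", {
  g <- strip_grid(nx = 24, ny = 3)
  r1 <- simulate_tissue(g, protocol_spec(), duration = 300, probes = c(12, 40),
                        trace_dt = 1, record_frames = FALSE)
  rest <- initial_state(cell_params())[["V"]]
  expect_lt(max(abs(r1$traces - rest)), 1)
  r2 <- simulate_tissue(g, protocol_spec(), duration = 300, probes = c(12, 40),
                        trace_dt = 1, record_frames = FALSE)
  expect_identical(r1$traces, r2$traces)
  expect_identical(r1$final$state, r2$final$state)
})

test_that("a planar wave propagates and activates the far edge", {
  g <- strip_grid(nx = 96, ny = 3)
  pr <- protocol_spec(stim_event(5, nodes_edge(g, "left", 5), 100, 2))
  rec <- simulate_tissue(g, pr, duration = 80, probes = c(48 + 96, 90 + 96),
                         trace_dt = 0.5, record_frames = FALSE)
  expect_gt(max(rec$traces[, 1]), 0)   # mid strip activates
  expect_gt(max(rec$traces[, 2]), 0)   # far end activates later
  t1 <- rec$trace_time[which(rec$traces[, 1] > -20)[1]]
  t2 <- rec$trace_time[which(rec$traces[, 2] > -20)[1]]
  expect_gt(t2, t1)
})

test_that("the stability bound on dt is enforced", {
  g <- strip_grid(nx = 16, ny = 3)
  expect_error(simulate_tissue(g, protocol_spec(), duration = 1, dt = 0.2),
               "stability")
})

test_that("a block event changes the trajectory only through its current", {
  g <- strip_grid(nx = 32, ny = 3)
  pr0 <- protocol_spec(stim_event(5, nodes_edge(g, "left", 5), 100, 2))
  prb <- protocol_spec(stim_event(5, nodes_edge(g, "left", 5), 100, 2),
                       block_event(0, "I_KACh", 0))
  r0 <- simulate_tissue(g, pr0, duration = 100, probes = 16 + 32,
                        trace_dt = 0.5, record_frames = FALSE)
  rb <- simulate_tissue(g, prb, duration = 100, probes = 16 + 32,
                        trace_dt = 0.5, record_frames = FALSE)
  # zero-fraction block is a no-op (paired-run equality)
  expect_identical(r0$traces, rb$traces)
  # full block lengthens the local AP
  prf <- protocol_spec(stim_event(5, nodes_edge(g, "left", 5), 100, 2),
                       block_event(0, "I_KACh", 1))
  rf <- simulate_tissue(g, prf, duration = 200, probes = 16 + 32,
                        trace_dt = 0.5, record_frames = FALSE)
  m0 <- ap_metrics(data.frame(time = r0$trace_time, V = r0$traces[, 1]),
                   stim_time = 5)
  mf <- ap_metrics(data.frame(time = rf$trace_time, V = rf$traces[, 1]),
                   stim_time = 5)
  expect_gt(mf$APD80, m0$APD80)
})

test_that("uncoupled myofibroblasts act as inexcitable obstacles", {
  g <- build_monolayer(nx = 32, ny = 32, diameter = 0.19, fib_fraction = 0.17,
                       variability = c(100, 100), seed = 5)
  pr <- protocol_spec(stim_event(5, nodes_edge(g, "left", 3), 100, 2))
  rec <- simulate_tissue(g, pr, duration = 60, probes = integer(0),
                         frame_dt = 2, fb_coupled = FALSE)
  fib <- which(g$type == 2L)
  last <- rec$frames[, , dim(rec$frames)[3]]
  # uncoupled fibroblasts never move from their own resting potential
  expect_true(all(abs(last[fib] - cell_params()$E_fb) < 1e-6))
})

test_that("integration blow-up reports the offending state variable", {
  # a absurdly large stimulus drives V to overflow
  st <- initial_state(cell_params())
  expect_error(
    simulate_cell(cell_params(), duration = 50, dt = 0.02,
                  stim = data.frame(start = 0, duration = 50,
                                    amplitude = 1e308)),
    "non-finite|blow-up")
})
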