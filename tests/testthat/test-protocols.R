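test_that("pacing reaches a steady state whose APD stabilises", {
  tr <- pace_cell(default_params, bcl = 500, n_beats = 6, record_dt = 0.05)
  beats <- attr(tr, "beats")
  expect_true(all(beats$captured))
  expect_true(attr(tr, "steady"))
  # doubling the beat count leaves the final APD80 within 1 ms (at 1 Hz,
  # where the slow delayed-rectifier gates deactivate fully between beats)
  trA <- pace_cell(default_params, bcl = 1000, n_beats = 6, record_dt = 0.05)
  trB <- pace_cell(default_params, bcl = 1000, n_beats = 12, record_dt = 0.05)
  expect_lt(abs(attr(trB, "beats")$APD80[12] - attr(trA, "beats")$APD80[6]), 1)
  # zero-amplitude stimulus: no capture, reported rather than raised
  tr0 <- pace_cell(default_params, bcl = 500, n_beats = 2, stim_amplitude = 0)
  expect_false(any(attr(tr0, "beats")$captured))
})

test_that("dynamic restitution is monotone and flat at long cycle lengths", {
  bcls <- c(900, 600, 400, 300, 250, 200)
  tab <- dynamic_restitution(default_params, bcls, beats_per_bcl = 4,
                             mode = "constitutive")
  expect_true(all(tab$captured))
  apd <- tab$apd80
  # non-increasing with decreasing BCL (small numerical slack)
  expect_true(all(diff(apd) <= 1.5))
  # decoupled beats: APD at very long BCL equals the fully rested value
  tab2 <- dynamic_restitution(default_params, c(2000, 1500),
                              beats_per_bcl = 3, mode = "constitutive")
  expect_lt(abs(tab2$apd80[1] - tab2$apd80[2]), 1.5)
  expect_error(dynamic_restitution(default_params, c(200, 300)), "descending")
})

test_that("holding current clamps the membrane near its target", {
  # at the natural resting potential the required current is almost zero
  rest <- initial_state(default_params)[["V"]]
  expect_lt(abs(holding_current_for(default_params, rest)), 0.05)
  # a -85 mV target needs a hyperpolarizing (negative) current ...
  i85 <- holding_current_for(default_params, -85)
  expect_lt(i85, 0)
  # ... and more negative targets need more negative current
  i95 <- holding_current_for(default_params, -95)
  expect_lt(i95, i85)
  # applying it holds V within 0.5 mV over a 1 s clamp-free run
  tr <- simulate_cell(default_params, duration = 1000, i_hold = i85,
                      state = initial_state(default_params, V = -85),
                      record_dt = 1)
  expect_lt(abs(utils::tail(tr$V, 1) - -85), 0.5)
  expect_error(holding_current_for(default_params, -20), "-120")
})

test_that("protocol events validate and order themselves", {
  g <- strip_grid(nx = 16, ny = 3)
  e1 <- stim_event(50, 1:4, 100, 2)
  e2 <- stim_event(10, 1:4, 100, 2)
  pr <- protocol_spec(e1, e2)
  expect_equal(vapply(unclass(pr), `[[`, 0, "time"), c(10, 50))
  tr <- pacing_train(0, 100, 5, 1:4)
  expect_length(tr, 5)
  expect_equal(tr[[5]]$time, 400)
  expect_error(block_event(0, "I_bogus"), "unknown")
  expect_error(block_event(0, "I_KACh", 1.5), "fraction")
  expect_error(simulate_tissue(g, protocol_spec(stim_event(500, 1:4)),
                               duration = 100), "beyond duration")
})

test_that("node-set helpers address the intended regions", {
  g <- build_monolayer(nx = 16, ny = 16, shape = "square")
  left <- nodes_edge(g, "left", 3)
  expect_true(all(((left - 1) %% 16) + 1 <= 3))
  rect <- nodes_rect(g, 5, 8, 2, 3)
  expect_length(rect, 8)
  dsc <- nodes_disc(g, 8, 8, 2)
  expect_true(length(dsc) >= 9 && length(dsc) <= 16)
})

test_that("tissue pacing flags capture and its loss", {
  g <- strip_grid(nx = 64, ny = 3)
  rec <- planar_pacing(g, cl = 400, n_beats = 2, record_frames = FALSE,
                       tail_ms = 200)
  expect_true(all(attr(rec, "beats")$captured))
  # far below refractoriness the second response fails
  rec2 <- planar_pacing(g, cl = 25, n_beats = 3, record_frames = FALSE,
                        tail_ms = 200)
  expect_false(all(attr(rec2, "beats")$captured))
})

test_that("capture scanning returns the smallest captured cycle length", {
  g <- strip_grid(nx = 64, ny = 3)
  # huge cycle lengths always capture: the scan returns the smallest tested
  sc <- min_capture_cl(g, c(800, 700, 600), mode = "constitutive",
                       n_beats = 4, check_last = 2)
  expect_equal(sc$min_cl, 600)
  expect_true(all(sc$table$captured))
})

test_that("S1-S2 cross-field auto-times the premature stimulus reproducibly", {
  g <- build_monolayer(nx = 48, ny = 48, shape = "square")
  r1 <- s1s2_cross_field(g, duration = 320, frame_dt = 4, max_wait_ms = 250)
  r2 <- s1s2_cross_field(g, duration = 320, frame_dt = 4, max_wait_ms = 250)
  expect_false(is.na(attr(r1, "s2_time")))
  expect_identical(attr(r1, "s2_time"), attr(r2, "s2_time"))
  expect_identical(r1$frames, r2$frames)
  # the S2 depolarizes the upper region
  first <- r1$frames[, , 2]
  expect_gt(max(first[, 40:48], na.rm = TRUE), -40)
})

test_that("burst pacing runs and reports an induction flag", {
  g <- build_monolayer(nx = 48, ny = 48, shape = "square")
  rec <- burst_pacing(g, cl = 120, n_stimuli = 4, observe_ms = 150,
                      frame_dt = 10)
  expect_type(attr(rec, "induced"), "logical")
  # a slow train on a small homogeneous sheet cannot sustain reentry
  rec2 <- burst_pacing(g, cl = 400, n_stimuli = 2, observe_ms = 200,
                       frame_dt = 10)
  expect_false(attr(rec2, "induced"))
})
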