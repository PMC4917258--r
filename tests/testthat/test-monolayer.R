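test_that("monolayer construction is seed-deterministic and well-counted", {
  g1 <- build_monolayer(nx = 64, ny = 64, diameter = 0.38, fib_fraction = 0.17,
                        variability = c(50, 150), seed = 11)
  g2 <- build_monolayer(nx = 64, ny = 64, diameter = 0.38, fib_fraction = 0.17,
                        variability = c(50, 150), seed = 11)
  expect_identical(g1$type, g2$type)
  expect_identical(g1$mult, g2$mult)
  g3 <- build_monolayer(nx = 64, ny = 64, diameter = 0.38, fib_fraction = 0.17,
                        variability = c(50, 150), seed = 12)
  expect_false(identical(g1$type, g3$type))
  # exact placement count
  n_masked <- sum(g1$type != 0L)
  expect_equal(sum(g1$type == 2L), round(0.17 * n_masked))
  # fibroblast fraction within one node of the request
  expect_lt(abs(sum(g1$type == 2L) / n_masked - 0.17), 1 / n_masked + 1e-9)
})

test_that("homogeneous disc has no fibroblasts and unit multipliers", {
  g <- build_monolayer(nx = 48, ny = 48, diameter = 0.28, fib_fraction = 0,
                       variability = c(100, 100), seed = 1)
  expect_equal(sum(g$type == 2L), 0)
  expect_true(all(g$mult == 1))
  # the disc is inscribed: corners stay outside
  expect_equal(g$type[1, 1], 0L)
  expect_equal(g$type[24, 24], 1L)
  expect_error(build_monolayer(nx = 16, ny = 16, diameter = 2),
               "too small")
  expect_error(build_monolayer(fib_fraction = 1.2), "fib_fraction")
})

test_that("variability multipliers respect their range and centre", {
  m <- variability_multipliers(500, c(50, 150), seed = 3)
  expect_equal(dim(m), c(500, 19))
  expect_true(all(m >= 0.5 & m <= 1.5))
  expect_equal(mean(m), 1, tolerance = 0.02)
  # degenerate range gives exactly 1
  m1 <- variability_multipliers(10, c(100, 100), seed = 3)
  expect_true(all(m1 == 1))
  expect_error(variability_multipliers(10, c(150, 50)), "X1 <= X2")
  # draws do not disturb the caller's RNG stream
  set.seed(99); a <- runif(1)
  set.seed(99); invisible(variability_multipliers(10, c(50, 150), seed = 1))
  b <- runif(1)
  expect_identical(a, b)
  # 19 designated conductances/fluxes
  expect_length(variability_targets(), 19)
})

test_that("APD-map quality control separates dispersion, steps and gradients", {
  ok <- qc_monolayer(make_fixture("apd_map_uniform", n = 32))
  expect_true(ok$accept)
  expect_equal(ok$dispersion, 0)
  # 25 ms step fails on dispersion
  bad <- qc_monolayer(make_fixture("apd_map_step", n = 32, spread = 25))
  expect_false(bad$accept)
  expect_equal(bad$reason, "dispersion")
  # 19 ms sharp step is within dispersion but non-uniform
  dom <- qc_monolayer(make_fixture("apd_map_step", n = 32, spread = 19))
  expect_false(dom$accept)
  expect_equal(dom$reason, "non-uniform")
  # 19 ms smooth gradient is accepted
  grad <- qc_monolayer(make_fixture("apd_map_gradient", n = 32, spread = 19))
  expect_true(grad$accept)
  expect_lt(grad$dispersion, 20)
})

test_that("grid serialization round-trips through text files", {
  g <- make_fixture("grid32", seed = 4)
  pre <- file.path(tempdir(), "grid_rt")
  write_grid(g, pre)
  g2 <- read_grid(pre)
  expect_identical(g$type, g2$type)
  expect_equal(unname(g$mult), unname(g2$mult))
  expect_equal(g$seed, g2$seed)
  expect_equal(g$dx, g2$dx)
})
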