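# Estimation machinery on constructed data (simulation-based estimates are
# exercised in the acceptance suite)

test_that("complex slope through origin recovers a synthetic response", {
  set.seed(4)
  b <- 0.3 + 0.1i
  E <- c(-0.002, -0.001, 0.001, 0.002)
  ok <- 0
  for (rep in 1:10) {
    v <- b * E + complex(real = rnorm(4, 0, 5e-5),
                         imaginary = rnorm(4, 0, 5e-5))
    fit <- borderzone:::slope_through_origin(E, v, rep(5e-5 + 5e-5i, 4))
    if (Mod(fit$slope - b) < 3 * Mod(fit$se)) ok <- ok + 1
  }
  expect_gte(ok, 8)
})

test_that("slope residual flags a nonlinear response", {
  E <- c(-0.002, -0.001, 0.001, 0.002)
  v <- 0.5 * E + 400 * E^2   # strong quadratic
  fit <- borderzone:::slope_through_origin(E, as.complex(v),
                                           rep(1e-6 + 1e-6i, 4))
  expect_gt(fit$resid_rel, 0.25)
})

test_that("relative drift recovers a constructed velocity difference", {
  t <- seq(5, 2000, by = 5)
  base <- data.frame(t = t, x = 40 + 3 * cos(t / 80), y = 40 + 3 * sin(t / 80))
  v <- c(0.004, -0.001)
  set.seed(1)
  pert <- base
  pert$x <- pert$x + v[1] * t + rnorm(length(t), 0, 1e-9)
  pert$y <- pert$y + v[2] * t + rnorm(length(t), 0, 1e-9)
  rd <- borderzone:::relative_drift(pert, base)
  expect_equal(Re(rd$v), v[1], tolerance = 1e-6)
  expect_equal(Im(rd$v), v[2], tolerance = 1e-6)
})

test_that("specific_force objects print and validate", {
  f <- specific_force(1 - 2i, 0.1 + 0.1i, "c")
  expect_output(print(f), "specific force")
  expect_identical(f$value, 1 - 2i)
})

test_that("force_curve interpolates monotonically and decays to zero", {
  d <- c(0.5, 1, 2, 3)
  fc <- force_curve(d, c(-1, -0.5, -0.1, -0.02), R0 = 0.4,
                    delta_alpha = -0.1)
  expect_equal(fc$fr(d), c(-1, -0.5, -0.1, -0.02))
  ## monotone between samples, zero beyond
  rr <- seq(0.5, 3, by = 0.01)
  expect_true(all(diff(fc$fr(rr)) >= -1e-12))
  expect_identical(fc$fr(5), 0)
  ## clamped below the first sample
  expect_equal(fc$fr(0.1), -1)
})
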