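# Single-cell Beeler-Reuter-Pumir kinetics

test_that("ik1_scale is the linear suppression factor and is monotone", {
  expect_identical(ik1_scale(0), 1)
  expect_identical(ik1_scale(1), 0)   # limit of the convention
  expect_identical(ik1_scale(0.5), 0.5)
  a <- seq(0, 0.99, length.out = 50)
  expect_true(all(diff(ik1_scale(a)) <= 0))
  expect_error(ik1_scale(-0.1), "alpha")
  expect_error(ik1_scale(1.5), "alpha")
})

test_that("cell parameter defaults match the neonatal reductions", {
  p <- brp_params()
  expect_equal(p$gNa_max, 0.6 * 4)    # 2.4 vs 4
  expect_equal(p$gs_max, 0.5 * 0.09)  # 0.045 vs 0.09
  expect_error(brp_params(alpha = 1), "alpha")
  expect_error(brp_params(alpha = -0.2), "alpha")
})

test_that("rest state at alpha = 0 is a true equilibrium of the RHS", {
  rs <- test_rest(0)
  expect_true(rs$converged)
  expect_lt(rs$residual, 1e-8)
  d <- cell_rhs(rs$state, brp_params(0))
  expect_lt(sqrt(sum(d^2)), 1e-8)
})

test_that("rest state is unique across distinct physiological starts", {
  p <- brp_params(0)
  rs1 <- test_rest(0)
  ## second bracket: start depolarized, long relaxation finds the same rest
  r2 <- step_cell(cell_state(-60, 5e-7), 0.05, p, n = 200000L)
  expect_lt(abs(r2[["V"]] - rs1$state[["V"]]), 1e-6)
})

test_that("steady-state gates zero the gate derivatives", {
  p <- brp_params(0.3)
  for (V in c(-80, -40, 0, 20)) {
    st <- cell_state(V, 1e-6)
    d <- cell_rhs(st, p)
    expect_lt(max(abs(d[3:8])), 1e-12)
  }
})

test_that("suprathreshold current depolarizes the rest state", {
  rs <- test_rest(0)
  d <- cell_rhs(rs$state, brp_params(0), I_ext = 30)
  expect_gt(d[["V"]], 0)
})

test_that("alpha above the automaticity threshold has no stable rest", {
  rs <- find_rest_state(brp_params(0.9), t_relax = 8000)
  expect_true(rs$oscillatory)
  expect_false(rs$converged)
})

test_that("gates remain in [0,1] for any dt (exponential update)", {
  p <- brp_params(0.2)
  st <- cell_state(-84, 1.8e-7)
  for (dt in c(0.01, 0.5, 5)) {
    out <- step_cell(st, dt, p, n = 5L)
    expect_true(all(out[3:8] >= 0 & out[3:8] <= 1))
  }
  ## huge dt from the true rest state (V update stays put there): the
  ## exponential update maps gates straight to g_inf, still inside [0,1]
  p0 <- brp_params(0)
  out <- step_cell(test_rest(0)$state, 1e4, p0, n = 1L)
  expect_true(all(out[3:8] >= 0 & out[3:8] <= 1))
})

test_that("slow pacing gives exactly one upstroke per stimulus", {
  p <- brp_params(0)
  rs <- test_rest(0)
  tr <- simulate_cell(p, duration = 3000, dt = 0.05, state = rs$state,
                      stim_times = c(50, 1500), record_dt = 0.5)
  up <- sum(tr$V[-1] > -20 & tr$V[-nrow(tr)] <= -20)
  expect_identical(up, 2L)
})

test_that("AP peak converges under dt halving (< 0.5 mV)", {
  p <- brp_params(0)
  rs <- test_rest(0)
  peak <- function(dt) {
    tr <- simulate_cell(p, duration = 400, dt = dt, state = rs$state,
                        stim_times = 10, record_dt = dt)
    max(tr$V)
  }
  expect_lt(abs(peak(0.05) - peak(0.025)), 0.5)
})

test_that("quiescent cell returns to rest within bounded time", {
  p <- brp_params(0)
  rs <- test_rest(0)
  tr <- simulate_cell(p, duration = 2500, dt = 0.05, state = rs$state,
                      stim_times = 10, record_dt = 1)
  expect_lt(abs(tail(tr$V, 1) - rs$state[["V"]]), 1)
})

test_that("cell_rhs rejects non-finite input", {
  st <- as.numeric(cell_state(-80))
  st[1] <- NaN
  expect_error(cell_rhs(st, brp_params()), "finite")
})
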