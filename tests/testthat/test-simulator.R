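# Tissue stepping, stability guard, determinism, checkpointing

test_that("dt above the stability bound is refused before stepping", {
  g <- grid_spec(10, 10, 1)
  pf <- parameter_fields(g, D_uniform = 0.01, alpha_uniform = 0.3)
  ## bound: h^2/(2*2*D) * 0.9 = 0.225 ms
  expect_error(step_tissue(init_fields(g, cell_state(-84)), pf, g,
                           brp_params(0.3),
                           sim_config(dt = 0.3, duration = 1)),
               "stability")
})

test_that("a relaxed quiescent grid is a fixed point of the stepper", {
  g <- grid_spec(8, 8, 1)
  pf <- parameter_fields(g, D_uniform = 0.002, alpha_uniform = 0)
  p <- brp_params(0)
  st <- init_fields(g, test_rest(0)$state)
  ## relax through the discrete map, then measure the per-step change
  st <- step_tissue(st, pf, g, p, sim_config(dt = 0.05, duration = 2000))
  st2 <- step_tissue(st, pf, g, p, sim_config(dt = 0.05, duration = 0.05))
  expect_lt(max(abs(st2$V - st$V)), 1e-10)
  expect_lt(max(abs(st2$f - st$f)), 1e-10)
})

test_that("identical (config, seed) runs give identical tip tables", {
  cfg <- border_protocol_config(nx = 24, ny = 30, h = 0.1, nu = 0.3,
                                alpha_top = 0.6, u = -0.004, dt = 0.1,
                                duration = 400, seed = 5L)
  r1 <- run_border_zone_2d(cfg)
  r2 <- run_border_zone_2d(cfg)
  expect_identical(r1$tracks, r2$tracks)
  expect_identical(r1$state$V, r2$state$V)
})

test_that("checkpoint/restart reproduces an uninterrupted run", {
  g <- grid_spec(12, 12, 1)
  pf <- parameter_fields(g, D_uniform = 0.002, alpha_uniform = 0.5)
  p <- brp_params(0.5)
  st <- init_fields(g, test_rest(0)$state)
  dims <- grid_dims(g)
  stim <- array(0, dims); stim[1:2, , 1] <- 30
  st <- step_tissue(st, pf, g, p, sim_config(dt = 0.05, duration = 2),
                    stim = stim)
  full <- step_tissue(st, pf, g, p, sim_config(dt = 0.05, duration = 100))
  half <- step_tissue(st, pf, g, p, sim_config(dt = 0.05, duration = 50))
  tmp <- tempfile()
  write_checkpoint(half, g, 50, tmp)
  resumed <- read_checkpoint(tmp)$state
  finish <- step_tissue(resumed, pf, g, p,
                        sim_config(dt = 0.05, duration = 50))
  ## text checkpoint round-trips at ~1e-15 relative; stepping amplifies
  ## only mildly over 50 ms
  expect_lt(max(abs(finish$V - full$V)), 1e-9)
})

test_that("trivial quiescent grid yields empty trajectories", {
  g <- grid_spec(5, 5, 1)
  pf <- parameter_fields(g, D_uniform = 0.001, alpha_uniform = 0)
  p <- brp_params(0)
  out <- run_tissue(init_fields(g, test_rest(0)$state), g, p,
                    sim_config(dt = 0.1, duration = 50, sample_dt = 10),
                    pf = pf)
  expect_identical(nrow(out$tracks), 0L)
})

test_that("measure_cv reports no propagation in region IV", {
  ## bottom-layer conditions: unexcitable and effectively uncoupled
  r <- measure_cv(brp_params(0), D = 1e-5, grid = grid_spec(40, 3, 1),
                  t_max = 300)
  expect_false(r$propagated)
  expect_true(is.na(r$cv))
})

test_that("measure_cv is deterministic", {
  g <- grid_spec(80, 3, 1)
  r1 <- measure_cv(brp_params(0.4), D = 0.01, grid = g, t_max = 400)
  r2 <- measure_cv(brp_params(0.4), D = 0.01, grid = g, t_max = 400)
  expect_true(r1$propagated)
  expect_identical(r1$cv, r2$cv)
})
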