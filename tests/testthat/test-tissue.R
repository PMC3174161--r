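# Border-zone profiles, heterogeneity, and the coupling operator

cfg0 <- border_zone_config(D0 = 0.0025, Dmin = 0, alpha_top = 0.6,
                           alpha_bottom = 0, y1_0 = 2, y2_0 = 4,
                           u = -0.002)

test_that("profiles clamp outside the ramp and are linear inside", {
  for (t in c(0, 500, 2000)) {
    y1 <- cfg0$y1_0 + cfg0$u * t
    y2 <- cfg0$y2_0 + cfg0$u * t
    expect_equal(profile_D(y1 - 1, t, cfg0), cfg0$Dmin)
    expect_equal(profile_D(y2 + 1, t, cfg0), cfg0$D0)
    expect_equal(profile_D((y1 + y2) / 2, t, cfg0),
                 (cfg0$Dmin + cfg0$D0) / 2)
    expect_equal(profile_alpha(y1 - 5, t, cfg0), cfg0$alpha_bottom)
    expect_equal(profile_alpha(y2 + 5, t, cfg0), cfg0$alpha_top)
  }
})

test_that("profiles translate rigidly with the border (moving frame)", {
  y <- seq(0, 8, by = 0.1)
  ## a feature at y moves to y + u*dt after dt
  for (dt in c(100, 750)) {
    expect_equal(profile_alpha(y, 0, cfg0),
                 profile_alpha(y + cfg0$u * dt, dt, cfg0))
    expect_equal(profile_D(y, 0, cfg0),
                 profile_D(y + cfg0$u * dt, dt, cfg0))
  }
})

test_that("smooth ramp option is monotone with the same limits", {
  cs <- border_zone_config(D0 = 1, Dmin = 0.1, alpha_top = 0.5,
                           alpha_bottom = 0, y1_0 = 1, y2_0 = 3,
                           ramp = "smooth")
  y <- seq(0, 4, by = 0.05)
  d <- profile_D(y, 0, cs)
  expect_true(all(diff(d) >= 0))
  expect_equal(d[1], 0.1); expect_equal(tail(d, 1), 1)
})

test_that("heterogeneity is reproducible, frozen, and well scaled", {
  g <- grid_spec(100, 100, 1)
  h1 <- sample_heterogeneity(g, nu = 0.1, seed = 42)
  h2 <- sample_heterogeneity(g, nu = 0.1, seed = 42)
  expect_identical(h1$xi, h2$xi)
  h3 <- sample_heterogeneity(g, nu = 0.1, seed = 43)
  expect_false(identical(h1$xi, h3$xi))
  ## 10^4 cells: sample sd of nu*xi within 5% of nu
  expect_lt(abs(sd(0.1 * h1$xi) - 0.1) / 0.1, 0.05)
})

test_that("nu = 0 reproduces the macroscopic profile exactly", {
  g <- grid_spec(10, 40, 1)
  het <- sample_heterogeneity(g, nu = 0, seed = 7)
  pf <- parameter_fields(g, cfg0, het, t = 0)
  y <- ((1:40) - 0.5) * g$h
  expect_equal(pf$alpha[1, , 1], pmin(1 - 1e-9, profile_alpha(y, 0, cfg0)))
})

test_that("alpha_cell is clamped to [0, 1) after adding noise", {
  g <- grid_spec(50, 50, 1)
  het <- sample_heterogeneity(g, nu = 2, seed = 3)
  pf <- parameter_fields(g, cfg0, het, t = 0)
  expect_true(all(pf$alpha >= 0 & pf$alpha < 1))
})

test_that("coupling operator conserves current for random fields", {
  set.seed(11)
  for (dims in list(c(12, 9, 1), c(7, 8, 5))) {
    g <- grid_spec(dims[1], dims[2], dims[3])
    pf <- parameter_fields(g, D_uniform = 0.01, alpha_uniform = 0.3)
    pf$D <- array(runif(prod(dims), 0, 0.02), dims)
    V <- array(rnorm(prod(dims), -40, 30), dims)
    ct <- coupling_term(V, pf, g)
    expect_lt(abs(sum(ct)) / max(sum(abs(ct)), 1e-300), 1e-10)
  }
})

test_that("uniform V gives zero coupling everywhere", {
  g <- grid_spec(6, 6, 1)
  pf <- parameter_fields(g, D_uniform = 0.01, alpha_uniform = 0)
  ct <- coupling_term(array(-55, c(6, 6, 1)), pf, g)
  expect_equal(max(abs(ct)), 0)
})

test_that("two coupled cells exchange antisymmetric currents", {
  g <- grid_spec(3, 3, 1)
  pf <- parameter_fields(g, D_uniform = 0.01, alpha_uniform = 0)
  V <- array(-80, c(3, 3, 1)); V[2, 2, 1] <- -20
  ct <- coupling_term(V, pf, g)
  expect_equal(ct[1, 2, 1], 0.01 * 60 / g$h^2)
  expect_equal(ct[2, 2, 1], -4 * 0.01 * 60 / g$h^2)
})

test_that("a D = 0 cell is fully isolated", {
  g <- grid_spec(5, 5, 1)
  pf <- parameter_fields(g, D_uniform = 0.01, alpha_uniform = 0)
  pf$D[3, 3, 1] <- 0
  V <- array(-80, c(5, 5, 1)); V[3, 3, 1] <- 20
  ct <- coupling_term(V, pf, g)
  ## no current anywhere: the only V contrast is across dead interfaces
  expect_equal(max(abs(ct)), 0)
})

test_that("R coupling operator matches the compiled stepper", {
  ## one tiny explicit step with frozen gates: dV from the kernel equals
  ## ionic + coupling computed in R
  g <- grid_spec(8, 7, 1)
  set.seed(5)
  pf <- parameter_fields(g, D_uniform = 0.002, alpha_uniform = 0.2)
  pf$D <- array(runif(56, 0, 0.003), c(8, 7, 1))
  p <- brp_params(0.2)
  rs <- test_rest(0)
  st <- init_fields(g, rs$state)
  st$V <- st$V + array(rnorm(56, 0, 5), c(8, 7, 1))
  dt <- 1e-4
  out <- step_tissue(st, pf, g, p, sim_config(dt = dt, duration = dt))
  ion <- apply(matrix(seq_len(56)), 1, function(i) {
    s <- vapply(st, function(a) a[[i]], numeric(1))
    cell_rhs(s, brp_params(pf$alpha[i]))[["V"]]
  })
  dV_expect <- dt * (ion + as.vector(coupling_term(st$V, pf, g)))
  expect_equal(as.vector(out$V - st$V), dV_expect, tolerance = 1e-6)
})
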