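# Asymptotic drift ODE: equilibria, tear-off, stability, integration

exp_curve <- function(dmax = 6) {
  d <- seq(0.1, dmax, by = 0.05)
  force_curve(d, F_r = -exp(-d), F_theta = rep(0, length(d)))
}

test_that("drift_rhs reduces to the pure gradient when delta_alpha = 0", {
  m <- drift_model(exp_curve(), delta_alpha = 0, hg = 0.3, gamma = 0.7)
  R <- complex(real = c(1, -2, 0.5), imaginary = c(0.2, 1, -3))
  expect_equal(drift_rhs(R, m), rep(0.3 * exp(0.7i), 3))
})

test_that("complex and polar forms agree at random points", {
  set.seed(1)
  d <- seq(0.1, 5, by = 0.1)
  cv <- force_curve(d, F_r = -exp(-d) * (1 + 0.3 * sin(d)),
                    F_theta = 0.4 * exp(-0.8 * d))
  m <- drift_model(cv, delta_alpha = 0.7, hg = 0.15, gamma = 1.2)
  for (k in 1:100) {
    r <- runif(1, 0.2, 4.5); th <- runif(1, -pi, pi)
    v <- drift_rhs(r * exp(1i * th), m)
    pol <- borderzone:::drift_rhs_polar(c(r, th), m)
    ## dR/dt = (dr/dt + i r dtheta/dt) e^{i theta}
    v2 <- (pol[1] + 1i * r * pol[2]) * exp(1i * th)
    expect_lt(Mod(v - v2), 1e-12)
  }
})

test_that("drift_rhs is singular at the origin and zero-extrapolated", {
  m <- drift_model(exp_curve(), 1, 0.1)
  expect_error(drift_rhs(0 + 0i, m), "singular")
  expect_equal(drift_rhs(100 + 0i, m), 0.1 + 0i)  # beyond range: force -> 0
})

test_that("analytic exponential-curve equilibrium radius is exact", {
  ## F_r(d) = -exp(-d), F_theta = 0, delta_alpha = 1:
  ## |F| = hg  at  r* = -log(hg); with hg = exp(-2), r* = 2
  m <- drift_model(exp_curve(), delta_alpha = 1, hg = exp(-2), gamma = 0)
  eq <- find_equilibria(m)
  expect_gte(nrow(eq), 1L)
  expect_lt(min(abs(eq$r - 2)), 1e-10)
})

test_that("tear-off threshold: zero curve, endpoint max, linearity", {
  d <- seq(0.5, 6, by = 0.1)
  z <- force_curve(d, rep(0, length(d)))
  expect_equal(tear_off_threshold(drift_model(z, 1, 0)), 0)
  mono <- force_curve(d, -exp(-d))
  m1 <- drift_model(mono, delta_alpha = 1, hg = 0)
  expect_equal(tear_off_threshold(m1), exp(-0.5), tolerance = 1e-6)
  m2 <- drift_model(mono, delta_alpha = 2, hg = 0)
  expect_equal(tear_off_threshold(m2), 2 * tear_off_threshold(m1),
               tolerance = 1e-12)
})

## random smooth synthetic curves with a rise-and-decay shape
random_model <- function(seed) {
  set.seed(seed)
  d <- seq(0.1, 6, by = 0.05)
  a <- runif(1, 0.5, 2); b <- runif(1, 0.5, 1.5); s <- sample(c(-1, 1), 1)
  Fr <- s * a * d * exp(-b * d)
  Ft <- runif(1, -0.5, 0.5) * a * d * exp(-runif(1, 0.8, 1.6) * d)
  da <- sample(c(-1, 1), 1) * runif(1, 0.4, 1.2)
  mmax <- max(abs(da) * sqrt(Fr^2 + Ft^2))
  hg <- runif(1, 0.15, 0.85) * mmax
  drift_model(force_curve(d, Fr, Ft), delta_alpha = da, hg = hg,
              gamma = runif(1, -pi, pi))
}

test_that("equilibria exist iff hg is below the tear-off threshold", {
  for (seed in 1:40) {
    m <- random_model(seed)
    eq <- find_equilibria(m)
    expect_gt(nrow(eq), 0)
    m_over <- drift_model(m$curve, m$delta_alpha,
                          hg = 1.05 * tear_off_threshold(m), m$gamma)
    expect_identical(nrow(find_equilibria(m_over)), 0L)
  }
})

test_that("equilibria match a brute-force scan of |velocity| minima", {
  for (seed in c(3, 17, 29)) {
    m <- random_model(seed)
    eq <- find_equilibria(m)
    expect_gt(nrow(eq), 0)
    ## brute force over a polar grid: deep local minima of |v| and the
    ## reported equilibria must identify the same points
    rg <- seq(0.12, 5.9, length.out = 300)
    tg <- seq(-pi, pi, length.out = 241)[-1]
    speed <- outer(rg, tg, function(r, th)
      Mod(drift_rhs(r * exp(1i * th), m)))
    dist_to_eq <- function(r0, t0)
      min(sqrt((eq$r - r0)^2 + (2 * eq$r * sin((eq$theta - t0) / 2))^2))
    ## interior local minima below 0.2 hg
    n_min <- 0
    for (i in 2:(length(rg) - 1)) for (j in 2:(length(tg) - 1)) {
      v <- speed[i, j]
      if (v > 0.2 * m$hg) next
      if (v <= min(speed[(i-1):(i+1), (j-1):(j+1)])) {
        n_min <- n_min + 1
        expect_lt(dist_to_eq(rg[i], tg[j]), 0.1)
      }
    }
    expect_gt(n_min, 0)
    ## conversely every equilibrium sits in a low-|v| region of the scan
    for (k in seq_len(nrow(eq))) {
      i <- which.min(abs(rg - eq$r[k])); j <- which.min(abs(tg - eq$theta[k]))
      expect_lt(speed[i, j], 0.2 * m$hg)
    }
  }
})

test_that("analytic stability conditions match Jacobian eigenvalues", {
  n_checked <- 0
  for (seed in 1:100) {
    m <- random_model(seed)
    eq <- find_equilibria(m)   # errors inside assess_stability on mismatch
    n_checked <- n_checked + sum(!is.na(eq$stable))
  }
  expect_gt(n_checked, 100)
})

test_that("attractive curve has a stable equilibrium left of the force maximum", {
  ## convention: velocity contribution is -delta_alpha * F_r * e^{i theta},
  ## so F_r > 0 with delta_alpha > 0 pulls the centre towards the disk
  d <- seq(0.1, 6, by = 0.05)
  Fr <- d * exp(-d)               # attractive for delta_alpha > 0
  cv <- force_curve(d, Fr)
  m <- drift_model(cv, delta_alpha = 1, hg = 0.5 * max(abs(Fr)), gamma = 0)
  eq <- find_equilibria(m)
  stable <- eq[which(eq$stable), ]
  expect_gte(nrow(stable), 1L)
  expect_true(all(stable$r < 1))  # maximum of |F_r| is at d = 1
})

test_that("no stable equilibrium exists near a repelling disk", {
  ## BRP-shaped curve: |F_r| rising then decaying, F_theta small;
  ## delta_alpha < 0 makes it repelling with curve F_r < 0 convention
  d <- seq(0.1, 6, by = 0.05)
  cv <- force_curve(d, F_r = -d * exp(-d), F_theta = 0.1 * d * exp(-d))
  for (hg_frac in c(0.3, 0.6, 0.9)) {
    m <- drift_model(cv, delta_alpha = 1,
                     hg = hg_frac * tear_off_threshold(
                       drift_model(cv, 1, 0)), gamma = 0.4)
    eq <- find_equilibria(m)
    expect_false(any(eq$stable, na.rm = TRUE))
  }
})

test_that("integrate_drift stays on a verified stable equilibrium", {
  d <- seq(0.1, 6, by = 0.05)
  cv <- force_curve(d, d * exp(-d))
  m <- drift_model(cv, 1, hg = 0.5 * max(d * exp(-d)), gamma = 0)
  eq <- find_equilibria(m)
  st <- eq[which(eq$stable)[1], ]
  R0 <- st$r * exp(1i * st$theta)
  tr <- integrate_drift(m, R0, T = 50)
  expect_lt(Mod(tail(tr$R, 1) - R0), 1e-8)
})

test_that("integrate_drift converges under tolerance halving", {
  d <- seq(0.1, 8, by = 0.05)
  cv <- force_curve(d, d * exp(-d), 0.2 * d * exp(-d))
  m <- drift_model(cv, 1, hg = 0.4 * max(d * exp(-d)), gamma = 0.5)
  R0 <- -4 + 2i
  t1 <- integrate_drift(m, R0, T = 60, tol = 1e-8)
  t2 <- integrate_drift(m, R0, T = 60, tol = 5e-9)
  pl <- sum(Mod(diff(t1$R)))
  expect_lt(Mod(tail(t1$R, 1) - tail(t2$R, 1)), 1e-6 * max(pl, 1))
})

test_that("attractive-disk trajectory terminates at the equilibrium behind the disk", {
  d <- seq(0.1, 8, by = 0.05)
  cv <- force_curve(d, d * exp(-d))
  m <- drift_model(cv, 1, hg = 0.4 * max(d * exp(-d)), gamma = 0)
  eq <- find_equilibria(m)
  st <- eq[which(eq$stable)[1], ]
  ## start up-gradient (the force drags towards +x, disk at origin)
  tr <- integrate_drift(m, -4 + 0.5i, T = 2000)
  expect_identical(tr$event, "equilibrium")
  Rend <- tail(tr$R, 1)
  expect_lt(Mod(Rend - st$r * exp(1i * st$theta)), 0.1)
  ## "behind" the disk: downstream of the dragging force direction
  expect_gt(Re(Rend), 0)
})

test_that("superpose sums forces and rejects mixed conventions", {
  f1 <- specific_force(0.3 + 0.1i, 0.01 + 0.01i, "conv A")
  f2 <- specific_force(-0.2 + 0.4i, 0.01 + 0.01i, "conv A")
  expect_equal(superpose(list(list(magnitude = 1, force = f1))), f1$value)
  expect_equal(superpose(list(list(magnitude = 1, force = f1),
                              list(magnitude = -1, force = f1))), 0 + 0i)
  set.seed(2)
  for (k in 1:5) {
    w <- rnorm(3); v <- complex(real = rnorm(3), imaginary = rnorm(3))
    fs <- lapply(1:3, function(i) list(magnitude = w[i], force = v[i]))
    expect_equal(superpose(fs), sum(w * v), tolerance = 1e-15)
  }
  f3 <- specific_force(1 + 0i, 0.1 + 0.1i, "conv B")
  expect_error(superpose(list(list(magnitude = 1, force = f1),
                              list(magnitude = 1, force = f3))),
               "convention")
})
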