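# Tip detection, filament extraction, trajectory analysis

test_that("tip detection is exact on linear fields", {
  g <- grid_spec(21, 21, 1)
  fx <- make_synthetic_fields("linear", g, x0 = 11.25, y0 = 8.5)
  tp <- detect_tips(fx$V, fx$f, V_iso = 0, f_iso = 0)
  expect_equal(nrow(tp), 1L)
  expect_equal(tp$x, 11.25, tolerance = 1e-12)
  expect_equal(tp$y, 8.5, tolerance = 1e-12)
})

test_that("disjoint isoline ranges give an empty result", {
  V <- matrix(5, 10, 10); f <- matrix(0.2, 10, 10)
  tp <- detect_tips(V, f, V_iso = 0, f_iso = 0.5)
  expect_identical(nrow(tp), 0L)
})

test_that("spiral-fixture tip is invariant under pattern rotation", {
  g <- grid_spec(41, 41, 1)
  tips <- lapply(c(0, 0.9, 2.2), function(ph) {
    fx <- make_synthetic_fields("spiral", g, phase = ph)
    detect_tips(fx$V, fx$f, V_iso = 0, f_iso = 0)
  })
  for (tp in tips) expect_equal(nrow(tp), 1L)
  for (tp in tips[-1]) {
    expect_lt(abs(tp$x - tips[[1]]$x), 0.1)
    expect_lt(abs(tp$y - tips[[1]]$y), 0.1)
  }
})

test_that("mirroring the fields flips chirality", {
  g <- grid_spec(41, 41, 1)
  fx <- make_synthetic_fields("spiral", g)
  tp <- detect_tips(fx$V, fx$f, V_iso = 0, f_iso = 0)
  tpm <- detect_tips(fx$V[41:1, ], fx$f[41:1, ], V_iso = 0, f_iso = 0)
  expect_equal(tpm$chirality, -tp$chirality)
})

test_that("extruded 2D spiral yields one straight filament of box height", {
  g <- grid_spec(31, 31, 8)
  fx <- make_synthetic_fields("extruded", g)
  fl <- extract_filaments(fx$V, fx$f, V_iso = 0, f_iso = 0)
  expect_equal(length(fl), 1L)
  expect_false(fl[[1]]$closed)
  ## straight within one cell: xy spread of the polyline
  xy <- fl[[1]]$points[, 1:2]
  expect_lt(max(dist(xy)), 1)
  expect_equal(fl[[1]]$length, g$nz - 1, tolerance = 0.15)
})

test_that("scroll-ring filament is closed with length within 5% of 2*pi*r", {
  g <- grid_spec(40, 40, 12)
  fx <- make_synthetic_fields("scroll_ring", g, r0 = 9)
  fl <- extract_filaments(fx$V, fx$f, V_iso = 0, f_iso = 0)
  expect_equal(length(fl), 1L)
  expect_true(fl[[1]]$closed)
  expect_lt(abs(fl[[1]]$length - 2 * pi * 9) / (2 * pi * 9), 0.05)
})

test_that("quiescent 3D fields give no filaments", {
  V <- array(-80, c(10, 10, 5)); f <- array(0.99, c(10, 10, 5))
  expect_identical(extract_filaments(V, f), list())
})

test_that("drift_velocity: closed circle has zero net velocity", {
  t <- seq(0, 1000, by = 5)
  x <- 10 + 3 * cos(2 * pi * t / 100)
  y <- 10 + 3 * sin(2 * pi * t / 100)
  dv <- drift_velocity(t, x, y)
  expect_equal(dv$period, 100, tolerance = 0.05)
  expect_lt(Mod(dv$velocity), 1e-3)
})

test_that("drift_velocity recovers translation of a cycloid within 1%", {
  t <- seq(0, 2000, by = 5)
  v0 <- complex(real = 0.004, imaginary = -0.002)
  x <- 30 + 3 * cos(2 * pi * t / 120) + Re(v0) * t
  y <- 30 + 3 * sin(2 * pi * t / 120) + Im(v0) * t
  dv <- drift_velocity(t, x, y)
  expect_lt(Mod(dv$velocity - v0) / Mod(v0), 0.01)
})

test_that("jittered cycloid velocity is recovered within uncertainty", {
  set.seed(99)
  t <- seq(0, 3000, by = 5)
  v0 <- complex(real = 0.003, imaginary = 0.001)
  hits <- 0
  for (rep in 1:5) {
    x <- 20 + 2 * cos(2 * pi * t / 150) + Re(v0) * t + rnorm(length(t), 0, 0.1)
    y <- 20 + 2 * sin(2 * pi * t / 150) + Im(v0) * t + rnorm(length(t), 0, 0.1)
    dv <- drift_velocity(t, x, y)
    if (Mod(dv$velocity - v0) < 3 * Mod(dv$se)) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("track linking follows two separated tips without identity swap", {
  times <- seq(0, 100, by = 5)
  tip_list <- lapply(times, function(t) {
    data.frame(x = c(10 + 0.02 * t, 30 - 0.02 * t),
               y = c(10, 30), x_mm = NA, y_mm = NA, chirality = c(1, -1))
  })
  tr <- track_tips(tip_list, times)
  expect_identical(length(unique(tr$track)), 2L)
  t1 <- tr[tr$track == tr$track[1], ]
  expect_true(all(abs(t1$y - t1$y[1]) < 1e-9))
})

test_that("count_spirals honours the persistence window", {
  tracks <- data.frame(track = c(rep(1, 20), rep(2, 3)),
                       t = c(seq(0, 950, by = 50), c(0, 50, 100)),
                       x = 0, y = 0, chirality = 1)
  expect_identical(count_spirals(tracks, t_after = 0, period = 100), 1L)
  expect_identical(count_spirals(tracks[0, ], 0, 100), 0L)
})
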