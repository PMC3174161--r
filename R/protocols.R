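## End-to-end protocols: border-zone runs in 2D and 3D, the escape-curve
## sweep over border speeds, deliberately arranged pinning experiments, and
## analytic field fixtures for detector tests.

#' Analytic field fixtures with known singularity geometry
#'
#' Generates V and f fields whose two-isoline singularities are known in
#' closed form, for testing the detectors without simulation.
#'
#' Types: `"linear"` (planes `V = x - x0`, `f = y - y0`, one crossing);
#' `"spiral"` (rigid Archimedean spiral phase about `(x0, y0)`:
#' `V = r cos(theta - k r + phase)`, `f = r sin(...)`, singular at the
#' centre); `"extruded"` (the spiral repeated along z); `"scroll_ring"`
#' (torus phase about a circular filament of radius `r0`).
#'
#' @param type fixture type.
#' @param grid a [grid_spec()].
#' @param x0,y0,z0 singularity location (cell units; defaults to the grid
#'   centre).
#' @param k spiral wavenumber (radians per cell).
#' @param phase rotation angle of the spiral pattern (radians).
#' @param r0 scroll-ring radius (cells).
#' @return list with arrays `V` and `f` (2D matrices for `"linear"` and
#'   `"spiral"`), plus the analytic geometry (`tip`, or `filament_length`).
#' @export
make_synthetic_fields <- function(type = c("linear", "spiral", "extruded",
                                           "scroll_ring"),
                                  grid, x0 = (grid$nx + 1) / 2,
                                  y0 = (grid$ny + 1) / 2,
                                  z0 = (grid$nz + 1) / 2,
                                  k = 0.2, phase = 0, r0 = grid$nx / 5) {
  type <- match.arg(type)
  xi <- seq_len(grid$nx); yi <- seq_len(grid$ny)
  switch(type,
    linear = {
      V <- outer(xi, yi, function(x, y) (x - x0) * 1.0)
      f <- outer(xi, yi, function(x, y) (y - y0) * 1.0)
      list(V = V, f = f, tip = c(x0, y0), V_iso = 0, f_iso = 0)
    },
    spiral = {
      X <- outer(xi, yi, function(x, y) x - x0)
      Y <- outer(xi, yi, function(x, y) y - y0)
      r <- sqrt(X^2 + Y^2)
      th <- atan2(Y, X)
      ph <- th - k * r + phase
      list(V = r * cos(ph), f = r * sin(ph), tip = c(x0, y0),
           V_iso = 0, f_iso = 0)
    },
    extruded = {
      sp <- make_synthetic_fields("spiral", grid, x0, y0, k = k,
                                  phase = phase)
      V <- array(sp$V, grid_dims(grid))
      f <- array(sp$f, grid_dims(grid))
      list(V = V, f = f, tip = c(x0, y0), V_iso = 0, f_iso = 0,
           filament_length = grid$nz - 1)
    },
    scroll_ring = {
      zi <- seq_len(grid$nz)
      V <- array(0, grid_dims(grid)); f <- array(0, grid_dims(grid))
      for (kz in zi) {
        rho <- sqrt(outer(xi - x0, yi - y0, function(a, b) a^2 + b^2))
        s1 <- rho - r0
        s2 <- kz - z0
        V[, , kz] <- s1
        f[, , kz] <- matrix(s2, grid$nx, grid$ny)
      }
      list(V = V, f = f, filament_length = 2 * pi * r0,
           V_iso = 0, f_iso = 0, r0 = r0)
    })
}

#' Default border-zone protocol configuration
#'
#' Desk-scale defaults for the moving-border protocols.  The bottom layer
#' is uncoupled and unexcitable (region IV); the top layer is well coupled
#' at moderate excitability (region V); the transitional band carries the
#' gradients and, with heterogeneity, region-III focal activity.
#'
#' @param nx,ny,nz box size (cells).
#' @param h cell size (mm).
#' @param D0 top-layer diffusivity (mm^2/ms).
#' @param Dmin bottom-layer diffusivity.
#' @param alpha_top,alpha_bottom excitability limits.
#' @param width border width (mm).
#' @param alpha_shift displacement of the excitability ramp below the
#'   coupling ramp (mm); defaults to `width`, so excitability is fully
#'   recovered where coupling starts to rise (region III band).
#' @param u border speed (mm/ms, negative = downward).
#' @param nu heterogeneity intensity.
#' @param dt time step (ms).
#' @param duration run length (ms); default until the border has left the
#'   box.
#' @param seed RNG seed for the frozen heterogeneity.
#' @return list (class `border_protocol_config`).
#' @export
border_protocol_config <- function(nx = 60, ny = 80, nz = 1, h = 0.1,
                                   D0 = 0.0025, Dmin = 0, alpha_top = 0.6,
                                   alpha_bottom = 0, width = 2,
                                   alpha_shift = width,
                                   u = -0.002, nu = 0.15, dt = 0.1,
                                   duration = NULL, seed = 1L) {
  y_top <- ny * h
  y2_0 <- y_top * 0.85
  y1_0 <- y2_0 - width
  if (is.null(duration)) {
    duration <- if (u < 0) (y2_0 + 2 * width) / abs(u) else 4000
  }
  structure(list(grid = grid_spec(nx, ny, nz, h),
                 bz = border_zone_config(D0 = D0, Dmin = Dmin,
                                         alpha_top = alpha_top,
                                         alpha_bottom = alpha_bottom,
                                         y1_0 = y1_0, y2_0 = y2_0, u = u,
                                         alpha_shift = alpha_shift),
                 nu = nu, dt = dt, duration = duration,
                 seed = as.integer(seed)),
            class = "border_protocol_config")
}

#' Moving border zone in 2D
#'
#' Runs the moving-profile 2D protocol from rest with online tip tracking.
#'
#' @param cfg a [border_protocol_config()] with `nz = 1`.
#' @param params a [brp_params()] template.
#' @param sample_dt tip sampling interval (ms).
#' @return list with `tracks`, `tips`, `times`, `state`, `het`, `cfg`.
#' @export
run_border_zone_2d <- function(cfg, params = brp_params(), sample_dt = 10) {
  g <- cfg$grid
  stopifnot(g$nz == 1L)
  het <- sample_heterogeneity(g, cfg$nu, cfg$seed)
  pf0 <- parameter_fields(g, cfg$bz, het, t = 0)
  st <- init_fields(g, rest_state_for(params, pf0))
  sc <- sim_config(dt = cfg$dt, duration = cfg$duration,
                   sample_dt = sample_dt)
  out <- run_tissue(st, g, params, sc, cfg = cfg$bz, het = het)
  out$het <- het
  out$cfg <- cfg
  out
}

#' Moving border zone in 3D
#'
#' Downward-moving layered slab with filament extraction at selected
#' sample times and a persistence report after the border leaves the box.
#'
#' @param cfg a [border_protocol_config()] with `nz > 1`.
#' @param params a [brp_params()] template.
#' @param sample_dt filament sampling interval (ms).
#' @param t_report times (ms) at which to extract filaments; default the
#'   end of the run.
#' @return list with `filaments` (list per report time), `n_filaments`,
#'   `state`, `t_exit` (border exit time), `cfg`.
#' @export
run_border_zone_3d <- function(cfg, params = brp_params(), sample_dt = 20,
                               t_report = NULL) {
  g <- cfg$grid
  stopifnot(g$nz > 1L)
  het <- sample_heterogeneity(g, cfg$nu, cfg$seed)
  pf0 <- parameter_fields(g, cfg$bz, het, t = 0)
  st <- init_fields(g, rest_state_for(params, pf0))
  t_exit <- if (cfg$bz$u < 0) (cfg$bz$y2_0 + 0.5) / abs(cfg$bz$u) else Inf
  if (is.null(t_report)) t_report <- cfg$duration
  t_report <- sort(t_report)
  cur <- st; t <- 0
  fil <- list()
  nstep_chunk <- max(1L, round(sample_dt / cfg$dt))
  n_chunks <- ceiling(cfg$duration / sample_dt)
  for (s in seq_len(n_chunks)) {
    pf <- parameter_fields(g, cfg$bz, het, t = t)
    cur <- step_chunk(cur, pf, g, params, cfg$dt, nstep_chunk)$state
    t <- t + nstep_chunk * cfg$dt
    due <- t_report[t_report <= t + 1e-9 & t_report > t - sample_dt + 1e-9]
    for (tr in due)
      fil[[sprintf("t%.0f", tr)]] <- extract_filaments(cur$V, cur$f,
                                                       h = g$h)
    if (t >= cfg$duration) break
  }
  list(filaments = fil,
       n_filaments = vapply(fil, length, integer(1)),
       state = cur, t_exit = t_exit, cfg = cfg)
}

#' Escape curve: persistent spirals vs border speed
#'
#' Sweeps the border speed over `speed_list`; for each speed, runs the
#' protocol for each seed and counts the activity that persists after the
#' border has left the box.  The escape window lies between the typical
#' spiral drift speed and the conduction velocity, so the count vanishes at
#' both extremes and peaks in between.
#'
#' @param speed_list border speeds (mm/ms, positive values; applied
#'   downward as `-speed`).
#' @param seeds integer seeds (>= 2).
#' @param cfg a [border_protocol_config()] template (its `u`, `seed`,
#'   `duration` are overridden per run).
#' @param params a [brp_params()] template.
#' @param t_margin extra time (ms) simulated past border exit before
#'   counting.
#' @return data.frame with columns `speed`, `mean_count`, `se`, plus
#'   attribute `counts` (matrix speeds x seeds).
#' @export
escape_curve <- function(speed_list, seeds, cfg, params = brp_params(),
                         t_margin = 400) {
  counts <- matrix(0, length(speed_list), length(seeds))
  g <- cfg$grid
  for (i in seq_along(speed_list)) {
    u <- -abs(speed_list[i])
    for (j in seq_along(seeds)) {
      cfg_ij <- cfg
      cfg_ij$bz$u <- u
      cfg_ij$seed <- as.integer(seeds[j])
      cfg_ij$duration <- (cfg$bz$y2_0 + 0.5) / abs(u) + t_margin
      if (g$nz > 1L) {
        run <- run_border_zone_3d(cfg_ij, params, t_report = cfg_ij$duration)
        counts[i, j] <- tail(run$n_filaments, 1)
      } else {
        run <- run_border_zone_2d(cfg_ij, params)
        per <- 150
        counts[i, j] <- count_spirals(run$tracks,
                                      t_after = cfg_ij$duration - t_margin,
                                      period = per)
      }
    }
  }
  out <- data.frame(speed = speed_list,
                    mean_count = rowMeans(counts),
                    se = apply(counts, 1, sd) / sqrt(length(seeds)))
  attr(out, "counts") <- counts
  out
}

#' Orbit-averaged tip path
#'
#' Rolling mean of a tip trajectory over the rotor's slow orbit period,
#' removing the deterministic circular component of the tip motion.
#'
#' @param trj data.frame with `t`, `x`, `y` (single-tip samples).
#' @param W averaging window (ms), about one orbit period.
#' @param by output spacing (ms).
#' @return data.frame `t`, `x`, `y` of the averaged path.
#' @export
orbit_average <- function(trj, W = 1900, by = 250) {
  t_out <- seq(min(trj$t) + W / 2, max(trj$t) - W / 2, by = by)
  if (length(t_out) < 2) stop("trajectory shorter than the averaging window")
  data.frame(t = t_out,
             x = vapply(t_out, function(tc)
               mean(trj$x[abs(trj$t - tc) <= W / 2]), numeric(1)),
             y = vapply(t_out, function(tc)
               mean(trj$y[abs(trj$t - tc) <= W / 2]), numeric(1)))
}

#' Deliberately arranged pinning experiment
#'
#' A spiral in a uniform medium is dragged by a constant advection force
#' past deliberately placed disk inhomogeneities of excitability; the
#' orbit-averaged tip path is classified as free drift, temporary stall,
#' or permanent pin.
#'
#' Arrangements: `"single_repelling"` (one disk with `delta_alpha > 0` on
#' the drift path: the spiral slows in front of it, detours, and resumes —
#' net progress is preserved), `"two_repelling"` (a second disk blocking
#' the detour route stops the drift altogether: net progress along the
#' drag direction stays bounded), `"single_attracting"`
#' (`delta_alpha < 0`: the spiral is captured and permanently stalled
#' just behind the disk, down-force of its centre).
#'
#' Classification uses progress along the free-drift direction of the
#' orbit-averaged path: `"permanent pin"` if the final-window speed drops
#' below `stall_frac` of the free-drift speed and total late progress is
#' bounded; `"temporary stall"` if some interior window is below
#' `stall_frac` (or the path detours by more than one orbit radius) while
#' final progress is comparable to free drift; `"free drift"` otherwise.
#'
#' @param arrangement one of the three cases above.
#' @param spiral a [prepare_spiral()] result.
#' @param E dragging advection magnitude (mm/ms-equivalent).
#' @param delta_alpha disk contrast magnitude (> 0; the sign is set by the
#'   arrangement).
#' @param R0 disk radius (mm).
#' @param place_ahead distance (mm) from the spiral centre to the leading
#'   disk centre, along the measured free-drift direction.
#' @param offset along/lateral placement (mm) of the detour-blocking
#'   second disk: it sits at `offset * (-i e_dir) + 0.4 e_dir` (the
#'   detour route of this chirality).
#' @param T total time (ms).
#' @param orbit_W orbit-averaging window (ms).
#' @param stall_frac speed fraction defining a stall.
#' @param v_free optionally, a pre-measured complex free-drift velocity
#'   (mm/ms) to skip the calibration runs.
#' @return list with `classification`, `trajectory` (raw tips),
#'   `path` (orbit-averaged), `v_free` (mm/ms), `progress` (cells, along
#'   the drag direction), `progress_free` (expected free progress),
#'   `disks`, `delta_alpha`, `R0`, `E`.
#' @export
pinning_experiment <- function(arrangement = c("single_repelling",
                                               "two_repelling",
                                               "single_attracting"),
                               spiral, E = 0.0007, delta_alpha = 0.3,
                               R0 = 0.5, place_ahead = 1.0, offset = 1.1,
                               T = 9000, orbit_W = 1900, stall_frac = 0.3,
                               v_free = NULL) {
  arrangement <- match.arg(arrangement)
  g <- spiral$grid
  stopifnot(nrow(spiral$tips) == 1)
  if (is.null(v_free)) {
    ref <- tip_trajectory(spiral$state, spiral$pf, g, spiral$params,
                          spiral$dt, min(T, 3000))
    free <- tip_trajectory(spiral$state, spiral$pf, g, spiral$params,
                           spiral$dt, min(T, 3000), E = E)
    v_free <- relative_drift(free, ref)$v * g$h
  }
  if (Mod(v_free) == 0) stop("no free drift under the chosen E")
  e_dir <- v_free / Mod(v_free)
  ctr <- complex(real = spiral$tips$x_mm[1], imaginary = spiral$tips$y_mm[1])
  sgn <- if (arrangement == "single_attracting") -1 else 1
  disks <- switch(arrangement,
    single_repelling = ctr + place_ahead * e_dir,
    single_attracting = ctr + place_ahead * e_dir,
    two_repelling = c(ctr + place_ahead * e_dir,
                      ctr + 0.4 * e_dir + offset * (-1i) * e_dir))
  xm <- axis_coord(g$nx, g$h); ym <- axis_coord(g$ny, g$h)
  pf <- spiral$pf
  da <- array(0, grid_dims(g))
  for (dc in disks) {
    dist2 <- outer(xm, ym, function(x, y) (x - Re(dc))^2 + (y - Im(dc))^2)
    da[, , 1] <- da[, , 1] + ifelse(dist2 <= R0^2, sgn * delta_alpha, 0)
  }
  pf$alpha <- pmin(1 - 1e-9, pmax(0, pf$alpha + da))
  trj <- tip_trajectory(spiral$state, pf, g, spiral$params, spiral$dt, T,
                        E = E)
  path <- orbit_average(trj, W = orbit_W)
  ## progress along the drag direction, in cells
  z <- complex(real = path$x, imaginary = path$y)
  s_along <- Re((z - z[1]) * Conj(e_dir))
  lat <- Im((z - z[1]) * Conj(e_dir))
  prog <- tail(s_along, 1)
  prog_free <- Mod(v_free) / g$h * (tail(path$t, 1) - path$t[1])
  vf_cells <- Mod(v_free) / g$h
  ## along-drag speed by regression, late window and sliding windows
  slope_in <- function(t0, t1) {
    k <- path$t >= t0 & path$t <= t1
    if (sum(k) < 4) return(NA_real_)
    unname(coef(lm(s_along[k] ~ path$t[k]))[2])
  }
  t0 <- path$t[1]; t1 <- tail(path$t, 1)
  v_late <- slope_in(t0 + 0.6 * (t1 - t0), t1)
  wins <- seq(t0, t1 - 1200, by = 300)
  v_win <- vapply(wins, function(w) slope_in(w, w + 1200), numeric(1))
  detour <- max(abs(lat))
  pinned <- (!is.na(v_late) && abs(v_late) < stall_frac * vf_cells) ||
    prog < 0.3 * prog_free
  stalled <- any(v_win < stall_frac * vf_cells, na.rm = TRUE)
  classification <-
    if (pinned) "permanent pin"
    else if (stalled || detour > 5) "temporary stall"
    else "free drift"
  list(classification = classification, trajectory = trj, path = path,
       v_free = v_free, v_late = v_late, progress = prog,
       progress_free = prog_free, v_windows = v_win, detour = detour,
       disks = disks, delta_alpha = sgn * delta_alpha, R0 = R0,
       stall_frac = stall_frac, E = E)
}
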