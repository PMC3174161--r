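## Explicit 2D/3D time stepping of the coupled tissue, stimulation
## protocols, spiral initiation, and conduction-velocity measurement.
##
## The voltage equation may carry an advection perturbation E * dV/dx
## (central differences) used to measure the curvature-equivalent
## (electrophoretic) drift force.

FIELD_NAMES <- c("V", "Ca", "m", "h", "j", "d", "f", "x1")

#' Simulation configuration
#'
#' @param dt time step (ms).  Must satisfy the explicit stability bound
#'   `dt <= safety * h^2 / (2 * dim * max(D))`.
#' @param duration total simulated time (ms).
#' @param E advection magnitude applied to V only (mV/mm per mV, i.e. the
#'   prefactor of `dV/dx`); 0 disables the perturbation.
#' @param sample_dt interval (ms) between tip/filament snapshots.
#' @param safety CFL safety factor in (0, 1].
#' @param seed integer seed recorded with results.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.1, duration = 1000, E = 0, sample_dt = 5,
                       safety = 0.9, seed = 1L) {
  stopifnot(dt > 0, duration > 0, sample_dt >= dt, safety > 0, safety <= 1)
  structure(list(dt = dt, duration = duration, E = E, sample_dt = sample_dt,
                 safety = safety, seed = as.integer(seed)),
            class = "sim_config")
}

#' Explicit stability bound on dt
#'
#' @param grid a [grid_spec()].
#' @param Dmax maximum diffusivity on the grid (mm^2/ms).
#' @return the forward-Euler diffusion bound `h^2 / (2 dim Dmax)` (ms).
#' @export
cfl_limit <- function(grid, Dmax) {
  if (Dmax <= 0) return(Inf)
  grid$h^2 / (2 * grid$dim * Dmax)
}

check_cfl <- function(grid, fields, simcfg) {
  lim <- cfl_limit(grid, max(fields$D)) * simcfg$safety
  if (simcfg$dt > lim)
    stop(sprintf("dt = %g exceeds the stability bound %g ms (h = %g, max D = %g)",
                 simcfg$dt, lim, grid$h, max(fields$D)))
  invisible(TRUE)
}

#' Uniform state fields on a grid
#'
#' @param grid a [grid_spec()].
#' @param state a cell state vector (e.g. a rest state); recycled to every
#'   cell.
#' @return named list of eight arrays (V, Ca, m, h, j, d, f, x1).
#' @export
init_fields <- function(grid, state) {
  stopifnot(length(state) == 8L)
  dims <- grid_dims(grid)
  setNames(lapply(seq_len(8), function(i) array(state[[i]], dims)),
           FIELD_NAMES)
}

## low-level chunk step; duplicates the state so callers keep ownership
step_chunk <- function(state, pf, grid, params, dt, nsteps, E = 0,
                       stim = NULL, stim_on = FALSE, probes = integer(0)) {
  st <- lapply(state, function(a) a + 0)   # force copy
  r <- tissue_run_cpp(st, pf$D, pf$alpha, grid$nx, grid$ny, grid$nz,
                      grid$h, dt, as.integer(nsteps), param_vec(params), E,
                      if (is.null(stim)) numeric(0) else stim,
                      as.integer(isTRUE(stim_on) && !is.null(stim)),
                      as.integer(probes))
  list(state = r$fields, probe_V = r$probe_V)
}

#' Advance tissue state
#'
#' One or more explicit steps of the full reaction-diffusion system:
#' forward Euler for V (ionic + coupling + optional advection `E dV/dx`)
#' and Ca, Rush-Larsen exponential updates for the gates, no-flux outer
#' boundaries.  Refuses to start if `dt` violates the stability bound.
#'
#' @param state named list of eight field arrays (see [init_fields()]).
#' @param pf a [parameter_fields()] object.
#' @param grid a [grid_spec()].
#' @param params a [brp_params()] object (its `alpha` is overridden per
#'   cell by `pf$alpha`).
#' @param simcfg a [sim_config()]; `duration` here is the time to advance.
#' @param stim optional per-cell stimulus current array (mV/ms), applied
#'   for the whole interval.
#' @return updated state list.
#' @export
step_tissue <- function(state, pf, grid, params, simcfg, stim = NULL) {
  check_cfl(grid, pf, simcfg)
  n <- max(1L, round(simcfg$duration / simcfg$dt))
  step_chunk(state, pf, grid, params, simcfg$dt, n, simcfg$E,
             stim, !is.null(stim))$state
}

## linear (0-based) index of cell (i, j, k)
cell_index0 <- function(grid, i, j, k = 1L)
  (i - 1L) + grid$nx * ((j - 1L) + grid$ny * (k - 1L))

#' Initiate a spiral wave by cross-field (S1-S2) stimulation
#'
#' An S1 plane wave is launched along x; when the tissue behind its back
#' at the future phase-singularity location repolarizes through `v_s2`,
#' an S2 half-field stimulus covering `x < x_break`, `y < ny/2` is applied,
#' whose free end curls into a single spiral.  After a settling time the
#' tip count is verified.
#'
#' @param grid a 2D [grid_spec()].
#' @param pf a [parameter_fields()] (usually uniform).
#' @param params a [brp_params()].
#' @param simcfg a [sim_config()]; its `duration` is the settling time
#'   after S2.
#' @param chirality +1 or -1; the mirrored S2 geometry gives the opposite
#'   rotation sense.
#' @param v_s2 repolarization threshold (mV) triggering S2.
#' @param x_break_frac S2 edge position as a fraction of nx.
#' @param s1_amp,s2_amp,stim_dur stimulus strengths (mV/ms) and duration (ms).
#' @return list with `state` (field list after settling), `tips` (tip table
#'   at the end), `ok` (exactly one tip), `t_s2` (S2 time, ms), and
#'   `period` (activation period at a probe near the core, ms, or NA).
#' @export
initiate_spiral <- function(grid, pf, params, simcfg, chirality = 1,
                            v_s2 = -50, x_break_frac = 0.6, s1_amp = 40,
                            s2_amp = 25, stim_dur = 2) {
  stopifnot(grid$nz == 1L)
  check_cfl(grid, pf, simcfg)
  dt <- simcfg$dt
  dims <- grid_dims(grid)
  mirror <- chirality < 0
  st <- init_fields(grid, rest_state_for(params, pf))
  s1 <- array(0, dims); s1[1:3, , 1] <- s1_amp
  xs2 <- round(grid$nx * x_break_frac)
  s2 <- array(0, dims)
  ys2 <- seq_len(floor(grid$ny / 2))
  if (mirror) ys2 <- grid$ny + 1L - ys2
  s2[1:xs2, ys2, 1] <- s2_amp
  ch <- function(state, n, stim = NULL, on = FALSE, probes = integer(0))
    step_chunk(state, pf, grid, params, dt, n, simcfg$E, stim, on, probes)
  r <- ch(st, round(stim_dur / dt), s1, TRUE)
  t <- stim_dur
  probe <- cell_index0(grid, xs2,
                       if (mirror) round(grid$ny * 0.25) else round(grid$ny * 0.75))
  fired <- FALSE
  repeat {
    r <- ch(r$state, round(2 / dt), probes = probe)
    t <- t + 2
    if (max(r$probe_V[, 1]) > -20) fired <- TRUE
    if (fired && r$probe_V[nrow(r$probe_V), 1] < v_s2) break
    if (t > 3000) stop("spiral initiation: no S2 window found")
  }
  t_s2 <- t
  r <- ch(r$state, round(stim_dur / dt), s2, TRUE)
  t <- t + stim_dur
  ## settle, recording the probe for the activation period
  n_settle <- max(1L, round(simcfg$duration / dt))
  r <- ch(r$state, n_settle, probes = probe)
  t <- t + simcfg$duration
  pv <- r$probe_V[, 1]
  up <- which(pv[-1] > -30 & pv[-length(pv)] <= -30)
  period <- if (length(up) >= 3) stats::median(diff(up)) * dt else NA_real_
  tp <- detect_tips(r$state$V[, , 1], r$state$f[, , 1], h = grid$h)
  list(state = r$state, tips = tp, ok = nrow(tp) == 1L, t_s2 = t_s2,
       period = period)
}

## rest state for the dominant alpha in the parameter fields (fall back to
## the steady-gate state at -84 mV when no stable rest exists)
rest_state_for <- function(params, pf) {
  a_med <- stats::median(pf$alpha)
  p <- brp_params(alpha = a_med, gNa_max = params$gNa_max,
                  gs_max = params$gs_max, k_K1_base = params$k_K1_base,
                  gNaC = params$gNaC, ENa = params$ENa)
  rs <- find_rest_state(p, t_relax = 5000)
  if (rs$converged) rs$state else as.numeric(cell_state(-84))
}

#' Plane-wave conduction velocity
#'
#' Launches a plane wave down a thin strip and times the upstroke
#' (V crossing -40 mV, linearly interpolated) at two planes away from the
#' ends.
#'
#' @param params a [brp_params()].
#' @param D uniform diffusivity (mm^2/ms).
#' @param grid optional [grid_spec()]; default a 200 x 3 strip.
#' @param dt time step (ms); default from the stability bound.
#' @param t_max maximum wait (ms).
#' @return list with `cv` (mm/ms, or NA), `cv_cells` (cells/ms),
#'   `propagated` (logical).
#' @export
measure_cv <- function(params, D, grid = grid_spec(200, 3, 1), dt = NULL,
                       t_max = 1500) {
  if (is.null(dt)) dt <- 0.5 * cfl_limit(grid, D)
  dt <- min(dt, 0.1)
  pf <- parameter_fields(grid, D_uniform = D, alpha_uniform = params$alpha)
  st <- init_fields(grid, rest_state_for(params, pf))
  dims <- grid_dims(grid)
  stim <- array(0, dims); stim[1:3, , 1] <- 40
  x1 <- round(grid$nx * 0.45); x2 <- round(grid$nx * 0.85)
  jmid <- max(1L, round(grid$ny / 2))
  probes <- c(cell_index0(grid, x1, jmid), cell_index0(grid, x2, jmid))
  r <- step_chunk(st, pf, grid, params, dt, round(2 / dt), 0, stim, TRUE,
                  probes)
  pv <- r$probe_V
  r <- step_chunk(r$state, pf, grid, params, dt, round(t_max / dt), 0,
                  probes = probes)
  pv <- rbind(pv, r$probe_V)
  cross <- apply(pv, 2, function(v) {
    i <- which(v[-1] > -40 & v[-length(v)] <= -40)[1]
    if (is.na(i)) return(NA_real_)
    (i + (-40 - v[i]) / (v[i + 1] - v[i])) * dt
  })
  if (any(is.na(cross)) || diff(cross) <= 0)
    return(list(cv = NA_real_, cv_cells = NA_real_, propagated = FALSE))
  cv <- (x2 - x1) * grid$h / diff(cross)
  list(cv = cv, cv_cells = cv / grid$h, propagated = TRUE)
}

#' Run a tissue simulation with online tip extraction
#'
#' Advances the state in chunks of `simcfg$sample_dt`, extracting tips
#' (2D) after every chunk, with optional moving border-zone profiles
#' re-evaluated per chunk.
#'
#' @param state initial field list.
#' @param grid a [grid_spec()].
#' @param params a [brp_params()].
#' @param simcfg a [sim_config()].
#' @param pf static [parameter_fields()]; alternatively supply `cfg`/`het`
#'   to rebuild moving profiles each chunk.
#' @param cfg optional [border_zone_config()] for a moving border.
#' @param het optional heterogeneity field.
#' @param t0 start time (ms) for the moving profiles.
#' @param V_iso,f_iso tip isoline values.
#' @param keep_fields if TRUE, return the final fields.
#' @return list with `tips` (list of per-sample tip tables), `times`,
#'   `tracks` (linked trajectories), `state` (final fields if requested).
#' @export
run_tissue <- function(state, grid, params, simcfg, pf = NULL, cfg = NULL,
                       het = NULL, t0 = 0, V_iso = -30, f_iso = 0.5,
                       keep_fields = TRUE) {
  moving <- is.null(pf)
  if (moving) stopifnot(!is.null(cfg))
  nchunk <- max(1L, round(simcfg$duration / simcfg$sample_dt))
  nstep <- max(1L, round(simcfg$sample_dt / simcfg$dt))
  tips <- vector("list", nchunk)
  times <- numeric(nchunk)
  t <- t0
  cur <- state
  for (s in seq_len(nchunk)) {
    pfs <- if (moving) parameter_fields(grid, cfg, het, t = t) else pf
    if (s == 1L) check_cfl(grid, pfs, simcfg)
    cur <- step_chunk(cur, pfs, grid, params, simcfg$dt, nstep,
                      simcfg$E)$state
    t <- t + nstep * simcfg$dt
    times[s] <- t
    tips[[s]] <- if (grid$nz == 1L)
      detect_tips(cur$V[, , 1], cur$f[, , 1], V_iso, f_iso, grid$h)
    else detect_tips(cur$V[, , ceiling(grid$nz / 2)],
                     cur$f[, , ceiling(grid$nz / 2)], V_iso, f_iso, grid$h)
  }
  tracks <- track_tips(tips, times)
  list(tips = tips, times = times, tracks = tracks,
       state = if (keep_fields) cur else NULL, t_end = t)
}
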