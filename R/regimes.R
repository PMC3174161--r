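## Activity-regime classification of an unstimulated heterogeneous network
## and the critical heterogeneity intensity nu_c(alpha) separating the
## quiescent and focal regimes, in 2D and thin 3D.

#' Classify the spontaneous activity regime of a network
#'
#' Runs the unstimulated network from rest and watches for self-generated
#' activity: the regime is `"focal"` if, after `settle_time`, some cell
#' crosses the upstroke threshold together with at least one of its
#' nearest neighbours (activity that spreads), `"quiescent"` otherwise.
#' Externally stimulated runs are outside this classification
#' (propagating-only activity is excluded by construction since no
#' stimulus is applied here).
#'
#' @param alpha mean excitability.
#' @param nu heterogeneity intensity.
#' @param D uniform diffusivity (mm^2/ms).
#' @param grid a [grid_spec()] (use `nz > 1` for thin-3D).
#' @param seed heterogeneity seed.
#' @param params a [brp_params()] template.
#' @param duration observation time (ms).
#' @param settle_time initial transient excluded from the verdict (ms).
#' @param v_up upstroke threshold (mV).
#' @param dt time step; default from the stability bound.
#' @return `"focal"` or `"quiescent"`.
#' @export
classify_regime <- function(alpha, nu, D, grid = grid_spec(30, 30, 1),
                            seed = 1L, params = brp_params(),
                            duration = 3000, settle_time = 500,
                            v_up = -30, dt = NULL) {
  if (is.null(dt)) dt <- min(0.1, 0.45 * grid$h^2 / (2 * grid$dim * max(D, 1e-12)))
  het <- sample_heterogeneity(grid, nu, seed)
  pf <- parameter_fields(grid, het = het, D_uniform = D,
                         alpha_uniform = alpha)
  p <- brp_params(alpha = alpha, gNa_max = params$gNa_max,
                  gs_max = params$gs_max, k_K1_base = params$k_K1_base,
                  gNaC = params$gNaC, ENa = params$ENa)
  ## start every cell from the rest state of the *mean* alpha cell; cells
  ## pushed into automaticity by their xi will depolarize on their own
  st <- init_fields(grid, rest_state_for(p, pf))
  chunk <- 25
  nstep <- max(1L, round(chunk / dt))
  t <- 0
  cur <- st
  while (t < duration) {
    cur <- step_chunk(cur, pf, grid, p, dt, nstep)$state
    t <- t + nstep * dt
    if (t <= settle_time) next
    if (max(cur$V) > v_up && spreads(cur$V, v_up, grid)) return("focal")
  }
  "quiescent"
}

## TRUE if some pair of nearest-neighbour cells is simultaneously above
## threshold
spreads <- function(V, v_up, grid) {
  A <- array(V, grid_dims(grid)) > v_up
  if (any(A[-1, , ] & A[-grid$nx, , ])) return(TRUE)
  if (any(A[, -1, ] & A[, -grid$ny, ])) return(TRUE)
  if (grid$nz > 1L && any(A[, , -1] & A[, , -grid$nz])) return(TRUE)
  FALSE
}

#' Critical heterogeneity intensity nu_c(alpha)
#'
#' For each alpha, bisects on nu between the two ends of `nu_bracket`,
#' deciding each probe by majority vote of [classify_regime()] over
#' `trials` independent heterogeneity seeds.  The bracket must straddle
#' the transition.
#'
#' @param alpha_list excitability values.
#' @param nu_bracket c(lo, hi) straddling the transition for every alpha.
#' @param D uniform diffusivity.
#' @param grid a [grid_spec()]; use `nz > 1` for the thin-3D curve.
#' @param trials odd number of heterogeneity realizations per probe.
#' @param seed base seed; trial seeds are `seed + (1:trials)`.
#' @param n_iter bisection iterations.
#' @param ... passed to [classify_regime()].
#' @return data.frame with `alpha`, `nu_c`, `nu_lo`, `nu_hi` (final
#'   bracket; the binomial uncertainty of the majority vote is one
#'   resolution step).
#' @export
transition_curve <- function(alpha_list, nu_bracket, D,
                             grid = grid_spec(30, 30, 1), trials = 3L,
                             seed = 1L, n_iter = 6L, ...) {
  trials <- as.integer(trials)
  if (trials %% 2L == 0L) trials <- trials + 1L
  vote <- function(alpha, nu) {
    lab <- vapply(seq_len(trials), function(k)
      classify_regime(alpha, nu, D, grid = grid, seed = seed + k, ...),
      character(1))
    sum(lab == "focal") > trials / 2
  }
  out <- NULL
  for (a in alpha_list) {
    lo <- nu_bracket[1]; hi <- nu_bracket[2]
    f_lo <- vote(a, lo); f_hi <- vote(a, hi)
    if (f_lo || !f_hi)
      stop(sprintf("nu bracket [%g, %g] does not straddle the transition at alpha = %g",
                   lo, hi, a))
    for (it in seq_len(n_iter)) {
      mid <- (lo + hi) / 2
      if (vote(a, mid)) hi <- mid else lo <- mid
    }
    out <- rbind(out, data.frame(alpha = a, nu_c = (lo + hi) / 2,
                                 nu_lo = lo, nu_hi = hi))
  }
  out
}
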