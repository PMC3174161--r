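## Beeler-Reuter-Pumir single-cell kinetics.
##
## The cell is the 1977 Beeler-Reuter ventricular myocyte with three
## neonatal modifications: the fast inward maximum permeability reduced to
## 60% of standard (2.4 vs 4), the slow inward to 50% (0.045 vs 0.09), and
## the inward rectifier i_K1 suppressed to a baseline fraction k_K1_base,
## scaled further by (1 - alpha) where alpha in [0, 1) is the excitability
## parameter.  High alpha removes so much rectifier that cells fire
## spontaneously (single-cell automaticity).
##
## State vector order used throughout: V, Ca, m, h, j, d, f, x1.

STATE_NAMES <- c("V", "Ca", "m", "h", "j", "d", "f", "x1")

#' Beeler-Reuter-Pumir cell parameters
#'
#' @param alpha excitability parameter in `[0, 1)`; scales the inward
#'   rectifier by `k_K1_base * (1 - alpha)`.  `alpha = 0` is the baseline
#'   neonatal cell; beyond roughly 0.65 (for the default `k_K1_base`) the
#'   isolated cell becomes automatic.
#' @param gNa_max fast inward maximum permeability (default 2.4, i.e. 60% of
#'   the adult Beeler-Reuter value 4).
#' @param gs_max slow inward maximum permeability (default 0.045, 50% of the
#'   adult value 0.09).
#' @param k_K1_base baseline neonatal suppression fraction of the inward
#'   rectifier, in (0, 1].
#' @param gNaC background sodium conductance.
#' @param ENa sodium reversal potential (mV).
#' @param stim_amp,stim_dur default stimulus amplitude (uA-equivalent,
#'   i.e. mV/ms with unit capacitance) and duration (ms).
#' @return an object of class `brp_params`.
#' @export
brp_params <- function(alpha = 0, gNa_max = 2.4, gs_max = 0.045,
                       k_K1_base = 0.5, gNaC = 0.003, ENa = 50,
                       stim_amp = 30, stim_dur = 2) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L)
  if (!is.finite(alpha) || alpha < 0 || alpha >= 1)
    stop("alpha must lie in [0, 1)")
  if (k_K1_base <= 0 || k_K1_base > 1)
    stop("k_K1_base must lie in (0, 1]")
  structure(list(alpha = alpha, gNa_max = gNa_max, gs_max = gs_max,
                 k_K1_base = k_K1_base, gNaC = gNaC, ENa = ENa,
                 stim_amp = stim_amp, stim_dur = stim_dur),
            class = "brp_params")
}

#' @export
print.brp_params <- function(x, ...) {
  cat("Beeler-Reuter-Pumir cell parameters\n")
  cat(sprintf("  alpha = %g, k_K1_base = %g  (i_K1 scale %.3g)\n",
              x$alpha, x$k_K1_base, x$k_K1_base * ik1_scale(x$alpha)))
  cat(sprintf("  gNa_max = %g, gs_max = %g, gNaC = %g, ENa = %g mV\n",
              x$gNa_max, x$gs_max, x$gNaC, x$ENa))
  invisible(x)
}

## flat parameter vector handed to the compiled kernels; alpha can be
## overridden per cell on the tissue side
param_vec <- function(params, alpha = params$alpha) {
  c(params$gNa_max, params$gNaC, params$ENa, params$gs_max,
    params$k_K1_base, alpha)
}

#' Excitability scaling of the inward rectifier
#'
#' Multiplier applied to the (already neonatally suppressed) inward
#' rectifier current: linear suppression `1 - alpha`.  It equals 1 at
#' `alpha = 0` and decreases monotonically towards 0 as `alpha` approaches 1.
#'
#' @param alpha excitability parameter(s) in `[0, 1)`; vectorized.  The
#'   value 1 is accepted as the (excluded) limit of the convention.
#' @return multiplier(s) in (0, 1].
#' @export
ik1_scale <- function(alpha) {
  if (!is.numeric(alpha) || any(!is.finite(alpha)) ||
      any(alpha < 0) || any(alpha > 1))
    stop("alpha must lie in [0, 1)")
  1 - alpha
}

#' Construct a cell state vector
#'
#' @param V membrane voltage (mV), in `[-120, 80]`.
#' @param Ca intracellular calcium (model units, > 0).
#' @param gates named or positional vector of the six gates
#'   (m, h, j, d, f, x1), each in `[0, 1]`; defaults to the steady-state
#'   values at `V`.
#' @return named numeric vector of length 8 with class `cell_state`.
#' @export
cell_state <- function(V = -84, Ca = 1.8e-7, gates = gate_inf(V)) {
  stopifnot(length(gates) == 6L)
  st <- c(V, Ca, unname(gates))
  names(st) <- STATE_NAMES
  validate_cell_state(st)
  structure(st, class = c("cell_state", "numeric"))
}

validate_cell_state <- function(st) {
  if (any(!is.finite(st))) stop("non-finite cell state")
  if (st[1] < -120 || st[1] > 80)
    stop("voltage outside [-120, 80] mV")
  if (st[2] <= 0) stop("Ca must be > 0")
  g <- st[3:8]
  if (any(g < 0) || any(g > 1)) stop("gates must lie in [0, 1]")
  invisible(st)
}

#' Hodgkin-Huxley rate coefficients of the six gates
#'
#' @param V voltage(s), mV.
#' @return matrix with one row per voltage and columns
#'   `alpha_m, beta_m, ..., alpha_x1, beta_x1`.
#' @export
gate_rates <- function(V) brp_rates_cpp(as.numeric(V))

#' Steady-state gate values `g_inf(V) = alpha_g / (alpha_g + beta_g)`
#'
#' @param V a single voltage (mV).
#' @return named vector of the six gate steady states (m, h, j, d, f, x1).
#' @export
gate_inf <- function(V) {
  r <- brp_rates_cpp(V)
  a <- r[1, seq(1, 11, by = 2)]
  b <- r[1, seq(2, 12, by = 2)]
  setNames(a / (a + b), c("m", "h", "j", "d", "f", "x1"))
}

#' Right-hand side of the single-cell model
#'
#' Time derivatives of all eight state variables: the voltage equation sums
#' the fast inward, slow inward, time-dependent outward and alpha-scaled
#' inward-rectifier currents plus any external current; gate derivatives are
#' `alpha_g(V) (1 - g) - beta_g(V) g`.
#'
#' @param state cell state vector (see [cell_state()]).
#' @param params [brp_params()] object.
#' @param I_ext external current density (mV/ms with unit capacitance).
#' @return named numeric vector of length 8 of time derivatives.
#' @export
cell_rhs <- function(state, params = brp_params(), I_ext = 0) {
  stopifnot(length(state) == 8L)
  if (any(!is.finite(state)) || !is.finite(I_ext))
    stop("non-finite input to cell_rhs")
  out <- cell_rhs_cpp(as.numeric(state), param_vec(params), I_ext)
  names(out) <- STATE_NAMES
  out
}

#' Advance a single cell in time
#'
#' Explicit update for V and Ca, exponential (Rush-Larsen) update for the
#' gates, so gates remain in `[0, 1]` for any `dt`.
#'
#' @param state cell state vector.
#' @param dt time step (ms), > 0.
#' @param params [brp_params()] object.
#' @param I_ext constant external current over the interval.
#' @param n number of steps to take.
#' @return the updated cell state.
#' @export
step_cell <- function(state, dt, params = brp_params(), I_ext = 0, n = 1L) {
  stopifnot(dt > 0, n >= 1)
  r <- cell_run_cpp(as.numeric(state), param_vec(params), dt, as.integer(n),
                    I_ext, 0, n * dt * (I_ext != 0), 0L)
  st <- r$state
  names(st) <- STATE_NAMES
  st
}

#' Simulate a single cell with an optional stimulus train
#'
#' @param params [brp_params()] object.
#' @param duration total time (ms).
#' @param dt time step (ms).
#' @param state initial state; defaults to the resting state (or the
#'   steady-gate state at -84 mV if no stable rest exists).
#' @param stim_times onset times (ms) of square stimulus pulses of amplitude
#'   `params$stim_amp` and duration `params$stim_dur`.
#' @param record_dt sampling interval of the returned trace (ms).
#' @return data.frame with columns `t`, `V`, `Ca`, and the six gates.
#' @export
simulate_cell <- function(params = brp_params(), duration = 1000, dt = 0.05,
                          state = NULL, stim_times = numeric(0),
                          record_dt = 1) {
  if (is.null(state)) {
    rs <- find_rest_state(params)
    state <- if (rs$converged) rs$state else cell_state(-84)
  }
  stride <- max(1L, round(record_dt / dt))
  edges <- sort(unique(c(0, stim_times, stim_times + params$stim_dur,
                         duration)))
  edges <- edges[edges >= 0 & edges <= duration]
  out <- NULL
  st <- as.numeric(state)
  for (i in seq_len(length(edges) - 1L)) {
    t0 <- edges[i]; t1 <- edges[i + 1L]
    n <- max(1L, round((t1 - t0) / dt))
    on <- any(stim_times <= t0 + 1e-9 & t0 < stim_times + params$stim_dur)
    amp <- if (on) params$stim_amp else 0
    r <- cell_run_cpp(st, param_vec(params), dt, n, amp, 0, if (on) n * dt else -1,
                      stride)
    tr <- r$trace
    tr[, 1] <- tr[, 1] + t0
    out <- rbind(out, if (i < length(edges) - 1L) tr[-nrow(tr), , drop = FALSE] else tr)
    st <- r$state
  }
  as.data.frame(out)
}

#' Find the resting state of a cell
#'
#' Relaxes the cell by long unstimulated integration, then polishes with
#' damped Newton iterations on the full right-hand side.  Cells above the
#' automaticity threshold (sustained voltage oscillations) are flagged as
#' having no stable rest state.
#'
#' @param params [brp_params()] object.
#' @param tol residual norm required for convergence.
#' @param t_relax relaxation time (ms) before Newton polishing.
#' @return list with elements `state` (the final state), `converged`
#'   (logical: residual norm < `tol` and non-oscillatory), `residual`
#'   (RHS norm), and `oscillatory` (logical).
#' @export
find_rest_state <- function(params = brp_params(), tol = 1e-8,
                            t_relax = 20000) {
  dt <- 0.05
  n <- round(t_relax / dt)
  r <- cell_run_cpp(as.numeric(cell_state(-84)), param_vec(params), dt, n,
                    0, -1, -1, max(1L, n %/% 2000))
  tr <- r$trace
  tailV <- tr[tr[, 1] > 0.7 * t_relax, "V"]
  oscillatory <- diff(range(tailV)) > 1
  st <- r$state
  res <- sqrt(sum(cell_rhs_cpp(st, param_vec(params), 0)^2))
  if (!oscillatory) {
    ## damped Newton with finite-difference Jacobian
    for (it in 1:50) {
      if (res < tol) break
      rhs <- cell_rhs_cpp(st, param_vec(params), 0)
      J <- matrix(0, 8, 8)
      for (k in 1:8) {
        e <- pmax(1e-8, abs(st[k]) * 1e-6)
        stp <- st; stp[k] <- stp[k] + e
        J[, k] <- (cell_rhs_cpp(stp, param_vec(params), 0) - rhs) / e
      }
      step <- tryCatch(solve(J, -rhs), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      repeat {
        stn <- st + lam * step
        ok <- stn[2] > 0 && all(stn[3:8] >= 0) && all(stn[3:8] <= 1) &&
          stn[1] > -120 && stn[1] < 80
        resn <- if (ok)
          sqrt(sum(cell_rhs_cpp(stn, param_vec(params), 0)^2)) else Inf
        if (resn < res || lam < 1e-4) break
        lam <- lam / 2
      }
      if (!is.finite(resn) || resn >= res) break
      st <- stn; res <- resn
    }
  }
  names(st) <- STATE_NAMES
  list(state = st, converged = (!oscillatory) && res < tol,
       residual = res, oscillatory = oscillatory)
}
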