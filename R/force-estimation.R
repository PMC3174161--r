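## Empirical estimation of the specific drift forces from direct
## simulations.  All forces are measured as drift velocities of a prepared
## spiral relative to an unperturbed control run started from the same
## state, which cancels the deterministic slow meander of the tip and
## isolates the linear response to the perturbation.
##
## Complex convention: real part = longitudinal component along +x (the
## perturbation direction), imaginary part = lateral component, positive
## counter-clockwise with respect to the perturbation direction.

#' Specific force object
#'
#' @param value complex force (longitudinal + i lateral) per unit
#'   perturbation.
#' @param se complex standard error.
#' @param convention character tag describing the sign convention.
#' @param details list of estimation metadata.
#' @return object of class `specific_force`.
#' @export
specific_force <- function(value, se, convention, details = list()) {
  stopifnot(is.complex(value) || is.numeric(value), Mod(se) > 0 || Mod(se) == 0)
  structure(list(value = as.complex(value), se = as.complex(se),
                 convention = convention, details = details),
            class = "specific_force")
}

#' @export
print.specific_force <- function(x, ...) {
  cat(sprintf("specific force: %.5g %+.5gi  (se %.2g + %.2gi)\n",
              Re(x$value), Im(x$value), Re(x$se), Im(x$se)))
  cat(" convention:", x$convention, "\n")
  invisible(x)
}

#' Prepare a settled spiral in a uniform medium
#'
#' Convenience wrapper: initiates by cross-field stimulation and settles.
#'
#' @param alpha background excitability.
#' @param D uniform diffusivity (mm^2/ms).
#' @param n box edge (cells).
#' @param h cell size (mm).
#' @param dt time step (ms); default near the stability bound.
#' @param settle settling time after S2 (ms).
#' @param chirality +1 or -1.
#' @param params optional [brp_params()] (its `alpha` is replaced).
#' @return list with `state`, `grid`, `params`, `pf`, `dt`, `tips`,
#'   `period`, `ok`.
#' @export
prepare_spiral <- function(alpha = 0.6, D = 0.0025, n = 120, h = 0.1,
                           dt = NULL, settle = 800, chirality = 1,
                           params = NULL) {
  g <- grid_spec(n, n, 1, h)
  if (is.null(dt)) dt <- min(0.1, 0.45 * h^2 / (4 * D))
  p <- if (is.null(params)) brp_params(alpha)
       else brp_params(alpha, params$gNa_max, params$gs_max,
                       params$k_K1_base, params$gNaC, params$ENa)
  pf <- parameter_fields(g, D_uniform = D, alpha_uniform = alpha)
  ini <- initiate_spiral(g, pf, p, sim_config(dt = dt, duration = settle),
                         chirality = chirality)
  list(state = ini$state, grid = g, params = p, pf = pf, dt = dt,
       tips = ini$tips, period = ini$period, ok = ini$ok)
}

## tip trajectory of a run; returns single-tip samples only
tip_trajectory <- function(state, pf, grid, params, dt, T, E = 0,
                           sample_dt = 5) {
  obs <- run_tissue(state, grid, params,
                    sim_config(dt = dt, duration = T, sample_dt = sample_dt,
                               E = E), pf = pf, keep_fields = FALSE)
  n1 <- vapply(obs$tips, nrow, 1L)
  sel <- which(n1 == 1)
  data.frame(t = obs$times[sel],
             x = vapply(obs$tips[sel], function(d) d$x, numeric(1)),
             y = vapply(obs$tips[sel], function(d) d$y, numeric(1)))
}

## drift velocity (cells/ms, complex) of a perturbed run relative to a
## control trajectory sharing its initial state; robust linear fit of the
## displacement difference against time
relative_drift <- function(trj, ref) {
  m <- merge(ref, trj, by = "t", suffixes = c("0", "1"))
  if (nrow(m) < 10) stop("too few matched tip samples for drift estimation")
  fx <- lm(I(x1 - x0) ~ t, data = m)
  fy <- lm(I(y1 - y0) ~ t, data = m)
  ## serial correlation: effective one independent sample per 10 samples
  infl <- sqrt(10)
  list(v = complex(real = coef(fx)[2], imaginary = coef(fy)[2]),
       se = complex(real = summary(fx)$coefficients[2, 2],
                    imaginary = summary(fy)$coefficients[2, 2]) * infl,
       n = nrow(m))
}

## complex least-squares slope through the origin of v against real g,
## with within-run ses propagated
slope_through_origin <- function(g, v, se) {
  s <- sum(g * v) / sum(g^2)
  resid <- v - s * g
  k <- length(g)
  se_fit <- if (k > 1) sqrt(sum(Mod(resid)^2) / (k - 1) / sum(g^2)) else 0
  se_prop <- sqrt(sum((g * Mod(se))^2)) / sum(g^2)
  list(slope = s, se = complex(real = 1, imaginary = 1) *
         max(se_fit, se_prop) / sqrt(2),
       resid_rel = if (sum(Mod(v)^2) > 0)
         sqrt(sum(Mod(resid)^2) / sum(Mod(v)^2)) else 0)
}

#' Electrophoretic (curvature-equivalent) specific force b2
#'
#' Measures the spiral drift velocity under the advection perturbation
#' `E dV/dx` for several small `E`, relative to an `E = 0` control, and
#' fits the complex slope of `v(E)` through the origin.  The
#' filament-motion coefficient is `B = -b2` (real part = filament tension,
#' imaginary part = binormal drift coefficient, up to the stated sign
#' conventions).
#'
#' @param spiral a [prepare_spiral()] result.
#' @param E_list advection magnitudes (mm/ms); small, ideally symmetric
#'   about 0.
#' @param T measurement window (ms).
#' @param nonlin_tol relative residual above which a nonlinearity warning
#'   is issued and the uncertainty widened.
#' @return a [specific_force()] with `details$B` (= -b2), `details$v`
#'   (per-E velocities, cells/ms), `details$resid_rel`.
#' @export
estimate_b2 <- function(spiral, E_list = c(-0.002, -0.001, 0.001, 0.002),
                        T = 1500, nonlin_tol = 0.25) {
  stopifnot(all(E_list != 0))
  g <- spiral$grid
  ref <- tip_trajectory(spiral$state, spiral$pf, g, spiral$params,
                        spiral$dt, T, E = 0)
  vs <- ses <- complex(length(E_list))
  for (i in seq_along(E_list)) {
    trj <- tip_trajectory(spiral$state, spiral$pf, g, spiral$params,
                          spiral$dt, T, E = E_list[i])
    rd <- relative_drift(trj, ref)
    vs[i] <- rd$v * g$h     # cells/ms -> mm/ms
    ses[i] <- rd$se * g$h
  }
  fit <- slope_through_origin(E_list, vs, ses)
  se <- fit$se
  if (fit$resid_rel > nonlin_tol) {
    warning(sprintf("v(E) relative residual %.2f exceeds %.2f: nonlinear regime",
                    fit$resid_rel, nonlin_tol))
    se <- se * 2
  }
  specific_force(fit$slope, se,
                 paste("b2: complex drift velocity per unit advection E;",
                       "Re = along +x, Im = counter-clockwise lateral"),
                 details = list(B = -fit$slope, E_list = E_list, v = vs,
                                v_se = ses, resid_rel = fit$resid_rel,
                                T = T))
}

#' Excitability-gradient specific force
#'
#' Imposes a shallow linear gradient of alpha along x on the prepared
#' spiral and measures the drift velocity relative to the uniform control,
#' for several gradient magnitudes; the complex slope per unit gradient is
#' the specific force.  Positive real part = drift towards higher alpha.
#'
#' @param spiral a [prepare_spiral()] result.
#' @param grad_list gradient magnitudes (alpha units per mm).
#' @param T measurement window (ms).
#' @return a [specific_force()].
#' @export
estimate_grad_alpha_force <- function(spiral,
                                      grad_list = c(-0.02, -0.01, 0.01, 0.02),
                                      T = 1500) {
  stopifnot(all(grad_list != 0))
  g <- spiral$grid
  a0 <- spiral$params$alpha
  x_mm <- axis_coord(g$nx, g$h)
  x0 <- if (nrow(spiral$tips)) (spiral$tips$x[1] - 0.5) * g$h else mean(x_mm)
  ref <- tip_trajectory(spiral$state, spiral$pf, g, spiral$params,
                        spiral$dt, T)
  vs <- ses <- complex(length(grad_list))
  for (i in seq_along(grad_list)) {
    amap <- pmin(1 - 1e-9, pmax(0, a0 + grad_list[i] * (x_mm - x0)))
    pf <- spiral$pf
    pf$alpha <- array(rep(amap, times = g$ny), grid_dims(g))
    trj <- tip_trajectory(spiral$state, pf, g, spiral$params, spiral$dt, T)
    if (nrow(trj) < 10 ||
        max(abs(trj$x - spiral$tips$x[1])) > 0.45 * g$nx)
      stop("spiral left the gradient window during measurement")
    rd <- relative_drift(trj, ref)
    vs[i] <- rd$v * g$h
    ses[i] <- rd$se * g$h
  }
  fit <- slope_through_origin(grad_list, vs, ses)
  specific_force(fit$slope, fit$se,
                 paste("excitability-gradient force: drift velocity (mm/ms)",
                       "per unit d(alpha)/dx (1/mm); Re > 0 = towards",
                       "higher alpha"),
                 details = list(grad_list = grad_list, v = vs, v_se = ses,
                                resid_rel = fit$resid_rel, T = T))
}

#' Interaction curve with a disk inhomogeneity
#'
#' For each distance `d`, a disk of radius `R0` and contrast `delta_alpha`
#' is placed at distance `d` from the settled spiral centre and the induced
#' drift velocity (relative to the unperturbed control) is resolved into
#' radial (positive = towards the disk centre) and azimuthal (positive =
#' clockwise around it) components, normalized by `delta_alpha`.
#'
#' @param spiral a [prepare_spiral()] result.
#' @param delta_alpha contrast of the probe disk.
#' @param R0 disk radius (mm).
#' @param d_list centre distances (mm).
#' @param T measurement window (ms).
#' @param direction unit-vector angle (radians) from the spiral centre to
#'   the disk centre.
#' @return a [force_curve()] with `details` attribute carrying per-distance
#'   velocities and uncertainties.
#' @export
estimate_inhomogeneity_curve <- function(spiral, delta_alpha = -0.05,
                                         R0 = 0.4, d_list = seq(0.5, 3, 0.5),
                                         T = 1000, direction = pi) {
  g <- spiral$grid
  stopifnot(nrow(spiral$tips) == 1)
  ctr <- c(spiral$tips$x_mm[1], spiral$tips$y_mm[1])
  xm <- axis_coord(g$nx, g$h); ym <- axis_coord(g$ny, g$h)
  ref <- tip_trajectory(spiral$state, spiral$pf, g, spiral$params,
                        spiral$dt, T)
  Fr <- Ft <- se_r <- se_t <- numeric(length(d_list))
  for (i in seq_along(d_list)) {
    cx <- ctr[1] + d_list[i] * cos(direction)
    cy <- ctr[2] + d_list[i] * sin(direction)
    dist2 <- outer(xm, ym, function(x, y) (x - cx)^2 + (y - cy)^2)
    pf <- spiral$pf
    da <- array(0, grid_dims(g))
    da[, , 1] <- ifelse(dist2 <= R0^2, delta_alpha, 0)
    pf$alpha <- pmin(1 - 1e-9, pmax(0, pf$alpha + da))
    trj <- tip_trajectory(spiral$state, pf, g, spiral$params, spiral$dt, T)
    rd <- relative_drift(trj, ref)
    v <- rd$v * g$h  # mm/ms, complex in (x, y)
    ## radial unit vector from spiral centre towards the disk centre
    e_r <- complex(real = cos(direction), imaginary = sin(direction))
    ## clockwise azimuthal unit vector w.r.t. the disk centre: at the
    ## spiral position (opposite side), clockwise = -i * (-e_r) = i e_r
    v_r <- Re(v * Conj(e_r))          # >0 = towards the disk
    v_t <- Re(v * Conj(1i * e_r))     # >0 = clockwise about the disk
    Fr[i] <- v_r / delta_alpha
    Ft[i] <- v_t / delta_alpha
    se_r[i] <- Mod(rd$se) * g$h / abs(delta_alpha)
    se_t[i] <- se_r[i]
  }
  fc <- force_curve(d_list, Fr, Ft, R0 = R0, delta_alpha = delta_alpha)
  attr(fc, "details") <- list(se_r = se_r, se_t = se_t, T = T,
                              direction = direction)
  fc
}
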