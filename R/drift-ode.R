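## Asymptotic motion model of a spiral centre: a constant gradient force of
## magnitude hg and direction gamma plus the distance-resolved interaction
## with a disk inhomogeneity of contrast delta_alpha, described by a
## sampled force curve (F_r(d), F_theta(d)).
##
## Conventions (stated on every public object): F_r > 0 drives the centre
## TOWARDS the inhomogeneity centre; F_theta > 0 drives it CLOCKWISE around
## the centre.  With R = r exp(i theta) the complex velocity is
##   dR/dt = hg exp(i gamma) - delta_alpha (F_r(r) + i F_theta(r)) exp(i theta)
## whose polar components are
##   dr/dt     = hg cos(gamma - theta) - delta_alpha F_r(r)
##   r dtheta/dt = hg sin(gamma - theta) - delta_alpha F_theta(r).

#' Sampled force curve of a disk inhomogeneity
#'
#' Distance-resolved specific force (per unit contrast delta_alpha) between
#' a spiral core and a disk inhomogeneity.  Interpolation between samples is
#' monotone cubic (Fritsch-Carlson); beyond the last sample the force is
#' taken to be zero (the response functions decay exponentially).
#'
#' @param d sampled distances (increasing, > 0).
#' @param F_r radial components (positive = towards the centre).
#' @param F_theta azimuthal components (positive = clockwise).
#' @param R0 disk radius of the probe (same length units as `d`).
#' @param delta_alpha contrast at which the curve was measured (metadata).
#' @return object of class `force_curve`; callable interpolators are in
#'   `$fr`, `$ftheta` (vectorized, zero outside `[min(d), max(d)]` above,
#'   clamped to the first sample below).
#' @export
force_curve <- function(d, F_r, F_theta = rep(0, length(d)), R0 = NA,
                        delta_alpha = NA) {
  stopifnot(length(d) >= 2, all(diff(d) > 0), length(F_r) == length(d),
            length(F_theta) == length(d))
  mk <- function(vals) {
    if (all(vals == 0)) return(function(r) rep(0, length(r)))
    sf <- splinefun(d, vals, method = "monoH.FC")
    dmin <- min(d); dmax <- max(d)
    function(r) {
      out <- sf(pmax(r, dmin))
      out[r > dmax] <- 0
      out
    }
  }
  structure(list(d = d, F_r = F_r, F_theta = F_theta,
                 fr = mk(F_r), ftheta = mk(F_theta),
                 R0 = R0, delta_alpha = delta_alpha,
                 convention = "F_r>0 toward centre; F_theta>0 clockwise"),
            class = "force_curve")
}

#' Asymptotic drift model
#'
#' @param curve a [force_curve()].
#' @param delta_alpha inhomogeneity contrast applied in the model.
#' @param hg magnitude of the constant gradient force (>= 0).
#' @param gamma direction of the gradient force (radians).
#' @return object of class `drift_model`.
#' @export
drift_model <- function(curve, delta_alpha, hg, gamma = 0) {
  stopifnot(inherits(curve, "force_curve"), hg >= 0)
  structure(list(curve = curve, delta_alpha = delta_alpha, hg = hg,
                 gamma = gamma), class = "drift_model")
}

#' Right-hand side of the drift ODE
#'
#' @param R complex centre position(s) relative to the inhomogeneity centre.
#' @param model a [drift_model()].
#' @return complex velocity, same length as `R`.
#' @export
drift_rhs <- function(R, model) {
  r <- Mod(R)
  if (any(r == 0)) stop("singular point: |R| = 0")
  Fg <- model$hg * exp(1i * model$gamma)
  Fr <- model$curve$fr(r)
  Ft <- model$curve$ftheta(r)
  Fg - model$delta_alpha * (Fr + 1i * Ft) * (R / r)
}

## polar form used for the Jacobian cross-check
drift_rhs_polar <- function(rtheta, model) {
  r <- rtheta[1]; th <- rtheta[2]
  Fr <- model$curve$fr(r); Ft <- model$curve$ftheta(r)
  c(model$hg * cos(model$gamma - th) - model$delta_alpha * Fr,
    (model$hg * sin(model$gamma - th) - model$delta_alpha * Ft) / r)
}

#' Tear-off threshold of the gradient force
#'
#' The critical magnitude above which no pinning equilibrium can exist:
#' `max_d |delta_alpha| sqrt(F_r^2 + F_theta^2)`.
#'
#' @param model a [drift_model()] (its `hg` is ignored).
#' @param n evaluation grid size over the sampled range.
#' @return critical force magnitude.
#' @export
tear_off_threshold <- function(model, n = 2001) {
  cv <- model$curve
  rg <- seq(min(cv$d), max(cv$d), length.out = n)
  max(abs(model$delta_alpha) * sqrt(cv$fr(rg)^2 + cv$ftheta(rg)^2))
}

#' Find pinning equilibria
#'
#' Radii solve `delta_alpha^2 (F_r^2 + F_theta^2)(r) = hg^2` (scan plus
#' bisection); the angle follows from the force balance
#' `exp(i theta) = hg exp(i gamma) / (delta_alpha (F_r + i F_theta))`.
#' Every returned equilibrium is verified to satisfy `|drift_rhs| <
#' 1e-10` of the force scale, and classified by [assess_stability()].
#'
#' @param model a [drift_model()].
#' @param n scan resolution in radius.
#' @return data.frame with columns `r`, `theta`, `stable` (logical, NA =
#'   marginal), `eig1`, `eig2` (complex eigenvalues of the planar
#'   linearization); zero rows if no equilibria.
#' @export
find_equilibria <- function(model, n = 2001) {
  cv <- model$curve
  rg <- seq(min(cv$d), max(cv$d), length.out = n)
  g <- model$delta_alpha^2 * (cv$fr(rg)^2 + cv$ftheta(rg)^2) - model$hg^2
  out <- NULL
  scale <- max(model$hg, tear_off_threshold(model), 1e-300)
  roots <- numeric(0)
  if (model$hg == 0) {
    ## equilibria where both components vanish simultaneously
    zr <- which(abs(cv$fr(rg)) + abs(cv$ftheta(rg)) == 0)
    if (length(zr)) roots <- rg[zr[1]]
  }
  sgn <- sign(g)
  idx <- which(sgn[-1] * sgn[-n] < 0)
  for (i in idx) {
    rt <- uniroot(function(r)
      model$delta_alpha^2 * (cv$fr(r)^2 + cv$ftheta(r)^2) - model$hg^2,
      c(rg[i], rg[i + 1]), tol = 1e-13)$root
    roots <- c(roots, rt)
  }
  ## exact tangency at grid points
  roots <- c(roots, rg[which(g == 0)])
  roots <- sort(unique(round(roots, 12)))
  for (rt in roots) {
    den <- model$delta_alpha * (cv$fr(rt) + 1i * cv$ftheta(rt))
    th <- if (Mod(den) == 0 && model$hg == 0) 0
          else Arg(model$hg * exp(1i * model$gamma) / den)
    Req <- rt * exp(1i * th)
    resid <- Mod(drift_rhs(Req, model))
    if (resid > 1e-10 * scale) next
    st <- assess_stability(model, rt, th)
    out <- rbind(out, data.frame(r = rt, theta = th, stable = st$stable,
                                 eig1 = st$eig[1], eig2 = st$eig[2]))
  }
  if (is.null(out))
    out <- data.frame(r = numeric(0), theta = numeric(0),
                      stable = logical(0), eig1 = complex(0), eig2 = complex(0))
  out
}

#' Linear stability of a pinning equilibrium
#'
#' Evaluates the two analytic stability conditions by local finite
#' differences of the force curve — an equilibrium at radius `r*` is stable
#' iff both `d/dr (F_r^2 + F_theta^2)` and `sign(delta_alpha) d/dr (r F_r)`
#' are positive at `r*` — and cross-checks the classification against the
#' eigenvalues of the numerical Jacobian of the planar system.  A
#' disagreement in a non-marginal case is an error.
#'
#' @param model a [drift_model()].
#' @param r,theta equilibrium position (verified by the caller).
#' @param eps relative finite-difference step.
#' @return list with `stable` (TRUE/FALSE, NA for marginal), `eig`
#'   (Jacobian eigenvalues), `cond1`, `cond2` (the two derivative
#'   conditions).
#' @export
assess_stability <- function(model, r, theta, eps = 1e-6) {
  cv <- model$curve
  dr <- max(r * eps, eps * diff(range(cv$d)))
  M2 <- function(x) cv$fr(x)^2 + cv$ftheta(x)^2
  cond1 <- (M2(r + dr) - M2(r - dr)) / (2 * dr)
  rfr <- function(x) x * cv$fr(x)
  cond2 <- sign(model$delta_alpha) * (rfr(r + dr) - rfr(r - dr)) / (2 * dr)
  analytic_stable <- cond1 > 0 && cond2 > 0
  ## numerical Jacobian of the polar planar system
  x0 <- c(r, theta)
  J <- matrix(0, 2, 2)
  hstep <- c(dr, 1e-6)
  for (k in 1:2) {
    xp <- x0; xp[k] <- xp[k] + hstep[k]
    xm <- x0; xm[k] <- xm[k] - hstep[k]
    J[, k] <- (drift_rhs_polar(xp, model) - drift_rhs_polar(xm, model)) /
      (2 * hstep[k])
  }
  eig <- eigen(J, only.values = TRUE)$values
  scale <- max(abs(eig), 1e-300)
  marginal <- any(abs(Re(eig)) < 1e-8 * scale) ||
    abs(cond1) < 1e-10 * max(abs(M2(r)), 1e-300) / max(r, 1e-300)
  jac_stable <- all(Re(eig) < 0)
  if (marginal)
    return(list(stable = NA, eig = eig, cond1 = cond1, cond2 = cond2))
  if (jac_stable != analytic_stable)
    stop(sprintf(paste0("stability disagreement at r = %g: analytic %s vs ",
                        "Jacobian %s"), r, analytic_stable, jac_stable))
  list(stable = jac_stable, eig = eig, cond1 = cond1, cond2 = cond2)
}

#' Integrate the drift ODE
#'
#' Adaptive Cash-Karp Runge-Kutta integration of the complex centre
#' position.  Events: convergence into an equilibrium (|velocity| below
#' `v_tol`) and escape beyond the sampled curve range (unbounded drift
#' under the constant force).
#'
#' @param model a [drift_model()].
#' @param R0 complex initial position.
#' @param T integration time.
#' @param tol local error tolerance.
#' @param v_tol equilibrium-event threshold on |velocity| (default
#'   `1e-6` of the force scale).
#' @return list with `t`, `R` (complex path), `event` (`"none"`,
#'   `"equilibrium"` or `"escape"`).
#' @export
integrate_drift <- function(model, R0, T, tol = 1e-9, v_tol = NULL) {
  scale <- max(model$hg, tear_off_threshold(model))
  if (is.null(v_tol)) v_tol <- 1e-6 * scale
  rmax <- max(model$curve$d)
  ## Cash-Karp coefficients
  a <- c(0, 1/5, 3/10, 3/5, 1, 7/8)
  b <- list(c(), c(1/5), c(3/40, 9/40), c(3/10, -9/10, 6/5),
            c(-11/54, 5/2, -70/27, 35/27),
            c(1631/55296, 175/512, 575/13824, 44275/110592, 253/4096))
  c5 <- c(37/378, 0, 250/621, 125/594, 0, 512/1771)
  c4 <- c(2825/27648, 0, 18575/48384, 13525/55296, 277/14336, 1/4)
  ## the origin is a coordinate singularity only; stop just if we land on it
  rmin <- 1e-9 * min(model$curve$d)
  t <- 0; R <- R0
  ts <- t; Rs <- R
  hstep <- min(T / 100, 1)
  event <- "none"
  while (t < T) {
    if (Mod(drift_rhs(R, model)) < v_tol) { event <- "equilibrium"; break }
    if (Mod(R) > rmax * 1.5 && model$hg > 0) { event <- "escape"; break }
    if (Mod(R) < rmin) { event <- "origin"; break }
    hstep <- min(hstep, T - t)
    k <- vector("complex", 6)
    ok <- FALSE
    for (trial in 1:60) {
      k[1] <- drift_rhs(R, model)
      bad <- FALSE
      for (s in 2:6) {
        Rt <- R + hstep * sum(b[[s]] * k[seq_len(s - 1)])
        if (Mod(Rt) < 1e-12) { bad <- TRUE; break }
        k[s] <- drift_rhs(Rt, model)
      }
      if (bad) { hstep <- hstep / 2; next }
      R5 <- R + hstep * sum(c5 * k)
      R4 <- R + hstep * sum(c4 * k)
      err <- Mod(R5 - R4)
      sc <- tol * max(1, Mod(R))
      if (err <= sc) {
        R <- R5; t <- t + hstep
        hstep <- hstep * min(5, max(0.2, 0.9 * (sc / max(err, 1e-300))^0.2))
        ok <- TRUE
        break
      }
      hstep <- hstep * max(0.1, 0.9 * (sc / err)^0.25)
      if (hstep < 1e-12 * T) stop("step-size collapse in integrate_drift")
    }
    if (!ok) stop("integrate_drift failed to take a step")
    ts <- c(ts, t); Rs <- c(Rs, R)
  }
  list(t = ts, R = Rs, event = event)
}

#' Superpose specific forces
#'
#' Weighted complex sum of specific forces sharing a sign convention.
#'
#' @param forces list of `list(magnitude =, force =)` pairs where `force`
#'   is a complex specific force (or a `specific_force` object).
#' @return complex net force.
#' @export
superpose <- function(forces) {
  conv <- NULL
  tot <- 0 + 0i
  for (f in forces) {
    val <- f$force
    if (inherits(val, "specific_force")) {
      if (!is.null(conv) && !identical(conv, val$convention))
        stop("mixed sign conventions in superpose()")
      conv <- val$convention
      val <- val$value
    }
    tot <- tot + f$magnitude * val
  }
  tot
}
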