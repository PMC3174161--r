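## Heterogeneous cell network: rectangular grid with nearest-neighbour Ohmic
## coupling, moving border-zone profiles of diffusivity D(y, t) and
## excitability alpha(y, t), and frozen per-cell Gaussian heterogeneity of
## alpha.

#' Grid specification
#'
#' @param nx,ny,nz cell counts along x, y, z (`nz = 1` for 2D); each >= 3
#'   except `nz` which may be 1.
#' @param h cell linear size (mm per cell).  All physical lengths are
#'   `h * cells`; results are reported in both units.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(nx, ny, nz = 1L, h = 0.1) {
  stopifnot(nx >= 3, ny >= 3, nz >= 1, h > 0)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 nz = as.integer(nz), h = h,
                 dim = if (nz > 1L) 3L else 2L),
            class = "grid_spec")
}

grid_dims <- function(grid) c(grid$nx, grid$ny, grid$nz)
n_cells <- function(grid) grid$nx * grid$ny * grid$nz

## cell-centre coordinates (mm) along one axis
axis_coord <- function(n, h) (seq_len(n) - 0.5) * h

#' Border-zone configuration
#'
#' Space-time profiles across the recovering ischaemic boundary.  Both
#' diffusivity and excitability ramp along y between the moving limits
#' `y1(t) = y1_0 + u t` and `y2(t) = y2_0 + u t` of the steepest part of the
#' gradient; the ramp translates rigidly with signed speed `u` (negative =
#' moving toward the bottom layer).
#'
#' @param D0 diffusivity of the well-coupled upper layer (mm^2/ms).
#' @param Dmin diffusivity of the bottom, uncoupled layer (>= 0).
#' @param alpha_top,alpha_bottom excitability limits above/below the ramp.
#' @param y1_0,y2_0 initial limits of the steepest part of the gradient
#'   (mm); `y2_0 > y1_0`.  The boundary width `y2_0 - y1_0` is constant.
#' @param u border speed along y (mm/ms, signed).
#' @param ramp ramp shape: `"linear"` (clamped piecewise-linear, default)
#'   or `"smooth"` (cubic smoothstep).
#' @param alpha_shift downward displacement (mm, >= 0) of the excitability
#'   ramp relative to the coupling ramp.  A positive shift makes
#'   excitability rise *below* the coupling gradient, creating the
#'   transitional band of high excitability and weak coupling (region III)
#'   where ectopic activity originates; with zero shift the two ramps
#'   coincide and no such band exists.
#' @return object of class `border_zone_config`.
#' @export
border_zone_config <- function(D0, Dmin = 0, alpha_top, alpha_bottom = 0,
                               y1_0, y2_0, u = 0, ramp = c("linear", "smooth"),
                               alpha_shift = 0) {
  ramp <- match.arg(ramp)
  stopifnot(y2_0 > y1_0, D0 >= Dmin, Dmin >= 0, alpha_shift >= 0)
  structure(list(D0 = D0, Dmin = Dmin, alpha_top = alpha_top,
                 alpha_bottom = alpha_bottom, y1_0 = y1_0, y2_0 = y2_0,
                 u = u, ramp = ramp, alpha_shift = alpha_shift),
            class = "border_zone_config")
}

ramp01 <- function(s, shape) {
  s <- pmin(1, pmax(0, s))
  if (shape == "smooth") s * s * (3 - 2 * s) else s
}

#' Diffusivity profile D(y, t)
#'
#' Equals `Dmin` below `y1(t)`, `D0` above `y2(t)`, with a monotone ramp in
#' between; the ramp translates at the border speed `u`.
#'
#' @param y coordinate(s) across the boundary (mm).
#' @param t time (ms).
#' @param cfg a [border_zone_config()].
#' @return diffusivity (mm^2/ms), vectorized over `y`.
#' @export
profile_D <- function(y, t, cfg) {
  s <- (y - (cfg$y1_0 + cfg$u * t)) / (cfg$y2_0 - cfg$y1_0)
  cfg$Dmin + (cfg$D0 - cfg$Dmin) * ramp01(s, cfg$ramp)
}

#' Excitability profile alpha(y, t)
#'
#' As [profile_D()] with limits `alpha_bottom` (below) and `alpha_top`
#' (above).
#'
#' @inheritParams profile_D
#' @return excitability, vectorized over `y`.
#' @export
profile_alpha <- function(y, t, cfg) {
  sh <- cfg$alpha_shift %||% 0
  s <- (y + sh - (cfg$y1_0 + cfg$u * t)) / (cfg$y2_0 - cfg$y1_0)
  cfg$alpha_bottom + (cfg$alpha_top - cfg$alpha_bottom) * ramp01(s, cfg$ramp)
}

#' Frozen Gaussian heterogeneity field
#'
#' Per-cell i.i.d. standard-normal deviates `xi`, frozen for the whole run;
#' the cell-level excitability is the macroscopic profile plus `nu * xi`.
#'
#' @param grid a [grid_spec()].
#' @param nu heterogeneity intensity (>= 0).
#' @param seed integer seed; the same seed reproduces `xi` exactly.
#' @return object of class `heterogeneity_field` with fields `xi`
#'   (array nx x ny x nz), `nu`, `seed`.
#' @export
sample_heterogeneity <- function(grid, nu, seed) {
  stopifnot(nu >= 0)
  xi <- withr_seed(seed, rnorm(n_cells(grid)))
  structure(list(xi = array(xi, grid_dims(grid)), nu = nu,
                 seed = as.integer(seed)),
            class = "heterogeneity_field")
}

## evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Per-cell parameter fields at a given time
#'
#' Evaluates the border-zone profiles at every cell centre and adds the
#' frozen heterogeneity to the excitability, clamping the result to
#' `[0, 1)`.  Heterogeneity applies to alpha only, not to D.
#'
#' @param grid a [grid_spec()].
#' @param cfg a [border_zone_config()], or `NULL` for uniform fields.
#' @param het a [sample_heterogeneity()] field, or `NULL` for none.
#' @param t time (ms) at which to evaluate the moving profiles.
#' @param D_uniform,alpha_uniform uniform values used when `cfg` is `NULL`.
#' @return object of class `parameter_fields` with arrays `D` and `alpha`
#'   (nx x ny x nz) plus the generating metadata.
#' @export
parameter_fields <- function(grid, cfg = NULL, het = NULL, t = 0,
                             D_uniform = NULL, alpha_uniform = NULL) {
  dims <- grid_dims(grid)
  if (is.null(cfg)) {
    stopifnot(!is.null(D_uniform), !is.null(alpha_uniform))
    D <- array(D_uniform, dims)
    a <- array(alpha_uniform, dims)
  } else {
    y <- axis_coord(grid$ny, grid$h)
    Dy <- profile_D(y, t, cfg)
    ay <- profile_alpha(y, t, cfg)
    D <- array(rep(Dy, each = grid$nx), dims)
    a <- array(rep(ay, each = grid$nx), dims)
  }
  if (!is.null(het) && het$nu > 0) a <- a + het$nu * het$xi
  a[] <- pmin(1 - 1e-9, pmax(0, a))
  structure(list(D = D, alpha = a, grid = grid, t = t,
                 cfg = cfg, het_seed = if (is.null(het)) NA_integer_ else het$seed,
                 nu = if (is.null(het)) 0 else het$nu),
            class = "parameter_fields")
}

#' Nearest-neighbour coupling operator
#'
#' Divergence-form inter-cellular current: for each cell,
#' `sum_j g_ij (V_j - V_i) / h^2` over the 4 (2D) or 6 (3D) nearest
#' neighbours, with interface conductance `g_ij = (D_i + D_j)/2` when both
#' diffusivities are positive and 0 otherwise (a `D = 0` cell is fully
#' isolated).  Outer boundaries are no-flux, so the grid sum of the result
#' vanishes for any input.
#'
#' @param V voltage array (nx x ny x nz, or a matrix for 2D).
#' @param fields a [parameter_fields()] object (its `D` is used).
#' @param grid a [grid_spec()]; defaults to the one in `fields`.
#' @return array of per-cell coupling currents (mV/ms).
#' @export
coupling_term <- function(V, fields, grid = fields$grid) {
  dims <- grid_dims(grid)
  V <- array(V, dims)
  D <- array(fields$D, dims)
  if (!all(dim(V) == dims)) stop("V does not match the grid")
  h2 <- grid$h^2
  out <- array(0, dims)
  shift <- function(A, ax, by) {
    ## shift array along axis ax by +1/-1, replicating nothing (NA pad)
    idx <- rep(list(quote(expr = )), 3)
    n <- dims[ax]
    src <- if (by > 0) c(NA_integer_, seq_len(n - 1)) else c(seq_len(n - 1) + 1L, NA_integer_)
    idx[[ax]] <- src
    A2 <- A[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    array(A2, dims)
  }
  axes <- if (grid$nz > 1L) 1:3 else 1:2
  for (ax in axes) {
    for (by in c(-1L, 1L)) {
      Dn <- shift(D, ax, by)
      Vn <- shift(V, ax, by)
      g <- ifelse(!is.na(Dn) & D > 0 & Dn > 0, (D + Dn) / 2, 0)
      dV <- Vn - V
      dV[is.na(dV)] <- 0
      out <- out + g * dV / h2
    }
  }
  out
}
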