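## Serialization: run configuration (JSON), tip/trajectory tables (CSV),
## force objects (JSON), and a legacy-VTK structured-points writer for 3D
## voltage snapshots.

#' Read a run configuration file
#'
#' Configurations are JSON with sections per module (`cell`, `grid`,
#' `border`, `sim`, `protocol`).  A bundled default encoding the package's
#' working point ships as `system.file("extdata", "paper-default.json",
#' package = "borderzone")`.
#'
#' @param path JSON file.
#' @return named list of sections.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  stopifnot(is.list(cfg))
  cfg
}

#' @rdname read_config
#' @param cfg configuration list.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

## config -> constructed objects
config_objects <- function(cfg) {
  cell <- cfg$cell %||% list()
  params <- do.call(brp_params, cell)
  g <- if (!is.null(cfg$grid)) do.call(grid_spec, cfg$grid) else NULL
  bz <- if (!is.null(cfg$border)) do.call(border_zone_config, cfg$border)
        else NULL
  sim <- if (!is.null(cfg$sim)) do.call(sim_config, cfg$sim) else sim_config()
  list(params = params, grid = g, border = bz, sim = sim,
       protocol = cfg$protocol %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a tip-track table as CSV
#'
#' Columns: `t_ms`, `x_mm`, `y_mm`, `x_cells`, `y_cells`, `chirality`,
#' `track_id`.
#'
#' @param tracks data.frame from [track_tips()] (positions in cell units).
#' @param path output CSV.
#' @param h cell size (mm).
#' @export
write_tracks_csv <- function(tracks, path, h = 0.1) {
  out <- data.frame(t_ms = tracks$t,
                    x_mm = (tracks$x - 0.5) * h,
                    y_mm = (tracks$y - 0.5) * h,
                    x_cells = tracks$x, y_cells = tracks$y,
                    chirality = tracks$chirality,
                    track_id = tracks$track)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a specific force or force curve as JSON
#'
#' @param x a `specific_force` or `force_curve` object.
#' @param path output file.
#' @export
write_force_json <- function(x, path) {
  if (inherits(x, "specific_force")) {
    obj <- list(kind = "specific_force",
                value = c(Re(x$value), Im(x$value)),
                se = c(Re(x$se), Im(x$se)),
                convention = x$convention)
  } else if (inherits(x, "force_curve")) {
    obj <- list(kind = "force_curve", d = x$d, F_r = x$F_r,
                F_theta = x$F_theta, R0 = x$R0,
                delta_alpha = x$delta_alpha, convention = x$convention)
  } else stop("unsupported object")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a 3D scalar field as legacy-VTK structured points
#'
#' ASCII legacy VTK, suitable for 3D visualization of voltage snapshots.
#'
#' @param A 3D array.
#' @param path output `.vtk` file.
#' @param name dataset name.
#' @param h grid spacing (mm).
#' @export
write_vtk_points <- function(A, path, name = "V", h = 0.1) {
  d <- dim(A)
  stopifnot(length(d) == 3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", name, "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g %g", h, h, h),
               sprintf("POINT_DATA %d", prod(d)),
               sprintf("SCALARS %s float 1", name),
               "LOOKUP_TABLE default"), con)
  writeLines(paste(format(as.vector(A), trim = TRUE)), con)
  invisible(path)
}

#' Save / restore a checkpoint of tissue state
#'
#' Plain-text checkpoint: one CSV of the eight state fields plus a JSON
#' sidecar with the grid and time.
#'
#' @param state field list.
#' @param grid a [grid_spec()].
#' @param t current time (ms).
#' @param path base path (writes `<path>.csv` and `<path>.json`).
#' @export
write_checkpoint <- function(state, grid, t, path) {
  df <- as.data.frame(lapply(state, as.vector))
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(nx = grid$nx, ny = grid$ny, nz = grid$nz,
                            h = grid$h, t = t),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_checkpoint
#' @return for `read_checkpoint`, a list with `state`, `grid`, `t`.
#' @export
read_checkpoint <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  df <- utils::read.csv(paste0(path, ".csv"))
  g <- grid_spec(meta$nx, meta$ny, meta$nz, meta$h)
  dims <- grid_dims(g)
  state <- setNames(lapply(FIELD_NAMES, function(nm) array(df[[nm]], dims)),
                    FIELD_NAMES)
  list(state = state, grid = g, t = meta$t)
}
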