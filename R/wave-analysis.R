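## Phase-singularity analysis.  The spiral tip at a given instant is defined
## as the intersection of two isolines, V = V_iso and f = f_iso, where f is
## the inactivation gate of the slow inward current; in 3D the same
## construction per voxel face yields scroll-filament crossings that are
## linked through voxels into polylines.

#' Detect spiral tips as isoline intersections
#'
#' For each grid square where both `V - V_iso` and `f - f_iso` change sign,
#' the bilinear interpolants of the two fields are intersected (Newton on
#' the 2x2 bilinear system).  Chirality is the sign of the cross product
#' `grad(V) x grad(f)` at the intersection.
#'
#' On fields that are linear in x and y the bilinear interpolant is exact,
#' so detected tips are exact to machine precision.
#'
#' @param V,f 2D numeric matrices on the same grid.
#' @param V_iso,f_iso isoline values.
#' @param h cell size (mm); positions are returned in mm and in cell units.
#' @return data.frame with columns `x`, `y` (cell units, 1-based grid
#'   coordinates), `x_mm`, `y_mm`, `chirality` (+1/-1).  Empty if none.
#' @export
detect_tips <- function(V, f, V_iso = -30, f_iso = 0.5, h = 0.1) {
  stopifnot(is.matrix(V), all(dim(V) == dim(f)))
  A <- V - V_iso; B <- f - f_iso
  nx <- nrow(A); ny <- ncol(A)
  a1 <- A[-nx, -ny]; a2 <- A[-1, -ny]; a3 <- A[-1, -1]; a4 <- A[-nx, -1]
  b1 <- B[-nx, -ny]; b2 <- B[-1, -ny]; b3 <- B[-1, -1]; b4 <- B[-nx, -1]
  candA <- pmin(a1, a2, a3, a4) <= 0 & pmax(a1, a2, a3, a4) >= 0
  candB <- pmin(b1, b2, b3, b4) <= 0 & pmax(b1, b2, b3, b4) >= 0
  cand <- which(candA & candB, arr.ind = TRUE)
  out <- NULL
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    ## bilinear coefficients on the unit square [0,1]^2
    fa <- c(A[i, j], A[i + 1, j] - A[i, j], A[i, j + 1] - A[i, j],
            A[i + 1, j + 1] - A[i + 1, j] - A[i, j + 1] + A[i, j])
    fb <- c(B[i, j], B[i + 1, j] - B[i, j], B[i, j + 1] - B[i, j],
            B[i + 1, j + 1] - B[i + 1, j] - B[i, j + 1] + B[i, j])
    uv <- c(0.5, 0.5)
    ok <- FALSE
    for (it in 1:30) {
      u <- uv[1]; v <- uv[2]
      F1 <- fa[1] + fa[2] * u + fa[3] * v + fa[4] * u * v
      F2 <- fb[1] + fb[2] * u + fb[3] * v + fb[4] * u * v
      j11 <- fa[2] + fa[4] * v; j12 <- fa[3] + fa[4] * u
      j21 <- fb[2] + fb[4] * v; j22 <- fb[3] + fb[4] * u
      detJ <- j11 * j22 - j12 * j21
      if (!is.finite(detJ) || abs(detJ) < 1e-14) break
      duv <- c(-(j22 * F1 - j12 * F2), -(-j21 * F1 + j11 * F2)) / detJ
      uv <- uv + pmax(pmin(duv, 0.75), -0.75)
      if (sqrt(sum(duv^2)) < 1e-12) { ok <- TRUE; break }
    }
    if (!ok) next
    u <- uv[1]; v <- uv[2]
    if (u < -0.02 || u > 1.02 || v < -0.02 || v > 1.02) next
    J <- matrix(c(fa[2] + fa[4] * v, fb[2] + fb[4] * v,
                  fa[3] + fa[4] * u, fb[3] + fb[4] * u), 2, 2)
    chir <- sign(J[1, 1] * J[2, 2] - J[2, 1] * J[1, 2])
    out <- rbind(out, c(i + u, j + v, chir))
  }
  if (is.null(out))
    return(data.frame(x = numeric(0), y = numeric(0), x_mm = numeric(0),
                      y_mm = numeric(0), chirality = numeric(0)))
  ## deduplicate near-identical solutions from adjacent candidate squares
  out <- out[!duplicated(round(out[, 1:2, drop = FALSE] * 4)), , drop = FALSE]
  data.frame(x = out[, 1], y = out[, 2],
             x_mm = (out[, 1] - 0.5) * h, y_mm = (out[, 2] - 0.5) * h,
             chirality = out[, 3])
}

#' Extract scroll-wave filaments from 3D fields
#'
#' Runs 2D tip detection on every voxel face (all three orientations);
#' crossings are linked through voxels sharing them into polylines.  Voxels
#' crossed by exactly two face points contribute a filament segment; chains
#' are traced into open or closed polylines.
#'
#' @param V,f 3D arrays on the same grid.
#' @param V_iso,f_iso isoline values.
#' @param h cell size (mm).
#' @return list of filaments; each is a list with `points` (n x 3 matrix,
#'   cell units), `closed` (logical), `length` (polyline arc length, cell
#'   units) and `length_mm`.
#' @export
extract_filaments <- function(V, f, V_iso = -30, f_iso = 0.5, h = 0.1) {
  stopifnot(length(dim(V)) == 3, all(dim(V) == dim(f)))
  d <- dim(V)
  pts <- NULL   # x, y, z (cell units)
  vox <- NULL   # voxel key of the two voxels sharing the face
  add_face <- function(tp, ax, slice) {
    ## tp: tips in face-plane coordinates (columns x,y of detect_tips)
    for (r in seq_len(nrow(tp))) {
      p3 <- switch(ax,
                   c(slice, tp$x[r], tp$y[r]),   # face normal to x
                   c(tp$x[r], slice, tp$y[r]),   # normal to y
                   c(tp$x[r], tp$y[r], slice))   # normal to z
      ## voxels on both sides of the face along the normal axis
      base <- floor(p3 - c(ax == 1, ax == 2, ax == 3) * 0.5)
      v1 <- p3; v1[ax] <- slice - 1
      v2 <- p3; v2[ax] <- slice
      key <- function(p) {
        ii <- pmin(pmax(c(floor(p3[1]), floor(p3[2]), floor(p3[3])), 1), d - 1)
        ii[ax] <- p[ax]
        paste(ii, collapse = ",")
      }
      k1 <- if (slice - 1 >= 1) key(v1) else NA
      k2 <- if (slice <= d[ax] - 1) key(v2) else NA
      pts <<- rbind(pts, p3)
      vox <<- rbind(vox, c(k1, k2))
    }
  }
  for (k in seq_len(d[3]))
    add_face(detect_tips(V[, , k], f[, , k], V_iso, f_iso, h), 3L, k)
  for (j in seq_len(d[2]))
    add_face(detect_tips(V[, j, ], f[, j, ], V_iso, f_iso, h), 2L, j)
  for (i in seq_len(d[1]))
    add_face(detect_tips(V[i, , ], f[i, , ], V_iso, f_iso, h), 1L, i)
  if (is.null(pts)) return(list())
  n <- nrow(pts)
  ## adjacency: two crossings are linked if they share a voxel
  vox_ids <- unique(na.omit(as.vector(vox)))
  adj <- vector("list", n)
  for (vk in vox_ids) {
    members <- which(vox[, 1] == vk | vox[, 2] == vk)
    if (length(members) == 2) {
      adj[[members[1]]] <- c(adj[[members[1]]], members[2])
      adj[[members[2]]] <- c(adj[[members[2]]], members[1])
    }
  }
  visited <- rep(FALSE, n)
  fils <- list()
  for (s in seq_len(n)) {
    if (visited[s]) next
    deg <- length(adj[[s]])
    if (deg > 1 && any(!visited[unlist(adj[[s]])])) {
      ## prefer starting from chain ends; handle later if loop
    }
    ## find a chain end reachable from s, else it's a loop
    start <- s
    repeat {
      nb <- setdiff(adj[[start]], NA)
      ends <- nb[!visited[nb]]
      if (length(adj[[start]]) <= 1) break
      ## walk to an end
      prev <- -1; cur <- start; steps <- 0
      repeat {
        nxt <- setdiff(adj[[cur]], prev)
        if (length(nxt) == 0 || steps > n) break
        prev <- cur; cur <- nxt[1]; steps <- steps + 1
        if (cur == start) break   # loop
      }
      start <- cur
      break
    }
    ## trace from start
    chain <- start; visited[start] <- TRUE
    prev <- -1; cur <- start
    closed <- FALSE
    repeat {
      nxt <- setdiff(adj[[cur]], prev)
      nxt <- nxt[!(nxt %in% chain[-1])]
      if (length(nxt) == 0) break
      if (nxt[1] == start) { closed <- TRUE; break }
      prev <- cur; cur <- nxt[1]
      chain <- c(chain, cur); visited[cur] <- TRUE
    }
    if (length(chain) < 2) { next }
    P <- pts[chain, , drop = FALSE]
    if (closed) P <- rbind(P, P[1, ])
    len <- sum(sqrt(rowSums(diff(P)^2)))
    fils[[length(fils) + 1]] <-
      list(points = P, closed = closed, length = len, length_mm = len * h)
  }
  fils
}

#' Link instantaneous tips into trajectories
#'
#' Nearest-neighbour association between consecutive samples with a maximum
#' jump per sampling interval; unmatched tips start new tracks.
#'
#' @param tip_list list of data.frames from [detect_tips()], one per sample.
#' @param times sample times (ms), same length.
#' @param max_jump maximum association distance (cell units) per interval.
#' @return data.frame with columns `track`, `t`, `x`, `y`, `chirality`.
#' @export
track_tips <- function(tip_list, times, max_jump = 2) {
  stopifnot(length(tip_list) == length(times))
  tracks <- data.frame(track = integer(0), t = numeric(0), x = numeric(0),
                       y = numeric(0), chirality = numeric(0))
  open_id <- integer(0); open_xy <- matrix(numeric(0), 0, 2)
  next_id <- 1L
  for (s in seq_along(tip_list)) {
    tp <- tip_list[[s]]
    assigned <- rep(NA_integer_, nrow(tp))
    if (nrow(tp) > 0 && length(open_id) > 0) {
      ## greedy minimal-distance matching
      dmat <- outer(seq_len(nrow(tp)), seq_along(open_id),
                    Vectorize(function(a, b)
                      sqrt((tp$x[a] - open_xy[b, 1])^2 +
                           (tp$y[a] - open_xy[b, 2])^2)))
      dmat <- matrix(dmat, nrow(tp), length(open_id))
      while (TRUE) {
        m <- which(dmat == min(dmat), arr.ind = TRUE)[1, , drop = FALSE]
        if (!is.finite(dmat[m]) || dmat[m] > max_jump) break
        assigned[m[1]] <- open_id[m[2]]
        dmat[m[1], ] <- Inf; dmat[, m[2]] <- Inf
        if (all(!is.finite(dmat))) break
      }
    }
    new_open_id <- integer(0); new_open_xy <- NULL
    for (r in seq_len(nrow(tp))) {
      id <- assigned[r]
      if (is.na(id)) { id <- next_id; next_id <- next_id + 1L }
      tracks <- rbind(tracks, data.frame(track = id, t = times[s],
                                         x = tp$x[r], y = tp$y[r],
                                         chirality = tp$chirality[r]))
      new_open_id <- c(new_open_id, id)
      new_open_xy <- rbind(new_open_xy, c(tp$x[r], tp$y[r]))
    }
    open_id <- new_open_id
    open_xy <- if (is.null(new_open_xy)) matrix(numeric(0), 0, 2) else new_open_xy
  }
  tracks
}

#' Rotation period and drift velocity of a tip trajectory
#'
#' The rotation period is estimated from the unwrapped angular phase of the
#' tip around a running centroid; the centre series is the sliding
#' one-period average of the tip position, and the drift velocity is the
#' complex slope of a linear regression of that series against time, with
#' uncertainty from the regression residuals.
#'
#' @param t,x,y tip samples (ms; cell units or mm — the velocity comes out
#'   in the same space units per ms).
#' @param min_periods minimum number of rotation periods required.
#' @return list with `period` (ms), `velocity` (complex, units of x per
#'   ms), `se` (complex standard error), `centre` (data.frame of the
#'   sliding centre series).
#' @export
drift_velocity <- function(t, x, y, min_periods = 5) {
  stopifnot(length(t) == length(x), length(x) == length(y))
  ord <- order(t); t <- t[ord]; x <- x[ord]; y <- y[ord]
  ## running centroid over a generous window for phase extraction
  cx <- stats::filter(x, rep(1 / 21, 21), sides = 2)
  cy <- stats::filter(y, rep(1 / 21, 21), sides = 2)
  cx[is.na(cx)] <- mean(x); cy[is.na(cy)] <- mean(y)
  ph <- atan2(y - as.numeric(cy), x - as.numeric(cx))
  dph <- diff(ph)
  dph <- dph - 2 * pi * round(dph / (2 * pi))
  total_angle <- abs(sum(dph))
  if (total_angle < 2 * pi * min_periods)
    stop(sprintf("trajectory spans %.1f rotations; need >= %d",
                 total_angle / (2 * pi), min_periods))
  period <- 2 * pi * (max(t) - min(t)) / total_angle
  ## sliding one-period averages
  ctr <- t(vapply(seq_along(t), function(i) {
    w <- which(t >= t[i] - period / 2 & t <= t[i] + period / 2)
    c(mean(t[w]), mean(x[w]), mean(y[w]))
  }, numeric(3)))
  ## keep interior points only (full window)
  keep <- ctr[, 1] >= min(t) + period / 2 & ctr[, 1] <= max(t) - period / 2
  ctr <- ctr[keep, , drop = FALSE]
  if (nrow(ctr) < 5) stop("too few interior centre samples")
  fx <- lm(ctr[, 2] ~ ctr[, 1]); fy <- lm(ctr[, 3] ~ ctr[, 1])
  v <- complex(real = coef(fx)[2], imaginary = coef(fy)[2])
  ## residuals of the centre series are serially correlated; scale the
  ## naive regression SE by an effective-sample-size factor of one sample
  ## per rotation period
  dt_s <- stats::median(diff(t))
  infl <- sqrt(max(1, period / dt_s))
  se <- complex(real = summary(fx)$coefficients[2, 2] * infl,
                imaginary = summary(fy)$coefficients[2, 2] * infl)
  list(period = period, velocity = v, se = se,
       centre = data.frame(t = ctr[, 1], x = ctr[, 2], y = ctr[, 3]))
}

#' Count persistent spirals after a given time
#'
#' A spiral is persistent if its tip track survives at least
#' `min_periods` rotation periods beyond `t_after`.
#'
#' @param tracks data.frame from [track_tips()].
#' @param t_after start of the counting window (ms).
#' @param period rotation period estimate (ms).
#' @param min_periods persistence requirement in periods (default 3).
#' @return integer count.
#' @export
count_spirals <- function(tracks, t_after, period, min_periods = 3) {
  if (nrow(tracks) == 0) return(0L)
  keep <- tracks$t >= t_after
  if (!any(keep)) return(0L)
  sp <- split(tracks$t[keep], tracks$track[keep])
  sum(vapply(sp, function(tt) diff(range(tt)) >= min_periods * period,
             logical(1)))
}
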