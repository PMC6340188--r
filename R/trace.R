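#' Velocity at arbitrary points and time
#'
#' Trilinear interpolation in space and linear interpolation in time with
#' periodic wrap: `t` is reduced modulo the cardiac period and the last
#' frame interpolates back to the first, so pathlines can run over several
#' cardiac cycles.
#'
#' @param field a [velocity_field()].
#' @param x n x 3 matrix (or 3-vector) of positions in mm; all points must
#'   lie inside the volume.
#' @param t time in ms (scalar).
#' @return n x 3 matrix of velocities in cm/s.
#' @export
velocity_at <- function(field, x, t) {
  stopifnot(inherits(field, "velocity_field"))
  x <- matrix(x, ncol = 3)
  v <- .velocity_at_safe(field, x, t)
  if (anyNA(v)) stopf("point outside the volume")
  v
}

# As velocity_at but NA rows for outside points (used by the integrator to
# detect exits without erroring).
.velocity_at_safe <- function(field, x, t) {
  nt <- dim(field$v)[5]
  dt_frame <- field$period / nt
  tau <- (t %% field$period) / dt_frame  # 0 .. nt
  f0 <- floor(tau) + 1
  wt <- tau - (f0 - 1)
  if (f0 > nt) { f0 <- 1; wt <- 0 }
  f1 <- if (f0 == nt) 1L else f0 + 1L
  out <- matrix(NA_real_, nrow(x), 3)
  for (k in 1:3) {
    a <- trilinear(field$v[, , , k, f0], x, field$spacing)
    b <- if (wt > 0) trilinear(field$v[, , , k, f1], x, field$spacing) else a
    out[, k] <- (1 - wt) * a + wt * b
  }
  out
}

#' Emit particle seeds from a plane
#'
#' Samples `n` points uniformly (seeded RNG) within the lumen mask of an
#' analysis plane: a lumen pixel is drawn uniformly, then the point is
#' jittered uniformly within the pixel.
#'
#' @param plane an [analysis_plane()] with a non-empty lumen.
#' @param n number of particles (>= 1).
#' @param frame release frame index (sets the release time).
#' @param seed integer RNG seed.
#' @param frame_times frame times of the target field in ms (frame 1 at 0 by
#'   default).
#' @return A data.frame with columns `x`, `y`, `z` (mm), `t0` (ms) and
#'   attribute `source` = plane vessel label.
#' @export
emit <- function(plane, n, frame = 1, seed = 1L, frame_times = NULL) {
  stopifnot(inherits(plane, "analysis_plane"))
  if (n < 1) stopf("n must be >= 1")
  sel <- which(plane$lumen)
  if (length(sel) == 0) stopf("empty lumen")
  b <- plane_basis(plane$normal)
  pts <- with_seed(seed, {
    pick <- sel[sample.int(length(sel), n, replace = TRUE)]
    ju <- stats::runif(n, -0.5, 0.5) * plane$pixel_size
    jw <- stats::runif(n, -0.5, 0.5) * plane$pixel_size
    plane$pixels[pick, , drop = FALSE] + outer(ju, b$e1) + outer(jw, b$e2)
  })
  t0 <- if (is.null(frame_times)) 0 else frame_times[frame]
  out <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3], t0 = t0)
  attr(out, "source") <- plane$vessel
  out
}

#' Integrate pathlines through the velocity field
#'
#' Classical 4th-order Runge-Kutta advection of massless particles through
#' the cardiac-periodic velocity field (1 cm/s = 0.01 mm/ms). A particle
#' terminates when it leaves the physical volume, when it enters the
#' zero-signal lumen exterior (if a lumen mask is supplied), or when it
#' reaches `duration` cardiac cycles. With `mode = "streamline"` the field
#' is frozen at the release time (steady streamlines instead of pathlines).
#'
#' @param field a [velocity_field()].
#' @param seeds data.frame from [emit()] (columns `x`, `y`, `z`, `t0`).
#' @param duration integration length in cardiac cycles (> 0).
#' @param dt time step in ms; default `period / (40 * n_frames)`.
#' @param lumen optional logical array; particles leaving it terminate.
#' @param mode `"pathline"` (time-varying field) or `"streamline"` (frozen).
#' @return A `pathline_set`: `times` (ms, common sample times), `positions`
#'   (steps x particles x 3), `speed` (steps x particles, cm/s),
#'   `termination` (factor per particle: `active`, `exited_volume`,
#'   `exited_lumen`, `max_time`), `source`.
#' @export
trace_pathlines <- function(field, seeds, duration = 2, dt = NULL,
                            lumen = NULL, mode = c("pathline", "streamline")) {
  stopifnot(inherits(field, "velocity_field"))
  mode <- match.arg(mode)
  if (duration <= 0) stopf("duration must be > 0")
  nt <- dim(field$v)[5]
  dt <- dt %||% (field$period / (40 * nt))
  if (dt <= 0) stopf("dt must be > 0")
  n <- nrow(seeds)
  t0 <- seeds$t0[1] %||% 0
  n_steps <- ceiling(duration * field$period / dt)
  pos <- matrix(c(seeds$x, seeds$y, seeds$z), n, 3)
  positions <- array(NA_real_, c(n_steps + 1, n, 3))
  speed <- matrix(NA_real_, n_steps + 1, n)
  positions[1, , ] <- pos
  active <- rep(TRUE, n)
  term <- rep("max_time", n)

  in_lumen <- function(p) {
    if (is.null(lumen)) return(rep(TRUE, nrow(p)))
    gs <- dim(lumen)
    ijk <- ceiling(sweep(p, 2, field$spacing, "/"))
    ok <- ijk[, 1] >= 1 & ijk[, 1] <= gs[1] & ijk[, 2] >= 1 &
      ijk[, 2] <= gs[2] & ijk[, 3] >= 1 & ijk[, 3] <= gs[3]
    ok[ok] <- lumen[ijk[ok, , drop = FALSE]]
    ok
  }

  vel <- function(p, t) {
    tt <- if (mode == "streamline") t0 else t
    .velocity_at_safe(field, p, tt)
  }
  v0 <- vel(pos, t0)
  speed[1, ] <- sqrt(rowSums(v0^2))

  t <- t0
  for (s in seq_len(n_steps)) {
    if (!any(active)) break
    p <- pos[active, , drop = FALSE]
    k1 <- vel(p, t)
    k2 <- vel(p + 0.5 * dt * 0.01 * k1, t + dt / 2)
    k3 <- vel(p + 0.5 * dt * 0.01 * k2, t + dt / 2)
    k4 <- vel(p + dt * 0.01 * k3, t + dt)
    step <- dt * 0.01 * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    bad <- is.na(step[, 1]) | is.na(step[, 2]) | is.na(step[, 3])
    newp <- p + ifelse(is.na(step), 0, step)
    # termination checks
    gs_mm <- dim(field$v)[1:3] * field$spacing
    outside <- bad | newp[, 1] < 0 | newp[, 1] > gs_mm[1] |
      newp[, 2] < 0 | newp[, 2] > gs_mm[2] |
      newp[, 3] < 0 | newp[, 3] > gs_mm[3]
    lum_ok <- rep(TRUE, nrow(newp))
    if (!is.null(lumen)) lum_ok[!outside] <-
      in_lumen(newp[!outside, , drop = FALSE])
    act_idx <- which(active)
    keep <- !outside & lum_ok
    term[act_idx[outside]] <- "exited_volume"
    term[act_idx[!outside & !lum_ok]] <- "exited_lumen"
    surv <- act_idx[keep]
    if (length(surv)) {
      pos[surv, ] <- newp[keep, , drop = FALSE]
      positions[s + 1, surv, ] <- newp[keep, , drop = FALSE]
      tt <- if (mode == "streamline") t0 else t + dt
      vs <- .velocity_at_safe(field, newp[keep, , drop = FALSE], tt)
      speed[s + 1, surv] <- sqrt(rowSums(vs^2))
    }
    active[act_idx[!keep]] <- FALSE
    t <- t + dt
  }
  structure(list(times = t0 + (0:n_steps) * dt, positions = positions,
                 speed = speed, termination = term,
                 source = attr(seeds, "source") %||% "", dt = dt,
                 duration = duration),
            class = "pathline_set")
}

#' @export
print.pathline_set <- function(x, ...) {
  cat(sprintf("<pathline_set> %d particles from '%s', %d samples, dt %.2f ms\n",
              dim(x$positions)[2], x$source, dim(x$positions)[1], x$dt))
  print(table(x$termination))
  invisible(x)
}

#' Source-to-sink streaming matrix
#'
#' Assigns each particle to the first sink region its trajectory enters
#' (first-entry semantics: a particle transiting several downstream
#' structures is credited to the first queried sink on its path). Sinks must
#' be pairwise disjoint; particles that never reach a sink count as
#' `unassigned`. Per source, fractions over sinks plus unassigned sum to 1.
#'
#' @param paths a [trace_pathlines()] result, or a list of them (one per
#'   source).
#' @param sinks named list of regions; each is `list(type = "box", min =,
#'   max =)` or `list(type = "sphere", center =, radius =)` in mm.
#' @return A `streaming_matrix`: `counts` and `fractions` matrices (source x
#'   sink, with an `unassigned` column), `n_emitted` per source.
#' @export
streaming_matrix <- function(paths, sinks) {
  if (inherits(paths, "pathline_set")) paths <- list(paths)
  if (is.null(names(sinks)) || any(names(sinks) == ""))
    stopf("sinks must be named")
  .inside <- function(region, p) {
    if (region$type == "box") {
      p[, 1] >= region$min[1] & p[, 1] <= region$max[1] &
        p[, 2] >= region$min[2] & p[, 2] <= region$max[2] &
        p[, 3] >= region$min[3] & p[, 3] <= region$max[3]
    } else if (region$type == "sphere") {
      rowSums(sweep(p, 2, region$center)^2) <= region$radius^2
    } else stopf("unknown sink type '%s'", region$type)
  }
  # disjointness check on a probe lattice covering all sink bounding boxes
  bounds <- lapply(sinks, function(r)
    if (r$type == "box") rbind(r$min, r$max)
    else rbind(r$center - r$radius, r$center + r$radius))
  lo <- do.call(pmin, lapply(bounds, function(b) b[1, ]))
  hi <- do.call(pmax, lapply(bounds, function(b) b[2, ]))
  probe <- as.matrix(expand.grid(
    seq(lo[1], hi[1], length.out = 25), seq(lo[2], hi[2], length.out = 25),
    seq(lo[3], hi[3], length.out = 25)))
  hits <- sapply(sinks, .inside, p = probe)
  if (any(rowSums(hits) > 1)) stopf("overlapping sinks")

  src_names <- vapply(paths, function(p) p$source, "")
  src_names[src_names == ""] <- paste0("source", seq_along(paths))[src_names == ""]
  counts <- matrix(0, length(paths), length(sinks) + 1,
                   dimnames = list(src_names, c(names(sinks), "unassigned")))
  for (i in seq_along(paths)) {
    pp <- paths[[i]]
    n <- dim(pp$positions)[2]
    assigned <- rep(NA_integer_, n)
    first_step <- rep(Inf, n)
    for (s in seq_along(sinks)) {
      for (p in seq_len(n)) {
        traj <- pp$positions[, p, ]
        ok <- !is.na(traj[, 1])
        if (!any(ok)) next
        ins <- .inside(sinks[[s]], traj[ok, , drop = FALSE])
        if (any(ins)) {
          step <- which(ok)[which(ins)[1]]
          if (step < first_step[p]) {
            first_step[p] <- step
            assigned[p] <- s
          }
        }
      }
    }
    for (s in seq_along(sinks))
      counts[i, s] <- sum(assigned == s, na.rm = TRUE)
    counts[i, length(sinks) + 1] <- sum(is.na(assigned))
  }
  fractions <- counts / rowSums(counts)
  structure(list(counts = counts, fractions = fractions,
                 n_emitted = rowSums(counts),
                 duration = paths[[1]]$duration),
            class = "streaming_matrix")
}

#' @export
print.streaming_matrix <- function(x, ...) {
  cat("<streaming_matrix> routing fractions (rows: sources)\n")
  print(round(x$fractions, 3))
  invisible(x)
}
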