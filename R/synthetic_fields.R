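# Analytic validation fields. These construct velocity_field objects
# directly (no network rasterization) with closed-form behaviour, for
# validating the interpolation, integration and streaming machinery.

#' Uniform steady velocity field
#'
#' Constant velocity everywhere; RK4 advection is exact on it.
#'
#' @param v 3-vector, cm/s.
#' @param grid_shape,spacing grid geometry.
#' @param period cardiac period in ms (the field is steady).
#' @param n_frames number of (identical) frames.
#' @return a [velocity_field()].
#' @export
make_uniform_field <- function(v, grid_shape = c(24, 24, 24), spacing = 1.5,
                               period = 100, n_frames = 2) {
  gs <- rep(grid_shape, length.out = 3)
  arr <- array(0, c(gs, 3, n_frames))
  for (k in 1:3) arr[, , , k, ] <- v[k]
  velocity_field(arr, spacing, (seq_len(n_frames) - 1) * period / n_frames,
                 period, provenance = list(source = "uniform"))
}

#' Rigid-rotation steady velocity field
#'
#' Solid-body rotation about a z-parallel axis: at radius r the speed is
#' `omega * r` (omega in rad/ms, r in mm, so speed in mm/ms = 100 cm/s ...
#' stored in cm/s). The field is linear in space, so trilinear interpolation
#' reproduces it exactly and integration error is attributable to the time
#' stepper alone — the canonical 4th-order convergence test.
#'
#' @param omega angular rate in rad/ms.
#' @param center rotation axis point (mm, x-y used).
#' @param grid_shape,spacing grid geometry.
#' @param period period in ms (steady field, used for time bookkeeping).
#' @param n_frames number of identical frames.
#' @return a [velocity_field()].
#' @export
make_rotation_field <- function(omega, center = NULL,
                                grid_shape = c(32, 32, 8), spacing = 1.5,
                                period = 1000, n_frames = 2) {
  gs <- rep(grid_shape, length.out = 3)
  sp <- rep(spacing, length.out = 3)
  center <- center %||% (gs * sp / 2)
  ctr <- voxel_centers(gs, sp)
  # mm/ms -> cm/s: 1 mm/ms = 100 cm/s
  vx <- array(-100 * omega * (ctr[, 2] - center[2]), gs)
  vy <- array(100 * omega * (ctr[, 1] - center[1]), gs)
  arr <- array(0, c(gs, 3, n_frames))
  for (f in seq_len(n_frames)) {
    arr[, , , 1, f] <- vx
    arr[, , , 2, f] <- vy
  }
  velocity_field(arr, sp, (seq_len(n_frames) - 1) * period / n_frames,
                 period, provenance = list(source = "rotation"))
}

# Plug-flow +z channel: square cross-section, constant axial speed.
.channel_mask <- function(gs, sp, center_xy, width) {
  ctr <- voxel_centers(gs, sp)
  array(abs(ctr[, 1] - center_xy[1]) <= width / 2 &
          abs(ctr[, 2] - center_xy[2]) <= width / 2, gs)
}

# Emission plane covering a square channel cross-section exactly: the pixel
# lattice plus jitter tiles the full channel width, so uniform-area emission
# equals uniform-flux emission under plug flow.
.channel_plane <- function(center_xy, width, z, vessel, pixel_size) {
  if (abs((width / pixel_size) %% 2 - 1) > 1e-9)
    stopf("width/pixel_size must be odd so pixels tile the channel exactly")
  half_px <- (width / pixel_size - 1) / 2
  p <- analysis_plane(c(center_xy, z), c(0, 0, 1), width / 2,
                      vessel = vessel, pixel_size = pixel_size)
  lim <- half_px * pixel_size + 1e-9
  lum <- matrix(abs(p$grid_u) <= lim, length(p$grid_u), length(p$grid_u))
  lum <- lum & matrix(abs(p$grid_u) <= lim, length(p$grid_u),
                      length(p$grid_u), byrow = TRUE)
  analysis_plane(c(center_xy, z), c(0, 0, 1), width / 2, vessel = vessel,
                 pixel_size = pixel_size, lumen = lum)
}

#' Streaming split phantom
#'
#' A plug-flow channel rising along +z that splits into two downstream
#' compartments at a plane `x = split_x`, positioned so that a fraction
#' `split_frac` of the channel flux (and, under plug flow, of uniformly
#' emitted particles) passes to the first sink. This emulates the
#' ductus-venosus stream preferentially supplying the foramen ovale, with a
#' known routing fraction as the oracle.
#'
#' @param split_frac flux fraction routed to the first sink (default 0.8).
#' @param speed plug axial speed, cm/s.
#' @param source,sink_names labels for the emitting vessel and the two
#'   sinks.
#' @param grid_shape,spacing grid geometry.
#' @return list: `field`, `plane` (emission plane), `sinks` (two disjoint
#'   boxes), `split_frac`.
#' @export
make_split_phantom <- function(split_frac = 0.8, speed = 20,
                               source = "DV", sink_names = c("FO", "RV"),
                               grid_shape = c(48, 48, 48), spacing = 1.5) {
  gs <- rep(grid_shape, length.out = 3)
  sp <- rep(spacing, length.out = 3)
  ext <- gs * sp
  width <- 17 * min(sp)  # odd pixel multiple at pixel_size = spacing
  ctr_xy <- ext[1:2] / 2
  zlo <- 4 * sp[3]; zhi <- ext[3] - 4 * sp[3]
  mask <- .channel_mask(gs, sp, ctr_xy, width)
  ctr <- voxel_centers(gs, sp)
  inz <- array(ctr[, 3] >= zlo & ctr[, 3] <= zhi, gs)
  arr <- array(0, c(gs, 3, 2))
  for (f in 1:2) arr[, , , 3, f] <- (mask & inz) * speed
  period <- 100
  field <- velocity_field(arr, sp, c(0, period / 2), period,
                          provenance = list(source = "split_phantom"))
  # Emit from the full-speed plug core (one voxel in from the channel wall,
  # clear of the trilinear edge ramp); the split plane is positioned so the
  # emitted stream - and under plug flow, its flux - divides split_frac /
  # (1 - split_frac) between the two compartments.
  emit_width <- width - 2 * min(sp)
  plane <- .channel_plane(ctr_xy, emit_width, zlo + 4 * sp[3], source,
                          min(sp))
  split_x <- ctr_xy[1] - emit_width / 2 + split_frac * emit_width
  z_sink <- c(zhi - 6 * sp[3], ext[3])
  sinks <- list(
    list(type = "box", min = c(ctr_xy[1] - width, ctr_xy[2] - width,
                               z_sink[1]),
         max = c(split_x, ctr_xy[2] + width, z_sink[2])),
    list(type = "box", min = c(split_x + 1e-9, ctr_xy[2] - width,
                               z_sink[1]),
         max = c(ctr_xy[1] + width, ctr_xy[2] + width, z_sink[2])))
  names(sinks) <- sink_names
  list(field = field, plane = plane, sinks = sinks, split_frac = split_frac)
}

#' Two-channel non-mixing phantom
#'
#' Two parallel, disjoint plug-flow channels with their own sources and
#' sinks; the streaming matrix must be exactly diagonal.
#'
#' @param speed plug axial speed, cm/s.
#' @param grid_shape,spacing grid geometry.
#' @return list: `field`, `planes` (two emission planes, labels `"A"`,
#'   `"B"`), `sinks` (boxes `"sink1"`, `"sink2"`).
#' @export
make_two_channel_phantom <- function(speed = 20, grid_shape = c(48, 48, 48),
                                     spacing = 1.5) {
  gs <- rep(grid_shape, length.out = 3)
  sp <- rep(spacing, length.out = 3)
  ext <- gs * sp
  width <- 9 * min(sp)
  cxa <- ext[1] * 0.28; cxb <- ext[1] * 0.72; cy <- ext[2] / 2
  zlo <- 4 * sp[3]; zhi <- ext[3] - 4 * sp[3]
  ctr <- voxel_centers(gs, sp)
  inz <- array(ctr[, 3] >= zlo & ctr[, 3] <= zhi, gs)
  maskA <- .channel_mask(gs, sp, c(cxa, cy), width)
  maskB <- .channel_mask(gs, sp, c(cxb, cy), width)
  arr <- array(0, c(gs, 3, 2))
  for (f in 1:2) arr[, , , 3, f] <- ((maskA | maskB) & inz) * speed
  field <- velocity_field(arr, sp, c(0, 50), 100,
                          provenance = list(source = "two_channel"))
  emit_width <- width - 2 * min(sp)
  planes <- list(.channel_plane(c(cxa, cy), emit_width, zlo + 4 * sp[3], "A",
                                min(sp)),
                 .channel_plane(c(cxb, cy), emit_width, zlo + 4 * sp[3], "B",
                                min(sp)))
  z_sink <- c(zhi - 6 * sp[3], ext[3])
  sinks <- list(
    sink1 = list(type = "box", min = c(cxa - width, cy - width, z_sink[1]),
                 max = c(cxa + width, cy + width, z_sink[2])),
    sink2 = list(type = "box", min = c(cxb - width, cy - width, z_sink[1]),
                 max = c(cxb + width, cy + width, z_sink[2])))
  list(field = field, planes = planes, sinks = sinks)
}
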