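#' Oriented analysis plane
#'
#' A square in-plane pixel grid centred on a vessel cross-section, with an
#' orientation normal, a lumen pixel mask and a pixel area. Through-plane
#' flow is integrated over the lumen pixels.
#'
#' @param center 3-vector, mm.
#' @param normal 3-vector (normalized internally).
#' @param radius plane half-width in mm (> 0); the default lumen mask is the
#'   inscribed disk.
#' @param vessel vessel label.
#' @param pixel_size in-plane pixel pitch in mm; by convention half the
#'   smallest voxel spacing of the field the plane will be applied to.
#' @param lumen optional logical matrix overriding the disk mask.
#' @return An object of class `analysis_plane` with fields `center`,
#'   `normal`, `radius`, `vessel`, `pixel_size`, `pixel_area`, `lumen`
#'   (logical matrix) and `pixels` (n x 3 matrix of pixel-centre world
#'   coordinates).
#' @export
analysis_plane <- function(center, normal, radius, vessel = "",
                           pixel_size = 0.75, lumen = NULL) {
  if (radius <= 0) stopf("radius must be > 0")
  if (pixel_size <= 0) stopf("pixel_size must be > 0")
  b <- plane_basis(normal)
  half <- ceiling(radius / pixel_size)
  u <- (seq(-half, half) ) * pixel_size
  g <- expand.grid(u = u, w = u)
  if (is.null(lumen)) {
    lumen <- matrix(g$u^2 + g$w^2 <= radius^2, length(u), length(u))
  } else {
    stopifnot(is.logical(lumen), all(dim(lumen) == c(length(u), length(u))))
  }
  pixels <- outer(g$u, b$e1) + outer(g$w, b$e2) +
    matrix(center, nrow(g), 3, byrow = TRUE)
  structure(list(center = center, normal = b$normal, radius = radius,
                 vessel = vessel, pixel_size = pixel_size,
                 pixel_area = pixel_size^2, lumen = lumen, pixels = pixels,
                 grid_u = u),
            class = "analysis_plane")
}

#' Plane through a network vessel
#'
#' Places an analysis plane at a fractional arc-length position along a
#' segment centerline, oriented along the local tangent, with radius equal
#' to the lumen radius plus a margin (so the partial-volume edge of the
#' rasterized vessel is captured).
#'
#' @param network a [network_spec()].
#' @param vessel vessel label.
#' @param at fractional position along the centerline in (0, 1).
#' @param margin extra plane radius in mm beyond the lumen radius.
#' @param pixel_size in-plane pixel pitch in mm.
#' @return An [analysis_plane()].
#' @export
plane_from_vessel <- function(network, vessel, at = 0.5, margin = 1.5,
                              pixel_size = 0.75) {
  seg <- network$segments[[vessel]]
  if (is.null(seg)) stopf("unknown segment '%s'", vessel)
  P <- seg$centerline
  lens <- sqrt(rowSums(diff(P)^2))
  cum <- c(0, cumsum(lens))
  target <- at * cum[length(cum)]
  p <- findInterval(target, cum, rightmost.closed = TRUE)
  p <- min(p, nrow(P) - 1)
  tloc <- (target - cum[p]) / lens[p]
  center <- P[p, ] + tloc * (P[p + 1, ] - P[p, ])
  tangent <- normalize(P[p + 1, ] - P[p, ])
  analysis_plane(center, tangent, seg$radius + margin, vessel = vessel,
                 pixel_size = pixel_size)
}

# Sample all plane pixels in the field at one frame; returns n x 3 velocity
# (NA outside the volume).
.sample_plane <- function(field, plane, frame) {
  sapply(1:3, function(k)
    trilinear(field$v[, , , k, frame], plane$pixels, field$spacing))
}

#' Align a plane normal with the local flow
#'
#' Iteratively replaces the plane normal with the direction of the
#' time-and-space mean velocity over the lumen pixels, re-sampling the plane
#' each iteration, until the normal rotates by less than `tol_deg` or
#' `max_iter` is reached. This mirrors adjusting a measurement contour until
#' velocity vectors are perpendicular to the cross-section.
#'
#' @param field a [velocity_field()].
#' @param plane an [analysis_plane()] intersecting the lumen.
#' @param max_iter maximum iterations.
#' @param tol_deg convergence tolerance on the normal rotation, degrees.
#' @return The aligned [analysis_plane()] (with `iterations` attribute).
#' @export
align_plane <- function(field, plane, max_iter = 10, tol_deg = 0.5) {
  stopifnot(inherits(field, "velocity_field"),
            inherits(plane, "analysis_plane"))
  nt <- dim(field$v)[5]
  for (it in seq_len(max_iter)) {
    vsum <- c(0, 0, 0)
    for (f in seq_len(nt)) {
      vm <- .sample_plane(field, plane, f)
      vm <- vm[plane$lumen & !is.na(vm[, 1]), , drop = FALSE]
      if (nrow(vm)) vsum <- vsum + colSums(vm)
    }
    if (vec_norm(vsum) < 1e-9)
      stopf("cannot orient plane: zero mean velocity in lumen")
    new_normal <- normalize(vsum)
    ang <- acos(pmin(pmax(sum(new_normal * plane$normal), -1), 1)) * 180 / pi
    plane <- analysis_plane(plane$center, new_normal, plane$radius,
                            vessel = plane$vessel,
                            pixel_size = plane$pixel_size)
    if (ang < tol_deg) break
  }
  attr(plane, "iterations") <- it
  plane
}

#' Through-plane flow waveform
#'
#' Integrates the through-plane velocity over the lumen pixels per cardiac
#' frame: `q = sum((v . normal) * pixel_area)`, trilinearly sampled at pixel
#' centres, in mL/s. Pixels falling outside the volume are excluded and
#' counted. The cycle mean (mL/min) and weight-indexed mean (mL/min per kg)
#' are attached.
#'
#' @param field a [velocity_field()].
#' @param plane an (aligned) [analysis_plane()] with a non-empty lumen mask.
#' @param weight fetal body mass in kg for flow indexing.
#' @return A `flow_waveform`: `q` (mL/s per frame), `frame_times`,
#'   `mean_flow` (mL/min), `indexed_flow` (mL/min/kg), `vessel`,
#'   `n_outside`.
#' @export
flow_waveform <- function(field, plane, weight = 1) {
  stopifnot(inherits(field, "velocity_field"),
            inherits(plane, "analysis_plane"))
  if (!any(plane$lumen)) stopf("empty lumen mask")
  nt <- dim(field$v)[5]
  q <- numeric(nt)
  n_outside <- 0L
  for (f in seq_len(nt)) {
    vm <- .sample_plane(field, plane, f)
    sel <- as.vector(plane$lumen)
    bad <- sel & is.na(vm[, 1])
    n_outside <- max(n_outside, sum(bad))
    sel <- sel & !is.na(vm[, 1])
    vn <- vm[sel, , drop = FALSE] %*% plane$normal
    # cm/s * mm^2 -> mL/s: 1 cm/s = 10 mm/s, 1 mL = 1000 mm^3
    q[f] <- sum(vn) * plane$pixel_area * 0.01
  }
  mean_flow <- mean(q) * 60
  structure(list(q = q, frame_times = field$frame_times,
                 period = field$period, mean_flow = mean_flow,
                 indexed_flow = mean_flow / weight, vessel = plane$vessel,
                 weight = weight, n_outside = n_outside),
            class = "flow_waveform")
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf("<flow_waveform> %s: mean %.2f mL/min (%.2f mL/min/kg)\n",
              x$vessel, x$mean_flow, x$indexed_flow))
  invisible(x)
}

#' Per-subject measurement table
#'
#' Collects indexed mean flows per vessel, derives combined pulmonary blood
#' flow (PBF = LPA + RPA) when both branches are present, the combined
#' ventricular output `CVO = 1.03 * (MPA + AAo)` (the factor accounts for
#' unmeasured coronary flow), and each vessel's share of CVO as an integer
#' percentage (rounded half away from zero).
#'
#' @param waveforms list of [flow_waveform()]s with distinct vessel labels,
#'   or a named numeric vector of indexed flows (mL/min per kg).
#' @param weight fetal body mass in kg.
#' @param cvo optional externally fixed CVO (mL/min per kg); by default
#'   computed from MPA and AAo (undefined if either is missing).
#' @return A `measurement_table` with `flows`, `weight`, `cvo`, `pct_cvo`.
#' @export
build_table <- function(waveforms, weight = 1, cvo = NULL) {
  if (is.numeric(waveforms)) {
    flows <- waveforms
    if (is.null(names(flows))) stopf("flows must be named by vessel")
  } else {
    vessels <- vapply(waveforms, function(w) w$vessel, "")
    if (anyDuplicated(vessels)) stopf("duplicate vessel labels")
    flows <- stats::setNames(vapply(waveforms, function(w) w$indexed_flow, 0),
                             vessels)
  }
  if (anyDuplicated(names(flows))) stopf("duplicate vessel labels")
  if (all(c("LPA", "RPA") %in% names(flows)) && !("PBF" %in% names(flows)))
    flows[["PBF"]] <- flows[["LPA"]] + flows[["RPA"]]
  if (is.null(cvo)) {
    cvo <- if (all(c("MPA", "AAo") %in% names(flows)))
      1.03 * (flows[["MPA"]] + flows[["AAo"]]) else NA_real_
  }
  pct <- if (is.finite(cvo))
    stats::setNames(as.integer(round_half_away(100 * flows / cvo)),
                    names(flows))
  else stats::setNames(integer(0), character(0))
  structure(list(flows = flows, weight = weight, cvo = cvo, pct_cvo = pct),
            class = "measurement_table")
}

#' @export
print.measurement_table <- function(x, ...) {
  cat(sprintf("<measurement_table> weight %.2f kg, CVO %s mL/min/kg\n",
              x$weight, if (is.finite(x$cvo)) sprintf("%.1f", x$cvo) else "NA"))
  df <- data.frame(vessel = names(x$flows),
                   indexed_flow = round(unname(x$flows), 1))
  if (length(x$pct_cvo)) df$pct_cvo <- unname(x$pct_cvo[df$vessel])
  print(df, row.names = FALSE)
  invisible(x)
}

#' Conservation-of-mass junction check
#'
#' Compares total measured flow entering and leaving a junction. The percent
#' difference uses the mean of the two sides as denominator by default
#' (symmetric and bounded); `denominator = "inflow"` is available. If any
#' named vessel is absent from the table the check is skipped with a
#' recorded reason rather than failing.
#'
#' @param table a [build_table()] result.
#' @param inflows,outflows vessel labels.
#' @param name label for the junction.
#' @param denominator `"mean"` or `"inflow"`.
#' @return A `junction_check`: `name`, `inflows`, `outflows`, `pct_diff`,
#'   `skipped`, `reason`.
#' @export
junction_check <- function(table, inflows, outflows, name = NULL,
                           denominator = c("mean", "inflow")) {
  stopifnot(inherits(table, "measurement_table"))
  denominator <- match.arg(denominator)
  name <- name %||% paste(paste(inflows, collapse = "+"), "=",
                          paste(outflows, collapse = "+"))
  missing <- setdiff(c(inflows, outflows), names(table$flows))
  if (length(missing)) {
    return(structure(list(name = name, inflows = inflows, outflows = outflows,
                          pct_diff = NA_real_, skipped = TRUE,
                          reason = paste("vessel(s) not measured:",
                                         paste(missing, collapse = ", "))),
                     class = "junction_check"))
  }
  qin <- sum(table$flows[inflows])
  qout <- sum(table$flows[outflows])
  den <- if (denominator == "mean") (qin + qout) / 2 else qin
  structure(list(name = name, inflows = inflows, outflows = outflows,
                 qin = qin, qout = qout,
                 pct_diff = 100 * abs(qin - qout) / den, skipped = FALSE,
                 reason = NULL),
            class = "junction_check")
}

#' The four standard fetal conservation checks
#'
#' IVCp vs RHV + DV + IVCd; SVC + IVCp vs MPA + FO; MPA vs DA + PBF; and
#' IVCp vs DAo.
#'
#' @param table a [build_table()] result.
#' @param denominator passed to [junction_check()].
#' @return list of `junction_check`s.
#' @export
default_junction_checks <- function(table, denominator = "mean") {
  list(
    junction_check(table, c("RHV", "DV", "IVCd"), "IVCp",
                   name = "IVCp = RHV + DV + IVCd", denominator = denominator),
    junction_check(table, c("SVC", "IVCp"), c("MPA", "FO"),
                   name = "SVC + IVCp = MPA + FO", denominator = denominator),
    junction_check(table, "MPA", c("DA", "PBF"),
                   name = "MPA = DA + PBF", denominator = denominator),
    junction_check(table, "IVCp", "DAo",
                   name = "IVCp = DAo", denominator = denominator))
}

#' Summarize junction consistency
#'
#' Arithmetic mean and sample standard deviation of the percent differences
#' over all (non-skipped) checks.
#'
#' @param checks list of [junction_check()]s.
#' @return list with `mean`, `sd`, `n`, `n1` (TRUE when only one check, in
#'   which case `sd` is reported as 0).
#' @export
consistency_summary <- function(checks) {
  if (inherits(checks, "junction_check")) checks <- list(checks)
  pd <- vapply(checks, function(c) c$pct_diff, 0)
  pd <- pd[!is.na(pd)]
  if (length(pd) == 0) stopf("no usable junction checks")
  list(mean = mean(pd),
       sd = if (length(pd) > 1) stats::sd(pd) else 0,
       n = length(pd), n1 = length(pd) == 1)
}

#' Method comparison: regression, Bland-Altman and paired t-test
#'
#' Ordinary least-squares regression of method A on method B (with a
#' normal-theory 95% confidence interval on the slope), the coefficient of
#' determination, Bland-Altman bias (mean of A - B) with 1.96 SD limits of
#' agreement, and a two-sided paired t-test.
#'
#' @param flow_a,flow_b paired measurements (e.g. volumetric 4D flow vs 2D
#'   planar flow), mL/min per kg; or a 2-column matrix/data.frame as
#'   `flow_a`.
#' @return A `method_comparison`: `slope`, `slope_ci`, `intercept`, `r2`,
#'   `bias`, `loa_low`, `loa_high`, `p`, `n`, `t_undefined`.
#' @export
compare_methods <- function(flow_a, flow_b = NULL) {
  if (is.null(flow_b)) {
    m <- as.matrix(flow_a)
    stopifnot(ncol(m) == 2)
    flow_a <- m[, 1]; flow_b <- m[, 2]
  }
  n <- length(flow_a)
  if (length(flow_b) != n) stopf("paired inputs must have equal length")
  if (n < 3) stopf("need at least 3 pairs")
  fit <- stats::lm(flow_a ~ flow_b)
  # identity pairs are a legitimate degenerate input (self-comparison);
  # silence the perfect-fit note from the normal-theory summary
  withCallingHandlers({
    ci <- tryCatch(stats::confint(fit, "flow_b", level = 0.95),
                   error = function(e) c(NA_real_, NA_real_))
    r2 <- summary(fit)$r.squared
  }, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  d <- flow_a - flow_b
  bias <- mean(d)
  sdd <- stats::sd(d)
  t_undefined <- sdd == 0
  p <- if (t_undefined) NA_real_ else
    stats::t.test(flow_a, flow_b, paired = TRUE)$p.value
  structure(list(slope = unname(stats::coef(fit)[2]),
                 slope_ci = as.numeric(ci),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2,
                 bias = bias, sd_diff = sdd,
                 loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
                 p = p, n = n, t_undefined = t_undefined),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("<method_comparison> n=%d  slope %.3f [%.3f, %.3f]  R2 %.3f\n",
           "  bias %.2f (LoA [%.2f, %.2f])  p %s\n"),
    x$n, x$slope, x$slope_ci[1], x$slope_ci[2], x$r2, x$bias, x$loa_low,
    x$loa_high, if (is.na(x$p)) "undefined (zero-variance differences)"
    else format.pval(x$p, digits = 3)))
  invisible(x)
}

#' Voxels per vessel diameter
#'
#' Converts a cross-sectional area (assumed circular) and a voxel size into
#' the number of voxels spanned by the vessel diameter — the standard check
#' that a vessel is resolved well enough for flow quantification (~3
#' voxels per diameter).
#'
#' @param area cross-sectional area, mm^2 (> 0; 0 allowed as a limit).
#' @param voxel voxel edge length, mm (> 0).
#' @return `2 * sqrt(area / pi) / voxel`.
#' @examples
#' voxels_per_diameter(21.5, 1.5)  # ~3.5, the smallest branch at 1.5 mm
#' @export
voxels_per_diameter <- function(area, voxel) {
  if (any(area < 0)) stopf("area must be >= 0")
  if (any(voxel <= 0)) stopf("voxel must be > 0")
  2 * sqrt(area / pi) / voxel
}
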