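#' Vessel segment
#'
#' One vessel of the network: a polyline centerline (mm), a lumen radius
#' (mm), and the flow waveform carried along the centerline direction
#' (positive flow runs from the first to the last centerline point).
#'
#' @param name vessel label, e.g. `"MPA"`, `"DV"`.
#' @param centerline numeric matrix (>= 2 rows, 3 columns) of ordered 3D
#'   points in mm; consecutive points must be distinct.
#' @param radius lumen radius in mm (> 0).
#' @param waveform a [waveform_spec()].
#' @return An object of class `vessel_segment`.
#' @export
vessel_segment <- function(name, centerline, radius, waveform) {
  centerline <- as.matrix(centerline)
  if (!is.character(name) || length(name) != 1) stopf("name must be a string")
  if (ncol(centerline) != 3 || nrow(centerline) < 2)
    stopf("centerline must be an n x 3 matrix with n >= 2 (segment '%s')", name)
  steps <- diff(centerline)
  if (any(rowSums(steps^2) == 0))
    stopf("consecutive centerline points must be distinct (segment '%s')", name)
  if (!is.numeric(radius) || radius <= 0) stopf("radius must be > 0 mm")
  stopifnot(inherits(waveform, "waveform_spec"))
  structure(list(name = name, centerline = centerline, radius = radius,
                 waveform = waveform),
            class = "vessel_segment")
}

#' Fetal vessel network
#'
#' A set of vessel segments plus the junctions at which conservation of mass
#' is asserted. The constructor checks that at every junction the summed
#' inflow mean flows match the summed outflow mean flows within `tol`
#' (relative); with `renormalize = TRUE` unbalanced junctions are repaired by
#' scaling their outflow waveforms by the common factor needed to balance.
#'
#' @param segments list of [vessel_segment()]s with distinct names.
#' @param junctions list of junctions, each `list(name =, inflows = c(...),
#'   outflows = c(...))` referencing segment names.
#' @param weight fetal body mass in kg (used to index flows).
#' @param tol relative imbalance tolerated at each junction (default 0.1%).
#' @param renormalize repair unbalanced junctions by rescaling outflows.
#' @return An object of class `flow_network`.
#' @export
network_spec <- function(segments, junctions = list(), weight = 1,
                         tol = 1e-3, renormalize = FALSE) {
  nms <- vapply(segments, function(s) s$name, "")
  if (anyDuplicated(nms)) stopf("duplicate segment names")
  names(segments) <- nms
  if (!is.numeric(weight) || weight <= 0) stopf("weight must be > 0 kg")
  for (j in junctions) {
    unknown <- setdiff(c(j$inflows, j$outflows), nms)
    if (length(unknown))
      stopf("junction '%s' references unknown segment(s): %s",
            j$name %||% "?", paste(unknown, collapse = ", "))
  }
  mean_of <- function(v) segments[[v]]$waveform$mean_flow
  if (renormalize) {
    for (j in junctions) {
      qin <- sum(vapply(j$inflows, mean_of, 0))
      qout <- sum(vapply(j$outflows, mean_of, 0))
      if (qout > 0 && abs(qin - qout) / max(qin, qout) > tol) {
        fac <- qin / qout
        for (v in j$outflows) {
          w <- segments[[v]]$waveform
          segments[[v]]$waveform <- waveform_spec(
            w$kind, w$period, w$mean_flow * fac, peak_frac = w$peak_frac,
            peak_to_mean = w$peak_to_mean,
            second_peak_ratio = w$second_peak_ratio,
            phase_shift = w$phase_shift)
        }
      }
    }
  }
  for (j in junctions) {
    qin <- sum(vapply(j$inflows, mean_of, 0))
    qout <- sum(vapply(j$outflows, mean_of, 0))
    if (max(qin, qout) > 0 && abs(qin - qout) / max(qin, qout) > tol)
      stopf("junction '%s' unbalanced: inflow %.2f vs outflow %.2f mL/min",
            j$name %||% "?", qin, qout)
  }
  structure(list(segments = segments, junctions = junctions, weight = weight),
            class = "flow_network")
}

# Indexed mean flows (mL/min per kg) used by the default network. Measured
# vessels keep their literature values; IVCp, RHV, FO and DA are derived so
# that every asserted junction conserves mass exactly (see the methods
# vignette for the derivation).
.default_indexed_flows <- c(
  UV = 197, DV = 144, IVCd = 117, RHV = 72, IVCp = 333, SVC = 181,
  FO = 230, MPA = 284, DA = 246, LPA = 19, RPA = 19, AAo = 245,
  BT = 158, DAo = 333)

.default_waveform_kinds <- c(
  UV = "constant", DV = "venous_biphasic", IVCd = "venous_biphasic",
  RHV = "venous_biphasic", IVCp = "venous_biphasic", SVC = "venous_biphasic",
  FO = "venous_biphasic", MPA = "arterial", DA = "arterial",
  LPA = "arterial", RPA = "arterial", AAo = "arterial", BT = "arterial",
  DAo = "arterial")

# Lumen radii (mm), sized so that peak centerline speeds stay below the high
# VENC (150 cm/s) at the default 2.8 kg weight, while the smallest branches
# (LPA/RPA) sit at the ~3.5 voxels-per-diameter resolution floor at 1.5 mm
# voxels (cross-sectional area 21.5 mm^2).
.default_radii <- c(
  UV = 4.5, DV = 2.62, IVCd = 4.0, RHV = 2.8, IVCp = 5.0, SVC = 4.0,
  FO = 4.5, MPA = 4.05, DA = 4.0, LPA = 2.62, RPA = 2.62, AAo = 4.1,
  BT = 3.5, DAo = 4.8)

# Stylized centerline layout (mm) inside a 144 mm cube: caudo-cranial +z,
# a central venous column, the ductus venosus and right hepatic vein joining
# the distal IVC at the proximal-IVC confluence, a right-heart junction
# splitting into foramen ovale and main pulmonary artery, the pulmonary
# bifurcation with the ductus arteriosus, and the aortic side fed by the FO.
.default_centerlines <- list(
  UV   = rbind(c(20, 32, 16), c(48, 48, 24)),
  DV   = rbind(c(48, 48, 24), c(72, 72, 48)),
  IVCd = rbind(c(72, 72, 16), c(72, 72, 48)),
  RHV  = rbind(c(96, 48, 24), c(72, 72, 48)),
  IVCp = rbind(c(72, 72, 48), c(72, 72, 80)),
  SVC  = rbind(c(72, 72, 126), c(72, 72, 82)),
  FO   = rbind(c(72, 72, 80), c(48, 80, 92)),
  MPA  = rbind(c(72, 72, 80), c(92, 72, 102)),
  DA   = rbind(c(92, 72, 102), c(106, 72, 122)),
  LPA  = rbind(c(92, 72, 102), c(76, 60, 108)),
  RPA  = rbind(c(92, 72, 102), c(108, 84, 98)),
  AAo  = rbind(c(48, 80, 92), c(44, 80, 124)),
  BT   = rbind(c(44, 80, 124), c(32, 80, 136)),
  DAo  = rbind(c(106, 72, 122), c(118, 72, 100), c(120, 72, 40)))

.default_junctions <- list(
  list(name = "ivcp_confluence", inflows = c("DV", "IVCd", "RHV"),
       outflows = "IVCp"),
  list(name = "right_heart", inflows = c("SVC", "IVCp"),
       outflows = c("MPA", "FO")),
  list(name = "pulmonary_bifurcation", inflows = "MPA",
       outflows = c("DA", "LPA", "RPA")),
  list(name = "lower_body", inflows = "IVCp", outflows = "DAo"))

#' Default fetal-sheep flow network
#'
#' Builds the stylized fetal circulation used by the phantom: umbilical vein
#' (UV) feeding the ductus venosus (DV), the DV / distal IVC / right hepatic
#' vein confluence into the proximal IVC, the right-heart split into foramen
#' ovale and main pulmonary artery, the pulmonary bifurcation with the ductus
#' arteriosus, and the aortic limb (AAo, brachiocephalic trunk, DAo). Segment
#' mean flows are literature-derived indexed values (mL/min per kg)
#' multiplied by `weight`; vessels whose published means are mutually
#' inconsistent under conservation of mass (IVCp, RHV, FO, DA) carry flows
#' derived from the asserted junction balances instead (see the methods
#' vignette).
#'
#' @param weight fetal body mass in kg.
#' @param heart_rate_bpm fetal heart rate (sets the cardiac period).
#' @return A [network_spec()] with four asserted junctions, all balanced.
#' @examples
#' net <- make_default_network(weight = 1)
#' net$segments$MPA$waveform$mean_flow  # 284 mL/min at 1 kg
#' @export
make_default_network <- function(weight = 2.8, heart_rate_bpm = 140) {
  if (!is.numeric(weight) || weight <= 0) stopf("weight must be > 0 kg")
  period <- 60000 / heart_rate_bpm
  segs <- lapply(names(.default_indexed_flows), function(v) {
    # arterial systole is phased so the peak coincides with a sampled frame
    # at the default 8-frame reconstruction (peak at 1/8 of the cycle)
    wf <- waveform_spec(.default_waveform_kinds[[v]], period = period,
                        mean_flow = .default_indexed_flows[[v]] * weight,
                        phase_shift = switch(.default_waveform_kinds[[v]],
                                             venous_biphasic = 0.08,
                                             arterial = -0.05, 0))
    vessel_segment(v, .default_centerlines[[v]], .default_radii[[v]], wf)
  })
  network_spec(segs, junctions = .default_junctions, weight = weight,
               renormalize = TRUE)
}

#' Exact volumetric flux oracle
#'
#' Evaluates the analytic waveform of one segment at a cardiac frame time (or
#' arbitrary time). This is the ground truth against which measured flow
#' waveforms are validated.
#'
#' @param network a [network_spec()].
#' @param segment_name vessel label present in the network.
#' @param frame cardiac frame index in `1..n_frames` (frame 1 at t = 0).
#' @param n_frames number of cardiac frames (default 8).
#' @param t_ms alternatively, explicit time(s) in ms (overrides `frame`).
#' @return flux in mL/s.
#' @export
analytic_flux <- function(network, segment_name, frame = NULL, n_frames = 8,
                          t_ms = NULL) {
  stopifnot(inherits(network, "flow_network"))
  seg <- network$segments[[segment_name]]
  if (is.null(seg)) stopf("unknown segment '%s'", segment_name)
  if (is.null(t_ms)) {
    if (is.null(frame)) stopf("supply frame or t_ms")
    if (any(frame < 1 | frame > n_frames))
      stopf("frame index out of range 1..%d", n_frames)
    t_ms <- (frame - 1) * seg$waveform$period / n_frames
  }
  waveform_flux(seg$waveform, t_ms)
}

#' @export
print.flow_network <- function(x, ...) {
  cat(sprintf("<flow_network> %d segments, %d junctions, weight %.2f kg\n",
              length(x$segments), length(x$junctions), x$weight))
  flows <- vapply(x$segments, function(s) s$waveform$mean_flow, 0)
  print(round(flows, 1))
  invisible(x)
}
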