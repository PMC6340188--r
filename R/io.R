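# On-disk layout
# ==============
# A phase stack is one NIfTI volume series per component (magnitude and the
# three phase components; the 4th dimension is the cardiac frame) plus a
# JSON sidecar with VENC, spacing, frame timing and seed. A velocity field
# stacks its three components along a 5th dimension with a provenance
# sidecar.

.nii_write <- function(arr, path, spacing) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(spacing, rep(1, length(dim(arr)) - 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a phase stack as NIfTI volumes plus a JSON sidecar
#'
#' Writes `<prefix>_mag.nii.gz`, `<prefix>_phx.nii.gz`, `<prefix>_phy.nii.gz`,
#' `<prefix>_phz.nii.gz` (4D, frames along the 4th dimension) and
#' `<prefix>_sidecar.json`.
#'
#' @param stack a `phase_stack`.
#' @param prefix path prefix (directories must exist).
#' @return the sidecar path, invisibly.
#' @export
write_phase_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "phase_stack"))
  .nii_write(stack$magnitude, paste0(prefix, "_mag.nii.gz"), stack$spacing)
  comp <- c("phx", "phy", "phz")
  for (k in 1:3)
    .nii_write(stack$phase[, , , k, ], paste0(prefix, "_", comp[k], ".nii.gz"),
               stack$spacing)
  sidecar <- list(venc = stack$venc, spacing_mm = stack$spacing,
                  frame_times_ms = stack$frame_times,
                  period_ms = stack$period,
                  seed = stack$meta$seed %||% NA)
  path <- paste0(prefix, "_sidecar.json")
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a phase stack written by [write_phase_stack()]
#'
#' @param prefix path prefix used when writing.
#' @return a `phase_stack`.
#' @export
read_phase_stack <- function(prefix) {
  sidecar <- jsonlite::read_json(paste0(prefix, "_sidecar.json"),
                                 simplifyVector = TRUE)
  mag <- as.array(RNifti::readNifti(paste0(prefix, "_mag.nii.gz")))
  dm <- dim(mag)
  phase <- array(NA_real_, c(dm[1:3], 3, dm[4]))
  for (k in 1:3) {
    comp <- c("phx", "phy", "phz")[k]
    phase[, , , k, ] <-
      as.array(RNifti::readNifti(paste0(prefix, "_", comp, ".nii.gz")))
  }
  structure(list(magnitude = mag, phase = phase, venc = sidecar$venc,
                 spacing = sidecar$spacing_mm,
                 frame_times = sidecar$frame_times_ms,
                 period = sidecar$period_ms,
                 meta = list(seed = sidecar$seed)),
            class = "phase_stack")
}

#' Write a velocity field as NIfTI plus provenance JSON
#'
#' `<prefix>_vel.nii.gz` is a 5D volume (x, y, z, frame, component, cm/s);
#' `<prefix>_provenance.json` carries geometry, timing and the processing
#' provenance.
#'
#' @param field a [velocity_field()].
#' @param prefix path prefix.
#' @return the provenance path, invisibly.
#' @export
write_velocity_field <- function(field, prefix) {
  stopifnot(inherits(field, "velocity_field"))
  .nii_write(aperm(field$v, c(1, 2, 3, 5, 4)), paste0(prefix, "_vel.nii.gz"),
             field$spacing)
  prov <- field$provenance
  prov$merge_source <- NULL  # voxelwise; too large for a sidecar
  sidecar <- list(spacing_mm = field$spacing,
                  frame_times_ms = field$frame_times,
                  period_ms = field$period, venc = field$venc,
                  provenance = prov)
  path <- paste0(prefix, "_provenance.json")
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a velocity field written by [write_velocity_field()]
#' @param prefix path prefix used when writing.
#' @return a [velocity_field()].
#' @export
read_velocity_field <- function(prefix) {
  sidecar <- jsonlite::read_json(paste0(prefix, "_provenance.json"),
                                 simplifyVector = TRUE)
  v <- as.array(RNifti::readNifti(paste0(prefix, "_vel.nii.gz")))
  velocity_field(aperm(v, c(1, 2, 3, 5, 4)), sidecar$spacing_mm,
                 sidecar$frame_times_ms, sidecar$period_ms,
                 venc = sidecar$venc,
                 provenance = as.list(sidecar$provenance))
}

#' Write flow waveforms as CSV
#'
#' Long-to-wide: one `frame_time_ms` column plus one `q_mL_s` column per
#' vessel.
#'
#' @param waveforms list of [flow_waveform()]s.
#' @param path output CSV path.
#' @export
write_waveforms_csv <- function(waveforms, path) {
  df <- data.frame(frame_time_ms = waveforms[[1]]$frame_times)
  for (w in waveforms) df[[paste0(w$vessel, "_q_mL_s")]] <- w$q
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the quantification report as JSON
#'
#' Bundles the measurement table, the junction checks with their summary,
#' and an optional method comparison into one JSON report.
#'
#' @param table a [build_table()] result.
#' @param checks list of [junction_check()]s (optional).
#' @param comparison a [compare_methods()] result (optional).
#' @param path output path.
#' @export
write_report_json <- function(table, checks = NULL, comparison = NULL, path) {
  rep <- list(weight_kg = table$weight,
              cvo_ml_min_kg = table$cvo,
              flows_ml_min_kg = as.list(table$flows),
              pct_cvo = as.list(table$pct_cvo))
  if (!is.null(checks)) {
    rep$junctions <- lapply(checks, function(c)
      list(name = c$name, pct_diff = c$pct_diff, skipped = c$skipped,
           reason = c$reason))
    ok <- !vapply(checks, function(c) c$skipped, TRUE)
    if (any(ok)) rep$consistency <- consistency_summary(checks[ok])
  }
  if (!is.null(comparison))
    rep$method_comparison <- unclass(comparison)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Export pathlines as legacy VTK polylines
#'
#' ASCII legacy VTK with one polyline per particle and a per-point scalar
#' `speed` array (cm/s) for colour-coding.
#'
#' @param paths a [trace_pathlines()] result.
#' @param path output `.vtk` path.
#' @export
write_pathlines_vtk <- function(paths, path) {
  stopifnot(inherits(paths, "pathline_set"))
  n <- dim(paths$positions)[2]
  pts <- list(); lines <- list(); speeds <- list()
  offset <- 0
  for (p in seq_len(n)) {
    traj <- paths$positions[, p, , drop = TRUE]
    ok <- which(!is.na(traj[, 1]))
    if (length(ok) < 2) next
    pts[[length(pts) + 1]] <- traj[ok, , drop = FALSE]
    speeds[[length(speeds) + 1]] <- paths$speed[ok, p]
    lines[[length(lines) + 1]] <- seq(offset, offset + length(ok) - 1)
    offset <- offset + length(ok)
  }
  allp <- do.call(rbind, pts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "pathlines", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", nrow(allp))),
             con)
  utils::write.table(format(allp, trim = TRUE), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  total <- sum(vapply(lines, length, 0L)) + length(lines)
  writeLines(sprintf("LINES %d %d", length(lines), total), con)
  for (l in lines)
    writeLines(paste(c(length(l), l), collapse = " "), con)
  writeLines(c(sprintf("POINT_DATA %d", nrow(allp)),
               "SCALARS speed float 1", "LOOKUP_TABLE default"), con)
  writeLines(format(unlist(speeds), trim = TRUE), con)
  invisible(path)
}

#' Export pathlines as long-format CSV
#'
#' Columns `particle_id`, `t_ms`, `x`, `y`, `z`, `speed`.
#'
#' @param paths a [trace_pathlines()] result.
#' @param path output CSV path.
#' @export
write_pathlines_csv <- function(paths, path) {
  stopifnot(inherits(paths, "pathline_set"))
  n <- dim(paths$positions)[2]
  dfs <- lapply(seq_len(n), function(p) {
    traj <- paths$positions[, p, , drop = TRUE]
    ok <- !is.na(traj[, 1])
    data.frame(particle_id = p, t_ms = paths$times[ok],
               x = traj[ok, 1], y = traj[ok, 2], z = traj[ok, 3],
               speed = paths$speed[ok, p])
  })
  utils::write.csv(do.call(rbind, dfs), path, row.names = FALSE)
  invisible(path)
}

#' Write a streaming matrix as CSV
#' @param sm a [streaming_matrix()] result.
#' @param path output CSV path.
#' @export
write_streaming_csv <- function(sm, path) {
  stopifnot(inherits(sm, "streaming_matrix"))
  df <- data.frame(source = rownames(sm$fractions), sm$fractions,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a network to JSON
#'
#' Stores segment centerlines, radii and waveform parameters plus junctions
#' and weight; [read_network_json()] reconstructs the [network_spec()].
#'
#' @param network a [network_spec()].
#' @param path output path.
#' @export
write_network_json <- function(network, path) {
  stopifnot(inherits(network, "flow_network"))
  segs <- lapply(network$segments, function(s)
    list(name = s$name, centerline = s$centerline, radius = s$radius,
         waveform = unclass(s$waveform)))
  jsonlite::write_json(list(segments = segs, junctions = network$junctions,
                            weight = network$weight),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  segs <- lapply(raw$segments, function(s) {
    w <- s$waveform
    wf <- waveform_spec(w$kind, w$period, w$mean_flow, peak_frac = w$peak_frac,
                        peak_to_mean = w$peak_to_mean,
                        second_peak_ratio = w$second_peak_ratio,
                        phase_shift = w$phase_shift)
    cl <- do.call(rbind, lapply(s$centerline, unlist))
    vessel_segment(s$name, cl, s$radius, wf)
  })
  junctions <- lapply(raw$junctions, function(j)
    list(name = j$name, inflows = unlist(j$inflows),
         outflows = unlist(j$outflows)))
  network_spec(segs, junctions = junctions, weight = raw$weight)
}

#' Serialize an analysis plane (geometry only) to a list / JSON
#' @param planes list of [analysis_plane()]s.
#' @param path output path.
#' @export
write_planes_json <- function(planes, path) {
  out <- lapply(planes, function(p)
    list(vessel = p$vessel, center = p$center, normal = p$normal,
         radius = p$radius, pixel_size = p$pixel_size))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_planes_json
#' @export
read_planes_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(p)
    analysis_plane(unlist(p$center), unlist(p$normal), p$radius,
                   vessel = p$vessel, pixel_size = p$pixel_size))
}

#' Literature fetal flow reference table
#'
#' Cross-species reference values for fetal flow distribution (mean indexed
#' flows in mL/min per kg and the same values as a percentage of combined
#' ventricular output), as published for human 2D PC CMR, mouse Doppler
#' ultrasound, sheep radiolabeled microspheres, sheep 2D PC CMR and sheep
#' volumetric (4D flow) CMR cohorts. Shipped as a static reference table.
#'
#' @return A data.frame with columns `species`, `method`, `vessel`,
#'   `mean_flow_ml_min_kg`, `pct_cvo`, `n_measurements`, `standard_error`.
#' @export
literature_flows <- function() {
  path <- system.file("extdata", "literature_flows.csv",
                      package = "fetalflow", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
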