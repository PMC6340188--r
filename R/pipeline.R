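# Configuration-driven pipeline: phantom -> reconstruct -> quantify -> trace.
# One config drives all stages; unknown keys are errors (silent
# misconfiguration is the main failure mode in pipeline reuse).

#' Default pipeline configuration
#'
#' Returns the full nested configuration with every tunable parameter at its
#' default. Stage sections: `phantom` (network and acquisition), `recon`
#' (static detection, background order, merging), `quant` (plane placement),
#' `trace` (emission and integration).
#'
#' @param out output directory.
#' @param seed master seed.
#' @return nested named list of class `pipeline_config`.
#' @export
default_config <- function(out = "fetalflow_out", seed = 1L) {
  structure(list(
    out = out,
    seed = as.integer(seed),
    phantom = list(
      weight = 2.8, heart_rate_bpm = 140,
      grid_shape = c(96L, 96L, 96L), spacing = 1.5, n_frames = 8L,
      vencs = c(50, 150), snr = Inf,
      background_order = 1L, background_amplitude = 0.3,
      profile = "parabolic"),
    recon = list(
      static_phase_std_max = 0.1, static_mag_min = 0.3,
      background_order = 1L, robust = TRUE, per_vector = FALSE,
      angio_threshold = 0.1),
    quant = list(
      plane_at = 0.5, plane_margin_mm = 1.5, align = FALSE,
      denominator = "mean"),
    trace = list(
      n_particles = 500L, duration_cycles = 2, dt_divisor = 40L,
      sources = c("MPA", "AAo"), sink_at = 0.9, sink_radius_scale = 1.5,
      sinks = c("DA", "AAo"))),
    class = "pipeline_config")
}

# Recursively verify that cfg only uses keys present in the reference
# config; unknown keys are rejected.
.check_keys <- function(cfg, ref, path = "") {
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown))
    stopf("unknown config key(s): %s",
          paste0(path, unknown, collapse = ", "))
  for (k in names(cfg))
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])))
      .check_keys(cfg[[k]], ref[[k]], paste0(path, k, "."))
  invisible(TRUE)
}

# Overlay user values onto the defaults, recursively.
.merge_config <- function(ref, cfg) {
  for (k in names(cfg)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])))
      ref[[k]] <- .merge_config(ref[[k]], cfg[[k]])
    else ref[[k]] <- cfg[[k]]
  }
  ref
}

#' Load and validate a pipeline configuration
#'
#' Reads YAML or JSON (by extension), validates every key against the
#' defaults (unknown keys are errors, not warnings), and fills unset values
#' from [default_config()].
#'
#' @param path config file (`.yaml`/`.yml`/`.json`), or `NULL` for pure
#'   defaults.
#' @param overrides named list applied on top (e.g. from CLI flags).
#' @return validated `pipeline_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  ref <- default_config()
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    cfg <- if (grepl("\\.json$", path)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else yaml::read_yaml(path)
  }
  .check_keys(cfg, ref)
  .check_keys(overrides, ref)
  out <- .merge_config(.merge_config(ref, cfg), overrides)
  if (!is.numeric(out$seed) || out$seed != as.integer(out$seed))
    stopf("seed must be an integer")
  out$seed <- as.integer(out$seed)
  # validated at spec construction too, but fail fast on config errors
  if (is.unsorted(out$phantom$vencs, strictly = TRUE))
    stopf("phantom.vencs must be strictly ascending")
  structure(out, class = "pipeline_config")
}

#' Write a configuration to YAML
#'
#' Round-trip stable: `save_config(load_config(p), p2)` yields identical
#' bytes for identical content.
#'
#' @param cfg a `pipeline_config`.
#' @param path output path.
#' @export
save_config <- function(cfg, path) {
  writeLines(yaml::as.yaml(unclass(cfg), precision = 15), path)
  invisible(path)
}

.log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

.acq_from_config <- function(cfg) {
  ph <- cfg$phantom
  bg <- if (!is.null(ph$background_order) && ph$background_amplitude > 0)
    default_background(ph$background_order, ph$background_amplitude,
                       seed = cfg$seed)
  else NULL
  acquisition_spec(grid_shape = ph$grid_shape, spacing = ph$spacing,
                   n_frames = ph$n_frames, vencs = ph$vencs, snr = ph$snr,
                   background = bg, seed = cfg$seed)
}

#' Run the phantom stage
#'
#' Builds the default network at the configured weight, rasterizes the
#' ground-truth velocity field, MR-encodes one phase stack per VENC, and
#' writes: the truth field, the phase stacks, the network JSON and a
#' per-frame oracle flux CSV.
#'
#' @param cfg a `pipeline_config`.
#' @return output directory, invisibly.
#' @export
run_phantom <- function(cfg) {
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  net <- make_default_network(weight = cfg$phantom$weight,
                              heart_rate_bpm = cfg$phantom$heart_rate_bpm)
  acq <- .acq_from_config(cfg)
  .log("phantom", "grid %s, %d frames, vencs %s, snr %s, seed %d",
       paste(acq$grid_shape, collapse = "x"), acq$n_frames,
       paste(acq$vencs, collapse = ","), format(acq$snr), acq$seed)
  truth <- sample_truth(net, acq, profile = cfg$phantom$profile)
  stacks <- encode(truth, acq)
  write_velocity_field(truth, file.path(cfg$out, "truth"))
  for (s in stacks)
    write_phase_stack(s, file.path(cfg$out, sprintf("stack_venc%03d", s$venc)))
  write_network_json(net, file.path(cfg$out, "network.json"))
  flux <- do.call(rbind, lapply(names(net$segments), function(v)
    data.frame(vessel = v, frame = seq_len(acq$n_frames),
               q_mL_s = analytic_flux(net, v, seq_len(acq$n_frames),
                                      n_frames = acq$n_frames))))
  utils::write.csv(flux, file.path(cfg$out, "oracle_flux.csv"),
                   row.names = FALSE)
  .log("phantom", "lumen voxels: %d, wrote %d stacks",
       sum(truth$masks$lumen), length(stacks))
  invisible(cfg$out)
}

#' Run the reconstruction stage
#'
#' Reads the phase stacks, converts phase to velocity, detects static
#' tissue, corrects the background phase, unwraps the highest-VENC field,
#' merges the dual-VENC pair (skipped with a log notice for single-VENC
#' input), and segments the PC angiogram. Writes the corrected field,
#' angiogram NIfTI and provenance.
#'
#' @param cfg a `pipeline_config`.
#' @return the corrected [velocity_field()], invisibly.
#' @export
run_reconstruct <- function(cfg) {
  prefixes <- sort(Sys.glob(file.path(cfg$out, "stack_venc*_sidecar.json")))
  if (length(prefixes) == 0) stopf("no phase stacks found in %s", cfg$out)
  prefixes <- sub("_sidecar\\.json$", "", prefixes)
  stacks <- lapply(prefixes, read_phase_stack)
  vencs <- vapply(stacks, function(s) s$venc, 0)
  stacks <- stacks[order(vencs)]
  high <- stacks[[length(stacks)]]

  static <- detect_static(high, cfg$recon$static_phase_std_max,
                          cfg$recon$static_mag_min)
  .log("reconstruct", "static voxels: %d", sum(static))
  fields <- lapply(stacks, function(s)
    correct_background(phase_to_velocity(s), static,
                       order = cfg$recon$background_order,
                       robust = cfg$recon$robust))
  fh <- unwrap_high(fields[[length(fields)]], static = static)
  .log("reconstruct", "unwrapped voxels: temporal %d, spatial %d",
       fh$provenance$unwrapped["temporal"], fh$provenance$unwrapped["spatial"])
  if (length(fields) == 1) {
    .log("reconstruct", "single VENC acquisition: dual-VENC merge skipped")
    merged <- fh
  } else {
    merged <- merge_dual_venc(fields[[1]], fh,
                              per_vector = cfg$recon$per_vector)
    .log("reconstruct", "merge fallback voxels: %d",
         merged$provenance$merge_counts["fallback"])
  }
  angio <- compute_angiogram(merged, stack = high,
                             threshold = cfg$recon$angio_threshold)
  write_velocity_field(merged, file.path(cfg$out, "corrected"))
  .nii_write(angio$intensity, file.path(cfg$out, "angiogram.nii.gz"),
             merged$spacing)
  .nii_write(angio$lumen + 0L, file.path(cfg$out, "lumen.nii.gz"),
             merged$spacing)
  invisible(merged)
}

#' Run the quantification stage
#'
#' Places a plane on every network vessel, measures flow waveforms through
#' the corrected field, builds the measurement table (CVO, %CVO), runs the
#' four conservation checks plus their summary, and optionally compares to a
#' second flow table. Writes waveform CSV and a JSON report.
#'
#' @param cfg a `pipeline_config`.
#' @param field optional in-memory [velocity_field()] (else read from disk).
#' @param reference_flows optional named vector of indexed flows from a
#'   second method for the comparison statistics.
#' @return list with `table`, `checks`, `summary`, `comparison`, invisibly.
#' @export
run_quantify <- function(cfg, field = NULL, reference_flows = NULL) {
  net <- read_network_json(file.path(cfg$out, "network.json"))
  if (is.null(field)) {
    prefix <- file.path(cfg$out, "corrected")
    if (!file.exists(paste0(prefix, "_provenance.json")))
      stopf("no corrected velocity field in %s", cfg$out)
    field <- read_velocity_field(prefix)
  }
  px <- min(field$spacing) / 2
  planes <- lapply(names(net$segments), function(v)
    plane_from_vessel(net, v, at = cfg$quant$plane_at,
                      margin = cfg$quant$plane_margin_mm, pixel_size = px))
  if (isTRUE(cfg$quant$align))
    planes <- lapply(planes, function(p) align_plane(field, p))
  waveforms <- lapply(planes, function(p)
    flow_waveform(field, p, weight = net$weight))
  table <- build_table(waveforms, weight = net$weight)
  checks <- default_junction_checks(table,
                                    denominator = cfg$quant$denominator)
  for (c in checks)
    .log("quantify", "%s: %s", c$name,
         if (c$skipped) paste("skipped -", c$reason)
         else sprintf("%.2f%%", c$pct_diff))
  ok <- !vapply(checks, function(c) c$skipped, TRUE)
  summ <- if (any(ok)) consistency_summary(checks[ok]) else NULL
  comparison <- NULL
  if (!is.null(reference_flows)) {
    common <- intersect(names(table$flows), names(reference_flows))
    if (length(common) >= 3)
      comparison <- compare_methods(table$flows[common],
                                    reference_flows[common])
  }
  write_waveforms_csv(waveforms, file.path(cfg$out, "waveforms.csv"))
  write_planes_json(planes, file.path(cfg$out, "planes.json"))
  write_report_json(table, checks, comparison,
                    path = file.path(cfg$out, "report.json"))
  .log("quantify", "CVO %.1f mL/min/kg over %d vessels", table$cvo,
       length(table$flows))
  invisible(list(table = table, checks = checks, summary = summ,
                 comparison = comparison))
}

#' Run the tracing stage
#'
#' Emits particles from the configured source vessels, integrates pathlines
#' over the configured number of cardiac cycles, computes the streaming
#' matrix into spherical sinks placed near the end of the configured sink
#' vessels, and writes VTK, CSV and matrix outputs.
#'
#' @param cfg a `pipeline_config`.
#' @param field optional in-memory [velocity_field()].
#' @return the [streaming_matrix()], invisibly.
#' @export
run_trace <- function(cfg, field = NULL) {
  net <- read_network_json(file.path(cfg$out, "network.json"))
  if (is.null(field)) field <- read_velocity_field(file.path(cfg$out,
                                                             "corrected"))
  if (cfg$trace$n_particles < 1) stopf("trace.n_particles must be >= 1")
  px <- min(field$spacing) / 2
  sinks <- list()
  for (v in cfg$trace$sinks) {
    seg <- net$segments[[v]]
    P <- seg$centerline
    at <- cfg$trace$sink_at
    ctr <- P[nrow(P), ] * at + P[1, ] * (1 - at)
    sinks[[v]] <- list(type = "sphere", center = ctr,
                       radius = cfg$trace$sink_radius_scale * seg$radius)
  }
  dt <- field$period / (cfg$trace$dt_divisor * dim(field$v)[5])
  all_paths <- list()
  for (src in cfg$trace$sources) {
    plane <- plane_from_vessel(net, src, at = 0.2, margin = 0,
                               pixel_size = px)
    seeds <- emit(plane, cfg$trace$n_particles, seed = cfg$seed)
    paths <- trace_pathlines(field, seeds,
                             duration = cfg$trace$duration_cycles, dt = dt)
    write_pathlines_vtk(paths, file.path(cfg$out,
                                         sprintf("pathlines_%s.vtk", src)))
    write_pathlines_csv(paths, file.path(cfg$out,
                                         sprintf("pathlines_%s.csv", src)))
    all_paths[[src]] <- paths
    .log("trace", "%s: %d particles, dt %.2f ms, %s", src,
         cfg$trace$n_particles, dt,
         paste(names(table(paths$termination)),
               table(paths$termination), collapse = ", "))
  }
  sm <- streaming_matrix(all_paths, sinks)
  write_streaming_csv(sm, file.path(cfg$out, "streaming_matrix.csv"))
  invisible(sm)
}

#' Run the full pipeline
#'
#' `phantom`, `reconstruct`, `quantify`, `trace` in order, honouring stage
#' selection.
#'
#' @param cfg a `pipeline_config`.
#' @param stages character vector of stages to run.
#' @return list of stage results, invisibly.
#' @export
run_pipeline <- function(cfg, stages = c("phantom", "reconstruct",
                                         "quantify", "trace")) {
  res <- list()
  if ("phantom" %in% stages) res$phantom <- run_phantom(cfg)
  if ("reconstruct" %in% stages) res$field <- run_reconstruct(cfg)
  if ("quantify" %in% stages)
    res$quant <- run_quantify(cfg, field = res$field)
  if ("trace" %in% stages) res$trace <- run_trace(cfg, field = res$field)
  invisible(res)
}
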