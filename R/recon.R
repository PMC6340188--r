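#' Convert wrapped phase to velocity
#'
#' Linear phase-contrast mapping `v = VENC * phi / pi` per component. No
#' unwrapping is attempted, so single-VENC velocities are bounded by the
#' VENC in magnitude.
#'
#' @param stack a `phase_stack`.
#' @return A [velocity_field()] with `venc` set and provenance recorded.
#' @export
phase_to_velocity <- function(stack) {
  stopifnot(inherits(stack, "phase_stack"))
  velocity_field(stack$venc * stack$phase / pi, stack$spacing,
                 stack$frame_times, stack$period, venc = stack$venc,
                 provenance = list(venc = stack$venc,
                                   corrections = character(0)))
}

#' Detect static tissue
#'
#' Static voxels are those whose phase barely changes over the cardiac cycle
#' (temporal standard deviation of every phase component below
#' `phase_std_max`) and whose time-mean magnitude is above `mag_min` times
#' the volume maximum (excluding air). The phase of these voxels estimates
#' the spatial background phase.
#'
#' @param stack a `phase_stack` with at least 2 frames.
#' @param phase_std_max temporal phase SD threshold in radians (> 0).
#' @param mag_min magnitude floor as a fraction of the volume maximum (> 0).
#' @return logical array (`static_mask`) marking static voxels.
#' @export
detect_static <- function(stack, phase_std_max = 0.1, mag_min = 0.3) {
  stopifnot(inherits(stack, "phase_stack"))
  if (dim(stack$magnitude)[4] < 2) stopf("need >= 2 frames")
  if (phase_std_max <= 0 || mag_min <= 0)
    stopf("thresholds must be positive")
  gs <- dim(stack$magnitude)[1:3]
  nt <- dim(stack$magnitude)[4]
  ok <- array(TRUE, gs)
  for (k in 1:3) {
    m <- array(0, gs); m2 <- array(0, gs)
    for (f in seq_len(nt)) {
      ph <- stack$phase[, , , k, f]
      m <- m + ph
      m2 <- m2 + ph^2
    }
    m <- m / nt
    v <- pmax(m2 / nt - m^2, 0) * nt / (nt - 1)
    ok <- ok & sqrt(v) < phase_std_max
  }
  mag <- mean4(stack$magnitude)
  ok <- ok & mag > mag_min * max(mag)
  if (!any(ok)) warning("static mask is empty")
  structure(ok, class = c("static_mask", class(ok)))
}

#' Background phase (eddy-current) correction
#'
#' Fits, per velocity component, a polynomial of the given order in the
#' voxel coordinates to the time-mean velocity over static-tissue voxels,
#' and subtracts the fitted surface from every voxel and frame. With
#' `robust = TRUE` the fit iteratively discards static voxels with large
#' residuals (guarding against non-static voxels that leak into the mask,
#' e.g. constant-flow lumen).
#'
#' @param field a [velocity_field()].
#' @param mask logical static-tissue array ([detect_static()]).
#' @param order polynomial order, one of 0, 1, 2.
#' @param robust iteratively trim outlying mask voxels before the final fit.
#' @param max_iter robust trimming iterations.
#' @param outlier_k residual cut in robust MADs.
#' @return The corrected [velocity_field()]; provenance records the order
#'   and the number of static voxels used.
#' @export
correct_background <- function(field, mask, order = 1, robust = FALSE,
                               max_iter = 5, outlier_k = 4) {
  stopifnot(inherits(field, "velocity_field"))
  if (!order %in% 0:2) stopf("order must be 0, 1 or 2")
  idx <- which(mask)
  if (length(idx) == 0) stopf("static mask is empty")
  gs <- dim(field$v)[1:3]
  nt <- dim(field$v)[5]
  basis <- poly_basis(voxel_centers_normalized(gs, field$spacing), order)
  if (length(idx) < ncol(basis))
    stopf("fewer static voxels (%d) than polynomial coefficients (%d)",
          length(idx), ncol(basis))

  vmean <- lapply(1:3, function(k) {
    m <- array(0, gs)
    for (f in seq_len(nt)) m <- m + field$v[, , , k, f]
    m / nt
  })

  keep <- rep(TRUE, length(idx))
  X_all <- basis[idx, , drop = FALSE]
  for (it in seq_len(if (robust) max_iter else 1)) {
    X <- X_all[keep, , drop = FALSE]
    coefs <- lapply(vmean, function(m)
      qr.coef(qr(X), m[idx][keep]))
    if (!robust) break
    worst <- rep(FALSE, length(idx))
    for (k in 1:3) {
      r <- X_all %*% coefs[[k]] - vmean[[k]][idx]
      # deviation from the median residual: a contaminated fit offsets all
      # residuals together, which must not flag the inliers. The absolute
      # floor (cm/s) keeps a noise-free fit from flagging round-off.
      med <- stats::median(r[keep])
      worst <- worst | abs(r - med) >
        outlier_k * max(stats::mad(r[keep]), 1e-3)
    }
    new_keep <- !worst
    # never trim away the majority: the fit must stay anchored to tissue
    if (sum(new_keep) < max(ncol(X_all), length(idx) / 2)) break
    if (identical(new_keep, keep)) break
    keep <- new_keep
  }

  for (k in 1:3) {
    surf <- array(basis %*% coefs[[k]], gs)
    for (f in seq_len(nt))
      field$v[, , , k, f] <- field$v[, , , k, f] - surf
  }
  field$provenance$corrections <- c(field$provenance$corrections,
                                    sprintf("background_order%d", order))
  field$provenance$static_voxels <- sum(keep)
  field
}

# Median of the rows of a small matrix with NAs (vectorised enough for the
# unwrapping frontier, which only ever needs it for flagged voxels).
.row_median <- function(m) {
  apply(m, 1, stats::median, na.rm = TRUE)
}

#' Temporal-then-spatial phase unwrapping of a high-VENC field
#'
#' First, per voxel and component, the frame series is unwrapped in time:
#' each frame value is shifted by the multiple of `2 * VENC` that minimizes
#' the jump from the previous (already unwrapped) frame. Second, a spatial
#' wavefront grown from trusted seed voxels (a static mask if supplied,
#' otherwise all voxels with time-mean speed below half the VENC) shifts
#' whole voxel series whose time-mean differs from the median of
#' already-unwrapped 6-neighbours by more than the VENC. Every change is an
#' exact integer multiple of `2 * VENC`; unaliased data pass through
#' unchanged.
#'
#' @param field_high a single-VENC [velocity_field()] (its `venc` must be
#'   set).
#' @param static optional logical array of trusted (unaliased) seed voxels.
#' @return The unwrapped [velocity_field()]; provenance records the number
#'   of voxels changed in each pass.
#' @export
unwrap_high <- function(field_high, static = NULL) {
  stopifnot(inherits(field_high, "velocity_field"))
  venc <- field_high$venc
  if (is.null(venc)) stopf("field has no VENC recorded (not single-VENC?)")
  gs <- dim(field_high$v)[1:3]
  nt <- dim(field_high$v)[5]
  n_temporal <- 0L

  # --- temporal pass --------------------------------------------------------
  for (k in 1:3) {
    prev <- field_high$v[, , , k, 1]
    for (f in seq_len(nt)[-1]) {
      cur <- field_high$v[, , , k, f]
      kk <- round((cur - prev) / (2 * venc))
      n_temporal <- n_temporal + sum(kk != 0)
      cur <- cur - 2 * venc * kk
      field_high$v[, , , k, f] <- cur
      prev <- cur
    }
  }

  # --- spatial pass (wavefront from trusted seeds) --------------------------
  vmean <- lapply(1:3, function(k) {
    m <- array(0, gs)
    for (f in seq_len(nt)) m <- m + field_high$v[, , , k, f]
    m / nt
  })
  if (is.null(static)) {
    speed <- sqrt(vmean[[1]]^2 + vmean[[2]]^2 + vmean[[3]]^2)
    static <- speed < venc / 2
  }
  n_spatial <- 0L
  if (any(static) && !all(static)) {
    offs <- neighbour_offsets(gs)
    shift_list <- list(c(1, -1), c(1, 1), c(2, -1), c(2, 1), c(3, -1), c(3, 1))
    for (k in 1:3) {
      done <- array(static, gs)
      m <- vmean[[k]]
      repeat {
        frontier <- array(FALSE, gs)
        for (s in shift_list)
          frontier <- frontier | shift3(done, s[1], s[2])
        frontier <- frontier & !done
        fr <- which(frontier)
        if (length(fr) == 0) break
        nbmat <- matrix(NA_real_, length(fr), 6)
        fx <- ((fr - 1) %% gs[1]) + 1
        fy <- ((fr - 1) %/% gs[1]) %% gs[2] + 1
        for (jn in seq_along(offs)) {
          nb <- fr + offs[jn]
          valid <- nb >= 1 & nb <= length(m)
          # guard index wrap-around across x and y array edges
          if (jn == 1) valid <- valid & fx != 1
          if (jn == 2) valid <- valid & fx != gs[1]
          if (jn == 3) valid <- valid & fy != 1
          if (jn == 4) valid <- valid & fy != gs[2]
          ok <- valid
          ok[valid] <- done[nb[valid]]
          nbmat[ok, jn] <- m[nb[ok]]
        }
        # quick screen: only voxels with a large neighbour gap can be aliased
        gap <- suppressWarnings(
          pmax(abs(nbmat[, 1] - m[fr]), abs(nbmat[, 2] - m[fr]),
               abs(nbmat[, 3] - m[fr]), abs(nbmat[, 4] - m[fr]),
               abs(nbmat[, 5] - m[fr]), abs(nbmat[, 6] - m[fr]), na.rm = TRUE))
        cand <- which(is.finite(gap) & gap > venc)
        if (length(cand)) {
          med <- .row_median(nbmat[cand, , drop = FALSE])
          dk <- round((m[fr[cand]] - med) / (2 * venc))
          fire <- which(dk != 0 & abs(m[fr[cand]] - med) > venc)
          if (length(fire)) {
            vox <- fr[cand][fire]
            shift <- 2 * venc * dk[fire]
            m[vox] <- m[vox] - shift
            n_spatial <- n_spatial + length(vox)
            ii <- arrayInd(vox, gs)
            for (f in seq_len(nt))
              field_high$v[cbind(ii, k, f)] <-
                field_high$v[cbind(ii, k, f)] - shift
          }
        }
        done[fr] <- TRUE
      }
    }
  }
  field_high$provenance$corrections <- c(field_high$provenance$corrections,
                                         "unwrap")
  field_high$provenance$unwrapped <- c(temporal = n_temporal,
                                       spatial = n_spatial)
  field_high
}

#' Merge dual-VENC velocity fields
#'
#' Keeps the precise low-VENC velocity wherever it agrees with the unwrapped
#' high-VENC velocity within one low VENC; otherwise the low-VENC value is
#' shifted by the nearest integer multiple of `2 * VENC_low` toward the
#' high-VENC value (alias correction). If the shifted value still disagrees
#' by more than one low VENC the voxel falls back to the high-VENC value and
#' is flagged. The comparison is per component by default; with
#' `per_vector = TRUE` a single decision is made per voxel from the largest
#' component disagreement.
#'
#' @param low low-VENC [velocity_field()].
#' @param high_unwrapped unwrapped high-VENC [velocity_field()], matching
#'   geometry.
#' @param per_vector make the aliasing decision per velocity vector rather
#'   than per component.
#' @return Merged [velocity_field()]; provenance records per-voxel sources
#'   (`0` low kept, `1` alias-corrected, `2` fallback to high) and counts.
#' @export
merge_dual_venc <- function(low, high_unwrapped, per_vector = FALSE) {
  stopifnot(inherits(low, "velocity_field"),
            inherits(high_unwrapped, "velocity_field"))
  check_geometry_match(low, high_unwrapped, "low and high VENC fields")
  if (is.null(low$venc) || is.null(high_unwrapped$venc) ||
      low$venc >= high_unwrapped$venc)
    stopf("need low.venc < high.venc")
  vl <- low$venc
  out <- low
  vlow <- low$v
  vhigh <- high_unwrapped$v
  diff <- vhigh - vlow
  if (per_vector) {
    dm <- dim(vlow)
    mx <- pmax(abs(diff[, , , 1, , drop = FALSE]),
               abs(diff[, , , 2, , drop = FALSE]),
               abs(diff[, , , 3, , drop = FALSE]))
    disagree <- array(rep(mx, times = 3), dm[c(1:3, 5, 4)])
    disagree <- aperm(disagree, c(1, 2, 3, 5, 4)) > vl
  } else {
    disagree <- abs(diff) > vl
  }
  kk <- round(diff / (2 * vl)) * disagree
  corrected <- vlow + 2 * vl * kk
  fallback <- abs(corrected - vhigh) > vl
  merged <- ifelse(fallback, vhigh, corrected)
  src <- array(0L, dim(vlow))
  src[disagree & !fallback & kk != 0] <- 1L
  src[fallback] <- 2L
  out$v <- merged
  out$venc <- NULL
  out$provenance <- list(
    vencs = c(low = vl, high = high_unwrapped$venc),
    corrections = union(low$provenance$corrections,
                        high_unwrapped$provenance$corrections),
    merge_source = src,
    merge_counts = c(low_kept = sum(src == 0L), corrected = sum(src == 1L),
                     fallback = sum(src == 2L)))
  out
}

#' Phase-contrast angiogram and lumen segmentation
#'
#' The angiogram intensity is the time-mean of `magnitude * speed`; the
#' lumen is the set of connected components (6-connectivity) of
#' above-threshold voxels reached from seed points (world mm), defaulting to
#' the global intensity maximum.
#'
#' @param field a [velocity_field()].
#' @param stack optional `phase_stack` supplying the magnitude (1 if
#'   missing).
#' @param threshold lumen threshold as a fraction of the intensity maximum,
#'   in (0, 1).
#' @param seeds optional n x 3 matrix of seed points in mm.
#' @return An `angiogram` object: `intensity` (3D array), `lumen` (logical
#'   array), `labels` (integer array, one label per seed component).
#' @export
compute_angiogram <- function(field, stack = NULL, threshold = 0.1,
                              seeds = NULL) {
  stopifnot(inherits(field, "velocity_field"))
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0,1)")
  gs <- dim(field$v)[1:3]
  nt <- dim(field$v)[5]
  intensity <- array(0, gs)
  for (f in seq_len(nt)) {
    speed <- sqrt(field$v[, , , 1, f]^2 + field$v[, , , 2, f]^2 +
                    field$v[, , , 3, f]^2)
    if (!is.null(stack)) speed <- speed * stack$magnitude[, , , f]
    intensity <- intensity + speed
  }
  intensity <- intensity / nt
  mask <- intensity > threshold * max(intensity)
  labels <- array(0L, gs)
  lumen <- array(FALSE, gs)
  if (max(intensity) > 0 && any(mask)) {
    if (is.null(seeds)) {
      seed_idx <- which.max(intensity)
    } else {
      seeds <- matrix(seeds, ncol = 3)
      ijk <- pmin(pmax(ceiling(sweep(seeds, 2, field$spacing, "/")), 1),
                  matrix(gs, nrow(seeds), 3, byrow = TRUE))
      seed_idx <- ijk[, 1] + (ijk[, 2] - 1) * gs[1] +
        (ijk[, 3] - 1) * gs[1] * gs[2]
    }
    for (s in seq_along(seed_idx)) {
      comp <- flood_fill(mask & labels == 0L, seed_idx[s])
      labels[comp] <- s
      lumen <- lumen | comp
    }
  }
  structure(list(intensity = intensity, lumen = lumen, labels = labels,
                 threshold = threshold),
            class = "angiogram")
}

#' @export
print.angiogram <- function(x, ...) {
  cat(sprintf("<angiogram> %s voxels, %d lumen voxels in %d component(s)\n",
              paste(dim(x$intensity), collapse = "x"), sum(x$lumen),
              max(x$labels)))
  invisible(x)
}
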