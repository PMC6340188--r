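test_that("phase_to_velocity applies the linear VENC mapping", {
  fix <- tube_stack(venc = 50, mean_flux = 1)
  f <- phase_to_velocity(fix$stack)
  expect_equal(f$v, 50 * fix$stack$phase / pi)
  expect_equal(f$venc, 50)
  # single-VENC magnitudes are bounded by the VENC
  expect_lte(max(abs(f$v)), 50)
})

test_that("static detection recovers the tissue mask on noise-free data", {
  # pulsatile plug-flow phantom: every lumen voxel carries an unambiguous
  # time-varying phase, so the static mask is exactly the tissue mask
  # (a parabolic profile necessarily has a thin near-wall shell whose slow
  # flow is indistinguishable from static tissue; see the vignette)
  net <- y_network()
  acq <- tube_acq(vencs = 50)
  tr <- sample_truth(net, acq, profile = "plug", supersample = 1)
  stk <- encode(tr, acq)[[1]]
  static <- detect_static(stk)
  expect_identical(as.vector(static), as.vector(tr$masks$tissue))
})

test_that("static detection is robust to noise at SNR 20", {
  net <- y_network()
  acq <- tube_acq(vencs = 50, snr = 20, seed = 9)
  tr <- sample_truth(net, acq)
  stk <- encode(tr, acq)[[1]]
  static <- detect_static(stk)
  recall <- sum(static & tr$masks$tissue) / sum(tr$masks$tissue)
  expect_gte(recall, 0.9)
  # static voxels do not invade the lumen core
  expect_lt(sum(static & tr$masks$core_lumen) / sum(tr$masks$core_lumen),
            0.35)
})

test_that("degenerate and invalid static detection inputs are handled", {
  fix <- tube_stack(venc = 50)
  expect_error(detect_static(fix$stack, phase_std_max = 0), "positive")
  expect_error(detect_static(fix$stack, mag_min = -1), "positive")
  # all-lumen volume: empty mask with a warning
  stk <- fix$stack
  stk$magnitude[] <- 0
  expect_warning(detect_static(stk), "empty")
})

test_that("matching-order background contamination is removed exactly", {
  fix <- tube_stack(venc = 150, mean_flux = 3)
  f0 <- phase_to_velocity(fix$stack)
  # inject a known linear offset into every component and frame
  gs <- dim(f0$v)[1:3]
  basis <- poly_basis(fetalflow:::voxel_centers_normalized(gs, f0$spacing), 1)
  coefs <- rbind(c(0.8, 1.5, -2, 0.7), c(-1, 0.5, 2, 1), c(3, -1, 0.2, -0.5))
  f <- f0
  for (k in 1:3) {
    surf <- array(basis %*% coefs[k, ], gs)
    for (fr in 1:8) f$v[, , , k, fr] <- f$v[, , , k, fr] + surf
  }
  mask <- fix$truth$masks$tissue
  fc <- correct_background(f, mask, order = 1)
  expect_lt(max(abs(fc$v - f0$v)), 1e-9)
  # mean static velocity per component below 0.1 cm/s
  for (k in 1:3)
    expect_lt(abs(mean(fc$v[, , , k, 1][mask])), 0.1)
})

test_that("background correction is idempotent and identity on clean data", {
  fix <- tube_stack(venc = 150, mean_flux = 3)
  f0 <- phase_to_velocity(fix$stack)
  mask <- fix$truth$masks$tissue
  f1 <- correct_background(f0, mask, order = 1)
  expect_lt(max(abs(f1$v - f0$v)), 1e-9)  # zero offset: unchanged
  f2 <- correct_background(f1, mask, order = 1)
  expect_lt(max(abs(f2$v - f1$v)), 1e-9)  # idempotent
})

test_that("under-ordered fit leaves the independent least-squares residual", {
  # quadratic contamination corrected at order 1: the residual equals the
  # best linear approximation error computed independently with lm()
  fix <- tube_stack(venc = 150, mean_flux = 0)  # zero-flow: pure background
  f <- phase_to_velocity(fix$stack)
  gs <- dim(f$v)[1:3]
  ctr <- fetalflow:::voxel_centers_normalized(gs, f$spacing)
  quad <- 2 * ctr[, 1]^2 - ctr[, 2] * ctr[, 3] + 0.5 * ctr[, 2]
  for (fr in 1:8) f$v[, , , 1, fr] <- f$v[, , , 1, fr] + array(quad, gs)
  mask <- fix$truth$masks$tissue
  fc <- correct_background(f, mask, order = 1)
  # independent oracle: base-R lm fit of the same contamination
  df <- data.frame(y = quad[mask], x1 = ctr[mask, 1], x2 = ctr[mask, 2],
                   x3 = ctr[mask, 3])
  resid_lm <- stats::residuals(stats::lm(y ~ x1 + x2 + x3, data = df))
  expect_equal(as.vector(fc$v[, , , 1, 1][mask]), as.vector(resid_lm),
               tolerance = 1e-8)
})

test_that("background correction errors when the mask is too small", {
  fix <- tube_stack(venc = 150)
  f <- phase_to_velocity(fix$stack)
  tiny <- array(FALSE, dim(f$v)[1:3])
  expect_error(correct_background(f, tiny, order = 1), "empty")
  tiny[1:2] <- TRUE
  expect_error(correct_background(f, tiny, order = 1), "fewer static")
  expect_error(correct_background(f, fix$truth$masks$tissue, order = 3),
               "order")
})

test_that("robust trimming shields the fit from constant-flow lumen", {
  # a constant-flow tube leaks into the static mask (zero temporal phase
  # variation); robust trimming must exclude it so the background fit stays
  # anchored to true tissue
  net <- tube_network(radius = 4, mean_flux = 8, kind = "constant")
  bg <- default_background(order = 1, amplitude = 0.3, seed = 3)
  acq <- tube_acq(vencs = 150, background = bg)
  tr <- sample_truth(net, acq)
  stk <- encode(tr, acq)[[1]]
  static <- detect_static(stk)
  expect_gt(sum(static & tr$masks$lumen), 0)  # the leak exists
  f <- phase_to_velocity(stk)
  plain <- correct_background(f, static, order = 1, robust = FALSE)
  rob <- correct_background(f, static, order = 1, robust = TRUE)
  err_plain <- max(abs(plain$v - tr$v))
  err_rob <- max(abs(rob$v - tr$v))
  expect_lt(err_rob, 0.1)
  expect_lt(err_rob, err_plain)
})

test_that("unwrapping is the identity on unaliased fields", {
  fix <- tube_stack(venc = 150, mean_flux = 3)
  f <- phase_to_velocity(fix$stack)
  u <- unwrap_high(f)
  expect_equal(u$v, f$v, tolerance = 1e-12)
})

test_that("an aliased voxel in a smooth neighbourhood is restored", {
  # true 160 cm/s under VENC 150 appears as -140; neighbours near 150
  venc <- 150
  gs <- c(12, 12, 12)
  v <- array(0, c(gs, 3, 2))
  v[, , 7:12, 3, ] <- 150  # smooth fast slab
  v[6, 6, 9, 3, ] <- -140  # aliased from 160
  f <- velocity_field(v, 1.5, c(0, 200), 400, venc = venc)
  static <- array(FALSE, gs); static[, , 1:6] <- TRUE
  u <- unwrap_high(f, static = static)
  expect_equal(u$v[6, 6, 9, 3, 1], 160)
  # untouched voxels unchanged
  expect_equal(u$v[2, 2, 8, 3, 1], 150)
})

test_that("unwrapping only ever changes values by multiples of 2 VENC", {
  venc <- 50
  set.seed(31)
  gs <- c(10, 10, 10)
  v <- array(stats::runif(prod(gs) * 3 * 4, -49, 49), c(gs, 3, 4))
  # sprinkle aliasing
  v[sample(length(v), 40)] <- stats::runif(40, -49, 49) + 100
  f <- velocity_field(v, 1.5, (0:3) * 100, 400, venc = venc)
  u <- unwrap_high(f)
  steps <- (u$v - v) / (2 * venc)
  expect_lt(max(abs(steps - round(steps))), 1e-9)
})

test_that("dual-VENC merging corrects aliases and keeps agreeing voxels", {
  # worked example: true 120, low VENC 50 aliases to 20, high reads 120
  gs <- c(6, 6, 6)
  lo <- velocity_field(array(20, c(gs, 3, 2)), 1.5, c(0, 200), 400, venc = 50)
  hi <- velocity_field(array(120, c(gs, 3, 2)), 1.5, c(0, 200), 400,
                       venc = 150)
  m <- merge_dual_venc(lo, hi)
  expect_equal(m$v[1, 1, 1, 1, 1], 120)  # 20 + 2*50*round(100/100)
  expect_equal(unname(m$provenance$merge_counts["fallback"]), 0)
  # agreeing voxels keep the low-VENC value
  hi2 <- velocity_field(array(21, c(gs, 3, 2)), 1.5, c(0, 200), 400,
                        venc = 150)
  m2 <- merge_dual_venc(lo, hi2)
  expect_equal(m2$v[1, 1, 1, 1, 1], 20)
  # geometry mismatch is an error
  hi3 <- velocity_field(array(0, c(4, 4, 4, 3, 2)), 1.5, c(0, 200), 400,
                        venc = 150)
  expect_error(merge_dual_venc(lo, hi3), "geometry")
  expect_error(merge_dual_venc(hi, lo), "low.venc < high.venc")
})

test_that("noise-free dual-VENC phantom merges back to truth exactly", {
  net <- tube_network(radius = 4, mean_flux = 135 * pi * 0.16 / 2 / 2.8,
                      kind = "arterial")
  acq <- tube_acq(vencs = c(50, 150))
  tr <- sample_truth(net, acq)
  expect_gt(max(abs(tr$v)), 50)  # the low VENC genuinely wraps
  stks <- encode(tr, acq)
  lo <- phase_to_velocity(stks[[1]])
  hi <- unwrap_high(phase_to_velocity(stks[[2]]))
  m <- merge_dual_venc(lo, hi)
  expect_lt(max(abs(m$v - tr$v)), 1e-9)
  # merge output minus low input is everywhere a multiple of 2 VENC_low
  steps <- (m$v - lo$v) / (2 * 50)
  expect_lt(max(abs(steps - round(steps))), 1e-9)
})

test_that("angiogram segmentation recovers the lumen", {
  fix <- tube_stack(venc = 150, mean_flux = 4)
  f <- phase_to_velocity(fix$stack)
  ang <- compute_angiogram(f, stack = fix$stack, threshold = 0.1)
  truth <- fix$truth$masks$core_lumen
  dice <- 2 * sum(ang$lumen & truth) / (sum(ang$lumen) + sum(truth))
  expect_gte(dice, 0.9)
  # zero-velocity field gives an empty lumen
  f0 <- f; f0$v[] <- 0
  ang0 <- compute_angiogram(f0, threshold = 0.1)
  expect_equal(sum(ang0$lumen), 0)
  expect_error(compute_angiogram(f, threshold = 1.2), "threshold")
})

test_that("two disjoint tubes give two labeled components", {
  w <- waveform_spec("constant", 400, 120)
  segs <- list(
    vessel_segment("L", rbind(c(12, 24, 8), c(12, 24, 40)), 3, w),
    vessel_segment("R", rbind(c(36, 24, 8), c(36, 24, 40)), 3, w))
  net <- network_spec(segs, weight = 1)
  acq <- tube_acq(n_frames = 2, vencs = 150)
  tr <- sample_truth(net, acq)
  f <- velocity_field(tr$v, tr$spacing, tr$frame_times, tr$period)
  ang <- compute_angiogram(f, threshold = 0.1,
                           seeds = rbind(c(12, 24, 24), c(36, 24, 24)))
  expect_equal(max(ang$labels), 2)
  expect_gt(sum(ang$labels == 1), 0)
  expect_gt(sum(ang$labels == 2), 0)
})

test_that("full reconstruction chain recovers truth under background", {
  # phantom -> encode (no noise, linear background) -> convert -> correct
  # -> unwrap -> merge reproduces the truth below the high VENC
  net <- y_network()
  bg <- default_background(order = 1, amplitude = 0.3, seed = 21)
  acq <- tube_acq(vencs = c(50, 150), background = bg)
  tr <- sample_truth(net, acq)
  stks <- encode(tr, acq)
  static <- detect_static(stks[[2]])
  lo <- correct_background(phase_to_velocity(stks[[1]]), static, order = 1,
                           robust = TRUE)
  hi <- correct_background(phase_to_velocity(stks[[2]]), static, order = 1,
                           robust = TRUE)
  hi <- unwrap_high(hi, static = static)
  m <- merge_dual_venc(lo, hi)
  expect_lt(max(abs(m$v - tr$v)), 0.1)
})
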