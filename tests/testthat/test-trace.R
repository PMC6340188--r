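test_that("velocity_at honours interpolation identities", {
  f <- make_rotation_field(0.005, grid_shape = c(16, 16, 8), spacing = 2,
                           period = 200)
  # voxel centre at a frame time returns the stored value exactly
  p <- c((5 - 0.5) * 2, (7 - 0.5) * 2, (3 - 0.5) * 2)
  expect_equal(as.vector(velocity_at(f, p, 0)), as.vector(f$v[5, 7, 3, , 1]))
  # periodicity: t = period equals t = 0
  expect_equal(velocity_at(f, p, f$period), velocity_at(f, p, 0))
  # midpoint between two voxels averages their values (linear field: exact)
  pmid <- p + c(1, 0, 0)
  expect_equal(as.vector(velocity_at(f, pmid, 0)),
               as.vector((f$v[5, 7, 3, , 1] + f$v[6, 7, 3, , 1]) / 2))
  expect_error(velocity_at(f, c(-5, 0, 0), 0), "outside")
})

test_that("temporal interpolation wraps the last frame onto the first", {
  gs <- c(8, 8, 8)
  v <- array(0, c(gs, 3, 4))
  for (fr in 1:4) v[, , , 1, fr] <- fr  # component 1 counts the frames
  f <- velocity_field(v, 2, (0:3) * 100, 400)
  p <- c(8, 8, 8)
  # halfway between the last frame (value 4) and the wrap to frame 1
  expect_equal(velocity_at(f, p, 350)[1], (4 + 1) / 2)
  expect_equal(velocity_at(f, p, 50)[1], 1.5)
})

test_that("emission is reproducible, in-lumen, and respects n", {
  p <- analysis_plane(c(18, 18, 12), c(0, 0, 1), radius = 6,
                      pixel_size = 0.75)
  s1 <- emit(p, 100, seed = 7)
  s2 <- emit(p, 100, seed = 7)
  expect_identical(s1, s2)
  s3 <- emit(p, 100, seed = 8)
  expect_false(identical(s1, s3))
  # all seeds within the lumen disk (radius + half-pixel jitter)
  r <- sqrt((s1$x - 18)^2 + (s1$y - 18)^2)
  expect_lte(max(r), 6 + 0.75)
  expect_equal(nrow(emit(p, 1, seed = 1)), 1)
  empty <- analysis_plane(c(18, 18, 12), c(0, 0, 1), radius = 6,
                          pixel_size = 0.75,
                          lumen = matrix(FALSE, 17, 17))
  expect_error(emit(empty, 10), "empty lumen")
})

test_that("advection through a uniform field is exact", {
  f <- make_uniform_field(c(10, 0, 0), grid_shape = c(48, 16, 16),
                          spacing = 2, period = 400)
  seeds <- data.frame(x = 10, y = 16, z = 16, t0 = 0)
  # 10 cm/s = 0.1 mm/ms; 100 ms -> 10 mm displacement, RK4 exact
  paths <- trace_pathlines(f, seeds, duration = 100 / 400, dt = 10)
  final <- paths$positions[11, 1, ]
  expect_equal(final, c(20, 16, 16), tolerance = 1e-12)
})

test_that("rigid rotation shows 4th-order step-size convergence", {
  omega <- 2 * pi / 1000  # one revolution per 1000 ms
  f <- make_rotation_field(omega, grid_shape = c(32, 32, 8), spacing = 2,
                           period = 1000)
  start <- c(32 + 12, 32, 8)
  err_at <- function(dt) {
    paths <- trace_pathlines(f, data.frame(x = start[1], y = start[2],
                                           z = start[3], t0 = 0),
                             duration = 0.25, dt = dt)
    idx <- max(which(!is.na(paths$positions[, 1, 1])))
    t_end <- paths$times[idx]
    ang <- omega * t_end
    exact <- c(32 + 12 * cos(ang), 32 + 12 * sin(ang), 8)
    sqrt(sum((paths$positions[idx, 1, ] - exact)^2))
  }
  e1 <- err_at(25)
  e2 <- err_at(12.5)
  expect_gte(e1 / e2, 8)   # 4th order: halving dt gains >= 2^3 even at the
                           # conservative bound (asymptotically 2^4)
  # radius drift over a full revolution is tiny at dt = period/1000
  paths <- trace_pathlines(f, data.frame(x = start[1], y = start[2],
                                         z = start[3], t0 = 0),
                           duration = 1, dt = 1)
  idx <- max(which(!is.na(paths$positions[, 1, 1])))
  r_end <- sqrt(sum((paths$positions[idx, 1, 1:2] - c(32, 32))^2))
  expect_lt(abs(r_end - 12) / 12, 1e-4)
})

test_that("time reversal returns steady-field particles to their seeds", {
  omega <- 2 * pi / 1000
  f <- make_rotation_field(omega, grid_shape = c(32, 32, 8), spacing = 2,
                           period = 1000)
  fneg <- f; fneg$v <- -f$v
  seeds <- data.frame(x = c(44, 38), y = c(32, 28), z = c(8, 8), t0 = 0)
  fwd <- trace_pathlines(f, seeds, duration = 0.2, dt = 1)
  idx <- max(which(!is.na(fwd$positions[, 1, 1])))
  back_seeds <- data.frame(x = fwd$positions[idx, , 1],
                           y = fwd$positions[idx, , 2],
                           z = fwd$positions[idx, , 3], t0 = 0)
  bwd <- trace_pathlines(fneg, back_seeds, duration = 0.2, dt = 1)
  for (i in 1:2)
    expect_lt(sqrt(sum((bwd$positions[idx, i, ] -
                          unlist(seeds[i, 1:3]))^2)), 1e-6)
})

test_that("particles stay on their launch streamline in a steady tube", {
  net <- tube_network(radius = 3, mean_flux = 3, kind = "constant")
  acq <- tube_acq(n_frames = 2)
  tr <- sample_truth(net, acq)
  seeds <- data.frame(x = c(23.25, 24.0), y = c(23.25, 23.6),
                      z = c(10, 10), t0 = 0)
  paths <- trace_pathlines(tr, seeds, duration = 2, dt = 2)
  for (i in 1:2) {
    ok <- !is.na(paths$positions[, i, 1])
    drift <- max(abs(paths$positions[ok, i, 1] - seeds$x[i]),
                 abs(paths$positions[ok, i, 2] - seeds$y[i]))
    expect_lt(drift, 0.15)  # 0.1 voxel at 1.5 mm spacing
  }
})

test_that("two non-mixing channels produce a diagonal streaming matrix", {
  ph <- make_two_channel_phantom()
  paths <- lapply(ph$planes, function(p) {
    seeds <- emit(p, 60, seed = 11)
    trace_pathlines(ph$field, seeds, duration = 3)
  })
  sm <- streaming_matrix(paths, ph$sinks)
  expect_equal(unname(sm$fractions["A", "sink1"]), 1)
  expect_equal(unname(sm$fractions["A", "sink2"]), 0)
  expect_equal(unname(sm$fractions["B", "sink2"]), 1)
  expect_equal(unname(sm$fractions["B", "sink1"]), 0)
  # rows sum to exactly 1 including unassigned
  expect_equal(unname(rowSums(sm$fractions)), c(1, 1))
})

test_that("particles that reach no sink are counted unassigned", {
  ph <- make_two_channel_phantom()
  seeds <- emit(ph$planes[[1]], 20, seed = 2)
  paths <- trace_pathlines(ph$field, seeds, duration = 0.05)  # far too short
  sm <- streaming_matrix(paths, ph$sinks)
  expect_equal(unname(sm$fractions[1, "unassigned"]), 1)
  expect_equal(sum(sm$counts[1, c("sink1", "sink2")]), 0)
})

test_that("overlapping sinks are rejected", {
  ph <- make_two_channel_phantom()
  bad <- ph$sinks
  bad$sink2 <- bad$sink1
  seeds <- emit(ph$planes[[1]], 5, seed = 2)
  paths <- trace_pathlines(ph$field, seeds, duration = 0.1)
  expect_error(streaming_matrix(paths, bad), "overlapping")
})

test_that("the 80/20 split phantom recovers the streaming fraction", {
  ph <- make_split_phantom(split_frac = 0.8)
  seeds <- emit(ph$plane, 1000, seed = 1)
  paths <- trace_pathlines(ph$field, seeds, duration = 3)
  sm <- streaming_matrix(paths, ph$sinks)
  expect_lt(abs(sm$fractions["DV", "FO"] - 0.8), 0.1)
  expect_equal(unname(rowSums(sm$fractions)), 1)
})

test_that("streamline mode freezes the field at the release time", {
  # pulsatile uniform field: pathlines see the time variation, streamlines
  # do not
  gs <- c(32, 12, 12)
  v <- array(0, c(gs, 3, 2))
  v[, , , 1, 1] <- 10; v[, , , 1, 2] <- 30
  f <- velocity_field(v, 2, c(0, 200), 400)
  seeds <- data.frame(x = 6, y = 12, z = 12, t0 = 0)
  stream <- trace_pathlines(f, seeds, duration = 0.25, dt = 10,
                            mode = "streamline")
  idx <- max(which(!is.na(stream$positions[, 1, 1])))
  # frozen at t0 = 0: constant 10 cm/s for 100 ms -> 10 mm
  expect_equal(stream$positions[idx, 1, 1], 6 + 10, tolerance = 1e-9)
  path <- trace_pathlines(f, seeds, duration = 0.25, dt = 10,
                          mode = "pathline")
  expect_gt(path$positions[idx, 1, 1], 6 + 10)
})
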