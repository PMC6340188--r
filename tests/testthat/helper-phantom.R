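# Shared fixture builders. All fixtures are generated in code; grids are
# kept small so individual tests stay fast.

# Straight tube phantom on a small grid. The axis passes through voxel
# centres (offset 23.25 mm at 1.5 mm spacing) so pointwise rasterization is
# exactly Poiseuille on the axis.
tube_network <- function(radius = 3, mean_flux = 3, kind = "arterial",
                         period = 400, axis = c(23.25, 23.25),
                         z = c(8, 40), peak_to_mean = NULL) {
  wf <- waveform_spec(kind, period = period, mean_flow = mean_flux * 60,
                      peak_to_mean = peak_to_mean)
  seg <- vessel_segment("TUBE", rbind(c(axis, z[1]), c(axis, z[2])),
                        radius, wf)
  network_spec(list(seg), weight = 1)
}

tube_acq <- function(n_frames = 8, vencs = c(50, 150), snr = Inf,
                     background = NULL, seed = 1L) {
  acquisition_spec(grid_shape = c(32, 32, 32), spacing = 1.5,
                   n_frames = n_frames, vencs = vencs, snr = snr,
                   background = background, seed = seed)
}

# Full single-VENC reconstruction input: tube phantom, encoded.
tube_stack <- function(venc = 150, ...) {
  net <- tube_network(...)
  acq <- tube_acq(vencs = venc)
  truth <- sample_truth(net, acq)
  list(net = net, acq = acq, truth = truth,
       stack = encode(truth, acq)[[1]])
}

# Tiny fetal-like Y-network: two inflows merging into one outflow, used for
# junction and blending behaviour at small scale.
y_network <- function(period = 400) {
  w1 <- waveform_spec("venous_biphasic", period, 300)
  w2 <- waveform_spec("venous_biphasic", period, 600)
  w3 <- waveform_spec("venous_biphasic", period, 900)
  segs <- list(
    vessel_segment("A", rbind(c(12, 12, 8), c(24, 24, 22)), 2.6, w1),
    vessel_segment("B", rbind(c(36, 36, 8), c(24, 24, 22)), 3.2, w2),
    vessel_segment("C", rbind(c(24, 24, 22), c(24, 24, 40)), 3.6, w3))
  network_spec(segs, junctions = list(list(name = "merge",
                                           inflows = c("A", "B"),
                                           outflows = "C")), weight = 1)
}

expect_all_finite <- function(x) expect_false(any(!is.finite(x)))
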