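test_that("5.7 um fibre reproduces the published double-cable geometry set", {
  ax <- build_axon(5.7, n_nodes = 21)
  expect_equal(ax$internode_um, 500)
  expect_equal(ax$node_diameter_um, 1.9)
  expect_equal(ax$axon_diameter_um, 3.4)
  expect_equal(ax$flut_um, 35)
  expect_equal(ax$lamellae, 80)
  # compartment pattern: 10 internodal segments between consecutive nodes
  expect_equal(length(ax$type), 11 * 20 + 1)
  expect_equal(unique(ax$type[2:11]), c("MYSA", "FLUT", "STIN"))
  expect_equal(sum(ax$type == "node"), 21)
  # bookkeeping identity: total length
  expect_equal(ax$total_length_um, 20 * 500 + 1, tolerance = 1e-12)
  expect_equal(sum(ax$length_um), ax$total_length_um)
})

test_that("unsupported fibres and degenerate node counts error", {
  expect_error(build_axon(4.0), "outside the supported range")
  expect_error(build_axon(20), "outside the supported range")
  expect_error(build_axon(5.7, n_nodes = 1), "n_nodes")
  # interpolation between published sets stays monotone
  a <- build_axon(6.5, n_nodes = 21)
  expect_true(a$internode_um > 500 && a$internode_um < 750)
})

test_that("axon rests quietly: no-stimulus drift < 1 mV over 3.5 ms", {
  ax <- test_axon()
  tr <- integrate_axon(ax, rep(0, length(ax$type)), make_pulse(100), amplitude = 0)
  expect_lt(max(abs(tr$V - ax$vrest)), 1)
  expect_false(detect_ap(tr)$spike)
  # time vector: constant step, right length
  expect_equal(length(tr$time_ms), 3.5 / 0.0025 + 1)
  expect_equal(unique(round(diff(tr$time_ms), 10)), 0.0025)
})

test_that("suprathreshold stimulus elicits a propagating spike with plausible velocity", {
  ax <- test_axon()
  drv <- point_source_drive(ax)
  tt <- titrate(ax, drv, make_pulse(100), baseline_mA = 1)
  tr <- integrate_axon(ax, drv, make_pulse(100), amplitude = 1.5 * tt$factor)
  det <- detect_ap(tr)
  expect_true(det$spike)
  # initiation near the most polarised (central) node, spread to both ends
  expect_lt(abs(det$initiation - 26), 3)
  expect_lte(min(det$nodes), 3)
  expect_gte(max(det$nodes), 49)
  # conduction velocity within the published band for a 5.7 um fibre
  cv <- conduction_velocity(tr)
  expect_gt(cv, 13)   # ~ 4.6 m/s per um +/- 50%
  expect_lt(cv, 40)
})

test_that("threshold is stable under time-step refinement (dt vs dt/4 within 2%)", {
  ax <- test_axon()
  drv <- point_source_drive(ax)
  p <- make_pulse(146)
  t1 <- titrate(ax, drv, p, baseline_mA = 1, dt_ms = 0.0025)
  t2 <- titrate(ax, drv, p, baseline_mA = 1, dt_ms = 0.0025 / 4)
  expect_lt(abs(t1$factor - t2$factor) / t2$factor, 0.02)
})

test_that("detect_ap distinguishes propagation from local depolarisation", {
  time <- seq(0, 3.5, by = 0.0025)
  flat <- structure(list(time_ms = time,
                         V = matrix(-80, length(time), 51), rest_mV = -80,
                         node_position_mm = seq(0, 25, length.out = 51)),
                    class = "membrane_trace")
  expect_false(detect_ap(flat)$spike)

  # synthetic upward crossings at nodes 40..60 of a 101-node trace
  V <- matrix(-80, length(time), 101)
  for (nd in 40:60) V[(400 + 4 * nd):(420 + 4 * nd), nd] <- 20
  syn <- structure(list(time_ms = time, V = V, rest_mV = -80,
                        node_position_mm = seq(0, 50, length.out = 101)),
                   class = "membrane_trace")
  det <- detect_ap(syn)
  expect_true(det$spike)
  expect_equal(det$nodes, 40:60)

  # a single-node event never qualifies
  V1 <- matrix(-80, length(time), 51); V1[500:520, 26] <- 20
  one <- structure(list(time_ms = time, V = V1, rest_mV = -80,
                        node_position_mm = seq(0, 25, length.out = 51)),
                   class = "membrane_trace")
  expect_false(detect_ap(one)$spike)
  # nor does a tight non-propagating cluster
  V2 <- matrix(-80, length(time), 51)
  V2[500:520, 25:27] <- 20
  clus <- structure(list(time_ms = time, V = V2, rest_mV = -80,
                         node_position_mm = seq(0, 25, length.out = 51)),
                    class = "membrane_trace")
  expect_false(detect_ap(clus)$spike)
})

test_that("extracellular sampling: constant, linear and symmetric profiles behave", {
  g <- build_phantom(radius_mm = 15, length_mm = 40, spacing_mm = 1,
                     layers = c(skin = 1.5, sat = 3.5, muscle = 5))
  ax <- build_axon(5.7, n_nodes = 21)   # 10 mm, fits the 40 mm trajectory
  tr <- make_nerve_trajectory(g, "median", 5.5)
  ca <- grid_coord_arrays(g)

  const <- sample_extracellular(fake_potential(array(0.25, g$shape), g), tr, ax)
  expect_true(all(abs(const$values_mV - 250) < 1e-9))

  # linear field: sampled values affine in arclength position (compartments
  # are unevenly spaced, so the residual of a line fit is the right check)
  linear <- sample_extracellular(fake_potential(ca$z * 1e-3, g), tr, ax)
  lf <- lm(linear$values_mV ~ ax$position_mm)
  expect_lt(max(abs(resid(lf))), 1e-9)

  # point source directly above the axon midpoint: symmetric profile
  mid <- c(0, 15 - 5.5 + 3, 20)
  r <- sqrt((ca$x - mid[1])^2 + (ca$y - mid[2])^2 + (ca$z - mid[3])^2)
  ps <- sample_extracellular(fake_potential(1 / pmax(r, 0.5), g), tr, ax)
  v <- ps$values_mV
  expect_lt(max(abs(v - rev(v))) / max(abs(v)), 1e-6)

  # source above node 10 (a grid-aligned z plane): that node takes the maximum
  r2 <- sqrt((ca$x)^2 + (ca$y - mid[2])^2 + (ca$z - 19.5)^2)
  ps2 <- sample_extracellular(fake_potential(1 / pmax(r2, 0.5), g), tr, ax)
  expect_equal(which.max(ps2$values_mV), which(ax$type == "node")[10])

  # trajectory shorter than the axon errors
  ax_long <- build_axon(5.7, n_nodes = 101)
  expect_error(sample_extracellular(fake_potential(array(0, g$shape), g), tr, ax_long),
               "shorter than the axon")
})

test_that("threshold monotonicity and mirror symmetry hold", {
  ax <- test_axon()
  drv <- point_source_drive(ax)
  p <- make_pulse(100)
  tt <- titrate(ax, drv, p, baseline_mA = 1)
  spikes <- sapply(c(0.8, 0.95, 1.05, 1.3, 2, 4), function(f)
    detect_ap(integrate_axon(ax, drv, p, amplitude = f * tt$factor))$spike)
  expect_equal(spikes, c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
  tm <- titrate(ax, rev(drv), p, baseline_mA = 1)
  expect_equal(tm$factor, tt$factor, tolerance = 1e-9)
})

test_that("charge-balanced pulse alone returns the axon to rest by 3.5 ms", {
  ax <- test_axon()
  drv <- point_source_drive(ax)
  p <- make_pulse(495)
  tt <- titrate(ax, drv, p, baseline_mA = 1)
  # just below threshold: the stimulus leaves no residual polarisation
  tr <- integrate_axon(ax, drv, p, amplitude = tt$bracket[1])
  expect_lt(max(abs(tr$V[nrow(tr$V), ] - ax$vrest)), 5)
})
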