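test_that("parallel plates in a uniform slab give the analytic linear potential", {
  g <- uniform_grid(c(8, 11, 8))
  pot <- solve_potential(g, dirichlet = list(
    anode = list(idx = plate_idx(g, 2, 11), value = 1),
    cathode = list(idx = plate_idx(g, 2, 1), value = -1)), tol = 1e-10)
  ys <- axis_centers(g, 2)
  analytic <- -1 + (ys - ys[1]) / (ys[11] - ys[1]) * 2
  dev <- max(abs(sweep(aperm(pot$phi, c(2, 1, 3)), 1, analytic)))
  expect_lt(dev / 2, 1e-8)   # relative to the 2 V span

  # resistor formula: I = sigma * A * dV / L (plate-centre gap 10 mm)
  cur <- electrode_current(pot)
  expect_equal(cur$anode_mA, 0.4610 * 64e-6 * 2 / 10e-3 * 1e3, tolerance = 0.02)
  expect_lt(cur$imbalance, 1e-3)
})

test_that("point-electrode pair matches superposed point-source kernels within 5%", {
  n <- 91L
  g <- uniform_grid(c(n, n, n))
  ctr <- 46L
  src <- lin_idx(g, ctr - 8, ctr, ctr)
  snk <- lin_idx(g, ctr + 8, ctr, ctr)
  pot <- solve_potential(g, dirichlet = list(anode = list(idx = src, value = 1),
                                             cathode = list(idx = snk, value = -1)),
                         tol = 1e-9)
  I_A <- electrode_current(pot)$anode_mA * 1e-3
  ca <- grid_coord_arrays(g)
  r1 <- sqrt((ca$x - (ctr - 8 - 0.5))^2 + (ca$y - (ctr - 0.5))^2 + (ca$z - (ctr - 0.5))^2) * 1e-3
  r2 <- sqrt((ca$x - (ctr + 8 - 0.5))^2 + (ca$y - (ctr - 0.5))^2 + (ca$z - (ctr - 0.5))^2) * 1e-3
  oracle <- I_A / (4 * pi * 0.4610) * (1 / r1 - 1 / r2)
  near_bnd <- ca$x < 15 | ca$x > n - 15 | ca$y < 15 | ca$y > n - 15 |
              ca$z < 15 | ca$z > n - 15
  sel <- r1 > 3e-3 & r2 > 3e-3 & (r1 < 7e-3 | r2 < 7e-3) & !near_bnd
  relerr <- abs(pot$phi[sel] - oracle[sel]) / abs(oracle[sel])
  expect_gt(sum(sel), 1000)
  expect_lt(max(relerr), 0.05)
})

test_that("potential extrema stay within the Dirichlet values and scaling is exact", {
  g <- uniform_grid(c(15, 15, 15))
  d1 <- list(anode = list(idx = lin_idx(g, 4, 8, 8), value = 2.38),
             cathode = list(idx = lin_idx(g, 12, 8, 8), value = -2.38))
  pot <- solve_potential(g, dirichlet = d1, tol = 1e-10)
  expect_gte(min(pot$phi), -2.38)
  expect_lte(max(pot$phi), 2.38)
  I1 <- electrode_current(pot)$anode_mA
  expect_true(is.finite(I1) && I1 > 0)

  # doubling both voltages doubles the current (superposition / linearity)
  d2 <- list(anode = list(idx = d1$anode$idx, value = 4.76),
             cathode = list(idx = d1$cathode$idx, value = -4.76))
  I2 <- electrode_current(solve_potential(g, dirichlet = d2, tol = 1e-10))$anode_mA
  expect_lt(abs(I2 - 2 * I1) / I2, 1e-9)

  # solution invariant under a tighter solver tolerance
  pot2 <- solve_potential(g, dirichlet = d1, tol = 1e-12)
  expect_lt(max(abs(pot2$phi - pot$phi)) / 4.76, 1e-6)
})

test_that("degenerate Dirichlet configurations are rejected with clear errors", {
  g <- uniform_grid(c(6, 6, 6))
  expect_error(solve_potential(g, dirichlet = list(
    a = list(idx = lin_idx(g, 2, 2, 2), value = 1),
    b = list(idx = lin_idx(g, 4, 4, 4), value = 1))), "single voltage")
  # disconnected: air plane splits the block
  lab <- g$label; lab[, , 3] <- tissue_codes()[["air"]]
  g2 <- voxel_grid(lab, 1)
  expect_error(solve_potential(g2, dirichlet = list(
    a = list(idx = lin_idx(g2, 2, 2, 1), value = 1),
    b = list(idx = lin_idx(g2, 2, 2, 6), value = -1))), "not connected")
  expect_error(solve_potential(g), "Dirichlet")
})

test_that("electric_field recovers uniform and slab gradients with the mm-to-m factor", {
  g <- uniform_grid(c(9, 9, 9))
  ca <- grid_coord_arrays(g)
  # phi = x with x in m: x_mm * 1e-3 -> |E| = 1 V/m
  ef <- electric_field(fake_potential(ca$x * 1e-3, g))
  expect_equal(unname(ef$Ex[3, 3, 3]), -1, tolerance = 1e-12)
  expect_equal(max(abs(ef$magnitude - 1)), 0, tolerance = 1e-12)

  # parallel-plate slab: |E| = dV / L everywhere inside
  gs <- uniform_grid(c(6, 9, 6))
  pot <- solve_potential(gs, dirichlet = list(
    anode = list(idx = plate_idx(gs, 2, 9), value = 1.5),
    cathode = list(idx = plate_idx(gs, 2, 1), value = -1.5)), tol = 1e-11)
  efs <- electric_field(pot)
  expect_equal(max(abs(efs$magnitude[, 2:8, ] - 3 / 8e-3)) / (3 / 8e-3), 0,
               tolerance = 1e-7)
  # magnitude is the Euclidean norm everywhere
  expect_equal(efs$magnitude, sqrt(efs$Ex^2 + efs$Ey^2 + efs$Ez^2))
})

test_that("point-source |E| decays as r^-2 on a log-log regression", {
  n <- 41L
  g <- uniform_grid(c(n, n, n))
  ca <- grid_coord_arrays(g)
  ctr <- 20.5
  r <- pmax(sqrt((ca$x - ctr)^2 + (ca$y - ctr)^2 + (ca$z - ctr)^2), 0.5) * 1e-3
  ef <- electric_field(fake_potential(1e-4 / r, g))
  iy <- 24:31  # r = 3..10 voxels along +y from the centre voxel
  rmm <- axis_centers(g, 2)[iy] - ctr
  slope <- unname(coef(lm(log(ef$magnitude[21, iy, 21]) ~ log(rmm)))[2])
  expect_gte(slope, -2.1)
  expect_lte(slope, -1.9)
})

test_that("scale_to_current is an exact linear rescaling", {
  g <- uniform_grid(c(10, 10, 10))
  pot <- solve_potential(g, dirichlet = list(
    anode = list(idx = lin_idx(g, 3, 5, 5), value = 1),
    cathode = list(idx = lin_idx(g, 8, 5, 5), value = -1)), tol = 1e-10)
  I <- electrode_current(pot)$anode_mA
  same <- scale_to_current(pot, I)
  expect_lt(max(abs(same$phi - pot$phi)) / max(abs(pot$phi)), 1e-12)
  twice <- scale_to_current(pot, 2 * I)
  ef1 <- electric_field(pot); ef2 <- electric_field(twice)
  expect_equal(max(ef2$magnitude), 2 * max(ef1$magnitude))

  # ratio of the two printed drive currents propagates exactly to max |E|
  a <- scale_to_current(pot, 19.7); b <- scale_to_current(pot, 1.75)
  expect_equal(max(electric_field(a)$magnitude) / max(electric_field(b)$magnitude),
               19.7 / 1.75, tolerance = 1e-12)
  expect_error(scale_to_current(fake_potential(array(0, dim = c(3, 3, 3)),
                                               uniform_grid(c(3, 3, 3))), 5))
})

test_that("phantom electrode current is grid-refinement consistent within 10%", {
  mk <- function(sp) {
    g <- build_phantom(radius_mm = 15, length_mm = 40, spacing_mm = sp, pad_mm = 4,
                       layers = c(skin = 1.5, sat = 3.5, muscle = 5))
    g <- place_electrodes(g, default_montage(g, separation_mm = 16))
    electrode_current(solve_potential(g, tol = 1e-8))$anode_mA
  }
  I1 <- mk(1); I05 <- mk(0.5)
  expect_lt(abs(I1 - I05) / I05, 0.10)
})
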