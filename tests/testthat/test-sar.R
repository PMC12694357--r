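test_that("averaging-domain geometry reproduces the 10 g radius", {
  r <- averaging_radius(0.01, 1007, "sphere")
  expect_equal(0.01 / 1007, 9.93e-6, tolerance = 1e-3)
  expect_equal(r, 0.01333, tolerance = 1e-3)
  expect_equal(averaging_radius(0.01, 1007, "hemisphere"), 0.01680,
               tolerance = 1e-3)
  # cube-root density scaling: 8x the density halves the spherical radius
  expect_equal(averaging_radius(0.01, 8 * 1007, "sphere"), r / 2)
  expect_error(averaging_radius(0, 1007), "> 0")
})

test_that("Biot-Savart fields match loop closed forms and scale linearly", {
  loop <- coil_spec(n_turns = 1, radius = 0.01, segments_per_turn = 64)
  ctr <- matrix(c(0, 0, 0), 1)
  B <- coil_bfield(loop, 1, ctr)
  b_ref <- MU0_test() * 1 / (2 * 0.01)
  expect_lt(abs(B[1, 3] - b_ref) / b_ref, 1e-3)  # 0.1% at 64 segments

  # far-field dipole decay: log-log slope -3 within 0.05
  z <- c(0.5, 1, 2)
  bz <- vapply(z, function(zz)
    coil_bfield(loop, 1, matrix(c(0, 0, zz), 1))[1, 3], 0)
  slopes <- diff(log(bz)) / diff(log(z))
  expect_true(all(abs(slopes + 3) < 0.05))

  # linearity in current, for both A and B
  pts <- matrix(c(0.02, 0.01, 0.005), 1)
  expect_equal(coil_vector_potential(loop, 2, pts),
               2 * coil_vector_potential(loop, 1, pts))
  expect_equal(coil_bfield(loop, 2, pts), 2 * coil_bfield(loop, 1, pts))

  # the loop vector potential vanishes on the symmetry axis
  A <- coil_vector_potential(loop, 1, matrix(c(0, 0, 0.005), 1))
  expect_lt(sqrt(sum(A^2)), 1e-15)

  # wire-radius exclusion zone
  on_wire <- matrix(c(0.01, 0, 0), 1)
  expect_error(coil_vector_potential(loop, 1, on_wire), "exclusion")
  expect_silent(coil_vector_potential(loop, 1, on_wire, on_wire = "clamp"))
})

test_that("induced E-field is linear in frequency and vanishes at DC", {
  a <- c(0, 1e-9, 3e-8)
  expect_equal(induced_efield(a, 0), c(0, 0, 0))
  expect_equal(induced_efield(a, 2e6), 2 * induced_efield(a, 1e6))
  expect_equal(induced_efield(1, 1.35e6), 2 * pi * 1.35e6)
  expect_error(induced_efield(a, -1), "frequency")
})

test_that("pointwise SAR applies sigma |E|^2 / rho per labelled voxel", {
  toy <- toy_sar_phantom(n = 2, spacing = 0.01)
  e <- array(10, dim = toy$dims)
  sar <- pointwise_sar(e, toy)
  expect_equal(sar[1, 1, 1], 0.12 * 100 / 1050)  # brain values
  expect_equal(sar[1, 1, 1], 0.011429, tolerance = 1e-4)
  # photonics label
  toy$labels[1, 1, 1] <- 1L
  sar2 <- pointwise_sar(e, toy)
  expect_equal(sar2[1, 1, 1], 1e-5 * 100 / 1300)
  expect_equal(sar2[1, 1, 1], 7.69e-7, tolerance = 1e-3)
  # air is zero by definition, zero field gives zero
  toy$labels[2, 2, 2] <- 0L
  expect_equal(pointwise_sar(e, toy)[2, 2, 2], 0)
  expect_equal(pointwise_sar(array(0, toy$dims), toy)[1, 2, 1], 0)
})

test_that("mass averaging of a constant field is constant and bounded by the peak", {
  toy <- toy_sar_phantom(n = 8, spacing = 0.01)
  sar <- array(0.25, dim = toy$dims)
  ker <- averaging_kernel(shape = "sphere", adaptive = TRUE,
                          rho_ref = 1050, max_radius = 0.06)
  avg <- mass_averaged_sar(sar, toy, ker)
  expect_equal(max(avg$avg, na.rm = TRUE), 0.25)
  expect_equal(min(avg$avg, na.rm = TRUE), 0.25)
  # realized mass within one voxel mass above the target
  vm <- 1050 * 0.01^3
  expect_true(all(avg$realized_mass >= 0.01, na.rm = TRUE))
  expect_true(all(avg$realized_mass < 0.01 + vm + 1e-12, na.rm = TRUE))

  # delta source: peak equals hot-voxel mass over the realized kernel mass
  sar2 <- array(0, dim = toy$dims); sar2[4, 4, 4] <- 1
  avg2 <- mass_averaged_sar(sar2, toy, ker)
  expect_equal(avg2$peak, vm / avg2$realized_mass[4, 4, 4])
  expect_equal(avg2$peak, vm / 0.01, tolerance = vm / 0.01)
  expect_equal(avg2$avg[4, 4, 4], avg2$peak)  # hot voxel attains the peak
  # averaged peak never exceeds the pointwise peak
  expect_lte(avg2$peak, max(sar2))
})

test_that("production mass averaging equals the brute-force oracle exactly", {
  set.seed(123)
  for (n in c(8, 16)) {
    spacing <- 0.005
    toy <- toy_sar_phantom(n = n, spacing = spacing)
    # carve some air pockets so the air-excluding path is exercised
    toy$labels[1:2, 1:2, 1:2] <- 0L
    toy$labels[n, n, ] <- 0L
    sar <- array(runif(n^3), dim = toy$dims)
    sar[toy$labels == 0L] <- 0
    mass <- voxel_mass(toy)
    tis <- tissue_mask(toy)
    target <- 40 * 1050 * spacing^3  # ~40 voxel masses
    for (shape in c("sphere", "hemisphere")) {
      for (adaptive in c(TRUE, FALSE)) {
        ker <- averaging_kernel(target_mass = target, shape = shape,
                                adaptive = adaptive, rho_ref = 1050,
                                radius = 4.2 * spacing,
                                max_radius = 8.2 * spacing)
        got <- mass_averaged_sar(sar, toy, ker)
        want <- oracle_mass_avg(sar, mass, tis, toy$spacing, target,
                                shape = shape, axis = ker$axis,
                                adaptive = adaptive, radius = ker$radius,
                                max_radius = ker$max_radius)
        expect_equal(got$avg, want$avg, tolerance = 0)
        expect_equal(got$realized_mass, want$realized_mass, tolerance = 0)
      }
    }
  }
})

test_that("adaptive sphere equals the fixed sphere deep inside homogeneous tissue", {
  n <- 16; spacing <- 0.005
  toy <- toy_sar_phantom(n = n, spacing = spacing)
  set.seed(4)
  sar <- array(runif(n^3), dim = toy$dims)
  vm <- 1050 * spacing^3
  # fixed radius of 3 voxels holds 123 voxel centers; match the adaptive
  # target to exactly that mass so both kernels cover the same voxel set
  offs <- expand.grid(-3:3, -3:3, -3:3)
  n_in <- sum(rowSums(offs^2) <= 9)
  target <- (n_in - 0.5) * vm  # reached after exactly n_in voxels
  ker_f <- averaging_kernel(target_mass = target, shape = "sphere",
                            adaptive = FALSE, radius = 3 * spacing + 1e-9)
  ker_a <- averaging_kernel(target_mass = target, shape = "sphere",
                            adaptive = TRUE, max_radius = 10 * spacing)
  fa <- mass_averaged_sar(sar, toy, ker_f)
  aa <- mass_averaged_sar(sar, toy, ker_a)
  interior <- 8 # > 3 voxels from every boundary
  expect_equal(aa$avg[interior, interior, interior],
               fa$avg[interior, interior, interior])
})

test_that("SAR scales with the square of the drive current", {
  cfg <- phantom_3d_config(brain_radius = 0.02, shell_thickness = 0.004,
                           device_size = c(0.006, 0.006, 0.006),
                           spacing = 0.004, margin = 0.004)
  ph <- make_phantom_3d(cfg)
  coil <- coil_spec(n_turns = 2, radius = 0.002, segments_per_turn = 16)
  pts <- voxel_centers(ph)
  a1 <- coil_vector_potential(coil, 0.01, pts, center = ph$coil_center,
                              axis = ph$coil_axis, on_wire = "clamp")
  a2 <- coil_vector_potential(coil, 0.02, pts, center = ph$coil_center,
                              axis = ph$coil_axis, on_wire = "clamp")
  e1 <- array(induced_efield(sqrt(rowSums(a1^2)), 1.35e6), ph$dims)
  e2 <- array(induced_efield(sqrt(rowSums(a2^2)), 1.35e6), ph$dims)
  s1 <- pointwise_sar(e1, ph)
  s2 <- pointwise_sar(e2, ph)
  expect_equal(s2, 4 * s1)
})

test_that("compliance report compares the averaged peak against the limit", {
  toy <- toy_sar_phantom(n = 8, spacing = 0.01)
  toy$labels[, , 1] <- 2L  # give the report a non-empty head shell
  ker <- averaging_kernel(shape = "sphere", adaptive = TRUE,
                          rho_ref = 1050, max_radius = 0.06)
  sar_lo <- array(0.5, dim = toy$dims)
  rep_lo <- sar_report(sar_lo, mass_averaged_sar(sar_lo, toy, ker), toy)
  expect_true(all(rep_lo$pass))
  expect_equal(rep_lo$avg_sar, c(0.5, 0.5))
  expect_equal(rep_lo$max_avg_sar, c(0.5, 0.5))
  expect_true(all(rep_lo$max_avg_sar >= rep_lo$avg_sar - 1e-12))

  sar_hi <- array(3, dim = toy$dims)
  rep_hi <- sar_report(sar_hi, mass_averaged_sar(sar_hi, toy, ker), toy)
  expect_false(any(rep_hi$pass))

  # insufficient tissue anywhere -> error from the adaptive kernel
  tiny <- toy_sar_phantom(n = 3, spacing = 0.002)
  expect_error(mass_averaged_sar(array(1, tiny$dims), tiny,
                                 averaging_kernel(max_radius = 0.004)),
               "insufficient tissue mass")
})
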