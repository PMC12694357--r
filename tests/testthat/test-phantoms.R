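test_that("default 2D phantom has the packaged four-layer geometry", {
  ph <- make_phantom_2d()
  expect_length(ph$layers, 4L)
  expect_equal(ph$boundaries_mm, c(0, 0.8, 1.3, 3.8, 7.3))
  expect_equal(phantom_depth(ph), 7.3)
  expect_true(is.infinite(ph$curvature_radius_mm))
  # vessel sits inside the gray-matter layer [1.3, 3.8] mm
  v <- ph$vessel
  expect_true(v$center_depth_mm - v$diameter_mm / 2 >= 1.3)
  expect_true(v$center_depth_mm + v$diameter_mm / 2 <= 3.8)
})

test_that("2D generator rejects geometric violations", {
  expect_error(
    make_phantom_2d(phantom_2d_config(vessel = vessel_spec(
      center_depth_mm = 2.5, diameter_mm = 3))),
    "exceeds")
  expect_error(
    make_phantom_2d(phantom_2d_config(vessel = vessel_spec(
      center_depth_mm = 1.4, diameter_mm = 0.5))),
    "inside the gray-matter layer")
  expect_error(
    make_phantom_2d(phantom_2d_config(vessel = vessel_spec(
      center_x_mm = 6))),
    "lateral")
  expect_error(vessel_spec(diameter_mm = 0), "diameter")
})

test_that("3D phantom mass and refinement behave consistently", {
  cfg <- phantom_3d_config()
  ph <- make_phantom_3d(cfg)
  analytic_mass <- (2/3) * pi * cfg$brain_radius^3 * cfg$props$brain$rho
  expect_lt(abs(region_mass(ph, "brain") - analytic_mass) / analytic_mass,
            0.05)
  expect_gt(region_mass(ph, "head"), 0)
  expect_gt(region_mass(ph, "photonics"), 0)
  # labels partition the grid
  expect_true(all(ph$labels %in% 0:3))

  # refinement consistency on a smaller geometry: halve the spacing and
  # compare the brain label against the coarse labels upsampled 2x
  cfg_c <- phantom_3d_config(brain_radius = 0.03, shell_thickness = 0.004,
                             device_size = c(0.006, 0.006, 0.006),
                             spacing = 0.004, margin = 0.004)
  cfg_f <- cfg_c; cfg_f$spacing <- cfg_c$spacing / 2
  coarse <- make_phantom_3d(cfg_c)
  fine <- make_phantom_3d(cfg_f)
  expect_equal(prod(fine$dims) / prod(coarse$dims), 8)
  up <- coarse$labels[rep(seq_len(coarse$dims[1]), each = 2),
                      rep(seq_len(coarse$dims[2]), each = 2),
                      rep(seq_len(coarse$dims[3]), each = 2)]
  a <- up == 3; b <- fine$labels == 3
  dice <- 2 * sum(a & b) / (sum(a) + sum(b))
  expect_gt(dice, 0.95)

  # no tissue at all -> error
  expect_error(make_phantom_3d(phantom_3d_config(brain_radius = 1e-4,
                                                 shell_thickness = 1e-4,
                                                 spacing = 0.05)),
               "no tissue")
})

test_that("fixture generation is deterministic and oracle-consistent", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- make_fixtures(d1, seed = 11)
  m2 <- make_fixtures(d2, seed = 11)
  expect_gte(nrow(m1), 6L)
  expect_identical(m1$md5, m2$md5)
  expect_true(all(file.exists(file.path(d1, m1$path))))
  expect_true(file.exists(file.path(d1, "manifest.json")))

  # stored toy mass-averaging example matches a brute-force recomputation
  toy_meta <- jsonlite::read_json(file.path(d1, "toy_sar_example.json"),
                                  simplifyVector = TRUE)
  toy <- toy_sar_phantom(n = toy_meta$n, spacing = toy_meta$spacing_m)
  sar <- array(0, dim = toy$dims)
  sar[toy_meta$hot_voxel[1], toy_meta$hot_voxel[2], toy_meta$hot_voxel[3]] <-
    toy_meta$sar_hot
  orc <- oracle_mass_avg(sar, voxel_mass(toy), tissue_mask(toy),
                         toy$spacing, toy_meta$target_mass_kg,
                         shape = "sphere", adaptive = TRUE,
                         max_radius = 0.06)
  expect_equal(max(orc$avg, na.rm = TRUE), toy_meta$expected_peak)
  hv <- toy_meta$hot_voxel
  expect_equal(orc$realized_mass[hv[1], hv[2], hv[3]],
               toy_meta$expected_realized_mass_at_peak)
})
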