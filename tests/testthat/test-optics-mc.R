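test_that("ballistic passage through a transparent slab is exact", {
  ph <- slab_phantom(mua_per_m = 0, mus_per_m = 0)
  res <- mc_simulate(ph, source_spec(n_sources = 1, incidence_deg = 0),
                     cfg = mc_config(n_photons = 1000, seed = 2))
  expect_identical(res$transmittance, 1)
  expect_identical(res$R, 0)
  expect_identical(res$absorbed, 0)
  expect_identical(res$closure_residual, 0)
})

test_that("absorption-only slabs agree with the Beer-Lambert closed form", {
  # transmission of an absorption-only slab is exp(-mua * L); check three
  # optical depths at n = 1e5 within 3 binomial standard errors
  src <- source_spec(n_sources = 1, incidence_deg = 0)
  n <- 1e5
  for (tau in c(0.5, 1, 2)) {
    ph <- slab_phantom(mua_per_m = tau * 1000, thickness_mm = 1)
    res <- mc_simulate(ph, src, cfg = mc_config(n_photons = n, seed = 97))
    expected <- exp(-tau)
    se <- sqrt(expected * (1 - expected) / n)
    expect_lt(abs(res$transmittance - expected), 3 * se)
    expect_lt(abs(res$closure_residual), 1e-9)
  }
})

test_that("energy closure holds to bookkeeping precision with scattering on", {
  ph <- make_phantom_2d() # full layered phantom with vessel
  res <- mc_simulate(ph, source_spec(),
                     cfg = mc_config(n_photons = 2e4, seed = 5, g = 0.9))
  expect_lt(abs(res$closure_residual), 1e-9)
  expect_true(all(res$absorption_map >= 0))
  expect_true(res$R >= 0 && res$transmittance >= 0 && res$side_escape >= 0)
})

test_that("identical seeds give bitwise-identical Monte Carlo results", {
  ph <- slab_phantom(mua_per_m = 1000, mus_per_m = 5000, thickness_mm = 2)
  cfg <- mc_config(n_photons = 5000, seed = 31, g = 0)
  a <- mc_simulate(ph, source_spec(), cfg = cfg)
  b <- mc_simulate(ph, source_spec(), cfg = cfg)
  expect_identical(a$R, b$R)
  expect_identical(a$absorption_map, b$absorption_map)
  expect_gt(a$r_diffuse, 0)
  c <- mc_simulate(ph, source_spec(), cfg = mc_config(n_photons = 5000,
                                                      seed = 32, g = 0))
  expect_false(identical(a$R, c$R))
})

test_that("scattering-free layered MC with deep mirror matches the analytic model", {
  layers <- list(
    a = tissue_optical_props("a", 1.0, mua = 200, mus = 0, thickness = 1),
    b = tissue_optical_props("b", 1.0, mua = 500, mus = 0, thickness = 2))
  ph <- make_phantom_2d(phantom_2d_config(layers = layers, vessel = NULL,
                                          width_mm = 60))
  src <- source_spec(n_sources = 1, incidence_deg = 20)
  ana <- analytic_reflectance(ph, src, s_alb = 1)
  n <- 1e5
  res <- mc_simulate(ph, src, cfg = mc_config(n_photons = n, seed = 13,
                                              g = 0, bottom_albedo = 1))
  se <- sqrt(ana * (1 - ana) / n)
  expect_lt(abs(res$R - ana), 3 * se)
})

test_that("penetration depth summarizes the cumulative absorption profile", {
  # all absorption in the first (surface) row
  m <- matrix(0, 10, 5); m[1, ] <- 1
  expect_lte(penetration_depth(m, dy_mm = 0.2), 0.2)
  # uniform absorption over depth D gives 0.9 D
  u <- matrix(1, 50, 4)
  expect_equal(penetration_depth(u, dy_mm = 0.1), 0.9 * 50 * 0.1)
  # two bins with a known split: 70% then 30%; 0.9 crossing sits 2/3 into
  # the second bin
  b <- matrix(c(0.7, 0.3), 2, 1)
  expect_equal(penetration_depth(b, dy_mm = 1), 1 + (0.9 - 0.7) / 0.3)
  expect_error(penetration_depth(matrix(0, 3, 3), dy_mm = 1), "zero total")
})

test_that("reflectance time series responds to blood-volume modulation", {
  ph <- make_phantom_2d()
  src <- source_spec(lambda_nm = 660)
  w <- pressure_waveform(dt = 0.05)
  # beta = 0: constant analytic series
  bs0 <- blood_state_series(sample_waveform(w), modulation_model(beta = 0))
  s0 <- reflectance_timeseries(ph, src, blood_series = bs0)
  expect_equal(diff(range(s0$R)), 0)

  # two-state toy: hand-computed Beer-Lambert difference
  mu <- blood_mua(default_hemoglobin_spectrum(), 660, blood_state(so2 = 0.97))
  base <- analytic_reflectance(make_phantom_2d(
    phantom_2d_config(vessel = NULL)), src)
  toy <- data.frame(t_s = c(0.5, 1.0), pressure_norm = c(0, 0),
                    volume_fraction = c(0.05, 0.055), so2 = 0.97)
  s2 <- reflectance_timeseries(ph, src, blood_series = toy)
  hand <- base * (exp(-1.64 * (0.05 / 0.05) * mu) -
                  exp(-1.64 * (0.055 / 0.05) * mu))
  expect_equal(s2$R[1] - s2$R[2], hand)

  # MC engine: bitwise-stable across reruns under the same master seed
  bs <- blood_state_series(sample_waveform(pressure_waveform(dt = 0.5)))
  cfg <- mc_config(n_photons = 2000, seed = 77, g = 0.9)
  m1 <- reflectance_timeseries(ph, src, blood_series = bs, engine = "mc",
                               cfg = cfg)
  m2 <- reflectance_timeseries(ph, src, blood_series = bs, engine = "mc",
                               cfg = cfg)
  expect_identical(m1$R, m2$R)
})
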