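test_that("delta_r is the max-min over the pulsatile window", {
  s <- reflectance_series(660, c(0.6, 0.8, 1.0), c(0.30, 0.35, 0.32))
  expect_equal(delta_r(s), 0.05)
  flat <- reflectance_series(660, c(0.6, 0.8), c(0.4, 0.4))
  expect_equal(delta_r(flat), 0)
  # ramp samples are excluded by the default window
  ramp <- reflectance_series(660, c(0.1, 0.7, 0.9), c(0.9, 0.31, 0.30))
  expect_equal(delta_r(ramp), 0.01)
  expect_error(delta_r(s, window = c(2, 3)), "empty")
})

test_that("theoretical delta-R follows the two-state Beer-Lambert form", {
  ph <- make_phantom_2d()
  m <- modulation_model(f0 = 0.05, beta = 0.15)
  w <- pressure_waveform(alpha = 1/3)
  expect_equal(delta_r_theoretical(default_hemoglobin_spectrum(), ph,
                                   modulation_model(beta = 0), 660,
                                   waveform = w), 0)
  # brute-force evaluation of the two volume-fraction extremes
  mu <- blood_mua(default_hemoglobin_spectrum(), 660, blood_state(so2 = 0.97))
  base <- analytic_reflectance(
    make_phantom_2d(phantom_2d_config(vessel = NULL)),
    source_spec(lambda_nm = 660))
  f_lo <- 0.05 * (1 - 0.15 * (2/3))
  f_hi <- 0.05 * (1 + 0.15 * (2/3))
  hand <- base * abs(exp(-1.64 * (f_lo / 0.05) * mu) -
                     exp(-1.64 * (f_hi / 0.05) * mu))
  expect_equal(delta_r_theoretical(default_hemoglobin_spectrum(), ph, m, 660,
                                   waveform = w), hand)
  # identical species columns make delta-R_J independent of so2
  fs <- flat_spectrum(0.6)
  d1 <- delta_r_theoretical(fs, ph, m, 550, waveform = w, so2 = 0.1)
  d2 <- delta_r_theoretical(fs, ph, m, 550, waveform = w, so2 = 0.9)
  expect_equal(d1, d2)
})

test_that("analytic per-wavelength delta-R equals its theoretical counterpart", {
  scan <- spectral_scan(make_phantom_2d(),
                        lambdas_nm = seq(600, 800, by = 10))
  expect_equal(scan$delta_r_sim, scan$delta_r_J, tolerance = 1e-12)
  agree <- compare_sim_vs_theory(band_analysis(scan,
                                               bands = list(c(600, 800))))
  expect_lt(agree$max_abs_dev, 1e-12)
})

test_that("band analysis selects 660 nm in the red band under defaults", {
  scan <- spectral_scan(make_phantom_2d())
  ba <- band_analysis(scan)
  expect_length(ba, 3L)
  expect_equal(ba[[3]]$band, c(600, 800))
  expect_equal(ba[[3]]$argmax_wavelength, 660)
})

test_that("band behaviour is qualitatively consistent with hemoglobin absorption", {
  scan <- spectral_scan(make_phantom_2d())
  ba <- band_analysis(scan)
  mean_r_green <- mean(ba[[2]]$mean_R)            # 500-600 nm
  mean_r_red <- mean(ba[[3]]$mean_R)              # 600-800 nm
  expect_lt(mean_r_green, mean_r_red)
  # delta-R in 400-500 nm exceeds delta-R in 700-800 nm
  nir <- scan$lambdas_nm >= 700 & scan$lambdas_nm <= 800
  expect_gt(max(ba[[1]]$delta_r_sim), max(scan$delta_r_sim[nir]))
})

test_that("delta-R vanishes monotonically as the modulation shrinks", {
  ph <- make_phantom_2d()
  betas <- c(0, 0.02, 0.05, 0.1, 0.15)
  dr <- vapply(betas, function(b)
    delta_r_theoretical(default_hemoglobin_spectrum(), ph,
                        modulation_model(f0 = 0.05, beta = b), 660), 0)
  expect_equal(dr[1], 0)
  expect_true(all(diff(dr) > 0))
})

test_that("band bookkeeping: ties, single bands and mismatches", {
  ph <- make_phantom_2d()
  # single-wavelength band: that wavelength is trivially the argmax
  scan <- spectral_scan(ph, lambdas_nm = c(660))
  one <- band_analysis(scan, bands = list(c(655, 665)))
  expect_equal(one[[1]]$argmax_wavelength, 660)
  # flat synthetic spectrum: all delta-R equal; tie broken to lowest lambda
  fscan <- spectral_scan(ph, spectrum = flat_spectrum(0.5),
                         lambdas_nm = seq(600, 700, by = 10))
  expect_equal(diff(range(fscan$delta_r_sim)), 0)
  fb <- band_analysis(fscan, bands = list(c(600, 700)))
  expect_equal(fb[[1]]$argmax_wavelength, 600)
  # empty band errors
  expect_error(band_analysis(fscan, bands = list(c(100, 200))),
               "no wavelengths")
  expect_error(compare_sim_vs_theory(list(1, 2)), "band_summary")
})

test_that("band summaries export one row per wavelength", {
  scan <- spectral_scan(make_phantom_2d())
  ba <- band_analysis(scan)
  p <- withr::local_tempfile(fileext = ".csv")
  write_band_summaries(ba, p)
  tab <- read.csv(p)
  expect_identical(names(tab),
                   c("lambda_nm", "delta_r_sim", "delta_r_J", "mean_R",
                     "band"))
  expect_equal(nrow(tab), sum(vapply(ba, function(b)
    length(b$lambdas_nm), 0L)))
})
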