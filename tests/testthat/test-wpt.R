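test_that("LC resonance and capacitor back-calculation are exact inverses", {
  expect_equal(resonance_frequency(15e-6, 926.6e-12), 1.35e6,
               tolerance = 1e-4)
  expect_equal(resonance_frequency(15e-6, 100e-12), 4.109e6,
               tolerance = 1e-4)
  expect_equal(required_capacitance(15e-6, 1.35e6), 926.6e-12,
               tolerance = 1e-4)
  expect_equal(required_capacitance(15e-6, 4.109e6), 100e-12,
               tolerance = 1e-3)
  # quadrupling L halves f0
  expect_equal(resonance_frequency(60e-6, 100e-12),
               resonance_frequency(15e-6, 100e-12) / 2)
  # round-trip identity over random valid values
  set.seed(8)
  L <- 10^runif(20, -7, -3)
  f0 <- 10^runif(20, 4, 8)
  expect_equal(resonance_frequency(L, required_capacitance(L, f0)), f0)
  expect_error(resonance_frequency(0, 1e-10), "> 0")
  expect_error(required_capacitance(15e-6, -1), "> 0")
})

test_that("S11 spectrum dips at resonance with the ESR-set depth", {
  # esr equal to z0: perfect match at series resonance
  matched <- resonant_circuit(coil_spec(esr = 50), f_target = 1.35e6)
  f0 <- resonance_frequency(15e-6, matched$capacitance)
  expect_lt(Mod((circuit_impedance(matched, f0) - 50) /
                (circuit_impedance(matched, f0) + 50)), 1e-9)

  # default esr of 53.31 ohm: |S11| = 3.31 / 103.31 at resonance
  circ <- resonant_circuit(coil_spec(), f_target = 1.35e6)
  s11_res <- (circuit_impedance(circ, f0) - 50) /
    (circuit_impedance(circ, f0) + 50)
  expect_equal(Mod(s11_res), 3.31 / 103.31, tolerance = 1e-6)
  expect_equal(Mod(s11_res), 0.0320, tolerance = 2e-3)

  sp <- s11_spectrum(circ)
  expect_true(all(Mod(sp$s11) <= 1 + 1e-12))           # passivity
  expect_equal(sp$resonance_freq, 1.35e6, tolerance = 1e-3)
  expect_equal(sp$min_return_loss_db, 29.87, tolerance = 1e-2)

  # open/short limits
  lim <- s11_spectrum(circ, freqs = c(1, 1e12))
  expect_equal(Mod(lim$s11), c(1, 1), tolerance = 1e-3)

  # argmin converges to the closed-form resonance as the grid refines
  coarse <- s11_spectrum(circ, freqs = seq(1e6, 2e6, length.out = 101))
  fine <- s11_spectrum(circ, freqs = seq(1e6, 2e6, length.out = 100001))
  f_true <- resonance_frequency(15e-6, circ$capacitance)
  expect_lt(abs(fine$resonance_freq - f_true),
            abs(coarse$resonance_freq - f_true) + 1e-9)
  expect_lt(abs(fine$resonance_freq - f_true) / f_true, 1e-4)
})

test_that("return-loss algebra and delivered power match the design figures", {
  expect_equal(return_loss_db(0.0321), 29.87, tolerance = 1e-3)
  expect_equal(s11_from_return_loss(29.87), 0.0321, tolerance = 1e-3)
  expect_equal(return_loss_db(1), 0)
  db <- c(0.5, 3, 10, 29.87)
  expect_equal(return_loss_db(s11_from_return_loss(db)), db)
  expect_error(return_loss_db(0), "S11")
  expect_error(return_loss_db(1.2), "S11")

  expect_equal(delivered_power_fraction(0.0321), 1 - 0.0321^2)
  expect_gt(delivered_power_fraction(0.0321), 0.95)
  expect_equal(delivered_power_fraction(0), 1)
  expect_equal(delivered_power_fraction(1), 0)
  expect_error(delivered_power_fraction(1.5), "S11")
})

test_that("parallel-tank topology peaks in impedance near the target", {
  circ <- resonant_circuit(coil_spec(esr = 5), f_target = 1.35e6,
                           topology = "parallel")
  freqs <- seq(1.2e6, 1.5e6, length.out = 20001)
  zmag <- Mod(circuit_impedance(circ, freqs))
  expect_lt(abs(freqs[which.max(zmag)] - 1.35e6) / 1.35e6, 0.01)
})

test_that("Touchstone export writes a parseable one-port MA file", {
  circ <- resonant_circuit(coil_spec())
  sp <- s11_spectrum(circ, freqs = seq(1e6, 2e6, length.out = 11))
  p <- withr::local_tempfile(fileext = ".s1p")
  write_touchstone(sp, p)
  lines <- readLines(p)
  expect_true(any(grepl("^# Hz S MA R 50", lines)))
  dat <- read.table(text = lines[!grepl("^[!#]", lines)])
  expect_equal(nrow(dat), 11L)
  expect_equal(dat$V1, sp$freqs)
  expect_equal(dat$V2, Mod(sp$s11), tolerance = 1e-9)
})

test_that("the design report flags the inconsistent nominal capacitor", {
  d <- wpt_design(coil_spec(), f_target = 1.35e6,
                  nominal_capacitance = 100e-12)
  expect_equal(d$capacitance, 926.6e-12, tolerance = 1e-4)
  expect_false(d$nominal_consistent)
  expect_equal(d$nominal_resonance_freq, 4.109e6, tolerance = 1e-3)
  d2 <- wpt_design(coil_spec(), f_target = 1.35e6,
                   nominal_capacitance = d$capacitance)
  expect_true(d2$nominal_consistent)
  expect_gt(d$delivered_power_fraction, 0.95)
})
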