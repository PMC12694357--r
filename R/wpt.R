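# Resonant inductive wireless-power link: LC resonance, S11 return loss,
# delivered-power fraction and Touchstone export.

#' Receiving-coil specification
#'
#' Electrical (L, ESR) and geometric description of the implant's receiving
#' coil. The inductance is a stated design input (15 uH); the geometry
#' (turns, radius, pitch) feeds the Biot-Savart field computation and is
#' not used to recompute L. The default ESR of 53.31 ohm is a documented
#' calibration constant: against a 50 ohm reference it reproduces the
#' design's -29.87 dB resonance dip.
#'
#' @param inductance coil inductance L (H), default 15e-6.
#' @param esr effective series resistance (ohm), >= 0.
#' @param n_turns number of turns.
#' @param radius coil radius (m).
#' @param spacing axial turn pitch (m).
#' @param segments_per_turn polyline discretization for field evaluation.
#' @return An object of class `coil_spec`.
#' @export
coil_spec <- function(inductance = 15e-6, esr = 53.31, n_turns = 10,
                      radius = 4e-3, spacing = 2e-4, segments_per_turn = 64) {
  if (inductance <= 0) stop("inductance must be > 0")
  if (esr < 0) stop("esr must be >= 0")
  if (radius <= 0) stop("radius must be > 0")
  if (n_turns < 1 || segments_per_turn < 3)
    stop("need >= 1 turn and >= 3 segments per turn")
  structure(list(inductance = inductance, esr = esr, n_turns = n_turns,
                 radius = radius, spacing = spacing,
                 segments_per_turn = segments_per_turn),
            class = "coil_spec")
}

#' LC resonance frequency
#'
#' `f0 = 1 / (2*pi*sqrt(L*C))`.
#'
#' @param L inductance (H), > 0.
#' @param C capacitance (F), > 0.
#' @return Resonance frequency (Hz).
#' @export
resonance_frequency <- function(L, C) {
  if (any(L <= 0) || any(C <= 0)) stop("L and C must be > 0")
  1 / (2 * pi * sqrt(L * C))
}

#' Capacitance required for a target resonance
#'
#' Algebraic inverse of [resonance_frequency()]:
#' `C = 1 / (L * (2*pi*f0)^2)`.
#'
#' @param L inductance (H), > 0.
#' @param f0 target resonance frequency (Hz), > 0.
#' @return Capacitance (F).
#' @export
required_capacitance <- function(L, f0) {
  if (any(L <= 0) || any(f0 <= 0)) stop("L and f0 must be > 0")
  1 / (L * (2 * pi * f0)^2)
}

#' Tuned resonant circuit
#'
#' Series R-L-C branch against a real reference impedance (default model:
#' the simplest circuit exhibiting the single-dip S11 of the link design).
#' A parallel-tank alternative (`topology = "parallel"`: C across the
#' R-L branch) is available. When `capacitance` is `NULL` it is
#' back-calculated from `f_target`.
#'
#' @param coil a [coil_spec()].
#' @param capacitance tuning capacitance (F), or `NULL` to back-calculate.
#' @param f_target target resonance (Hz), used when `capacitance` is `NULL`
#'   (default 1.35 MHz).
#' @param z0 reference impedance (ohm), default 50.
#' @param topology `"series"` (default) or `"parallel"`.
#' @return An object of class `resonant_circuit`.
#' @export
resonant_circuit <- function(coil = coil_spec(), capacitance = NULL,
                             f_target = 1.35e6, z0 = 50,
                             topology = c("series", "parallel")) {
  topology <- match.arg(topology)
  stopifnot(inherits(coil, "coil_spec"))
  if (z0 <= 0) stop("z0 must be > 0")
  if (is.null(capacitance))
    capacitance <- required_capacitance(coil$inductance, f_target)
  if (capacitance <= 0) stop("capacitance must be > 0")
  structure(list(coil = coil, capacitance = capacitance, z0 = z0,
                 topology = topology),
            class = "resonant_circuit")
}

#' @export
print.resonant_circuit <- function(x, ...) {
  f0 <- resonance_frequency(x$coil$inductance, x$capacitance)
  cat(sprintf(
    "<resonant_circuit> L=%.4g uH, C=%.4g pF, ESR=%.4g ohm (%s, z0=%g): f0=%.4g MHz\n",
    x$coil$inductance * 1e6, x$capacitance * 1e12, x$coil$esr, x$topology,
    x$z0, f0 / 1e6))
  invisible(x)
}

#' Input impedance of the tuned circuit
#' @param circuit a [resonant_circuit()].
#' @param freqs frequencies (Hz), > 0.
#' @return Complex impedance vector.
#' @export
circuit_impedance <- function(circuit, freqs) {
  stopifnot(inherits(circuit, "resonant_circuit"))
  if (any(freqs <= 0)) stop("frequencies must be > 0")
  w <- 2 * pi * freqs
  zl <- circuit$coil$esr + 1i * w * circuit$coil$inductance
  zc <- 1 / (1i * w * circuit$capacitance)
  if (circuit$topology == "series") zl + zc else (zl * zc) / (zl + zc)
}

#' S11 reflection spectrum of the tuned coil
#'
#' `S11(f) = (Z(f) - z0) / (Z(f) + z0)`; for a passive circuit
#' `|S11| <= 1`. The minimum of `|S11|` locates the resonance.
#'
#' @param circuit a [resonant_circuit()].
#' @param freqs frequency grid (Hz); default 0.5-3 MHz, 2001 linear points.
#' @return An object of class `s11_spectrum`: list with `freqs`, `s11`
#'   (complex), `s11_db` (return loss with sign, `20*log10|S11|`),
#'   `resonance_freq` (argmin |S11|), `min_s11_mag`, `min_return_loss_db`.
#' @export
s11_spectrum <- function(circuit,
                         freqs = seq(0.5e6, 3e6, length.out = 2001)) {
  z <- circuit_impedance(circuit, freqs)
  s11 <- (z - circuit$z0) / (z + circuit$z0)
  mag <- Mod(s11)
  i <- which.min(mag)
  structure(list(freqs = freqs, s11 = s11,
                 s11_db = 20 * log10(pmax(mag, .Machine$double.xmin)),
                 resonance_freq = freqs[i], min_s11_mag = mag[i],
                 min_return_loss_db = return_loss_db(max(mag[i], .Machine$double.xmin))),
            class = "s11_spectrum")
}

#' @export
print.s11_spectrum <- function(x, ...) {
  cat(sprintf(
    "<s11_spectrum> %d points, %.4g-%.4g MHz; dip |S11|=%.4g (RL %.4g dB) at %.4g MHz\n",
    length(x$freqs), min(x$freqs) / 1e6, max(x$freqs) / 1e6, x$min_s11_mag,
    x$min_return_loss_db, x$resonance_freq / 1e6))
  invisible(x)
}

#' Return loss in dB and its inverse
#'
#' `RL = -20 * log10(|S11|)`; the inverse maps a return loss back to
#' `|S11| = 10^(-RL/20)`.
#'
#' @param s11_magnitude reflection-coefficient magnitude in (0, 1\].
#' @return Return loss (dB), >= 0.
#' @export
return_loss_db <- function(s11_magnitude) {
  if (any(s11_magnitude <= 0) || any(s11_magnitude > 1))
    stop("|S11| must lie in (0, 1]")
  -20 * log10(s11_magnitude)
}

#' @rdname return_loss_db
#' @param db return loss (dB), >= 0.
#' @export
s11_from_return_loss <- function(db) {
  if (any(db < 0)) stop("return loss must be >= 0 dB")
  10^(-db / 20)
}

#' Fraction of incident power delivered past the port
#'
#' `1 - |S11|^2`.
#'
#' @param s11_magnitude reflection-coefficient magnitude in \[0, 1\].
#' @return Delivered power fraction in \[0, 1\].
#' @export
delivered_power_fraction <- function(s11_magnitude) {
  if (any(s11_magnitude < 0) || any(s11_magnitude > 1))
    stop("|S11| must lie in [0, 1]")
  1 - s11_magnitude^2
}

#' Write a one-port S-parameter file (Touchstone 1.0, MA format)
#'
#' @param spectrum an `s11_spectrum`.
#' @param path output `.s1p` path.
#' @param z0 reference impedance recorded in the option line.
#' @return `path`, invisibly.
#' @export
write_touchstone <- function(spectrum, path, z0 = 50) {
  stopifnot(inherits(spectrum, "s11_spectrum"))
  lines <- c(
    "! 1-port S-parameters (reflection coefficient of the tuned coil)",
    sprintf("# Hz S MA R %g", z0),
    sprintf("%.10g %.10g %.10g", spectrum$freqs, Mod(spectrum$s11),
            Arg(spectrum$s11) * 180 / pi))
  writeLines(lines, path)
  invisible(path)
}

#' Link design report
#'
#' Back-calculates the tuning capacitor for a target resonance, sweeps S11
#' and summarizes the link. Flags the nominal-capacitor inconsistency when
#' a `nominal_capacitance` is supplied whose resonance departs from the
#' target by more than 1%.
#'
#' @param coil a [coil_spec()].
#' @param f_target target resonance (Hz).
#' @param z0 reference impedance (ohm).
#' @param nominal_capacitance optional nominal capacitor value (F) to check
#'   against the back-calculated one.
#' @return List with the circuit, spectrum, back-calculated capacitance,
#'   resonance frequency, dip |S11|, return loss, delivered power fraction
#'   and (optionally) the nominal-capacitance consistency check.
#' @export
wpt_design <- function(coil = coil_spec(), f_target = 1.35e6, z0 = 50,
                       nominal_capacitance = NULL) {
  circuit <- resonant_circuit(coil, f_target = f_target, z0 = z0)
  spec <- s11_spectrum(circuit)
  out <- list(circuit = circuit, spectrum = spec,
              capacitance = circuit$capacitance,
              resonance_freq = resonance_frequency(coil$inductance,
                                                   circuit$capacitance),
              min_s11_mag = spec$min_s11_mag,
              min_return_loss_db = spec$min_return_loss_db,
              delivered_power_fraction = delivered_power_fraction(spec$min_s11_mag))
  if (!is.null(nominal_capacitance)) {
    f_nom <- resonance_frequency(coil$inductance, nominal_capacitance)
    out$nominal_capacitance <- nominal_capacitance
    out$nominal_resonance_freq <- f_nom
    out$nominal_consistent <- abs(f_nom - f_target) / f_target <= 0.01
  }
  out
}
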