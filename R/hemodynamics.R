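# Cardiac pressure waveform and its mapping to time-varying blood state.

#' Piecewise cardiac pressure waveform
#'
#' Normalized (dimensionless) blood-pressure drive over a 1.5 s window.
#' The first 0.5 s is a numerical ramp-up of no physiological meaning,
#' `P(t) = (1 - alpha) * sin(pi * (t - ramp_start))`; the pulsatile phase
#' (0.5-1.5 s) is `P(t) = (1 - alpha) * cos(2*pi * (t - pulse_start))`
#' (period 1.0 s as written), or a triangular wave of the same period and
#' amplitude when `shape = "triangle"`. `alpha` is the systolic fraction of
#' the cardiac cycle; its default 1/3 reflects systole occupying about a
#' third of the cycle. The two phases are continuous at the boundary
#' (sin(pi/2) = cos(0)) for every alpha.
#'
#' @param alpha systolic-fraction coefficient in (0, 1).
#' @param ramp_start,ramp_end ramp phase window (s).
#' @param pulse_start,pulse_end pulsatile phase window (s);
#'   `ramp_end` must equal `pulse_start`.
#' @param dt sampling step (s), > 0.
#' @param shape pulsatile phase shape, `"cosine"` (default) or `"triangle"`.
#' @return An object of class `pressure_waveform`.
#' @export
pressure_waveform <- function(alpha = 1/3, ramp_start = 0, ramp_end = 0.5,
                              pulse_start = 0.5, pulse_end = 1.5, dt = 0.01,
                              shape = c("cosine", "triangle")) {
  shape <- match.arg(shape)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (ramp_end != pulse_start) stop("ramp_end must equal pulse_start")
  if (!(ramp_start < ramp_end && pulse_start < pulse_end))
    stop("phase windows must be nonempty")
  if (dt <= 0) stop("dt must be > 0")
  structure(list(alpha = alpha, ramp_start = ramp_start, ramp_end = ramp_end,
                 pulse_start = pulse_start, pulse_end = pulse_end, dt = dt,
                 shape = shape),
            class = "pressure_waveform")
}

#' @export
print.pressure_waveform <- function(x, ...) {
  cat(sprintf(
    "<pressure_waveform> alpha=%.4g, ramp [%g, %g] s, pulse [%g, %g] s (%s), dt=%g s\n",
    x$alpha, x$ramp_start, x$ramp_end, x$pulse_start, x$pulse_end, x$shape,
    x$dt))
  invisible(x)
}

#' Evaluate the normalized pressure waveform
#'
#' @param t time(s) in seconds, within `[ramp_start, pulse_end]`.
#' @param w a [pressure_waveform()].
#' @return Normalized pressure value(s), bounded by `1 - alpha` in magnitude.
#' @export
pressure <- function(t, w = pressure_waveform()) {
  stopifnot(inherits(w, "pressure_waveform"))
  if (any(t < w$ramp_start - 1e-12 | t > w$pulse_end + 1e-12))
    stop(sprintf("t outside simulated window [%g, %g] s",
                 w$ramp_start, w$pulse_end))
  amp <- 1 - w$alpha
  ramp <- t < w$pulse_start
  out <- numeric(length(t))
  out[ramp] <- amp * sin(pi * (t[ramp] - w$ramp_start))
  tp <- t[!ramp] - w$pulse_start
  out[!ramp] <- if (w$shape == "cosine") {
    amp * cos(2 * pi * tp)
  } else {
    # triangular wave, period 1 s, max +amp at tp = 0, min -amp at tp = 0.5
    frac <- tp %% 1
    amp * (1 - 4 * pmin(frac, 1 - frac))
  }
  out
}

#' Sample the waveform over its full window
#'
#' Samples `[ramp_start, pulse_end]` at step `dt`; the endpoint is always
#' included, so a `dt` larger than the window still emits both endpoints.
#' At the phase boundary the two definitions agree, so a single sample is
#' emitted there.
#'
#' @param w a [pressure_waveform()].
#' @return data.frame with columns `t_s`, `pressure_norm`.
#' @export
sample_waveform <- function(w = pressure_waveform()) {
  stopifnot(inherits(w, "pressure_waveform"))
  t <- seq(w$ramp_start, w$pulse_end, by = w$dt)
  if (t[length(t)] < w$pulse_end) t <- c(t, w$pulse_end)
  data.frame(t_s = t, pressure_norm = pressure(t, w))
}

#' Pressure-to-blood-volume modulation model
#'
#' Maps the normalized pressure to a time-varying blood volume fraction:
#' `f(t) = f0 * (1 + beta * P(t))`. The pair (f0, beta) are calibration
#' constants of the package's optical coupling (defaults f0 = 0.05,
#' beta = 0.15).
#'
#' @param f0 baseline blood volume fraction in (0, 1\].
#' @param beta fractional modulation amplitude per unit normalized pressure.
#' @return An object of class `modulation_model`.
#' @export
modulation_model <- function(f0 = 0.05, beta = 0.15) {
  if (!(f0 > 0 && f0 <= 1)) stop("f0 must lie in (0, 1]")
  if (beta < 0) stop("beta must be >= 0")
  if (f0 * (1 + beta) > 1 || f0 * (1 - beta) < 0)
    stop("modulation drives volume fraction outside [0, 1]")
  structure(list(f0 = f0, beta = beta), class = "modulation_model")
}

#' Time series of blood states from a sampled waveform
#'
#' @param series data.frame from [sample_waveform()] (columns `t_s`,
#'   `pressure_norm`).
#' @param m a [modulation_model()].
#' @param so2 constant oxygen saturation for the whole series.
#' @return data.frame with columns `t_s`, `pressure_norm`, `volume_fraction`,
#'   `so2`.
#' @export
blood_state_series <- function(series, m = modulation_model(), so2 = 0.97) {
  stopifnot(inherits(m, "modulation_model"),
            all(c("t_s", "pressure_norm") %in% names(series)))
  f <- m$f0 * (1 + m$beta * series$pressure_norm)
  if (any(f < 0 | f > 1))
    stop("modulation drives volume fraction outside [0, 1]")
  data.frame(t_s = series$t_s, pressure_norm = series$pressure_norm,
             volume_fraction = f, so2 = so2)
}

#' Write a sampled waveform / blood-state series as columnar text
#'
#' @param series data.frame from [sample_waveform()] or
#'   [blood_state_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(series, path) {
  write.csv(series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
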