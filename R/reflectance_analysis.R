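# Delta-R metrics, spectral band summaries and optimal-wavelength selection.

#' Cardiac-cycle reflectance variation (delta-R)
#'
#' Max minus min reflectance over the pulsatile window. The ramp-up phase
#' is excluded by default (it carries no physiological meaning).
#'
#' @param series a [reflectance_series()].
#' @param window time window (s), default `c(0.5, 1.5)` (pulsatile phase).
#' @return delta-R >= 0. Errors on an empty window.
#' @export
delta_r <- function(series, window = c(0.5, 1.5)) {
  stopifnot(inherits(series, "reflectance_series"))
  keep <- series$times >= window[1] & series$times <= window[2]
  if (!any(keep)) stop("empty delta-R window")
  r <- series$R[keep]
  max(r) - min(r)
}

#' Theoretical reflectance variation (delta-R_J)
#'
#' Closed-form counterpart of [delta_r()]: the absolute difference of the
#' modified Beer-Lambert reflectance between the diastolic and systolic
#' blood-volume extremes of the pulsatile waveform,
#' `f0 * (1 -+ beta * (1 - alpha))`.
#'
#' @param spectrum a [hemoglobin_spectrum()].
#' @param phantom a `layered_phantom_2d` with a vessel.
#' @param modulation a [modulation_model()].
#' @param lambda_nm wavelength (nm).
#' @param waveform a [pressure_waveform()] (supplies the pressure amplitude
#'   `1 - alpha`).
#' @param so2 oxygen saturation.
#' @param s_alb,l_rt,f_ref analytic-model constants, see
#'   [analytic_reflectance()].
#' @return delta-R_J >= 0.
#' @export
delta_r_theoretical <- function(spectrum, phantom, modulation, lambda_nm,
                                waveform = pressure_waveform(), so2 = 0.97,
                                s_alb = 1, l_rt = 1.64, f_ref = 0.05) {
  stopifnot(inherits(modulation, "modulation_model"),
            inherits(waveform, "pressure_waveform"))
  amp <- 1 - waveform$alpha
  f_dia <- modulation$f0 * (1 - modulation$beta * amp)
  f_sys <- modulation$f0 * (1 + modulation$beta * amp)
  src <- source_spec(lambda_nm = lambda_nm)
  ph <- phantom
  ph$vessel$state <- blood_state(so2 = so2,
                                 volume_fraction = ph$vessel$state$volume_fraction)
  r_dia <- analytic_reflectance(ph, src, spectrum, s_alb = s_alb,
                                l_rt = l_rt, f_ref = f_ref,
                                volume_fraction = f_dia)
  r_sys <- analytic_reflectance(ph, src, spectrum, s_alb = s_alb,
                                l_rt = l_rt, f_ref = f_ref,
                                volume_fraction = f_sys)
  abs(r_dia - r_sys)
}

#' Scan the pulsatile reflectance across a wavelength grid
#'
#' Runs [reflectance_timeseries()] at every wavelength and pairs each
#' series with its theoretical delta-R_J.
#'
#' @param phantom a `layered_phantom_2d` with a vessel.
#' @param spectrum a [hemoglobin_spectrum()].
#' @param waveform a [pressure_waveform()].
#' @param modulation a [modulation_model()].
#' @param lambdas_nm wavelength grid (nm); default the spectrum's 10 nm
#'   grid.
#' @param so2 oxygen saturation.
#' @param engine `"analytic"` or `"mc"`.
#' @param source template [source_spec()] (its wavelength is overridden).
#' @param s_alb,l_rt,f_ref analytic-model constants.
#' @param cfg an [mc_config()] (MC engine only).
#' @return An object of class `reflectance_scan`: list with `lambdas_nm`,
#'   `series` (list of [reflectance_series()]), `delta_r_sim`,
#'   `delta_r_J`, `mean_R` (cycle-mean over the pulsatile window), `engine`.
#' @export
spectral_scan <- function(phantom, spectrum = default_hemoglobin_spectrum(),
                          waveform = pressure_waveform(),
                          modulation = modulation_model(),
                          lambdas_nm = spectrum$wavelengths_nm,
                          so2 = 0.97, engine = c("analytic", "mc"),
                          source = source_spec(),
                          s_alb = 1, l_rt = 1.64, f_ref = 0.05,
                          cfg = mc_config()) {
  engine <- match.arg(engine)
  bs <- blood_state_series(sample_waveform(waveform), modulation, so2 = so2)
  window <- c(waveform$pulse_start, waveform$pulse_end)
  series <- lapply(lambdas_nm, function(wl) {
    src <- source
    src$lambda_nm <- wl
    reflectance_timeseries(phantom, src, spectrum, bs, engine = engine,
                           s_alb = s_alb, l_rt = l_rt, f_ref = f_ref,
                           cfg = cfg)
  })
  in_win <- bs$t_s >= window[1] & bs$t_s <= window[2]
  structure(list(
    lambdas_nm = lambdas_nm,
    series = series,
    delta_r_sim = vapply(series, delta_r, 0, window = window),
    delta_r_J = vapply(lambdas_nm, function(wl)
      delta_r_theoretical(spectrum, phantom, modulation, wl,
                          waveform = waveform, so2 = so2, s_alb = s_alb,
                          l_rt = l_rt, f_ref = f_ref), 0),
    mean_R = vapply(series, function(s) mean(s$R[in_win]), 0),
    engine = engine, window = window),
    class = "reflectance_scan")
}

#' Per-band spectral summary of delta-R metrics
#'
#' Splits the scan into wavelength bands and summarizes each: per-wavelength
#' temporal delta-R (simulated) and theoretical delta-R_J, the band's
#' spectral range of cycle-mean reflectance (max - min across the band),
#' the wavelength maximizing temporal delta-R (ties broken toward the
#' lowest wavelength) and the wavelength minimizing cycle-mean reflectance.
#' Bands are half-open `[lo, hi)` except the last, which includes its upper
#' edge.
#'
#' @param scan a `reflectance_scan` from [spectral_scan()].
#' @param bands list of `c(lo, hi)` nm pairs; default the three standard
#'   bands 400-500, 500-600, 600-800 nm.
#' @return List of `band_summary` objects (fields `band`, `lambdas_nm`,
#'   `delta_r_sim`, `delta_r_J`, `mean_R`, `band_spectral_range`,
#'   `argmax_wavelength`, `argmin_mean_R`).
#' @export
band_analysis <- function(scan,
                          bands = list(c(400, 500), c(500, 600), c(600, 800))) {
  stopifnot(inherits(scan, "reflectance_scan"))
  lapply(seq_along(bands), function(bi) {
    b <- bands[[bi]]
    last <- bi == length(bands)
    keep <- scan$lambdas_nm >= b[1] &
      (if (last) scan$lambdas_nm <= b[2] else scan$lambdas_nm < b[2])
    if (!any(keep)) stop(sprintf("band [%g, %g] contains no wavelengths",
                                 b[1], b[2]))
    wl <- scan$lambdas_nm[keep]
    drs <- scan$delta_r_sim[keep]
    drj <- scan$delta_r_J[keep]
    mr <- scan$mean_R[keep]
    structure(list(
      band = b, lambdas_nm = wl,
      delta_r_sim = drs, delta_r_J = drj, mean_R = mr,
      band_spectral_range = max(mr) - min(mr),
      argmax_wavelength = wl[which.max(drs)],  # which.max: first = lowest wl
      argmin_mean_R = wl[which.min(mr)]),
      class = "band_summary")
  })
}

#' @export
print.band_summary <- function(x, ...) {
  cat(sprintf(
    "<band_summary> %g-%g nm: argmax dR at %g nm (dR=%.4g), min mean R at %g nm\n",
    x$band[1], x$band[2], x$argmax_wavelength, max(x$delta_r_sim),
    x$argmin_mean_R))
  invisible(x)
}

#' Agreement between simulated and theoretical delta-R
#'
#' @param summaries list of `band_summary` from [band_analysis()].
#' @return data.frame with one row per band: `band_lo`, `band_hi`,
#'   `max_abs_dev` and `max_rel_dev` between `delta_r_sim` and `delta_r_J`.
#' @export
compare_sim_vs_theory <- function(summaries) {
  if (!length(summaries) || !all(vapply(summaries, inherits, TRUE,
                                        "band_summary")))
    stop("expected a list of band_summary objects")
  do.call(rbind, lapply(summaries, function(s) {
    dev <- abs(s$delta_r_sim - s$delta_r_J)
    rel <- dev / pmax(abs(s$delta_r_J), .Machine$double.eps)
    data.frame(band_lo = s$band[1], band_hi = s$band[2],
               max_abs_dev = max(dev), max_rel_dev = max(rel))
  }))
}

#' Export band summaries as columnar text
#'
#' One row per wavelength with `lambda_nm, delta_r_sim, delta_r_J, mean_R,
#' band`.
#'
#' @param summaries list of `band_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_band_summaries <- function(summaries, path) {
  df <- do.call(rbind, lapply(summaries, function(s)
    data.frame(lambda_nm = s$lambdas_nm, delta_r_sim = s$delta_r_sim,
               delta_r_J = s$delta_r_J, mean_R = s$mean_R,
               band = sprintf("%g-%g", s$band[1], s$band[2]))))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
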