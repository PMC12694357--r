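# Monte Carlo configuration, simulation wrapper, penetration depth and the
# pulsatile reflectance time-series driver.

#' Monte Carlo engine configuration
#'
#' @param n_photons number of photon packets (>= 1).
#' @param seed RNG seed (R's RNG drives the C++ engine; identical seeds give
#'   bitwise-identical results).
#' @param g scattering anisotropy in \[-1, 1\] sampled from the 2D
#'   (wrapped) Henyey-Greenstein phase function; default 0.9.
#' @param weight_threshold packet weight below which Russian roulette is
#'   played (default 1e-4).
#' @param roulette_survival survival probability (default 0.1). Survivors
#'   are not re-amplified; a killed packet deposits its residual weight
#'   locally, keeping the energy ledger exact at the cost of a bias bounded
#'   by `weight_threshold`.
#' @param grid_spacing_mm absorption-map bin size (mm) in both axes.
#' @param bottom_albedo specular reflectivity of the deep boundary in
#'   \[0, 1\]. 0 (default) transmits; 1 realizes the double-pass
#'   modified Beer-Lambert geometry of [analytic_reflectance()].
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(n_photons = 10000, seed = 1, g = 0.9,
                      weight_threshold = 1e-4, roulette_survival = 0.1,
                      grid_spacing_mm = 0.1, bottom_albedo = 0) {
  if (n_photons < 1) stop("n_photons must be >= 1")
  if (g < -1 || g > 1) stop("anisotropy g must lie in [-1, 1]")
  if (weight_threshold < 0 || weight_threshold >= 1)
    stop("weight_threshold must lie in [0, 1)")
  if (roulette_survival <= 0 || roulette_survival > 1)
    stop("roulette_survival must lie in (0, 1]")
  if (grid_spacing_mm <= 0) stop("grid spacing must be > 0")
  if (bottom_albedo < 0 || bottom_albedo > 1)
    stop("bottom_albedo must lie in [0, 1]")
  structure(list(n_photons = as.integer(n_photons), seed = as.integer(seed),
                 g = g, weight_threshold = weight_threshold,
                 roulette_survival = roulette_survival,
                 grid_spacing_mm = grid_spacing_mm,
                 bottom_albedo = bottom_albedo),
            class = "mc_config")
}

#' Effective vessel absorption coefficient per mm
#'
#' Unit bridge between the normalized blood exponent of the analytic model
#' and the geometric mm scale of the Monte Carlo phantom: the vessel medium
#' is given the per-mm absorption that accumulates the normalized exponent
#' `l_rt * (f/f_ref) * mua_blood` over a normal-incidence double pass
#' through the vessel diameter.
#'
#' @param spectrum a [hemoglobin_spectrum()].
#' @param lambda_nm wavelength (nm).
#' @param state a [blood_state()].
#' @param diameter_mm vessel diameter (mm).
#' @param l_rt,f_ref calibration constants, see [analytic_reflectance()].
#' @return Absorption coefficient (1/mm).
#' @export
vessel_mua_per_mm <- function(spectrum, lambda_nm, state, diameter_mm,
                              l_rt = 1.64, f_ref = 0.05) {
  mu <- blood_mua(spectrum, lambda_nm, state)
  l_rt * (state$volume_fraction / f_ref) * mu / (2 * diameter_mm)
}

#' Run the 2D Monte Carlo transport simulation
#'
#' Photon packets enter through the top surface at the source incidence
#' angle (single Fresnel specular loss at entry, Snell refraction through
#' internal index steps, no partial internal reflections), propagate with
#' exponential free paths, deposit `w * mua/mut` per interaction into a
#' gridded absorption map, and scatter through 2D Henyey-Greenstein angles.
#' Requires flat interfaces (`curvature_radius_mm = Inf`).
#'
#' @param phantom a `layered_phantom_2d` (flat interfaces).
#' @param source a [source_spec()].
#' @param spectrum a [hemoglobin_spectrum()].
#' @param cfg an [mc_config()].
#' @return An object of class `mc_result` with fields `R` (total
#'   reflectance, specular + diffuse), `r_specular`, `r_diffuse`,
#'   `transmittance`, `side_escape`, `absorbed`, `closure_residual`,
#'   `absorption_map` (rows = depth bins), `grid_dx_mm`, `grid_dy_mm`.
#' @export
mc_simulate <- function(phantom, source, spectrum = default_hemoglobin_spectrum(),
                        cfg = mc_config()) {
  stopifnot(inherits(phantom, "layered_phantom_2d"),
            inherits(source, "source_spec"),
            inherits(cfg, "mc_config"))
  if (!is.infinite(phantom$curvature_radius_mm))
    stop("the Monte Carlo engine requires flat interfaces")
  mua <- vapply(phantom$layers, `[[`, 0, "mua") / 1000   # 1/m -> 1/mm
  mus <- vapply(phantom$layers, `[[`, 0, "mus") / 1000
  n <- vapply(phantom$layers, `[[`, 0, "refractive_index")
  if (any(mua < 0) || any(mus < 0)) stop("nonphysical optical properties")
  g <- rep(cfg$g, length(mua))
  if (is.null(phantom$vessel)) {
    vx <- vy <- 0; vr <- -1; v_mua <- v_mus <- v_g <- 0
  } else {
    v <- phantom$vessel
    vx <- v$center_x_mm
    vy <- v$center_depth_mm
    vr <- v$diameter_mm / 2
    v_mua <- vessel_mua_per_mm(spectrum, source$lambda_nm, v$state,
                               v$diameter_mm)
    host <- grep("gray", names(phantom$layers))[1]
    if (is.na(host))
      host <- findInterval(vy, phantom$boundaries_mm, rightmost.closed = TRUE)
    v_mus <- mus[host]
    v_g <- cfg$g
  }
  src_x <- if (source$n_sources == 1) 0 else
    seq(-phantom$width_mm / 4, phantom$width_mm / 4,
        length.out = source$n_sources)
  set.seed(cfg$seed)
  raw <- mc2d_run(phantom$boundaries_mm, mua, mus, g, n,
                  vx, vy, vr, v_mua, v_mus, v_g,
                  phantom$width_mm, src_x, source$source_diameter_mm,
                  source$incidence_deg, phantom$ambient_index,
                  cfg$n_photons, cfg$weight_threshold, cfg$roulette_survival,
                  cfg$grid_spacing_mm, cfg$grid_spacing_mm,
                  cfg$bottom_albedo)
  closure <- raw$r_specular + raw$r_diffuse + raw$transmittance +
    raw$side_escape + raw$absorbed - 1
  structure(list(R = raw$r_specular + raw$r_diffuse,
                 r_specular = raw$r_specular, r_diffuse = raw$r_diffuse,
                 transmittance = raw$transmittance,
                 side_escape = raw$side_escape, absorbed = raw$absorbed,
                 closure_residual = closure,
                 absorption_map = raw$absorption_map,
                 grid_dx_mm = raw$grid_dx, grid_dy_mm = raw$grid_dy,
                 n_photons = cfg$n_photons),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(
    "<mc_result> n=%d  R=%.4f (spec %.4f)  T=%.4f  A=%.4f  side=%.4f  closure=%.1e\n",
    x$n_photons, x$R, x$r_specular, x$transmittance, x$absorbed,
    x$side_escape, x$closure_residual))
  invisible(x)
}

#' Penetration depth from an absorbed-energy map
#'
#' Depth at which the cumulative absorbed energy (integrated over the
#' lateral axis, surface downward) reaches `fraction` of the total absorbed
#' energy, linearly interpolated within the crossing bin.
#'
#' @param result an `mc_result`, or a numeric matrix of absorbed energy
#'   (rows = depth bins) with `dy_mm` giving the bin height.
#' @param fraction cumulative-energy fraction defining the depth
#'   (default 0.9).
#' @param dy_mm depth bin height (mm), required when `result` is a bare
#'   matrix.
#' @return Depth in mm. Errors when total absorption is zero.
#' @export
penetration_depth <- function(result, fraction = 0.9, dy_mm = NULL) {
  if (inherits(result, "mc_result")) {
    map <- result$absorption_map
    dy <- result$grid_dy_mm
  } else {
    map <- as.matrix(result)
    if (is.null(dy_mm)) stop("dy_mm is required for a bare matrix")
    dy <- dy_mm
  }
  rows <- rowSums(map)
  tot <- sum(rows)
  if (tot <= 0) stop("zero total absorption: penetration depth undefined")
  cum <- c(0, cumsum(rows)) / tot
  i <- which(cum >= fraction)[1] # first edge at/above target
  if (i == 1L) return(0)
  frac_in_bin <- (fraction - cum[i - 1]) / (cum[i] - cum[i - 1])
  ((i - 2) + frac_in_bin) * dy
}

#' Pulsatile reflectance time series
#'
#' Drives the phantom's vessel through a blood-state series and records the
#' reflectance at each time sample. The analytic engine evaluates the
#' modified Beer-Lambert model (deterministic); the Monte Carlo engine runs
#' one simulation per time step with per-step seeds derived from the master
#' seed (`cfg$seed + step index`) and the deep mirror set to `s_alb`.
#'
#' @param phantom a `layered_phantom_2d` with a vessel.
#' @param source a [source_spec()].
#' @param spectrum a [hemoglobin_spectrum()].
#' @param blood_series data.frame from [blood_state_series()].
#' @param engine `"analytic"` (default) or `"mc"`.
#' @param s_alb,l_rt,f_ref analytic-model constants, see
#'   [analytic_reflectance()].
#' @param cfg an [mc_config()] (MC engine only).
#' @return An object of class `reflectance_series`: list with `lambda_nm`,
#'   `times` (s), `R`, `engine`.
#' @export
reflectance_timeseries <- function(phantom, source,
                                   spectrum = default_hemoglobin_spectrum(),
                                   blood_series,
                                   engine = c("analytic", "mc"),
                                   s_alb = 1, l_rt = 1.64, f_ref = 0.05,
                                   cfg = mc_config()) {
  engine <- match.arg(engine)
  stopifnot(inherits(phantom, "layered_phantom_2d"))
  if (is.null(phantom$vessel))
    stop("reflectance_timeseries requires a phantom with a vessel")
  f <- blood_series$volume_fraction
  so2 <- blood_series$so2[1]
  state <- blood_state(so2 = so2, volume_fraction = phantom$vessel$state$volume_fraction)
  if (engine == "analytic") {
    # static layer exponent once, blood exponent vectorized over time
    base <- analytic_reflectance(
      phantom_without_vessel(phantom), source, spectrum, s_alb = s_alb)
    mu_b <- blood_mua(spectrum, source$lambda_nm, state)
    R <- base * exp(-l_rt * (f / f_ref) * mu_b)
  } else {
    R <- vapply(seq_along(f), function(i) {
      ph <- phantom
      ph$vessel$state <- blood_state(so2 = so2, volume_fraction = f[i])
      ci <- cfg
      ci$seed <- cfg$seed + i
      ci$bottom_albedo <- s_alb
      mc_simulate(ph, source, spectrum, ci)$R
    }, 0)
  }
  reflectance_series(source$lambda_nm, blood_series$t_s, R, engine)
}

#' @noRd
phantom_without_vessel <- function(phantom) {
  phantom$vessel <- NULL
  phantom
}

#' Reflectance series container
#'
#' @param lambda_nm wavelength (nm).
#' @param times sample times (s), strictly increasing.
#' @param R reflectance values in \[0, 1\].
#' @param engine engine label.
#' @return An object of class `reflectance_series`.
#' @export
reflectance_series <- function(lambda_nm, times, R, engine = "analytic") {
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (length(times) != length(R)) stop("times and R must align")
  if (any(R < 0 | R > 1)) stop("reflectance must lie in [0, 1]")
  structure(list(lambda_nm = lambda_nm, times = times, R = R,
                 engine = engine),
            class = "reflectance_series")
}

#' Write a reflectance series as columnar text
#' @param series a `reflectance_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reflectance_series <- function(series, path) {
  stopifnot(inherits(series, "reflectance_series"))
  write.csv(data.frame(t_s = series$times, lambda_nm = series$lambda_nm,
                       R = series$R),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
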