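# Tissue and blood optical/electrical property tables and spectral lookup.

# Packaged hemoglobin absorption table, 400-890 nm on a 10 nm grid.
# Coefficients are in the normalized 1/m scale of the packaged dataset and are
# treated as normative; they are symmetric about the 580 nm HbO2 peak (1.7).
.hb_table <- local({
  wl <- seq(400, 890, by = 10)
  hbo2 <- c(
    0.202300, 0.204633, 0.208964, 0.216663, 0.229764, 0.251071, 0.284202,
    0.333382, 0.403002, 0.496848, 0.617055, 0.762966, 0.930128, 1.109794,
    1.289221, 1.452905, 1.58467, 1.67029, 1.7, 1.67029, 1.58467, 1.452905,
    1.289223, 1.10979, 0.930128, 0.762966, 0.617055, 0.496848, 0.403002,
    0.333382, 0.284202, 0.251071, 0.229761, 0.216663, 0.208903, 0.204633,
    0.202301, 0.201097, 0.200503, 0.200221, 0.200093, 0.200038, 0.200014,
    0.200005, 0.200001, 0.200002, 0.200002, 0.200007, 0.200002, 0.200007
  )
  hb <- c(
    0.128565, 0.143936, 0.165728, 0.195634, 0.235335, 0.286270, 0.349352,
    0.424652, 0.511112, 0.606335, 0.70653, 0.806648, 0.900737, 0.982496,
    1.045959, 1.086207, 1.1, 1.086207, 1.045959, 0.982496, 0.900737,
    0.806648, 0.70653, 0.606335, 0.511112, 0.424652, 0.349352, 0.286270,
    0.235335, 0.195634, 0.165728, 0.143936, 0.128565, 0.118063, 0.111108,
    0.106645, 0.10386, 0.102187, 0.101201, 0.100645, 0.100335, 0.100169,
    0.100083, 0.100040, 0.100018, 0.100008, 0.100003, 0.100001, 0.100006,
    0.100002
  )
  data.frame(wavelength_nm = wl, mua_hbo2_per_m = hbo2, mua_hb_per_m = hb)
})

#' Construct a hemoglobin absorption spectrum
#'
#' A wavelength-gridded pair of absorption coefficients for oxygenated
#' (HbO2) and deoxygenated (Hb) hemoglobin, shared grid, strictly
#' increasing wavelengths, positive coefficients.
#'
#' @param wavelengths_nm numeric vector of wavelengths (nm), strictly
#'   increasing, no duplicates.
#' @param mua_hbo2 absorption coefficients of HbO2 per wavelength (1/m).
#' @param mua_hb absorption coefficients of Hb per wavelength (1/m).
#' @return An object of class `hemoglobin_spectrum`.
#' @seealso [default_hemoglobin_spectrum()], [blood_mua()]
#' @export
hemoglobin_spectrum <- function(wavelengths_nm, mua_hbo2, mua_hb) {
  if (length(wavelengths_nm) == 0L)
    stop("empty spectrum: at least one wavelength is required")
  if (length(mua_hbo2) != length(wavelengths_nm) ||
      length(mua_hb) != length(wavelengths_nm))
    stop("wavelength grid and coefficient columns must have equal length")
  if (anyNA(wavelengths_nm) || anyNA(mua_hbo2) || anyNA(mua_hb))
    stop("spectrum contains missing values")
  if (any(diff(wavelengths_nm) <= 0))
    stop("wavelengths must be strictly increasing (no duplicates)")
  if (any(mua_hbo2 <= 0) || any(mua_hb <= 0))
    stop("absorption coefficients must be positive")
  structure(
    list(wavelengths_nm = as.numeric(wavelengths_nm),
         mua_hbo2 = as.numeric(mua_hbo2),
         mua_hb = as.numeric(mua_hb)),
    class = "hemoglobin_spectrum"
  )
}

#' @export
print.hemoglobin_spectrum <- function(x, ...) {
  cat(sprintf("<hemoglobin_spectrum> %d wavelengths, %g-%g nm\n",
              length(x$wavelengths_nm), min(x$wavelengths_nm),
              max(x$wavelengths_nm)))
  invisible(x)
}

#' Packaged hemoglobin absorption spectrum
#'
#' The package's normative HbO2/Hb absorption table: 400-890 nm in 10 nm
#' steps. The HbO2 column peaks at 1.7 /m (580 nm); both columns decrease
#' monotonically above 580/560 nm respectively.
#'
#' @return A `hemoglobin_spectrum`.
#' @export
default_hemoglobin_spectrum <- function() {
  hemoglobin_spectrum(.hb_table$wavelength_nm,
                      .hb_table$mua_hbo2_per_m,
                      .hb_table$mua_hb_per_m)
}

#' Read / write hemoglobin spectra as columnar text
#'
#' Comma- or tab-separated text with header
#' `wavelength_nm,mua_hbo2_per_m,mua_hb_per_m`. Values round-trip exactly
#' (written with full precision).
#'
#' @param path file path.
#' @param sep field separator for writing, `","` (default) or `"\t"`.
#' @return `read_spectrum` returns a `hemoglobin_spectrum`; `write_spectrum`
#'   returns `path` invisibly.
#' @export
read_spectrum <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- read.csv(path, sep = sep, colClasses = "character")
  need <- c("wavelength_nm", "mua_hbo2_per_m", "mua_hb_per_m")
  if (!all(need %in% names(tab)))
    stop("spectrum table must have columns ", paste(need, collapse = ", "))
  if (nrow(tab) == 0L) stop("empty spectrum table")
  hemoglobin_spectrum(as.numeric(tab$wavelength_nm),
                      as.numeric(tab$mua_hbo2_per_m),
                      as.numeric(tab$mua_hb_per_m))
}

#' @rdname read_spectrum
#' @param spectrum a `hemoglobin_spectrum`.
#' @export
write_spectrum <- function(spectrum, path, sep = ",") {
  stopifnot(inherits(spectrum, "hemoglobin_spectrum"))
  df <- data.frame(
    wavelength_nm = format(spectrum$wavelengths_nm, digits = 17, trim = TRUE),
    mua_hbo2_per_m = format(spectrum$mua_hbo2, digits = 17, trim = TRUE),
    mua_hb_per_m = format(spectrum$mua_hb, digits = 17, trim = TRUE)
  )
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Blood optical state
#'
#' Oxygen saturation and blood volume fraction, both bounded in \[0, 1\].
#' Default saturation 0.97 (arterial blood).
#'
#' @param so2 oxygen saturation fraction.
#' @param volume_fraction blood volume fraction of the vessel compartment.
#' @return An object of class `blood_state`.
#' @export
blood_state <- function(so2 = 0.97, volume_fraction = 0.05) {
  if (!is.numeric(so2) || so2 < 0 || so2 > 1)
    stop("so2 must lie in [0, 1]")
  if (!is.numeric(volume_fraction) || volume_fraction < 0 || volume_fraction > 1)
    stop("volume_fraction must lie in [0, 1]")
  structure(list(so2 = so2, volume_fraction = volume_fraction),
            class = "blood_state")
}

#' Blood absorption coefficient at a wavelength
#'
#' Saturation-weighted Beer-Lambert mixture of the two hemoglobin species:
#' `mua = so2 * mua_HbO2(lambda) + (1 - so2) * mua_Hb(lambda)`.
#' Off-grid wavelengths are piecewise-linearly interpolated on the spectrum
#' grid; wavelengths outside the grid range are an error.
#'
#' @param spectrum a [hemoglobin_spectrum()].
#' @param lambda_nm wavelength(s) in nm, within the grid range.
#' @param state a [blood_state()] (only `so2` is used).
#' @return Absorption coefficient(s), 1/m (same normalized scale as the
#'   spectrum table).
#' @export
blood_mua <- function(spectrum, lambda_nm, state = blood_state()) {
  stopifnot(inherits(spectrum, "hemoglobin_spectrum"),
            inherits(state, "blood_state"))
  rng <- range(spectrum$wavelengths_nm)
  if (any(lambda_nm < rng[1] | lambda_nm > rng[2]))
    stop(sprintf("wavelength outside spectral grid [%g, %g] nm",
                 rng[1], rng[2]))
  hbo2 <- approx(spectrum$wavelengths_nm, spectrum$mua_hbo2, lambda_nm)$y
  hb <- approx(spectrum$wavelengths_nm, spectrum$mua_hb, lambda_nm)$y
  state$so2 * hbo2 + (1 - state$so2) * hb
}

#' Tissue optical/thermal/electrical property set
#'
#' One tissue layer's bulk properties. Thermal fields (`thermal_conductivity`,
#' `heat_capacity`) are stored for completeness but consumed by no operation
#' in this package (no bioheat model).
#'
#' @param name tissue label.
#' @param refractive_index real refractive index, >= 1.
#' @param mua absorption coefficient (1/m).
#' @param mus scattering coefficient (1/m).
#' @param thickness layer depth (mm).
#' @param thermal_conductivity W/(m K).
#' @param density kg/m^3.
#' @param heat_capacity J/(kg K).
#' @param electrical_conductivity S/m.
#' @return An object of class `tissue_optical_props`.
#' @export
tissue_optical_props <- function(name, refractive_index, mua, mus, thickness,
                                 thermal_conductivity = NA_real_,
                                 density = NA_real_,
                                 heat_capacity = NA_real_,
                                 electrical_conductivity = NA_real_) {
  num <- c(refractive_index = refractive_index, mua = mua, mus = mus,
           thickness = thickness)
  if (any(!is.finite(num))) stop("core optical properties must be finite")
  if (refractive_index < 1) stop("refractive_index must be >= 1")
  if (mua < 0 || mus < 0 || thickness <= 0)
    stop("mua, mus must be >= 0 and thickness > 0")
  extra <- c(thermal_conductivity, density, heat_capacity,
             electrical_conductivity)
  if (any(extra < 0, na.rm = TRUE))
    stop("physical quantities must be nonnegative")
  structure(list(name = name, refractive_index = refractive_index,
                 mua = mua, mus = mus, thickness = thickness,
                 thermal_conductivity = thermal_conductivity,
                 density = density, heat_capacity = heat_capacity,
                 electrical_conductivity = electrical_conductivity),
            class = "tissue_optical_props")
}

#' Packaged layered-phantom tissue properties
#'
#' The four default layers of the 2D optical phantom, surface inward:
#' polyurethane encapsulant (0.8 mm), cerebrospinal fluid (0.5 mm),
#' gray/white matter (2.5 mm) and cerebellum (3.5 mm), with refractive
#' indices, optical coefficients (1/m), thermal and electrical properties.
#'
#' @return Named list of [tissue_optical_props()], in depth order.
#' @export
default_tissue_layers <- function() {
  list(
    polyurethane = tissue_optical_props(
      "polyurethane", refractive_index = 1.6, mua = 0.0001, mus = 0.5,
      thickness = 0.8, thermal_conductivity = 0.15, density = 1200,
      heat_capacity = 1800, electrical_conductivity = 1e-5),
    csf = tissue_optical_props(
      "csf", refractive_index = 1.33, mua = 0.0013, mus = 0.01,
      thickness = 0.5, thermal_conductivity = 0.5, density = 1007,
      heat_capacity = 3850, electrical_conductivity = 0.12),
    gray_matter = tissue_optical_props(
      "gray_matter", refractive_index = 1.5, mua = 0.0009, mus = 0.05,
      thickness = 2.5, thermal_conductivity = 0.5, density = 1045,
      heat_capacity = 3500, electrical_conductivity = 0.12),
    cerebellum = tissue_optical_props(
      "cerebellum", refractive_index = 1.42, mua = 0.0002, mus = 0.1,
      thickness = 3.5, thermal_conductivity = 0.51, density = 1045,
      heat_capacity = 3653, electrical_conductivity = 0.45)
  )
}

#' Electromagnetic tissue properties for SAR
#'
#' @param name label, one of the phantom's material names
#'   (e.g. "photonics", "head", "brain").
#' @param sigma electrical conductivity (S/m), >= 0.
#' @param rho mass density (kg/m^3), > 0.
#' @return An object of class `em_tissue_props`.
#' @export
em_tissue_props <- function(name, sigma, rho) {
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  if (!is.finite(rho) || rho <= 0) stop("rho must be > 0")
  structure(list(name = name, sigma = sigma, rho = rho),
            class = "em_tissue_props")
}

#' Packaged electromagnetic property set
#'
#' Conductivity and density for the three SAR materials: the photonics
#' device package (sigma = 1e-5 S/m, rho = 1300), head tissue (0.15 S/m,
#' 1100) and brain (0.12 S/m, 1050).
#'
#' @return Named list of [em_tissue_props()].
#' @export
default_em_tissues <- function() {
  list(
    photonics = em_tissue_props("photonics", sigma = 1e-5, rho = 1300),
    head = em_tissue_props("head", sigma = 0.15, rho = 1100),
    brain = em_tissue_props("brain", sigma = 0.12, rho = 1050)
  )
}

#' Read / write tissue property sets as key-value text
#'
#' Debian-control-style blocks (one per tissue, blank-line separated), keys
#' matching the [tissue_optical_props()] field names. Round-trips exactly.
#'
#' @param path file path.
#' @return `read_tissue_props` returns a named list of
#'   [tissue_optical_props()]; `write_tissue_props` returns `path` invisibly.
#' @export
read_tissue_props <- function(path) {
  m <- read.dcf(path)
  out <- lapply(seq_len(nrow(m)), function(i) {
    row <- as.list(m[i, ])
    num <- lapply(row[setdiff(names(row), "name")],
                  function(v) if (is.na(v)) NA_real_ else as.numeric(v))
    do.call(tissue_optical_props, c(list(name = row$name), num))
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' @rdname read_tissue_props
#' @param tissues named list of [tissue_optical_props()].
#' @export
write_tissue_props <- function(tissues, path) {
  m <- do.call(rbind, lapply(tissues, function(tp) {
    vals <- unclass(tp)
    vapply(vals, function(v)
      if (is.character(v)) v else format(v, digits = 17, trim = TRUE), "")
  }))
  write.dcf(m, path)
  invisible(path)
}
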