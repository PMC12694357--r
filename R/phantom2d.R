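# 2D layered brain phantom with an embedded vessel (optical model geometry).

#' Vessel specification for the 2D phantom
#'
#' @param center_depth_mm depth of the vessel center below the surface (mm).
#' @param diameter_mm vessel diameter (mm). The default 0.5 mm is a
#'   documented package choice (configurable).
#' @param state a [blood_state()].
#' @param center_x_mm lateral position of the vessel center (mm), 0 = domain
#'   center.
#' @return An object of class `vessel_spec`.
#' @export
vessel_spec <- function(center_depth_mm = 2.5, diameter_mm = 0.5,
                        state = blood_state(), center_x_mm = 0) {
  if (diameter_mm <= 0) stop("vessel diameter must be > 0")
  if (center_depth_mm <= 0) stop("vessel depth must be > 0")
  stopifnot(inherits(state, "blood_state"))
  structure(list(center_depth_mm = center_depth_mm, diameter_mm = diameter_mm,
                 state = state, center_x_mm = center_x_mm),
            class = "vessel_spec")
}

#' Configuration for the 2D layered phantom generator
#'
#' Defaults reproduce the packaged four-layer geometry (polyurethane 0.8 mm,
#' CSF 0.5 mm, gray/white matter 2.5 mm, cerebellum 3.5 mm; total depth
#' 7.3 mm) with a 0.5 mm vessel centred in the gray-matter layer.
#'
#' @param layers named list of [tissue_optical_props()] surface inward.
#' @param vessel a [vessel_spec()] or `NULL` for a vessel-free phantom.
#' @param curvature_radius_mm radius of interface curvature (mm);
#'   `Inf` = flat interfaces (default, used for analytic oracles).
#' @param width_mm lateral domain width (mm).
#' @param ambient_index refractive index of the medium above the surface.
#' @return An object of class `phantom_2d_config`.
#' @export
phantom_2d_config <- function(layers = default_tissue_layers(),
                              vessel = vessel_spec(),
                              curvature_radius_mm = Inf,
                              width_mm = 10,
                              ambient_index = 1.0) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  lapply(layers, function(l) stopifnot(inherits(l, "tissue_optical_props")))
  if (!is.null(vessel)) stopifnot(inherits(vessel, "vessel_spec"))
  if (width_mm <= 0) stop("width_mm must be > 0")
  if (ambient_index < 1) stop("ambient_index must be >= 1")
  if (!is.infinite(curvature_radius_mm) && curvature_radius_mm <= 0)
    stop("curvature_radius_mm must be > 0 or Inf")
  structure(list(layers = layers, vessel = vessel,
                 curvature_radius_mm = curvature_radius_mm,
                 width_mm = width_mm, ambient_index = ambient_index),
            class = "phantom_2d_config")
}

#' Build the 2D layered phantom
#'
#' Deterministic given the configuration (the `seed` argument is accepted
#' for generator-interface uniformity; this generator draws no random
#' numbers). Validates that the vessel lies entirely inside the gray-matter
#' layer (the third layer of the default stack; generally, the layer whose
#' name contains "gray", else the layer containing the vessel center).
#'
#' @param cfg a [phantom_2d_config()].
#' @param seed unused; kept for generator-interface symmetry.
#' @return An object of class `layered_phantom_2d` with fields `layers`,
#'   `boundaries_mm` (cumulative interface depths, starting at 0), `vessel`,
#'   `width_mm`, `ambient_index`, `curvature_radius_mm`.
#' @export
make_phantom_2d <- function(cfg = phantom_2d_config(), seed = NULL) {
  stopifnot(inherits(cfg, "phantom_2d_config"))
  th <- vapply(cfg$layers, `[[`, 0, "thickness")
  boundaries <- c(0, unname(cumsum(th)))
  if (!is.null(cfg$vessel)) {
    v <- cfg$vessel
    host <- grep("gray", names(cfg$layers))
    if (length(host) == 0L)
      host <- findInterval(v$center_depth_mm, boundaries,
                           rightmost.closed = TRUE)
    host <- host[1]
    lo <- boundaries[host]; hi <- boundaries[host + 1]
    r <- v$diameter_mm / 2
    if (v$diameter_mm > th[host])
      stop("vessel diameter exceeds its host layer thickness")
    if (v$center_depth_mm - r < lo || v$center_depth_mm + r > hi)
      stop("vessel must lie entirely inside the gray-matter layer")
    if (abs(v$center_x_mm) + r > cfg$width_mm / 2)
      stop("vessel must lie inside the lateral domain")
  }
  structure(list(layers = cfg$layers, boundaries_mm = boundaries,
                 vessel = cfg$vessel, width_mm = cfg$width_mm,
                 ambient_index = cfg$ambient_index,
                 curvature_radius_mm = cfg$curvature_radius_mm),
            class = "layered_phantom_2d")
}

#' @export
print.layered_phantom_2d <- function(x, ...) {
  cat(sprintf("<layered_phantom_2d> %d layers, depth %.3g mm, width %.3g mm%s\n",
              length(x$layers), max(x$boundaries_mm), x$width_mm,
              if (is.null(x$vessel)) ", no vessel"
              else sprintf(", vessel d=%.3g mm at %.3g mm depth",
                           x$vessel$diameter_mm, x$vessel$center_depth_mm)))
  invisible(x)
}

#' Total phantom depth (mm)
#' @param phantom a `layered_phantom_2d`.
#' @return Depth in mm.
#' @export
phantom_depth <- function(phantom) {
  stopifnot(inherits(phantom, "layered_phantom_2d"))
  max(phantom$boundaries_mm)
}
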