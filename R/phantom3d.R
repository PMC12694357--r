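# 3D voxel head phantom: hemispherical brain, head shell and the implanted
# photonics device, on a regular grid.

# label codes used throughout the SAR stack
.LBL <- c(air = 0L, photonics = 1L, head = 2L, brain = 3L)

#' Configuration for the 3D voxel head phantom
#'
#' The default desk-scale geometry: a hemispherical brain (radius 7 cm,
#' dome pointing toward the device) under a 0.7 cm head shell, with a
#' 1 cm^3 photonics device box sitting on the shell apex. The z axis points
#' from the device down into the head; the device occupies
#' `z in [0, device_size[3]]` and tissue begins at the shell apex directly
#' beneath it.
#'
#' @param brain_radius brain hemisphere radius (m).
#' @param shell_thickness head (skull/scalp) shell thickness (m).
#' @param device_size device box edge lengths (m), x/y/z.
#' @param spacing voxel edge length (m), scalar or length-3.
#' @param margin air margin around the tissue (m).
#' @param props named list of [em_tissue_props()] for labels
#'   `photonics`, `head`, `brain`.
#' @return An object of class `phantom_3d_config`.
#' @export
phantom_3d_config <- function(brain_radius = 0.07, shell_thickness = 0.007,
                              device_size = c(0.01, 0.01, 0.01),
                              spacing = 0.002, margin = 0.004,
                              props = default_em_tissues()) {
  if (brain_radius <= 0 || shell_thickness <= 0)
    stop("brain radius and shell thickness must be > 0")
  if (any(device_size <= 0)) stop("device dimensions must be > 0")
  spacing <- rep_len(spacing, 3L)
  if (any(spacing <= 0)) stop("spacing must be > 0")
  need <- c("photonics", "head", "brain")
  if (!all(need %in% names(props)))
    stop("props must cover photonics, head and brain")
  lapply(props, function(p) stopifnot(inherits(p, "em_tissue_props")))
  structure(list(brain_radius = brain_radius,
                 shell_thickness = shell_thickness,
                 device_size = device_size, spacing = spacing,
                 margin = margin, props = props),
            class = "phantom_3d_config")
}

#' Build the 3D voxel head phantom
#'
#' Deterministic given the configuration. Labels partition the grid into
#' air, photonics, head shell and brain; each voxel is classified by its
#' center. The device box is placed adjacent to the tissue surface (its
#' lower face touches the shell apex); the receiving coil is registered at
#' the device center with its axis along +z (into the head).
#'
#' @param cfg a [phantom_3d_config()].
#' @param seed unused; kept for generator-interface symmetry.
#' @return An object of class `voxel_phantom_3d` with fields `dims`,
#'   `spacing` (m), `origin` (center of voxel \[1,1,1\], m), `labels`
#'   (integer array, 0 air / 1 photonics / 2 head / 3 brain),
#'   `label_names`, `props`, `coil_center`, `coil_axis`.
#' @export
make_phantom_3d <- function(cfg = phantom_3d_config(), seed = NULL) {
  stopifnot(inherits(cfg, "phantom_3d_config"))
  rb <- cfg$brain_radius
  rs <- rb + cfg$shell_thickness
  dev <- cfg$device_size
  sp <- cfg$spacing
  # hemisphere center on the z axis; shell apex at z = dev[3]
  cz <- dev[3] + rs
  half_xy <- rs + cfg$margin
  z_lo <- -cfg$margin
  z_hi <- cz + cfg$margin
  # guard against float fuzz flipping an exact quotient over the ceiling
  nx <- ceiling(2 * half_xy / sp[1] - 1e-9)
  ny <- ceiling(2 * half_xy / sp[2] - 1e-9)
  nz <- ceiling((z_hi - z_lo) / sp[3] - 1e-9)
  origin <- c(-half_xy + sp[1] / 2, -half_xy + sp[2] / 2, z_lo + sp[3] / 2)
  xs <- origin[1] + (seq_len(nx) - 1) * sp[1]
  ys <- origin[2] + (seq_len(ny) - 1) * sp[2]
  zs <- origin[3] + (seq_len(nz) - 1) * sp[3]

  labels <- array(.LBL[["air"]], dim = c(nx, ny, nz))
  x3 <- array(rep(xs, times = ny * nz), dim = c(nx, ny, nz))
  y3 <- array(rep(rep(ys, each = nx), times = nz), dim = c(nx, ny, nz))
  z3 <- array(rep(zs, each = nx * ny), dim = c(nx, ny, nz))
  d2 <- x3^2 + y3^2 + (z3 - cz)^2
  dome <- z3 <= cz                 # hemisphere: dome toward the device
  labels[d2 <= rs^2 & dome] <- .LBL[["head"]]
  labels[d2 <= rb^2 & dome] <- .LBL[["brain"]]
  in_dev <- abs(x3) <= dev[1] / 2 & abs(y3) <= dev[2] / 2 &
    z3 >= 0 & z3 <= dev[3]
  labels[in_dev] <- .LBL[["photonics"]]
  if (!any(labels == .LBL[["head"]] | labels == .LBL[["brain"]]))
    stop("no tissue voxels: check geometry and spacing")

  structure(list(dims = c(nx, ny, nz), spacing = sp, origin = origin,
                 labels = labels, label_names = names(.LBL),
                 props = cfg$props,
                 coil_center = c(0, 0, dev[3] / 2),
                 coil_axis = c(0, 0, 1)),
            class = "voxel_phantom_3d")
}

#' @export
print.voxel_phantom_3d <- function(x, ...) {
  n <- table(factor(x$labels, levels = .LBL, labels = names(.LBL)))
  cat(sprintf("<voxel_phantom_3d> %d x %d x %d voxels @ %s mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              paste(format(x$spacing * 1000), collapse = " x ")))
  cat("  ", paste(sprintf("%s=%d", names(n), n), collapse = "  "), "\n")
  invisible(x)
}

#' Per-voxel coordinates, density, mass and tissue mask
#'
#' Helpers used by the SAR stack. "Tissue" means head or brain (air and the
#' device package are excluded from mass-averaging kernels and region
#' statistics).
#'
#' @param phantom a `voxel_phantom_3d`.
#' @return `voxel_centers`: n x 3 matrix (m). `voxel_density`: array of
#'   densities (kg/m^3, 0 for air). `voxel_mass`: array of voxel masses
#'   (kg, 0 for air). `tissue_mask`: logical array.
#' @export
voxel_centers <- function(phantom) {
  d <- phantom$dims; sp <- phantom$spacing; o <- phantom$origin
  xs <- o[1] + (seq_len(d[1]) - 1) * sp[1]
  ys <- o[2] + (seq_len(d[2]) - 1) * sp[2]
  zs <- o[3] + (seq_len(d[3]) - 1) * sp[3]
  cbind(rep(xs, times = d[2] * d[3]),
        rep(rep(ys, each = d[1]), times = d[3]),
        rep(zs, each = d[1] * d[2]))
}

#' @rdname voxel_centers
#' @export
voxel_density <- function(phantom) {
  rho <- c(0, phantom$props$photonics$rho, phantom$props$head$rho,
           phantom$props$brain$rho)
  array(rho[phantom$labels + 1L], dim = phantom$dims)
}

#' @rdname voxel_centers
#' @export
voxel_mass <- function(phantom) {
  voxel_density(phantom) * prod(phantom$spacing)
}

#' @rdname voxel_centers
#' @export
tissue_mask <- function(phantom) {
  array(phantom$labels == .LBL[["head"]] | phantom$labels == .LBL[["brain"]],
        dim = phantom$dims)
}

#' Total mass of a labelled region (kg)
#' @param phantom a `voxel_phantom_3d`.
#' @param label one of "photonics", "head", "brain".
#' @return Mass in kg.
#' @export
region_mass <- function(phantom, label) {
  code <- .LBL[[label]]
  sum(voxel_mass(phantom)[phantom$labels == code])
}
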