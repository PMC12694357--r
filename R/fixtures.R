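# Deterministic fixture generator: packaged tables, waveform series, small
# phantoms and a toy mass-averaging example, with a checksum manifest.

#' Write the package's fixture set
#'
#' Writes, into `out_dir`: the packaged hemoglobin spectrum, the tissue
#' optical property blocks, the electromagnetic property table, the default
#' sampled waveform with blood states, a small flat 2D phantom description,
#' a coarse 3D voxel phantom, and a toy SAR-map example whose 10 g-averaged
#' peak is stored alongside for oracle recomputation. All outputs are plain
#' text and bit-reproducible for a given `(seed)`; a `manifest.json` lists
#' relative paths with md5 checksums.
#'
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed (the generators are deterministic; the seed is
#'   fixed before writing for interface symmetry).
#' @return Invisibly, the manifest as a data.frame (`path`, `md5`).
#' @export
make_fixtures <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  paths <- character()

  p <- file.path(out_dir, "hemoglobin_spectrum.csv")
  write_spectrum(default_hemoglobin_spectrum(), p)
  paths <- c(paths, p)

  p <- file.path(out_dir, "tissue_optical_props.dcf")
  write_tissue_props(default_tissue_layers(), p)
  paths <- c(paths, p)

  p <- file.path(out_dir, "em_tissue_props.csv")
  em <- default_em_tissues()
  write.csv(data.frame(name = vapply(em, `[[`, "", "name"),
                       sigma_s_per_m = vapply(em, `[[`, 0, "sigma"),
                       rho_kg_per_m3 = vapply(em, `[[`, 0, "rho")),
            p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)

  p <- file.path(out_dir, "waveform_default.csv")
  write_waveform(blood_state_series(sample_waveform(pressure_waveform())), p)
  paths <- c(paths, p)

  p <- file.path(out_dir, "phantom2d_default.json")
  ph2 <- make_phantom_2d(phantom_2d_config())
  jsonlite::write_json(list(
    boundaries_mm = ph2$boundaries_mm,
    layer_names = names(ph2$layers),
    width_mm = ph2$width_mm, ambient_index = ph2$ambient_index,
    vessel = list(center_depth_mm = ph2$vessel$center_depth_mm,
                  diameter_mm = ph2$vessel$diameter_mm,
                  so2 = ph2$vessel$state$so2,
                  volume_fraction = ph2$vessel$state$volume_fraction)),
    p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)

  p <- file.path(out_dir, "phantom3d_coarse.json")
  cfg3 <- phantom_3d_config(brain_radius = 0.006, shell_thickness = 0.002,
                            device_size = c(0.004, 0.004, 0.004),
                            spacing = 0.002, margin = 0.002)
  ph3 <- make_phantom_3d(cfg3)
  jsonlite::write_json(list(
    dims = ph3$dims, spacing_m = ph3$spacing, origin_m = ph3$origin,
    label_names = ph3$label_names, labels = as.integer(ph3$labels)),
    p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)

  # toy mass-averaging example: all-brain cube with one hot voxel
  p <- file.path(out_dir, "toy_sar_example.json")
  toy <- toy_sar_phantom(n = 8, spacing = 0.01)
  sar <- array(0, dim = toy$dims)
  sar[4, 4, 4] <- 1
  ker <- averaging_kernel(target_mass = 0.01, shape = "sphere",
                          adaptive = TRUE, rho_ref = toy$props$brain$rho,
                          max_radius = 0.06)
  avg <- mass_averaged_sar(sar, toy, ker)
  jsonlite::write_json(list(
    n = 8, spacing_m = 0.01, hot_voxel = c(4, 4, 4), sar_hot = 1,
    target_mass_kg = ker$target_mass, shape = ker$shape,
    expected_peak = avg$peak,
    expected_realized_mass_at_peak = avg$realized_mass[4, 4, 4]),
    p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)

  rel <- basename(paths)
  manifest <- data.frame(path = rel,
                         md5 = unname(tools::md5sum(paths)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Homogeneous all-brain cubic test phantom
#'
#' A cube of brain tissue (no air, no device) used by the mass-averaging
#' oracle tests and the toy fixture.
#'
#' @param n voxels per edge.
#' @param spacing voxel edge (m).
#' @param props EM property set (brain entry used).
#' @return A `voxel_phantom_3d`.
#' @export
toy_sar_phantom <- function(n = 8, spacing = 0.01,
                            props = default_em_tissues()) {
  structure(list(dims = c(n, n, n), spacing = rep(spacing, 3),
                 origin = rep(spacing / 2, 3),
                 labels = array(3L, dim = c(n, n, n)),
                 label_names = c("air", "photonics", "head", "brain"),
                 props = props,
                 coil_center = c(0, 0, 0), coil_axis = c(0, 0, 1)),
            class = "voxel_phantom_3d")
}
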