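# Independent oracles and small builders shared across the test files.

# Brute-force mass-averaged SAR: plain R loops following the documented
# neighbour ordering contract (increasing squared physical distance, ties
# by dz, dy, dx ascending). Kept deliberately naive and separate from the
# production kernel.
oracle_mass_avg <- function(sar, mass, tissue, spacing, target_mass,
                            shape = c("sphere", "hemisphere"),
                            axis = c(0, 0, 1), adaptive = TRUE,
                            radius = NULL, max_radius = NULL) {
  shape <- match.arg(shape)
  dims <- dim(sar)
  rmax <- if (adaptive) max_radius else radius
  kx <- floor(rmax / spacing[1]); ky <- floor(rmax / spacing[2])
  kz <- floor(rmax / spacing[3])
  offs <- expand.grid(dx = -kx:kx, dy = -ky:ky, dz = -kz:kz)
  px <- offs$dx * spacing[1]; py <- offs$dy * spacing[2]
  pz <- offs$dz * spacing[3]
  d2 <- px^2 + py^2 + pz^2
  keep <- d2 <= rmax^2 + 1e-15
  if (shape == "hemisphere") {
    ax <- axis / sqrt(sum(axis^2))
    keep <- keep & (px * ax[1] + py * ax[2] + pz * ax[3] >= -1e-12)
  }
  offs <- offs[keep, ]; d2 <- d2[keep]
  ord <- order(d2, offs$dz, offs$dy, offs$dx)
  offs <- offs[ord, ]

  avg <- array(NA_real_, dims)
  realized <- array(NA_real_, dims)
  for (iz in seq_len(dims[3])) for (iy in seq_len(dims[2]))
    for (ix in seq_len(dims[1])) {
      if (!tissue[ix, iy, iz]) next
      m <- 0; num <- 0; reached <- !adaptive
      for (k in seq_len(nrow(offs))) {
        jx <- ix + offs$dx[k]; jy <- iy + offs$dy[k]; jz <- iz + offs$dz[k]
        if (jx < 1 || jx > dims[1] || jy < 1 || jy > dims[2] ||
            jz < 1 || jz > dims[3]) next
        if (!tissue[jx, jy, jz]) next
        m <- m + mass[jx, jy, jz]
        num <- num + sar[jx, jy, jz] * mass[jx, jy, jz]
        if (adaptive && m >= target_mass) { reached <- TRUE; break }
      }
      if (!reached) next
      if (m > 0) { avg[ix, iy, iz] <- num / m; realized[ix, iy, iz] <- m }
    }
  list(avg = avg, realized_mass = realized)
}

# single-layer absorbing/scattering slab phantom (no vessel)
slab_phantom <- function(mua_per_m, mus_per_m = 0, thickness_mm = 1,
                         n = 1.0, width_mm = 60) {
  make_phantom_2d(phantom_2d_config(
    layers = list(slab = tissue_optical_props("slab", n, mua = mua_per_m,
                                              mus = mus_per_m,
                                              thickness = thickness_mm)),
    vessel = NULL, width_mm = width_mm))
}

MU0_test <- function() 4e-7 * pi

# a synthetic flat spectrum (equal, wavelength-independent columns)
flat_spectrum <- function(value = 0.5, wavelengths = seq(400, 890, by = 10)) {
  hemoglobin_spectrum(wavelengths, rep(value, length(wavelengths)),
                      rep(value, length(wavelengths)))
}
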