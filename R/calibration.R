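# Shift calibration: each aberration mode displaces the PSF axially and/or
# laterally (spherical aberration moves the focal plane, coma translates the
# spot). During measurement and correction those displacements are cancelled
# by compensating defocus and tilt terms so the sharpness metric responds to
# the aberration's shape, not to the displacement it drags along.

# sub-voxel peak position (nm, relative to the grid center) by quadratic
# interpolation of the intensity around the brightest voxel
psf_peak_position <- function(data, voxel) {
  d <- dim(data)
  i <- arrayInd(which.max(data), d)
  pos <- numeric(3)
  for (ax in 1:3) {
    j <- i[ax]
    delta <- 0
    if (j > 1 && j < d[ax]) {
      im <- i; im[ax] <- j - 1L
      ip <- i; ip[ax] <- j + 1L
      y0 <- data[i]; ym <- data[im]; yp <- data[ip]
      den <- ym - 2 * y0 + yp
      if (den < 0) delta <- 0.5 * (ym - yp) / den
    }
    pos[ax] <- (j + delta - (floor(d[ax] / 2) + 1L))
  }
  # data is [y, x, z]; voxel is c(dz, dy, dx)
  c(y = pos[1] * voxel[2], x = pos[2] * voxel[3], z = pos[3] * voxel[1])
}

#' Calibrate the PSF displacement induced by an aberration mode
#'
#' Generates uncompensated PSFs at plus and minus one initial-step unit of the
#' mode and fits a line to the interpolated peak-voxel displacement, giving
#' the axial and lateral shift per unit magnitude. The result is cached per
#' mode and configuration.
#'
#' @param mode aberration mode identifier
#' @param config an [optical_config()]
#' @param unit magnitude used for the two calibration PSFs (defaults to the
#'   mode class's initial sampling step)
#' @return list with `axial` (nm per unit magnitude) and `lateral`
#'   (named `c(x, y)`, nm per unit magnitude)
#' @export
calibrate_mode_shifts <- function(mode, config, unit = NULL) {
  if (!is_known_mode(mode)) stop("unknown aberration mode: '", mode, "'", call. = FALSE)
  if (mode %in% shift_modes) {
    # these modes are displacements by construction
    return(switch(mode,
      tilt_x = list(axial = 0, lateral = c(x = 1, y = 0)),
      tilt_y = list(axial = 0, lateral = c(x = 0, y = 1)),
      defocus_offset = list(axial = -1, lateral = c(x = 0, y = 0))))
  }
  if (is.null(unit)) unit <- mode_step(mode)
  key <- paste0("calib|", mode, "|", unit, "|", config_key(config))
  cache_get_or(key, function() {
    pp <- psf_peak_position(
      make_psf(config, aberration_spec(magnitudes = stats::setNames(unit, mode)),
               compensate = FALSE)$data, config$voxel)
    pm <- psf_peak_position(
      make_psf(config, aberration_spec(magnitudes = stats::setNames(-unit, mode)),
               compensate = FALSE)$data, config$voxel)
    sl <- (pp - pm) / (2 * unit)
    list(axial = unname(sl["z"]), lateral = c(x = unname(sl["x"]),
                                              y = unname(sl["y"])))
  })
}

# fold compensating defocus/tilt terms into a spec so the generated PSF stays
# centered; displacement modes themselves are left untouched
compensated_spec <- function(spec, config) {
  dz <- 0; dx <- 0; dy <- 0
  for (m in setdiff(names(spec), shift_modes)) {
    a <- spec_get(spec, m)
    if (a == 0) next
    sh <- calibrate_mode_shifts(m, config)
    dz <- dz + sh$axial * a          # defocus_offset d displaces the PSF by -d
    dx <- dx - sh$lateral["x"] * a   # tilt_x t displaces the PSF by +t
    dy <- dy - sh$lateral["y"] * a
  }
  if (dz == 0 && dx == 0 && dy == 0) return(spec)
  v <- unclass(spec)
  v["defocus_offset"] <- spec_get(spec, "defocus_offset") + dz
  v["tilt_x"] <- spec_get(spec, "tilt_x") + dx
  v["tilt_y"] <- spec_get(spec, "tilt_y") + dy
  aberration_spec(magnitudes = v[v != 0 | names(v) %in% names(spec)])
}
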