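#' Optical configuration of a 3D wide-field acquisition
#'
#' Bundles the physical parameters needed to build pupil functions, PSFs and
#' OTFs: objective numerical aperture, emission wavelength, immersion
#' refractive index, voxel spacing, stack shape and the side length of the
#' square pupil grid.
#'
#' @param na numerical aperture of the objective (dimensionless, > 0)
#' @param wavelength emission wavelength in nm
#' @param n_immersion refractive index of the immersion medium; must satisfy
#'   `na <= n_immersion`
#' @param voxel voxel spacing in nm as `c(dz, dy, dx)`
#' @param shape stack shape in voxels as `c(nz, ny, nx)`
#' @param pupil_size side of the square pupil grid in pixels (>= 256; smaller
#'   grids alias the pupil phase)
#' @param immersion_thickness design thickness of the immersion layer in nm;
#'   sets the lever arm of the Gibson-Lanni spherical-aberration and defocus
#'   optical path differences
#' @return an object of class `optical_config`
#' @export
#' @examples
#' cfg <- optical_config(na = 1.42, wavelength = 528, n_immersion = 1.515,
#'                       voxel = c(267, 92, 92), shape = c(32, 64, 64),
#'                       pupil_size = 256)
optical_config <- function(na, wavelength, n_immersion,
                           voxel = c(267, 92, 92),
                           shape = c(128, 128, 128),
                           pupil_size = 512,
                           immersion_thickness = 1.5e5) {
  stopifnot(is.numeric(na), length(na) == 1, is.finite(na),
            is.numeric(wavelength), length(wavelength) == 1,
            is.numeric(n_immersion), length(n_immersion) == 1,
            length(voxel) == 3, length(shape) == 3,
            length(pupil_size) == 1)
  if (na <= 0) stop("`na` must be > 0", call. = FALSE)
  if (wavelength <= 0) stop("`wavelength` must be > 0", call. = FALSE)
  if (na / n_immersion > 1)
    stop("`na` must not exceed `n_immersion` (asin(NA/n) undefined)", call. = FALSE)
  if (any(voxel <= 0)) stop("all voxel spacings must be > 0", call. = FALSE)
  shape <- as.integer(shape)
  if (any(shape < 1)) stop("all shape entries must be >= 1", call. = FALSE)
  pupil_size <- as.integer(pupil_size)
  if (pupil_size < 256)
    stop("`pupil_size` must be at least 256 pixels to avoid aliasing artifacts",
         call. = FALSE)
  if (shape[2] > pupil_size || shape[3] > pupil_size)
    stop("lateral stack shape exceeds the computable pupil-grid field", call. = FALSE)
  # pupil circle must occupy less than half the grid, or the wrapped replicas
  # of the pupil overlap (aliasing)
  r_pix <- na * pupil_size * max(voxel[2:3]) / wavelength
  if (r_pix >= pupil_size / 2)
    stop("pupil radius NA/lambda exceeds the pupil grid's Nyquist limit; ",
         "increase `pupil_size` or decrease the lateral voxel size", call. = FALSE)
  structure(
    list(na = na, wavelength = wavelength, n_immersion = n_immersion,
         voxel = as.numeric(voxel), shape = shape,
         pupil_size = pupil_size,
         immersion_thickness = immersion_thickness),
    class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  NA %.3f, lambda %g nm, n %.4f (theta = %.1f deg)\n",
              x$na, x$wavelength, x$n_immersion,
              asin(x$na / x$n_immersion) * 180 / pi))
  cat(sprintf("  stack %d x %d x %d (z,y,x), voxel %g x %g x %g nm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel[1], x$voxel[2], x$voxel[3]))
  cat(sprintf("  pupil grid %d px, immersion thickness %g um\n",
              x$pupil_size, x$immersion_thickness / 1e3))
  invisible(x)
}

# collection half-angle in the immersion medium
collection_angle <- function(config) asin(config$na / config$n_immersion)

# lateral/axial cut-off frequencies of the incoherent imaging system (cycles/nm)
frequency_limits <- function(config) {
  theta <- collection_angle(config)
  list(k_lat = 2 * config$na / config$wavelength,
       k_ax  = config$n_immersion * (1 - cos(theta)) / config$wavelength)
}

# pupil-grid frequency axes (cycles/nm, corner order); col = u (x), row = v (y)
pupil_freqs <- function(config) {
  n <- config$pupil_size
  list(ku = fft_freq(n, config$voxel[3]),
       kv = fft_freq(n, config$voxel[2]))
}

# key identifying everything a PSF depends on except the aberrations
config_key <- function(config) {
  paste(config$na, config$wavelength, config$n_immersion,
        paste(config$voxel, collapse = ","),
        paste(config$shape, collapse = ","),
        config$pupil_size, config$immersion_thickness, sep = "|")
}
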