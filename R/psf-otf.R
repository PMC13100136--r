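# Theoretical 3D PSFs by per-slice 2D inverse Fourier transforms of the
# pupil, stacked over sequential defocus positions, and their 3D OTFs split
# into amplitude (MTF) and phase (PTF) components.

# package-level cache for ideal MTFs, calibrations etc.
.phicao_cache <- new.env(parent = emptyenv())

cache_get_or <- function(key, compute) {
  if (!exists(key, envir = .phicao_cache, inherits = FALSE))
    assign(key, compute(), envir = .phicao_cache)
  get(key, envir = .phicao_cache, inherits = FALSE)
}

# |ifft2(P(z))|^2 stacked over the config's defocus positions and cropped to
# the configured lateral shape. `p_static` is the corner-order complex pupil
# including all z-independent phase; the defocus OPD (nm per nm of z) is
# added per slice. Returns array [ny, nx, nz].
pupil_defocus_stack <- function(config, p_static, idx, wd_unit_idx) {
  n <- config$pupil_size
  nz <- config$shape[1]; ny <- config$shape[2]; nx <- config$shape[3]
  sel_y <- crop_index(ny, n)
  sel_x <- crop_index(nx, n)
  icz <- floor(nz / 2) + 1L
  k <- 2 * pi / config$wavelength
  out <- array(0, dim = c(ny, nx, nz))
  base <- matrix(0i, n, n)
  pv <- p_static[idx]
  for (iz in seq_len(nz)) {
    z <- (iz - icz) * config$voxel[1]
    p <- base
    p[idx] <- pv * exp(1i * k * z * wd_unit_idx)
    a <- stats::fft(p, inverse = TRUE)
    out[, , iz] <- (Mod(a)^2)[sel_y, sel_x]
  }
  out
}

#' Compute a theoretical 3D point spread function
#'
#' Builds the (aberrated) pupil, inverse-transforms it slice by slice over the
#' configured defocus range, takes the squared modulus, and crops the central
#' region to the configured stack shape.
#'
#' By default the axial and lateral displacements that each aberration mode
#' induces are cancelled by calibrated compensating defocus/tilt terms
#' (`compensate = TRUE`), so the PSF stays centered on the grid while its
#' shape carries the aberration. Pure `tilt_x`/`tilt_y`/`defocus_offset`
#' terms are never compensated (they are displacements by definition).
#'
#' @inheritParams make_pupil
#' @param compensate cancel calibrated per-mode focal/lateral shifts
#' @return a `psf3d`: list with `data` (array `[ny, nx, nz]`, nonnegative),
#'   `config` and the (compensated) `spec`
#' @export
make_psf <- function(config, spec = aberration_spec(),
                     amplitude_model = c("none", "b_prime"), dn2 = 0,
                     compensate = TRUE) {
  amplitude_model <- match.arg(amplitude_model)
  if (compensate) spec <- compensated_spec(spec, config)
  if (config$shape[2] > config$pupil_size || config$shape[3] > config$pupil_size)
    stop("configured shape larger than the computable pupil field", call. = FALSE)
  g <- pupil_grids(config)
  mask <- g$kr2 < (config$na / config$wavelength)^2
  amp <- matrix(0, config$pupil_size, config$pupil_size)
  amp[mask] <- 1
  if (amplitude_model == "b_prime")
    amp[mask] <- amp[mask] * b_prime_amplitude(config, dn2)[mask]
  w <- build_wavefront(spec, config)
  p_static <- ifftshift(amp * exp((2i * pi / config$wavelength) * w))
  mask_c <- ifftshift(mask)
  idx <- which(mask_c)
  wd_unit <- ifftshift(sqrt(pmax(config$n_immersion^2 -
                                   config$wavelength^2 * g$kr2, 0)) -
                         config$n_immersion)[idx]
  data <- pupil_defocus_stack(config, p_static, idx, wd_unit)
  structure(list(data = data, config = config, spec = spec,
                 amplitude_model = amplitude_model, dn2 = dn2),
            class = "psf3d")
}

#' @export
print.psf3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<psf3d> %d x %d x %d (y,x,z), peak %.4g, total %.4g\n",
              d[1], d[2], d[3], max(x$data), sum(x$data)))
  if (length(x$spec)) print(x$spec)
  invisible(x)
}

#' 3D OTF of a PSF, split into amplitude (MTF) and phase (PTF)
#'
#' Applies a 3D Fourier transform to the PSF (with its center moved to the
#' transform origin so an unaberrated PSF has a flat phase) and stores the
#' amplitude and phase components DC-centered, together with the frequency
#' axes and the lateral/axial support limits of the imaging system.
#'
#' @param psf a `psf3d` (or an `image_stack`)
#' @return an `otf3d`: list with `amplitude` (MTF, >= 0), `phase` (PTF,
#'   radians in (-pi, pi]), frequency axes `kx`, `ky`, `kz` (cycles/nm,
#'   DC-centered) and `limits` (lateral and axial cut-off frequencies)
#' @export
psf_to_otf <- function(psf) {
  data <- if (inherits(psf, "psf3d")) psf$data else psf$data
  config <- psf$config
  if (!all(is.finite(data))) stop("PSF contains non-finite values", call. = FALSE)
  if (all(data == 0)) stop("all-zero PSF: OTF phase undefined", call. = FALSE)
  o <- stats::fft(ifftshift(data))
  lim <- frequency_limits(config)
  structure(list(
    amplitude = fftshift(Mod(o)),
    phase = fftshift(Arg(o)),
    kx = fftshift(fft_freq(dim(data)[2], config$voxel[3])),
    ky = fftshift(fft_freq(dim(data)[1], config$voxel[2])),
    kz = fftshift(fft_freq(dim(data)[3], config$voxel[1])),
    limits = lim, config = config), class = "otf3d")
}

#' @export
print.otf3d <- function(x, ...) {
  d <- dim(x$amplitude)
  cat(sprintf("<otf3d> %d x %d x %d, DC amplitude %.4g\n", d[1], d[2], d[3],
              x$amplitude[floor(d[1] / 2) + 1, floor(d[2] / 2) + 1,
                          floor(d[3] / 2) + 1]))
  cat(sprintf("  support: |k_lat| < %.4g, |k_ax| < %.4g cycles/nm\n",
              x$limits$k_lat, x$limits$k_ax))
  invisible(x)
}

# corner-order PTF of the aberrated PSF for a spec (internal fast path)
aberrated_ptf_corner <- function(config, spec, compensate = TRUE) {
  psf <- make_psf(config, spec, compensate = compensate)
  Arg(stats::fft(ifftshift(psf$data)))
}

# corner-order ideal MTF, normalized to unit DC (cached per config)
ideal_mtf_corner <- function(config) {
  cache_get_or(paste0("mtf|", config_key(config)), function() {
    psf <- make_psf(config, aberration_spec(), compensate = FALSE)
    a <- Mod(stats::fft(ifftshift(psf$data)))
    a / a[1]
  })
}

# corner-order logical support box |kx| < kxmax & |ky| < kymax & |kz| < kzmax
support_mask_corner <- function(config) {
  cache_get_or(paste0("supp|", config_key(config)), function() {
    lim <- frequency_limits(config)
    nz <- config$shape[1]; ny <- config$shape[2]; nx <- config$shape[3]
    kx <- abs(fft_freq(nx, config$voxel[3]))
    ky <- abs(fft_freq(ny, config$voxel[2]))
    kz <- abs(fft_freq(nz, config$voxel[1]))
    okx <- kx < lim$k_lat; oky <- ky < lim$k_lat; okz <- kz < lim$k_ax
    outer(outer(oky, okx, `&`), okz, `&`)
  })
}
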