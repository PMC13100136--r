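# Pupil functions: hard-edged circular support of radius NA/lambda, phase
# from the summed mode wavefronts plus the defocus term, optionally with the
# B' amplitude modulation used during correction.

# Fresnel-transmission x wavefront-compression amplitude factor over the
# pupil, for a sample refractive index n + dn2 emitting into the immersion
# medium of index n. Mean of s- and p-polarized amplitude transmissions times
# the compression apodization sqrt(n cos(theta_i) / (n_s cos(theta_s))).
b_prime_amplitude <- function(config, dn2) {
  g <- pupil_grids(config)
  n <- config$n_immersion
  ns <- n + dn2
  sin_i <- config$wavelength * sqrt(g$kr2) / n     # immersion-side angle
  sin_i[sin_i > 1] <- 1
  cos_i <- sqrt(1 - sin_i^2)
  sin_s <- n * sin_i / ns                           # sample-side angle (Snell)
  b <- matrix(0, nrow(sin_s), ncol(sin_s))
  ok <- sin_s < 1                                   # beyond: no propagating wave
  cos_s <- sqrt(pmax(1 - sin_s[ok]^2, 0))
  ci <- cos_i[ok]
  ts <- 2 * ns * cos_s / (ns * cos_s + n * ci)
  tp <- 2 * ns * cos_s / (ns * ci + n * cos_s)
  compression <- sqrt((n * ci) / (ns * cos_s))
  b[ok] <- 0.5 * (ts + tp) * compression
  b
}

#' Build a (possibly aberrated) pupil function
#'
#' The pupil is 1 inside the circle u^2 + v^2 < (NA/lambda)^2 and 0 outside;
#' aberrations multiply a unit-modulus phase factor exp(i 2 pi / lambda
#' (W_a + W_d(z) + W_t)) onto it. With `amplitude_model = "b_prime"` the
#' amplitude inside the support is additionally modulated by the
#' Fresnel-transmission x wavefront-compression factor for a sample-side
#' index mismatch `dn2`.
#'
#' @param config an [optical_config()]
#' @param spec an [aberration_spec()]
#' @param z axial (defocus) offset in nm
#' @param amplitude_model `"none"` (phase-only pupil) or `"b_prime"`
#' @param dn2 sample-side refractive-index mismatch for the B' model
#' @return a `pupil_function`: complex `pupil_size` x `pupil_size` matrix,
#'   DC-centered, with the support mask as attribute `mask`
#' @export
make_pupil <- function(config, spec = aberration_spec(), z = 0,
                       amplitude_model = c("none", "b_prime"), dn2 = 0) {
  amplitude_model <- match.arg(amplitude_model)
  g <- pupil_grids(config)
  mask <- g$kr2 < (config$na / config$wavelength)^2
  amp <- matrix(0, config$pupil_size, config$pupil_size)
  amp[mask] <- 1
  if (amplitude_model == "b_prime")
    amp[mask] <- amp[mask] * b_prime_amplitude(config, dn2)[mask]
  w <- build_wavefront(spec, config)
  if (z != 0)
    w <- w + unclass(make_wavefront("defocus_offset", z, config))
  p <- amp * exp((2i * pi / config$wavelength) * w)
  p[!mask] <- 0
  structure(p, class = "pupil_function", mask = mask, config = config,
            amplitude_model = amplitude_model, dn2 = dn2)
}

#' @export
print.pupil_function <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<pupil_function> %d x %d px, NA/lambda radius %.1f px, amplitude model: %s\n",
              nrow(x), ncol(x),
              cfg$na * cfg$pupil_size * cfg$voxel[3] / cfg$wavelength,
              attr(x, "amplitude_model")))
  invisible(x)
}
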