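# Aberration removal: Wiener deconvolution with the aberrated OTF
# (amplitude and phase), re-imposing the ideal MTF, with an optional
# Fresnel/compression amplitude model of the pupil driven by the sample-side
# index mismatch estimated from the measured immersion-side mismatch.

#' Parameters of the correction step
#'
#' @param wiener Wiener constant of the amplitude-and-phase deconvolution
#'   (default 0.01, relative to a unit-peak MTF)
#' @param reference_depth depth (nm) at which the sample-side wavefront is
#'   matched to the measured immersion-side wavefront (default 5 um)
#' @param use_amplitude_model apply the B' amplitude modulation to the
#'   correction pupil
#' @return a `correction_params` list
#' @export
correction_params <- function(wiener = 0.01, reference_depth = 5000,
                              use_amplitude_model = FALSE) {
  stopifnot(wiener > 0, wiener < 1, reference_depth > 0)
  structure(list(wiener = wiener, reference_depth = reference_depth,
                 use_amplitude_model = use_amplitude_model),
            class = "correction_params")
}

# piston+defocus-free residual of a pupil-support vector: remove the
# least-squares projection onto {1, defocus OPD}
residual_wavefront <- function(w, wd) {
  x <- cbind(1, wd)
  w - x %*% qr.solve(x, w)
}

#' Estimate the sample-side index mismatch from the measured immersion-side one
#'
#' The measurement parametrizes spherical aberration by the immersion-medium
#' index mismatch; the amplitude model needs the sample-side mismatch. The
#' latter is chosen so the spherical-aberration wavefront of an emitter at
#' the reference depth best matches (least squares over the pupil support,
#' after removing piston and defocus) the measured immersion-side wavefront.
#'
#' @param spec an [aberration_spec()] containing the measured `sa` term
#' @param config an [optical_config()]
#' @param params [correction_params()]; `reference_depth` is used
#' @param interval search interval for the mismatch
#' @return the estimated sample-side index mismatch (0 when `spec` has no
#'   `sa` term)
#' @export
estimate_dn2 <- function(spec, config, params = correction_params(),
                         interval = c(-0.1, 0.1)) {
  dn1 <- spec_get(spec, "sa")
  if (dn1 == 0) return(0)
  g <- pupil_grids(config)
  mask <- g$kr2 < (config$na / config$wavelength)^2
  kr2 <- g$kr2[mask]
  n <- config$n_immersion
  wd <- sqrt(pmax(n^2 - config$wavelength^2 * kr2, 0))
  w1 <- residual_wavefront(
    config$immersion_thickness *
      (sqrt(pmax((n + dn1)^2 - config$wavelength^2 * kr2, 0)) - wd), wd)
  depth_opd <- function(dn2)
    params$reference_depth *
      (sqrt(pmax((n + dn2)^2 - config$wavelength^2 * kr2, 0)) - wd)
  obj <- function(dn2) sum((residual_wavefront(depth_opd(dn2), wd) - w1)^2)
  stats::optimize(obj, interval = interval, tol = 1e-7)$minimum
}

#' Correct a 3D stack for measured aberrations
#'
#' Builds the aberrated OTF `O'' = A'' e^(i phi'')` for the measured spec
#' (optionally with the B' amplitude-modulated pupil), then applies the
#' amplitude-and-phase Wiener filter `A e^(-i phi'') / (A'' + w^2)` inside
#' the frequency support (zero outside), where `A` is the same-configuration
#' ideal MTF: the aberrated amplitude and phase are deconvolved and the ideal
#' MTF is re-imposed. Negative output values are retained.
#'
#' @param stack an [image_stack()]
#' @param spec the measured [aberration_spec()] (or a `cao_fit`)
#' @param params [correction_params()]
#' @return the corrected [image_stack()]
#' @export
correct_stack <- function(stack, spec, params = correction_params()) {
  if (inherits(spec, "cao_fit")) spec <- spec$estimate
  config <- stack$config
  dn2 <- 0
  amodel <- "none"
  if (params$use_amplitude_model) {
    dn2 <- estimate_dn2(spec, config, params)
    amodel <- "b_prime"
  }
  psf_ab <- make_psf(config, spec, amplitude_model = amodel, dn2 = dn2,
                     compensate = TRUE)
  o <- stats::fft(ifftshift(psf_ab$data))
  o <- o / Mod(o[1])                      # unit-DC aberrated MTF
  a <- ideal_mtf_corner(config)
  supp <- support_mask_corner(config)
  h <- array(0i, dim = dim(o))
  # phase unwound, amplitude divided by the real A'' + w^2: keeps the
  # Wiener magnitude A/(A'' + w^2) while the denominator cannot vanish
  am <- Mod(o[supp])
  h[supp] <- a[supp] * (Conj(o[supp]) / pmax(am, 1e-300)) / (am + params$wiener^2)
  out <- Re(ifft(stats::fft(stack$data) * h))
  image_stack(out, config, background = stack$background)
}

#' Strehl ratio of a corrected image against a reference
#'
#' @param corrected,reference [image_stack()]s (or arrays) of the same object
#' @return ratio of peak intensities
#' @export
strehl_ratio <- function(corrected, reference) {
  a <- if (inherits(corrected, "image_stack")) corrected$data else corrected
  b <- if (inherits(reference, "image_stack")) reference$data else reference
  max(a) / max(b)
}

#' Peak-intensity recovery versus number of optical sections
#'
#' Simulates a point source carrying spherical aberration, retains only
#' `section_counts` optical sections at the Nyquist axial interval around the
#' brightest plane (all other sections zero), corrects each sparse stack with
#' the true aberration, and reports the corrected peak intensity as a
#' percentage of the aberration-free, fully sampled peak.
#'
#' @param config an [optical_config()]
#' @param dn1 spherical-aberration magnitude (immersion index mismatch)
#' @param section_counts integer vector of section numbers (>= 1)
#' @param params [correction_params()]
#' @return data.frame with `sections` and `recovery_percent`
#' @export
intensity_recovery_curve <- function(config, dn1, section_counts = c(3, 5),
                                     params = correction_params()) {
  stopifnot(all(section_counts >= 1))
  spec <- aberration_spec(sa = dn1)
  h_ref <- make_psf(config, aberration_spec())$data
  h_ab <- if (dn1 == 0) h_ref else make_psf(config, spec)$data
  nz <- config$shape[1]
  # Nyquist axial interval of the imaging system, in sections
  k_ax <- frequency_limits(config)$k_ax
  spacing <- max(1L, as.integer(round(1 / (2 * k_ax) / config$voxel[1])))
  iz_peak <- arrayInd(which.max(h_ab), dim(h_ab))[3]
  rec <- vapply(section_counts, function(ns) {
    keep <- iz_peak + spacing * (seq_len(ns) - (ns + 1) %/% 2)
    keep <- keep[keep >= 1 & keep <= nz]
    sparse <- array(0, dim = dim(h_ab))
    sparse[, , keep] <- h_ab[, , keep]
    corr <- correct_stack(image_stack(sparse, config), spec, params)
    100 * max(corr$data) / max(h_ref)
  }, numeric(1))
  data.frame(sections = section_counts, recovery_percent = rec)
}
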