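# Wavefronts: optical path difference (OPD) surfaces over the pupil, in nm.
#
# Spherical aberration and defocus follow the Gibson-Lanni picture: both are
# optical path differences accumulated across the immersion layer, defocus by
# varying its thickness, SA by mismatching its refractive index. Coma,
# astigmatism and tilt are low-order polynomials in the pupil coordinates;
# higher orders use Zernike polynomials in Wyant ordering.

# pupil coordinate grids, DC-centered; rows = v (y), cols = u (x)
pupil_grids <- function(config) {
  fr <- pupil_freqs(config)
  ku <- fftshift(fr$ku)
  kv <- fftshift(fr$kv)
  n <- config$pupil_size
  KU <- matrix(ku, n, n, byrow = TRUE)
  KV <- matrix(kv, n, n)
  list(ku = KU, kv = KV, kr2 = KU^2 + KV^2)
}

# OPD across the immersion layer for index n_eff relative to design index n,
# per Gibson-Lanni; kr2 = ku^2 + kv^2 in (cycles/nm)^2
immersion_opd <- function(n_eff, config, kr2) {
  lam2 <- config$wavelength^2
  t <- config$immersion_thickness
  t * (sqrt(pmax(n_eff^2 - lam2 * kr2, 0)) -
         sqrt(pmax(config$n_immersion^2 - lam2 * kr2, 0)))
}

#' Generate the wavefront (OPD surface) of a single aberration mode
#'
#' Returns the optical path difference over the pupil grid, in nm, for one
#' aberration mode at the given magnitude. `sa` magnitudes are immersion
#' refractive-index mismatches; `coma_*`, `astig_*` and `z<j>` magnitudes are
#' coefficients in wavelength units at the pupil edge; `tilt_x`/`tilt_y` and
#' `defocus_offset` magnitudes are lateral/axial displacements in nm.
#'
#' @param mode mode identifier (see [aberration_spec()])
#' @param magnitude mode magnitude (finite)
#' @param config an [optical_config()]
#' @return a `wavefront`: a `pupil_size` x `pupil_size` matrix of OPD values
#'   in nm, DC-centered, with the generating mode and magnitude as attributes
#' @export
make_wavefront <- function(mode, magnitude, config) {
  if (!is.numeric(magnitude) || length(magnitude) != 1 || !is.finite(magnitude))
    stop("`magnitude` must be a single finite number", call. = FALSE)
  if (!is_known_mode(mode))
    stop("unknown aberration mode: '", mode, "'", call. = FALSE)
  g <- pupil_grids(config)
  lam <- config$wavelength
  w <- switch(mode,
    sa = immersion_opd(config$n_immersion + magnitude, config, g$kr2),
    coma_u = {
      ru <- lam * g$ku / config$na; rv <- lam * g$kv / config$na
      magnitude * lam * (ru^2 + rv^2) * ru
    },
    coma_v = {
      ru <- lam * g$ku / config$na; rv <- lam * g$kv / config$na
      magnitude * lam * (ru^2 + rv^2) * rv
    },
    astig_0 = {
      ru <- lam * g$ku / config$na
      0.5 * magnitude * lam * ru^2
    },
    astig_45 = {
      ru <- lam * g$ku / config$na; rv <- lam * g$kv / config$na
      0.5 * magnitude * lam * ((ru + rv) / sqrt(2))^2
    },
    # phase (2 pi / lambda) W_t = -2 pi (x ku + y kv): shifts the PSF by
    # exactly the requested displacement
    tilt_x = -lam * magnitude * g$ku,
    tilt_y = -lam * magnitude * g$kv,
    defocus_offset = magnitude *
      (sqrt(pmax(config$n_immersion^2 - lam^2 * g$kr2, 0)) - config$n_immersion),
    {
      # Zernike z<j>
      ru <- lam * g$ku / config$na; rv <- lam * g$kv / config$na
      rho <- sqrt(ru^2 + rv^2)
      phi <- atan2(rv, ru)
      magnitude * lam * zernike_wyant(wyant_index(mode), rho, phi)
    })
  if (mode == "sa") {
    # remove piston so that zero magnitude gives an identically zero grid
    ic <- floor(config$pupil_size / 2) + 1L
    w <- w - w[ic, ic]
  }
  structure(w, class = "wavefront", mode = mode, magnitude = magnitude,
            config = config)
}

# sum of mode wavefronts for a spec (plain matrix, nm)
build_wavefront <- function(spec, config) {
  n <- config$pupil_size
  w <- matrix(0, n, n)
  for (m in names(spec)) {
    a <- spec_get(spec, m)
    if (a != 0) w <- w + unclass(make_wavefront(m, a, config))
  }
  w
}

#' Root-mean-square wavefront error of an aberration spec
#'
#' RMS of the combined OPD surface over the pupil support, in nm.
#'
#' @param spec an [aberration_spec()]
#' @param config an [optical_config()]
#' @param piston_free subtract the support mean (piston) before taking the RMS
#' @return RMS wavefront error in nm
#' @export
rms_wavefront <- function(spec, config, piston_free = TRUE) {
  g <- pupil_grids(config)
  mask <- g$kr2 < (config$na / config$wavelength)^2
  w <- build_wavefront(spec, config)[mask]
  if (piston_free) w <- w - mean(w)
  sqrt(mean(w^2))
}
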