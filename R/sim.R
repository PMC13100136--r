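# 3D structured illumination: three-beam illumination pupils (three Gaussian
# spots), aberrated SIM PSFs and order OTFs, 5-phase order separation, the
# modulation-amplitude aberration metric, and a minimal generalized-Wiener
# recombination so the metric is exercisable end to end.

#' Configuration of the 3D-SIM illumination
#'
#' Three-beam geometry: per illumination angle, the excitation pupil carries
#' Gaussian spots at diffraction orders n = -1, 0, +1; the n = +/-1 spots sit
#' at `+/- zoom * k_frac * NA / lambda` (rounded onto the image frequency
#' lattice so order separation and band shifting are exact) and are phase
#' stepped by `+/- 2 pi s / 5` over the five pattern phases.
#'
#' @param config the detection-side [optical_config()]
#' @param n_angles number of illumination rotations
#' @param angles rotation angles in radians (default evenly spaced from 0)
#' @param n_phases number of pattern phases (must be 5)
#' @param k_frac first-order spot offset as a fraction of NA/lambda
#' @param zoom pupil zoom coefficient applied to the spot positions
#' @param spot_sigma Gaussian spot standard deviation in pupil-grid pixels
#' @return a `sim_config`
#' @export
sim_config <- function(config, n_angles = 3, angles = NULL, n_phases = 5,
                       k_frac = 0.9, zoom = 1, spot_sigma = 0.4) {
  if (n_phases != 5)
    stop("three-beam SIM separation requires exactly 5 phases", call. = FALSE)
  stopifnot(spot_sigma > 0, n_angles >= 1)
  if (is.null(angles)) angles <- (seq_len(n_angles) - 1) * pi / n_angles
  stopifnot(length(angles) == n_angles)
  k1 <- zoom * k_frac * config$na / config$wavelength
  if (k1 >= config$na / config$wavelength)
    stop("first-order spot lies outside the pupil (zoom * k_frac >= 1)",
         call. = FALSE)
  ny <- config$shape[2]; nx <- config$shape[3]
  dy <- config$voxel[2]; dx <- config$voxel[3]
  ang <- lapply(angles, function(a) {
    cx <- round(k1 * cos(a) * nx * dx)   # integer cycles across the field
    cy <- round(k1 * sin(a) * ny * dy)
    list(angle = a, cycles = c(y = cy, x = cx),
         mu1 = c(y = cy / (ny * dy), x = cx / (nx * dx)))
  })
  structure(list(config = config, n_angles = n_angles, n_phases = n_phases,
                 k_frac = k_frac, zoom = zoom, spot_sigma = spot_sigma,
                 angles = ang), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d angle(s) x %d phases, spot sigma %.2g px\n",
              x$n_angles, x$n_phases, x$spot_sigma))
  for (a in x$angles)
    cat(sprintf("  angle %5.1f deg: pattern %d x-cycles, %d y-cycles (|mu1| %.4g /nm)\n",
                a$angle * 180 / pi, a$cycles["x"], a$cycles["y"],
                sqrt(sum(a$mu1^2))))
  invisible(x)
}

# pupil-lattice pixels composing the three Gaussian spots of one angle:
# data.frame with spot frequencies (cycles/nm), amplitudes and order index
sim_spot_table <- function(config, sim, angle_index,
                           beam_weights = c(1, 1, 1)) {
  a <- sim$angles[[angle_index]]
  n <- config$pupil_size
  dku <- 1 / (n * config$voxel[3])
  dkv <- 1 / (n * config$voxel[2])
  sig <- sim$spot_sigma
  r <- max(2L, ceiling(4 * sig))
  offs <- expand.grid(ov = -r:r, ou = -r:r)
  rows <- list()
  for (i in 1:3) {
    nn <- c(-1L, 0L, 1L)[i]
    w <- beam_weights[i]
    if (w == 0) next
    pu <- nn * a$mu1["x"] / dku      # spot center in pupil pixels (real)
    pv <- nn * a$mu1["y"] / dkv
    iu <- round(pu) + offs$ou
    iv <- round(pv) + offs$ov
    amp <- w * exp(-((iu - pu)^2 + (iv - pv)^2) / (2 * sig^2))
    keep <- amp > 1e-6 * max(abs(beam_weights))
    if (max(abs(c(iu[keep], iv[keep]))) >= n / 2)
      stop("illumination spot falls off the pupil grid", call. = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      ku = iu[keep] * dku, kv = iv[keep] * dkv, amp = amp[keep], order = nn)
  }
  do.call(rbind, rows)
}

#' 3D illumination intensity profile of one SIM angle/phase
#'
#' Evaluates the three-spot excitation pupil (aberration and compensation
#' phases applied, defocus swept over the configured sections) directly on
#' the image grid and returns the squared field, normalized to approximately
#' unit mean.
#' With both side beams weighted zero the illumination is uniform
#' (conventional wide-field excitation).
#'
#' @param config detection [optical_config()]
#' @param sim a [sim_config()]
#' @param spec an [aberration_spec()] applied to the illumination path
#' @param angle_index illumination rotation (1-based)
#' @param phase_index pattern phase s in 0..4
#' @param beam_weights amplitudes of the n = -1, 0, +1 beams
#' @param compensate cancel calibrated mode shifts (as in [make_psf()])
#' @return numeric array `[ny, nx, nz]`
#' @export
make_sim_illumination <- function(config, sim, spec = aberration_spec(),
                                  angle_index = 1, phase_index = 0,
                                  beam_weights = c(1, 1, 1),
                                  compensate = TRUE) {
  ny <- config$shape[2]; nx <- config$shape[3]; nz <- config$shape[1]
  if (all(beam_weights[c(1, 3)] == 0))
    return(array(1, dim = c(ny, nx, nz)))
  if (compensate) spec <- compensated_spec(spec, config)
  spots <- sim_spot_table(config, sim, angle_index, beam_weights)
  # aberration and defocus OPD at the spot frequencies
  lam <- config$wavelength
  kr2 <- spots$ku^2 + spots$kv^2
  wab <- numeric(nrow(spots))
  if (length(spec)) {
    wgrid <- build_wavefront(spec, config)
    n <- config$pupil_size
    ic <- floor(n / 2) + 1L
    dku <- 1 / (n * config$voxel[3]); dkv <- 1 / (n * config$voxel[2])
    wab <- wgrid[cbind(round(spots$kv / dkv) + ic, round(spots$ku / dku) + ic)]
  }
  wd <- sqrt(pmax(config$n_immersion^2 - lam^2 * kr2, 0)) - config$n_immersion
  phase0 <- spots$order * 2 * pi * phase_index / 5
  cbase <- spots$amp * exp(1i * (phase0 + 2 * pi / lam * wab))
  yv <- (seq_len(ny) - (floor(ny / 2) + 1)) * config$voxel[2]
  xv <- (seq_len(nx) - (floor(nx / 2) + 1)) * config$voxel[3]
  vy <- exp(2i * pi * outer(yv, spots$kv))          # ny x J
  vx <- exp(2i * pi * outer(spots$ku, xv))          # J x nx
  icz <- floor(nz / 2) + 1L
  out <- array(0, dim = c(ny, nx, nz))
  for (iz in seq_len(nz)) {
    z <- (iz - icz) * config$voxel[1]
    cz <- cbase * exp(2i * pi / lam * z * wd)
    out[, , iz] <- Mod(vy %*% (cz * vx))^2
  }
  # pixels within one Gaussian spot add coherently over the (small) field, so
  # the mean intensity is close to the sum of squared per-order amplitude sums
  norm <- sum(tapply(spots$amp, spots$order, sum)^2)
  out / norm
}

#' Theoretical 3D-SIM PSF
#'
#' Product of the (aberrated) three-beam illumination profile and the
#' (aberrated) wide-field detection PSF; illumination and detection share the
#' same aberration spec.
#'
#' @inheritParams make_sim_illumination
#' @return a `psf3d`
#' @export
make_sim_psf <- function(config, sim, spec = aberration_spec(),
                         angle_index = 1, phase_index = 0,
                         beam_weights = c(1, 1, 1), compensate = TRUE) {
  ill <- make_sim_illumination(config, sim, spec, angle_index, phase_index,
                               beam_weights, compensate)
  det <- make_psf(config, spec, compensate = compensate)
  structure(list(data = ill * det$data, config = config, spec = det$spec,
                 amplitude_model = "none", dn2 = 0), class = "psf3d")
}

#' Simulate a raw 3D-SIM acquisition
#'
#' Multiplies the object by the illumination profile of every (angle, phase)
#' and convolves with the aberrated wide-field detection PSF; optionally adds
#' Poisson background noise per frame.
#'
#' @param object numeric array `[ny, nx, nx]` or [image_stack()]
#' @param config detection [optical_config()]
#' @param sim a [sim_config()]
#' @param spec an [aberration_spec()] shared by illumination and detection
#' @param peak_snr optional peak SNR of additive Poisson noise
#' @param seed RNG seed for the noise
#' @param beam_weights amplitudes of the n = -1, 0, +1 beams
#' @return a `sim_raw`: list with `data` indexed `[y, x, z, phase, angle]`,
#'   `config`, `sim`
#' @export
make_sim_raw <- function(object, config, sim, spec = aberration_spec(),
                         peak_snr = NULL, seed = NULL,
                         beam_weights = c(1, 1, 1)) {
  obj <- if (inherits(object, "image_stack")) object$data else object
  stopifnot(all(dim(obj) == config$shape[c(2, 3, 1)]))
  det <- make_psf(config, spec)
  hdet <- stats::fft(ifftshift(det$data))
  d <- array(0, dim = c(dim(obj), sim$n_phases, sim$n_angles))
  for (a in seq_len(sim$n_angles)) {
    for (s in seq_len(sim$n_phases)) {
      ill <- make_sim_illumination(config, sim, spec, a, s - 1, beam_weights)
      d[, , , s, a] <- Re(ifft(stats::fft(obj * ill) * hdet))
    }
  }
  if (max(d) > 0) d <- 100 * d / max(d)
  if (!is.null(peak_snr)) {
    mu <- (100 / peak_snr)^2
    d <- d + with_seed(seed, array(stats::rpois(length(d), mu), dim = dim(d)))
  }
  structure(list(data = d, config = config, sim = sim), class = "sim_raw")
}

#' @export
print.sim_raw <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<sim_raw> %d x %d x %d voxels, %d phases x %d angles\n",
              d[1], d[2], d[3], d[4], d[5]))
  invisible(x)
}

#' Pseudo-wide-field image of a raw SIM stack
#'
#' Sums the raw frames over all illumination phases (and rotations), washing
#' out the pattern and leaving a high-SNR wide-field-equivalent stack.
#'
#' @param raw a `sim_raw`
#' @return an [image_stack()]
#' @export
pseudo_widefield <- function(raw) {
  s <- apply(raw$data, c(1, 2, 3), sum)
  image_stack(s, raw$config)
}

#' Separate the frequency orders of a raw SIM stack
#'
#' Solves the 5-phase mixing system per illumination angle: the order-m
#' component is `(1/5) sum_s raw_s exp(-i m 2 pi s / 5)`. Returns the complex
#' spectra (FFT order) of orders m = 0, 1, 2 per angle; the m = -1, -2 bands
#' are their conjugate reflections.
#'
#' @param raw a `sim_raw`
#' @return list (one entry per angle) of lists with spectra `D0`, `D1`, `D2`
#' @export
separate_orders <- function(raw) {
  if (dim(raw$data)[4] != 5)
    stop("order separation requires the complete 5-phase set", call. = FALSE)
  lapply(seq_len(raw$sim$n_angles), function(a) {
    comps <- lapply(0:2, function(m) {
      acc <- array(0i, dim = dim(raw$data)[1:3])
      for (s in 0:4)
        acc <- acc + raw$data[, , , s + 1, a] * exp(-1i * m * 2 * pi * s / 5)
      stats::fft(acc / 5)
    })
    names(comps) <- c("D0", "D1", "D2")
    comps
  })
}

# band-centered order OTFs of one angle (corner-order complex arrays,
# normalized so the order-0 DC is 1), from the separated SIM PSF
sim_order_otfs <- function(config, sim, angle_index,
                           spec = aberration_spec(),
                           beam_weights = c(1, 1, 1)) {
  det <- make_psf(config, spec)
  ills <- lapply(0:4, function(s)
    make_sim_illumination(config, sim, spec, angle_index, s, beam_weights))
  cyc <- sim$angles[[angle_index]]$cycles
  otfs <- lapply(0:2, function(m) {
    acc <- array(0i, dim = dim(det$data))
    for (s in 0:4)
      acc <- acc + (ills[[s + 1]] * det$data) * exp(-1i * m * 2 * pi * s / 5)
    o <- stats::fft(ifftshift(acc / 5))
    shift_spectrum(o, c(m * cyc["y"], m * cyc["x"], 0))
  })
  names(otfs) <- c("O0", "O1", "O2")
  dc <- Mod(otfs$O0[1])
  lapply(otfs, function(o) o / dc)
}

#' Modulation amplitude of one interference order
#'
#' Correlates the overlap of the order-0 and order-m data bands, each
#' multiplied by the other band's OTF: `c_m e^(i phi_m)` is the complex
#' correlation of `D_0(k) O_m(k + mu_m)` with `D_m(k + mu_m) O_0(k)` at the
#' lattice-aligned pattern shift (optionally searched over neighboring
#' lattice shifts), and the modulation depth is its squared modulus.
#'
#' @param d0,dm corner-order spectra of the separated orders (see
#'   [separate_orders()])
#' @param o0,om corner-order band-centered order OTFs
#' @param mu_cycles integer pattern shift of order m in frequency bins,
#'   `c(y, x)`
#' @param search lattice search radius around `mu_cycles` (0 = fixed shift)
#' @return list with `c` (complex), `depth` (`|c|^2`), `phase`, and the
#'   lattice `shift` used
#' @export
modulation_amplitude <- function(d0, dm, o0, om, mu_cycles, search = 0) {
  best <- NULL
  for (oy in -search:search) for (ox in -search:search) {
    sh <- c(mu_cycles[1] + oy, mu_cycles[2] + ox, 0)
    p1 <- d0 * shift_spectrum(om, sh)
    p2 <- shift_spectrum(dm, sh) * o0
    den <- sum(Mod(p1)^2)
    if (den == 0) stop("empty overlap between the order bands", call. = FALSE)
    cc <- sum(Conj(p1) * p2) / den
    if (is.null(best) || Mod(cc) > Mod(best$c))
      best <- list(c = cc, depth = Mod(cc)^2, phase = Arg(cc), shift = sh[1:2])
  }
  best
}

# objective closure: sum of order-1 and order-2 modulation depths of one
# angle as a function of a trial aberration spec (Eq: order OTFs keep their
# ideal amplitude, only the phase component carries the trial aberration)
sim_modulation_objective <- function(raw, angle_index) {
  config <- raw$config
  sep <- separate_orders(raw)[[angle_index]]
  ideal <- sim_order_otfs(config, raw$sim, angle_index)
  amps <- lapply(ideal, Mod)
  cyc <- raw$sim$angles[[angle_index]]$cycles
  function(spec_trial) {
    phi <- aberrated_ptf_corner(config, spec_trial)
    ph <- exp(1i * phi)
    o0 <- amps$O0 * ph
    v <- 0
    for (m in 1:2) {
      om <- amps[[paste0("O", m)]] * ph
      v <- v + modulation_amplitude(sep$D0, sep[[paste0("D", m)]], o0, om,
                                    m * c(cyc["y"], cyc["x"]))$depth
    }
    v
  }
}

# pattern most perpendicular to a laterally asymmetric mode's axis
select_sim_angle <- function(sim, mode) {
  axis <- switch(mode, coma_u = 0, tilt_x = 0, coma_v = pi / 2,
                 tilt_y = pi / 2, NULL)
  if (is.null(axis)) return(1L)
  pa <- vapply(sim$angles, function(a) a$angle, numeric(1))
  which.max(abs(sin(pa - axis)))
}

#' Measure aberrations from a raw 3D-SIM stack
#'
#' Runs the same sampled-and-fitted magnitude search as
#' [measure_aberrations()], with either the modulation-amplitude objective
#' (cross-correlation of separated orders, sensitive to the trial phase) or
#' the pseudo-wide-field sharpness objective. With the modulation objective,
#' laterally asymmetric modes are scanned on the illumination angle most
#' perpendicular to their asymmetry axis.
#'
#' @param raw a `sim_raw`
#' @param modes as in [measure_aberrations()]
#' @param objective `"modulation"` or `"pseudo_wfm"`
#' @inheritParams measure_aberrations
#' @return a `cao_fit`
#' @export
measure_aberrations_sim <- function(raw, modes = "sa", n_iterations = 2,
                                    plan = sampling_plan(),
                                    params = metric_params(),
                                    objective = c("modulation", "pseudo_wfm"),
                                    verbose = FALSE) {
  objective <- match.arg(objective)
  modes <- resolve_modes(modes)
  if (objective == "pseudo_wfm") {
    fit <- measure_aberrations(pseudo_widefield(raw), modes, n_iterations,
                               plan, params, verbose = verbose)
    fit$objective <- "pseudo_wfm"
    return(fit)
  }
  objs <- list()
  obj_for <- function(mode) {
    a <- select_sim_angle(raw$sim, mode)
    key <- as.character(a)
    if (is.null(objs[[key]]))
      objs[[key]] <<- sim_modulation_objective(raw, a)
    objs[[key]]
  }
  out <- measure_engine(function(spec_trial, mode) obj_for(mode)(spec_trial),
                        modes, raw$config, n_iterations, plan,
                        verbose = verbose)
  out$config <- raw$config
  out$params <- params
  out$plan <- plan
  out$objective <- "modulation"
  class(out) <- "cao_fit"
  out
}

#' Minimal generalized-Wiener 3D-SIM reconstruction
#'
#' Separates the orders of each angle, shifts every band (m = -2..2) to its
#' true frequency position, weights it by the conjugate of its
#' (optionally aberration-carrying) order OTF, sums over bands and angles,
#' applies a Wiener denominator and a triangular apodization, and transforms
#' back. Intended to exercise the modulation metric end to end, not as a
#' production SIM reconstruction.
#'
#' @param raw a `sim_raw`
#' @param spec [aberration_spec()] used for the order OTFs (the measured
#'   aberration; empty for an uncorrected reconstruction)
#' @param fits optional list (per angle) of complex modulation amplitudes
#'   `c(m=1, m=2)` applied as band weights
#' @param wiener Wiener constant (relative to unit-DC order OTFs)
#' @param apodize apply the triangular apodization
#' @return an [image_stack()] (native voxel grid, extended-resolution content)
#' @export
reconstruct_sim <- function(raw, spec = aberration_spec(), fits = NULL,
                            wiener = 0.02, apodize = TRUE) {
  config <- raw$config
  sep_all <- separate_orders(raw)
  dims <- dim(raw$data)[1:3]
  num <- array(0i, dim = dims)
  den <- array(0, dim = dims)
  for (a in seq_len(raw$sim$n_angles)) {
    sep <- sep_all[[a]]
    if (any(vapply(sep, is.null, logical(1))))
      stop("missing separated order", call. = FALSE)
    otfs <- sim_order_otfs(config, raw$sim, a, spec)
    cyc <- raw$sim$angles[[a]]$cycles
    for (m in -2:2) {
      am <- abs(m)
      w_m <- if (!is.null(fits) && am > 0) {
        cm <- fits[[a]][am]
        if (m < 0) Conj(cm) else cm
      } else 1
      if (m >= 0) {
        dm <- sep[[paste0("D", am)]]
        om <- otfs[[paste0("O", am)]]
      } else {
        # negative band: conjugate reflection of the positive one
        dm <- Conj(flip_spectrum(sep[[paste0("D", am)]]))
        om <- Conj(flip_spectrum(otfs[[paste0("O", am)]]))
      }
      dsh <- shift_spectrum(dm, c(m * cyc["y"], m * cyc["x"], 0))
      num <- num + Conj(w_m * om) * dsh
      den <- den + Mod(w_m * om)^2
    }
  }
  s <- num / (den + wiener^2)
  if (apodize) {
    lim <- frequency_limits(config)
    mu2 <- 2 * max(vapply(raw$sim$angles, function(a)
      sqrt(sum(a$mu1^2)), numeric(1)))
    klcut <- lim$k_lat + mu2
    k1 <- max(vapply(raw$sim$angles, function(a) sqrt(sum(a$mu1^2)),
                     numeric(1)))
    n <- config$n_immersion; lam <- config$wavelength
    kzbeat <- (n / lam) * (1 - sqrt(pmax(1 - (lam * k1 / n)^2, 0)))
    kscut <- lim$k_ax + kzbeat
    kx <- fft_freq(dims[2], config$voxel[3])
    ky <- fft_freq(dims[1], config$voxel[2])
    kz <- fft_freq(dims[3], config$voxel[1])
    kl <- sqrt(outer(ky^2, kx^2, `+`))
    q <- sqrt(array(kl^2 / klcut^2, dim = dims) +
                array(rep(kz^2, each = dims[1] * dims[2]),
                      dim = dims) / kscut^2)
    s <- s * pmax(0, 1 - q)
  }
  image_stack(Re(ifft(s)), config)
}
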