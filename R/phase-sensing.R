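# Aberration measurement from a 3D wide-field stack: phase-only Wiener
# deconvolution with trial phase transfer functions, a penalized
# intensity-variance sharpness metric evaluated behind a cone bandpass
# filter, and a sampled-then-polynomial-fitted magnitude search iterated
# over modes and measurement cycles.

#' Parameters of the sharpness metric
#'
#' @param gamma penalty weight on the variance of squared negative
#'   intensities (default 10)
#' @param wiener Wiener constant of the phase-only deconvolution filter,
#'   relative to a unit-peak ideal MTF (default 0.22)
#' @param chi scaling factor of the cone bandpass filter (default 1.8)
#' @return a `metric_params` list
#' @export
metric_params <- function(gamma = 10, wiener = 0.22, chi = 1.8) {
  stopifnot(gamma >= 0, wiener > 0, wiener < 1, chi > 0)
  structure(list(gamma = gamma, wiener = wiener, chi = chi),
            class = "metric_params")
}

#' Sampling plan of the magnitude search
#'
#' Five initial samples per mode, centered on the running estimate with a
#' mode-class-specific step (refractive-index mismatch 0.01 for spherical
#' aberration, 0.125 wavelengths for coma/astigmatism, 0.5 for Zernike
#' coefficients), refined by typically two extra points bracketing the
#' running maximum, then a polynomial fit through the points nearest the
#' peak.
#'
#' @param step_sa initial step for `sa` (index mismatch units)
#' @param step_seidel initial step for coma/astigmatism (wavelength units)
#' @param step_zernike initial step for Zernike coefficients (wavelengths)
#' @param n_initial number of initial samples (odd, symmetric about center)
#' @param n_refine number of refinement rounds (each adds up to 2 points)
#' @param fit_order polynomial order of the peak fit
#' @param fit_points number of samples (nearest the peak) entering the fit
#' @return a `sampling_plan` list
#' @export
sampling_plan <- function(step_sa = 0.01, step_seidel = 0.125,
                          step_zernike = 0.5, n_initial = 5, n_refine = 2,
                          fit_order = 5, fit_points = 5) {
  stopifnot(n_initial >= 3, n_initial %% 2 == 1, n_refine >= 0,
            fit_order >= 2, fit_points >= 3)
  structure(list(step_sa = step_sa, step_seidel = step_seidel,
                 step_zernike = step_zernike, n_initial = n_initial,
                 n_refine = n_refine, fit_order = fit_order,
                 fit_points = fit_points), class = "sampling_plan")
}

# phase-only Wiener filter, corner order, rescaled to exactly unit DC gain
# so deconvolution conserves total intensity. Conjugate-regularized form
# A e^(-i phi) / (A^2 + w^2): the trial phase is unwound exactly while the
# amplitude gain is independent of the trial and vanishes where the ideal
# MTF does, so frequencies carrying no signal (only noise) are not amplified
# (a literal complex denominator A e^(i phi) + w^2 can nearly vanish where
# A ~ w^2 and phi ~ pi, which makes the metric blow up at large trial
# magnitudes, and a real denominator A + w^2 amplifies out-of-support noise
# by 1/w^2, which buries the metric at low SNR).
phase_only_filter_corner <- function(config, phi_corner, wiener) {
  a <- ideal_mtf_corner(config)
  supp <- support_mask_corner(config)
  g <- array(0i, dim = dim(a))
  g[supp] <- a[supp] * exp(-1i * phi_corner[supp]) / (a[supp]^2 + wiener^2)
  g / g[1]
}

#' Phase-only deconvolution of a 3D stack
#'
#' Unwinds a trial aberrated phase from the stack spectrum while applying the
#' Wiener-regularized ideal (unaberrated) MTF amplitude,
#' `D' = D A e^(-i phi') / (A^2 + w^2)`, inside the system's frequency
#' support (zero outside), then transforms back. The amplitude part does not
#' depend on the trial phase, so scanning a mode modifies only the phase
#' content of the image. The filter is rescaled to unit DC gain, so total
#' image intensity is conserved.
#'
#' @param stack an [image_stack()]
#' @param ptf an `otf3d` (its phase component is used) or a DC-centered phase
#'   array of the same shape as the stack
#' @param params [metric_params()]; only `wiener` is used
#' @return the deconvolved [image_stack()]
#' @export
phase_only_deconvolve <- function(stack, ptf, params = metric_params()) {
  phi <- if (inherits(ptf, "otf3d")) ptf$phase else ptf
  if (!all(dim(phi) == dim(stack$data)))
    stop("PTF and stack dimensions do not match", call. = FALSE)
  g <- phase_only_filter_corner(stack$config, ifftshift(phi), params$wiener)
  out <- Re(ifft(stats::fft(stack$data) * g))
  image_stack(out, stack$config, background = stack$background)
}

# cone bandpass mask in corner order (logical). The passband condition is
# scale-invariant in |k|: it keeps directions within the collection cone,
# (4 pi / chi) (|k_lat| sin(theta) - |k_ax| cos(theta)) >= |k|,
# with theta = asin(NA/n); the DC voxel always passes.
bandpass_mask_corner <- function(config, chi = 1.8) {
  key <- paste0("band|", chi, "|", config_key(config))
  cache_get_or(key, function() {
    theta <- collection_angle(config)
    nz <- config$shape[1]; ny <- config$shape[2]; nx <- config$shape[3]
    kx <- fft_freq(nx, config$voxel[3])
    ky <- fft_freq(ny, config$voxel[2])
    kz <- fft_freq(nz, config$voxel[1])
    kl <- sqrt(outer(ky^2, kx^2, `+`))
    kl3 <- array(kl, dim = c(ny, nx, nz))
    ks3 <- array(rep(abs(kz), each = ny * nx), dim = c(ny, nx, nz))
    (4 * pi / chi) * (kl3 * sin(theta) - ks3 * cos(theta)) >=
      sqrt(kl3^2 + ks3^2)
  })
}

#' Cone bandpass mask of the metric
#'
#' @param config an [optical_config()]
#' @param params [metric_params()]; `chi` sets the cone opening
#' @param centered return the mask DC-centered (default) or in FFT order
#' @return logical array of the configured stack shape
#' @export
bandpass_mask <- function(config, params = metric_params(), centered = TRUE) {
  m <- bandpass_mask_corner(config, params$chi)
  if (centered) fftshift(m) else m
}

#' Apply the metric's cone bandpass filter to a stack
#'
#' @inheritParams phase_only_deconvolve
#' @return the filtered [image_stack()]
#' @export
bandpass_filter <- function(stack, params = metric_params()) {
  m <- bandpass_mask_corner(stack$config, params$chi)
  out <- Re(ifft(stats::fft(stack$data) * m))
  image_stack(out, stack$config, background = stack$background)
}

metric_value <- function(x, gamma) {
  pos <- x[x >= 0]
  neg <- x[x < 0]
  vp <- if (length(pos) > 1) stats::var(pos^2) else 0
  vn <- if (length(neg) > 1) stats::var(neg^2) else 0
  vp - gamma * vn
}

#' Penalized intensity-variance sharpness metric
#'
#' Variance of the squared intensities over the nonnegative voxels minus
#' `gamma` times the variance of the squared intensities over the negative
#' voxels. The stack is passed through the cone bandpass filter first
#' (disable with `bandpass = FALSE` if it already was).
#'
#' @inheritParams phase_only_deconvolve
#' @param bandpass apply [bandpass_filter()] before evaluating
#' @return scalar metric value
#' @export
sharpness_metric <- function(stack, params = metric_params(), bandpass = TRUE) {
  x <- if (bandpass) bandpass_filter(stack, params)$data else stack$data
  metric_value(x, params$gamma)
}

# ---- magnitude search ------------------------------------------------------

# evaluate `objective(alpha)` on the sampling plan and fit the peak.
# Returns list(estimate, samples, fit_ok).
scan_magnitude <- function(objective, center, step, plan) {
  offs <- (seq_len(plan$n_initial) - (plan$n_initial + 1) / 2) * step
  alphas <- center + offs
  vals <- vapply(alphas, objective, numeric(1))
  for (r in seq_len(plan$n_refine)) {
    ok <- is.finite(vals)
    if (!any(ok)) break
    best <- alphas[ok][which.max(vals[ok])]
    # bracket the running maximum ever more tightly: +/- step/2, +/- step/4, ...
    cand <- best + c(-0.5, 0.5) * step / 2^(r - 1)
    cand <- cand[vapply(cand, function(a)
      all(abs(a - alphas) > 1e-9 * max(step, 1e-12)), logical(1))]
    if (!length(cand)) next
    alphas <- c(alphas, cand)
    vals <- c(vals, vapply(cand, objective, numeric(1)))
  }
  ok <- is.finite(vals)
  samples <- data.frame(alpha = alphas, value = vals)[order(alphas), ]
  if (sum(ok) < plan$fit_points) {
    warning("fewer than ", plan$fit_points,
            " usable metric samples; falling back to the discrete maximum",
            call. = FALSE)
    return(list(estimate = alphas[ok][which.max(vals[ok])],
                samples = samples, fit_ok = FALSE))
  }
  a <- alphas[ok]; v <- vals[ok]
  best <- a[which.max(v)]
  keep <- order(abs(a - best))[seq_len(plan$fit_points)]
  a <- a[keep]; v <- v[keep]
  deg <- min(plan$fit_order, length(a) - 1)
  mu <- mean(a); sc <- max(stats::sd(a), 1e-12)
  x <- (a - mu) / sc
  fit <- stats::lm(v ~ stats::poly(x, degree = deg, raw = TRUE))
  cf <- stats::coef(fit)
  cf[is.na(cf)] <- 0
  predict_poly <- function(xx) drop(outer(xx, 0:deg, `^`) %*% cf)
  # argmax restricted to the convex hull of the fitted samples
  opt <- stats::optimize(function(xx) predict_poly(xx),
                         interval = range(x), maximum = TRUE)
  # guard: a sampled point may beat the interior optimum
  cand_x <- c(opt$maximum, range(x))
  est_x <- cand_x[which.max(predict_poly(cand_x))]
  list(estimate = mu + sc * est_x, samples = samples, fit_ok = TRUE)
}

#' Scan one aberration mode and estimate its magnitude
#'
#' Evaluates the sharpness metric at trial magnitudes of one mode (all other
#' modes held at their accumulated estimates), refines the sampling around
#' the running maximum, and returns the fitted argmax.
#'
#' @param stack an [image_stack()] (background-subtract it first for raw data)
#' @param mode the mode to scan
#' @param plan a [sampling_plan()]
#' @param params [metric_params()]
#' @param accumulated an [aberration_spec()] of already-measured magnitudes
#' @return list with `estimate` (the measured magnitude), `samples`
#'   (data.frame of scanned magnitudes and metric values) and `fit_ok`
#' @export
scan_mode <- function(stack, mode, plan = sampling_plan(),
                      params = metric_params(),
                      accumulated = aberration_spec()) {
  obj <- wfm_objective(stack, params)
  scan_magnitude(function(a) obj(spec_set(accumulated, mode, a)),
                 center = spec_get(accumulated, mode),
                 step = mode_step(mode, plan), plan)
}

# closure evaluating the WFM sharpness objective for a trial spec; the stack
# spectrum, bandpass mask and ideal MTF are computed once
wfm_objective <- function(stack, params) {
  config <- stack$config
  d_spec <- stats::fft(stack$data)
  band <- bandpass_mask_corner(config, params$chi)
  force(ideal_mtf_corner(config))
  function(spec_trial) {
    phi <- aberrated_ptf_corner(config, spec_trial)
    g <- phase_only_filter_corner(config, phi, params$wiener)
    x <- Re(ifft(d_spec * g * band))
    metric_value(x, params$gamma)
  }
}

# shared measurement engine: cycles over modes, scanning residual magnitudes
# about the accumulated estimate; objective(spec_trial, mode) -> scalar
measure_engine <- function(objective, modes, config, n_iterations, plan,
                           init = aberration_spec(), verbose = FALSE) {
  modes <- order_modes(modes)
  est <- init
  traces <- list()
  per_cycle <- matrix(NA_real_, n_iterations, length(modes),
                      dimnames = list(NULL, modes))
  rms_w <- numeric(0)
  rms_update <- numeric(0)
  best_cycle <- 0
  stopped <- FALSE
  for (cy in seq_len(n_iterations)) {
    prev <- est
    for (m in modes) {
      res <- scan_magnitude(function(a) objective(spec_set(est, m, a), m),
                            center = spec_get(est, m),
                            step = mode_step(m, plan), plan)
      est <- spec_set(est, m, res$estimate)
      traces[[length(traces) + 1]] <-
        cbind(data.frame(cycle = cy, mode = m), res$samples)
      if (verbose)
        message(sprintf("  cycle %d %-10s -> %+.5g", cy, m, res$estimate))
    }
    per_cycle[cy, ] <- vapply(modes, function(m) spec_get(est, m), numeric(1))
    rms_w <- c(rms_w, rms_wavefront(est, config))
    delta <- vapply(modes, function(m) spec_get(est, m) - spec_get(prev, m),
                    numeric(1))
    rms_update <- c(rms_update,
                    rms_wavefront(aberration_spec(
                      magnitudes = stats::setNames(delta, modes)), config))
    rel <- abs(delta) / vapply(modes, mode_step, numeric(1), plan = plan)
    if (cy >= 2 && all(rel < 0.02)) break
    if (cy >= 3 && rms_update[cy] > rms_update[cy - 1] &&
        rms_update[cy - 1] > rms_update[cy - 2]) {
      # divergent trace: revert to the estimate before the two bad cycles
      est <- aberration_spec(magnitudes = stats::setNames(
        per_cycle[cy - 2, ], modes))
      best_cycle <- cy - 2
      stopped <- TRUE
      warning("metric trace diverged; reporting cycle ", cy - 2, call. = FALSE)
      break
    }
  }
  n_done <- length(rms_w)
  list(estimate = est,
       per_cycle = per_cycle[seq_len(n_done), , drop = FALSE],
       traces = do.call(rbind, traces),
       rms_wavefront = rms_w, rms_update = rms_update,
       n_cycles = n_done, diverged = stopped,
       best_cycle = if (stopped) best_cycle else n_done)
}

resolve_modes <- function(modes) {
  if (length(modes) == 1 && modes == "seidel") return(seidel_modes)
  if (length(modes) == 1 && grepl("^zernike:[0-9]+$", modes)) {
    jmax <- as.integer(sub("^zernike:", "", modes))
    if (jmax < 4) stop("zernike:N requires N >= 4", call. = FALSE)
    return(paste0("z", 4:jmax))
  }
  bad <- modes[!vapply(modes, is_known_mode, logical(1))]
  if (length(bad))
    stop("unknown mode(s): ", paste(bad, collapse = ", "), call. = FALSE)
  modes
}

#' Measure optical aberrations from a 3D wide-field stack
#'
#' Emulates sensor-less adaptive optics computationally: for each requested
#' mode, the stack is phase-only deconvolved with a series of trial phase
#' transfer functions and the magnitude maximizing the sharpness metric is
#' retained; cycles repeat the scan about the accumulated estimate until the
#' update becomes negligible.
#'
#' @param stack an [image_stack()]
#' @param modes `"seidel"` (SA, coma, astigmatism), `"zernike:N"` (Wyant
#'   indices 4..N) or an explicit character vector of modes
#' @param n_iterations maximum number of measurement cycles
#' @param plan a [sampling_plan()]
#' @param params [metric_params()]
#' @param background subtract the border-median background first
#' @param init starting [aberration_spec()]
#' @param verbose print per-mode progress
#' @return an object of class `cao_fit`; see [coef.cao_fit()],
#'   [plot.cao_fit()], [summary.cao_fit()]
#' @export
measure_aberrations <- function(stack, modes = "seidel", n_iterations = 3,
                                plan = sampling_plan(),
                                params = metric_params(),
                                background = TRUE,
                                init = aberration_spec(), verbose = FALSE) {
  modes <- resolve_modes(modes)
  if (length(modes) == 0) {
    return(structure(list(estimate = init, per_cycle = NULL, traces = NULL,
                          rms_wavefront = numeric(0),
                          rms_update = numeric(0), n_cycles = 0,
                          diverged = FALSE, config = stack$config,
                          params = params, plan = plan,
                          objective = "sharpness"), class = "cao_fit"))
  }
  if (background) stack <- subtract_background(stack)
  obj <- wfm_objective(stack, params)
  out <- measure_engine(function(spec_trial, mode) obj(spec_trial),
                        modes, stack$config, n_iterations, plan,
                        init = init, verbose = verbose)
  out$config <- stack$config
  out$params <- params
  out$plan <- plan
  out$objective <- "sharpness"
  class(out) <- "cao_fit"
  out
}
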