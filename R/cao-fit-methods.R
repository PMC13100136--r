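# S3 methods for the measurement result.

#' @export
print.cao_fit <- function(x, ...) {
  cat(sprintf("<cao_fit> %s objective, %d cycle(s)%s\n", x$objective,
              x$n_cycles, if (isTRUE(x$diverged)) " [diverged, best kept]" else ""))
  if (length(x$estimate)) print(x$estimate) else cat("  (no modes scanned)\n")
  if (length(x$rms_wavefront))
    cat(sprintf("  RMS wavefront %.1f nm (%.3f lambda)\n",
                utils::tail(x$rms_wavefront, 1),
                utils::tail(x$rms_wavefront, 1) / x$config$wavelength))
  invisible(x)
}

#' Measured aberration magnitudes
#'
#' @param object a `cao_fit`
#' @param ... unused
#' @return named numeric vector of magnitudes (index-mismatch units for `sa`,
#'   wavelength units for the polynomial modes, nm for displacements)
#' @export
coef.cao_fit <- function(object, ...) {
  stats::setNames(as.numeric(object$estimate), names(object$estimate))
}

#' Summarize a measurement
#'
#' @param object a `cao_fit`
#' @param ... unused
#' @return a `summary.cao_fit` with the per-cycle estimates and RMS traces
#' @export
summary.cao_fit <- function(object, ...) {
  structure(list(estimate = object$estimate, per_cycle = object$per_cycle,
                 rms_wavefront = object$rms_wavefront,
                 rms_update = object$rms_update,
                 n_cycles = object$n_cycles, objective = object$objective,
                 wavelength = object$config$wavelength),
            class = "summary.cao_fit")
}

#' @export
print.summary.cao_fit <- function(x, ...) {
  cat(sprintf("Aberration measurement (%s objective)\n", x$objective))
  if (!is.null(x$per_cycle)) {
    cat("Per-cycle estimates:\n")
    print(round(x$per_cycle, 5))
  }
  if (length(x$rms_wavefront)) {
    cat("RMS wavefront per cycle (nm): ",
        paste(sprintf("%.1f", x$rms_wavefront), collapse = ", "), "\n")
    cat("RMS update per cycle (nm):    ",
        paste(sprintf("%.2f", x$rms_update), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plot the metric traces of a measurement
#'
#' One panel per scanned mode showing the sampled objective values against
#' the trial magnitude for each cycle, with the final estimate marked.
#'
#' @param x a `cao_fit`
#' @param cycles which cycles to draw (default all)
#' @param ... passed to [graphics::plot()]
#' @export
plot.cao_fit <- function(x, cycles = NULL, ...) {
  if (is.null(x$traces)) {
    warning("no traces to plot", call. = FALSE)
    return(invisible(x))
  }
  tr <- x$traces
  if (!is.null(cycles)) tr <- tr[tr$cycle %in% cycles, ]
  modes <- unique(tr$mode)
  nm <- length(modes)
  old <- graphics::par(mfrow = c(ceiling(nm / 2), min(nm, 2)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (m in modes) {
    d <- tr[tr$mode == m, ]
    graphics::plot(d$alpha, d$value, col = d$cycle, pch = 19,
                   xlab = "trial magnitude", ylab = "objective", main = m, ...)
    for (cy in unique(d$cycle)) {
      dd <- d[d$cycle == cy, ]
      graphics::lines(dd$alpha[order(dd$alpha)], dd$value[order(dd$alpha)],
                      col = cy, lty = 3)
    }
    graphics::abline(v = spec_get(x$estimate, m), col = "red")
  }
  invisible(x)
}

#' Predict the optical response implied by a measurement
#'
#' @param object a `cao_fit`
#' @param type `"psf"` (aberrated PSF), `"otf"` (its MTF/PTF split) or
#'   `"wavefront"` (pupil OPD surface, nm)
#' @param ... unused
#' @return a `psf3d`, `otf3d` or wavefront matrix
#' @export
predict.cao_fit <- function(object, type = c("psf", "otf", "wavefront"),
                            ...) {
  type <- match.arg(type)
  if (type == "wavefront") return(build_wavefront(object$estimate, object$config))
  psf <- make_psf(object$config, object$estimate)
  if (type == "psf") psf else psf_to_otf(psf)
}

#' Simulate stacks under the fitted aberration
#'
#' Generates point phantoms imaged with the measured aberration, optionally
#' with Poisson background noise — useful for checking what the fitted
#' wavefront does to a known object.
#'
#' @param object a `cao_fit`
#' @param nsim number of stacks
#' @param seed RNG seed (noise only)
#' @param peak_snr optional peak SNR of added Poisson noise
#' @param ... unused
#' @return list of [image_stack()]s
#' @export
simulate.cao_fit <- function(object, nsim = 1, seed = NULL, peak_snr = NULL,
                             ...) {
  base <- make_point_phantom(object$config, aberration = object$estimate)
  lapply(seq_len(nsim), function(i) {
    if (is.null(peak_snr)) base
    else add_poisson_noise(base, peak_snr,
                           seed = if (is.null(seed)) NULL else seed + i - 1)
  })
}

#' Wavefront surface of a measured aberration spec
#'
#' @param fit a `cao_fit` (or an [aberration_spec()])
#' @param config required when `fit` is a bare spec
#' @return DC-centered OPD matrix (nm) over the pupil grid
#' @export
fitted_wavefront <- function(fit, config = NULL) {
  if (inherits(fit, "cao_fit")) {
    build_wavefront(fit$estimate, fit$config)
  } else {
    stopifnot(!is.null(config))
    build_wavefront(fit, config)
  }
}
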