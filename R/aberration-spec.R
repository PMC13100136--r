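#' Aberration decomposition as (mode, magnitude) pairs
#'
#' An `aberration_spec` is an ordered, named set of wavefront modes with their
#' magnitudes. Supported modes:
#' \itemize{
#'   \item `sa` -- spherical aberration; the magnitude is the immersion-medium
#'     refractive-index mismatch (Gibson-Lanni model, dimensionless).
#'   \item `coma_u`, `coma_v` -- third-order coma along the pupil u (x) and
#'     v (y) axes; magnitude in wavelength units at the pupil edge.
#'   \item `astig_0`, `astig_45` -- astigmatism along the u axis and in the
#'     frame rotated by 45 degrees; wavelength units.
#'   \item `z<j>` -- Zernike mode with Wyant single index j >= 1 (e.g. `z8` is
#'     primary spherical); coefficient in wavelength units, non-normalized
#'     polynomials.
#'   \item `tilt_x`, `tilt_y` -- pure lateral image shifts in nm.
#'   \item `defocus_offset` -- axial image shift in nm (immersion-thickness
#'     defocus term).
#' }
#'
#' @param ... named magnitudes, e.g. `aberration_spec(sa = 0.01, coma_u = 0.25)`
#' @param magnitudes alternatively, a named numeric vector
#' @return an object of class `aberration_spec` (named numeric vector)
#' @export
#' @examples
#' aberration_spec(sa = 0.01)
#' aberration_spec(magnitudes = c(z8 = 1, z9 = -0.5))
aberration_spec <- function(..., magnitudes = NULL) {
  vals <- c(unlist(list(...)), magnitudes)
  if (is.null(vals) || length(vals) == 0)
    return(structure(stats::setNames(numeric(0), character(0)),
                     class = "aberration_spec"))
  nm <- names(vals)
  if (is.null(nm) || any(nm == ""))
    stop("all aberration magnitudes must be named by mode", call. = FALSE)
  if (anyDuplicated(nm))
    stop("duplicate aberration mode identifiers: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  bad <- nm[!vapply(nm, is_known_mode, logical(1))]
  if (length(bad))
    stop("unknown aberration mode(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(!is.finite(vals)))
    stop("aberration magnitudes must be finite", call. = FALSE)
  structure(as.numeric(stats::setNames(vals, nm)), names = nm,
            class = "aberration_spec")
}

seidel_modes <- c("sa", "coma_u", "coma_v", "astig_0", "astig_45")
shift_modes  <- c("tilt_x", "tilt_y", "defocus_offset")

is_known_mode <- function(mode) {
  if (mode %in% c(seidel_modes, shift_modes)) return(TRUE)
  grepl("^z[0-9]+$", mode) && wyant_index(mode) >= 1
}

wyant_index <- function(mode) as.integer(sub("^z", "", mode))

# unit of one initial sampling step for each mode class
mode_step <- function(mode, plan = sampling_plan()) {
  if (mode == "sa") return(plan$step_sa)
  if (mode %in% c("coma_u", "coma_v", "astig_0", "astig_45"))
    return(plan$step_seidel)
  if (grepl("^z", mode)) return(plan$step_zernike)
  stop("mode '", mode, "' is not scannable", call. = FALSE)
}

# canonical scan order: SA, coma, astigmatism, then Zernike by Wyant index
order_modes <- function(modes) {
  z <- grepl("^z[0-9]+$", modes)
  c(intersect(seidel_modes, modes),
    modes[z][order(vapply(modes[z], wyant_index, integer(1)))],
    setdiff(modes[!z], seidel_modes))
}

spec_get <- function(spec, mode) {
  if (mode %in% names(spec)) unclass(spec)[[mode]] else 0
}

spec_set <- function(spec, mode, value) {
  v <- unclass(spec)
  v[mode] <- value
  aberration_spec(magnitudes = v)
}

#' @export
print.aberration_spec <- function(x, ...) {
  if (length(x) == 0) {
    cat("<aberration_spec> (none)\n")
    return(invisible(x))
  }
  cat("<aberration_spec>\n")
  units <- vapply(names(x), function(m) {
    if (m == "sa") "delta-n"
    else if (m %in% shift_modes) "nm"
    else "lambda"
  }, character(1))
  for (i in seq_along(x))
    cat(sprintf("  %-14s %+.5g [%s]\n", names(x)[i], unclass(x)[i], units[i]))
  invisible(x)
}
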