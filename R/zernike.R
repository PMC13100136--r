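# Zernike polynomials in the Wyant single-index convention.
#
# Wyant ordering groups terms as j = g^2 + 2(g - m) for the cos(m phi) term
# and j = g^2 + 2(g - m) + 1 for sin(m phi) (m > 0), with the rotationally
# symmetric term of each group at j = g(g + 2); the radial order is
# n = 2g - m. Index 0 is piston, 1/2 tilt, 3 defocus, 4/5 primary
# astigmatism, 6/7 primary coma, 8 primary spherical. Polynomials are
# non-normalized: each mode has unit amplitude at the pupil edge for the
# rotationally symmetric terms and unit radial polynomial coefficient scale
# otherwise (R_n^m(1) = 1).

# (n, m, parity) for a Wyant index j >= 0; parity "cos" or "sin"
wyant_nm <- function(j) {
  stopifnot(j >= 0, j == as.integer(j))
  g <- floor(sqrt(j))
  rem <- j - g^2
  m <- g - rem %/% 2
  list(n = 2 * g - m, m = m, parity = if (rem %% 2 == 0) "cos" else "sin")
}

# radial polynomial R_n^m(rho)
zernike_radial <- function(n, m, rho) {
  out <- 0
  for (k in 0:((n - m) / 2)) {
    out <- out + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m) / 2 - k) * factorial((n - m) / 2 - k)) *
      rho^(n - 2 * k)
  }
  out
}

#' Evaluate a Zernike polynomial (Wyant index)
#'
#' @param j Wyant single index (>= 0)
#' @param rho radial pupil coordinate (1 at the pupil edge)
#' @param phi azimuthal angle in radians
#' @return numeric of the same shape as `rho`
#' @export
zernike_wyant <- function(j, rho, phi) {
  p <- wyant_nm(j)
  rad <- zernike_radial(p$n, p$m, rho)
  if (p$m == 0) return(rad)
  if (p$parity == "cos") rad * cos(p$m * phi) else rad * sin(p$m * phi)
}
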