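# Synthetic test objects: aberrated point sources, axial two-point pairs,
# bead fields, Bezier-curve fiber phantoms, and additive Poisson noise at a
# controlled peak signal-to-noise ratio.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Evaluate a second-order Bezier curve
#'
#' `B(p) = (1-p)^2 C0 + 2 (1-p) p C1 + p^2 C2` for `p` in `[0, 1]`.
#'
#' @param c0,c1,c2 numeric 3-vectors (control points)
#' @param p curve parameter(s) in `[0, 1]`
#' @return matrix with one row per `p` and one column per coordinate
#' @export
bezier_point <- function(c0, c1, c2, p) {
  stopifnot(length(c0) == 3, length(c1) == 3, length(c2) == 3)
  if (any(p < 0 | p > 1))
    stop("curve parameter `p` must lie in [0, 1]", call. = FALSE)
  b <- outer((1 - p)^2, c0) + outer(2 * (1 - p) * p, c1) + outer(p^2, c2)
  dimnames(b) <- list(NULL, c("x", "y", "z"))
  b
}

# FFT convolution of an object grid with a PSF (both [ny, nx, nz])
convolve_psf <- function(obj, psf_data) {
  Re(ifft(stats::fft(obj) * stats::fft(ifftshift(psf_data))))
}

#' Simulate point sources imaged with an aberrated PSF
#'
#' Places delta objects at the given voxel offsets from the stack center,
#' convolves with the (optionally aberrated) theoretical PSF and normalizes
#' the peak intensity to `peak`.
#'
#' @param config an [optical_config()]
#' @param offsets integer matrix (one row per point) of `(dz, dy, dx)` voxel
#'   offsets from the stack center; `NULL` places a single centered point
#' @param aberration an [aberration_spec()] applied to the PSF
#' @param peak peak intensity after normalization (default 100)
#' @param weights relative intensities of the points
#' @return an [image_stack()]
#' @export
make_point_phantom <- function(config, offsets = NULL,
                               aberration = aberration_spec(), peak = 100,
                               weights = NULL) {
  if (is.null(offsets)) offsets <- matrix(0, 1, 3)
  offsets <- matrix(as.integer(round(offsets)), ncol = 3)
  ny <- config$shape[2]; nx <- config$shape[3]; nz <- config$shape[1]
  ctr <- c(floor(nz / 2) + 1L, floor(ny / 2) + 1L, floor(nx / 2) + 1L)
  if (is.null(weights)) weights <- rep(1, nrow(offsets))
  obj <- array(0, dim = c(ny, nx, nz))
  for (i in seq_len(nrow(offsets))) {
    iz <- ctr[1] + offsets[i, 1]; iy <- ctr[2] + offsets[i, 2]
    ix <- ctr[3] + offsets[i, 3]
    if (iz < 1 || iz > nz || iy < 1 || iy > ny || ix < 1 || ix > nx)
      stop("point position outside the volume", call. = FALSE)
    obj[iy, ix, iz] <- obj[iy, ix, iz] + weights[i]
  }
  psf <- make_psf(config, aberration)
  out <- convolve_psf(obj, psf$data)
  image_stack(peak * out / max(out), config)
}

#' Simulate an axial two-point source
#'
#' @param config an [optical_config()]
#' @param separation axial separation in nm (split symmetrically about the
#'   focal plane, rounded to whole sections)
#' @inheritParams make_point_phantom
#' @return an [image_stack()]
#' @export
make_two_point_phantom <- function(config, separation,
                                   aberration = aberration_spec(),
                                   peak = 100) {
  half <- round(separation / 2 / config$voxel[1])
  make_point_phantom(config,
                     offsets = rbind(c(-half, 0, 0), c(half, 0, 0)),
                     aberration = aberration, peak = peak)
}

#' Simulate a random field of beads
#'
#' Spherical beads at uniform random positions, rasterized by voxel-center
#' distance, convolved with the (optionally aberrated) PSF, peak-normalized.
#'
#' @param config an [optical_config()]
#' @param n_beads number of beads
#' @param radius bead radius in nm (sub-voxel radii give single-voxel beads)
#' @param seed RNG seed for the positions
#' @param margin border margin (voxels) kept free of bead centers
#' @inheritParams make_point_phantom
#' @return an [image_stack()]
#' @export
make_bead_phantom <- function(config, n_beads = 10, radius = 50, seed = 1,
                              aberration = aberration_spec(), peak = 100,
                              margin = 8) {
  ny <- config$shape[2]; nx <- config$shape[3]; nz <- config$shape[1]
  obj <- array(0, dim = c(ny, nx, nz))
  mg <- pmin(margin, (c(nz, ny, nx) - 2) / 2)   # keep feasible on small grids
  pos <- with_seed(seed, cbind(
    stats::runif(n_beads, mg[1] + 1, nz - mg[1]),
    stats::runif(n_beads, mg[2] + 1, ny - mg[2]),
    stats::runif(n_beads, mg[3] + 1, nx - mg[3])))
  rz <- max(1, ceiling(radius / config$voxel[1]))
  ry <- max(1, ceiling(radius / config$voxel[2]))
  rx <- max(1, ceiling(radius / config$voxel[3]))
  for (i in seq_len(n_beads)) {
    zz <- max(1, floor(pos[i, 1] - rz)):min(nz, ceiling(pos[i, 1] + rz))
    yy <- max(1, floor(pos[i, 2] - ry)):min(ny, ceiling(pos[i, 2] + ry))
    xx <- max(1, floor(pos[i, 3] - rx)):min(nx, ceiling(pos[i, 3] + rx))
    for (z in zz) for (y in yy) for (x in xx) {
      d2 <- ((z - pos[i, 1]) * config$voxel[1])^2 +
        ((y - pos[i, 2]) * config$voxel[2])^2 +
        ((x - pos[i, 3]) * config$voxel[3])^2
      if (d2 <= max(radius, min(config$voxel) / 2)^2) obj[y, x, z] <- 1
    }
  }
  psf <- make_psf(config, aberration)
  out <- convolve_psf(obj, psf$data)
  image_stack(peak * out / max(out), config)
}

#' Rasterize random Bezier-curve fibers
#'
#' Control points are sampled uniformly in the volume; solid tubes of the
#' given radius are rasterized around each quadratic Bezier curve (a voxel is
#' inside a fiber when its center lies within the radius of the densely
#' sampled curve). Returns the binary tube volume at full axial sampling.
#'
#' @param config an [optical_config()] (pre-decimation shape)
#' @param n_fibers number of fibers (default 50)
#' @param radius fiber radius in nm (default 180)
#' @param seed RNG seed for the control points
#' @return numeric array `[ny, nx, nz]` of 0/1 tube occupancy
#' @export
rasterize_fibers <- function(config, n_fibers = 50, radius = 180, seed = 1) {
  ny <- config$shape[2]; nx <- config$shape[3]; nz <- config$shape[1]
  dz <- config$voxel[1]; dy <- config$voxel[2]; dx <- config$voxel[3]
  ext <- c(nx * dx, ny * dy, nz * dz)   # physical extent (x, y, z)
  obj <- array(0, dim = c(ny, nx, nz))
  if (n_fibers == 0) return(obj)
  if (radius < min(dy, dx))
    stop("fiber radius must be at least one lateral voxel", call. = FALSE)
  cps <- with_seed(seed, lapply(seq_len(n_fibers), function(i)
    list(c0 = stats::runif(3) * ext, c1 = stats::runif(3) * ext,
         c2 = stats::runif(3) * ext)))
  vox_diag <- sqrt(dx^2 + dy^2 + dz^2)
  # stamp neighborhood: voxels within radius of a curve sample point
  nrx <- ceiling(radius / dx); nry <- ceiling(radius / dy)
  nrz <- ceiling(radius / dz)
  nb <- expand.grid(oy = -nry:nry, ox = -nrx:nrx, oz = -nrz:nrz)
  for (cp in cps) {
    # crude curve length from a coarse polyline, then sample densely enough
    coarse <- bezier_point(cp$c0, cp$c1, cp$c2, seq(0, 1, length.out = 33))
    len <- sum(sqrt(rowSums(diff(coarse)^2)))
    np <- max(9, ceiling(2 * len / vox_diag) + 1)
    pts <- bezier_point(cp$c0, cp$c1, cp$c2, seq(0, 1, length.out = np))
    for (i in seq_len(np)) {
      px <- pts[i, 1]; py <- pts[i, 2]; pz <- pts[i, 3]
      cx <- round(px / dx + 0.5); cy <- round(py / dy + 0.5)
      cz <- round(pz / dz + 0.5)
      vy <- cy + nb$oy; vx <- cx + nb$ox; vz <- cz + nb$oz
      ok <- vy >= 1 & vy <= ny & vx >= 1 & vx <= nx & vz >= 1 & vz <= nz
      if (!any(ok)) next
      d2 <- ((vx[ok] - 0.5) * dx - px)^2 + ((vy[ok] - 0.5) * dy - py)^2 +
        ((vz[ok] - 0.5) * dz - pz)^2
      hit <- which(ok)[d2 <= radius^2]
      if (length(hit)) obj[cbind(vy[hit], vx[hit], vz[hit])] <- 1
    }
  }
  obj
}

#' Keep every third optical section
#'
#' Sections 1, 4, 7, ... are retained (indices 0, 3, 6, ... zero-based),
#' giving `ceiling(nz / 3)` sections.
#'
#' @param data array `[ny, nx, nz]`
#' @param factor decimation factor (default 3)
#' @return the decimated array
#' @export
decimate_sections <- function(data, factor = 3) {
  nz <- dim(data)[3]
  data[, , seq(1, nz, by = factor), drop = FALSE]
}

#' Simulate an imaged fiber phantom
#'
#' Rasterizes random Bezier fibers, reduces axial sampling threefold, then
#' convolves with the (optionally aberrated) theoretical PSF at the decimated
#' axial spacing and normalizes the peak to `peak`.
#'
#' @inheritParams rasterize_fibers
#' @param aberration an [aberration_spec()] applied to the PSF
#' @param decimate axial decimation factor (default 3)
#' @param peak peak intensity after normalization
#' @return an [image_stack()] whose config has the decimated axial spacing
#' @export
make_fiber_phantom <- function(config, n_fibers = 50, radius = 180, seed = 1,
                               aberration = aberration_spec(), decimate = 3,
                               peak = 100) {
  tubes <- rasterize_fibers(config, n_fibers, radius, seed)
  dec <- decimate_sections(tubes, decimate)
  cfg_dec <- optical_config(config$na, config$wavelength, config$n_immersion,
                            voxel = c(config$voxel[1] * decimate,
                                      config$voxel[2], config$voxel[3]),
                            shape = c(dim(dec)[3], config$shape[2],
                                      config$shape[3]),
                            pupil_size = config$pupil_size,
                            immersion_thickness = config$immersion_thickness)
  psf <- make_psf(cfg_dec, aberration)
  out <- convolve_psf(dec, psf$data)
  if (max(out) > 0) out <- peak * out / max(out)
  image_stack(out, cfg_dec)
}

#' Add Poisson background noise at a given peak signal-to-noise ratio
#'
#' The stack is peak-normalized to 100 and Poisson-distributed counts with
#' mean `mu = (100 / peak_snr)^2` are added voxelwise, so the background
#' standard deviation is `100 / peak_snr`. With `mode = "shot"` the signal
#' itself is Poisson-resampled on top of the background mean instead.
#'
#' @param stack an [image_stack()] (nonnegative)
#' @param peak_snr peak signal-to-noise ratio (> 0)
#' @param seed RNG seed
#' @param mode `"additive"` (background only) or `"shot"`
#' @return the noisy [image_stack()], with `mu` and `peak_snr` as attributes
#' @export
add_poisson_noise <- function(stack, peak_snr, seed = NULL,
                              mode = c("additive", "shot")) {
  mode <- match.arg(mode)
  if (!is.numeric(peak_snr) || peak_snr <= 0)
    stop("`peak_snr` must be > 0", call. = FALSE)
  mu <- (100 / peak_snr)^2
  h <- stack$data
  if (min(h) < 0) h <- pmax(h, 0)
  sig <- 100 * h / max(h)
  n <- length(sig)
  noisy <- with_seed(seed, {
    if (mode == "additive") sig + stats::rpois(n, mu)
    else stats::rpois(n, sig + mu)
  })
  out <- image_stack(array(noisy, dim = dim(sig)), stack$config)
  attr(out, "mu") <- mu
  attr(out, "peak_snr") <- 100 / sqrt(mu)
  out
}
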