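# Shared fixtures. Configurations are kept as small as the pupil-grid
# constraint allows so each PSF build stays in the 0.1-1 s range; fixtures
# are memoized per test session.

.fx <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (!exists(name, envir = .fx, inherits = FALSE))
    assign(name, force(expr), envir = .fx)
  get(name, envir = .fx, inherits = FALSE)
}

# standard bench configuration: Fig-2-style optics on a reduced grid
tiny_config <- function(nz = 16, n = 32)
  optical_config(na = 1.42, wavelength = 528, n_immersion = 1.515,
                 voxel = c(267, 92, 92), shape = c(nz, n, n),
                 pupil_size = 256)

bench_config <- function()
  fx("bench_config",
     optical_config(na = 1.42, wavelength = 528, n_immersion = 1.515,
                    voxel = c(267, 92, 92), shape = c(32, 64, 64),
                    pupil_size = 256))

# full simulation protocol of the accuracy study
protocol_config <- function()
  fx("protocol_config",
     optical_config(na = 1.42, wavelength = 528, n_immersion = 1.515,
                    voxel = c(267, 92, 92), shape = c(128, 128, 128),
                    pupil_size = 512))

ideal_psf_bench <- function() fx("ideal_psf_bench", make_psf(bench_config()))

# axial asymmetry of the brightest-voxel z-profile (0 for a symmetric PSF)
axial_asymmetry <- function(data) {
  d <- dim(data)
  i <- arrayInd(which.max(data), d)
  p <- data[i[1], i[2], ]
  p <- p / sum(p)
  ctr <- floor(d[3] / 2) + 1
  k <- seq_len(min(ctr - 1, d[3] - ctr))
  sum(abs(p[ctr + k] - p[ctr - k]))
}

# dip ratio of an on-axis two-point profile: min between the peaks over the
# smaller peak; < 0.735 (the Rayleigh dip) counts as resolved
dip_ratio <- function(stack, iz1, iz2) {
  d <- dim(stack$data)
  p <- stack$data[floor(d[1] / 2) + 1, floor(d[2] / 2) + 1, ]
  dip <- min(p[iz1:iz2])
  pk <- min(max(p[(iz1 - 1):(iz1 + 1)]), max(p[(iz2 - 1):(iz2 + 1)]))
  dip / pk
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected)), tol)
}
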