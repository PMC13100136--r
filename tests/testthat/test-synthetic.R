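test_that("the quadratic Bezier curve hits its anchor identities", {
  c0 <- c(0, 0, 0); c1 <- c(10, 5, 2); c2 <- c(20, 0, 8)
  expect_equal(drop(bezier_point(c0, c1, c2, 0)), c(x = 0, y = 0, z = 0))
  expect_equal(drop(bezier_point(c0, c1, c2, 1)), c(x = 20, y = 0, z = 8))
  expect_equal(drop(bezier_point(c0, c1, c2, 0.5)),
               c(x = 0.25 * 0 + 0.5 * 10 + 0.25 * 20,
                 y = 0.5 * 5, z = 0.5 * 2 + 0.25 * 8))
  expect_error(bezier_point(c0, c1, c2, 1.2), "\\[0, 1\\]")
})

test_that("a straight fiber rasterizes as a solid tube of the stated radius", {
  # fiber protocol voxels: 90 x 90 nm lateral, 270 nm axial
  cfg <- optical_config(na = 1.42, wavelength = 528, n_immersion = 1.515,
                        voxel = c(270, 90, 90), shape = c(9, 32, 32),
                        pupil_size = 256)
  r <- 180
  # oracle: analytic distance to the densely sampled curves, every voxel
  vol <- rasterize_fibers(cfg, n_fibers = 2, radius = r, seed = 7)
  cps <- phicao:::with_seed(7, lapply(1:2, function(i)
    list(c0 = stats::runif(3) * c(32 * 90, 32 * 90, 9 * 270),
         c1 = stats::runif(3) * c(32 * 90, 32 * 90, 9 * 270),
         c2 = stats::runif(3) * c(32 * 90, 32 * 90, 9 * 270))))
  p <- seq(0, 1, length.out = 4001)
  curves <- lapply(cps, function(cp) bezier_point(cp$c0, cp$c1, cp$c2, p))
  dmin <- array(Inf, dim = dim(vol))
  for (iz in 1:9) for (iy in 1:32) for (ix in 1:32) {
    cx <- (ix - 0.5) * 90; cy <- (iy - 0.5) * 90; cz <- (iz - 0.5) * 270
    for (cv in curves)
      dmin[iy, ix, iz] <- min(dmin[iy, ix, iz],
                              min((cv[, 1] - cx)^2 + (cv[, 2] - cy)^2 +
                                    (cv[, 3] - cz)^2))
  }
  dmin <- sqrt(dmin)
  diag_half <- sqrt(90^2 + 90^2 + 270^2) / 2
  # every marked voxel truly lies within the radius; every voxel safely
  # inside the tube is marked (slack = curve sampling spacing)
  expect_true(all(dmin[vol == 1] <= r + 1))
  expect_true(all(vol[dmin <= r - diag_half] == 1))
  expect_gt(sum(vol), 0)
})

test_that("fiber stacks decimate axially and honor the peak convention", {
  cfg <- optical_config(na = 1.42, wavelength = 528, n_immersion = 1.515,
                        voxel = c(90, 90, 90), shape = c(27, 32, 32),
                        pupil_size = 256)
  expect_equal(dim(decimate_sections(array(0, c(4, 4, 27))))[3], 9)
  expect_equal(dim(decimate_sections(array(0, c(4, 4, 8))))[3], 3)
  st <- make_fiber_phantom(cfg, n_fibers = 3, radius = 180, seed = 2)
  expect_equal(dim(st$data)[3], 9)
  expect_equal(st$config$voxel[1], 270)
  expect_equal(max(st$data), 100)
  expect_true(all(st$data >= 0))
  # zero fibers give an all-zero stack
  st0 <- make_fiber_phantom(cfg, n_fibers = 0, seed = 2)
  expect_true(all(st0$data == 0))
})

test_that("point phantoms are placed, normalized and merge below resolution", {
  cfg <- bench_config()
  st <- make_point_phantom(cfg)
  expect_equal(max(st$data), 100)
  psf <- make_psf(cfg)
  expect_rel_equal(st$data, 100 * psf$data / max(psf$data), 1e-9)
  off <- make_point_phantom(cfg, offsets = rbind(c(3, -4, 5)))
  i <- arrayInd(which.max(off$data), dim(off$data))
  ctr <- floor(dim(off$data) / 2) + 1
  expect_lte(max(abs(i - ctr - c(-4, 5, 3))), 1)
  # an axial pair below the axial resolution merges into one blob: the dip
  # between the two source planes stays above the Rayleigh criterion
  pair <- make_two_point_phantom(cfg, separation = 2 * cfg$voxel[1])
  p <- pair$data[33, 33, ]
  ctr <- floor(dim(pair$data)[3] / 2) + 1
  expect_gt(p[ctr] / min(p[ctr - 1], p[ctr + 1]), 0.735)
  expect_error(make_point_phantom(cfg, offsets = rbind(c(0, 0, 200))),
               "outside")
})

test_that("Poisson noise follows the stated mean and is seed-deterministic", {
  cfg <- tiny_config(nz = 8, n = 16)
  flat <- image_stack(array(100, dim = c(16, 16, 8)), cfg)
  n1 <- add_poisson_noise(flat, peak_snr = 100, seed = 3)
  expect_equal(attr(n1, "mu"), 1)
  n2 <- add_poisson_noise(flat, peak_snr = 10, seed = 3)
  expect_equal(attr(n2, "mu"), 100)
  # sample mean of the added counts within 3 standard errors of mu
  big <- image_stack(array(100, dim = c(64, 64, 32)), bench_config())
  mu <- (100 / 12)^2
  noise <- add_poisson_noise(big, peak_snr = 12, seed = 5)$data - 100
  se <- sqrt(mu / length(noise))
  expect_lt(abs(mean(noise) - mu), 3 * se)
  # determinism and seed sensitivity
  expect_identical(add_poisson_noise(flat, 10, seed = 9)$data,
                   add_poisson_noise(flat, 10, seed = 9)$data)
  expect_false(identical(add_poisson_noise(flat, 10, seed = 9)$data,
                         add_poisson_noise(flat, 10, seed = 10)$data))
  expect_error(add_poisson_noise(flat, -2), "peak_snr")
})

test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- tiny_config(nz = 8, n = 32)
  expect_identical(rasterize_fibers(cfg, 2, 180, seed = 4),
                   rasterize_fibers(cfg, 2, 180, seed = 4))
  expect_identical(make_bead_phantom(cfg, 5, seed = 6)$data,
                   make_bead_phantom(cfg, 5, seed = 6)$data)
  sim <- sim_config(cfg)
  raw1 <- make_sim_raw(array(1, c(32, 32, 8)), cfg, sim, peak_snr = 10,
                       seed = 2)
  raw2 <- make_sim_raw(array(1, c(32, 32, 8)), cfg, sim, peak_snr = 10,
                       seed = 2)
  expect_identical(raw1$data, raw2$data)
})
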