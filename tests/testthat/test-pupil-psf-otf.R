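test_that("the unaberrated pupil is a hard-edged binary disk", {
  cfg <- tiny_config()
  p <- make_pupil(cfg)
  g <- phicao:::pupil_grids(cfg)
  mask <- g$kr2 < (cfg$na / cfg$wavelength)^2
  expect_true(all(Mod(p)[mask] == 1))
  expect_true(all(Mod(p)[!mask] == 0))
  # a specific frequency outside the circle maps to zero
  ic <- floor(cfg$pupil_size / 2) + 1
  edge <- ic + ceiling((cfg$na / cfg$wavelength) /
                         (1 / (cfg$pupil_size * cfg$voxel[3]))) + 1
  expect_identical(unclass(p)[ic, edge], 0 + 0i)
})

test_that("phase-only aberrations never change the pupil amplitude", {
  cfg <- tiny_config()
  p0 <- make_pupil(cfg)
  p1 <- make_pupil(cfg, aberration_spec(sa = 0.01, coma_v = 0.4, z9 = 1.2),
                   z = 500)
  expect_equal(as.vector(Mod(p1)), as.vector(Mod(p0)), tolerance = 1e-12)
})

test_that("the B' amplitude model modulates only the supported amplitude", {
  cfg <- tiny_config()
  p0 <- make_pupil(cfg)
  pb <- make_pupil(cfg, amplitude_model = "b_prime", dn2 = -0.02)
  mask <- attr(p0, "mask")
  expect_true(all(Mod(pb)[!mask] == 0))
  expect_false(isTRUE(all.equal(Mod(pb)[mask], Mod(p0)[mask])))
  expect_true(all(is.finite(Mod(pb))))
  # dn2 = 0 reduces to the plain binary pupil
  pb0 <- make_pupil(cfg, amplitude_model = "b_prime", dn2 = 0)
  expect_equal(as.vector(Mod(pb0)), as.vector(Mod(p0)), tolerance = 1e-12)
})

test_that("a pupil circle beyond the grid Nyquist limit is rejected", {
  expect_error(
    optical_config(na = 1.42, wavelength = 528, n_immersion = 1.515,
                   voxel = c(267, 200, 200), shape = c(8, 32, 32),
                   pupil_size = 256),
    "Nyquist")
})

test_that("the unaberrated PSF is symmetric axially and laterally", {
  psf <- ideal_psf_bench()
  d <- psf$data
  dm <- dim(d)
  cz <- floor(dm[3] / 2) + 1
  for (k in c(2, 5, 9))
    expect_rel_equal(d[, , cz + k], d[, , cz - k], 1e-6)
  # point reflection in (x, y), unpaired first row/col excluded
  for (iz in c(cz, cz + 4)) {
    sl <- d[, , iz]
    expect_rel_equal(sl[2:dm[1], 2:dm[2]], sl[dm[1]:2, dm[2]:2], 1e-6)
  }
})

test_that("spherical aberration makes the axial profile asymmetric", {
  psf_sa <- fx("psf_sa_bench",
               make_psf(bench_config(), aberration_spec(sa = 0.008)))
  expect_lt(axial_asymmetry(ideal_psf_bench()$data), 1e-10)
  expect_gt(axial_asymmetry(psf_sa$data), 0.05)
})

test_that("a tilt term displaces the PSF by the requested amount", {
  cfg <- tiny_config()
  shift_nm <- 4 * cfg$voxel[3]
  p0 <- make_psf(cfg)
  pt <- make_psf(cfg, aberration_spec(tilt_x = shift_nm))
  i0 <- arrayInd(which.max(p0$data), dim(p0$data))
  it <- arrayInd(which.max(pt$data), dim(pt$data))
  expect_equal(it[2] - i0[2], 4)
  expect_equal(it[1], i0[1])
  # sub-voxel check through the intensity centroid near the peak
  w <- pt$data[, , i0[3]]
  cx <- sum(col(w) * w) / sum(w)
  expect_lt(abs(cx - (i0[2] + shift_nm / cfg$voxel[3])), 0.5)
})

test_that("total PSF intensity is invariant under pure tilt (shift theorem)", {
  # uncropped field so no energy leaves the computed window
  cfg <- optical_config(na = 1.42, wavelength = 528, n_immersion = 1.515,
                        voxel = c(267, 92, 92), shape = c(4, 256, 256),
                        pupil_size = 256)
  s0 <- sum(make_psf(cfg)$data)
  st <- sum(make_psf(cfg, aberration_spec(tilt_x = 300, tilt_y = -150))$data)
  expect_rel_equal(st, s0, 1e-6)
})

test_that("zero-magnitude SA reproduces the empty-spec PSF bit for bit", {
  cfg <- tiny_config()
  expect_identical(make_psf(cfg, aberration_spec(sa = 0))$data,
                   make_psf(cfg)$data)
})

test_that("the OTF separates into a consistent amplitude and phase", {
  psf <- ideal_psf_bench()
  otf <- psf_to_otf(psf)
  d <- dim(otf$amplitude)
  ctr <- floor(d / 2) + 1
  # DC amplitude equals the PSF total, DC phase is zero
  expect_rel_equal(otf$amplitude[ctr[1], ctr[2], ctr[3]], sum(psf$data), 1e-9)
  expect_lt(abs(otf$phase[ctr[1], ctr[2], ctr[3]]), 1e-12)
  expect_true(all(otf$amplitude >= 0))
  expect_true(all(abs(otf$phase) <= pi))
  expect_error(psf_to_otf(structure(list(
    data = array(0, dim(psf$data)), config = psf$config), class = "psf3d")),
    "all-zero")
})

test_that("OTFs of real PSFs are Hermitian: amplitude even, phase odd", {
  psf <- fx("psf_mix_bench",
            make_psf(bench_config(), aberration_spec(sa = 0.006, coma_u = 0.3)))
  otf <- psf_to_otf(psf)
  d <- dim(otf$amplitude)
  sub <- function(a) a[2:d[1], 2:d[2], 2:d[3]]
  refl <- function(a) a[d[1]:2, d[2]:2, d[3]:2]
  expect_rel_equal(sub(otf$amplitude), refl(otf$amplitude), 1e-6)
  # phase odd where the amplitude is meaningful
  amp <- sub(otf$amplitude)
  sig <- amp > 1e-6 * max(amp)
  expect_lt(max(abs(sub(otf$phase)[sig] + refl(otf$phase)[sig])), 1e-6)
})

test_that("an unaberrated centered PSF has a flat phase transfer function", {
  otf <- psf_to_otf(ideal_psf_bench())
  carrier <- otf$amplitude > 0.01 * max(otf$amplitude)
  # phase is 0 modulo the sign flips of near-zero real OTF values
  ph <- otf$phase[carrier]
  expect_lt(max(pmin(abs(ph), abs(abs(ph) - pi))), 1e-3)
  expect_lt(mean(abs(ph) > pi / 2), 0.02)
})

test_that("aberrations move the 3D phase more than the 3D amplitude", {
  otf0 <- psf_to_otf(ideal_psf_bench())
  otf1 <- psf_to_otf(fx("psf_sa_bench",
                        make_psf(bench_config(), aberration_spec(sa = 0.008))))
  w <- otf0$amplitude > 0.01 * max(otf0$amplitude)
  a0 <- otf0$amplitude / max(otf0$amplitude)
  a1 <- otf1$amplitude / max(otf1$amplitude)
  rel_mtf <- sqrt(mean((a1[w] - a0[w])^2)) / sqrt(mean(a0[w]^2))
  # compare unit-modulus phase factors so wrapping cannot hide a change
  rel_ptf <- sqrt(mean(Mod(exp(1i * otf1$phase[w]) -
                             exp(1i * otf0$phase[w]))^2)) / sqrt(2)
  expect_gt(rel_ptf, rel_mtf)
})
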