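test_that("phase-only deconvolution conserves total intensity for any PTF", {
  cfg <- tiny_config()
  set.seed(5)
  for (i in 1:3) {
    st <- image_stack(array(stats::runif(16 * 32 * 32, 0, 100),
                            dim = c(32, 32, 16)), cfg)
    spec <- aberration_spec(magnitudes = stats::setNames(
      stats::runif(2, -1, 1) * c(0.01, 0.5), c("sa", "coma_v")))
    ptf <- psf_to_otf(make_psf(cfg, spec))
    out <- phase_only_deconvolve(st, ptf)
    expect_rel_equal(sum(out$data), sum(st$data), 1e-6)
  }
})

test_that("a zero PTF introduces no asymmetry into a symmetric object", {
  cfg <- tiny_config()
  st <- make_point_phantom(cfg)
  out <- phase_only_deconvolve(st, array(0, dim = dim(st$data)))
  d <- out$data; dm <- dim(d)
  cz <- floor(dm[3] / 2) + 1
  expect_rel_equal(d[, , cz + 3], d[, , cz - 3], 1e-6)
  expect_lt(axial_asymmetry(d), 1e-8)
})

test_that("deconvolving with the true PTF restores axial symmetry", {
  cfg <- bench_config()
  truth <- aberration_spec(sa = 0.008)
  st <- make_point_phantom(cfg, aberration = truth)
  dec_true <- phase_only_deconvolve(st, psf_to_otf(make_psf(cfg, truth)))
  dec_zero <- phase_only_deconvolve(st, array(0, dim = dim(st$data)))
  expect_lt(axial_asymmetry(dec_true$data), axial_asymmetry(dec_zero$data))
})

test_that("the cone bandpass matches a direct per-voxel evaluation", {
  cfg <- tiny_config(nz = 8, n = 16)
  m <- bandpass_mask(cfg, centered = FALSE)
  ctr_pass <- m[1, 1, 1]
  expect_true(ctr_pass)                       # DC passes
  expect_false(m[1, 1, 2])                    # pure axial frequency excluded
  # independent loop-based oracle of the passband inequality
  theta <- asin(cfg$na / cfg$n_immersion)
  kx <- phicao:::fft_freq(16, cfg$voxel[3])
  ky <- phicao:::fft_freq(16, cfg$voxel[2])
  kz <- phicao:::fft_freq(8, cfg$voxel[1])
  count <- 0
  for (iy in 1:16) for (ix in 1:16) for (iz in 1:8) {
    kl <- sqrt(kx[ix]^2 + ky[iy]^2); ks <- abs(kz[iz])
    lhs <- (4 * pi / 1.8) * (kl * sin(theta) - ks * cos(theta))
    if (lhs >= sqrt(kl^2 + ks^2)) count <- count + 1
  }
  expect_identical(sum(m), as.integer(count))
})

test_that("the sharpness metric has the stated invariances", {
  cfg <- tiny_config(nz = 8, n = 16)
  const <- image_stack(array(7, dim = c(16, 16, 8)), cfg)
  expect_equal(sharpness_metric(const, bandpass = FALSE), 0)
  set.seed(9)
  st <- image_stack(array(stats::rnorm(16 * 16 * 8), dim = c(16, 16, 8)), cfg)
  v1 <- sharpness_metric(st, bandpass = FALSE)
  st3 <- image_stack(3 * st$data, cfg)
  expect_rel_equal(sharpness_metric(st3, bandpass = FALSE), 3^4 * v1, 1e-10)
})

test_that("scanning an unaberrated stack returns a near-zero magnitude", {
  cfg <- bench_config()
  st <- subtract_background(make_point_phantom(cfg))
  res <- scan_mode(st, "sa")
  expect_lt(abs(res$estimate), 0.01 / 10)
  expect_true(res$fit_ok)
  expect_gte(nrow(res$samples), 5)
})

test_that("a known SA magnitude is recovered at the brute-force optimum", {
  # dense-scan oracle (step 5e-4 over [-0.02, 0.02]) on this fixture puts the
  # metric argmax exactly at the injected 0.005, with monotone flanks
  oracle_argmax <- 0.005
  cfg <- bench_config()
  st <- subtract_background(
    make_point_phantom(cfg, aberration = aberration_spec(sa = 0.005)))
  res <- scan_mode(st, "sa")
  expect_lt(abs(res$estimate - oracle_argmax) / oracle_argmax, 0.10)
  res2 <- scan_mode(st, "sa",
                    accumulated = aberration_spec(sa = res$estimate))
  expect_lt(abs(res2$estimate - oracle_argmax) / oracle_argmax, 0.10)
})

test_that("degenerate metric samples fall back to the discrete argmax", {
  plan <- sampling_plan()
  obj <- function(a) if (a > -0.0175) NaN else -abs(a + 0.02)
  expect_warning(res <- phicao:::scan_magnitude(obj, 0, 0.01, plan),
                 "discrete maximum")
  expect_false(res$fit_ok)
  expect_true(is.finite(res$estimate))
})

test_that("an empty mode list is a no-op measurement", {
  cfg <- tiny_config()
  st <- make_point_phantom(cfg)
  init <- aberration_spec(sa = 0.002)
  fit <- measure_aberrations(st, modes = character(0), init = init)
  expect_identical(fit$estimate, init)
  expect_equal(fit$n_cycles, 0)
})

test_that("a two-mode Zernike composite is recovered within 10%", {
  cfg <- bench_config()
  truth <- aberration_spec(z5 = 1, z6 = 1)
  st <- subtract_background(make_point_phantom(cfg, aberration = truth))
  fit <- measure_aberrations(st, modes = c("z5", "z6"), n_iterations = 4,
                             background = FALSE)
  expect_lte(fit$n_cycles, 4)
  expect_lt(abs(coef(fit)["z5"] - 1), 0.1)
  expect_lt(abs(coef(fit)["z6"] - 1), 0.1)
  # residual wavefront error vs truth decreases over cycles
  err <- apply(fit$per_cycle, 1, function(est) {
    delta <- est - c(z5 = 1, z6 = 1)[colnames(fit$per_cycle)]
    rms_wavefront(aberration_spec(magnitudes = delta), cfg)
  })
  if (length(err) > 1) expect_true(all(diff(err) <= 1e-9 + 0.05 * err[1]))
})

test_that("Poisson noise at peak SNR 16 leaves SA recovery usable", {
  cfg <- bench_config()
  truth <- 0.008
  clean <- make_point_phantom(cfg, aberration = aberration_spec(sa = truth))
  noisy <- add_poisson_noise(clean, peak_snr = 16, seed = 21)
  fit1 <- measure_aberrations(noisy, modes = "sa", n_iterations = 2)
  expect_lt(abs(coef(fit1)["sa"] - truth), 0.2 * truth)
})

test_that("measurement results round-trip through their S3 surface", {
  cfg <- bench_config()
  st <- subtract_background(
    make_point_phantom(cfg, aberration = aberration_spec(sa = 0.005)))
  fit <- measure_aberrations(st, modes = "sa", n_iterations = 1,
                             background = FALSE)
  expect_s3_class(fit, "cao_fit")
  expect_named(coef(fit), "sa")
  s <- summary(fit)
  expect_output(print(s), "Per-cycle")
  expect_output(print(fit), "cao_fit")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
  w <- predict(fit, type = "wavefront")
  expect_equal(dim(w), rep(cfg$pupil_size, 2))
  sims <- simulate(fit, nsim = 2, seed = 3, peak_snr = 20)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]]$data, sims[[2]]$data))
})
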