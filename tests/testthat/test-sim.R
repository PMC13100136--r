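sim_fix <- function() {
  fx("sim_fix", {
    cfg <- tiny_config(nz = 16, n = 64)
    list(cfg = cfg, sim = sim_config(cfg, n_angles = 3))
  })
}

test_that("the illumination pattern has the configured fringe frequency", {
  f <- sim_fix()
  ill <- make_sim_illumination(f$cfg, f$sim, angle_index = 1, phase_index = 0)
  sl <- ill[, , 9]
  sp <- Mod(stats::fft(sl - mean(sl)))
  pk <- arrayInd(which.max(sp), dim(sp)) - 1L
  cx <- abs(f$sim$angles[[1]]$cycles["x"])
  expect_true(pk[2] %in% c(cx, 64 - cx))
  expect_equal(pk[1], 0L)
  expect_gt(min(ill), -1e-12)
  expect_rel_equal(mean(ill), 1, 0.1)
})

test_that("pattern phases are periodic with period five", {
  f <- sim_fix()
  i0 <- make_sim_illumination(f$cfg, f$sim, angle_index = 2, phase_index = 0)
  i5 <- make_sim_illumination(f$cfg, f$sim, angle_index = 2, phase_index = 5)
  expect_rel_equal(i5, i0, 1e-12)
  i2 <- make_sim_illumination(f$cfg, f$sim, angle_index = 2, phase_index = 2)
  expect_gt(max(abs(i2 - i0)), 0.1)
})

test_that("zero side-beam weight reduces the SIM PSF to the wide-field PSF", {
  f <- sim_fix()
  p0 <- make_sim_psf(f$cfg, f$sim, beam_weights = c(0, 1, 0))
  expect_identical(p0$data, make_psf(f$cfg)$data)
})

test_that("an off-pupil spot position is rejected", {
  f <- sim_fix()
  expect_error(sim_config(f$cfg, k_frac = 1.2), "outside the pupil")
})

test_that("order separation inverts the 5-phase mixing exactly", {
  f <- sim_fix()
  set.seed(31)
  dims <- c(64, 64, 16)
  c0 <- array(stats::runif(prod(dims), 1, 2), dims)
  c1 <- array(complex(real = stats::rnorm(prod(dims)),
                      imaginary = stats::rnorm(prod(dims))), dims) * 0.2
  c2 <- array(complex(real = stats::rnorm(prod(dims)),
                      imaginary = stats::rnorm(prod(dims))), dims) * 0.1
  data <- array(0, dim = c(dims, 5, 1))
  for (s in 0:4) {
    ph <- exp(1i * 2 * pi * s / 5)
    data[, , , s + 1, 1] <- Re(c0 + c1 * ph + Conj(c1) / ph +
                                 c2 * ph^2 + Conj(c2) / ph^2)
  }
  raw <- structure(list(data = data, config = f$cfg,
                        sim = sim_config(f$cfg, n_angles = 1)),
                   class = "sim_raw")
  sep <- separate_orders(raw)[[1]]
  expect_lt(max(Mod(sep$D0 - stats::fft(c0))) / max(Mod(stats::fft(c0))), 1e-6)
  expect_lt(max(Mod(sep$D1 - stats::fft(c1))) / max(Mod(stats::fft(c1))), 1e-6)
  expect_lt(max(Mod(sep$D2 - stats::fft(c2))) / max(Mod(stats::fft(c2))), 1e-6)
})

test_that("summing the phases of raw data yields five times the zero order", {
  f <- sim_fix()
  obj <- array(0, dim = c(64, 64, 16))
  set.seed(3)
  obj[cbind(sample(10:54, 12, TRUE), sample(10:54, 12, TRUE),
            sample(4:13, 12, TRUE))] <- 1
  raw <- fx("sim_raw_beads", make_sim_raw(obj, f$cfg, f$sim))
  sep <- separate_orders(raw)
  ps <- apply(raw$data[, , , , 1], c(1, 2, 3), sum)
  d0 <- Re(phicao:::ifft(sep[[1]]$D0))
  expect_rel_equal(ps, 5 * d0, 1e-9)
  pw <- pseudo_widefield(raw)
  expect_equal(dim(pw$data), c(64, 64, 16))
})

test_that("a fringe-free object leaves the high orders empty", {
  f <- sim_fix()
  raw <- make_sim_raw(array(1, dim = c(64, 64, 16)), f$cfg, f$sim)
  sep <- separate_orders(raw)[[1]]
  expect_lt(max(Mod(sep$D1)) / max(Mod(sep$D0)), 0.02)
  expect_lt(max(Mod(sep$D2)) / max(Mod(sep$D0)), 0.02)
})

test_that("modulation amplitude tracks the generated modulation depth", {
  f <- sim_fix()
  obj <- array(0, dim = c(64, 64, 16))
  set.seed(17)
  obj[cbind(sample(10:54, 10, TRUE), sample(10:54, 10, TRUE),
            sample(5:12, 10, TRUE))] <- 1
  # relative order-1 content 3c/(1+2c^2) grows with the side-beam weight c
  # up to c = 1/sqrt(2); stay below that so the true depth is monotone
  depths <- c(0.2, 0.4, 0.6)
  ot <- phicao:::sim_order_otfs(f$cfg, f$sim, 1)
  cyc <- f$sim$angles[[1]]$cycles
  got <- vapply(depths, function(cc) {
    raw <- make_sim_raw(obj, f$cfg, f$sim, beam_weights = c(cc, 1, cc))
    sep <- separate_orders(raw)[[1]]
    modulation_amplitude(sep$D0, sep$D1, ot$O0, ot$O1,
                         c(cyc["y"], cyc["x"]))$depth
  }, numeric(1))
  expect_true(all(diff(got) > 0))     # monotone in the true depth
  # data generated with the model's own beam weights have depth ~ 1
  raw <- fx("sim_raw_beads", make_sim_raw(obj, f$cfg, f$sim))
  sep <- separate_orders(raw)[[1]]
  full <- modulation_amplitude(sep$D0, sep$D1, ot$O0, ot$O1,
                               c(cyc["y"], cyc["x"]))$depth
  expect_gt(full, 0.05)
  # the zero order correlated with itself has unit amplitude by convention
  c0 <- modulation_amplitude(sep$D0, sep$D0, ot$O0, ot$O0, c(0, 0))
  expect_equal(c0$c, 1 + 0i)
  expect_equal(c0$depth, 1)
  z <- modulation_amplitude(sep$D0, array(0i, dim = dim(sep$D1)),
                            ot$O0, ot$O1, c(cyc["y"], cyc["x"]))
  expect_equal(z$depth, 0)
})

test_that("the modulation objective peaks at the generating aberration", {
  f <- sim_fix()
  obj <- array(0, dim = c(64, 64, 16))
  set.seed(17)
  obj[cbind(sample(10:54, 10, TRUE), sample(10:54, 10, TRUE),
            sample(5:12, 10, TRUE))] <- 1
  truth <- 0.006
  raw <- make_sim_raw(obj, f$cfg, f$sim, spec = aberration_spec(sa = truth))
  mobj <- phicao:::sim_modulation_objective(raw, 1)
  as <- seq(-0.002, 0.014, by = 0.002)
  vs <- vapply(as, function(a) mobj(aberration_spec(sa = a)), numeric(1))
  expect_equal(as[which.max(vs)], truth)
  i <- which.max(vs)
  expect_true(all(diff(vs[1:i]) > 0) && all(diff(vs[i:length(vs)]) < 0))
})

test_that("an unaberrated SIM stack measures near-zero aberration", {
  f <- sim_fix()
  obj <- array(0, dim = c(64, 64, 16))
  set.seed(3)
  obj[cbind(sample(10:54, 12, TRUE), sample(10:54, 12, TRUE),
            sample(4:13, 12, TRUE))] <- 1
  raw <- fx("sim_raw_beads", make_sim_raw(obj, f$cfg, f$sim))
  fit <- measure_aberrations_sim(raw, modes = "sa", n_iterations = 1)
  expect_lt(abs(coef(fit)["sa"]), 0.002)
})

test_that("reconstruction is artifact-free on a uniform object", {
  f <- sim_fix()
  raw <- make_sim_raw(array(1, dim = c(64, 64, 16)), f$cfg, f$sim)
  rec <- reconstruct_sim(raw)
  mid <- rec$data[17:48, 17:48, 8]
  expect_lt(stats::sd(mid) / mean(mid), 0.02)
})

test_that("reconstruction resolves beads below the wide-field limit", {
  cfg <- optical_config(na = 1.42, wavelength = 528, n_immersion = 1.515,
                        voxel = c(250, 40, 40), shape = c(16, 64, 64),
                        pupil_size = 256)
  sim <- sim_config(cfg, n_angles = 3)
  obj <- array(0, dim = c(64, 64, 16))
  obj[33, 31, 9] <- 1
  obj[33, 35, 9] <- 1      # 160 nm apart, below the ~186 nm wide-field limit
  raw <- make_sim_raw(obj, cfg, sim)
  nmax <- function(p) sum(diff(sign(diff(p))) == -2)
  pw <- pseudo_widefield(raw)$data[33, 26:40, 9]
  pr <- reconstruct_sim(raw)$data[33, 26:40, 9]
  expect_equal(nmax(pw), 1)              # unresolved in pseudo-widefield
  expect_equal(nmax(pr), 2)              # resolved after reconstruction
})

test_that("correcting the reconstruction with the true spec raises the peak", {
  f <- sim_fix()
  obj <- array(0, dim = c(64, 64, 16))
  obj[33, 33, 9] <- 1
  raw <- make_sim_raw(obj, f$cfg, f$sim, spec = aberration_spec(sa = 0.008))
  rec0 <- reconstruct_sim(raw)
  rec1 <- reconstruct_sim(raw, spec = aberration_spec(sa = 0.008))
  expect_gt(max(rec1$data), 1.1 * max(rec0$data))
})

test_that("subregional SIM correction degenerates correctly", {
  f <- sim_fix()
  obj <- array(0, dim = c(64, 64, 16))
  obj[33, 33, 9] <- 1
  raw <- make_sim_raw(obj, f$cfg, f$sim)
  whole <- region(0, 0, 16, 0, 64, 0, 64)
  rec_reg <- correct_by_region_sim(raw, list(whole), list(aberration_spec()))
  rec <- reconstruct_sim(raw)
  expect_rel_equal(rec_reg$data, rec$data, 1e-12)
})
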