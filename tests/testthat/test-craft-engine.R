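# The time-domain decomposer: noise estimation, sub-band decimation,
# subspace initialisation, variable-projection refinement, selection,
# and the orchestrated fit.

test_that("noise estimator is calibrated on pure Gaussian records", {
  ok <- 0
  for (i in 1:100) {
    fid <- synthesize_fid(empty_resonances(), acq_grid(1e-3, 4096),
                          noise_sigma = 1, seed = 800 + i)
    s <- estimate_noise_sigma(fid)
    if (s >= 0.9 && s <= 1.1) ok <- ok + 1
  }
  expect_gte(ok, 95)
})

test_that("noise estimator vanishes on zero and slow noiseless signals", {
  z <- synthesize_fid(empty_resonances(), acq_grid(1e-3, 64))
  expect_equal(estimate_noise_sigma(z), 0)
  # a strong noiseless sinusoid sampled fast relative to its evolution
  # (|s| * dwell ~ 1e-6) is suppressed by the differencing
  fast <- synthesize_fid(resonance_set(0, 10, 1, 0.4), acq_grid(1e-6, 4096))
  expect_lte(estimate_noise_sigma(fast), 1e-6 * 10)
  expect_error(estimate_noise_sigma(synthesize_fid(
    empty_resonances(), acq_grid(1e-3, 4))), "at least 8")
})

test_that("sub-band decimation: identity, in-band recovery, attenuation", {
  g <- acq_grid(1e-4, 4096)
  fid <- synthesize_fid(resonance_set(400, 1, 5, 0.2), g)
  # full-width band centred at zero passes the record through untouched
  expect_identical(subband_decimate(fid, 0, spectral_width(g))$samples,
                   fid$samples)
  # a band centred on the signal yields a DC damped exponential with the
  # same amplitude and decay (fit the decimated record to check)
  dec <- subband_decimate(fid, 400, 100)
  expect_lt(dec$grid$n_points, g$n_points)
  cand <- initial_model(dec, 4)
  expect_equal(nrow(cand), 1L)
  expect_lt(abs(cand$frequency_hz), 0.5)       # shifted to DC
  expect_equal(cand$amplitude, 1, tolerance = 0.01)
  expect_equal(cand$decay_rate, 5, tolerance = 0.01)
  expect_equal(cand$phase_rad, 0.2, tolerance = 0.01)
  # far out-of-band signal is crushed below 1e-4 of its input power
  far <- synthesize_fid(resonance_set(2000, 1, 5), g)
  dec_far <- subband_decimate(far, 400, 100)
  expect_lt(mean(Mod(dec_far$samples)^2) / mean(Mod(far$samples)^2), 1e-4)
  expect_error(subband_decimate(fid, 6000, 100), "outside the spectral width")
})

test_that("matrix-pencil initialisation recovers known components", {
  # single noiseless component: essentially exact recovery
  g <- acq_grid(1e-3, 512)
  fid <- synthesize_fid(resonance_set(100, 1, 5, 0.3), g)
  cand <- initial_model(fid, 5)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$frequency_hz, 100, tolerance = 1e-6)
  expect_equal(cand$amplitude, 1, tolerance = 1e-6)
  expect_equal(cand$decay_rate, 5, tolerance = 1e-6)
  expect_equal(cand$phase_rad, 0.3, tolerance = 1e-6)
  # all-zero record: empty candidate list
  expect_equal(nrow(initial_model(synthesize_fid(
    empty_resonances(), g), 5)), 0L)
  # two components 3 Hz apart on a 100 ms record: well below the 10 Hz
  # Rayleigh limit, still resolved by the subspace method
  g2 <- acq_grid(1e-3, 100)
  truth <- resonance_set(c(50, 53), c(1, 0.8), c(5, 5), c(0.3, -1.0))
  cand2 <- initial_model(synthesize_fid(truth, g2), 6)
  expect_equal(nrow(cand2), 2L)
  m <- match_components(cand2, truth, 1)
  expect_equal(m$frequency_hz, truth$frequency_hz, tolerance = 1e-3)
  expect_equal(m$amplitude, truth$amplitude, tolerance = 1e-3)
  expect_equal(m$decay_rate, truth$decay_rate, tolerance = 1e-3)
  expect_error(initial_model(synthesize_fid(truth, g2), 50), "max_order")
})

test_that("refinement is a fixed point on exact candidates", {
  g <- acq_grid(1e-3, 256)
  truth <- fixture_six()
  fid <- synthesize_fid(truth, g)
  out <- refine_components(fid, truth)
  expect_false(out$unrefined)
  m <- match_components(out$components, truth, 1)
  expect_equal(m$frequency_hz, truth$frequency_hz, tolerance = 1e-9)
  expect_equal(m$amplitude, truth$amplitude, tolerance = 1e-9)
  expect_lt(out$residual_rms, 1e-9)
  expect_error(refine_components(fid, truth[0, ]), "non-empty")
})

test_that("refinement pulls a perturbed candidate back to the truth", {
  g <- acq_grid(1e-3, 512)
  truth <- resonance_set(100, 1, 5, 0.3)
  fid <- synthesize_fid(truth, g)
  bad <- truth
  bad$frequency_hz <- 100 + 0.3 * (5 / pi)   # off by 0.3 linewidths
  out <- refine_components(fid, bad)
  expect_equal(out$components$frequency_hz, 100, tolerance = 1e-4 * 100)
  expect_equal(out$components$amplitude, 1, tolerance = 1e-4)
  expect_equal(out$components$decay_rate, 5, tolerance = 1e-4 * 5)
})

test_that("reported frequency uncertainty tracks the Cramer-Rao bound", {
  g <- acq_grid(1e-3, 1024)
  truth <- resonance_set(73.3, 1, 4, 0.7)
  crb <- oracle_crb(1, 0.7, 73.3, 4, 1e-3, 1024, 0.01)
  fhat <- sehat <- numeric(40)
  for (i in 1:40) {
    fid <- synthesize_fid(truth, g, noise_sigma = 0.01, seed = 900 + i)
    cmp <- coef(craft(fid))
    expect_equal(nrow(cmp), 1L)
    fhat[i] <- cmp$frequency_hz
    sehat[i] <- cmp$se_frequency_hz
  }
  expect_gt(sd(fhat) / crb[3], 0.5)
  expect_lt(sd(fhat) / crb[3], 2)
  expect_gt(mean(sehat) / crb[3], 0.5)
  expect_lt(mean(sehat) / crb[3], 2)
})

test_that("the detection rule keeps resolved and drops unresolved amplitudes", {
  comp <- data.frame(frequency_hz = c(0, 50), amplitude = c(10, 2),
                     decay_rate = c(2, 2), phase_rad = c(0, 0),
                     se_frequency_hz = 0.1, se_amplitude = c(1, 1),
                     se_decay_rate = 0.1, se_phase = 0.1)
  kept <- select_components(comp, 1, detection_k = 3)
  expect_equal(kept$amplitude, 10)
  disc <- attr(kept, "discarded")
  expect_equal(disc$amplitude, 2)
  expect_true(all(disc$score < 3))
})

test_that("pure-noise records yield (almost) no components", {
  fp <- 0
  for (i in 1:30) {
    fid <- synthesize_fid(empty_resonances(), acq_grid(1e-3, 256),
                          noise_sigma = 1, seed = 2000 + i)
    fp <- fp + nrow(coef(craft(fid)))
  }
  expect_lte(fp / 30, 0.1)
})

test_that("craft recovers a six-component truncated record exactly", {
  truth <- fixture_six()
  fid <- synthesize_fid(truth, acq_grid(1e-3, 128))
  fit <- craft(fid)
  expect_s3_class(fit, "craft")
  expect_equal(nrow(coef(fit)), 6L)
  m <- match_components(coef(fit), truth, 2)
  rel <- function(est, tru) max(abs(est - tru) / abs(tru))
  expect_lt(rel(m$frequency_hz, truth$frequency_hz), 1e-4)
  expect_lt(rel(m$amplitude, truth$amplitude), 1e-4)
  expect_lt(rel(m$decay_rate, truth$decay_rate), 1e-4)
  expect_lt(rel(m$phase_rad, truth$phase_rad), 1e-4)
  expect_lt(fit$residual_rms, 1e-9)
  # fitted() reproduces the record; residuals() are machine-level
  expect_lt(max(Mod(residuals(fit))), 1e-8)
})

test_that("craft holds up under noise at per-component SNR ~20", {
  truth <- fixture_six()
  g <- acq_grid(1e-3, 512)
  sigma <- min(truth$amplitude) / 20
  amps <- matrix(NA_real_, 5, 6)
  for (i in 1:5) {
    fit <- craft(synthesize_fid(truth, g, sigma, seed = 4000 + i))
    m <- match_components(coef(fit), truth, 3)
    amps[i, ] <- m$amplitude
  }
  expect_lt(max(abs(sweep(amps, 2, truth$amplitude, "/") - 1)), 0.10)
})

test_that("craft returns an empty table on empty or pure-noise input", {
  z <- synthesize_fid(empty_resonances(), acq_grid(1e-3, 256))
  expect_equal(nrow(coef(craft(z))), 0L)
  noise <- synthesize_fid(empty_resonances(), acq_grid(1e-3, 256),
                          noise_sigma = 1, seed = 5)
  expect_equal(nrow(coef(craft(noise))), 0L)
})

test_that("decomposition is equivariant under a global phase shift", {
  truth <- fixture_six()
  fid <- synthesize_fid(truth, acq_grid(1e-3, 256))
  fit0 <- craft(fid)
  dphi <- 1.1
  fid2 <- fid
  fid2$samples <- fid$samples * exp(1i * dphi)
  fit2 <- craft(fid2)
  m0 <- coef(fit0)[order(coef(fit0)$frequency_hz), ]
  m2 <- coef(fit2)[order(coef(fit2)$frequency_hz), ]
  expect_equal(m2$frequency_hz, m0$frequency_hz, tolerance = 1e-6)
  expect_equal(m2$amplitude, m0$amplitude, tolerance = 1e-6)
  expect_equal(wrap_phase(m2$phase_rad - m0$phase_rad - dphi),
               rep(0, 6), tolerance = 1e-6)
})

test_that("long records go through sub-bands and land on the same answer", {
  truth <- resonance_set(c(-150, 100), c(1, 1), c(1.5, 1.5), c(0.2, -0.5))
  fid <- synthesize_fid(truth, acq_grid(1e-3, 4096))
  fit <- craft(fid)
  expect_equal(nrow(coef(fit)), 2L)
  m <- match_components(coef(fit), truth, 1)
  expect_equal(m$amplitude, truth$amplitude, tolerance = 1e-4)
  expect_equal(m$decay_rate, truth$decay_rate, tolerance = 1e-4)
  expect_true(all(coef(fit)$band_id > 0))
})

test_that("resynthesis: auto-sizing, round trip, envelope", {
  truth <- resonance_set(c(-50, 80), c(1, 0.5), c(2, 4), c(0.3, -0.9))
  fid <- synthesize_fid(truth, acq_grid(1e-3, 256))
  fit <- craft(fid)
  # slowest decay 2/s with factor 4: a 2.0 s record
  out <- simulate_from_table(fit, length_factor = 4)
  expect_equal(acq_time(out$grid), 2, tolerance = 2e-3)
  expect_identical(out$provenance, "craft_resimulated")
  # resynthesis on the source grid reproduces the input
  back <- simulate_from_table(fit, grid_out = fid$grid)
  expect_equal(back$samples, fid$samples, tolerance = 1e-6)
  # single-component envelope at three spot times
  one <- craft(synthesize_fid(resonance_set(0, 2, 3, 0), acq_grid(1e-3, 256)))
  sim <- simulate_from_table(one, grid_out = acq_grid(1e-2, 64))
  tt <- c(1, 21, 41)
  expect_equal(Mod(sim$samples[tt]), 2 * exp(-3 * (tt - 1) * 1e-2),
               tolerance = 1e-6)
  expect_error(simulate_from_table(craft(synthesize_fid(
    empty_resonances(), acq_grid(1e-3, 64)))), "empty table")
})

test_that("reconstructed spectra scale exactly and keep Lorentzian widths", {
  fit <- craft(synthesize_fid(resonance_set(10, 1, pi, 0),
                              acq_grid(1e-3, 512)))
  s1 <- craft_spectrum(fit, vertical_scale = 1)
  s06 <- craft_spectrum(fit, vertical_scale = 0.6)
  expect_equal(s06$intensities, 0.6 * s1$intensities, tolerance = 1e-12)
  # lambda = pi: FWHM is 1 Hz
  expect_equal(peak_fwhm(s1, 10, 20), 1, tolerance = 0.05)
  # linearity: a two-component spectrum is the sum of the singles
  two <- resonance_set(c(-40, 60), c(1, 2), c(3, 5), c(0.2, 1.0))
  gout <- acq_grid(1e-3, 2048)
  sp_two <- craft_spectrum(two, grid_out = gout, phase_correct = FALSE)
  sp_a <- craft_spectrum(two[1, ], grid_out = gout, phase_correct = FALSE)
  sp_b <- craft_spectrum(two[2, ], grid_out = gout, phase_correct = FALSE)
  expect_equal(sp_two$intensities, sp_a$intensities + sp_b$intensities,
               tolerance = 1e-9)
})

test_that("the fit residual honours the estimated noise level", {
  truth <- fixture_six()
  fid <- synthesize_fid(truth, acq_grid(1e-3, 512), noise_sigma = 0.05,
                        seed = 31)
  fit <- craft(fid)
  expect_lte(fit$residual_rms, fit$noise_sigma_hat * 1.2)
})
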