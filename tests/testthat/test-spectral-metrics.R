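# Fourier processing, SNR/peak metrics, LOD studies and quantification.

test_that("fourier_spectrum basics: delta record, Lorentzian width", {
  g <- acq_grid(1e-3, 256)
  delta <- synthesize_fid(empty_resonances(), g)
  delta$samples[1] <- 1 + 0i
  sp <- fourier_spectrum(delta)
  expect_lt(diff(range(Mod(sp$intensities))), 1e-12)  # flat magnitude
  long <- synthesize_fid(resonance_set(60, 1, 4, 0), acq_grid(1e-3, 8192))
  spl <- fourier_spectrum(long, zero_fill_factor = 8)
  expect_equal(peak_fwhm(spl, 60, 30), 4 / pi, tolerance = 0.02)
  expect_equal(spl$freq_hz[which.max(Re(spl$intensities))], 60,
               tolerance = 0.1)
})

test_that("truncated-record lineshape matches the brute-force DFT oracle", {
  g <- acq_grid(1e-3, 4096)
  fid <- truncate_fid(synthesize_fid(resonance_set(100, 1, 2, 0), g), 128)
  sp <- fourier_spectrum(fid, zero_fill_factor = 64, phase_correct = FALSE)
  # quasi-continuous oracle evaluation on a dense grid around the peak
  fgrid <- seq(60, 140, by = 0.05)
  Xo <- oracle_dft(fid$samples, 1e-3, fgrid)
  # peak FWHM from the oracle profile
  yo <- Re(Xo)
  half <- max(yo) / 2
  above <- range(which(yo > half))
  fwhm_oracle <- fgrid[above[2]] - fgrid[above[1]]
  expect_gt(fwhm_oracle, 2 / pi)   # truncation broadened beyond lambda/pi
  expect_equal(peak_fwhm(sp, 100, 30), fwhm_oracle, tolerance = 0.01)
  # first sinc sidelobe amplitude matches the oracle within 1 %
  ring <- fgrid > 100 + 1.3 / 0.128 & fgrid < 100 + 2.5 / 0.128
  side_oracle <- max(abs(Re(Xo[ring])))
  mask <- sp$freq_hz > 100 + 1.3 / 0.128 & sp$freq_hz < 100 + 2.5 / 0.128
  expect_equal(max(abs(Re(sp$intensities[mask]))), side_oracle,
               tolerance = 0.01)
})

test_that("the documented DFT convention satisfies Parseval", {
  fid <- synthesize_fid(resonance_set(c(10, -200), c(1, 2), c(3, 5)),
                        acq_grid(1e-3, 128), noise_sigma = 0.1, seed = 9)
  sp <- fourier_spectrum(fid, phase_correct = FALSE)
  expect_equal(sum(Mod(fid$samples)^2),
               mean(Mod(sp$intensities)^2), tolerance = 1e-9)
})

test_that("SNR follows the stated height-over-noise-height convention", {
  g <- acq_grid(1e-3, 400, carrier_ppm = 0)
  # constructed spectrum: signal height 30, noise of sd 5 (height 10)
  f <- seq(-199.5, 200, by = 1)
  y <- rep(c(5, -5), length.out = length(f))
  y[f > 150] <- 0
  y[300] <- 30
  sp <- structure(list(freq_hz = f, ppm = hz_to_ppm(g, f),
                       intensities = as.complex(y), grid = g,
                       provenance = "ft_conventional", scale = 1),
                  class = "nmr_spectrum")
  sig_win <- hz_to_ppm(g, c(90, 120))
  noi_win <- hz_to_ppm(g, c(-150, -50))
  got <- measure_snr(sp, sig_win, noi_win)
  noise_sd <- sd(y[f >= -150 & f <= -50])
  expect_equal(got, 30 / (2 * noise_sd))
  expect_equal(got, 3.0, tolerance = 0.01)   # the 3:1 detection condition
  # all-zero noise window: infinite sentinel
  expect_identical(measure_snr(sp, sig_win, hz_to_ppm(g, c(160, 199))), Inf)
  expect_error(measure_snr(sp, hz_to_ppm(g, c(90, 120)),
                           hz_to_ppm(g, c(100, 130))), "disjoint")
  expect_error(measure_snr(sp, sig_win, hz_to_ppm(g, c(500, 600))),
               "no spectrum points")
})

test_that("measured SNR agrees with the analytic expectation", {
  g <- acq_grid(1e-3, 512)
  truth <- resonance_set(100, 1, 2, 0)
  sigma <- 0.02
  # the expected height is taken from the phased clean spectrum: the
  # zeroth-order correction aligns the tallest (off-bin-centre) peak
  clean <- fourier_spectrum(synthesize_fid(truth, g), phase_correct = TRUE)
  h <- max(Re(clean$intensities))
  expected <- h / (2 * sigma * sqrt(512))   # per-bin noise sd sigma*sqrt(N)
  sig_win <- hz_to_ppm(g, c(80, 120))
  noi_win <- hz_to_ppm(g, c(-400, -200))
  snrs <- vapply(1:50, function(i)
    measure_snr(fourier_spectrum(synthesize_fid(truth, g, sigma,
                                                seed = 7000 + i)),
                sig_win, noi_win), numeric(1))
  expect_equal(mean(snrs), expected, tolerance = 0.15)
})

test_that("peak counting honours thresholds and the separation rule", {
  g <- acq_grid(1e-3, 256)
  expect_identical(count_peaks(craft(synthesize_fid(empty_resonances(), g)),
                               0), 0L)
  expect_identical(count_peaks(craft(synthesize_fid(fixture_six(),
                                                    acq_grid(1e-3, 128))),
                               0), 6L)
  # three well-separated peaks; threshold between the 2nd and 3rd tallest
  three <- resonance_set(c(-300, 0, 300), c(3, 2, 1), c(3, 3, 3))
  sp <- fourier_spectrum(synthesize_fid(three, acq_grid(1e-3, 2048)),
                         phase_correct = FALSE)
  h <- sort(vapply(c(-300, 0, 300), function(f0)
    max(Re(sp$intensities[abs(sp$freq_hz - f0) < 20])), numeric(1)))
  expect_identical(count_peaks(sp, mean(h[1:2])), 2L)
  expect_identical(count_peaks(sp, h[1] / 2), 3L)
})

test_that("lod_study: noiseless detection, identical-scheme fold of 1", {
  tmpl <- resonance_set(100, 1, 2, 0, t1_s = 1, t2_s = 0.5)
  g <- acq_grid(1e-3, 256)
  grid_amp <- c(0.01, 0.1, 1)
  schemes <- list(lod_scheme(conventional_scheme(1), g, "ft", "a"),
                  lod_scheme(conventional_scheme(1), g, "ft", "b"))
  st <- lod_study(tmpl, schemes, grid_amp, total_time_s = 10,
                  noise_sigma = 0, n_seeds = 2, seed = 5)
  # no noise: every amplitude is detected, LOD is the smallest grid point
  expect_equal(st$a$lod_amplitude, 0.01)
  expect_equal(fold_improvement(st, "a", "b"), 1.0)
})

test_that("spike recovery: exact table, ratio invariance, missing standard", {
  truth <- data.frame(label = c("x", "y"), frequency_hz = c(-100, 150),
                      spiked_amount = c(2, 0.5), n_fluorine = c(2, 3))
  isd <- list(frequency_hz = 40, amount = 1, n_fluorine = 3)
  tab <- data.frame(frequency_hz = c(-100, 40, 150),
                    amplitude = c(2 * 2, 1 * 3, 0.5 * 3))
  rec <- percent_recovery(tab, truth, isd, match_tol_hz = 5)
  expect_equal(rec$recovery_pct, c(100, 100))
  tab2 <- tab
  tab2$amplitude <- tab$amplitude * 2
  expect_equal(percent_recovery(tab2, truth, isd,
                                match_tol_hz = 5)$recovery_pct,
               c(100, 100))
  tab3 <- tab[tab$frequency_hz != 40, ]
  expect_error(percent_recovery(tab3, truth, isd, match_tol_hz = 5),
               "internal standard not found")
})
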