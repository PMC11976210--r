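# Bloch propagation, steady states and SSFP acquisition simulation.

test_that("bloch_cycle handles the trivial limits", {
  r <- resonance_set(0, 1, 2, t1_s = 1, t2_s = 0.5)
  eq <- c(0, 0, 1)
  # zero flip: equilibrium is untouched for any inter-pulse time
  expect_equal(bloch_cycle(eq, r, ssfp_scheme(0, 0.01)), eq)
  expect_equal(bloch_cycle(eq, r, ssfp_scheme(0, 5)), eq)
  # 90-degree pulse followed by essentially complete relaxation
  expect_equal(bloch_cycle(eq, r, ssfp_scheme(90, 50)), eq,
               tolerance = 1e-12)
  expect_error(bloch_cycle(eq, resonance_set(0, 1, 2), ssfp_scheme(90, 0.01)),
               "t1_s and t2_s")
})

test_that("bloch_cycle matches the rotation/relaxation matrix oracle", {
  cases <- expand.grid(flip = c(30, 77), f = c(0, 37), phase = c(0, 45))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    r <- resonance_set(cs$f, 1, 2, t1_s = 1, t2_s = 0.5)
    sch <- ssfp_scheme(cs$flip, 0.01, pulse_phase_deg = cs$phase)
    state <- c(0.2, -0.1, 0.8)
    expect_equal(bloch_cycle(state, r, sch),
                 oracle_bloch_cycle(state, cs$flip, cs$phase, cs$f,
                                    0.01, 1, 0.5),
                 tolerance = 1e-12)
  }
})

test_that("steady state: trivial limits, route agreement, fixed point", {
  r <- resonance_set(0, 1, 2, t1_s = 1, t2_s = 0.5)
  expect_equal(Mod(ssfp_steady_state(r, ssfp_scheme(0, 0.01))), 0)
  # tp >> T1: full recovery each cycle, 90-degree pulse gives |M+| = 1
  expect_equal(Mod(ssfp_steady_state(r, ssfp_scheme(90, 60))), 1,
               tolerance = 1e-9)
  set.seed(3)
  for (i in 1:6) {
    rr <- resonance_set(stats::runif(1, -200, 200), 1, 2,
                        t1_s = stats::runif(1, 0.5, 3),
                        t2_s = stats::runif(1, 0.1, 0.5))
    sch <- ssfp_scheme(stats::runif(1, 10, 170), stats::runif(1, 0.005, 0.05))
    s_solve <- ssfp_steady_state(rr, sch, method = "solve")
    s_iter <- ssfp_steady_state(rr, sch, method = "iterate")
    expect_lt(Mod(s_solve - s_iter), 1e-9)
    # the pre-pulse fixed point reproduces itself under one more cycle
    m <- c(0, 0, 1)
    for (k in 1:5000) m <- bloch_cycle(m, rr, sch)
    expect_lt(max(abs(bloch_cycle(m, rr, sch) - m)), 1e-10)
  }
  # off-resonance spec example: 60 deg, tp 5 ms, T1 2 s, T2 0.8 s, 37 Hz
  rr <- resonance_set(37, 1, 1 / 0.8, t1_s = 2, t2_s = 0.8)
  sch <- ssfp_scheme(60, 0.005)
  expect_lt(Mod(ssfp_steady_state(rr, sch, "solve") -
                ssfp_steady_state(rr, sch, "iterate")), 1e-9)
})

test_that("on-resonance steady state matches the classical closed forms", {
  # constant-phase train: denominator 1 - (E1+E2)cos(a) + E1*E2;
  # phase-alternated train: the textbook 1 - (E1-E2)cos(a) - E1*E2 form
  for (flip in c(20, 45, 60, 90, 130)) {
    for (tp in c(0.005, 0.02, 0.1)) {
      r <- resonance_set(0, 1, 2, t1_s = 1, t2_s = 0.5)
      a <- flip * pi / 180
      E1 <- exp(-tp / 1)
      E2 <- exp(-tp / 0.5)
      s_const <- ssfp_steady_state(r, ssfp_scheme(flip, tp))
      expect_lt(abs(Mod(s_const) - oracle_ssfp_closed_const(a, E1, E2)),
                1e-9)
      s_alt <- ssfp_steady_state(r, ssfp_scheme(flip, tp,
                                                phase_alternate = TRUE))
      expect_lt(abs(Mod(s_alt) - oracle_ssfp_closed_alt(a, E1, E2)), 1e-9)
    }
  }
})

test_that("scan_budget floors the time/Tp quotient", {
  expect_identical(scan_budget(1, ssfp_scheme(60, 0.1)), 10L)
  # a 15-minute experiment at Tp = 15.7 ms
  expect_identical(scan_budget(900, ssfp_scheme(60, 0.0157)),
                   as.integer(floor(900 / 0.0157)))
  expect_identical(scan_budget(0.05, ssfp_scheme(60, 0.1)), 0L)
  expect_error(scan_budget(-1, ssfp_scheme(60, 0.1)))
})

test_that("ssfp acquisition: window guard, relaxed limit, scan invariance", {
  r <- resonance_set(25, 1, 2, 0.7, t1_s = 1, t2_s = 0.5)
  g <- acq_grid(1e-3, 128)
  sch <- ssfp_scheme(60, 0.2, acq_window_s = 0.1)
  expect_error(simulate_ssfp_acquisition(r, sch, g),
               "acquisition window")
  expect_error(simulate_ssfp_acquisition(resonance_set(25, 1, 2),
                                         ssfp_scheme(60, 0.2), g),
               "t1_s and t2_s")
  # tp >> T1 and flip 90: every scan starts from equilibrium, so the
  # record equals the conventional one (the post-pulse magnetization
  # lies along +y, a fixed 90-degree receiver phase)
  relaxed <- ssfp_scheme(90, 60, acq_window_s = 0.2, n_scans = 1)
  # tp >> t2 deliberately leaves the steady-state regime here
  fs <- suppressWarnings(simulate_ssfp_acquisition(r, relaxed, g))
  fc <- synthesize_fid(r, g)
  expect_equal(fs$samples, fc$samples * 1i, tolerance = 1e-9)
  # noiseless output is independent of the scan count
  sch2 <- ssfp_scheme(60, 0.2, n_scans = 1000)
  sch1 <- ssfp_scheme(60, 0.2, n_scans = 1)
  expect_equal(simulate_ssfp_acquisition(r, sch2, g)$samples,
               simulate_ssfp_acquisition(r, sch1, g)$samples)
  # steady-state regime violation warns
  expect_warning(simulate_ssfp_acquisition(
    resonance_set(25, 1, 2, t1_s = 0.3, t2_s = 0.1), ssfp_scheme(60, 0.2),
    g), "steady-state regime")
})

test_that("co-added SSFP noise follows the 1/sqrt(n) law", {
  r <- resonance_set(50, 1, 2, 0, t1_s = 1, t2_s = 0.5)
  g <- acq_grid(1e-3, 128)
  clean <- simulate_ssfp_acquisition(r, ssfp_scheme(60, 0.2), g)$samples
  s1 <- s100 <- numeric(50)
  for (i in 1:50) {
    f1 <- simulate_ssfp_acquisition(r, ssfp_scheme(60, 0.2, n_scans = 1),
                                    g, 1, seed = 300 + i)
    f2 <- simulate_ssfp_acquisition(r, ssfp_scheme(60, 0.2, n_scans = 100),
                                    g, 1, seed = 600 + i)
    s1[i] <- sd(Re(f1$samples - clean))
    s100[i] <- sd(Re(f2$samples - clean))
  }
  expect_equal(mean(s1) / mean(s100), 10, tolerance = 0.2)
})

test_that("mean spectral SNR is non-decreasing in the scan count", {
  r <- resonance_set(50, 1, 2, 0, t1_s = 1, t2_s = 0.5)
  g <- acq_grid(1e-3, 128)
  sig_win <- hz_to_ppm(g, c(40, 60))
  noi_win <- hz_to_ppm(g, c(-350, -150))
  mean_snr <- function(nsc) {
    mean(vapply(1:12, function(i) {
      fid <- simulate_ssfp_acquisition(r, ssfp_scheme(60, 0.2, n_scans = nsc),
                                       g, 1.5, seed = 5000 + i)
      measure_snr(fourier_spectrum(fid), sig_win, noi_win)
    }, numeric(1)))
  }
  curve <- vapply(c(1, 10, 100), mean_snr, numeric(1))
  expect_true(all(diff(curve) > 0))
})

test_that("ssfp_response reports the banding profile", {
  sch <- ssfp_scheme(60, 0.21)
  resp <- ssfp_response(c(0, 1 / 0.21, 0.5 / 0.21), sch, 0.3, 0.3)
  # periodic in 1/Tp; band extremes differ
  expect_equal(resp[1], resp[2], tolerance = 1e-9)
  expect_false(isTRUE(all.equal(resp[1], resp[3], tolerance = 1e-3)))
  expect_true(all(resp > 0 & resp <= 1))
})
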