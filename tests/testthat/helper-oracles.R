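# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the package's own vectorised code paths.

# direct per-sample summation of damped sinusoids (trigonometric form)
oracle_fid_samples <- function(res, dwell, n, t0 = 0) {
  out <- complex(real = rep(0, n), imaginary = 0)
  for (i in seq_len(n)) {
    t <- t0 + (i - 1) * dwell
    acc_re <- 0
    acc_im <- 0
    for (k in seq_len(nrow(res))) {
      env <- res$amplitude[k] * exp(-res$decay_rate[k] * t)
      ang <- res$phase_rad[k] + 2 * pi * res$frequency_hz[k] * t
      acc_re <- acc_re + env * cos(ang)
      acc_im <- acc_im + env * sin(ang)
    }
    out[i] <- complex(real = acc_re, imaginary = acc_im)
  }
  out
}

# closed-form infinite-record sampled spectrum (geometric series limit):
# X(f) = sum_k c_k / (1 - z_k exp(-2i pi f dt))
oracle_dtft_inf <- function(comp, dwell, freq_hz) {
  X <- complex(real = rep(0, length(freq_hz)), imaginary = 0)
  for (k in seq_len(nrow(comp))) {
    ck <- comp$amplitude[k] * exp(1i * comp$phase_rad[k])
    zk <- exp((-comp$decay_rate[k] + 2i * pi * comp$frequency_hz[k]) * dwell)
    X <- X + ck / (1 - zk * exp(-2i * pi * freq_hz * dwell))
  }
  X
}

# brute-force DFT of a record at arbitrary frequencies (no FFT)
oracle_dft <- function(samples, dwell, freq_hz, t0 = 0) {
  times <- t0 + (seq_along(samples) - 1) * dwell
  vapply(freq_hz, function(f)
    sum(samples * exp(-2i * pi * f * times)), complex(1))
}

# one SSFP cycle as an explicit 3x3 rotation/relaxation matrix product
oracle_bloch_cycle <- function(state, flip_deg, phase_deg, f_hz, tp, t1, t2) {
  a <- flip_deg * pi / 180
  psi <- phase_deg * pi / 180
  rz <- function(th) matrix(c(cos(th), sin(th), 0,
                              -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rx <- matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, 3)
  P <- rz(psi) %*% rx %*% rz(-psi)
  th <- 2 * pi * f_hz * tp
  E1 <- exp(-tp / t1)
  E2 <- exp(-tp / t2)
  m <- P %*% state
  m <- diag(c(E2, E2, E1)) %*% rz(th) %*% m + c(0, 0, 1 - E1)
  drop(m)
}

# Cramer-Rao standard deviations for one damped complex sinusoid in
# circular Gaussian noise (per-quadrature sd sigma); order (a, phi, f, lam)
oracle_crb <- function(a, phi, f, lam, dwell, n, sigma) {
  times <- (seq_len(n) - 1) * dwell
  e <- exp((-lam + 2i * pi * f) * times)
  u <- a * exp(1i * phi) * e
  J <- cbind(c(Re(e * exp(1i * phi)), Im(e * exp(1i * phi))),
             c(Re(1i * u), Im(1i * u)),
             c(Re(2i * pi * times * u), Im(2i * pi * times * u)),
             c(Re(-times * u), Im(-times * u)))
  sqrt(diag(solve(crossprod(J))) * sigma^2)
}

# closed-form on-resonance SSFP steady-state magnitudes
# (constant-phase train and phase-alternated train)
oracle_ssfp_closed_const <- function(alpha_rad, E1, E2) {
  sin(alpha_rad) * (1 - E1) /
    (1 - (E1 + E2) * cos(alpha_rad) + E1 * E2)
}
oracle_ssfp_closed_alt <- function(alpha_rad, E1, E2) {
  sin(alpha_rad) * (1 - E1) /
    (1 - (E1 - E2) * cos(alpha_rad) - E1 * E2)
}

# match fitted components to a truth set by frequency; returns the fit
# rows reordered to the truth rows (error if any truth row unmatched)
match_components <- function(fit_comp, truth, tol_hz) {
  idx <- vapply(truth$frequency_hz, function(f) {
    d <- abs(fit_comp$frequency_hz - f)
    i <- which.min(d)
    if (d[i] > tol_hz) NA_integer_ else i
  }, integer(1))
  stopifnot(!anyNA(idx))
  fit_comp[idx, , drop = FALSE]
}

# standard well-separated multi-component fixtures
fixture_six <- function() {
  resonance_set(c(-350, -180, -60, 90, 220, 380),
                c(1.2, 0.8, 2.0, 1.0, 1.5, 0.6),
                c(4, 6, 5, 3, 7, 5),
                c(0.4, -2.0, 1.1, 2.5, -0.7, 0.9))
}

fixture_twelve <- function() {
  resonance_set(
    frequency_hz = c(-460, -390, -310, -240, -170, -95, -30, 55, 130,
                     215, 300, 405),
    amplitude = c(1.2, 0.7, 2.1, 1.0, 0.5, 1.6, 0.9, 1.3, 0.6, 1.8,
                  1.1, 0.8),
    decay_rate = c(4, 6, 5, 3, 7, 5, 4.5, 6.5, 3.5, 5.5, 4.2, 6.1),
    phase_rad = c(0.4, -2.0, 1.1, 2.5, -0.7, 0.9, -1.4, 0.3, 2.1, -2.6,
                  1.7, -0.2))
}

empty_resonances <- function() {
  resonance_set(numeric(0), numeric(0), numeric(0))
}
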