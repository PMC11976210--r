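# Damped-sinusoid signal model: resonance sets, acquisition grids, FIDs.
#
# The time-domain model throughout the package is
#   s(t) = sum_k a_k * exp(i*phi_k) * exp((-lambda_k + i*2*pi*f_k) * t)
# with a_k >= 0 (amplitude), f_k the offset from the carrier in Hz,
# lambda_k > 0 the decay rate in 1/s (lambda = 1/T2*), phi_k the phase in
# radians.  Complex receiver noise is circular Gaussian, equal variance in
# both quadratures.

#' Wrap phases into \eqn{[-\pi, \pi)}
#'
#' @param phase_rad numeric vector of phases in radians.
#' @return numeric vector of the same length, wrapped into \eqn{[-\pi,\pi)}.
#' @export
wrap_phase <- function(phase_rad) {
  ((phase_rad + pi) %% (2 * pi)) - pi
}

#' Construct a set of resonances (damped sinusoids)
#'
#' A resonance is one exponentially damped sinusoid, described by the four
#' fundamental NMR parameters: frequency (offset from the carrier, Hz),
#' amplitude (arbitrary intensity units, proportional to spin count times
#' concentration), decay rate (\eqn{\lambda = 1/T_2^*}, 1/s) and phase
#' (radians).  Optional longitudinal/transverse relaxation times
#' \code{t1_s}/\code{t2_s} are required only by the SSFP physics engine,
#' and \code{n_fluorine} (equivalent 19F nuclei per molecule) only by the
#' quantification helpers.
#'
#' @param frequency_hz signed frequency offsets from the carrier, Hz.
#' @param amplitude nonnegative amplitudes.
#' @param decay_rate positive decay rates \eqn{\lambda} in 1/s; the
#'   noiseless envelope of each component is \code{exp(-decay_rate * t)}.
#'   The full width at half maximum of the corresponding Lorentzian line is
#'   \code{decay_rate / pi} Hz.
#' @param phase_rad phases in radians; normalised into \eqn{[-\pi,\pi)}.
#' @param t1_s optional longitudinal relaxation times, s.
#' @param t2_s optional transverse relaxation times, s (requires
#'   \code{t1_s >= t2_s > 0} where both are given).
#' @param n_fluorine optional positive integer counts of equivalent
#'   fluorine nuclei.
#' @param label optional character labels.
#' @return a \code{data.frame} of class \code{"resonance_set"} with one row
#'   per resonance.
#' @examples
#' resonance_set(frequency_hz = c(-100, 100), amplitude = 1, decay_rate = 2)
#' @export
resonance_set <- function(frequency_hz, amplitude, decay_rate, phase_rad = 0,
                          t1_s = NA_real_, t2_s = NA_real_,
                          n_fluorine = NA_real_, label = NA_character_) {
  n <- max(length(frequency_hz), length(amplitude), length(decay_rate))
  res <- data.frame(
    frequency_hz = rep_len(as.numeric(frequency_hz), n),
    amplitude    = rep_len(as.numeric(amplitude), n),
    decay_rate   = rep_len(as.numeric(decay_rate), n),
    phase_rad    = wrap_phase(rep_len(as.numeric(phase_rad), n)),
    t1_s         = rep_len(as.numeric(t1_s), n),
    t2_s         = rep_len(as.numeric(t2_s), n),
    n_fluorine   = rep_len(as.numeric(n_fluorine), n),
    label        = rep_len(as.character(label), n),
    stringsAsFactors = FALSE
  )
  validate_resonance_set(res)
  class(res) <- c("resonance_set", "data.frame")
  res
}

validate_resonance_set <- function(res) {
  stopifnot(is.data.frame(res))
  if (nrow(res) == 0L) return(invisible(res))
  if (any(!is.finite(res$frequency_hz)))
    stop("resonance frequencies must be finite")
  if (any(res$amplitude < 0))
    stop("resonance amplitudes must be nonnegative")
  if (any(res$decay_rate <= 0))
    stop("resonance decay rates must be positive")
  both <- !is.na(res$t1_s) & !is.na(res$t2_s)
  if (any(both & (res$t2_s <= 0 | res$t1_s < res$t2_s)))
    stop("relaxation times must satisfy t1_s >= t2_s > 0")
  invisible(res)
}

#' Define a uniform acquisition grid
#'
#' Bookkeeping for a uniformly sampled complex FID: sample spacing (dwell
#' time), number of points, observe frequency and carrier position.  The
#' acquisition time is \code{dwell_s * n_points} and the spectral width is
#' \code{1/dwell_s}.  The package-wide sign convention maps positive
#' frequency offsets to higher (less negative) ppm:
#' \code{ppm = carrier_ppm + f_hz / spectrometer_mhz}, with chemical shifts
#' referenced so the usual 19F PFAS region is negative (CFCl3 = 0 ppm).
#'
#' @param dwell_s sample spacing in seconds (> 0).
#' @param n_points number of complex points (positive integer).
#' @param spectrometer_mhz observe frequency in MHz; the default 470.4 is
#'   the 19F frequency at 11.7 T.
#' @param carrier_ppm chemical shift of the carrier (transmitter) in ppm.
#' @return an object of class \code{"acq_grid"}.
#' @examples
#' g <- acq_grid(dwell_s = 1e-3, n_points = 512)
#' spectral_width(g)
#' @export
acq_grid <- function(dwell_s, n_points, spectrometer_mhz = 470.4,
                     carrier_ppm = -110) {
  stopifnot(is.numeric(dwell_s), length(dwell_s) == 1L, dwell_s > 0,
            is.numeric(n_points), length(n_points) == 1L, n_points >= 1,
            n_points == round(n_points),
            is.numeric(spectrometer_mhz), spectrometer_mhz > 0,
            is.numeric(carrier_ppm), length(carrier_ppm) == 1L)
  structure(list(dwell_s = dwell_s, n_points = as.integer(n_points),
                 spectrometer_mhz = spectrometer_mhz,
                 carrier_ppm = carrier_ppm),
            class = "acq_grid")
}

#' @rdname acq_grid
#' @param grid an \code{acq_grid}.
#' @export
spectral_width <- function(grid) 1 / grid$dwell_s

#' @rdname acq_grid
#' @export
acq_time <- function(grid) grid$dwell_s * grid$n_points

#' Convert between frequency offsets (Hz) and chemical shift (ppm)
#'
#' @param grid an \code{acq_grid} carrying the observe frequency and
#'   carrier position.
#' @param f_hz,ppm values to convert.
#' @return numeric vector of converted values.
#' @export
hz_to_ppm <- function(grid, f_hz) grid$carrier_ppm + f_hz / grid$spectrometer_mhz

#' @rdname hz_to_ppm
#' @export
ppm_to_hz <- function(grid, ppm) (ppm - grid$carrier_ppm) * grid$spectrometer_mhz

#' @export
print.acq_grid <- function(x, ...) {
  cat(sprintf("Acquisition grid: %d points, dwell %.6g s (SW %.6g Hz)\n",
              x$n_points, x$dwell_s, 1 / x$dwell_s))
  cat(sprintf("  acquisition time %.6g s; observe %.4f MHz, carrier %.4g ppm\n",
              x$dwell_s * x$n_points, x$spectrometer_mhz, x$carrier_ppm))
  invisible(x)
}

# internal constructor; t0_s is the absolute time of the first sample
# (nonzero only for sub-band decimated records, where the settling region
# of the linear-phase filter has been discarded)
new_fid <- function(samples, grid, n_scans = 1L,
                    provenance = "conventional", t0_s = 0) {
  stopifnot(length(samples) == grid$n_points, all(is.finite(Re(samples))),
            all(is.finite(Im(samples))), n_scans >= 1)
  structure(list(samples = as.complex(samples), grid = grid,
                 n_scans = as.integer(n_scans), provenance = provenance,
                 t0_s = t0_s),
            class = "nmr_fid")
}

#' Sample times of an FID
#'
#' @param fid an \code{nmr_fid}.
#' @return numeric vector of absolute sample times in seconds.
#' @export
fid_times <- function(fid) {
  fid$t0_s + (seq_len(fid$grid$n_points) - 1) * fid$grid$dwell_s
}

# noiseless model evaluation at arbitrary times (vectorised over components)
eval_model <- function(res, times) {
  s <- complex(real = rep(0, length(times)), imaginary = 0)
  for (k in seq_len(nrow(res))) {
    s <- s + res$amplitude[k] * exp(1i * res$phase_rad[k]) *
      exp((-res$decay_rate[k] + 2i * pi * res$frequency_hz[k]) * times)
  }
  s
}

# circular complex Gaussian noise, per-quadrature standard deviation sigma
complex_noise <- function(n, sigma) {
  complex(real = stats::rnorm(n, sd = sigma),
          imaginary = stats::rnorm(n, sd = sigma))
}

#' Synthesize a conventional FID from a resonance set
#'
#' Evaluates the sum of damped sinusoids on the acquisition grid and adds
#' circular complex Gaussian noise (independent real/imaginary components,
#' each with standard deviation \code{noise_sigma}).  When
#' \code{n_scans > 1} the returned record is the scan \emph{mean} of
#' \code{n_scans} co-added transients: the signal is unchanged and the
#' effective noise standard deviation is \code{noise_sigma / sqrt(n_scans)}
#' (the per-scan noise draws are independent, so the mean is generated
#' directly at the reduced standard deviation).
#'
#' @param resonances a \code{resonance_set} (may have zero rows).
#' @param grid an \code{acq_grid}.
#' @param noise_sigma per-scan, per-quadrature noise standard deviation
#'   (>= 0).
#' @param seed optional integer seed; identical inputs and seed give
#'   bit-identical output.
#' @param n_scans number of co-added transients (mean convention).
#' @return an \code{nmr_fid} with provenance \code{"conventional"}.
#' @examples
#' r <- resonance_set(0, 1, 1)
#' f <- synthesize_fid(r, acq_grid(1e-3, 1024))
#' Mod(f$samples[1])   # 1: amplitude at t = 0
#' @export
synthesize_fid <- function(resonances, grid, noise_sigma = 0, seed = NULL,
                           n_scans = 1L) {
  stopifnot(inherits(grid, "acq_grid"))
  if (!is.numeric(noise_sigma) || length(noise_sigma) != 1L ||
      noise_sigma < 0)
    stop("noise_sigma must be a single nonnegative number")
  validate_resonance_set(resonances)
  times <- (seq_len(grid$n_points) - 1) * grid$dwell_s
  s <- eval_model(resonances, times)
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    s <- s + complex_noise(grid$n_points, noise_sigma / sqrt(n_scans))
  }
  new_fid(s, grid, n_scans = n_scans, provenance = "conventional")
}

#' Truncate an FID to its first points
#'
#' Keeps the first \code{n_keep} samples unchanged and updates the grid;
#' the dwell time is untouched.  This models the severe truncation of an
#' SSFP record relative to a full conventional acquisition.
#'
#' @param fid an \code{nmr_fid}.
#' @param n_keep number of samples to keep (1..n_points).
#' @return an \code{nmr_fid} of length \code{n_keep}.
#' @export
truncate_fid <- function(fid, n_keep) {
  stopifnot(inherits(fid, "nmr_fid"))
  if (!is.numeric(n_keep) || length(n_keep) != 1L ||
      n_keep != round(n_keep) || n_keep < 1 || n_keep > fid$grid$n_points)
    stop("n_keep must be an integer in [1, n_points]")
  g <- fid$grid
  g$n_points <- as.integer(n_keep)
  new_fid(fid$samples[seq_len(n_keep)], g, n_scans = fid$n_scans,
          provenance = fid$provenance, t0_s = fid$t0_s)
}

#' @export
print.nmr_fid <- function(x, ...) {
  cat(sprintf("<nmr_fid> %d complex points, dwell %.6g s, %d scan(s), provenance '%s'\n",
              x$grid$n_points, x$grid$dwell_s, x$n_scans, x$provenance))
  cat(sprintf("  acquisition window %.6g s, SW %.6g Hz, observe %.4f MHz\n",
              acq_time(x$grid), spectral_width(x$grid), x$grid$spectrometer_mhz))
  invisible(x)
}

#' @export
plot.nmr_fid <- function(x, ...) {
  t <- fid_times(x)
  graphics::plot(t, Re(x$samples), type = "l", xlab = "time (s)",
                 ylab = "intensity", ...)
  graphics::lines(t, Im(x$samples), col = "grey60")
  graphics::legend("topright", legend = c("real", "imag"), lty = 1,
                   col = c("black", "grey60"), bty = "n")
  invisible(x)
}
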