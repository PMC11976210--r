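# Conventional Fourier processing and spectrum metrics: SNR, peak
# counting, linewidths, limit-of-detection studies, spike-recovery
# quantification.
#
# DFT convention: X_k = sum_n x_n exp(-2*pi*i*n*k/N) (R's fft), so
# Parseval reads sum |x_n|^2 = (1/N) sum |X_k|^2.

new_spectrum <- function(freq_hz, intensities, grid, provenance,
                         scale = 1) {
  stopifnot(length(freq_hz) == length(intensities),
            all(diff(freq_hz) > 0))
  structure(list(freq_hz = freq_hz, ppm = hz_to_ppm(grid, freq_hz),
                 intensities = as.complex(intensities), grid = grid,
                 provenance = provenance, scale = scale),
            class = "nmr_spectrum")
}

#' Fourier spectrum of an FID
#'
#' Applies optional exponential apodization (line broadening
#' \code{apodization_hz} in Hz: multiplication by
#' \code{exp(-pi * lb * t)}), zero fills to
#' \code{zero_fill_factor * n_points}, discrete-Fourier-transforms, and
#' corrects the phase.  The frequency axis is in Hz relative to the
#' carrier (ascending), with a derived ppm axis.  Phase correction is
#' zeroth-order only: the constant phase that makes the real part of the
#' tallest magnitude peak maximal (first-order correction is not needed
#' for synthetic, delay-free data; records with nonzero \code{t0_s} are
#' first re-referenced to t = 0 by the corresponding linear phase).
#'
#' @param fid an \code{nmr_fid}.
#' @param zero_fill_factor integer >= 1.
#' @param apodization_hz exponential line broadening in Hz (>= 0).
#' @param phase_correct apply the zeroth-order phase correction
#'   (default TRUE).
#' @return an object of class \code{"nmr_spectrum"} with fields
#'   \code{freq_hz}, \code{ppm}, \code{intensities} (complex),
#'   \code{provenance}, \code{scale}.
#' @export
fourier_spectrum <- function(fid, zero_fill_factor = 1L,
                             apodization_hz = 0, phase_correct = TRUE) {
  stopifnot(inherits(fid, "nmr_fid"), zero_fill_factor >= 1,
            zero_fill_factor == round(zero_fill_factor),
            apodization_hz >= 0)
  n <- fid$grid$n_points
  dt <- fid$grid$dwell_s
  t_rel <- (seq_len(n) - 1) * dt
  y <- fid$samples
  if (apodization_hz > 0) y <- y * exp(-pi * apodization_hz * t_rel)
  nz <- n * as.integer(zero_fill_factor)
  if (nz > n) y <- c(y, complex(real = rep(0, nz - n), imaginary = 0))
  X <- stats::fft(y)
  sw <- 1 / dt
  f <- (seq_len(nz) - 1) / (nz * dt)
  f[f >= sw / 2] <- f[f >= sw / 2] - sw
  ord <- order(f)
  f <- f[ord]
  X <- X[ord]
  if (fid$t0_s != 0)                        # re-reference to t = 0
    X <- X * exp(2i * pi * f * fid$t0_s)
  phase0 <- 0
  if (phase_correct && any(Mod(X) > 0)) {
    peak <- which.max(Mod(X))
    phase0 <- -Arg(X[peak])
    X <- X * exp(1i * phase0)
  }
  sp <- new_spectrum(f, X, fid$grid, provenance = switch(
    fid$provenance, ssfp = "ft_ssfp", craft_resimulated = "craft",
    "ft_conventional"))
  sp$phase0_rad <- phase0
  sp
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %d points, %.5g..%.5g ppm, provenance '%s', scale %g\n",
              length(x$freq_hz), min(x$ppm), max(x$ppm), x$provenance,
              x$scale))
  invisible(x)
}

#' @export
plot.nmr_spectrum <- function(x, ...) {
  graphics::plot(x$ppm, Re(x$intensities), type = "l",
                 xlim = rev(range(x$ppm)), xlab = "ppm",
                 ylab = "intensity", ...)
  invisible(x)
}

window_idx <- function(spectrum, window_ppm) {
  stopifnot(is.numeric(window_ppm), length(window_ppm) == 2L)
  lo <- min(window_ppm); hi <- max(window_ppm)
  idx <- which(spectrum$ppm >= lo & spectrum$ppm <= hi)
  if (length(idx) == 0L)
    stop("window [", lo, ", ", hi, "] ppm contains no spectrum points")
  idx
}

#' Signal-to-noise ratio of a spectrum
#'
#' SNR = (maximum real intensity in the signal window) / (noise height),
#' with the noise height fixed by convention at twice the standard
#' deviation of the real intensities in the noise window.  A 3:1 SNR is
#' the conventional limit of detection.  When the noise window is exactly
#' flat (zero standard deviation, e.g. a reconstructed noiseless
#' spectrum) the sentinel \code{Inf} is returned if the signal height is
#' positive, else 0.
#'
#' @param spectrum an \code{nmr_spectrum}.
#' @param signal_window_ppm,noise_window_ppm disjoint length-2 ppm
#'   intervals inside the axis range.
#' @return a nonnegative number (possibly \code{Inf}).
#' @export
measure_snr <- function(spectrum, signal_window_ppm, noise_window_ppm) {
  si <- window_idx(spectrum, signal_window_ppm)
  ni <- window_idx(spectrum, noise_window_ppm)
  if (max(min(signal_window_ppm), min(noise_window_ppm)) <
      min(max(signal_window_ppm), max(noise_window_ppm)))
    stop("signal and noise windows must be disjoint")
  sig <- max(Re(spectrum$intensities[si]))
  noise_height <- 2 * stats::sd(Re(spectrum$intensities[ni]))
  if (!is.finite(noise_height) || noise_height == 0)
    return(if (sig > 0) Inf else 0)
  sig / noise_height
}

#' Count detectable peaks
#'
#' For a fitted table (a \code{craft} object or components data.frame):
#' the number of retained components with amplitude above the threshold.
#' For a spectrum: the number of local maxima of the real part exceeding
#' the threshold, subject to a minimum-separation rule — within any group
#' of maxima closer than \code{min_separation_hz} only the tallest is
#' counted (default separation: 3 frequency bins).
#'
#' @param x a \code{craft} fit, components \code{data.frame}, or
#'   \code{nmr_spectrum}.
#' @param threshold nonnegative intensity/amplitude threshold.
#' @param min_separation_hz minimum peak separation for spectra.
#' @return an integer count.
#' @export
count_peaks <- function(x, threshold, min_separation_hz = NULL) {
  stopifnot(threshold >= 0)
  if (inherits(x, "craft")) x <- x$components
  if (is.data.frame(x))
    return(sum(x$amplitude > threshold))
  stopifnot(inherits(x, "nmr_spectrum"))
  y <- Re(x$intensities)
  n <- length(y)
  if (n < 3) return(0L)
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] &
                y[2:(n - 1)] >= y[3:n]) + 1L
  cand <- cand[y[cand] > threshold]
  if (length(cand) <= 1L) return(length(cand))
  df <- x$freq_hz[2] - x$freq_hz[1]
  min_sep <- if (is.null(min_separation_hz)) 3 * df else
    max(min_separation_hz, df)
  # greedy by height: suppress smaller maxima within min_sep of a kept one
  cand <- cand[order(y[cand], decreasing = TRUE)]
  kept <- numeric(0)
  for (i in cand) {
    fi <- x$freq_hz[i]
    if (all(abs(kept - fi) >= min_sep)) kept <- c(kept, fi)
  }
  length(kept)
}

#' Full width at half maximum of a spectral peak
#'
#' Locates the maximum of the real part nearest \code{at_hz} (or the
#' global maximum) and measures the width at half that height by linear
#' interpolation of the two crossings.
#'
#' @param spectrum an \code{nmr_spectrum}.
#' @param at_hz optional frequency near the peak of interest.
#' @param search_hz half-width of the search window around \code{at_hz}.
#' @return the FWHM in Hz.
#' @export
peak_fwhm <- function(spectrum, at_hz = NULL, search_hz = NULL) {
  y <- Re(spectrum$intensities)
  f <- spectrum$freq_hz
  if (is.null(at_hz)) {
    ipk <- which.max(y)
  } else {
    sel <- if (is.null(search_hz)) seq_along(f) else
      which(abs(f - at_hz) <= search_hz)
    if (length(sel) == 0L) stop("empty search window")
    ipk <- sel[which.max(y[sel])]
  }
  half <- y[ipk] / 2
  if (y[ipk] <= 0) stop("peak height is not positive")
  il <- ipk
  while (il > 1L && y[il] > half) il <- il - 1L
  ir <- ipk
  while (ir < length(y) && y[ir] > half) ir <- ir + 1L
  if (y[il] > half || y[ir] > half)
    stop("half-height crossing outside the spectrum")
  xl <- f[il] + (half - y[il]) / (y[il + 1L] - y[il]) * (f[il + 1L] - f[il])
  xr <- f[ir - 1L] + (half - y[ir - 1L]) / (y[ir] - y[ir - 1L]) *
    (f[ir] - f[ir - 1L])
  xr - xl
}

# acquisition scheme wrappers for LOD studies -------------------------------

#' Conventional (single-pulse) acquisition scheme
#'
#' @param recycle_s recycle time per scan in seconds (> 0); the number of
#'   scans in a study of total time T is \code{floor(T / recycle_s)}.
#' @param label text label.
#' @return an object of class \code{"conventional_scheme"}.
#' @export
conventional_scheme <- function(recycle_s, label = "conventional") {
  stopifnot(is.numeric(recycle_s), recycle_s > 0)
  structure(list(recycle_s = recycle_s, label = label),
            class = "conventional_scheme")
}

#' Bundle an acquisition scheme with a grid and a processing path
#'
#' @param acquisition a \code{\link{conventional_scheme}} or
#'   \code{\link{ssfp_scheme}}.
#' @param grid the \code{acq_grid} this scheme acquires on (for SSFP it
#'   must fit the acquisition window).
#' @param processing \code{"ft"} (Fourier transform) or \code{"craft"}
#'   (time-domain decomposition, then clean reconstruction).
#' @param label text label for reports.
#' @return an object of class \code{"lod_scheme"}.
#' @export
lod_scheme <- function(acquisition, grid, processing = c("ft", "craft"),
                       label = NULL) {
  processing <- match.arg(processing)
  stopifnot(inherits(acquisition, c("conventional_scheme", "ssfp_scheme")),
            inherits(grid, "acq_grid"))
  if (is.null(label))
    label <- paste0(if (inherits(acquisition, "ssfp_scheme")) "ssfp"
                    else "conventional", "+", processing)
  structure(list(acquisition = acquisition, grid = grid,
                 processing = processing, label = label),
            class = "lod_scheme")
}

#' Monte-Carlo limit-of-detection study
#'
#' For each scheme and each trial amplitude (a proxy for concentration),
#' simulates the full acquisition for the shared total experiment time,
#' processes it along the scheme's path (FT for conventional and SSFP;
#' decomposition plus clean reconstruction for SSFP+CRAFT), measures the
#' spectral SNR, and averages over seeds.  The limit of detection is the
#' smallest grid amplitude whose mean SNR reaches 3 (the conventional 3:1
#' detection condition); when the curve never reaches 3 the LOD is
#' \code{NA} and flagged.  For the CRAFT path the reconstructed spectrum
#' is noiseless, so the SNR is the \code{Inf} sentinel whenever the
#' analyte is recovered by the decomposition and 0 otherwise; the LOD is
#' then the smallest amplitude at which the analyte is recovered.
#'
#' @param resonance_template single-row \code{resonance_set}; its
#'   amplitude is replaced by each grid value in turn.
#' @param schemes a list of \code{\link{lod_scheme}} objects.
#' @param amplitude_grid increasing positive amplitudes to try.
#' @param total_time_s shared total experiment time, s.
#' @param noise_sigma per-scan, per-quadrature noise standard deviation.
#' @param n_seeds Monte-Carlo replicates per amplitude.
#' @param signal_window_ppm,noise_window_ppm SNR windows; defaults are
#'   derived from the template frequency (a narrow window around the
#'   analyte, and a noise window on the opposite side of the carrier).
#' @param craft_cfg decomposer configuration for CRAFT paths.
#' @param seed base seed; replicate r at amplitude index a uses
#'   \code{seed + 1000 * a + r} for every scheme, so schemes see matched
#'   noise ensembles.
#' @return an object of class \code{"lod_study"}: a list of per-scheme
#'   results, each with \code{concentration_grid}, \code{snr_curve},
#'   \code{lod_amplitude} and \code{scheme_label}.  See
#'   \code{\link{fold_improvement}}.
#' @export
lod_study <- function(resonance_template, schemes, amplitude_grid,
                      total_time_s, noise_sigma, n_seeds = 10,
                      signal_window_ppm = NULL, noise_window_ppm = NULL,
                      craft_cfg = craft_config(), seed = 1) {
  resonance_template <- as.data.frame(resonance_template)
  stopifnot(nrow(resonance_template) == 1L, length(amplitude_grid) > 0,
            all(diff(amplitude_grid) > 0), length(schemes) > 0)
  results <- lapply(schemes, function(sch) {
    stopifnot(inherits(sch, "lod_scheme"))
    g <- sch$grid
    f0 <- resonance_template$frequency_hz
    sw <- spectral_width(g)
    if (is.null(signal_window_ppm)) {
      half <- max(20, 8 * resonance_template$decay_rate / pi,
                  4 / acq_time(g))
      sig_win <- hz_to_ppm(g, f0 + c(-half, half))
    } else sig_win <- signal_window_ppm
    if (is.null(noise_window_ppm)) {
      nc <- if (abs(f0) > sw / 8) -f0 else f0 + sw / 4
      nc <- max(min(nc, sw * 0.375), -sw * 0.375)
      noi_win <- hz_to_ppm(g, nc + c(-sw / 16, sw / 16))
    } else noi_win <- noise_window_ppm
    snr_curve <- vapply(seq_along(amplitude_grid), function(ai) {
      a <- amplitude_grid[ai]
      res <- resonance_template
      res$amplitude <- a
      class(res) <- c("resonance_set", "data.frame")
      snrs <- vapply(seq_len(n_seeds), function(r) {
        sd_i <- seed + 1000L * ai + r
        if (inherits(sch$acquisition, "ssfp_scheme")) {
          sc <- sch$acquisition
          sc$n_scans <- max(1L, scan_budget(total_time_s, sc))
          fid <- simulate_ssfp_acquisition(res, sc, g, noise_sigma,
                                           seed = sd_i)
        } else {
          ns <- max(1L, floor(total_time_s / sch$acquisition$recycle_s))
          fid <- synthesize_fid(res, g, noise_sigma, seed = sd_i,
                                n_scans = ns)
        }
        if (sch$processing == "ft") {
          measure_snr(fourier_spectrum(fid), sig_win, noi_win)
        } else {
          fit <- craft(fid, craft_cfg)
          if (nrow(fit$components) == 0L) return(0)
          measure_snr(craft_spectrum(fit), sig_win, noi_win)
        }
      }, numeric(1))
      mean(snrs)
    }, numeric(1))
    crossing <- which(snr_curve >= 3)
    lod <- if (length(crossing) == 0L) NA_real_ else
      amplitude_grid[min(crossing)]
    list(concentration_grid = amplitude_grid, snr_curve = snr_curve,
         lod_amplitude = lod, scheme_label = sch$label)
  })
  names(results) <- vapply(results, `[[`, character(1), "scheme_label")
  structure(results, class = "lod_study")
}

#' @export
print.lod_study <- function(x, ...) {
  for (r in x)
    cat(sprintf("  %-24s LOD amplitude: %s\n", r$scheme_label,
                if (is.na(r$lod_amplitude)) "not reached (curve < 3)"
                else format(r$lod_amplitude, digits = 4)))
  invisible(x)
}

#' Detection-limit fold improvement between two schemes
#'
#' @param study an object from \code{\link{lod_study}}.
#' @param a,b scheme labels or indices; the return value is
#'   \code{lod(a) / lod(b)} — how many times lower scheme b's detection
#'   limit is than scheme a's.
#' @return a positive number (NA if either LOD is undefined).
#' @export
fold_improvement <- function(study, a, b) {
  stopifnot(inherits(study, "lod_study"))
  la <- study[[a]]$lod_amplitude
  lb <- study[[b]]$lod_amplitude
  if (is.na(la) || is.na(lb)) return(NA_real_)
  la / lb
}

#' Internal-standard spike-recovery quantification
#'
#' Converts fitted amplitudes to amounts via an internal standard of
#' known amount, normalising per equivalent fluorine:
#' \deqn{\mathrm{amount}_i = \frac{A_i}{A_{IS}} \cdot
#'       \frac{nF_{IS}}{nF_i} \cdot \mathrm{amount}_{IS},}
#' and reports \code{100 * amount / spiked_amount} per compound.
#'
#' @param measured a \code{craft} fit or components \code{data.frame}
#'   (needs \code{frequency_hz} and \code{amplitude}).
#' @param truth a \code{data.frame} with columns \code{label},
#'   \code{frequency_hz}, \code{spiked_amount}, \code{n_fluorine}.
#' @param internal_standard a one-row list/data.frame with
#'   \code{frequency_hz}, \code{amount}, \code{n_fluorine}.
#' @param match_tol_hz frequency tolerance for matching fitted components
#'   to compounds (default: 4 times the source record's Rayleigh limit
#'   for a \code{craft} fit, else required).
#' @param response optional acquisition response function
#'   \code{function(frequency_hz) -> factor}: fitted amplitudes are
#'   divided by it before ratioing.  For SSFP data acquired with uniform
#'   relaxation times (relaxation agent) this is
#'   \code{\link{ssfp_response}}, which divides out the offset-dependent
#'   steady-state banding; conventional data need no correction.
#' @return a \code{data.frame} with one row per truth compound:
#'   \code{label}, \code{spiked_amount}, \code{measured_amount},
#'   \code{recovery_pct} (NA when the compound was not recovered).
#' @export
percent_recovery <- function(measured, truth, internal_standard,
                             match_tol_hz = NULL, response = NULL) {
  if (inherits(measured, "craft")) {
    if (is.null(match_tol_hz))
      match_tol_hz <- 4 / acq_time(measured$source_grid)
    measured <- measured$components
  }
  measured <- as.data.frame(measured)
  if (is.null(match_tol_hz))
    stop("match_tol_hz is required when 'measured' is a plain table")
  isd <- as.data.frame(internal_standard)
  stopifnot(nrow(isd) == 1L,
            all(c("frequency_hz", "amount", "n_fluorine") %in% names(isd)),
            all(c("label", "frequency_hz", "spiked_amount", "n_fluorine")
                %in% names(truth)))
  match_amp <- function(f0) {
    if (nrow(measured) == 0L) return(NA_real_)
    d <- abs(measured$frequency_hz - f0)
    hit <- which(d <= match_tol_hz)
    if (length(hit) == 0L) return(NA_real_)
    # several fitted components within tolerance are one split signal
    a <- sum(measured$amplitude[hit])
    if (!is.null(response)) a <- a / response(f0)
    a
  }
  a_is <- match_amp(isd$frequency_hz)
  if (is.na(a_is))
    stop("internal standard not found in the measured table within ",
         signif(match_tol_hz, 4), " Hz")
  amounts <- vapply(seq_len(nrow(truth)), function(i) {
    a_i <- match_amp(truth$frequency_hz[i])
    (a_i / a_is) * (isd$n_fluorine / truth$n_fluorine[i]) * isd$amount
  }, numeric(1))
  data.frame(label = truth$label, spiked_amount = truth$spiked_amount,
             measured_amount = amounts,
             recovery_pct = 100 * amounts / truth$spiked_amount,
             stringsAsFactors = FALSE)
}
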