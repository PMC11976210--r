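# S3 methods for fitted "craft" objects.

#' @export
print.craft <- function(x, ...) {
  k <- nrow(x$components)
  cat(sprintf("CRAFT decomposition: %d component(s) from a %d-point FID\n",
              k, x$source_grid$n_points))
  cat(sprintf("  residual rms %.4g (per quadrature), noise level %.4g\n",
              x$residual_rms, x$noise_sigma_hat))
  if (k > 0) {
    show <- x$components[, c("ppm", "frequency_hz", "amplitude",
                             "fwhm_hz", "phase_rad")]
    print(format(show, digits = 5), row.names = FALSE)
  }
  invisible(x)
}

#' Summarise a CRAFT fit
#'
#' @param object a \code{craft} fit.
#' @param ... unused.
#' @return an object of class \code{"summary.craft"}.
#' @export
summary.craft <- function(object, ...) {
  structure(list(components = object$components,
                 residual_rms = object$residual_rms,
                 noise_sigma_hat = object$noise_sigma_hat,
                 n_points = object$source_grid$n_points,
                 acq_time = acq_time(object$source_grid),
                 order_trace = object$model_order_trace),
            class = "summary.craft")
}

#' @export
print.summary.craft <- function(x, ...) {
  cat(sprintf("CRAFT decomposition of a %d-point record (%.4g s)\n",
              x$n_points, x$acq_time))
  cat(sprintf("  %d retained component(s); residual rms %.4g; noise %.4g\n",
              nrow(x$components), x$residual_rms, x$noise_sigma_hat))
  if (nrow(x$components) > 0) print(format(x$components, digits = 5),
                                    row.names = FALSE)
  disc <- x$order_trace$discarded
  if (!is.null(disc) && nrow(disc) > 0)
    cat(sprintf("  %d candidate(s) discarded by the detection rule\n",
                nrow(disc)))
  invisible(x)
}

#' Extract the amplitude-frequency table of a CRAFT fit
#'
#' @param object a \code{craft} fit.
#' @param ... unused.
#' @return the components \code{data.frame} (frequency, ppm, amplitude,
#'   decay rate, FWHM, phase, standard errors, band id).
#' @export
coef.craft <- function(object, ...) object$components

#' @export
fitted.craft <- function(object, ...) {
  if (nrow(object$components) == 0L)
    return(complex(real = rep(0, object$source_grid$n_points),
                   imaginary = 0))
  res <- resonance_set(object$components$frequency_hz,
                       object$components$amplitude,
                       object$components$decay_rate,
                       object$components$phase_rad)
  eval_model(res, fid_times(object$fid))
}

#' @export
residuals.craft <- function(object, ...) {
  object$fid$samples - fitted(object)
}

#' Resynthesize an FID from a CRAFT fit
#'
#' \code{predict} on a new acquisition grid is noiseless resynthesis of
#' the fitted components; see \code{\link{simulate_from_table}}.
#'
#' @param object a \code{craft} fit.
#' @param grid_out optional output \code{acq_grid}; default auto-sizes to
#'   \code{resim_length_factor} decay constants.
#' @param length_factor overrides the auto-sizing factor.
#' @param ... unused.
#' @return an \code{nmr_fid}.
#' @export
predict.craft <- function(object, grid_out = NULL, length_factor = NULL,
                          ...) {
  simulate_from_table(object, grid_out, length_factor)
}

#' Simulate noisy replicate FIDs from a CRAFT fit
#'
#' Draws replicates of the source record: fitted model on the source grid
#' plus circular Gaussian noise at the estimated noise level.
#'
#' @param object a \code{craft} fit.
#' @param nsim number of replicates.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a list of \code{nmr_fid} objects.
#' @export
simulate.craft <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  base <- fitted(object)
  g <- object$source_grid
  lapply(seq_len(nsim), function(i)
    new_fid(base + complex_noise(g$n_points, object$noise_sigma_hat), g,
            provenance = "craft_resimulated"))
}

#' Plot a CRAFT fit
#'
#' Overlays the clean reconstructed spectrum on the Fourier transform of
#' the input record (ppm axis, decreasing to the right as is conventional
#' for NMR).
#'
#' @param x a \code{craft} fit.
#' @param vertical_scale intensity scale for the reconstruction.
#' @param ... passed to \code{plot}.
#' @export
plot.craft <- function(x, vertical_scale = 1, ...) {
  ft <- fourier_spectrum(x$fid)
  graphics::plot(ft$ppm, Re(ft$intensities), type = "l", col = "grey60",
                 xlim = rev(range(ft$ppm)), xlab = "ppm",
                 ylab = "intensity", ...)
  if (nrow(x$components) > 0) {
    cs <- craft_spectrum(x, vertical_scale = vertical_scale)
    graphics::lines(cs$ppm, Re(cs$intensities), col = "black")
  }
  graphics::legend("topright", legend = c("FT of input", "reconstruction"),
                   col = c("grey60", "black"), lty = 1, bty = "n")
  invisible(x)
}
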