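# Steady-state free precession (SSFP) engine.
#
# A pulse train with inter-pulse time Tp much shorter than T2 drives the
# magnetization into a steady state that is sampled between every pair of
# pulses, so thousands of transients fit in the time of one conventional
# scan.  One cycle of the train is modelled as an affine map on the Bloch
# vector m = (mx, my, mz):
#   pulse:       m -> P m        (rotation by the flip angle about an axis
#                                 in the transverse plane set by the pulse
#                                 phase)
#   precession + relaxation over Tp:
#                m -> D F m + b  (F: rotation about z by 2*pi*f*Tp;
#                                 D = diag(E2, E2, E1), b = (0, 0, 1-E1);
#                                 E1 = exp(-Tp/T1), E2 = exp(-Tp/T2))
# The steady state is the fixed point of the composite map, obtained
# either by solving the 3x3 linear system exactly or by iterating the
# cycle; both routes are exposed and must agree.

#' Define an SSFP pulse-train scheme
#'
#' @param flip_deg RF flip angle in degrees (0..180).
#' @param tp_s inter-pulse interval \eqn{T_p} in seconds (> 0).  The
#'   steady-state regime requires \code{tp_s} much shorter than every
#'   simulated T2; a warning is issued when violated.
#' @param acq_window_s per-scan acquisition window in seconds
#'   (0 < acq_window_s <= tp_s); the FID grid passed to
#'   \code{\link{simulate_ssfp_acquisition}} must fit inside it.
#' @param n_scans number of co-added transients.
#' @param pulse_phase_deg constant RF pulse phase in degrees (angle of the
#'   rotation axis from +x in the transverse plane).
#' @param phase_alternate if \code{TRUE}, the pulse phase alternates by
#'   180 degrees on successive pulses (off by default: the constant-phase
#'   train is the canonical SSFP description).
#' @param dead_time_s receiver dead time: leading samples within this
#'   window are blanked in simulated acquisitions (default 0).
#' @return an object of class \code{"ssfp_scheme"}.
#' @export
ssfp_scheme <- function(flip_deg, tp_s, acq_window_s = tp_s, n_scans = 1L,
                        pulse_phase_deg = 0, phase_alternate = FALSE,
                        dead_time_s = 0) {
  stopifnot(is.numeric(flip_deg), length(flip_deg) == 1L,
            flip_deg >= 0, flip_deg <= 180,
            is.numeric(tp_s), tp_s > 0,
            is.numeric(acq_window_s), acq_window_s > 0,
            acq_window_s <= tp_s + 1e-12,
            n_scans >= 1, dead_time_s >= 0)
  structure(list(flip_deg = flip_deg, tp_s = tp_s,
                 acq_window_s = acq_window_s, n_scans = as.integer(n_scans),
                 pulse_phase_deg = pulse_phase_deg,
                 phase_alternate = isTRUE(phase_alternate),
                 dead_time_s = dead_time_s),
            class = "ssfp_scheme")
}

#' @export
print.ssfp_scheme <- function(x, ...) {
  cat(sprintf("SSFP scheme: flip %g deg, Tp %g s, window %g s, %d scan(s)%s\n",
              x$flip_deg, x$tp_s, x$acq_window_s, x$n_scans,
              if (x$phase_alternate) ", phase-alternated" else ""))
  invisible(x)
}

# rotation about z by theta (right-handed)
rot_z <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

# rotation about x by alpha: maps (0,0,1) -> (0, sin a, cos a)
rot_x <- function(alpha) {
  c_ <- cos(alpha); s_ <- sin(alpha)
  matrix(c(1, 0, 0, 0, c_, -s_, 0, s_, c_), 3, 3)
}

# pulse rotation: flip about an axis at angle psi from +x in the xy plane
pulse_matrix <- function(flip_deg, phase_deg) {
  a <- flip_deg * pi / 180
  psi <- phase_deg * pi / 180
  rot_z(psi) %*% rot_x(a) %*% rot_z(-psi)
}

# affine free-precession + relaxation step: m -> A m + b
precess_relax <- function(resonance, tp_s) {
  if (is.na(resonance$t1_s) || is.na(resonance$t2_s))
    stop("SSFP propagation requires t1_s and t2_s on every resonance")
  e1 <- exp(-tp_s / resonance$t1_s)
  e2 <- exp(-tp_s / resonance$t2_s)
  theta <- 2 * pi * resonance$frequency_hz * tp_s
  list(A = diag(c(e2, e2, e1)) %*% rot_z(theta), b = c(0, 0, 1 - e1))
}

#' One SSFP pulse-train cycle of the Bloch vector
#'
#' Applies one cycle — RF rotation by the flip angle about the axis set by
#' the pulse phase, then free precession by \eqn{2\pi f T_p} about z with
#' transverse decay \eqn{E_2 = e^{-T_p/T_2}} and longitudinal recovery
#' toward equilibrium with \eqn{E_1 = e^{-T_p/T_1}}.
#'
#' @param state numeric length-3 Bloch vector \code{c(mx, my, mz)}
#'   relative to the equilibrium magnetization M0 = 1.
#' @param resonance a single-row \code{\link{resonance_set}} with
#'   \code{t1_s} and \code{t2_s} set.
#' @param scheme an \code{\link{ssfp_scheme}}.
#' @param scan_index 1-based cycle counter; only relevant for
#'   phase-alternated trains, where odd/even cycles use phases differing
#'   by 180 degrees.
#' @return the Bloch vector after one cycle.
#' @export
bloch_cycle <- function(state, resonance, scheme, scan_index = 1L) {
  stopifnot(is.numeric(state), length(state) == 3L, all(is.finite(state)))
  resonance <- as.data.frame(resonance)
  stopifnot(nrow(resonance) == 1L)
  phase <- scheme$pulse_phase_deg +
    if (scheme$phase_alternate && scan_index %% 2 == 0) 180 else 0
  p <- pulse_matrix(scheme$flip_deg, phase)
  fr <- precess_relax(resonance, scheme$tp_s)
  drop(fr$A %*% (p %*% state) + fr$b)
}

# composite one-cycle (or two-cycle, if alternating) affine map m -> A m + b,
# plus the pulse matrix used for the reported (post-pulse) state
ssfp_cycle_map <- function(resonance, scheme) {
  fr <- precess_relax(resonance, scheme$tp_s)
  p1 <- pulse_matrix(scheme$flip_deg, scheme$pulse_phase_deg)
  a1 <- fr$A %*% p1
  if (!scheme$phase_alternate)
    return(list(A = a1, b = fr$b, P = p1))
  p2 <- pulse_matrix(scheme$flip_deg, scheme$pulse_phase_deg + 180)
  # period-2 map starting just before an odd-indexed pulse
  a2 <- fr$A %*% p2
  list(A = a2 %*% a1, b = drop(a2 %*% fr$b) + fr$b, P = p1)
}

#' Steady-state transverse magnetization of an SSFP train
#'
#' Returns the post-pulse transverse magnetization \code{mx + 1i*my} of the
#' fixed point of \code{\link{bloch_cycle}}.  The fixed point is found
#' either by solving the linear system \code{(I - A) m = b} exactly
#' (\code{method = "solve"}) or by iterating the cycle map until successive
#' states differ by less than \code{tol} (\code{method = "iterate"}); the
#' two routes agree to high precision for physical parameters.
#'
#' @inheritParams bloch_cycle
#' @param method \code{"solve"} (exact linear fixed point, default) or
#'   \code{"iterate"} (power iteration of the cycle map).
#' @param tol convergence tolerance for the iterative route.
#' @param max_iter iteration cap; non-convergence signals unphysical
#'   parameters and is an error.
#' @return a complex scalar: post-pulse \code{mx + 1i*my} at steady state.
#' @examples
#' r <- resonance_set(0, 1, 2, t1_s = 1, t2_s = 0.5)
#' ssfp_steady_state(r, ssfp_scheme(flip_deg = 30, tp_s = 0.01))
#' @export
ssfp_steady_state <- function(resonance, scheme,
                              method = c("solve", "iterate"),
                              tol = 1e-12, max_iter = 1e5) {
  method <- match.arg(method)
  resonance <- as.data.frame(resonance)
  stopifnot(nrow(resonance) == 1L)
  mp <- ssfp_cycle_map(resonance, scheme)
  if (method == "solve") {
    m <- tryCatch(solve(diag(3) - mp$A, mp$b),
                  error = function(e) stop("singular SSFP fixed-point system: ",
                                           conditionMessage(e)))
  } else {
    m <- c(0, 0, 1)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      m_new <- drop(mp$A %*% m + mp$b)
      if (max(abs(m_new - m)) < tol) { m <- m_new; converged <- TRUE; break }
      m <- m_new
    }
    if (!converged)
      stop("SSFP fixed-point iteration did not converge within max_iter; ",
           "check relaxation times and Tp")
  }
  post <- drop(mp$P %*% m)
  complex(real = post[1], imaginary = post[2])
}

#' Off-resonance steady-state response profile
#'
#' Magnitude of the SSFP steady-state transverse amplitude as a function
#' of frequency offset, for given relaxation times.  This is the banding
#' profile intrinsic to SSFP (the response depends on the precession
#' angle \eqn{2\pi f T_p} and is periodic in \eqn{1/T_p}); dividing fitted
#' amplitudes by it calibrates SSFP data for quantification when the
#' relaxation times are uniform across compounds (e.g. dominated by a
#' paramagnetic relaxation agent).
#'
#' @param frequency_hz numeric vector of offsets.
#' @param scheme an \code{\link{ssfp_scheme}}.
#' @param t1_s,t2_s relaxation times assumed for every offset.
#' @return numeric vector of response magnitudes in (0, 1].
#' @export
ssfp_response <- function(frequency_hz, scheme, t1_s, t2_s) {
  vapply(frequency_hz, function(f)
    Mod(ssfp_steady_state(resonance_set(f, 1, 1 / t2_s, t1_s = t1_s,
                                        t2_s = t2_s), scheme)),
    numeric(1))
}

#' Number of SSFP scans that fit in a total experiment time
#'
#' @param total_time_s total experiment time in seconds (> 0).
#' @param scheme an \code{\link{ssfp_scheme}}.
#' @return \code{floor(total_time_s / tp_s)} as an integer.
#' @examples
#' scan_budget(900, ssfp_scheme(60, tp_s = 0.0157))  # a 15-minute budget
#' @export
scan_budget <- function(total_time_s, scheme) {
  stopifnot(is.numeric(total_time_s), length(total_time_s) == 1L,
            total_time_s > 0)
  as.integer(floor(total_time_s / scheme$tp_s))
}

#' Simulate a co-added SSFP acquisition
#'
#' Each resonance contributes a damped sinusoid whose initial complex
#' amplitude is \code{amplitude * exp(1i*phase_rad) *
#' ssfp_steady_state(...)} and whose decay rate is
#' \code{max(decay_rate, 1/t2_s)} — the pure-T2 decay plus whatever
#' inhomogeneity broadening is already folded into \code{decay_rate}.  The
#' returned record is the mean of \code{n_scans} transients with
#' independent per-scan noise, so the signal amplitude is scan-independent
#' and the noise standard deviation shrinks as \code{1/sqrt(n_scans)} (the
#' scan mean of independent Gaussian draws is generated directly at the
#' reduced standard deviation).
#'
#' @param resonances a \code{resonance_set}; \code{t1_s} and \code{t2_s}
#'   must be set on every row.
#' @param scheme an \code{\link{ssfp_scheme}} (its \code{n_scans} is used).
#' @param grid an \code{acq_grid}; \code{dwell_s * n_points} must not
#'   exceed the scheme's acquisition window.
#' @param noise_sigma per-scan, per-quadrature noise standard deviation.
#' @param seed optional integer seed for reproducibility.
#' @return an \code{nmr_fid} with provenance \code{"ssfp"}.
#' @export
simulate_ssfp_acquisition <- function(resonances, scheme, grid,
                                      noise_sigma = 0, seed = NULL) {
  stopifnot(inherits(scheme, "ssfp_scheme"), inherits(grid, "acq_grid"))
  validate_resonance_set(resonances)
  if (acq_time(grid) > scheme$acq_window_s + 1e-12)
    stop("acquisition grid (", signif(acq_time(grid), 6),
         " s) exceeds the SSFP acquisition window (",
         signif(scheme$acq_window_s, 6), " s)")
  if (nrow(resonances) > 0) {
    if (any(is.na(resonances$t1_s)) || any(is.na(resonances$t2_s)))
      stop("SSFP simulation requires t1_s and t2_s on every resonance")
    if (any(scheme$tp_s >= resonances$t2_s))
      warning("steady-state regime violated: tp_s >= t2_s for at least one resonance")
  }
  times <- (seq_len(grid$n_points) - 1) * grid$dwell_s
  s <- complex(real = rep(0, grid$n_points), imaginary = 0)
  for (k in seq_len(nrow(resonances))) {
    rk <- resonances[k, , drop = FALSE]
    ss <- ssfp_steady_state(rk, scheme)
    lam <- max(rk$decay_rate, 1 / rk$t2_s)
    s <- s + rk$amplitude * exp(1i * rk$phase_rad) * ss *
      exp((-lam + 2i * pi * rk$frequency_hz) * times)
  }
  if (scheme$dead_time_s > 0)
    s[times < scheme$dead_time_s] <- 0 + 0i
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    s <- s + complex_noise(grid$n_points, noise_sigma / sqrt(scheme$n_scans))
  }
  new_fid(s, grid, n_scans = scheme$n_scans, provenance = "ssfp")
}
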