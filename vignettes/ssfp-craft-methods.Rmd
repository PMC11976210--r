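---
title: "SSFP acquisition and time-domain decomposition: models and methods"
author: "craftnmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SSFP acquisition and time-domain decomposition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craftnmr)
```

This vignette documents the models implemented by `craftnmr`, the
numerical choices behind them, what the synthetic-data generator does and
does not emulate, and the known limitations.  Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The signal model

A free induction decay is modelled as a finite sum of exponentially
damped complex sinusoids on a uniform grid of dwell time $\Delta t$:

$$ s(t_n) \;=\; \sum_{k=1}^{K} a_k\, e^{i\varphi_k}\,
   e^{(-\lambda_k + i 2\pi f_k)\,t_n} \;+\; \varepsilon_n , $$

with amplitude $a_k \ge 0$, frequency $f_k$ (signed offset from the
carrier, Hz), decay rate $\lambda_k = 1/T_2^* > 0$ (s⁻¹) and phase
$\varphi_k \in [-\pi,\pi)$.  These four parameters per component are, for
practical purposes, orthogonal, and they carry the same information as
the frequency-domain spectrum: the Lorentzian line of component $k$ has
FWHM $\lambda_k/\pi$ Hz.  The decay rate — not $T_2^*$ — is the primary
parameter package-wide, which avoids $1/x$ singularities during fitting;
$T_2^*$ and FWHM are derived views.

Receiver noise $\varepsilon_n$ is circular complex Gaussian: independent
real and imaginary components, each of standard deviation $\sigma$,
white across samples.  This is the standard quadrature-receiver model;
no other noise structure is simulated.

Sign conventions, fixed package-wide: positive frequency offsets map to
higher (less negative) ppm via
$\mathrm{ppm} = \mathrm{carrier} + f/\nu_0$ with $\nu_0$ the observe
frequency in MHz; ¹⁹F shifts are referenced so the PFAS region is
negative (CFCl₃ = 0 ppm).  The default observe frequency is 470.4 MHz
(¹⁹F at 11.7 T); it is a free parameter of `acq_grid()` because the
field strength is sample-specific in practice.

**Scan co-addition returns the mean, not the sum.**  A record flagged as
$N$ scans has unchanged signal amplitude and noise standard deviation
$\sigma/\sqrt{N}$.  This pure convention keeps amplitudes comparable
across acquisition schemes and makes SNR bookkeeping transparent.  The
per-scan noise draws are independent, so the mean is generated directly
at the reduced standard deviation — distributionally identical and
cheaper than simulating every transient.

## 2. The SSFP engine

Steady-state free precession drives the spins with a rapid train of
identical pulses separated by $T_p \ll T_2$.  One cycle is an affine map
on the Bloch vector $m = (m_x, m_y, m_z)$ (equilibrium $M_0 = 1$):

* pulse: rotation by the flip angle $\alpha$ about an axis in the
  transverse plane set by the pulse phase;
* free precession by $\theta = 2\pi f T_p$ about $z$ with transverse
  decay $E_2 = e^{-T_p/T_2}$ and longitudinal recovery
  $m_z \mapsto 1 - E_1 + E_1 m_z$, $E_1 = e^{-T_p/T_1}$.

`ssfp_steady_state()` returns the post-pulse transverse magnetization of
the fixed point, computed either by solving the $3{\times}3$ linear
system $(I - A)m = b$ exactly or by iterating the cycle map; the
propagation route is the source of truth and the two routes agree to
$10^{-9}$ (asserted in the tests).

On resonance the fixed point has a closed form.  For the
**constant-phase** train the Bloch algebra gives

$$ |M_+| \;=\; \frac{\sin\alpha\,(1-E_1)}{1 - (E_1+E_2)\cos\alpha + E_1E_2}, $$

while the textbook expression with denominator
$1-(E_1-E_2)\cos\alpha - E_1E_2$ is the steady state of the
**phase-alternated** train (equivalently, constant phase at precession
angle $\pi$).  Both closed forms are verified against the propagation
route under their respective validity conditions; conflating the two is
a common source of confusion, which is why the package asserts each one
explicitly.  The constant-phase train is the default
(`phase_alternate = FALSE`), matching the canonical SSFP description;
alternation is exposed as a scheme option.  Receiver dead time defaults
to zero and is configurable as leading-sample blanking.

`simulate_ssfp_acquisition()` gives each resonance an initial complex
amplitude $a_k e^{i\varphi_k} \cdot M_+(f_k)$ and decay rate
$\max(\lambda_k, 1/T_{2,k})$ — the $T_2$ decay plus whatever
inhomogeneity broadening was already folded into $\lambda_k$.  The
off-resonance dependence of $M_+$ (SSFP *banding*, periodic in $1/T_p$)
is simulated faithfully, not suppressed: it is intrinsic physics and a
known artifact source.  `ssfp_response()` exposes the banding profile
directly, which Section 6 uses for quantification.  The actual flip
angles, inter-pulse times and phase cycling used in any given experiment
are instrument-specific; the defaults used in examples and tests
(flip 60°, $T_p$ well under $T_2$) are physically reasonable stand-ins,
not measured settings.

## 3. The decomposer

`craft()` converts a (possibly severely truncated) record into an
amplitude–frequency table without a Fourier transform.  The pipeline:

1. **Noise estimate.**  The per-quadrature noise level is estimated from
   the spectral floor: $\hat\sigma = \mathrm{median}|X_k| / \sqrt{N\ln 4}$,
   the Rayleigh-consistent median of the DFT magnitudes.  Sparse NMR
   signals perturb the median only through their Lorentzian tails.  The
   exported `estimate_noise_sigma()` implements the complementary
   time-domain estimator — median absolute first difference, pooled over
   quadratures, scaled by $1.4826/\sqrt 2$ — which is excellent when all
   signal content evolves slowly on the dwell-time scale but is biased
   upward by broadband components (a component with pole $s$ leaks
   $|e^{s\Delta t}-1|$ of its amplitude into the differences).  The
   decomposer therefore uses the spectral floor internally.

2. **Sub-band decimation** (records longer than 2048 points; shorter
   records are fitted in one full-band pass).  The spectral width is
   split into 16 uniform bands with 10 % overlap.  Each band is
   frequency-shifted to DC, low-pass filtered with a linear-phase
   Hamming-windowed FIR (cutoff 25 % beyond the band edge; DC gain
   pinned to exactly 1; the filter's settling regions are discarded and
   the retained samples keep their absolute time), and decimated by the
   largest factor that leaves at least a factor-2 guard band.  Bands
   whose strongest DFT bin is below 3× the spectral median are skipped
   outright — a pure-noise bin exceeds that threshold with probability
   $\sim 4\times10^{-6}$, and a component failing it could not pass the
   final detection rule either.

3. **Matrix-pencil initialisation** (`initial_model()`).  A Hankel
   pencil $X_1, X_2$ is built from the samples (pencil parameter
   $L \approx N/3$, capped at 128 columns for speed); the poles
   $z_k = e^{(-\lambda_k + i2\pi f_k)\Delta t}$ are the eigenvalues of
   the order-truncated pencil and the complex amplitudes follow from a
   linear Vandermonde solve.  The model order is chosen by a
   singular-value threshold
   $\max(10^{-3} s_1,\; 3 \times \text{noise level})$, where the noise
   level is the **median singular value of the pencil itself**: it is
   machine-small for noiseless records, tracks the noise bulk otherwise,
   and — unlike sample-based estimates — is not inflated by in-band
   signal.  (Empirically the largest singular value of a pure-noise
   pencil of the shapes used here stays below ~2.6× the median, so the
   multiplier 3 admits no noise components; the false-alarm rate is
   measured in the acceptance checks.)  Candidates with
   $|z_k| \ge 1$ (nonpositive decay) are discarded.  Everything is
   deterministic for fixed input.

4. **Variable-projection refinement** (`refine_components()`).  Only the
   frequencies and log decay rates are nonlinear parameters; for any
   trial values the complex amplitudes are the exact linear
   least-squares solution, so the Levenberg–Marquardt outer problem has
   just $2K$ unknowns.  The log parameterisation keeps
   $\lambda_k > 0$ (with a $10^{-10}$ floor against underflow for
   near-undamped components).  Standard errors for all four parameters
   come from the Gauss–Newton covariance of the full model at the
   solution, with the residual variance on the degrees of freedom
   $2N - 4K$.  If the optimiser fails to beat the candidate model's
   residual, the candidates are returned unchanged and flagged; the
   refined residual is never allowed to exceed the starting one.
   Candidates with frequencies equal to machine tolerance are merged
   before fitting (a duplicated column makes the linear design
   singular).

5. **Cross-band merging and joint refinement.**  Components recovered
   from overlapping bands within the merge tolerance — default half the
   record's Rayleigh resolution, $0.5/T_\mathrm{acq}$ Hz, below which
   two fits are the same physical component seen from two bands — are
   merged keeping the lower-residual band's fit, and the merged set is
   re-refined jointly against the full unfiltered record (this also
   removes any residual passband droop from the band filters).

6. **Detection** (`select_components()`).  A component is retained iff
   its amplitude exceeds $k$ times its own amplitude standard error
   (default $k = 3$) — i.e. the component is resolved above the
   randomness of the data points.  Discarded components are logged with
   their scores, survivors are re-refined, and a relative
   machine-precision amplitude floor ($10^{-9}$ of the record maximum)
   removes the numerical residue that signal-free bands contribute on
   noiseless input, whose standard errors would otherwise be smaller
   still.

The returned `craft` object is a fitted model in the classic R sense:
`coef()`, `fitted()`, `residuals()`, `predict()` (resynthesis on a new
grid), `simulate()` (noisy replicates at the estimated noise level),
`plot()` and `summary()` all behave as expected.

**Reconstruction.**  `simulate_from_table()` resynthesizes a noiseless
record; auto-sizing uses `resim_length_factor` (constrained to [3, 5],
default 4 — the mid-range) times the slowest decay constant, long enough
that the subsequent Fourier transform in `craft_spectrum()` adds no
significant truncation artifacts.  No apodization is applied anywhere in
the reconstruction path.  The auto-sized record length is capped at
262144 points so that a near-undamped component cannot request an
unbounded resynthesis.  `vertical_scale = 0.6` reproduces the overlay
convention of scaling the reconstruction down by 40 % when comparing
against noise-bearing Fourier spectra whose analyte peaks are broadened.

## 4. Fourier processing and metrics

`fourier_spectrum()` uses the plain DFT convention
$X_k = \sum_n x_n e^{-2\pi i nk/N}$ (Parseval:
$\sum|x_n|^2 = N^{-1}\sum|X_k|^2$, asserted in the tests), optional
exponential apodization $e^{-\pi\,\mathrm{lb}\,t}$ and zero filling.
Phase correction is zeroth-order only — the constant phase that
maximises the real part of the tallest magnitude peak — because
synthetic, delay-free records need no first-order term; records whose
first sample is not at $t=0$ (decimated sub-bands) are re-referenced by
the corresponding linear phase first.

SNR follows the height-over-noise-height convention: the maximum real
intensity in the signal window divided by **twice the standard
deviation** of the real intensities in the noise window.  The factor 2
is a fixed documented convention chosen so that the conventional 3:1
limit-of-detection criterion applies; a noiseless window returns the
sentinel `Inf` (reconstructed spectra are noise-free, which is why peak
*counts*, not SNR, are the useful metric for them).  Peak counting on
spectra uses local maxima above a threshold with a minimum-separation
rule (default 3 frequency bins; the tallest maximum in a conflicting
group wins).

`lod_study()` runs the full simulate–process–measure loop over an
amplitude grid and seeds, schemes sharing a total experiment time and
matched noise ensembles.  The limit of detection is the smallest grid
amplitude whose mean SNR reaches 3.  On the decomposition path the
reconstructed spectrum is noiseless, so the SNR is effectively a
detection indicator: the LOD is the smallest amplitude at which the
analyte is recovered by the fit.  Amplitude is used as the concentration
proxy throughout — the two are proportional at fixed acquisition
settings.

## 5. What the generator emulates — and what it does not

The synthetic fixtures (`pfas_fixture()`) place resonances at the
chemical shifts characteristic of the main ¹⁹F functional-group regions
seen in environmental screening: TFA (−77 ppm), inorganic fluoride
(−121.4 ppm), aromatic-CF₃ compounds (−61.5 to −68.1 ppm), the
fluorotelomer-alcohol CF₂ (−113.4 ppm), and the diagnostic head-group
CF₂ resonances of PFCAs (−118.7), PFSAs (−117.9), sulfonamides (−117.7,
−117.2) and fluorotelomer species (−116.6, −115.5 ppm).  Default
relaxation times (T₁ 1.2 s, T₂ 0.6 s; T₂* = T₂) are typical of small
fluorinated molecules in solution; amplitudes default to one unit per
equivalent fluorine.  The six-compound quantification standard is a
synthetic composition over these regions — the mixtures used in real
spike-recovery work are not publicly enumerated, so no claim of
compound-level correspondence is made.

Deliberately **not** modelled: J-coupling multiplets, chemical-exchange
lineshapes, non-uniform sampling, gradient spoiling, B₁ inhomogeneity,
temperature/frequency drift, solvent backgrounds and baseline
distortions.  Passing tests therefore demonstrate the estimator's
statistical and numerical behaviour on the stated signal model, not
robustness to every artifact of real spectrometers; on real data the
practical resolution limit will be set by lineshape deviations from the
Lorentzian model rather than by the record length.

## 6. Quantification

`percent_recovery()` converts fitted amplitudes to amounts through an
internal standard of known amount, normalising per equivalent fluorine:

$$ \mathrm{amount}_i = \frac{A_i}{A_{IS}}\cdot
   \frac{nF_{IS}}{nF_i}\cdot \mathrm{amount}_{IS}. $$

For conventional acquisitions this is the whole story.  SSFP amplitudes,
however, carry the offset-dependent steady-state response of Section 2,
so uncorrected amplitude ratios are biased by the banding profile.  When
relaxation times are uniform across compounds — the regime a
paramagnetic relaxation agent is added to approach, which is also what
makes SSFP quantification viable at all — the response depends only on
the offset and is exactly computable by the Bloch engine.  Passing
`response = function(f) ssfp_response(f, scheme, t1, t2)` divides it
out.  The end-to-end acceptance check runs the six-compound standard
through a 200 ms-window SSFP acquisition at per-component SNR 20 with
this correction and recovers amounts to within a few percent; without
uniform relaxation (or with compound-dependent relaxation left
uncorrected) SSFP remains semi-quantitative, which is a real limitation
of the technique, not of the implementation.

## 7. Problem sizes, tolerances and degenerate inputs

* Test and acceptance studies use records of 100–8192 points, up to 12
  components, 8–100 Monte-Carlo seeds per study, and a 6144-point
  sub-band decomposition for the quantification study — sizes chosen so
  the full suite exercises every code path (single-pass, sub-band,
  noiseless, noisy) while remaining quick on one CPU.
* Convergence: fixed-point iteration tolerance $10^{-12}$ (error after
  $10^5$ iterations signals unphysical parameters);
  Levenberg–Marquardt `ftol`/`ptol` $10^{-14}$, 200 iterations.
* Degenerate inputs: empty resonance sets synthesize all-zero records;
  all-zero and pure-noise records decompose to empty tables; empty
  tables refuse to resynthesize; candidate lists must be non-empty for
  refinement; sub-bands outside the spectral width, acquisition grids
  exceeding the SSFP window, and missing relaxation times are errors.
* Components whose decay is slower than the record can determine
  ($\lambda T_\mathrm{acq} \ll 1$) are reported with correspondingly
  inflated standard errors rather than suppressed; how the original
  processing chain treats this regime is not publicly specified, so this
  behaviour is a documented package choice.

## 8. Known limitations

* The decomposer is a functionally equivalent open implementation of
  time-domain reduction to amplitude–frequency tables — subspace
  initialisation, variable projection, $k\sigma$ detection — not a
  reimplementation of any proprietary engine's internals; only the
  table contract is shared.
* Model-order selection is capped per band (`max_order_per_band`,
  default 12); a band genuinely containing more distinct components
  than the cap will merge or drop the weakest.
* The detection rule controls false positives tightly (measured
  false-alarm rate ≲ 0.1 per pure-noise record) at the cost of
  conservative behaviour near the detection limit.
* Zeroth-order phasing only; strongly delay-distorted experimental data
  would need first-order correction before decomposition.
* JCAMP-DX support covers the package's own NTUPLES complex-FID dialect
  (lossless round trip), not the full diversity of vendor JCAMP
  writers; vendor raw directories are out of scope.
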