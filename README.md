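# craftnmr

Steady-state free precession (SSFP) NMR simulation and time-domain
spectral decomposition in R, motivated by ¹⁹F screening of per- and
polyfluoroalkyl substances (PFAS) in environmental and biological
samples.

## The problem

An NMR free induction decay (FID) is a sum of exponentially damped
sinusoids, each fully described by four parameters: frequency *f*,
amplitude *a*, decay rate *λ* = 1/T₂\* and phase *φ*:

```
s(t) = Σₖ aₖ exp(i φₖ) exp((−λₖ + i 2π fₖ) t) + noise
```

SSFP acquisition applies a rapid pulse train (inter-pulse time
T_p ≪ T₂) so the spins never relax and thousands of transients are
co-added per minute — a large sensitivity gain.  The price is a severely
truncated record: Fourier transforming it produces sinc sidelobes and
inflated linewidths that bury exactly the weak signals the extra
sensitivity was meant to reveal.

`craftnmr` sidesteps the Fourier transform.  The `craft()` fitting
function reduces the truncated record directly in the time domain to an
amplitude–frequency table — one {*f*, *a*, *λ*, *φ*} row per component,
with standard errors — via

1. **matrix-pencil (Hankel-SVD) initialisation**, with sub-band
   decimation for long records,
2. **variable-projection nonlinear least squares** (amplitudes and
   phases solved linearly at every step; only frequencies and log decay
   rates are nonlinear parameters), and
3. a ***k*·σ amplitude-uncertainty detection rule** (a component is kept
   only if its amplitude exceeds *k* = 3 times its own standard error).

Because the linewidth of a fitted component is *λ/π* Hz regardless of
how short the record was, spectra reconstructed from the table are free
of truncation artifacts and noise.  The package also provides a Bloch
steady-state engine for SSFP pulse trains, conventional Fourier
processing, SNR/linewidth/peak metrics, Monte-Carlo limit-of-detection
studies, internal-standard spike-recovery quantification, JCAMP-DX
import/export, built-in ¹⁹F fixture sets, and a YAML-driven pipeline.

## A worked example

A six-component ¹⁹F mixture, truncated to 128 points — far too short
for the Fourier transform to resolve cleanly:

```r
library(craftnmr)

grid <- acq_grid(dwell_s = 1e-3, n_points = 128)   # 0.128 s record
truth <- resonance_set(
  frequency_hz = c(-350, -180, -60, 90, 220, 380),
  amplitude    = c(1.2, 0.8, 2.0, 1.0, 1.5, 0.6),
  decay_rate   = c(4, 6, 5, 3, 7, 5),
  phase_rad    = c(0.4, -2.0, 1.1, 2.5, -0.7, 0.9))
fit <- craft(synthesize_fid(truth, grid))
fit
```

```
CRAFT decomposition: 6 component(s) from a 128-point FID
  residual rms 5.8e-15 (per quadrature), noise level 0.4714
     ppm frequency_hz amplitude fwhm_hz phase_rad
 -110.74         -350       1.2 1.27324       0.4
 -110.38         -180       0.8 1.90986      -2.0
 -110.13          -60       2.0 1.59155       1.1
 -109.81           90       1.0 0.95493       2.5
 -109.53          220       1.5 2.22817      -0.7
 -109.19          380       0.6 1.59155       0.9
```

(The reported "noise level" is the spectral-floor estimate, which on a
short noiseless multi-component record reflects Lorentzian leakage
rather than true noise; the machine-level residual is the meaningful
figure here.)

All four parameters of every component are recovered to machine
precision (the fitted FWHM column is exactly λ/π).  A clean,
noise-free spectrum of any length follows from the table:

```r
spec <- craft_spectrum(fit)        # resynthesised at 4 decay constants
plot(spec)
coef(fit)                          # the full table with standard errors
```

The Fourier transform of the same 128-point record
(`fourier_spectrum(...)`) shows ~10-fold linewidth inflation and ~7 %
sinc sidelobes — the comparison the package's acceptance checks
quantify.  A full three-panel comparison (conventional 1D vs SSFP-FT vs
SSFP-CRAFT) is produced by the bundled pipeline:

```r
run_pipeline(system.file("extdata", "figure1_style_demo.yaml",
                         package = "craftnmr"), "demo_out")
```

A thin command-line front end over the same functions lives at
`inst/cli/craftnmr.R` (subcommands `report`, `simulate`, `decompose`,
`spectrum`, `lod`, `recover`).

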