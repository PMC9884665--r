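---
title: "Estimating opsin spectral sensitivity by heterologous action spectroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating opsin spectral sensitivity by heterologous action spectroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actispec)
```

## The problem

A visual pigment is characterized by its spectral sensitivity curve and in
particular by its peak wavelength, λmax. When an opsin cannot be purified in
a form that yields an interpretable absorbance spectrum — a common situation
for non-model opsins such as coral opsins — λmax can still be estimated
*functionally*: express the opsin in cultured cells together with a
luminescent cAMP reporter, stimulate with narrow-band LEDs, and exploit the
univariance of the pigment response. Every photoreceptor response of a given
size corresponds to one effective photon dose; wavelength only scales how
efficiently delivered photons are absorbed. This package implements that
inference chain and the sequence-level checks that usually accompany it.

## From trace to amplitude

The raw observable is a luminescence time series from a dish of
reporter-expressing cells, irradiated exactly once. Preprocessing is
deliberately minimal:

* **Baseline normalization.** The trace is divided by its mean over the 60 s
  immediately preceding stimulus onset (samples with
  t ∈ [onset − 60, onset)). This makes traces from different dishes
  comparable and the analysis invariant to luminometer gain. The operation
  is idempotent and requires at least two baseline samples.
* **Amplitude extraction.** The scalar response `V` is the peak of the
  normalized trace within a post-stimulus window (default 600 s), minus 1.
  The raw literature rarely states the extraction rule; a peak statistic was
  chosen because the transients rise and decay slowly and a peak is
  gain-invariant and insensitive to the exact decay shape. Because a raw
  per-sample maximum tracks the highest noise excursion rather than the
  response, a centered moving average (default 20 s, configurable, 0 to
  disable) is applied before peak picking; it is exact whenever the response
  plateau is wider than the smoothing window, and it attenuates a smooth
  transient by a wavelength-independent factor that the downstream fit
  absorbs (see below). Negative amplitudes are reported, not clipped:
  non-responding constructs are data.

## The intensity–response curve

At the 470 nm reference wavelength, replicate-mean amplitudes across a
neutral-density intensity series are fit with the Hill sigmoid
V = Vmax·Iⁿ/(Iⁿ + Kⁿ). Choices that the data do not dictate, and how they
were resolved:

* **Optimizer.** Bounded Levenberg–Marquardt least squares
  (`minpack.lm::nlsLM`), intensities rescaled by their maximum for
  conditioning. Starting values: Vmax₀ = 1.05 × max mean response, K₀ = the
  observed intensity whose mean response is nearest Vmax₀/2, n₀ = 1. Bounds:
  n ∈ (0.1, 10], K within [min(I)/100, 100·max(I)]. The fit is equivariant
  to flux-unit rescaling (K rescales, Vmax and n do not).
* **Replicate handling.** The fit is to replicate means per intensity, not
  pooled replicates; replicate SEMs are carried for reporting only.
  Residuals are unweighted (no weighting scheme is standard for 5-point
  series; 1/SEM² weights would be dominated by the worst-estimated point at
  n = 3).
* **Inversion.** I = K·(V/(Vmax − V))^(1/n) is exact on (0, Vmax).
  Amplitudes ≤ 0 are "below range" and amplitudes ≥ Vmax "saturating";
  both are non-invertible and excluded, per wavelength, with a warning
  rather than an abort, because real assays contain non-responders.

## From amplitudes to an action spectrum

For each wavelength-series replicate, the amplitude is pushed through the
inverse Hill curve, giving the equivalent reference flux I_eq. Sensitivity
is proportional to I_eq divided by the photons actually delivered at that
wavelength; wavelength means are normalized so the best wavelength reads
exactly 1, and SEMs are computed across replicate-level normalized values.

The A1 (11-*cis* retinal) Govardovskii template supplies the fitting curve:
an alpha band S_α = 1/(exp[69.7(a − x)] + exp[28(0.922 − x)] +
exp[−14.9(1.104 − x)] + 0.674) with x = λmax/λ and
a = 0.8795 + 0.0459·exp[−(λmax − 300)²/11940], plus a beta band
0.26·exp{−[(λ − (189 + 0.315·λmax))/(−40.5 + 0.195·λmax)]²}. The beta band
is included by default (blue pigments have a non-negligible cis peak below
~420 nm) and can be disabled. Because the analytic sum peaks only
approximately at the nominal λmax and approximately at 1, the curve is
renormalized to unit peak by a dense 0.1 nm scan of 300–700 nm rather than
by assuming S(λmax) = 1.

**λmax estimation** minimizes the residual sum of squares between the
measured sensitivities s_i and a·S(λ_i; λmax):

* With the default *free scale*, a* = max(0, Σs_i·t_i / Σt_i²) is the
  closed-form least-squares factor. Pinning both curves at unit peak
  (`free_scale = FALSE` is provided) forces the fit through whichever data
  point happened to be noisiest-high; the free scale removes that bias and
  makes the estimator invariant to the data normalization. It also absorbs
  any wavelength-independent multiplicative attenuation introduced upstream
  (smoothing, reporter kinetics), which is why such factors cancel through
  the pipeline.
* The estimate is continuous: a coarse scan of λmax over 330–650 nm at 5 nm
  (ties broken toward the lower wavelength) brackets the minimum, then
  bounded scalar minimization within ±10 nm refines it to sub-nm precision.
  A 2 nm-step RSS profile over ±20 nm (a 41 nm window) around the estimate
  is attached as the goodness-of-fit diagnostic; integer-nm λmax reports are
  roundings of the continuous estimate, not grid points. If a profile grid
  point numerically undercuts the continuous optimum (the truth sitting
  exactly on the grid), the better value is kept. An estimate pinned at the
  scan boundary sets `boundary_warning`: the true peak likely lies outside
  the probed band.

## Sequence-level opsin checks

Two diagnostics, both in bovine rhodopsin numbering via global pairwise
alignment (Needleman–Wunsch as implemented by `Biostrings`, BLOSUM62,
affine gaps opening 10 / extension 1 — all config-exposed since no single
convention is canonical): the chromophore-binding lysine at position 296,
and the counterion sites 94, 113 and 181, where "negatively charged" means
Asp or Glu (no pKa modelling). The 348-residue bovine rhodopsin reference is
embedded in the package, so the checks run offline. An opsin with no D/E at
any of the three sites cannot stabilize the protonated Schiff base there —
a sequence-level hint of UV sensitivity or a non-canonical counterion.
Profile- or structure-based numbering schemes would be alternatives;
pairwise global alignment is the documented choice, and the aligner's
traceback tie-break is deterministic (identical inputs give byte-identical
reports) though not user-selectable.

## The synthetic assay generator

`assay_design()` / `simulate_experiment()` emulate the statistical structure
the analysis assumes: a five-LED wavelength series (410/430/470/510/540 nm)
at fixed quantum flux (default 6.2 × 10¹⁴ photons cm⁻² s⁻¹), a five-point
470 nm intensity series (default log-spaced over ±1.5 decades around K, the
neutral-density analogue), and n = 3 replicate dishes, each irradiated
exactly once. Each trace is

baseline(t) · [1 + V·k(t − onset)] + noise,

with an exponentially drifting baseline (default 1000 counts, −10⁻⁴ s⁻¹), a
unit-peak rise–decay kernel k(t) = c·(1 − e^(−t/τ_rise))·e^(−t/τ_decay)
(defaults τ_rise = 60 s, τ_decay = 600 s, chosen to resemble slow
cAMP-reporter transients; they are configuration, not biological claims),
and i.i.d. Gaussian noise with SD `noise_sd` × baseline (default 0.05, a
nominal value — real replicate scatter is only indirectly observable).
The target amplitude V follows the design's Hill parameters (defaults
Vmax = 0.8, K = 10¹⁵ photons cm⁻² s⁻¹, n = 1 — placing the LED flux on the
rising limb of the sigmoid, as a usable assay requires) applied to the
effective dose flux·S(λ)/S(470) under the design's true template. Noise
enters on the luminescence, not on amplitudes, so the preprocessing stage is
exercised. The 5 s stimulus is modelled as an instantaneous dose: the
analysis never uses within-stimulus dynamics.

Setting `tau_rise = NULL` (step kernel) with zero drift and zero noise gives
the *idealized* generator for which the pipeline is exactly adjoint: every
intermediate — amplitude, equivalent flux, relative sensitivity, λmax —
equals its generating value to numerical tolerance, and the test suite
verifies recovery of λmax to 0.1 nm and of the Hill parameters to 10⁻⁶
relative for true peaks across 440–500 nm. With kinetics or drift enabled,
peak attenuation is (nearly) a common multiplicative factor that the free
scale and the dose fit absorb; the residual drift-induced offset is well
below replicate noise.

What the generator does **not** emulate: mechanistic
receptor/G-protein/reporter biochemistry, photoproduct accumulation,
reciprocity failure over the 5 s stimulus, correlated (non-Gaussian) noise,
or construct-to-construct expression differences. Passing recovery tests
therefore validate the *inference chain under its own assumptions*, not the
biology of any particular assay.

## Problem sizes and determinism

The shipped tests run the stochastic recovery study at 200 seeded
simulations of the full design (30 traces each, 2 s sampling, 690 s traces)
and check that the median |λ̂max − truth| stays within 4 nm at 5% replicate
noise; the same-sized study on noise applied directly to sensitivities is
run as a separate property. All randomness flows through explicit integer
seeds; the generator restores the session RNG state, and identical designs
produce byte-identical trace CSVs.

## Known limitations

* Only the A1 chromophore template is provided; A2 pigments, bleaching
  spectra and self-screening corrections are out of scope.
* The RSS profile is a diagnostic, not a confidence interval; bootstrap
  uncertainty on λmax would be a natural extension.
* Five wavelengths constrain a one-parameter template well near 440–520 nm
  but poorly outside the LED span; the boundary warning flags the obvious
  failure mode, not every identifiability problem.
* Whether to fit with the beta band and with a free or pinned scale are
  exposed as options because the conventional analyses do not agree; the
  defaults (beta on, free scale) are the package's choice and noise-free
  results are insensitive to either.
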