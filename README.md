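# actispec

Heterologous action spectroscopy (HAS) analysis for visual pigments in R.

Many opsins — notably the coral and other cnidarian opsins that resist
purification — never yield a clean absorbance spectrum from detergent-
solubilized pigment. HAS sidesteps the biochemistry: cells heterologously
expressing the opsin (plus a luminescent cAMP reporter such as GloSensor)
are flashed with narrow-band LEDs, and the wavelength- and
intensity-dependence of the second-messenger response is inverted into a
spectral sensitivity curve. `actispec` implements that inversion end to end,
for experimentalists analysing GloSensor-style luminescence assays and for
anyone who needs a tested Govardovskii-template fitting engine.

## The model

Three pieces, chained:

1. **Response amplitude.** Each luminescence trace is normalized to its mean
   over the 60 s immediately preceding irradiation; the response amplitude
   `V` is the post-stimulus peak of the normalized trace minus 1.

2. **Intensity–response (Hill) curve.** At the 470 nm reference wavelength,
   amplitudes across a neutral-density intensity series follow

   V = Vmax · Iⁿ / (Iⁿ + Kⁿ)

   with `I` the photon flux (photons cm⁻² s⁻¹), `K` the half-saturating
   flux and `n` the Hill exponent. Its inverse,
   I = K · (V / (Vmax − V))^(1/n), converts any amplitude into the
   *equivalent 470 nm photon flux* that would have elicited it.

3. **Template fit.** Relative sensitivity at wavelength λ is the equivalent
   flux per photon delivered, normalized to a unit maximum. The A1
   (11-*cis* retinal) Govardovskii template S(λ; λmax) — an alpha band in
   x = λmax/λ plus a Gaussian beta band — is fit to these points by least
   squares with a closed-form multiplicative scale, and λmax is located by a
   coarse 330–650 nm scan followed by continuous refinement. A residual-
   sum-of-squares (RSS) profile on a 2 nm grid documents the goodness of
   fit.

A sequence module covers the standard sanity checks on the opsins
themselves: global alignment to bovine rhodopsin (Needleman–Wunsch,
BLOSUM62, affine gaps) to read out the chromophore-binding Lys296 and the
counterion sites 94/113/181 in bovine numbering. A synthetic-data module
generates complete assays — drifting baselines, rise–decay transients,
replicate noise — with known ground truth, so the whole pipeline is testable
without a luminometer.

## Worked example

Simulate a noisy assay for a blue-sensitive pigment (true λmax = 472 nm,
5 LEDs × 3 dishes, 5-point intensity series × 3 dishes, 5% replicate noise)
and run the full analysis:

```r
library(actispec)

design     <- assay_design(true_lambda_max = 472, noise_sd = 0.05, seed = 7L)
experiment <- simulate_experiment(design)
result     <- run_pipeline(experiment$traces)

result$dose
#> intensity-response curve @ 470 nm: Vmax = 0.7966, K = 1.032e+15 photons/cm2/s, n = 0.9354
#>   fit: RSS = 8.639e-05 over 6 intensities

result$sensitivities
#>   wavelength_nm rel_sensitivity        sem n_replicates
#> 1           410       0.3641614 0.02795845            3
#> 2           430       0.5729204 0.02282146            3
#> 3           470       1.0000000 0.03316635            3
#> 4           510       0.5224828 0.03054102            3
#> 5           540       0.1514618 0.01837012            3

result$fit
#> lambda-max fit: 471.89 nm (RSS = 0.00541, scale = 0.9506)
#>   RSS profile: 452-492 nm at 2 nm steps
```

The fitted Hill curve (Vmax ≈ 0.80, K ≈ 1.0 × 10¹⁵) recovers the generating
parameters (0.8, 1 × 10¹⁵, 1); the five relative sensitivities track the
unit-peak template at 472 nm; and the estimated λmax of 471.89 nm lands
0.11 nm from the truth. `plot(result$fit, points = result$sensitivities)`
draws the fitted spectrum and the RSS profile.

Sequence checks work directly on amino-acid strings or FASTA files:

```r
rep <- counterion_report(align_to_bovine(bovine_rhodopsin(), "bovine"))
rep
#> bovine: Lys296 present; sites 94/113/181 = T/E/E; negative at {113, 181}
```

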