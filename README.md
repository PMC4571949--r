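# rhospec

Spectral-tuning analysis of invertebrate visual pigments in R.

## The problem

Site-directed mutants of a rhodopsin shift its absorbance peak
(λ<sub>max</sub>), and the size and direction of those shifts is the
primary readout in spectral-tuning studies — for example, testing
whether a candidate counterion residue is required for visible-light
absorption. In fly photoreceptors neither pigment state is measured
directly:

* the dark **R-form** λ<sub>max</sub> is estimated by fitting a
  fixed-shape absorbance template to an electrophysiological
  **spectral-sensitivity** spectrum, restricted to the visible window
  (the dominant UV peak comes from a separate sensitizing pigment and
  must be excluded);
* the photoactivated **M-form** (metarhodopsin) λ<sub>max</sub> is
  estimated from a microspectrophotometric **difference spectrum**
  DS(λ) = M(λ) − R(λ), decomposed with the R-form λ<sub>max</sub> held
  fixed at the electrophysiological value.

`rhospec` implements both estimators around the log-normal rhodopsin
α-band template

S(λ) = exp[ −a₀ x² (1 + a₁ x + a₂ x²) ],  x = log₁₀(λ / λ<sub>max</sub>)

with a₀ = 380, a₁ = 6.09, a₂ = 3a₁²/8 by default (Stavenga, Smits &
Hoenders 1993; coefficients are data and can be swapped via config).
The difference spectrum is modelled with two free non-negative
amplitudes,

DS(λ) = a<sub>M</sub>·S(λ; λ<sub>M</sub>) − a<sub>R</sub>·S(λ; λ<sub>R</sub>),

solved in closed form at each candidate λ<sub>M</sub> (1-nm grid search
plus golden-section refinement to 0.01 nm). Fit quality is the Pearson
correlation between the fitted curve and the data over the fitting
window. Signed shifts versus a wild-type reference (positive = red
shift) are assembled into a pigment report table.

The package also bundles the companion stages such a study uses, each
testable on synthetic data: gap-excluding p-distances, neighbor-joining
and UPGMA trees with bootstrap supports and Newick export
(opsin-family phylogenies), and binding-pocket distance reports from
PDB coordinates (residues within a cutoff of the chromophore, and
side-chain-oxygen distances to the Schiff-base nitrogen).

## Worked example

Simulate a mutant recording (R-form at 486 nm, M-form at 551 nm), fit
both stages, and report the shift against a 480/560 nm wild type:

```r
library(rhospec)

s   <- simulate_sensitivity(486, noise_sigma = 0.02, seed = 42)
fit <- fit_sensitivity(s)
fit
#> R-form fit: lambda_max = 485.93 nm  (r = 0.9988, n = 201, window 420-620 nm)

ds   <- simulate_difference(486, 551, amplitude_R = 0.9, amplitude_M = 0.8,
                            noise_sigma = 0.01, seed = 42)
mfit <- fit_difference(ds, lambda_max_R_fixed = fit$lambda_max_R)
mfit
#> M-form fit: lambda_max = 551.01 nm  aM = 0.800 aR = 0.900  (r = 0.9998, R fixed at 485.933 nm)

compute_shift(fit$lambda_max_R, 480)
#> $shift      [1] 5.932925
#> $direction  [1] "red"

recs <- list(
  pigment_record("Rh1", 480, 560, 0.983, 0.997, 3, 7),
  pigment_record("Rh1 D147N", fit$lambda_max_R, mfit$lambda_max_M,
                 fit$correlation, mfit$correlation, 13, 13))
pigment_table(recs, reference = "Rh1")
#> genotype     R    M    corr_SS  corr_MSP  n_SS  n_MSP  shift_R  shift_M
#> Rh1          480  560  0.983    0.997     3     7      0        0
#> Rh1 D147N    486  551  0.999    1.000     13    13     6        -9
#> (shifts vs Rh1; positive = red shift)
```

The fitted peaks land within a tenth of a nanometre of the generating
values despite the noise and the overlapping UV band; the table rounds
to whole nm and classifies D147N as 6 nm red-shifted in the R-form and
9 nm blue-shifted in the M-form.

Batch analyses are driven by `run_pipeline()` with a YAML config (see
`?read_run_config`); genotypes whose difference spectrum is missing or
whose fit fails get `NA` entries without aborting the batch.

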