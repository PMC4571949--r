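---
title: "Estimating visual-pigment lambda-max from sensitivity and difference spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating visual-pigment lambda-max from sensitivity and difference spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhospec)
```

## The model

A rhodopsin's visible absorbance band (the α band) has a nearly
invariant shape when plotted against log wavelength, so the whole
family of pigments can be described by a single fixed-shape template
parameterized only by the peak wavelength λ~max~. `rhospec` uses the
log-normal form

$$S(\lambda) = \exp\!\left[-a_0\,x^2\,(1 + a_1 x + a_2 x^2)\right],
\qquad x = \log_{10}(\lambda/\lambda_{max}),$$

with defaults $a_0 = 380$, $a_1 = 6.09$, $a_2 = 3a_1^2/8$ (Stavenga,
Smits & Hoenders 1993, *Vision Research* 33:1011). The template equals
1 at λ~max~, lies in $[0,1]$, and is strictly unimodal — the
discriminant condition $a_1^2 < 4a_2$, enforced at construction, keeps
the exponent's polynomial positive so no secondary lobes can appear.
With the defaults the full width at half maximum at λ~max~ = 480 nm is
96.25 nm, with the steeper limb on the long-wavelength side, as
observed for rhodopsins. The coefficients are stored as data
(`template_coefficients()`, or a YAML key via
`load_template_coefficients()`), never baked into the evaluator, so an
alternative published α-band parameterization can be swapped in.
Only the α band is modelled: in fly R1–6 photoreceptors the dominant
UV peak of the sensitivity spectrum is contributed by a separate
sensitizing pigment that transfers energy to the rhodopsin, not by a
β band of the pigment itself, so the UV region is excluded from
fitting rather than modelled.

### R-form estimation from spectral sensitivity

`fit_sensitivity()` minimizes
$\sum_w (d(\lambda) - s\,S(\lambda;\lambda_{max}))^2$ over a visible
fitting window $w$, with the scale $s \ge 0$ profiled out in closed
form at each candidate λ~max~. The optimizer is a 1-nm grid search
over the search interval followed by bracketed golden-section
refinement to 0.01 nm: deterministic, immune to starting-value choice,
and unaffected by the secondary UV peak outside the window. Ties on
the coarse grid resolve to the smaller λ~max~. Data are normalized to
unit maximum inside the window before fitting (the reported scale
refers to the original units), making the estimate invariant to the
arbitrary units of relative sensitivity.

Defaults, all configurable because the underlying measurement
conventions vary between laboratories and are rarely published in
full:

| parameter | default | why |
|---|---|---|
| working grid | 300–700 nm, 1-nm step | spans the UV band through the M-form tail |
| sensitivity window | 420–620 nm | excludes the sensitizing-pigment peak near 350 nm |
| λ~max~ search | 400–650 nm | generous bracket around fly visible pigments |
| refinement tolerance | 0.01 nm | far below the whole-nm reporting precision |

### M-form estimation from difference spectra

Bistable fly pigments photoconvert between the dark R-form and a
thermally stable M-form, and microspectrophotometry measures the
absorbance difference DS = M − R in situ. `build_difference()` models
this as

$$DS(\lambda) = a_M\,S(\lambda;\lambda_M) - a_R\,S(\lambda;\lambda_R),$$

and `fit_difference()` inverts it with λ~R~ *fixed* to the value
determined electrophysiologically for the same genotype, as the
measurement design dictates. Two separate amplitudes are fitted rather
than a single photoconversion fraction: photoconversion need not be
complete and the in-situ path length is uncalibrated, and unequal
amplitudes absorb both effects. At each candidate λ~M~ the amplitudes
are solved by exact two-variable non-negative least squares (the
interior solution when feasible, otherwise the better of the two
boundary fits); a fit that pins an amplitude at zero is flagged
`clamped`. The case analysis also covers the rank-deficient candidate
λ~M~ = λ~R~, where the two template columns are collinear. The default
MSP window is 440–650 nm, covering the negative R-depletion lobe
through the M-form tail. No baseline term is fitted by default —
difference spectra are nominally zero in the absorption-free tails —
but `offset = TRUE` adds a free constant for drifting baselines.

Fit quality for both stages is the Pearson product–moment correlation
between the fitted curve and the data over the fitting window
(`fit_correlation()`), the statistic conventionally printed next to
each λ~max~ in pigment tables.

### Shift reporting

`compute_shift()` is mutant minus reference, positive = red shift.
`pigment_table()` assembles per-genotype records into a report whose
rendered form rounds wavelengths and shifts to whole nm (half away
from zero — the convention matching how such tables are printed) while
the machine-readable TSV keeps full precision and round-trips
losslessly. Missing measurements render as `NA`; a genotype whose
difference spectrum could not be recorded simply has no M-form
columns, and `run_pipeline()` isolates per-genotype failures the same
way rather than aborting a batch.

## What the synthetic generators emulate

`simulate_sensitivity()` produces the two-peaked structure of fly R1–6
recordings: a Gaussian UV band (center 350 nm, σ 25 nm, twice the
visible peak height by default) plus the α band, with additive
homoscedastic Gaussian noise, clipped at zero. The Gaussian is a
deliberate simplification — only the presence of a dominant UV peak
matters for testing the window logic, not its true shape. Real
recordings differ in ways the generator does not model:
photon-noise heteroscedasticity, lamp-line artifacts, and the
energy-transfer coupling between the two bands. Passing tests
therefore demonstrate estimator correctness under the stated noise
model, not instrument-level realism. One measurable consequence of
the overlap: with the default UV band, the tail inside the 420–620 nm
window biases a noiseless single-genotype fit by about 0.2 nm
(toward shorter wavelengths); the bias is common to all genotypes
fitted with the same window, so *shifts* between genotypes are
unaffected at whole-nm precision. `simulate_difference()` adds
Gaussian noise to the analytic two-template difference.

`simulate_alignment()` evolves gap-free protein alignments on a known
rooted tree under the simplest equal-rates model (Poisson numbers of
events per site per branch, each replacing the residue uniformly among
the other 19), for which the expected p-distance at path length $d$
has the closed form $\tfrac{19}{20}(1 - e^{-20d/19})$ used as a test
oracle. This produces clean, fully supported clades for bootstrap
checks; it is not a realistic model of opsin evolution and is not
meant to be. `simulate_structure()` emits toy PDB ATOM/HETATM records
with a lysine-bound chromophore (`LYR`, Schiff-base nitrogen `NZ`)
surrounded by randomly placed residues, for exercising the distance
reports. All generators are pure functions of their arguments and
seed.

## Phylogeny stage choices

Distances are gap-excluding p-distances — simple, fully specified, and
sufficient to recover topologies on the cleanly diverged alignments
this stage is used with; model-corrected distances are out of scope.
Neighbor joining follows the standard Q-criterion agglomeration with
closed-form branch lengths; negative branch lengths are clamped to
zero with the deficit transferred to the sibling branch so the joined
pair's path length is preserved; ties join the pair whose clusters
contain the lexicographically smallest leaf labels, making results
independent of input order. UPGMA is unweighted average linkage with
node height at half the mean inter-cluster distance; its output is
ultrametric by construction. Bootstrap supports resample alignment
columns with replacement and score each internal split of the
full-data tree by its replicate frequency: unrooted bipartitions for
NJ, rooted clades for UPGMA. Outgroup rooting applies to NJ trees;
UPGMA's root comes from its own construction, which an outgroup
re-rooting would contradict, so the outgroup label is validated but
the UPGMA root kept. Newick output carries branch lengths at 6
significant digits with supports as internal node labels.

## Structure stage choices

PDB files are parsed fixed-column (first model, alternate locations
other than `A` dropped). Distances use heavy atoms only — pocket
contacts are conventionally reported with hydrogens omitted, and most
models carry none — with `include_hydrogens = TRUE` available.
Side-chain oxygens are identified by standard PDB atom names (`OD1`,
`OD2`, `OE1`, `OE2`, `OG`, `OG1`, `OH`); backbone carbonyl and
terminal oxygens are deliberately excluded since the report concerns
side-chain proximity to the Schiff-base nitrogen. Residues without a
side-chain oxygen are retained in the ranking with a flagged missing
distance rather than silently dropped. The Schiff-base nitrogen atom
name is configurable because chromophore naming varies between model
files.

## Numerical and testing notes

The test suite sizes its simulations to run in seconds while keeping
Monte-Carlo error well inside the asserted tolerances: bias checks use
100 noisy replicates (sensitivity at σ = 0.02; difference spectra at
5% of peak-to-peak), the closed-form p-distance check uses 50
alignments of 1000 columns, and bootstrap-support checks use a
7-taxon alignment of 1000–2000 columns with 50–100 replicates —
enough that every internal branch is unambiguous. Regression fixtures
(template FWHM, difference-spectrum extrema) were frozen from dense
0.01-nm scans of the implemented formulas. Degenerate inputs fail
loudly by design: constant or all-zero spectra in the fitting window,
fewer than five window points, grids requiring extrapolation,
non-monotone wavelength columns, taxon pairs with no comparable
alignment columns, and chromophore selectors matching nothing all
raise informative errors rather than returning plausible numbers.

## Known limitations

* The template is a single α band; A1/A2 template families,
  temperature effects, and β bands are out of scope.
* Sensitivity fitting treats relative sensitivity as proportional to
  relative absorbance over the fitting window; no quantal or
  log-sensitivity corrections are applied.
* The MSP stage takes absorbance-difference spectra as its contract
  input; `absorbance_from_transmission()` is provided for raw
  transmissions, but smoothing and baseline handling of raw
  instrument output are the caller's responsibility.
* Photoequilibrium dynamics and M-form thermal decay are not
  modelled.
* The phylogeny stage takes an existing alignment; it does not align.
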