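---
title: "Quantifying fatty acyl compositions from Raman spectra with simulated TAG calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fatty acyl compositions from Raman spectra with simulated TAG calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acylquant)
```

## The measurement model

A Raman spectrum of a fat is, to good approximation, a nonnegative linear
combination of its molecular constituents' spectra plus a slowly varying
fluorescence/stray-light background and channel noise. `acylquant` models
fat composition through the five acyl groups that dominate mammalian
triacylglycerols (TAGs): myristate (MA), palmitate (PA), stearate (SA),
oleate (OA) and linoleate (LA), expressed in mole percent. Every ester
contributes exactly one C=O group, so after background and baseline
removal the area of the ester C=O stretching band (1720–1770 cm⁻¹)
serves as a per-mole internal intensity standard; all modeling happens on
these normalized spectra.

The central obstacle is that a TAG calibration set with controlled
compositions cannot realistically be prepared, while the corresponding
FAME mixtures can. The package's core method bridges the two ester
forms. For each acyl group, pooled pure-FAME and pure-TAG replicate
spectra are decomposed by PCA (channels mean-centered over the pooled
set). In a two-class pool the first component captures the systematic
class contrast and the replicate noise falls predominantly into later
components, so the spectral variance

$$\Delta S_{Di} = (Sc_{TAGi} - Sc_{FAMEi})\, L_{PC1 i}$$

(class-mean PC1 scores times the unit PC1 loading) is a noise-filtered
estimate of the TAG-minus-FAME difference spectrum. With a single
noise-free spectrum per class it *equals* the difference spectrum — a
property the test suite asserts exactly. The sign of the loading is
arbitrary and cancels in the product. A FAME mixture spectrum with mole
fractions $C_i$ then yields a simulated TAG mixture spectrum

$$S_{TAGx} = S_{FAMEx} + \sum_i \Delta S_{Di}\, C_i .$$

$C_i$ enters as a mole *fraction* (mole % divided by 100): this is the
only convention under which a pure FAME receives exactly its full
pure-component delta, and the package's reconstruction test (pure FAME
in, pure TAG out, to within 2%) pins it down. Compositions are divided
by 100 at this boundary and nowhere else.

On simulated TAG calibration spectra, one PLS1 model per acyl group is
trained over that model's spectral windows; predictions are affine in
the windowed channels. CLSR (unconstrained) and NNLSR (nonnegative)
least-squares unmixing against the five pure spectra are included as the
model-free baselines they are in practice; NNLSR is solved by the
Lawson–Hanson active-set method and verified against the
Karush–Kuhn–Tucker conditions.

## Preprocessing

The chain is fixed: background subtraction (optional), iterative
polynomial baseline correction, ester-band normalization — in that
order, everywhere. Baseline correction fits a degree-3 polynomial
(default) and iteratively refits on the points not lying more than one
noise standard deviation above the current fit, the noise scale being
estimated from the negative residuals; points flagged as peak therefore
stop attracting the baseline, while the margin keeps roughly the lower
half of the noise distribution anchoring the fit, which makes the
iteration stable (a hard cut that discards everything above the fit can
cascade until a handful of points let the polynomial swing freely — a
kept-fraction floor of 20% of channels guards the degenerate case). The
scheme is equivariant under polynomial shifts of the input, which makes
the full preprocessing chain idempotent: applying it a second time
changes nothing beyond numerical noise, asserted at 1e-9.

Defaults: grid 650–1800 cm⁻¹ at 1 cm⁻¹ (1151 channels), baseline order
3 with up to 20 iterations, normalization window 1720–1770 cm⁻¹.
Windows are closed intervals, stored ascending and rendered descending
(`"1800-1700,1500-1380,..."`), the convention spectra are read in.

## The synthetic data generator

No spectra are distributed with the package, so a generator stands in
for the instrument. Pure components are sums of pseudo-Voigt bands
(Lorentzian fraction η per band) whose positions follow standard lipid
Raman assignments: ester C=O at 1740 cm⁻¹ (FAME), CH₂/CH₃ bending at
1439/1455 cm⁻¹ ordered SA > PA > MA, CH₂ twist at 1302 cm⁻¹, C–C
skeletal bands at 1063–1129 cm⁻¹, species-distinct features in the
930–650 cm⁻¹ region, and C=C stretching/bending bands near 1655 and
1265 cm⁻¹ that are present only for OA/LA and stronger for LA (two
double bonds) than OA (one). TAG counterparts differ by a +4 cm⁻¹,
1.3× broader C=O band, a shifted CH₂/CH₃-to-ester amplitude ratio,
replaced methyl-ester (862 cm⁻¹) versus glycerol-ester (820/875 cm⁻¹)
bands, and slightly shifted C=C bands — so the FAME→TAG difference
energy concentrates near 1740 and in the 1500–1400 and 900–800 cm⁻¹
regions, as the pipeline assumes; a property test requires at least 60%
of the squared difference there.

Band amplitudes and widths are package design values, versioned in
`inst/extdata/band_models.json` rather than code. One deliberate
calibration: each model's C=O amplitude is set so that every pure
spectrum within a class has the identical ester-band area (13.0 for
FAMEs, 16.5 for TAGs, arbitrary units). Physically this encodes "one
ester per mole"; mathematically it makes ester-band normalization
commute with linear mixing, so the noiseless closed loop is exactly
self-consistent.

Mixtures are linear in mole fraction with two noise terms, both relative
to the maximum pure-component intensity: i.i.d. Gaussian channel noise
(`sigma_rel`, default 0.01) and a random polynomial drift
(`drift_order` 2, `drift_amp_rel` 0.02) emulating fluorescence
undulation. These defaults were chosen once so that the closed-loop
prediction errors land in the few-percent regime typical of Raman
chemometrics. The mixture design — 165 training and 20 test
compositions by default — always contains the five pure vertices, the
ten 50/50 binary midpoints and the centroid, topped up with flat
Dirichlet draws over the simplex; this guarantees pure-component
presence and simplex coverage without favoring any species. All
randomness flows through explicit integer seeds; per-sample seeds are
scrambled from the global seed with a multiplicative mix so that nearby
global seeds do not share noise streams.

What the generator does *not* emulate: acyl–acyl interaction effects in
mixed TAGs (the transfer model itself assumes per-acyl additivity and
will degrade where chains interact), polarization and crystal-orientation
effects of solid fats, fluorescence photobleaching kinetics, detector
nonlinearity, and wavenumber miscalibration. Passing tests therefore
demonstrate internal correctness and noise robustness of the algorithms,
not instrument-grade accuracy on real samples.

## Model selection

The number of latent variables is chosen per model by 10-fold
cross-validation, taking the global RMSECV minimum (smallest count on
ties). NIPALS stops extracting components at the effective rank of the
problem: a component whose score spread falls below `rank_tol = 1e-4`
of the first component's is not extracted. This guard matters in the
noiseless closed loop, where the training spectra are exactly linear in
five components up to a ~0.2% preprocessing nonlinearity; without it,
cross-validation happily selects those minuscule directions (they are
consistent within the simulated population) and their near-zero score
variance turns into explosive regression coefficients on test spectra.

Spectral windows may be given explicitly — the five published per-acyl
window sets are built in as `table1_windows()` and are the default — or
searched greedily: starting from the empty set over the breakpoint
partition {650, 800, 930, 1110, 1200, 1280, 1380, 1500, 1700, 1800},
the region that most lowers RMSECV is added until no addition improves
it by more than 1e-6, with numerical ties (relative 1e-9) resolved in
favor of the higher-wavenumber region. Adjacent pool regions share one
endpoint; window validation therefore rejects only overlap of positive
measure.

Predictions are reported raw — they may fall below 0 or above 100 mole %
and are flagged, never clipped, and no sum-to-100 constraint is imposed:
the five modeled acyl groups need not exhaust a real fat, and the
composition summary reports the remainder as "unknown" (negative if
predictions over-sum, with a flag).

## Metrics and clustering

RMSE uses the $n$ denominator (accuracy against known values, in its
RMSEC/RMSEP roles); the sample SD uses $n-1$ (precision around a mean);
the standard error is SD$/\sqrt n$. The two denominators are
deliberately different and both tested against hand-computed values.

Per-sample compositions are clustered by Euclidean median linkage
(WPGMC): Lance–Williams updates on squared distances,
$d^2(k, i\cup j) = \tfrac12 d^2(k,i) + \tfrac12 d^2(k,j) - \tfrac14 d^2(i,j)$,
with heights reported as square roots, which reproduces the geometric
midpoint property (each merged cluster is represented by the midpoint of
its parents — the independent oracle the tests compare against). Ties
merge the lowest pair index. Median linkage can invert (a later merge
lower than an earlier one); nothing in the implementation assumes
monotone heights. Cutting into $k$ clusters undoes the last $k-1$
merges in agglomeration order — for monotone trees this is exactly
cutting the $k-1$ highest merges, and for inverted trees it still yields
exactly $k$ clusters, which a height-based cut cannot guarantee.

## Problem sizes and runtime

The test suite and the acceptance script run the full design (165
training, 20 test spectra, 1151 channels) for the end-to-end checks —
one such closed loop takes under two seconds on a single core — and
reduced designs (40 training samples, fixed latent-variable counts) for
the 20-seed comparison of transfer-trained versus directly FAME-trained
models, where only the ordering of errors matters, not their absolute
scale. Property tests over 100 seeds use a 5 cm⁻¹ grid.

## Known limitations

- The transfer model is strictly per-acyl additive; interaction effects
  between unlike acyl chains within one TAG are outside the model and
  will appear as unexplained residual on real fats.
- The PCA scores are class means; with very few replicates the loading
  direction absorbs some replicate noise, and the delta's advantage over
  a plain mean difference is then in its consistency, not magnitude.
- Low concentrations inherit the few-percent model error: a species
  present at 2 mole % cannot be reliably distinguished from zero.
- The greedy window search evaluates one region at a time; window
  combinations whose value only appears jointly can be missed. The
  built-in published window sets sidestep this for the five standard
  models.
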