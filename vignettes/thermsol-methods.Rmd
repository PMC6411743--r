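---
title: "Statistical methods for thermal proteome and solubility profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for thermal proteome and solubility profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermsol)
```

# The measurement problem

Thermal proteome profiling (TPP) heats aliquots of a cell lysate to a
gradient of temperatures and quantifies, by multiplexed (TMT) mass
spectrometry, how much of each protein remains soluble. A ligand that binds
a protein usually shifts its melting curve; measuring that shift across a
grid of ligand doses times temperatures (2D-TPP) turns a qualitative shift
into a half-maximal effective concentration, reported as
`pEC50 = -log10(EC50 in molar)`. Solubility proteome profiling (SPP) keeps
the temperature fixed and instead compares, per protein, the abundance
extracted with a mild detergent (NP40) over a ligand dose series against the
abundance extracted with a strong detergent (SDS); the SDS/NP40 vehicle
ratio measures how much of the protein sits in an insoluble state, and a
dose-dependent rise of the NP40 signal measures ligand-driven
solubilization.

`thermsol` implements the statistical layer of these experiments: the
dose-response model and its null comparison, the sliding temperature-window
F-statistics, a stratified permutation-based false discovery rate, hit
calling and affinity assignment, SPP normalization and insoluble-proteome
classification, melting-curve fitting with melting-point (Tm) extraction,
and protein-complex co-melting analysis. A set of generators produces
synthetic datasets with known ground truth in exactly the layouts the
analysis expects, so every stage is testable end to end without raw mass
spectrometry data.

# Models

## Dose-response and its null

The response of protein `i` in temperature window `j` and replicate `r` is
modeled as a four-parameter logistic in the log10-transformed molar dose
`x`:

```
mu(x) = c + (d - c) / (1 + exp(b (x - e)))
```

with slope `b`, lower level `c`, maximal level `d` and inflection `e`. The
null model is the intercept `mu = c`, whose least-squares solution is the
arithmetic mean. Because `x` is the log10 molar dose, the reported affinity
is `pEC50 = -e`; with this sign convention all fitted EC50s fall inside or
near the tested concentration window, which is the internal consistency
check for the convention. The vehicle (0 mM) measurement, whose fold change
is 1 by construction, enters the fit at a pseudo-dose two decades below the
lowest tested dose - the standard anchoring convention for dose-response
fits; `include_vehicle_point = FALSE` drops it.

Least squares is solved by a Levenberg-Marquardt loop (written in C++, as
the permutation scheme below refits tens of thousands of small series per
dataset) with a deterministic multi-start: `e` starts at every distinct
observed dose and at the median dose; the sign of `b` comes from the rank
correlation of dose and response; `c` and `d` start at the response range.
Parameters are clamped to `c, d` in `[0, 10 max(y)]`, `|b| <= 50` and `e`
within the observed dose range plus two decades; the convergence tolerance
is `1e-10` on the residual sum of squares with an iteration budget of 100
per start. On noise-free series the loop converges quadratically well
inside the budget (residuals reach machine precision); on noisy series the
objective can creep along a flat valley indefinitely, so a start that
exhausts its budget contributes its best point rather than being
discarded - dropping such fits would deflate the permuted score
distribution and bias the FDR downward. A fit on a degenerate dose axis,
or one whose residual sum of squares ends above the null model's, is
replaced by the null-equivalent result, so the derived F component is zero
rather than negative.

## Sliding-window F-statistics (2D-TPP)

Fold changes are computed against the vehicle at the same temperature,
plex and replicate, then median-centered on the log2 scale within each TMT
label, and the vehicle is re-pinned at exactly 1. For every pair of
adjacent temperatures the (dose, fold change) points of both temperatures
are pooled per replicate - a ligand-induced stability change should appear
at two consecutive temperatures, and pooling doubles the points per fit
without biasing the inflection, since both temperatures share it. The
per-replicate component is `(RSS_H0 - RSS_H1) / RSS_H1`, floored at zero;
the window score `F_ij` is the median over replicates. A perfect fit
(`RSS_H1 = 0`) would yield an infinite component; such sentinels are
replaced by the largest finite component in the dataset so a single exact
interpolation cannot dominate the median.

Windows only count when their extreme fold change (the value with the
largest `|log2|`) passes the gate `phi_max > h` or `phi_max < 1/h`, with
`h = 1.5` throughout. The per-protein score sums `ln(F_ij)` over gated
windows - a log-scale combination that behaves like a geometric mean and
limits the leverage of outlier windows. As printed, the sum could admit
negative terms when `F_ij < 1`; a window whose sigmoid barely beats the
intercept carries no evidence and should not cancel signal elsewhere, so
negative log terms are floored at zero by default
(`allow_negative_log_terms = TRUE` restores the literal sum).

## Permutation FDR

Significance comes from permutations rather than an F distribution: the
per-protein scores are not classically distributed (pooled windows, median
over replicates, gated log-sums). Non-vehicle fold changes are shuffled
jointly across proteins, doses and replicates within strata of identical
temperature and qupm category (the number of unique quantified peptides,
binned `2, 3, 4, 5+`) - temperature and peptide count both drive the noise
level, so stratifying keeps the permuted data exchangeable with the
original under the null. Vehicle references are never moved. For every
candidate threshold `theta` (each distinct original score), with `r`
original scores and `v_b` permuted scores at or above it, the FDR estimate
averages `2 v_b / (r + v_b)` over the `B` permutations (default 100; ties
on the permuted side count as hits, which is conservative, and the printed
factor 2 is used as given). The raw curve is monotonized by a cumulative
minimum from the loosest to the strictest threshold - so a higher-scoring
protein never receives a larger FDR than a lower-scoring one - and clipped
to `[0, 1]`, since the raw estimate can exceed 1 for small `r`. Hits
require FDR at or below 1% and a nonzero combined score. Permutation seeds
are derived from the master seed by counter, so results do not depend on
execution order.

## pEC50 assignment

Each hit receives the median over replicates of `-e` fitted in the window
starting at the lowest temperature where the gate fold change was observed
in at least two replicates, clipped to `[min tested pEC50 - 1,
pseudo-vehicle pEC50]`. Replicate fits whose inflection lands on the
parameter box are not identified and are excluded from the median; if a
window yields no usable replicate fit, the next qualifying temperature is
tried. The estimate is reported at the onset temperature of the effect,
where the amplitude is by construction near the gate - precise for EC50s
inside the tested dose window, and increasingly an extrapolation for more
potent ligands (see Limitations).

## SPP

Intensities are normalized by a simplified variance-stabilizing transform:
each sample is calibrated onto the protein-wise median reference by a
robust affine fit (least trimmed squares), passed through the generalized
log `glog2(x) = log2((x + sqrt(x^2 + c^2))/2)` with the shoulder `c` at the
5% quantile of the reference, and back-transformed to the raw scale; fold
changes are then taken against the NP40 vehicle of the same replicate.
The contract is variance flattening across the intensity range and removal
of per-sample scale - bit-compatibility with the published vsn algorithm is
a non-goal. The calibration presumes that most proteins do not change
between samples; it holds in the published designs (roughly a tenth of the
proteome is insoluble) and degrades if a majority of proteins respond.

A protein belongs to the insoluble proteome when its replicate-median
SDS/NP40 vehicle ratio is at least 1.5 - at least 50% more protein
extracted by the strong detergent, boundary inclusive. Dose-dependent
solubility changes are detected like 2D-TPP effects collapsed to a single
temperature: proteins whose median fold change reaches `h` (or `1/h`) at
one or more doses are fitted once across all pooled replicates against the
intercept null, scored with the same F-statistic, and assessed with the
same permutation FDR with strata reduced to qupm bins. Hits require both
the 1% FDR and the fold-change gate, and get `pEC50_s = -e` from the joint
fit, clipped to the tested dose range plus one decade on either side. Fits
use raw ratios; `fit_on_log = TRUE` switches to log2 ratios.

## Melting curves and co-melting

TPP-TR profiles (fractions normalized to the lowest temperature) are
fitted with the plateau sigmoid in inverse temperature,
`f(T) = (1 - p)/(1 + exp(b - a/T)) + p`, the functional family of the
established TPP analysis tools; Tm solves `f(Tm) = 0.5` in closed form and
exists only when the fitted curve crosses 0.5 within the measured range
plus 5 degrees C. Fits are flagged valid when `r2 >= 0.8` and the plateau
is below 0.3 (both configurable), common practice for melting-curve
quality control.

The co-melting distance between two profiles is the average squared
per-temperature deviation. On 10-point profiles with values in `[0, 1]`,
the published proximity cutoff of 0.02 is dimensionally consistent with an
averaged squared quantity, not with a root-sum-square (which would exceed
it for any visible separation); `comelt_metric = "rss"` is available for
sensitivity analysis. Complexes require at least three quantified
subunits; the observed statistic is the mean pairwise distance, the null
distribution is the same statistic over random same-size subsets of all
quantified proteins, and the p-value carries the `+1` correction, making
it valid (stochastically at least uniform) under the null by construction.
Group comparisons of melting-point shifts or solubilization use Wilcoxon
signed-rank (paired) or rank-sum (unpaired) tests; protein class labels
are user-supplied.

# The synthetic-data generators

The generators emit the published layouts exactly: 2D-TPP with five
concentrations (vehicle plus 0.005, 0.05, 0.5 and 2 mM by default) over
ten temperatures (42-60.1 degrees C), one TMT10 plex per pair of
neighboring temperatures, three replicates; SPP with one NP40 vehicle,
eight NP40 doses (0.1-10 mM) and one SDS vehicle per TMT10 plex, three
replicates; TPP-TR with ten temperatures (37.0-66.3 degrees C), vehicle
versus treated, two replicates.

Per protein, a vehicle melting curve is drawn from the plateau-sigmoid
family with Tm uniform in 45-55 degrees C, plateau in 0.02-0.15 and
steepness `a = 1100`, which gives a 10-90% transition width of roughly 10
degrees C at Tm 50 - typical of human TPP data. In 2D layouts the dose
effect follows the four-parameter logistic with the protein's true pEC50
and a Hill-type slope of 1 (the natural choice for single-site binding),
and its amplitude ramps in proportionally to the melted fraction of the
vehicle curve: at temperatures where the protein is still fully folded
there is nothing to stabilize, which is exactly the structure the sliding
window statistic exploits. Class fractions default to 10% stabilized and
2% destabilized, matching the published proportions. In SPP layouts the
SDS vehicle carries the total abundance, the NP40 vehicle the soluble
share, and solubilized proteins release a sigmoidal share of their
insoluble pool (full release at saturation by default), so mass balance -
NP40 never above SDS in expectation - holds by construction; about a tenth
of the proteome is insoluble (fraction 0.4-0.9), and a quarter of that is
solubilizable. Complex subunits share one melting-profile template plus a
configurable Tm jitter.

Noise is multiplicative lognormal with a stated coefficient of variation
(default 0.1; the source study does not state noise magnitudes, so the
default is a generator choice representative of TMT protein-level ratios),
applied per measurement with mean exactly 1. The generators are pure
functions of their configuration and seed.

What the generators do not emulate: peptide-level variation and rollup,
missing values beyond incomplete layouts, isotope impurity, batch effects
between plexes beyond a per-label scale (which the median normalization
removes by design), and correlated noise between doses of one plex.
Passing the suite therefore demonstrates that the statistics are
implemented correctly and calibrated under the stated noise model, not
that real acquisitions meet that model.

# Numerical choices and degenerate inputs

* Dose series with fewer than `min_points_per_fit` (default 5) usable
  points are skipped silently at the pipeline level; replicates drop out
  of the window median individually.
* A missing vehicle drops the affected temperature for that plex, logged.
* `F` components: `rss1 = 0` with `rss0 > 0` gives an infinity sentinel,
  capped at the dataset's largest finite component; `rss0 = rss1 = 0`
  gives 0.
* Insoluble classification with a zero NP40 vehicle returns an infinite
  ratio, an insoluble call and a flag.
* All-tied paired differences make the signed-rank p-value `NA` rather
  than 1.
* The LTS calibration samples subsets internally; it runs under a fixed
  local RNG state, and the caller's random stream is untouched.

# Problem sizes used in the checks

The test suite exercises the pipelines at 200 proteins, 10 temperatures,
5 doses and 3 replicates with 50 permutations; FDR calibration averages 20
independent null datasets, power and recovery use two spiked datasets per
pipeline, and the randomization test's null calibration uses 200 runs of
199 randomizations. The acceptance script reproduces the same quantities
at the same sizes (10 null datasets). These sizes hold the sampling error
of the reported rates near one percentage point.

# Known limitations

* pEC50 assignment at the effect-onset temperature is noisy by design (the
  amplitude there is near the gate) and, for ligands more potent than the
  lowest tested dose, relies on the pseudo-dose vehicle anchor: the anchor
  pins the fold change at 1 two decades below the lowest dose, while the
  true curve of a sub-range EC50 is already rising there, so the
  least-squares optimum - not merely the optimizer - is biased toward
  weaker affinities by up to a decade. Median absolute recovery errors
  under the synthetic conditions are about 0.2 decades for EC50s inside
  the tested window and 0.5-1 decade beyond it. Dose series should be
  designed to bracket the affinities of interest.
* The SPP `pEC50_s` clip to the tested dose range plus one decade bounds
  reported potencies at the low-dose edge; more potent solubilizers are
  reported at the clip.
* The simplified variance-stabilizing normalization assumes a majority of
  unresponsive proteins per sample.
* The co-melting proximity cutoff 0.02 is calibrated for 10-point
  profiles on the average-squared-deviation scale; profiles on other
  grids need a recalibrated cutoff.

# A worked run

```{r example, eval = FALSE}
library(thermsol)

sim <- simulate_2dtpp(sim_config("TPP_2D", n_proteins = 100, seed = 42,
                                 noise_cv = 0.05))
res <- tpp2d(sim$quant, sim$meta,
             analysis_config(n_permutations = 50, seed = 42))
print(res)
merge(res$scores[res$scores$hit, ], sim$truth)[, c("protein_id", "direction",
                                                   "pEC50", "true_pEC50")]
```
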