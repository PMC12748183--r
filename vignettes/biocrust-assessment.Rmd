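---
title: "Assessing biocrust restoration experiments: indices, SQI and GRA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing biocrust restoration experiments: indices, SQI and GRA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biocrustr)
```

## The assessment problem

A biocrust restoration experiment sprays microbial inocula (diatoms,
*Bacillus megaterium*, or a mixture) onto degraded soil and asks, after a
growth period, whether the treated soil is *better*. "Better" spans a dozen
indicators measured per pot — saturated water content (SWC), aggregate
stability (MWD, GMD, PAD), pH, organic carbon (SOC), total and available
nitrogen and phosphorus (TN, TP, AN, AP), and enzyme activities (sucrase
SC, urease UE) — in two layers (the crust itself and the soil beneath),
plus plant biomass. This package condenses those measurements into three
comparable summaries: per-indicator effect percentages, a weighted Soil
Quality Index, and a grey relational ranking. Everything operates on a
validated treatment × replicate × indicator table (`indicator_matrix()`)
with per-indicator direction metadata kept in configuration, not in the
data file: larger values are favourable for every indicator except pH and
PAD, which are smaller-the-better.

## Aggregate stability indices

Dry sieving fractionates mechanically stable aggregates, wet sieving
water-stable ones; both use four size classes (>2, 2–0.25, 0.25–0.053,
<0.053 mm). For normalized mass fractions $W_i$ and class mean diameters
$X_i$,

$$\mathrm{MWD} = \sum_i X_i W_i, \qquad
  \mathrm{GMD} = \exp\Big(\sum_i W_i \ln X_i\Big),$$

and with $DR_{0.25}$, $WR_{0.25}$ the dry/wet >0.25 mm contents,

$$\mathrm{PAD} = \frac{DR_{0.25} - WR_{0.25}}{DR_{0.25}} \times 100.$$

Numerical choices:

* **Fraction normalization.** Inputs may arrive as raw masses, percentages
  or fractions; they are always renormalized to sum 1 before either index
  is computed. The geometric mean in particular is meaningless on
  percentage weights, so normalization is not optional. Both indices are
  therefore invariant to rescaling all masses, and by the weighted AM–GM
  inequality GMD ≤ MWD always.
* **Class mean diameters.** Sieving reports bounds, not means. Interior
  classes use bound midpoints; the open ">2 mm" class uses 1.5× its lower
  bound (giving 3.0 mm) and the open "<0.053 mm" class half its upper
  bound. The defaults (3.0, 1.125, 0.1515, 0.0265 mm) are configurable via
  `sieve_scheme()` since labs differ here.
* **Negative PAD.** If wet sieving retains more coarse material than dry
  sieving, PAD is negative. It is reported as computed (and flagged in
  printing), never clamped: a sign carries information about cementation.
* All computation is at full precision; rounding to the conventional two
  decimals happens only in reports.

Degenerate inputs fail loudly: an all-zero composition, a scheme without a
0.25 mm boundary, a zero dry-mode $DR_{0.25}$, and mismatched dry/wet
schemes are each distinct errors.

## Chain-method surface roughness

A chain of length $L_1$ draped over the crust projects to a shorter
horizontal length $L_2$; roughness is $C_r = (1 - L_2/L_1)\times 100$,
zero for a flat surface, scale-invariant, strictly decreasing in $L_2$.
Field practice takes several placements per pot in the inter-plant spaces;
`mean_chain_roughness()` averages placements arithmetically, the natural
choice when no placement is privileged. The bundled default chain length is
43.0 mm.

## The minimum-data-set Soil Quality Index

The SQI pipeline has four phases, all parameters exposed with the
conventional defaults:

1. **PCA** on the Pearson correlation matrix of the pooled samples
   (`correlation_pca()`). Indicators are implicitly z-scored; directions
   are *not* sign-flipped here — direction enters only at scoring. Loadings
   are eigenvectors scaled by $\sqrt{\lambda}$; each loading column is
   oriented so its largest-magnitude entry is positive, purely for
   reproducible reports (all selection rules use absolute values).
2. **Retention** by the Kaiser criterion: components with eigenvalue ≥ 1
   (`kaiser_threshold`, inclusive at the boundary).
3. **Selection.** Per retained component, candidates are indicators with
   absolute loading within 10% of that component's maximum
   (`loading_window = 0.10`). An indicator falling in several components'
   windows is assigned to the component where its loading is largest and
   counted once. Within a component, candidates connected by pairwise
   |r| ≥ 0.60 (`redundancy_r`) form a redundancy group and contribute a
   single indicator: the member with the largest communality over the
   retained components (the per-variable "variance explained" quantity),
   ties broken by loading magnitude, then input order. Components are
   processed in variance order, and a later component's candidate is
   dropped when it already correlates at |r| ≥ 0.60 with a selected
   indicator — this cross-component screen is what lets a retained
   component contribute nothing when its information is already
   represented, which is routinely observed in published minimum data
   sets.
4. **Weighting and scoring.** Weights are normalized communalities,
   $W_i = h_i / \sum_j h_j$, so they are non-negative and sum to one.
   Each MDS indicator is scored by a piecewise linear function: 0 below
   the lower threshold, 1 above the upper, linear between
   (mirrored for smaller-the-better indicators). Thresholds default to the
   observed min/max of the indicator across all samples — which spans the
   full [0, 1] score range within the study — and can be overridden with
   fixed agronomic thresholds when cross-study comparability matters.
   Finally $SQI = \sum_i W_i S_i \in [0, 1]$, computed per pot and averaged
   per treatment (per-pot computation preserves within-treatment
   dispersion; a means-only mode is available via `per_replicate = FALSE`).

The index is monotone: improving any MDS indicator in its favourable
direction, holding selection, thresholds and weights fixed, never lowers
the SQI.

### What indicator selection can and cannot recover

The test suite exercises selection on planted data
(`generate_planted_blocks()`): 12 indicators in 4 latent blocks of 3,
within-block correlation 0.85, uncorrelated across blocks, 40 samples.
When every block surfaces in some retained component's loading window, the
pipeline provably selects exactly one indicator per block, and the suite
asserts this conditional property sharply. Coverage itself, however, is
limited by the spectrum: with *equal* within-block correlations the four
block eigenvalues of the population correlation matrix are exactly
degenerate (each $1 + 2 \times 0.85 = 2.7$), so sample principal components
rotate freely inside the leading four-dimensional eigenspace and a rotated
component can hide an entire block below the 10% loading window. Across
300 planted seeds, all four blocks reached a window in 74% of runs — and
recovery equalled coverage exactly, i.e. the selection rules extract
everything the windows offer. Without factor rotation (deliberately out of
scope, as the standard minimum-data-set procedure uses unrotated
components) no selection rule can beat that ceiling; real indicator sets,
whose blocks are never exactly exchangeable, do not sit at this worst
case.

## Grey Relational Analysis

GRA ranks entities by closeness to an idealized reference. Stages: select
indicators; standardize each column to [0, 1] with the favourable pole at
1 (min–max for larger-the-better, mirrored for smaller-the-better), which
makes the reference sequence the all-ones vector — constructing the
reference after standardization is numerically equivalent to taking
per-indicator optima before it, and simpler; compute absolute deviations
from the reference and their global extrema $\Delta_{\min}, \Delta_{\max}$
(0 and 1 after min–max standardization with non-constant columns);
coefficients

$$\eta_i(k) = \frac{\Delta_{\min} + \rho\,\Delta_{\max}}
                   {\Delta_i(k) + \rho\,\Delta_{\max}},$$

with the distinguishing coefficient $\rho = 0.5$ by default ($\rho$
compresses all coefficients toward 1 as it grows but preserves the
deviation ordering); and the grade $r_i = \frac{1}{n}\sum_k \eta_i(k)$,
deliberately unweighted. With $\rho = 0.5$ and min–max standardization
every coefficient and grade lies in [1/3, 1]. A constant indicator across
entities is a degeneracy error naming the indicator; exact agreement with
the reference under $\rho = 0$ is guarded to $\eta = 1$.

Entities default to treatment means over replicates (one grade per
treatment); `entity_mode = "per_replicate"` treats every pot as an entity
to expose within-treatment dispersion. Grades are invariant to indicator
order and entity labels, and a treatment that dominates every indicator in
its favourable direction grades exactly 1.

## The synthetic-data generator

`generate_experiment()` emulates the four-treatment pot experiment: values
are `baseline × treatment shift + Gaussian noise`, three replicates per
treatment. The default profile (`default_soil_profile()`) takes the
physical-indicator baselines, shifts and noise standard deviations directly
from the bundled published treatment means ± sd (SWC, MWD, GMD, PAD);
chemical and enzymatic baselines use the published initial-soil values of
the source site (pH 7.03, SOC 13.89 g/kg, TN 1.14 g/kg, TP 110.38 mg/kg)
together with field-typical alkaline-N (60 mg/kg), available-P (10 mg/kg),
sucrase (20 mg glucose/g/24 h) and urease (0.5 mg NH₄⁺-N/g/24 h) levels;
their shift ratios follow the published percentage changes and orderings
(diatom: SOC +21%, AN +12.8%, AP +48%, sucrase +47.9%, lowest pH;
*B. megaterium*: TN +30%, urease +190%; mixed crust: strong structural
gains but mild nutrient and enzyme depletion). Each (treatment, indicator)
cell draws from an independent stream seeded by a stable hash of its
labels, so adding an indicator never perturbs the others and the output is
a pure function of (profile, seed). Positive-only indicators are drawn by
truncation-by-resampling (cap 100 retries) rather than absolute value,
which leaves means essentially undistorted at the small truncation
probabilities involved.

What the generator emulates: treatment-mean structure, replicate-level
Gaussian noise at published magnitudes, direction conventions. What it does
not: between-indicator residual correlations within a pot beyond those
induced by treatment structure, layer coupling (crust vs. soil values are
generated independently if both are wanted), measurement censoring, or any
mechanistic soil process. Passing tests therefore demonstrate the
*machinery* — selection, weighting, ranking, reproducibility — under
realistic magnitudes, not field validity of any particular index value.
In particular the published index levels themselves (SQI ≈ 0.4–0.6) are
not reproducible without the underlying raw per-pot matrix, which was not
deposited; the suite instead asserts the distributional claim that
directionally faithful effect profiles rank both single-inoculum
treatments above control and the mixed crust in ≥ 90% of seeded runs
(observed: 93/100).

## Problem sizes and runtime choices

The test and acceptance workloads are sized for quick iteration: 100
random 4×10 GRA instances against a loop-level oracle (equality to
1e-12), 20 random 6-indicator PCA instances against `prcomp` (1e-10),
1000 random sieve compositions for the AM–GM and simplex properties, 100
seeded runs each for the directional-ordering and planted-block recovery
rates, and 300 seed-averaged experiments for the generator's mean
calibration (each cell within three standard errors of its configured
mean). The whole suite completes in well under a minute.

## Known limitations

* Significance testing (ANOVA, multiple-range letters) is intentionally
  absent; the package computes indices, not inference, and standard R
  tools apply directly to its outputs.
* Observed-range scoring thresholds make SQI values study-relative;
  cross-study comparisons need fixed thresholds supplied explicitly.
* The planted-block recovery ceiling discussed above: indicator sets with
  exactly exchangeable correlated blocks are adversarial for unrotated
  PCA selection.
* Unbalanced designs are rejected rather than handled; the intended
  experiments are small and complete.
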