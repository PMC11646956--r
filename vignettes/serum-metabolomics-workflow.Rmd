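---
title: "QC-driven preprocessing, PLS-DA validation and pathway enrichment for untargeted serum metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QC-driven preprocessing, PLS-DA validation and pathway enrichment for untargeted serum metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serumPLS)
```

## The analysis this package implements

`serumPLS` implements the downstream statistical workflow of a multi-platform
(LC-MS + GC-MS) untargeted serum metabolomics study of a three-group male
cohort (White European, South Asian, African Caribbean; 287/143/142 subjects,
ages 40–86). Starting from deconvolved peak tables it covers:

1. **Pooled-QC based feature filtering** — presence in at least 10% of QC
   injections (inclusive), QC relative standard deviation strictly below 40%,
   and a blank signal ratio filter.
2. **Signal-drift correction** — per-feature, per-batch LOESS smoothing of
   pooled-QC intensities over injection order (QC-RLSC), division of every
   injection by the interpolated curve, and between-batch rescaling on QC
   medians.
3. **Imputation and scaling** — cubic-spline imputation of missing cells over
   the acquisition order, log10 transformation, Pareto scaling.
4. **PLS-DA classification** with bootstrap validation (out-of-bag test
   sets), permutation null models, and optional SMOTE class balancing.
5. **VIP-based feature selection** (VIP > 1 and top-10% modes) with
   accurate-mass adduct annotation and plausibility gating.
6. **Mummichog-style pathway enrichment** — nonparametric feature ranking,
   m/z-to-compound mapping, one-tailed Fisher's exact tests, a resampling
   adjustment, and Benjamini–Hochberg FDR control.

A synthetic-data generator reproduces the statistical structure these methods
assume, with recorded ground truth, so every stage can be validated by
parameter recovery.

## The discriminant model

PLS-DA regresses the centred one-hot class indicator matrix
$Y \in \{0,1\}^{n \times k}$ on the centred intensity matrix
$X \in \mathbb{R}^{n \times p}$ by NIPALS PLS2. For each component $a$ the
weight vector $w_a$ is the dominant left singular vector of $X_{a-1}^T
Y_{a-1}$ (found by the NIPALS power iteration), scores are $t_a = X_{a-1}
w_a$, and both blocks are deflated by the rank-one approximation. The
iteration is run on the $k \times k$ cross-product $Z^T Z$ with
$Z = X_{a-1}^T Y_{a-1}$, which has the same fixed point as the classical
score/weight alternation but costs one $O(npk)$ product per component. Each
weight vector is unit-norm with a deterministic sign (largest-magnitude
element positive), so fits are reproducible. A new sample is assigned the
class with the largest predicted indicator value; exact ties go to the
lexicographically first label.

Variable importance in projection aggregates the squared weights across
components, weighted by the Y-variance each component explains,

$$\mathrm{VIP}_j \;=\; \sqrt{\,p \cdot
  \frac{\sum_a \mathrm{SSY}_a (w_{aj}/\lVert w_a\rVert)^2}
       {\sum_a \mathrm{SSY}_a}}, \qquad
  \mathrm{SSY}_a = \lVert q_a \rVert^2 \, (t_a^{\!\top} t_a),$$

which normalises so that the mean of squared VIPs over the model's features
is exactly 1 — the property the test suite asserts to $10^{-8}$.

### Validation design

"Test sets" are the out-of-bag samples of each bootstrap resample: the
training set is drawn with replacement ($n$ of $n$), and the roughly
$n(1-1/e) \approx 0.632n$ unique drawn samples train the model while the
remainder are scored. The component count is chosen per training set by an
inner 7-fold cross-validation over $A \in [1, 15]$ (misclassification loss,
ties to the smaller $A$); there is no canonical component count for this
kind of data, so selecting it inside the resampling loop is the neutral
choice. Null models repeat one full bootstrap cycle per iteration with
permuted labels; the empirical p-value of the observed mean CCR is
$(1 + \#\{\text{null} \ge \text{observed}\})/(n_{\mathrm{perm}} + 1)$.

SMOTE is exposed in three modes: `off` (default), `fold` (balancing applied
to each bootstrap training set only, so no synthetic point ever reaches a
test set) and `global` (balancing before resampling, as is sometimes done in
practice, at the cost of leakage). The leak-free mode is the default because
out-of-bag error estimates are only honest when test samples are real.

## Preprocessing choices and their rationale

* **Boundary semantics.** QC presence is inclusive ("at least 10%"); QC RSD
  is strict ("less than 40%"); blank ratio is inclusive at its threshold.
  The RSD uses the sample (n−1) standard deviation.
* **Blank ratio threshold.** No specific fold-change is standard; the
  default is 3 (`filterConfig(blank_ratio_min = 3)`), a common practice
  value, and a feature with no observed blank signal is kept.
* **Drift model.** Degree-1 LOESS with span 0.75 of the QC points per batch,
  fitted per feature and batch, with direct-surface prediction so injections
  outside the QC range are extrapolated rather than clamped. Batches with
  fewer than 4 QCs fall back to a median-ratio (constant) correction with a
  warning; features whose fitted divisor is non-positive anywhere are
  flagged and left uncorrected rather than corrupted.
* **Stage order.** Imputation runs after drift correction (splines operate
  on the drift-corrected scale) and before the log transform; QC and blank
  injections are dropped before the transformation stages because the
  downstream statistics operate on study samples.
* **Zeros before log10** are replaced by half the feature's minimum positive
  value, the standard detection-limit surrogate.
* **Pareto scaling** divides the centred feature by the square root of its
  SD, so a scaled feature's variance equals its pre-scaling SD — a defining
  property the tests assert, alongside idempotence of the filter stages on
  their own output.

## What the synthetic generator emulates — and what it does not

The generator reproduces, per acquisition batch: blanks, an opening pooled
QC, study samples with a QC every 10 injections, and a closing QC. Feature
baselines are log-normal (log10 means uniform on [4, 7]); biological
between-subject scatter is 0.2 log10 units (roughly a 50% biological CV,
mid-range for serum); pooled QCs are the cohort mean profile with 5%
technical CV; blanks carry 2% of the median sample signal; a smooth
multiplicative cubic drift with 10% maximum amplitude acts per batch; and
missingness is intensity-dependent (logistic in standardised log intensity,
calibrated to the requested overall rate), mimicking detection-limit
censoring — which is what makes spline imputation meaningful. Planted
class-discriminative features receive a +0.3 log10 mean shift in one
affected class each, features being assigned to the classes in rotation; the
`"small"` preset plants 5% of 200 features, the `"paper"` preset scales the
feature counts to the study's 1758 (LC) or 1253 (GC).

Acquisition details such as batch count or QC spacing are cohort-run
properties the workflow cannot infer from a feature table; 4 batches
and a QC every 10 injections are typical presets, not study facts. The
generator does **not** model chromatographic peak shapes, isotope patterns,
correlated metabolite modules, retention-time drift, or adduct multiplicity
per metabolite — so passing recovery tests demonstrate that the statistics
behave correctly under the stated noise model, not that real serum data will
reach the same classification rates.

The demographic defaults mirror the study cohort (group sizes 287/143/142;
ages 63.66±10.68 / 56.97±11.12 / 54.01±10.63 years truncated to [40, 86];
BMI 27.47±3.89 / 27.75±3.70 / 27.80±4.86 kg/m²; covariate rates derived
from the printed drinker/smoker/morbidity counts). One printed demographic
cell (White European alcohol, "74: 141 (0.34)") is internally inconsistent —
74/141 ≈ 0.52 but 74/215 ≈ 0.34, suggesting the denominator of the printed
ratio included the 72 subjects with missing alcohol data; both readings are
noted here and that cell is excluded from exact-reproduction checks. The
White European smoking cell (21:266, printed 0.07, recomputed 0.08) has the
same character.

## Numerical and design decisions

* **RSD vs %CV.** The filtering description treats "relative standard
  deviation" and "coefficient of variance" as one 40% threshold; they are
  the same quantity and are implemented as a single filter.
* **Feature-wise between-batch normalisation.** Whether between-batch LOESS
  normalisation acts feature-wise or globally is ambiguous in the source
  description; feature-wise is the standard QC-RLSC reading and is what is
  implemented.
* **Nonparametric ranking.** Two groups use the Mann–Whitney U test, exact
  when both groups have ≤ 8 observations and no ties; three or more groups
  use Kruskal–Wallis with the chi-square approximation. For the exact MW
  path the test suite checks equality with full enumeration of rank
  assignments. For KW the H statistic is checked against a from-scratch
  computation; at the tiny sizes where full permutation enumeration is
  feasible the chi-square p is an approximation by construction, so the
  tests assert the statistic exactly and the p-value as the chi-square tail
  of that statistic.
* **Enrichment.** Compound-level (not empirical-compound/isotope-level)
  mapping: a feature may map to several compounds, and each compound counts
  once in the significant set regardless of how many features or adducts hit
  it, preventing multi-adduct double counting. The Fisher test is one-tailed
  for enrichment — the only direction a pathway over-representation claim
  can take; the resampling adjustment redraws random feature sets of the
  significant set's size through the same m/z mapping, with 1000 draws by
  default. Headline enrichment p-values reported for real cohorts depend on
  the real feature lists and the database versions used to map them, and are
  not reproducible at desk scale; the bundled 12-compound,
  4-pathway table is explicitly a toy stand-in, and larger random libraries
  for calibration are generated in code.
* **Annotation.** Positive-mode adducts [M+H]+, [M+Na]+, [M+K]+, [M+NH4]+
  with a 5 ppm default tolerance (none is stated in the source study);
  accurate-mass-only matches are MSI level 3 at best. Plausibility rules
  relabel implausible candidates (e.g. a lipid eluting in the first two
  minutes of a reversed-phase gradient) as "unknown/unidentified" rather
  than dropping them.
* **Welch t-tests** for the pairwise per-metabolite group comparisons
  ("pairwise t-test" is otherwise unspecified), BH-adjusted across pairs.
* **Ratios at caller precision.** The printed demographic table is
  inconsistent in its own rounding (1.5 vs 1.09), so `groupRatio` takes the
  number of decimals as an argument.

## Problem sizes used by the validation suite

The test suite and acceptance script exercise the full stack at a scale
chosen so the whole run completes in minutes: the `"small"` preset (572
subjects, 200 features, 4 batches) with 200 bootstrap and 200 permutation
iterations for the planted-effect study, chance-level checks at n = 120 with
200 permutations, VIP normalisation over 50 random models, oracle-equality
sweeps (20 random PLS problems; every 2×2 enrichment table over universes up
to 30 compounds; full Mann–Whitney enumeration up to 6 + 6), and enrichment
null calibration over 50 independent no-effect runs. The bootstrap and
permutation counts used in a real analysis (1000 each, the package defaults)
simply scale these up.

## Known limitations

* The GC platform is emulated only through its feature-table shape; true
  fragment-spectrum library matching (and hence MSI level 2 identification)
  is out of scope, and GC features are annotated by accurate mass against
  the bundled table as a stand-in.
* LOESS drift correction assumes a smooth drift captured by ≥ 4 QCs per
  batch; pathological QC layouts degrade to median-ratio correction.
* Spline imputation over injection order borrows signal from neighbouring
  injections, which are different subjects; it is the stated method of the
  workflow, not an endorsement of its optimality.
* The empirical p-value floor is $1/(n_{\mathrm{perm}}+1)$; "p = 0.005" from
  200 permutations means "never exceeded", not a precise tail estimate.
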