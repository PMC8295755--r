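---
title: "Methods: quantitative genetics of drought response from tree rings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative genetics of drought response from tree rings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(provdrought)
```

# The estimation problem

A provenance trial plants seed sources from across a species' range in one
common garden, removing site effects from among-population comparisons.
Increment cores taken decades later contain, for every tree, a yearly growth
record spanning several droughts. Treating each drought as a repeated
measurement of the same individuals lets three quantities be estimated:

* **how strongly** growth responds to drought (resistance and recovery),
* **how consistently** provenances rank across droughts (phenotypic
  stability), and
* **how much of the variation is anchored in the individual** —
  repeatability, the intraclass correlation that bounds heritability from
  above, and from it the coefficient of additive genetic variation
  ($CV_A$), a mean-standardized upper bound on evolvability.

This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic-data generator does and does not emulate.

# Drought identification

## Site precipitation

Monthly precipitation from surrounding stations is combined by inverse
distance weighting with weights $d^{-p}$ on great-circle distances
(default power $p = 2$, the geostatistical convention). A site within 1 m
of a station takes that station's series verbatim; the tolerance merely
avoids dividing by a near-zero distance. IDW output is always inside the
per-month range of the contributing stations.

## SPI

The standardized precipitation index at scale $k$ months transforms the
backward-looking $k$-month sum ending in each month into a standard-normal
quantile. Per calendar month, a gamma distribution is fitted to the
positive sums of a calibration window (default: the full series; at least
20 defined sums are required, otherwise the month is left missing). Zero
sums receive a point mass $q = n_0/(n+1)$ — the plotting-position variant,
which keeps $q$ away from 0 and 1 — and the mixture
$H(x) = q + (1-q)\,G(x)$ is mapped through $\Phi^{-1}$.

The gamma fit solves the exact likelihood equation
$\log\alpha - \psi(\alpha) = \log\bar x - \overline{\log x}$ by Newton
iteration started from Thom's closed-form approximation; the scale is
$\bar x/\alpha$. Because the equation is solved to relative tolerance
$10^{-12}$, the fit agrees with any other maximum-likelihood route to
numerical precision — the test suite checks agreement with an
independently coded brute-force optimiser to $10^{-6}$ on the SPI scale.

Two deliberate guards: a calendar month whose calibration sums are all
numerically equal gets SPI 0 (the median of a degenerate distribution),
and $H$ is clamped to $[\tfrac{1}{2(n+1)}, 1-\tfrac{1}{2(n+1)}]$ so that
sums far outside the calibration support map to the most extreme quantile
$n$ observations can justify rather than to $\pm\infty$. The clamp caps
|SPI| at about 2.9 for a 40-year calibration; users who need deeper tails
should calibrate on longer series.

One property worth stating precisely: the SPI transform pins the fitted
mean and geometric mean, not the median, so the per-calendar-month sample
median of SPI values is an order statistic with standard error
$\approx \sqrt{\pi/2}/\sqrt{n}$ — about 0.2 at $n = 40$. Normalization
checks on the median are therefore only meaningful on long series; the
package's property test uses a 1000-year synthetic series, where the
median band $\pm 0.15$ and the SD band $[0.8, 1.2]$ hold per calendar
month.

## Event selection

Detection flags a calendar year when any growing-season month
(April–September by default) at any requested scale (default 1 and 3
months, the scales on which short agronomically relevant droughts appear)
falls below a threshold (default $-1.5$, the "severe" class boundary;
moderate/severe/extreme are $< -1$, $< -1.5$, $< -2$ with strict
inequalities). In practice drought years for comparative analysis are
curated by inspection of the SPI plots, so a configured event list
overrides detection verbatim and detection is advisory. Event lists may
differ per site: consecutive dry years can hit one species a year earlier
than another, and the configuration mirrors that rather than arbitrating
automatically.

# Resistance and recovery

Both indices are ratios of raw ring widths, so they are invariant to any
per-tree rescaling (age, vigour, measurement units) and deliberately not
computed on basal-area increments: changing the dimensionality of the
trait changes its variance and hence every downstream variance component.

* $Res = I_{dr}/I_{9yr}$ with $I_{9yr}$ the arithmetic mean of the 9-year
  window centred on the event. The window includes the drought year
  itself; whether to exclude it is a genuine fork — exclusion makes the
  reference slightly "cleaner" but the centred-window description implies
  inclusion — so inclusion is the default and `include_event = FALSE` is
  available. A 9-year window spans year-to-year variation yet stays short
  enough that the age trend within it is negligible.
* $Rec = I_{postdr}/I_{dr}$ with $I_{postdr}$ the mean of the 2 years
  after the event.

Records are missing, with a recorded reason, when the window is incomplete
or a denominator is an exactly-zero (missing) ring. When the 2-year
post-window of one event contains another configured event the record is
flagged `biased` but still computed: recovery then conflates
revitalisation with the next drought's onset, and the flag lets plots and
tables mark it rather than drop it.

# Phenotypic stability

The environmental index of an event is the unweighted mean over provenance
means — provenances are the units of inference, so a provenance with more
surviving trees must not drag the baseline. Each provenance's event means
are regressed on the index by ordinary least squares. The focal provenance
is *not* excluded from the index: with the classic definition and a
complete table, the slopes average to exactly 1 (the package tests this
identity to $10^{-10}$ on randomized tables), which anchors the
interpretation of $b \approx 1$ as average stability.

For species summaries, $b_{dev}$ is the mean of $|1-b|$ over all
provenances. For the instability summary $b_{ist}$ two definitions
circulate — the mean slope of unstable provenances ($b > 1$) and their
mean deviation from 1. The deviation form matches the "instability"
semantics (it is 0-anchored and comparable to $b_{dev}$) and is the
default; the mean-slope form is selectable. With only three drought events
a slope is estimated from three points; `fw_regression()` warns below four
events and always reports `n_events`, and the rank-correlation view
(Spearman, average ranks for ties) is provided as the assumption-free
companion.

# Repeatability and evolvability

## Transform

Response ratios are positive and right-skewed, so values are
log-transformed first and then standardized to mean 0 and sample SD 1
(divisor $n-1$). The order matters only through the recorded constants
(both are affine on the log scale and repeatability is invariant to affine
maps); log-first is used and the constants are stored with the result so
the transform is invertible. Zero or negative records are excluded
upstream with flags rather than fudged with offsets.

## REML

The model is a Gaussian random-intercept model: per tree for
provenance-level estimates, provenance-plus-tree (trees nested) for the
species-level estimate. Variance components are estimated by restricted
maximum likelihood, implemented directly:

* One grouping factor: the restricted likelihood is profiled down to the
  variance ratio $\gamma = \sigma^2_A/\sigma^2_W$ using the group-sum
  closed form; the analytic score equation in $\gamma$ is bracketed and
  solved by root finding to machine tolerance. On balanced data with an
  interior optimum this reproduces the classical mean-squares estimators
  $\hat\sigma^2_W = MS_W$, $\hat\sigma^2_A = (MS_A - MS_W)/k$ exactly —
  the test suite checks agreement to $10^{-6}$ over randomized balanced
  layouts, and agreement with an independent mixed-model implementation
  on unbalanced and nested layouts.
* Two components: the profiled restricted likelihood over the two
  log-ratios is maximised quasi-Newton (L-BFGS-B) from three fixed starts
  (a deterministic guard against flat likelihoods), with per-provenance
  dense Cholesky blocks — block sizes are tens of observations, so dense
  algebra is both simplest and fast.

Components are truncated at zero and flagged as boundary estimates; a
boundary repeatability of 0 is reported with SE 0 and never counted as
significant. The component covariance is the inverse observed-information
matrix from central finite differences of the restricted log-likelihood at
the optimum (relative step $10^{-4}$), and the SE of
$r = \sigma^2_A/(\sigma^2_A+\sigma^2_W)$ follows by the delta method. On
simulated 200-tree designs the delta SE matches the Monte-Carlo SD of
$\hat r$ well within a factor of 1.3; at 16 trees (a realistic provenance)
it remains calibrated but the estimate itself is noisy, which is why
per-provenance results always carry their SE and a significance label
($r/\mathrm{se} > z_{1-\alpha/2}$, default $\alpha = 0.05$).

## Model comparison

The within-species fixed-effect structure (drought event, provenance,
their interaction) is evaluated by a stepwise sequence of tree
random-intercept models fitted by **maximum likelihood**, not REML:
restricted likelihoods of models with different fixed effects are not
comparable, so LR tests demand ML. Each step reports the parameter count
(fixed effects plus the two variance parameters — the intercept-only model
has 3), AIC $= 2p - 2\ell$, log-likelihood, LR $= 2\Delta\ell$ and the
$\chi^2$ p-value on the parameter difference. Repeatability itself is
always taken from the REML fits. Across-species comparisons use a
fixed-effects two-way ANOVA (species × drought year, with interaction) on
tree-level records, with Tukey HSD pairwise tests summarised as compact
letters (insert-and-absorb construction).

## Evolvability

$V_A = r \cdot V_P$ treats repeatability as the upper bound of $h^2$, so
$V_A$ and $CV_A = 100\sqrt{V_A}/\bar X$ are upper bounds too. $V_P$ and
$\bar X$ are taken on the **raw trait scale** within the provenance
(sample variance and mean over tree-event records) while $r$ comes from
the transformed scale; the pairing follows the standard formula chain for
ratio traits and is recorded here because it is a modelling convention,
not a mathematical identity. $CV_A$ is invariant to rescaling the trait,
which is the point of mean-standardisation.

# The synthetic-data generator

The generator is the package's substitute for field data and the reference
for every recovery test. Its defaults mirror a single-species lowland
conifer trial: 11 provenances × 16 trees, years 1970–2010, drought events
1993/2000/2003, ~500 mm annual precipitation from per-calendar-month gamma
draws with growing-season dry spells (factor 0.3) embedded in event years.

Ring widths follow
$w(t) = G_{tree}\cdot \mathrm{age}(t) \cdot m(t) \cdot e^{\varepsilon(t)}$
with a modified negative-exponential age trend
($2.5\,e^{-0.04\,\mathrm{age}} + 1.2$ mm), lognormal tree baseline
(SD 0.10) and year noise (SD 0.05), and an event multiplier
$m = \exp(-(0.4 + P_{prov} + A_{tree} + \varepsilon_{event}))$: a mean
multiplier of $e^{-0.4} \approx 0.67$, provenance effects (SD 0.05), tree
sensitivity — the additive-genetic signal — (SD 0.10) and event-level
residuals (SD 0.15), all on the log scale. Two cores per tree add
lognormal measurement noise (SD 0.02). Every random effect lives on the
log scale so the generator is conjugate to the log-transformed analysis
model, giving the closed mapping
$r_{true} = \sigma^2_{sens}/(\sigma^2_{sens}+\sigma^2_{resid})$
(0.31 at the defaults). Draws happen in fixed-size blocks with event
residuals last, so dropping the events yields the exact no-drought
counterfactual under the same seed.

What it does **not** emulate: spatial autocorrelation among neighbouring
trees, cross-dating and measurement error structure beyond iid lognormal
noise, climate-driven year-to-year growth (the SPI series and the
ring-width series are generated independently), survival/mortality
selection, and age-trend misspecification. Passing recovery tests
therefore demonstrate estimator correctness under the assumed
variance-component model, not robustness to these field realities.

# Problem sizes and determinism

The test suite exercises estimator recovery at 500 trees × 3 events
(tolerance ±0.05 on $r$), SE calibration and null significance rates with
200 seeded replicates of the 16-tree design, 200 replicates of the
11-provenance model-selection null, and the various algebraic identities
at machine-level tolerances; these sizes make the Monte-Carlo bounds tight
enough to be informative while keeping a full run in well under a minute
per block. All simulation entry points take a single integer seed and are
bitwise reproducible; the pipeline writes plain CSV/JSON artifacts and a
rerun under the same configuration is byte-identical, which the suite
asserts.

# Known limitations

* Three drought events is the floor for repeatability and the
  Finlay–Wilkinson regression; both are reported with uncertainty, but
  users should treat per-provenance slopes from three events as
  descriptive.
* Repeatability upper-bounds heritability; without pedigree or genomic
  relatedness the additive variance cannot be separated from permanent
  environmental and non-additive genetic effects.
* The SPI implementation covers precipitation-only drought; no
  temperature/evapotranspiration indices.
* Resistance windows spanning series ends or missing rings produce
  missing records; the completeness report should be inspected before
  comparing provenances with very different coverage.
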