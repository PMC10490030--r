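---
title: "Methods: isoform-resolved vitamin E intake assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isoform-resolved vitamin E intake assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tocointake)
```

## The scoring model

A semiquantitative FFQ asks for the usual number of servings per week of
each listed item; portion sizes are fixed by the instrument. The scoring
model is deliberately linear. For respondent $i$, item $j$ with portion
$m_j$ grams and member-food set $F_j$, and isoform $k$:

$$x_{ik} \;=\; \sum_j \frac{s_{ij}}{7}\cdot\frac{m_j}{100}\cdot
\frac{1}{|F_j|}\sum_{f\in F_j} c_{fk},$$

where $c_{fk}$ is the content of isoform $k$ in food $f$ (mg/100 g) and
$s_{ij}$ the reported servings per week (fractions allowed). Three
assumptions are embedded:

* **Unweighted pooling.** Items that pool several foods ("Almonds/sunflower
  seeds") use the plain mean of the member foods' contents. No consumption
  weights are available at the item level, and introducing market-share
  weights would add a data dependency without changing the interface; users
  who want weights can pre-average their own composition rows.
* **Fixed 7-day normalisation.** Servings are asked per week, so portions
  per day are `servings / 7` with no day-of-week weighting. The instrument's
  6-month reference period affects interpretation (usual intake), not
  arithmetic.
* **Density 1 for volume portions.** The two volume items (vegetable
  juices, almond drink; 200 mL) are scored as 200 g against mg/100 g
  contents. Both are close to water density, so the error is well under the
  uncertainty of the composition data.

Accumulation over items is done in instrument order for bit-reproducible
outputs; group subtotals partition the same sum, and a reconciliation test
holds them to the daily totals within 1e-9 relative.

One instrument row pools wholemeal bread with other wholegrain products and
prints two portion conventions (35 g per slice of bread, 75 g per cup of
other products). A single line item needs a single portion; the built-in
instrument uses 35 g — the first-named food, and the one eaten most
frequently in the target population — and documents the 75 g alternative
here. Users scoring cereal-heavy diets should split the row in a custom
instrument (YAML in/out is provided).

## α-tocopherol equivalents

Activity weights convert an isoform vector to mg of α-tocopherol
equivalents: 1.0, 0.4, 0.1, 0.01 for α-, β-, γ-, δ-tocopherol and 0.3,
0.05, 0.01 for α-, β-, γ-tocotrienol. Two genuinely open choices are made
explicit and configurable:

* **δ-tocotrienol weight.** The conventional seven-term formula omits
  δ-tocotrienol. The default weight is therefore 0 — the package follows
  the convention verbatim rather than silently "fixing" it — and
  `conversion_weights(delta_t3 = 0.01)` adopts the eight-term variant.
* **Manufacturer-added vitamin E.** Fortification is tracked in its own
  `added_vit_e` component, never silently merged into natural α-tocopherol.
  It enters α-TE with weight 1 by default (`fold_added_as_alpha`), since
  added vitamin E is α-tocopherol or an ester of it; a reporting flag can
  additionally fold it into the displayed α-T column, off by default so the
  natural-isoform columns stay pure.

Because all weights are nonnegative and the α-T weight is 1, α-TE ≥ α-T
holds for every intake vector — a useful sanity check on any summary table:
an "α-TE" mean printed below the α-T mean of the same sample cannot have
been produced by this formula and usually signals a metric or labelling
slip in the source being compared against.

## Adequacy classification

Frameworks are rows of (framework, metric, sex, threshold, UL). The three
built-ins key NIPH–NIH–NRI to α-TE and NIH and EFSA to α-tocopherol — each
framework is compared on the metric its reference values are defined on,
and a user can re-key a framework by editing the table. Two boundary
conventions are fixed and documented rather than configurable: intake
exactly at the threshold counts adequate (≥), and the UL is exceeded only
strictly (>). Both follow the usual reading of "meets the reference value"
and "did not exceed the UL"; neither affects continuous data in practice.

## Agreement statistics

The Bland–Altman machinery is implemented in the package. Differences are
**signed**, $d_i = a_i - b_i$; the bias is their mean; the SD uses the
$n-1$ denominator; limits of agreement are $\text{bias} \pm k\,SD$ with
$k = 1.96$ by default. A mean of *absolute* differences is sometimes
reported in method-comparison tables, but symmetric limits about it are
incoherent (a negative lower limit is impossible), so this package uses the
signed bias throughout. Points exactly on a limit count as within (the
index counts *strictly* beyond). The Bland–Altman index is
$100\,\cdot\,n_{\text{beyond}}/n$; good agreement defaults to index ≤ 5%
(the 95%-within convention), with `index_threshold = 10` exposing the laxer
published alternative. Zero variance of differences yields a warning and an
index of 0 rather than an error, so that degenerate noise-free fixtures
remain scorable.

Spearman's ρ (midranks, two-sided p from the t approximation), the
Mann–Whitney U (normal approximation with tie and continuity corrections),
and the Shapiro–Wilk gate are delegated to the corresponding routines in
base R's stats package; these approximations are the appropriate regime for
cohort-sized samples (hundreds of respondents), and the test suite checks
them against exhaustive pair-counting and midrank-Pearson oracles at small
n. The gate routes a comparison to the nonparametric path when either
series has p ≤ 0.05 — dietary intake distributions are almost always
right-skewed, so this is the expected path at realistic n.

## The synthetic cohort generator

`gen_cohort()` emulates a paired-method validation study: every respondent
answers the FFQ and provides one reference measurement. Its defaults are
fixed at the design of such a study in an adult European population —
447 respondents, 73% women — and at consumption behaviour that reproduces
realistic intake magnitudes (cohort mean α-tocopherol ≈ 12–18 mg/day,
tocopherol sum in the low twenties, tocotrienol sum near 1 mg/day,
tocopherols ≈ 95% of the vitamin E pool, with oils/nuts dominating
tocopherols and wholegrain cereals the tocotrienols):

* usual servings per week per item: gamma(shape 1.2, scale 5/3), mean 2,
  right-skewed like real frequency data;
* zero inflation 0.35: the probability a given respondent never consumes a
  given item;
* record noise: the reference measurement is the FFQ-derived intake times
  $e^\varepsilon$, $\varepsilon \sim N(0, \sigma^2)$ with $\sigma = 0.35$
  per isoform, sums recomputed from the noised components, then an additive
  per-variable bias, truncated at zero.

A single random stream ordered (respondent, item) makes every output a pure
function of the seed. Truncation at zero slightly distorts an injected
negative bias at high $\sigma$; the parameter-recovery test therefore uses
small $\sigma$.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: within-person day-to-day variance (a real 1-day
record is one draw from a person's intake distribution, not a noised copy
of their usual intake), correlated item frequencies (diet patterns),
differential misreporting by food group (fat under-reporting), and real
composition values. Synthetic composition tables are labelled as such in
their provenance; a loader for user-supplied tables (e.g. USDA-derived) is
the intended production path.

## Numerical and interface choices

* Intakes are kept at full double precision end to end; rounding (e.g. to
  1 decimal for presentation) happens only in report writers
  (`write_intake(report_decimals =)`), never before classification or
  agreement analysis.
* Missing composition cells and missing response items are errors under the
  default strict policy; permissive flags map them to zero with a warning
  and, for responses, a per-respondent completeness fraction. Silent zeros
  would bias intake downward, which for an adequacy instrument is the
  costly direction.
* Validation errors carry typed condition classes
  (`tocointake_validation_error`, `_schema_error`, `_lookup_error`,
  `_domain_error`) and name the offending row or column.
* All tabular I/O is delimited text (comma or tab, auto-detected);
  instruments serialise to YAML; intake tables also to JSON.

## Problem sizes

The test suite exercises the engines at the sizes the statistics need, not
more: brute-force scoring oracles at 4–5 respondents × 41 items, agreement
fixtures at n = 20–100, index calibration at 10,000 i.i.d. normal
differences (expected index $2\Phi(-1.96) \approx 5\%$, accepted in
[4, 6]), and bias recovery at n = 2000 with ±0.2 mg tolerance (Monte-Carlo
error shrinking as $1/\sqrt{n}$). The acceptance script scores the default
447-respondent cohort. The full suite runs in well under a minute.

## Known limitations

* Usual-intake modelling (NCI-style within/between-person variance
  decomposition) is out of scope; the package estimates intake from the
  FFQ as asked, per respondent.
* No probability-of-adequacy (EAR cut-point) assessment; classification is
  a per-person threshold comparison.
* Proportional-bias (regression-based) Bland–Altman variants and
  repeated-measures limits are not implemented.
* The built-in instrument targets adult European diets; the 8 food groups
  and portion sizes are not validated for children or other food cultures.
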