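# tocointake

Dietary intake assessment for the eight vitamin E isoforms — the four
tocopherols (α, β, γ, δ) and the four tocotrienols — from semiquantitative
food frequency questionnaire (FFQ) data.

Most food-composition tables report vitamin E only as a single
α-tocopherol-equivalent number, yet the eight isoforms differ sharply in
biological activity and in their food sources (oils and nuts for
tocopherols, wholegrain cereals for tocotrienols). `tocointake` scores a
vitamin E–focused FFQ against a per-isoform composition database, so that
individual and group intake can be assessed isoform by isoform, compared
against dietary reference values, and validated against a second assessment
method. It is aimed at nutritional epidemiologists and dietitians working
with questionnaire data.

## What it computes

**Intake.** For respondent *i* and instrument item *j* with portion size
*m<sub>j</sub>* (g) and reported servings per week *s<sub>ij</sub>*, the
daily intake of isoform *k* is

> x<sub>ik</sub> = Σ<sub>j</sub> (s<sub>ij</sub> / 7) · (m<sub>j</sub> / 100) · c̄<sub>jk</sub>

where c̄<sub>jk</sub> is the unweighted mean content (mg/100 g) of isoform
*k* over the foods pooled by item *j*. Group subtotals, tocopherol and
tocotrienol sums, and the total follow by addition.

**α-tocopherol equivalents.** Total vitamin E activity is expressed as

> α-TE (mg) = 1.0·αT + 0.4·βT + 0.1·γT + 0.01·δT + 0.3·αT3 + 0.05·βT3 + 0.01·γT3

with δ-tocotrienol carrying weight 0 under the conventional formula (any
weight, e.g. 0.01, can be supplied), and manufacturer-added vitamin E
folded in at weight 1 by default.

**Adequacy.** Each intake is classified against three built-in adult
reference frameworks — NIPH–NIH–NRI (AI in α-TE: 10 mg/d men, 8 women; UL
300), NIH (RDA in α-T: 15 mg/d both sexes; UL 1000) and EFSA (AI in α-T:
13 mg/d men, 11 women; UL 300) — with sex-specific thresholds
(intake ≥ threshold is adequate; intake > UL flags excess).

**Method agreement.** Paired intakes from two methods (e.g. FFQ vs 1-day
dietary record) are compared with Bland–Altman limits of agreement
(bias ± 1.96·SD of differences), the Bland–Altman index (% of pairs beyond
the limits; ≤ 5% is conventionally good agreement), Spearman rank
correlation, and the Mann–Whitney U test, with a Shapiro–Wilk gate for
method selection.

A built-in 41-item instrument covering 8 food groups ships with the
package, together with a synthetic-cohort generator (`gen_cohort()`) that
produces FFQ responses and paired record intakes with controllable noise
and bias, so the whole pipeline runs without any external data.

## Worked example

```r
library(tocointake)

inst   <- builtin_instrument()                      # 41 items, 8 food groups
db     <- make_fixture_db(seed = 1, instrument = inst)
cohort <- gen_cohort(synth_config(n_respondents = 100), inst, db, seed = 1)
intake <- cohort$ffq_intake

dplyr::select(intake, respondent_id, alpha_t, gamma_t,
              sum_tocopherols, sum_tocotrienols, alpha_te)
#> # A tibble: 100 × 6
#>   respondent_id alpha_t gamma_t sum_tocopherols sum_tocotrienols alpha_te
#>   <chr>           <dbl>   <dbl>           <dbl>            <dbl>    <dbl>
#> 1 resp_0001       25.7     9.54            36.6            1.40     27.2
#> 2 resp_0002        8.97    4.37            13.8            0.149     9.71
#> 3 resp_0003       17.2     6.73            24.7            0.125    18.2
#> 4 resp_0004       10.5     5.36            16.5            0.341    11.3
```

Each row is one respondent's estimated daily intake in mg: respondent 1
eats an oil- and nut-rich diet (36.6 mg of tocopherols/day), respondent 2
a low-fat one (13.8 mg). Adequacy against the three reference frameworks:

```r
adequacy_summary(classify_adequacy(intake))
#> # A tibble: 3 × 6
#>   framework    metric       n pct_adequate pct_inadequate pct_ul_exceeded
#> 1 EFSA         alpha_t    100           77             23               0
#> 2 NIH          alpha_t    100           51             49               0
#> 3 NIPH-NIH-NRI alpha_te   100           97              3               0
```

Roughly half the simulated cohort meets the strict NIH RDA of 15 mg
α-tocopherol/day while nearly all meet the Polish α-TE AI — the
classification depends strongly on which framework (and which metric) is
used, which is exactly why the package keys each framework to its own
metric. Agreement of the FFQ with the paired synthetic 1-day record:

```r
joined <- dplyr::inner_join(tibble::as_tibble(intake),
                            tibble::as_tibble(cohort$record_intake),
                            by = "respondent_id", suffix = c("_ffq", "_rec"))
bland_altman(joined, alpha_te_ffq, alpha_te_rec, variable = "alpha-TE")
#> Bland-Altman agreement (alpha-TE), n = 100
#>   bias -2.861, SD of differences 8.506
#>   limits of agreement [-19.532, 13.811] (k = 1.96)
#>   92 of 100 within limits; index 8.00% (poor agreement at 5%)
```

The bias says the FFQ under-reads the record by 2.9 mg α-TE/day on
average; 8% of respondents fall beyond the limits of agreement, above the
5% convention (but below the laxer 10% threshold some studies use —
`index_threshold = 10` adopts it). `autoplot()` on the returned object
draws the Bland–Altman plot; `tidy()`/`glance()` give the per-pair and
one-row summaries.

A command-line front end is installed at
`system.file("exec", "tocointake", package = "tocointake")` with
subcommands `intake`, `adequacy`, `agree`, `synth`.

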