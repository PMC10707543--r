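# fitindex

Hierarchical physical-fitness evaluation index systems for elite athletes.

Sport-science institutes evaluating national-squad athletes face a recurring
construction problem: reduce dozens of candidate measurements to a
manageable, weighted, hierarchical index system, derive sex-specific scoring
standards from a small reference cohort, and produce per-athlete scores and
ratings that survive statistical scrutiny. fitindex implements that workflow
end to end, for analysts who build such systems and for coaching staff who
apply one:

* **Delphi screening** — retain candidate indexes with expert-panel mean ≥ 4
  (on a 1–5 importance scale) and coefficient of variation < 0.25; expert
  authority coefficients and questionnaire test-retest reliability.
* **Index reduction** — R-type (variable) hierarchical clustering with a
  scale-invariant 1 − |r| dissimilarity, then one representative per cluster:
  singletons stand for themselves, pairs are resolved by declared domain
  knowledge, and larger clusters keep the member with the highest forced-entry
  OLS coefficient of determination R² on its cluster mates.
* **Weighting** — five-level frequency scoring of an expert panel and
  summation-normalization, w_i = total_i / Σ total, within every sibling set
  of the hierarchy.
* **Percentile standards and scoring** — per-index P10/P25/P50/P75/P90
  dividing points (theoretical band occupancy 10/15/50/15/10 %), five bands
  scored 1–5 with direction-aware orientation for low-optimal indexes, and
  the three-stage weighted composite

  N = Σ nᵢwᵢ (tertiary band × tertiary weight → primary score × primary
  weight → comprehensive score, maximum 5),

  plus general (mean ± SD) and ideal (directional P90/P10 target) fitness
  models.
* **Validation** — exact two-sided r×c independence test by complete
  enumeration of margin-fixed tables (with a seeded Monte Carlo fallback) and
  Kendall tau-b test-retest reliability.
* **Synthetic cohorts** — a block-correlated multivariate-normal generator
  with two-tier effects, so the whole pipeline is testable without any
  protected athlete data.

The published freestyle-skiing-aerials reference system (3 primary domains,
11 representative indexes, both sexes) ships as bundled plain-text fixtures:
cutoffs, weights, per-athlete scores and ratings, general/ideal models.

## Worked example

Fit an evaluation model to a (here: simulated) male reference cohort and
score athletes:

```r
library(fitindex)

cohort <- simulate_cohort(aerials_cohort_spec("male", n = 100, seed = 3))
fm <- fitness_model(cohort, "male")
fm
#> Physical-fitness evaluation model (male, fitted), reference n = 100
#>   3 primary domains, 11 tertiary indexes
#>   comprehensive bands: <2.50 | 2.75 | 3.21 | 3.43 | >3.43

pr <- predict(fm)
head(pr[, c("athlete_id", "body_form", "physiological_function",
            "physical_quality", "comprehensive", "comprehensive_rating")], 4)
#>   athlete_id body_form physiological_function physical_quality comprehensive
#> 1    ath0001     0.425                 1.0164           1.0920        2.5334
#> 2    ath0002     0.805                 0.8877           1.2558        2.9485
#> 3    ath0003     0.885                 0.8778           1.0500        2.8128
#> 4    ath0004     0.475                 1.2144           0.9660        2.6554
#>   comprehensive_rating
#> 1                 Poor
#> 2              Average
#> 3              Average
#> 4                 Poor
```

Each row is one athlete: the three primary columns are weighted domain
scores, `comprehensive` is their full-precision sum N (at most 5), and the
rating maps N through the cohort's own percentile bands. Against the
published standards instead:

```r
csm <- aerials_composite_standard("male")
rate(4.11, csm)                 # the top athlete's printed comprehensive score
#> [1] "Excellent"
fisher_exact(aerials_rating_frequencies("male"))  # elite vs excellent tiers
#> [1] 0.003196803
```

Expert-panel screening:

```r
panel <- simulate_expert_panel(panel_spec(12, c("grip", "vo2max", "reaction"),
                                          c("high", "high", "low"), seed = 1))
screen_items(panel)
#>       item     mean        sd        cv retained
#> 1     grip 4.583333 0.5149287 0.1123481     TRUE
#> 2   vo2max 4.333333 0.6513389 0.1503090     TRUE
#> 3 reaction 2.916667 1.2401124 0.4251814    FALSE
```

A thin command-line front end over the same functions is installed at
`inst/exec/fitindex` (`fitindex simulate`, `score`, `build-standards`,
`delphi`, `select-indexes`, `weights`, `verify`, `validate-config`).

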