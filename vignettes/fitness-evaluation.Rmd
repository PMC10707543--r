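---
title: "Building hierarchical fitness evaluation index systems"
author: "fitindex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building hierarchical fitness evaluation index systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitindex)
```

## The problem

Coaching staff of elite squads need a defensible way to turn a battery of
heterogeneous measurements — anthropometry, physiology, strength and speed
tests — into a single comparable fitness score per athlete, plus per-domain
diagnostics. fitindex implements the complete construction workflow for such a
system, exercised here on the published freestyle-skiing-aerials reference
system (three primary domains — body form, physiological function, physical
quality — over eleven representative tertiary indexes, for a two-tier
male/female national squad), but the machinery is generic: any hierarchy of
indexes with declared optimality directions can be supplied as a YAML
configuration.

The workflow has five stages, each an exported module surface:

1. **Delphi screening** of the candidate index pool by an expert panel.
2. **Index reduction** by R-type (variable) clustering and regression-based
   representative selection.
3. **Weighting** of the surviving indexes by expert importance scores.
4. **Percentile scoring standards** and three-stage weighted aggregation.
5. **Validation** statistics (exact contingency test, rank-correlation
   test-retest reliability).

## Delphi screening

Experts score each candidate index for importance on a 1–5 scale. An index is
retained when the panel mean is at least 4.0 (inclusive) and the coefficient
of variation, CV = SD/mean, is below 0.25 (strict) — high importance *and*
high consensus. The CV uses the sample SD (n−1 denominator); the convention is
not fixed by the protocol, so it is stated here once and used everywhere.
Expert credibility is summarized by the authority coefficient, the mean of a
judgment-basis and a familiarity self-rating, with ≥ 0.70 conventionally read
as high authority; questionnaire stability across two survey rounds is the
correlation of pooled paired scores (Pearson by default, Spearman available).

```{r}
panel <- simulate_expert_panel(panel_spec(12, c("grip", "vo2max", "reaction"),
                                          consensus = c("high", "high", "low"),
                                          seed = 1))
screen_items(panel)
```

## Index reduction

Retained indexes are grouped by hierarchical clustering of the *variables*
(not the athletes). The dissimilarity is 1 − |r| with average linkage by
default: absolute correlation makes the partition invariant to affine
rescaling and sign flips of any index (so second-per-metre vs metre-per-second
conventions cannot change the clusters); 1 − r and complete/Ward linkage are
available for comparison. The number of clusters per domain is supplied by
the analyst (dendrogram plus theory), not chosen automatically.

One representative is selected per cluster by a three-way rule: singletons
represent themselves; 2-member clusters are resolved by a declared
domain-knowledge override (e.g. pelvis width over shoulder width, relative
over absolute power), because no regression can decide between two variables;
clusters of three or more run a forced-entry OLS of each member on all other
members and keep the member with the highest coefficient of determination —
the variable best explained by its cluster, hence the least information lost
by dropping the rest. R² ties (rare with continuous data) break by larger
mean absolute correlation with cluster mates, then id order — deterministic by
construction.

```{r}
blocks <- list(paste0("len", 1:3), paste0("strength", 1:3))
spec <- cohort_spec(unlist(blocks), means = rep(10, 6), sds = rep(2, 6),
                    n = 100, blocks = blocks, seed = 2)
cohort <- simulate_cohort(spec)
cl <- cluster_variables(cohort, spec$indexes, n_clusters = 2)
cl
select_representatives(cl, cohort)
```

## Weighting

Weights come from a 14-expert importance survey: per index, the five score
levels are multiplied by their frequencies and summed (equivalently, the
column sum of raw scores), then totals are normalized within each sibling set
— the tertiary children of one primary, and the set of primaries — so each
set sums to exactly 1 before display rounding. The published weight table
ships as a fixture (`aerials_hierarchy()` carries it) because the expert raw
scores behind it were never released; `derive_weights()` recomputes weights
when a panel table is available.

## Percentile standards, scoring, rating

Per index and sex, the reference cohort's P10/P25/P50/P75/P90 dividing points
are computed by linear interpolation between order statistics
(`quantile(type = 7)`; configurable, since other software defaults differ —
published cutoffs therefore ship as literal fixtures and the estimator choice
affects only newly built standards). The five bands score 1–5 with
theoretical occupancies 10/15/50/15/10 %. Boundary conventions follow the
published band typography exactly: the middle band is closed at both ends
(`P25 ≤ v ≤ P75`), good is `(P75, P90]`, excellent `(P90, ∞)`, poor
`[P10, P25)`, fail `(−∞, P10)`; low-optimal indexes (sprint time, balance-pad
squat time) mirror the mapping. P50 is stored but never used in banding. A
degenerate standard (all cutoffs equal, e.g. a constant cohort) carries no
discriminating information and scores every value 3.

Aggregation is the weighted composite N = Σ nᵢwᵢ in three stages: tertiary
band score × tertiary weight → summed to the primary score → × primary weight
→ summed to the comprehensive score (maximum 5). All arithmetic is full
precision; rounding half-away-from-zero to 2 decimals happens only at
display. The same percentile construction applied to the cohort's own primary
and comprehensive score columns yields the composite rating standard
(Fail/Poor/Average/Good/Excellent).

`fitness_model()` packages the whole stage: standards, training-cohort
reports, composite standard, the general model (per-index mean ± SD) and the
ideal model (the excellent-band boundary per index: P90 with a ≥ target, or
P10 with ≤ for low-optimal indexes).

```{r}
cohort <- simulate_cohort(aerials_cohort_spec("male", n = 100, seed = 3))
fm <- fitness_model(cohort, "male")
fm
head(predict(fm)[, c("athlete_id", "comprehensive", "comprehensive_rating")])
```

## Validation statistics

`rating_frequency()` cross-tabulates ratings by cohort group, and
`fisher_exact()` runs the exact two-sided r×c independence test by complete
enumeration of all tables with the observed margins, summing the
probabilities of tables no more probable than the observed one (the standard
exact convention; the protocol names no other). Probabilities are computed in
log space and compared with a relative tolerance of 1e-9, so ties at the
observed probability are always counted; base R offers no arbitrary-precision
integers, and log-space with an explicit tie tolerance gives the same
accepted-table set as rational arithmetic for every n within the enumeration
bound (n ≤ 40; beyond it `fisher_exact_mc()` provides a seeded Monte Carlo
fallback via Patefield sampling with an add-one estimator). Test-retest
stability of composite scores uses Kendall's tau-b from the full O(n²) pair
count — tie-corrected, because ties are common on a 2-decimal score scale.

## The synthetic-data generator

Because the reference cohort's raw measurements were never deposited, every
stage is exercised on synthetic cohorts. `cohort_spec()` draws multivariate
normal measurements with marginal means and SDs defaulting to the published
general model, a block correlation structure (within-block r = 0.8,
between-block 0.1 by default — strong enough that cluster recovery is
near-certain, which keeps the selection tests sharp), an additive elite-tier
shift in SD units (sign-flipped for low-optimal indexes), and truncation at
zero, since anthropometric and performance values cannot be negative. The
block matrix is checked for positive definiteness and shrunk toward the
identity until it passes. Gaussian marginals are an emulation chosen because
the reference models are stated as M ± SD; the generator does not reproduce
skewness, measurement error structure, or athlete-level correlation between
tiers, so passing tests demonstrate correctness of the *procedure*, not
distributional claims about real athletes.

## Reproduction limits of the published tables

Three facts about the published fixtures are worth knowing before comparing
output to the printed tables:

* Several printed per-athlete rows are not self-consistent: the three primary
  weighted scores do not sum, at 2 decimals, to the printed comprehensive
  score (drift up to 0.13). `aerials_weighted_scores()` flags the consistent
  rows; exact reproduction is asserted only there.
* Nine printed rating cells conflict with the published cutoff bands applied
  to the published weighted scores — decisively, the same printed score 1.31
  appears with ratings Excellent, Good and Good, so no banding convention can
  reproduce all cells; the source must have rated unrounded scores.
  `aerials_nonverifiable_ratings()` lists all nine (three of them are
  acknowledged in the source).
* The claimed "p < 0.001" for the tier contrast is not reproducible from the
  printed frequency table: complete enumeration (and any exact software)
  gives 16/5005 ≈ 0.0032 for males and ≈ 0.021 for females.

## Problem sizes and numerical choices

Property checks in the test suite use cohorts of n = 10⁴ for band-occupancy
and parameter-recovery checks (±2 percentage points and 3 SE respectively),
n = 200 over 100 seeds for cluster recovery, and 200+ random margin
configurations at n ≤ 20 for the exact-test cross-validation — sizes at which
the Monte Carlo error of each check is far below its tolerance. Percentile
estimation, tie-breaks, degenerate-standard behaviour and the exact-test tie
tolerance are all fixed as described above and are deliberate design
decisions of this package where the original protocol is silent.
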