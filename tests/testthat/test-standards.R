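test_that("percentile dividing points use linear interpolation between order statistics", {
  s <- build_scoring_standard(1:100, "high_optimal", index = "demo")
  expect_equal(unname(s$cutoffs),
               c(10.9, 25.75, 50.5, 75.25, 90.1))
  expect_identical(score_index(95, s), 5L)
  expect_error(build_scoring_standard(1:9, "high_optimal"), "insufficient")
  expect_error(build_scoring_standard(c(1:20, Inf), "high_optimal"),
               "non-finite")
})

test_that("a large normal sample lands P90 on the closed-form normal quantile", {
  set.seed(100)
  x <- rnorm(1e5, 21.94, 0.85)
  s <- build_scoring_standard(x, "high_optimal")
  expect_equal(s$cutoffs[["p90"]], 21.94 + qnorm(0.9) * 0.85, tolerance = 0.05)
  expect_equal(s$cutoffs[["p10"]], 21.94 - qnorm(0.9) * 0.85, tolerance = 0.05)
})

test_that("constant cohorts give the degenerate everyone-average rule", {
  s <- build_scoring_standard(rep(7.5, 12), "high_optimal")
  expect_true(all(s$cutoffs == 7.5))
  expect_identical(score_index(c(0, 7.5, 99), s), c(3L, 3L, 3L))
})

test_that("high-optimal banding follows the published boundary typography", {
  std <- aerials_standards("male")
  # power clean 100 kg sits in the good band (>98 ~ 103)
  expect_identical(score_index(100, std$power_clean), 4L)
  expect_identical(score_index(c(70, 75, 79, 80, 98, 99, 103, 104),
                               std$power_clean),
                   c(1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L))
  # value exactly at P75 stays in the closed middle band
  expect_identical(score_index(std$power_clean$cutoffs[["p75"]],
                               std$power_clean), 3L)
})

test_that("low-optimal banding is the mirror image", {
  std <- aerials_standards("male")
  expect_identical(score_index(3.80, std$sprint_30m), 5L)  # < 3.84, excellent
  expect_identical(score_index(c(3.84, 4.01, 4.02, 4.58, 4.60, 5.12, 5.13),
                               std$sprint_30m),
                   c(4L, 4L, 3L, 3L, 2L, 2L, 1L))
})

test_that("three-stage aggregation reproduces hand-computed composites", {
  h <- aerials_hierarchy()
  terts <- tertiary_ids(h)
  for (sex in c("male", "female")) {
    all5 <- setNames(rep(5L, length(terts)), terts)
    rep5 <- aggregate_scores(all5, h, sex)
    w <- h$weights[[sex]]
    # weights sum to 1 at both stages only up to printed rounding, so the
    # all-excellent composite equals 5 * (stagewise weight sums)
    expected <- sum(vapply(primary_ids(h), function(p)
      w[[p]] * sum(5 * w[scored_children(h, p)]), 0))
    expect_equal(rep5$comprehensive, expected)
    expect_equal(rep5$comprehensive, 5, tolerance = 0.1)
  }
  # mixed bands, male: hand-computed three-stage arithmetic
  bands <- setNames(c(3L, 4L, 2L, 5L, 3L, 3L, 4L, 5L, 2L, 3L, 4L), terts)
  got <- aggregate_scores(bands, h, "male")
  w <- h$weights$male
  bf <- sum(bands[1:4] * w[terts[1:4]])
  pf <- sum(bands[5:7] * w[terts[5:7]])
  pq <- sum(bands[8:11] * w[terts[8:11]])
  expect_equal(got$body_form_unweighted, bf)
  expect_equal(got$body_form, bf * 0.25)
  expect_equal(got$comprehensive, bf * 0.25 + pf * 0.33 + pq * 0.42)
  expect_error(aggregate_scores(bands[-1], h, "male"), "no band score")
})

test_that("composite equals 5 iff every band is excellent (up to weight rounding)", {
  h <- aerials_hierarchy()
  terts <- tertiary_ids(h)
  w <- h$weights$male
  set.seed(30)
  for (i in 1:50) {
    bands <- setNames(sample(1:5, length(terts), TRUE), terts)
    comp <- aggregate_scores(bands, h, "male")$comprehensive
    lo <- aggregate_scores(setNames(rep(1L, 11), terts), h, "male")$comprehensive
    hi <- aggregate_scores(setNames(rep(5L, 11), terts), h, "male")$comprehensive
    expect_gte(comp, lo - 1e-12)
    expect_lte(comp, hi + 1e-12)
    if (comp >= hi - 1e-12) expect_true(all(bands == 5))
  }
})

test_that("composite standards band the report columns like a direct percentile call", {
  set.seed(77)
  cohort <- simulate_cohort(aerials_cohort_spec("male", n = 100, seed = 77))
  fm <- fitness_model(cohort, "male")
  cs <- build_composite_standard(fm$reports, "male")
  expect_equal(cs$columns$comprehensive$cutoffs[["p90"]],
               unname(quantile(fm$reports$comprehensive, 0.9, type = 7)))
  expect_equal(cs$columns$body_form$cutoffs[["p25"]],
               unname(quantile(fm$reports$body_form, 0.25, type = 7)))
  # a cohort of identical reports degenerates to the everyone-average rule
  flat <- fm$reports; flat[, -1] <- 1
  dcs <- build_composite_standard(flat, "male",
                                  columns = c(attr(fm$reports, "primaries"),
                                              "comprehensive"))
  expect_identical(rate(c(0.2, 1, 4), dcs), rep("Average", 3))
})

test_that("published composite cutoffs rate the worked examples as printed", {
  csm <- aerials_composite_standard("male")
  csf <- aerials_composite_standard("female")
  expect_identical(rate(4.11, csm), "Excellent")
  expect_identical(rate(2.34, csf), "Fail")
  expect_identical(rate(2.80, csm), "Poor")    # lower band edge inclusive
  expect_identical(rate(0.82, csm, "body_form"), "Good")
  expect_error(rate(1, csm, "nope"), "no column")
  # ordering invariant of the published male comprehensive cutoffs
  cc <- csm$columns$comprehensive$cutoffs
  expect_true(all(diff(cc[c("p10", "p25", "p75", "p90")]) >= 0))
})

test_that("the general model is the per-index mean and sample SD", {
  h <- tiny_hierarchy()
  m <- as_measurement_table(
    data.frame(athlete_id = c("a", "b"), sex = "male",
               x1 = c(20, 22), x2 = c(9, 11)), h)
  gm <- build_general_model(m, c("x1", "x2"), "male")
  expect_equal(gm$mean, c(21, 10))
  expect_equal(gm$sd, c(sqrt(2), sqrt(2)))
  expect_error(build_general_model(m[1, ], c("x1"), "male"), "at least 2")
})

test_that("general-model recovery from a large simulated cohort", {
  spec <- aerials_cohort_spec("male", n = 10000, seed = 19)
  gm <- build_general_model(simulate_cohort(spec), spec$indexes, "male")
  expect_true(all(abs(gm$mean - spec$means) / spec$means < 0.02))
})

test_that("ideal thresholds are the excellent-band boundaries, direction-aware", {
  for (sex in c("male", "female")) {
    got <- build_ideal_model(aerials_standards(sex))
    pub <- aerials_ideal_model(sex)
    expect_equal(got$threshold, pub$threshold)
    expect_identical(got$inequality, pub$inequality)
  }
  got <- build_ideal_model(aerials_standards("male"))
  expect_equal(got$threshold[got$index == "achilles_tendon_length"], 22.83)
  expect_identical(got$inequality[got$index == "sprint_30m"], "<=")
  expect_equal(got$threshold[got$index == "sprint_30m"], 3.84)
  # degenerate standard: threshold equals the constant
  s <- build_scoring_standard(rep(4, 10), "high_optimal", index = "flat")
  expect_equal(build_ideal_model(list(s))$threshold, 4)
})
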