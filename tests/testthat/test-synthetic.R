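test_that("cohort simulation is deterministic under a fixed seed", {
  spec <- aerials_cohort_spec("male", seed = 5)
  expect_identical(simulate_cohort(spec), simulate_cohort(spec))
  d <- simulate_cohort(spec)
  expect_identical(nrow(d), 15L)
  expect_identical(sum(d$tier == "elite"), 6L)
  expect_true(all(d$sex == "male"))
  expect_s3_class(d, "measurement_table")
})

test_that("marginal means and SDs are recovered at large n", {
  spec <- aerials_cohort_spec("female", n = 10000, tier_effect = 0, seed = 6)
  d <- simulate_cohort(spec)
  for (id in spec$indexes) {
    se <- spec$sds[[id]] / sqrt(10000)
    expect_lt(abs(mean(d[[id]]) - spec$means[[id]]), 3 * se)
  }
})

test_that("zero between-block correlation gives near-independent columns", {
  spec <- cohort_spec(paste0("v", 1:6), rep(50, 6), rep(5, 6), n = 10000,
                      blocks = as.list(paste0("v", 1:6)),
                      between_block_r = 0, seed = 7)
  d <- simulate_cohort(spec)
  r <- cor(as.data.frame(d)[, spec$indexes])
  expect_true(all(abs(r[upper.tri(r)]) < 0.05))
})

test_that("block designs produce the requested correlation structure", {
  blocks <- list(c("a", "b"), c("c", "d"))
  spec <- cohort_spec(c("a", "b", "c", "d"), rep(10, 4), rep(1, 4), n = 5000,
                      blocks = blocks, within_block_r = 0.8,
                      between_block_r = 0.1, seed = 8)
  d <- simulate_cohort(spec)
  r <- cor(as.data.frame(d)[, c("a", "b", "c", "d")])
  expect_lt(abs(r["a", "b"] - 0.8), 0.05)
  expect_lt(abs(r["a", "c"] - 0.1), 0.05)
  # assembled matrix is positive definite even under aggressive settings
  tough <- cohort_spec(paste0("x", 1:8), rep(1, 8), rep(1, 8),
                       blocks = as.list(paste0("x", 1:8)),
                       between_block_r = -0.3)
  ev <- eigen(tough$correlation, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("the elite tier shift moves each index in its favourable direction", {
  spec <- cohort_spec(c("jump", "sprint"), c(100, 5), c(10, 0.5),
                      n = c(elite = 2000, excellent = 2000),
                      directions = c("high_optimal", "low_optimal"),
                      tier_effect = 1, seed = 9)
  d <- simulate_cohort(spec)
  el <- d$tier == "elite"
  expect_gt(mean(d$jump[el]) - mean(d$jump[!el]), 5)     # +1 SD = +10
  expect_lt(mean(d$sprint[el]) - mean(d$sprint[!el]), -0.25)
})

test_that("values are truncated at zero", {
  spec <- cohort_spec("x", means = 0.1, sds = 5, n = 500, seed = 10)
  expect_true(all(simulate_cohort(spec)$x >= 0))
})

test_that("spec validation rejects impossible designs", {
  expect_error(cohort_spec(c("a", "b"), c(1, 2), c(1, -1)), "positive")
  expect_error(cohort_spec(c("a", "b"), c(1, 2), c(1, 1),
                           blocks = list("a")), "partition")
  expect_error(cohort_spec("a", 1, 1, n = c(pro = 5)), "elite")
})

test_that("panel consensus levels drive the retention rule as designed", {
  retained_high <- logical(300); rejected_low <- logical(300)
  for (s in 1:300) {
    hi <- simulate_expert_panel(panel_spec(12, 1, "high", seed = s))
    lo <- simulate_expert_panel(panel_spec(12, 1, "low", seed = 10000 + s))
    retained_high[s] <- screen_items(hi)$retained
    rejected_low[s] <- screen_items(lo)$cv >= 0.25
  }
  expect_gt(mean(retained_high), 0.98)
  expect_gt(mean(rejected_low), 0.85)
})

test_that("a single-expert panel builds but cannot be screened", {
  p <- simulate_expert_panel(panel_spec(1, 4, "medium", seed = 1))
  expect_identical(dim(p), c(1L, 4L))
  expect_error(screen_items(p), "at least 2 experts")
})

test_that("the full pipeline closes end to end at small and large n", {
  for (sex in c("male", "female")) {
    for (n in c(15, 100)) {
      co <- simulate_cohort(aerials_cohort_spec(sex, n = n, seed = n))
      fm <- fitness_model(co, sex)
      pr <- predict(fm, co)
      expect_identical(nrow(pr), as.integer(n))
      expect_true(all(pr$comprehensive_rating %in%
                        c("Fail", "Poor", "Average", "Good", "Excellent")))
    }
  }
})
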