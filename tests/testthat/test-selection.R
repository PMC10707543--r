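make_table <- function(df) {
  df$athlete_id <- sprintf("a%03d", seq_len(nrow(df)))
  df$sex <- "male"
  class(df) <- c("measurement_table", "data.frame")
  df
}

test_that("perfectly correlated indexes cluster together", {
  set.seed(1)
  x <- rnorm(40)
  m <- make_table(data.frame(a = x, b = 2 * x + rnorm(40, 0, 0.01),
                             c = rnorm(40)))
  cl <- cluster_variables(m, c("a", "b", "c"), n_clusters = 2)
  grp <- lapply(cl$clusters, sort)
  expect_true(any(vapply(grp, identical, TRUE, y = c("a", "b"))))
})

test_that("block-correlated cohorts are recovered at the generating partition", {
  blocks <- list(paste0("len", 1:4), paste0("wid", 1:2),
                 paste0("cir", 1:3), paste0("cmp", 1:6))
  ids <- unlist(blocks)
  spec <- cohort_spec(ids, means = rep(10, 15), sds = rep(2, 15), n = 200,
                      blocks = blocks, within_block_r = 0.8,
                      between_block_r = 0.1, seed = 42)
  cl <- cluster_variables(simulate_cohort(spec), ids, n_clusters = 4)
  found <- lapply(cl$clusters, sort)
  for (b in blocks)
    expect_true(any(vapply(found, identical, TRUE, y = sort(b))))
})

test_that("degenerate cuts and defective inputs behave as declared", {
  m <- tiny_cohort(20)
  cl <- cluster_variables(m, c("x1", "x2"), n_clusters = 2)
  expect_true(all(lengths(cl$clusters) == 1))
  m$x2 <- 7
  expect_error(cluster_variables(m, c("x1", "x2"), 2), "constant column.*x2")
  m2 <- tiny_cohort(20); m2$x1[3] <- NA
  expect_error(cluster_variables(m2, c("x1", "x2"), 2), "missing values")
  expect_error(cluster_variables(tiny_cohort(20), c("x1", "x2"), 5),
               "n_clusters")
})

test_that("clustering is invariant to athlete order and affine index rescaling", {
  set.seed(8)
  base <- simulate_cohort(cohort_spec(paste0("v", 1:6), rep(5, 6), rep(1, 6),
                                      n = 80,
                                      blocks = list(paste0("v", 1:3),
                                                    paste0("v", 4:6)),
                                      seed = 8))
  ids <- paste0("v", 1:6)
  ref <- cluster_variables(base, ids, 2)$clusters
  perm <- base[sample(nrow(base)), ]
  perm$v2 <- -3 * perm$v2 + 100           # sign flip + affine rescale
  perm$v5 <- perm$v5 / 7 + 2
  got <- cluster_variables(perm, ids, 2)$clusters
  expect_identical(lapply(ref, sort), lapply(got, sort))
})

test_that("the best-explained cluster member wins the R-squared contest", {
  set.seed(4)
  b <- rnorm(60); c <- rnorm(60)
  m <- make_table(data.frame(a = (b + c) / 2 + rnorm(60, 0, 0.05),
                             b = b, c = c))
  ch <- representative_by_r2(c("a", "b", "c"), m)
  expect_identical(ch$chosen, "a")
  expect_identical(ch$rule, "max_r2")
  expect_gt(ch$r2[["a"]], 0.9)
  # independent closed form from the inverse correlation matrix
  oracle <- r2_from_correlation(as.data.frame(m)[, c("a", "b", "c")])
  expect_equal(unname(ch$r2), unname(oracle[c("a", "b", "c")]),
               tolerance = 1e-10)
})

test_that("r2 selection agrees with the closed-form oracle on random clusters", {
  set.seed(13)
  for (i in 1:20) {
    k <- sample(3:6, 1)
    n <- 40
    x <- matrix(rnorm(n * k), n, k) %*% matrix(rnorm(k * k, sd = 0.6), k, k)
    colnames(x) <- paste0("w", seq_len(k))
    m <- make_table(as.data.frame(x))
    ch <- representative_by_r2(colnames(x), m)
    oracle <- r2_from_correlation(x)
    expect_equal(unname(ch$r2), unname(oracle), tolerance = 1e-8)
    expect_identical(ch$chosen, names(which.max(oracle)))
  }
})

test_that("independent noise variables give near-zero R2 with a deterministic winner", {
  set.seed(6)
  m <- make_table(data.frame(a = rnorm(100), b = rnorm(100), c = rnorm(100)))
  ch <- representative_by_r2(c("a", "b", "c"), m)
  expect_true(all(ch$r2 < 0.15))
  expect_identical(ch$chosen, names(which.max(ch$r2)))
})

test_that("collinear clusters raise a singularity error", {
  x <- rnorm(30)
  m <- make_table(data.frame(a = x, b = x, c = x))
  expect_error(representative_by_r2(c("a", "b", "c"), m), "collinearity")
  expect_error(representative_by_r2(c("a", "b"), m), "fewer than 3")
})

test_that("representative selection dispatches singleton, override and regression rules", {
  set.seed(2)
  blocks <- list(c("p1", "p2", "p3", "p4"), c("pelvis", "shoulder"), "run")
  ids <- unlist(blocks)
  spec <- cohort_spec(ids, rep(20, 7), rep(3, 7), n = 100, blocks = blocks,
                      seed = 2)
  m <- simulate_cohort(spec)
  cl <- cluster_variables(m, ids, 3)
  pair_name <- names(Filter(function(x) setequal(x, c("pelvis", "shoulder")),
                            cl$clusters))
  choices <- select_representatives(cl, m,
                                    overrides = setNames(list("pelvis"),
                                                         pair_name))
  rules <- vapply(choices, `[[`, "", "rule")
  expect_setequal(unname(rules), c("singleton", "domain_override", "max_r2"))
  picked <- vapply(choices, `[[`, "", "chosen")
  expect_true("pelvis" %in% picked)
  expect_true("run" %in% picked)
  expect_error(select_representatives(cl, m), "override")
})
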