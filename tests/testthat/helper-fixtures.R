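# tiny two-level hierarchy used across io/standards tests
tiny_hierarchy <- function() {
  index_hierarchy(
    data.frame(id = c("p1", "x1", "x2"),
               level = c("primary", "tertiary", "tertiary"),
               parent_id = c(NA, "p1", "p1"),
               direction = c(NA, "high_optimal", "low_optimal")),
    weights = list(male = c(p1 = 1, x1 = 0.6, x2 = 0.4)))
}

# small deterministic cohort on the tiny hierarchy
tiny_cohort <- function(n = 12, seed = 1) {
  set.seed(seed)
  as_measurement_table(
    data.frame(athlete_id = sprintf("a%02d", seq_len(n)), sex = "male",
               x1 = rnorm(n, 50, 5), x2 = rnorm(n, 10, 1)),
    tiny_hierarchy())
}

# independent closed-form R^2 of each variable on the others, from the
# correlation matrix: R2_i = 1 - 1 / [R^-1]_ii
r2_from_correlation <- function(x) {
  Rinv <- solve(cor(x))
  1 - 1 / diag(Rinv)
}

# brute-force two-sided hypergeometric p for a 2x2 table
hyper_2x2_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}

# random margin-conditioned contingency table with all margins positive
random_table <- function(r, c, n) {
  repeat {
    tab <- matrix(0L, r, c)
    idx <- cbind(sample(r, n, TRUE), sample(c, n, TRUE))
    for (k in seq_len(n)) tab[idx[k, 1], idx[k, 2]] <- tab[idx[k, 1], idx[k, 2]] + 1L
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) return(tab)
  }
}
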