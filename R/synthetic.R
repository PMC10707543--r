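# save/restore the global RNG state so seeded simulations stay local
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Specify a synthetic athlete cohort
#'
#' Describes a two-tier, single-sex cohort of multivariate-normal index
#' measurements with block correlation structure: indexes inside one
#' block share correlation `within_block_r`, indexes of different blocks
#' `between_block_r`. Elite-tier athletes receive an additive shift of
#' `tier_effect` SD units in the favourable direction of each index
#' (positive for high-optimal, negated for low-optimal).
#'
#' @param indexes character vector of index ids.
#' @param means,sds numeric vectors of marginal means and SDs (SDs > 0).
#' @param sex `"male"` or `"female"`.
#' @param n number of athletes: a scalar (untired cohort) or a named
#'   vector `c(elite = ..., excellent = ...)`.
#' @param blocks list of index-id groups partitioning `indexes`; default
#'   every index in its own block (no within-block structure).
#' @param within_block_r,between_block_r block correlations (defaults
#'   0.8 and 0.1, strong enough that variable clustering recovers the
#'   blocks almost surely).
#' @param directions optimality direction per index (recycled;
#'   default high-optimal).
#' @param tier_effect elite-tier shift in SD units (default 0).
#' @param seed optional integer seed stored in the spec.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(indexes, means, sds, sex = "male", n = 100,
                        blocks = NULL, within_block_r = 0.8,
                        between_block_r = 0.1, directions = "high_optimal",
                        tier_effect = 0, seed = NULL) {
  sex <- match.arg(sex, SEXES)
  p <- length(indexes)
  stopifnot(length(means) == p, length(sds) == p)
  if (any(sds <= 0)) stop("SDs must be positive")
  blocks <- blocks %||% as.list(indexes)
  if (!setequal(unlist(blocks), indexes) || length(unlist(blocks)) != p)
    stop("blocks must partition the indexes")
  directions <- rep_len(directions, p)
  bad <- setdiff(directions, DIRECTIONS)
  if (length(bad)) stop("unknown direction '", bad[1], "'")
  if (!is.null(names(n)) || length(n) > 1) {
    if (length(n) != 2 || !setequal(names(n), c("elite", "excellent")))
      stop("n must be scalar or named c(elite = , excellent = )")
  }
  spec <- structure(list(indexes = indexes, means = setNames(means, indexes),
                         sds = setNames(sds, indexes), sex = sex, n = n,
                         blocks = blocks, within_block_r = within_block_r,
                         between_block_r = between_block_r,
                         directions = setNames(directions, indexes),
                         tier_effect = tier_effect, seed = seed),
                    class = "cohort_spec")
  spec$correlation <- .block_correlation(spec)   # validates positive definiteness
  spec
}

# assemble the block correlation matrix, shrinking toward identity if needed
.block_correlation <- function(spec, max_shrink = 50) {
  p <- length(spec$indexes)
  R <- matrix(spec$between_block_r, p, p,
              dimnames = list(spec$indexes, spec$indexes))
  for (b in spec$blocks) R[b, b] <- spec$within_block_r
  diag(R) <- 1
  for (i in 0:max_shrink) {
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) > 1e-8)
      return(R)
    R <- 0.9 * R + 0.1 * diag(p)
    dimnames(R) <- list(spec$indexes, spec$indexes)
  }
  stop("block correlation matrix is not positive definite even after shrinkage")
}

#' Draw a synthetic cohort
#'
#' Multivariate normal draws with the spec's block correlation and
#' marginal means/SDs, the elite-tier shift applied, and values
#' truncated at zero (anthropometric and performance measurements cannot
#' be negative). Deterministic under a fixed seed.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; defaults to the seed stored in the spec.
#' @return a `measurement_table` with columns `athlete_id`, `sex`,
#'   `tier` (when the spec is tiered) and one column per index.
#' @export
simulate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  tiered <- length(spec$n) > 1
  ntot <- sum(spec$n)
  p <- length(spec$indexes)
  L <- chol(spec$correlation)
  Z <- matrix(rnorm(ntot * p), ntot, p)
  X <- Z %*% L
  X <- sweep(X, 2, spec$sds, `*`)
  X <- sweep(X, 2, spec$means, `+`)
  colnames(X) <- spec$indexes
  tier <- if (tiered)
    rep(c("elite", "excellent"), c(spec$n[["elite"]], spec$n[["excellent"]]))
  else rep("excellent", ntot)
  if (tiered && spec$tier_effect != 0) {
    shift <- spec$tier_effect * spec$sds *
      ifelse(spec$directions == "high_optimal", 1, -1)
    X[tier == "elite", ] <- sweep(X[tier == "elite", , drop = FALSE], 2,
                                  shift, `+`)
  }
  X <- pmax(X, 0)
  out <- data.frame(athlete_id = sprintf("ath%04d", seq_len(ntot)),
                    sex = spec$sex, stringsAsFactors = FALSE)
  if (tiered) out$tier <- tier
  out <- cbind(out, as.data.frame(X))
  class(out) <- c("measurement_table", "data.frame")
  out
}

#' Specify a synthetic expert panel
#'
#' Each item is scored on the 1..5 importance scale under one of three
#' consensus regimes: `high` concentrates mass on 4-5 (P(5) = 0.6,
#' P(4) = 0.35, P(3) = 0.05), `medium` centres on 3-4 with wider spread,
#' `low` is near-uniform.
#'
#' @param n_experts number of experts (rows).
#' @param items character vector of item ids, or an integer count.
#' @param consensus per-item consensus level in `{"high", "medium",
#'   "low"}` (recycled).
#' @param seed optional integer seed.
#' @return list of class `panel_spec`.
#' @export
panel_spec <- function(n_experts, items, consensus = "high", seed = NULL) {
  if (is.numeric(items) && length(items) == 1)
    items <- paste0("item", seq_len(items))
  consensus <- rep_len(consensus, length(items))
  bad <- setdiff(consensus, c("high", "medium", "low"))
  if (length(bad)) stop("unknown consensus level '", bad[1], "'")
  structure(list(n_experts = n_experts, items = items,
                 consensus = setNames(consensus, items), seed = seed),
            class = "panel_spec")
}

.CONSENSUS_PROBS <- list(
  high   = c(0, 0, 0.05, 0.35, 0.60),
  medium = c(0.05, 0.15, 0.30, 0.35, 0.15),
  low    = c(0.20, 0.20, 0.20, 0.20, 0.20))

#' Draw a synthetic expert panel
#'
#' @param spec a [panel_spec()].
#' @param seed integer seed; defaults to the spec's.
#' @return an `expert_scores` matrix, experts x items.
#' @export
simulate_expert_panel <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "panel_spec"))
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  m <- vapply(spec$items, function(item)
    sample(1:5, spec$n_experts, replace = TRUE,
           prob = .CONSENSUS_PROBS[[spec$consensus[[item]]]]),
    numeric(spec$n_experts))
  m <- matrix(m, nrow = spec$n_experts,
              dimnames = list(NULL, spec$items))
  as_expert_scores(m)
}

#' Default synthetic cohort spec for the aerials reference system
#'
#' Marginal means and SDs are the published general-model values for the
#' eleven representative indexes; each representative stems from a
#' different variable cluster, so blocks are singletons and the residual
#' between-index correlation is the default 0.1.
#'
#' @param sex `"male"` or `"female"`.
#' @param n cohort size (scalar or named elite/excellent vector);
#'   defaults to the published tier sizes (male 6 + 9, female 5 + 9).
#' @param tier_effect elite shift in SD units (default 1).
#' @param seed optional integer seed.
#' @return a [cohort_spec()].
#' @export
aerials_cohort_spec <- function(sex = "male", n = NULL, tier_effect = 1,
                                seed = NULL) {
  sex <- match.arg(sex, SEXES)
  gm <- aerials_general_model(sex)
  h <- aerials_hierarchy()
  n <- n %||% if (sex == "male") c(elite = 6, excellent = 9)
              else c(elite = 5, excellent = 9)
  cohort_spec(indexes = gm$index, means = gm$mean, sds = gm$sd, sex = sex,
              n = n, blocks = as.list(gm$index),
              directions = index_direction(h, gm$index),
              tier_effect = tier_effect, seed = seed)
}
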