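#' Rating-by-group contingency table
#'
#' Cross-tabulates rating labels against cohort groups (e.g. elite vs
#' excellent tier), with all five rating levels always present as rows.
#'
#' @param rating character vector of rating labels (Fail .. Excellent).
#' @param group parallel vector of group labels.
#' @return integer matrix of class `rating_contingency`, 5 rows
#'   (Fail..Excellent) by one column per group; column sums equal group
#'   sizes.
#' @export
rating_frequency <- function(rating, group) {
  if (!length(rating)) stop("no rated reports")
  if (length(rating) != length(group)) stop("rating and group lengths differ")
  if (anyNA(group)) stop("athlete with missing group label")
  bad <- setdiff(unique(rating), RATING_LEVELS)
  if (length(bad)) stop("unknown rating label '", bad[1], "'")
  tab <- table(factor(rating, levels = RATING_LEVELS), factor(group))
  m <- matrix(as.integer(tab), nrow = length(RATING_LEVELS),
              dimnames = list(rating = RATING_LEVELS,
                              group = colnames(tab)))
  structure(m, class = c("rating_contingency", class(m)))
}

# log multivariate-hypergeometric probability constant and table term
.log_table_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

#' Exact r x c test of independence by full enumeration
#'
#' Two-sided exact test conditioning on both margins: enumerates every
#' contingency table with the observed row and column sums, computes its
#' multivariate-hypergeometric probability, and sums the probabilities of
#' all tables no more probable than the observed one (the standard exact
#' r x c convention). Probabilities are compared in log space with a
#' relative tolerance of `tol` on the "<=" comparison, so ties at the
#' observed probability are always included. All-zero rows and columns
#' are dropped before testing (they contribute nothing). For 2 x 2
#' tables the result coincides with the classical hypergeometric
#' two-sided sum.
#'
#' @param table integer matrix of counts (e.g. a [rating_frequency()]
#'   result); total n must not exceed `max_n`.
#' @param tol relative tolerance for probability comparisons.
#' @param max_n enumeration bound (default 40); beyond it the full table
#'   set is too large and [fisher_exact_mc()] should be used.
#' @return the exact two-sided p-value in (0, 1].
#' @seealso [fisher_exact_mc()] for the seeded Monte Carlo fallback.
#' @export
#' @examples
#' fisher_exact(matrix(c(1, 9, 11, 3), 2, 2))
fisher_exact <- function(table, tol = 1e-9, max_n = 40) {
  tab <- as.matrix(unclass(table))
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be ",
                                                   "non-negative integers")
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need at least 2 non-empty rows and 2 non-empty columns")
  n <- sum(tab)
  if (n > max_n)
    stop("n = ", n, " exceeds the enumeration bound (", max_n,
         "); use fisher_exact_mc() for a seeded Monte Carlo p-value")
  rs <- rowSums(tab); cs <- colSums(tab)
  lp_obs <- .log_table_prob(tab)
  cutoff <- lp_obs + log1p(tol)

  r <- length(rs); cdim <- length(cs)
  acc <- new.env(parent = emptyenv()); acc$p <- 0
  cur <- matrix(0L, r, cdim)

  fill_cell <- function(i, j, row_left, col_left) {
    if (j == cdim) {                      # last cell of row fixed by margin
      v <- row_left
      if (v > col_left[j]) return(invisible())
      cur[i, j] <<- v
      col_left[j] <- col_left[j] - v
      next_row(i, col_left)
      return(invisible())
    }
    for (v in 0:min(row_left, col_left[j])) {
      cur[i, j] <<- v
      cl <- col_left; cl[j] <- cl[j] - v
      fill_cell(i, j + 1, row_left - v, cl)
    }
  }
  next_row <- function(i, col_left) {
    if (i == r - 1) {                      # last row fixed by column margins
      cur[r, ] <<- col_left
      lp <- .log_table_prob(cur)
      if (lp <= cutoff) acc$p <- acc$p + exp(lp)
      return(invisible())
    }
    fill_cell(i + 1, 1, rs[i + 1], col_left)
  }
  next_row(0, cs)
  min(acc$p, 1)
}

#' Monte Carlo p-value for the exact r x c test
#'
#' Samples tables with the observed margins from the conditional null
#' (Patefield's algorithm via [stats::r2dtable()]) and estimates the
#' probability that a table is no more probable than the observed one.
#' Uses the add-one estimator (n_extreme + 1) / (n_sim + 1), which is
#' never zero.
#'
#' @inheritParams fisher_exact
#' @param n_sim number of sampled tables.
#' @param seed optional integer seed (local to this call).
#' @return list with `p`, its Monte Carlo standard error `se`, and
#'   `n_sim`.
#' @export
fisher_exact_mc <- function(table, n_sim = 1e5, seed = NULL, tol = 1e-9) {
  tab <- as.matrix(unclass(table))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need at least 2 non-empty rows and 2 non-empty columns")
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  cutoff <- .log_table_prob(tab) + log1p(tol)
  sims <- r2dtable(n_sim, rowSums(tab), colSums(tab))
  hits <- vapply(sims, function(s) .log_table_prob(s) <= cutoff, logical(1))
  p <- (sum(hits) + 1) / (n_sim + 1)
  list(p = p, se = sqrt(p * (1 - p) / n_sim), n_sim = n_sim)
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation computed from the full O(n^2)
#' concordant/discordant pair count; appropriate for test-retest
#' stability of composite scores, where ties on a 2-decimal scale are
#' common.
#'
#' @param first,second paired numeric vectors, length >= 3.
#' @return tau-b in \[-1, 1\].
#' @export
#' @examples
#' kendall_tau(1:8, c(2, 1, 3, 4, 5, 6, 8, 7))  # two swapped pairs
kendall_tau <- function(first, second) {
  if (length(first) != length(second)) stop("paired lists of equal length required")
  n <- length(first)
  if (n < 3) stop("need at least 3 paired observations")
  if (anyNA(first) || anyNA(second)) stop("missing values not allowed")
  if (length(unique(first)) == 1 || length(unique(second)) == 1)
    stop("all values tied; tau undefined")
  dx <- sign(outer(first, first, `-`))
  dy <- sign(outer(second, second, `-`))
  s <- sum(dx * dy * upper.tri(dx))
  n0 <- n * (n - 1) / 2
  n1 <- sum(choose(table(first), 2))
  n2 <- sum(choose(table(second), 2))
  s / sqrt((n0 - n1) * (n0 - n2))
}
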