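#' Validate an expert score table
#'
#' Expert panels score candidate indexes on a five-level importance scale.
#' The table is a numeric matrix with one row per expert and one column
#' per item; every cell must be an integer in 1..5.
#'
#' @param x matrix or data.frame of expert-by-item scores.
#' @return numeric matrix of class `expert_scores`.
#' @export
as_expert_scores <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) colnames(m) <- paste0("item", seq_len(ncol(m)))
  ok <- is.na(m) | (m >= 1 & m <= 5 & m == round(m))
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("score at expert %d, item '%s' is not an integer in 1..5",
                 bad[1], colnames(m)[bad[2]]))
  }
  structure(m, class = c("expert_scores", class(m)))
}

#' Delphi retention screening of candidate indexes
#'
#' For each item, computes the panel mean, sample standard deviation
#' (n - 1 denominator) and coefficient of variation CV = SD / mean, and
#' retains items with mean >= 4.0 (inclusive) and CV < 0.25 (strict).
#'
#' @param scores an expert-by-item score table ([as_expert_scores()]);
#'   at least 2 experts, no missing cells among screened items.
#' @param items optional character vector restricting the items screened.
#' @return data.frame of class `delphi_screening` with columns `item`,
#'   `mean`, `sd`, `cv`, `retained`.
#' @export
#' @examples
#' s <- as_expert_scores(rbind(c(4, 5), c(4, 1), c(5, 5), c(3, 1),
#'                             c(4, 5), c(4, 1)))
#' screen_items(s)
screen_items <- function(scores, items = NULL) {
  scores <- as_expert_scores(scores)
  if (!is.null(items)) {
    missing_items <- setdiff(items, colnames(scores))
    if (length(missing_items))
      stop("unknown item '", missing_items[1], "'")
    scores <- scores[, items, drop = FALSE]
  }
  if (nrow(scores) < 2) stop("screening needs at least 2 experts")
  if (anyNA(scores)) {
    bad <- colnames(scores)[colSums(is.na(scores)) > 0]
    stop("missing scores for item: ", paste(bad, collapse = ", "))
  }
  mu <- colMeans(scores)
  if (any(mu <= 0)) stop("non-positive item mean; scores must lie in 1..5")
  s <- apply(scores, 2, sd)
  cv <- s / mu
  out <- data.frame(item = colnames(scores), mean = unname(mu),
                    sd = unname(s), cv = unname(cv),
                    retained = unname(mu >= 4 & cv < 0.25),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("delphi_screening", "data.frame")
  out
}

#' Expert authority coefficient
#'
#' The authority of an expert is the arithmetic mean of their
#' judgment-basis and familiarity self-ratings (both fractions in
#' \[0, 1\]); a coefficient >= 0.70 denotes a high degree of authority.
#'
#' @param judgment_basis numeric in \[0, 1\].
#' @param familiarity numeric in \[0, 1\] (recycled against
#'   `judgment_basis`).
#' @return data.frame with columns `coefficient` and `high_authority`.
#' @export
#' @examples
#' authority_coefficient(0.90, 0.82)  # 0.86, high
authority_coefficient <- function(judgment_basis, familiarity) {
  if (any(!is.finite(judgment_basis)) || any(!is.finite(familiarity)) ||
      any(judgment_basis < 0 | judgment_basis > 1) ||
      any(familiarity < 0 | familiarity > 1))
    stop("judgment_basis and familiarity must lie in [0, 1]")
  coefficient <- (judgment_basis + familiarity) / 2
  data.frame(coefficient = coefficient, high_authority = coefficient >= 0.70)
}

#' Test-retest reliability of repeated expert questionnaires
#'
#' Correlation between the paired scores of two survey rounds, pooled
#' over all (expert, item) cells. The estimator is configurable: Pearson
#' (default) or Spearman.
#'
#' @param first,second expert score tables with identical experts (rows)
#'   and items (columns).
#' @param method `"pearson"` or `"spearman"`.
#' @return correlation coefficient in \[-1, 1\].
#' @export
retest_reliability <- function(first, second, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  first <- as_expert_scores(first)
  second <- as_expert_scores(second)
  if (!identical(dim(first), dim(second)) ||
      !identical(colnames(first), colnames(second)))
    stop("the two rounds must cover the same experts and items")
  x <- as.vector(unclass(first))
  y <- as.vector(unclass(second))
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in a round; correlation undefined")
  cor(x, y, method = method)
}
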