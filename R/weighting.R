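#' Five-level frequency scores of expert importance ratings
#'
#' For each item, counts the number of experts giving each level 1..5 and
#' sums level times frequency — algebraically the column sum of the raw
#' scores, computed here via the frequency decomposition the elicitation
#' protocol describes.
#'
#' @param scores an expert-by-item score table ([as_expert_scores()]).
#' @param items optional subset of item ids.
#' @return named numeric vector, item -> total score.
#' @export
#' @examples
#' # 8 fives, 4 fours, 2 threes -> 62
#' level_frequency_scores(matrix(rep(c(5, 4, 3), c(8, 4, 2)), ncol = 1))
level_frequency_scores <- function(scores, items = NULL) {
  scores <- as_expert_scores(scores)
  if (!is.null(items)) {
    miss <- setdiff(items, colnames(scores))
    if (length(miss)) stop("unknown item '", miss[1], "'")
    scores <- scores[, items, drop = FALSE]
  }
  if (nrow(scores) == 0) stop("empty expert set")
  if (anyNA(scores)) stop("missing scores")
  vapply(colnames(scores), function(item) {
    freq <- tabulate(scores[, item], nbins = 5)
    sum(seq_len(5) * freq)
  }, numeric(1))
}

#' Summation-normalization weights
#'
#' Converts per-item total scores of one sibling set into weights
#' w_i = total_i / sum(total), which sum to 1 exactly before any display
#' rounding.
#'
#' @param totals positive named numeric vector of item total scores.
#' @return named numeric vector of weights.
#' @export
#' @examples
#' normalize_weights(c(a = 62, b = 70, c = 84))
normalize_weights <- function(totals) {
  if (!length(totals)) stop("empty totals")
  if (any(!is.finite(totals)) || any(totals < 0))
    stop("totals must be finite and non-negative")
  if (sum(totals) == 0) stop("degenerate input: all totals are zero")
  totals / sum(totals)
}

#' Derive sibling-set weights from an expert panel
#'
#' Runs [level_frequency_scores()] + [normalize_weights()] within every
#' sibling set of the hierarchy (the tertiary children of each primary,
#' and the primaries themselves) and attaches the result for the given
#' sex. Published weight tables can instead be attached directly with
#' [set_weights()].
#'
#' @param hierarchy an [index_hierarchy()].
#' @param scores expert-by-item table whose columns cover every primary
#'   and tertiary index id.
#' @param sex `"male"` or `"female"`.
#' @return the hierarchy with derived weights attached for `sex`.
#' @export
derive_weights <- function(hierarchy, scores, sex) {
  sex <- match.arg(sex, SEXES)
  scores <- as_expert_scores(scores)
  w <- numeric(0)
  for (set in sibling_sets(hierarchy)) {
    miss <- setdiff(set, colnames(scores))
    if (length(miss)) stop("no expert scores for index '", miss[1], "'")
    w <- c(w, normalize_weights(level_frequency_scores(scores, set)))
  }
  weights <- hierarchy$weights %||% list()
  weights[[sex]] <- w
  set_weights(hierarchy, weights)
}
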