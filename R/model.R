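#' Fit a physical-fitness evaluation model to a reference cohort
#'
#' The central fitting function. From a single-sex reference cohort of
#' raw measurements it builds the complete evaluation apparatus:
#' per-index percentile scoring standards (P10/P25/P50/P75/P90 bands,
#' direction-aware), the three-stage weighted scoring of the cohort
#' itself, the composite (primary + comprehensive) rating standard
#' derived from those scores, the general model (per-index mean and SD)
#' and the ideal model (directional 90th-percentile targets).
#'
#' @param data a `measurement_table` (or coercible data.frame) holding
#'   the reference cohort; rows of other sexes are ignored.
#' @param sex which sex to fit, `"male"` or `"female"`.
#' @param hierarchy an [index_hierarchy()] carrying weights for `sex`;
#'   defaults to the published aerials system ([aerials_hierarchy()]).
#' @param type percentile estimator type (see [stats::quantile()];
#'   default 7, linear interpolation between order statistics).
#' @return object of class `fitness_model` with elements `hierarchy`,
#'   `sex`, `n`, `standards` (per-index [scoring_standard()]s),
#'   `reports` (the training cohort's `score_report`), `composite`
#'   ([composite_standard()]), `general` and `ideal`
#'   (`fitness_profile`s), `call`.
#' @seealso [predict.fitness_model()] to score new athletes,
#'   [aerials_reference_model()] for the published system.
#' @export
#' @examples
#' cohort <- simulate_cohort(aerials_cohort_spec("male", n = 60, seed = 1))
#' fm <- fitness_model(cohort, sex = "male")
#' head(predict(fm, cohort))
fitness_model <- function(data, sex, hierarchy = aerials_hierarchy(),
                          type = 7) {
  sex <- match.arg(sex, SEXES)
  data <- as_measurement_table(as.data.frame(data), hierarchy)
  data <- data[data$sex == sex, , drop = FALSE]
  if (nrow(data) < 10)
    stop("need at least 10 athletes of sex '", sex, "' to build standards")
  w <- hierarchy_weights(hierarchy, sex)   # fails early if weights absent
  stopifnot(length(w) > 0)
  terts <- tertiary_ids(hierarchy)
  standards <- lapply(terts, function(id)
    build_scoring_standard(data[[id]], index_direction(hierarchy, id),
                           index = id, sex = sex, type = type,
                           units = hierarchy$nodes$units[
                             hierarchy$nodes$id == id]))
  names(standards) <- terts
  bands <- band_scores(data, standards)
  reports <- aggregate_scores(bands, hierarchy, sex)
  composite <- build_composite_standard(reports, sex, type = type)
  general <- build_general_model(data, terts, sex)
  ideal <- build_ideal_model(standards)
  structure(list(hierarchy = hierarchy, sex = sex, n = nrow(data),
                 standards = standards, reports = reports,
                 composite = composite, general = general, ideal = ideal,
                 source = "fitted", call = match.call()),
            class = "fitness_model")
}

#' The published aerials evaluation system as a fitness model
#'
#' Assembles a `fitness_model` from the bundled published fixtures
#' (per-index cutoffs, composite cutoffs, weights, general and ideal
#' models) instead of fitting to raw data, which the source never
#' deposited. [predict()] works as for a fitted model.
#'
#' @param sex `"male"` or `"female"`.
#' @return a `fitness_model` (element `source = "published"`).
#' @export
aerials_reference_model <- function(sex = "male") {
  sex <- match.arg(sex, SEXES)
  structure(list(hierarchy = aerials_hierarchy(), sex = sex,
                 n = if (sex == "male") 15L else 14L,
                 standards = aerials_standards(sex), reports = NULL,
                 composite = aerials_composite_standard(sex),
                 general = aerials_general_model(sex),
                 ideal = aerials_ideal_model(sex),
                 source = "published", call = match.call()),
            class = "fitness_model")
}

#' Score and rate athletes with a fitness model
#'
#' Bands each tertiary measurement against the model's scoring
#' standards, runs the three-stage weighted aggregation, and rates the
#' primary and comprehensive weighted scores against the composite
#' standard.
#'
#' @param object a `fitness_model`.
#' @param newdata a `measurement_table` (or coercible data.frame) of the
#'   model's sex; defaults to the training cohort.
#' @param ... unused.
#' @return a `score_report` data.frame with rating columns appended and
#'   per-tertiary band scores in attribute `bands`.
#' @export
predict.fitness_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$reports))
      stop("published reference model has no training cohort; supply newdata")
    reports <- object$reports
    bands <- NULL
  } else {
    newdata <- as_measurement_table(as.data.frame(newdata), object$hierarchy)
    other <- newdata$sex != object$sex
    if (any(other))
      stop("newdata contains ", sum(other), " athlete(s) not of sex '",
           object$sex, "'")
    bands <- band_scores(newdata, object$standards)
    reports <- aggregate_scores(bands, object$hierarchy, object$sex)
  }
  out <- rate_reports(reports, object$composite)
  attr(out, "bands") <- bands
  out
}

#' @export
print.fitness_model <- function(x, ...) {
  cat("Physical-fitness evaluation model (", x$sex, ", ", x$source,
      "), reference n = ", x$n, "\n", sep = "")
  cat("  ", length(primary_ids(x$hierarchy)), " primary domains, ",
      length(x$standards), " tertiary indexes\n", sep = "")
  cs <- x$composite$columns$comprehensive$cutoffs
  cat(sprintf("  comprehensive bands: <%.2f | %.2f | %.2f | %.2f | >%.2f\n",
              cs[["p10"]], cs[["p25"]], cs[["p75"]], cs[["p90"]], cs[["p90"]]))
  invisible(x)
}

#' @export
summary.fitness_model <- function(object, ...) {
  cuts <- t(vapply(object$standards, function(s) s$cutoffs, numeric(5)))
  comp <- t(vapply(object$composite$columns, function(s) s$cutoffs, numeric(5)))
  out <- list(sex = object$sex, n = object$n, source = object$source,
              cutoffs = cuts, composite = comp,
              weights = coef(object), general = object$general,
              ideal = object$ideal)
  class(out) <- "summary.fitness_model"
  out
}

#' @export
print.summary.fitness_model <- function(x, ...) {
  cat("Fitness evaluation model (", x$sex, ", ", x$source, "), n = ", x$n,
      "\n\nPer-index dividing points:\n", sep = "")
  print(round_display(x$cutoffs, 2))
  cat("\nComposite dividing points (weighted-score scale):\n")
  print(round_display(x$composite, 2))
  cat("\nWeights:\n")
  print(x$weights)
  invisible(x)
}

#' Weights of a fitness model
#'
#' @param object a `fitness_model`.
#' @param ... unused.
#' @return named numeric vector of the model's sex-specific weights
#'   (primaries and tertiary indexes).
#' @export
coef.fitness_model <- function(object, ...) {
  hierarchy_weights(object$hierarchy, object$sex)
}

#' Simulate cohorts from a fitness model's general profile
#'
#' Draws synthetic cohorts whose marginal means and SDs are the model's
#' general-model values (independent indexes; use [cohort_spec()]
#' directly for block-correlated designs).
#'
#' @param object a `fitness_model`.
#' @param nsim number of cohorts.
#' @param seed integer seed.
#' @param n athletes per cohort (default: the model's reference n).
#' @param ... unused.
#' @return a `measurement_table`, or a list of them when `nsim > 1`.
#' @export
simulate.fitness_model <- function(object, nsim = 1, seed = NULL,
                                   n = object$n, ...) {
  gm <- object$general
  spec <- cohort_spec(indexes = gm$index, means = gm$mean, sds = gm$sd,
                      sex = object$sex, n = n, blocks = as.list(gm$index),
                      between_block_r = 0,
                      directions = index_direction(object$hierarchy, gm$index))
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  sims <- lapply(seq_len(nsim), function(i) simulate_cohort(spec, seed = NULL))
  if (nsim == 1) sims[[1]] else sims
}

#' Plot a fitness model's scoring bands
#'
#' One horizontal band chart per tertiary index on the standardized
#' scale (cutoffs centred on the general-model mean, in SD units), with
#' low-optimal indexes flipped so that "better" always points right.
#'
#' @param x a `fitness_model`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fitness_model <- function(x, ...) {
  gm <- x$general
  ids <- gm$index
  z <- t(vapply(seq_along(ids), function(i) {
    s <- x$standards[[ids[i]]]
    cut <- (s$cutoffs[c("p10", "p25", "p75", "p90")] - gm$mean[i]) / gm$sd[i]
    if (s$direction == "low_optimal") -rev(cut) else cut
  }, numeric(4)))
  k <- length(ids)
  graphics::plot(NULL, xlim = range(z, -2.5, 2.5), ylim = c(0.5, k + 0.5),
                 yaxt = "n", xlab = "standardized cutoff (SD units, better →)",
                 ylab = "", ...)
  graphics::axis(2, at = seq_len(k), labels = ids, las = 2, cex.axis = 0.7)
  for (i in seq_len(k)) {
    graphics::segments(min(z[i, ]) - 1, i, max(z[i, ]) + 1, i,
                       col = "grey80")
    graphics::points(z[i, ], rep(i, 4), pch = 3)
  }
  invisible(x)
}
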