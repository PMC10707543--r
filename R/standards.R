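#' Construct a per-index scoring standard
#'
#' A scoring standard holds the percentile dividing points of one index
#' in one sex's reference cohort and orients the five scoring bands by
#' the index's optimality direction. P50 is stored among the dividing
#' points but plays no role in banding.
#'
#' @param index index id.
#' @param sex `"male"` or `"female"`.
#' @param direction `"high_optimal"` or `"low_optimal"`.
#' @param p10,p25,p75,p90 band cutoffs in the index's units,
#'   non-decreasing.
#' @param p50 optional median (published cutoff tables omit it).
#' @param units free-text units string.
#' @return object of class `scoring_standard`.
#' @export
scoring_standard <- function(index, sex, direction, p10, p25, p75, p90,
                             p50 = NA_real_, units = "") {
  direction <- match.arg(direction, DIRECTIONS)
  sex <- match.arg(sex, SEXES)
  cuts <- c(p10 = p10, p25 = p25, p50 = p50, p75 = p75, p90 = p90)
  known <- cuts[!is.na(cuts)]
  if (any(!is.finite(known))) stop("non-finite cutoff for '", index, "'")
  if (is.unsorted(known)) stop("cutoffs of '", index, "' are not ordered ",
                               "P10 <= P25 <= P50 <= P75 <= P90")
  structure(list(index = index, sex = sex, direction = direction,
                 cutoffs = cuts, units = units),
            class = "scoring_standard")
}

#' Build a percentile scoring standard from a reference cohort
#'
#' Computes the empirical P10/P25/P50/P75/P90 dividing points of the
#' values by linear interpolation between order statistics
#' ([stats::quantile()] type 7 by default; the estimator is
#' configurable), giving theoretical band occupancies of
#' 10/15/50/15/10 percent.
#'
#' @param values numeric vector, >= 10 non-missing finite values.
#' @param direction optimality direction of the index.
#' @param index,sex,units metadata carried into the standard.
#' @param type quantile estimator type (see [stats::quantile()]).
#' @return a [scoring_standard()].
#' @export
#' @examples
#' s <- build_scoring_standard(1:100, "high_optimal")
#' s$cutoffs[["p10"]]  # 10.9
build_scoring_standard <- function(values, direction, index = "", sex = "male",
                                   units = "", type = 7) {
  values <- values[!is.na(values)]
  if (any(!is.finite(values))) stop("non-finite values for '", index, "'")
  if (length(values) < 10)
    stop("insufficient sample for '", index, "': need >= 10 non-missing ",
         "values, got ", length(values))
  q <- quantile(values, probs = c(0.10, 0.25, 0.50, 0.75, 0.90),
                type = type, names = FALSE)
  scoring_standard(index, sex, direction, p10 = q[1], p25 = q[2], p50 = q[3],
                   p75 = q[4], p90 = q[5], units = units)
}

#' @export
print.scoring_standard <- function(x, ...) {
  cat("Scoring standard '", x$index, "' (", x$sex, ", ", x$direction,
      if (nzchar(x$units)) paste0(", ", x$units), ")\n", sep = "")
  print(round_display(x$cutoffs, 2))
  invisible(x)
}

#' Band score of a measurement against a scoring standard
#'
#' Five-band mapping fixed by the published band typography. For a
#' high-optimal index: value > P90 scores 5 (Excellent); P75 < value <=
#' P90 scores 4 (Good); P25 <= value <= P75 scores 3 (Average, closed at
#' both ends); P10 <= value < P25 scores 2 (Poor); value < P10 scores 1
#' (Fail). Low-optimal indexes mirror the mapping (value < P10 scores
#' 5, ..., value > P90 scores 1). A degenerate standard (all cutoffs
#' equal) carries no discriminating information: every value scores 3.
#'
#' @param value numeric vector of raw measurements.
#' @param standard a [scoring_standard()].
#' @return integer band scores in 1..5 (`NA` for missing values).
#' @export
score_index <- function(value, standard) {
  stopifnot(inherits(standard, "scoring_standard"))
  cut <- standard$cutoffs
  p10 <- cut[["p10"]]; p25 <- cut[["p25"]]
  p75 <- cut[["p75"]]; p90 <- cut[["p90"]]
  if (p10 == p90) return(ifelse(is.na(value), NA_integer_, 3L))
  hi <- ifelse(value > p90, 5L,
        ifelse(value > p75, 4L,
        ifelse(value >= p25, 3L,
        ifelse(value >= p10, 2L, 1L))))
  lo <- ifelse(value < p10, 5L,
        ifelse(value < p25, 4L,
        ifelse(value <= p75, 3L,
        ifelse(value <= p90, 2L, 1L))))
  out <- if (standard$direction == "high_optimal") hi else lo
  out[is.na(value)] <- NA_integer_
  as.integer(out)
}

#' Band scores of a cohort on all indexes
#'
#' @param measurements a `measurement_table`.
#' @param standards named list of [scoring_standard()]s keyed by index id.
#' @return integer matrix, athletes x indexes, rownames = athlete ids.
#' @export
band_scores <- function(measurements, standards) {
  ids <- names(standards)
  miss <- setdiff(ids, names(measurements))
  if (length(miss)) stop("measurements lack index '", miss[1], "'")
  m <- sapply(ids, function(i)
    score_index(as.data.frame(measurements)[[i]], standards[[i]]))
  m <- matrix(as.integer(m), ncol = length(ids),
              dimnames = list(measurements$athlete_id, ids))
  m
}

#' Three-stage weighted aggregation of band scores
#'
#' Implements the weighted composite score N = sum(n_i w_i): each
#' tertiary band score n_i is multiplied by its tertiary weight w_i; the
#' weighted scores of one primary's tertiary children sum to the primary
#' (unweighted) score; that score times the primary weight gives the
#' primary weighted score; the three primary weighted scores sum to the
#' comprehensive score N. All arithmetic is at full precision; display
#' rounding happens only in [write_report()].
#'
#' @param bands integer matrix from [band_scores()] (or a named vector
#'   for a single athlete), one column per tertiary index of the
#'   hierarchy.
#' @param hierarchy an [index_hierarchy()] with weights for `sex`.
#' @param sex which weight map to use.
#' @return data.frame of class `score_report`: `athlete_id`, per-primary
#'   `<id>_unweighted` and `<id>` (weighted) columns, `comprehensive`.
#'   The per-tertiary weighted scores are attached as attribute
#'   `tertiary_weighted`; the primary ids as attribute `primaries`.
#' @export
aggregate_scores <- function(bands, hierarchy, sex) {
  if (is.null(dim(bands))) bands <- t(as.matrix(bands))
  w <- hierarchy_weights(hierarchy, sex)
  prims <- primary_ids(hierarchy)
  terts <- tertiary_ids(hierarchy)
  miss <- setdiff(terts, colnames(bands))
  if (length(miss)) stop("no band score for tertiary index '", miss[1], "'")
  if (anyNA(bands[, terts]))
    stop("missing band scores; every tertiary index must be scored")
  miss <- setdiff(c(prims, terts), names(w))
  if (length(miss)) stop("no weight for index '", miss[1], "'")

  tw <- sweep(bands[, terts, drop = FALSE], 2, w[terts], `*`)
  out <- data.frame(athlete_id = rownames(bands) %||%
                      paste0("athlete", seq_len(nrow(bands))),
                    stringsAsFactors = FALSE, row.names = NULL)
  for (p in prims) {
    kids <- scored_children(hierarchy, p)
    unw <- rowSums(tw[, kids, drop = FALSE])
    out[[paste0(p, "_unweighted")]] <- unname(unw)
    out[[p]] <- unname(unw * w[[p]])
  }
  out$comprehensive <- rowSums(out[, prims, drop = FALSE])
  attr(out, "tertiary_weighted") <- tw
  attr(out, "primaries") <- prims
  class(out) <- c("score_report", "data.frame")
  out
}

#' Construct a composite (primary + comprehensive) standard
#'
#' @param sex `"male"` or `"female"`.
#' @param columns named list; each element a numeric vector with names
#'   `p10`, `p25`, `p75`, `p90` (optionally `p50`) on the weighted-score
#'   scale. Must include a `comprehensive` element.
#' @return object of class `composite_standard` whose `columns` are
#'   high-optimal [scoring_standard()]s.
#' @export
composite_standard <- function(sex, columns) {
  stopifnot(is.list(columns), length(names(columns)) == length(columns))
  cols <- lapply(names(columns), function(nm) {
    cv <- columns[[nm]]
    scoring_standard(nm, sex, "high_optimal",
                     p10 = cv[["p10"]], p25 = cv[["p25"]],
                     p50 = if ("p50" %in% names(cv)) cv[["p50"]] else NA_real_,
                     p75 = cv[["p75"]], p90 = cv[["p90"]])
  })
  names(cols) <- names(columns)
  structure(list(sex = sex, columns = cols), class = "composite_standard")
}

#' Build the composite standard from a cohort of score reports
#'
#' Applies [build_scoring_standard()] (high-optimal: larger weighted
#' scores are better) to each primary weighted-score column and to the
#' comprehensive column of the reports.
#'
#' @param reports a `score_report` data.frame (>= 10 rows).
#' @param sex sex of the cohort.
#' @param columns columns to band; defaults to the report's primary ids
#'   plus `comprehensive`.
#' @inheritParams build_scoring_standard
#' @return a [composite_standard()].
#' @export
build_composite_standard <- function(reports, sex, columns = NULL, type = 7) {
  columns <- columns %||% c(attr(reports, "primaries"), "comprehensive")
  if (is.null(columns)) stop("cannot infer report columns; pass `columns`")
  cols <- lapply(columns, function(nm) {
    s <- build_scoring_standard(reports[[nm]], "high_optimal", index = nm,
                                sex = sex, type = type)
    s$cutoffs
  })
  names(cols) <- columns
  composite_standard(sex, cols)
}

#' @export
print.composite_standard <- function(x, ...) {
  cat("Composite standard (", x$sex, ")\n", sep = "")
  tab <- t(sapply(x$columns, function(s) round_display(s$cutoffs, 2)))
  print(tab)
  invisible(x)
}

#' Rating label of a weighted score
#'
#' Maps a primary or comprehensive weighted score through the same
#' five-band rule as [score_index()] onto the labels Fail, Poor,
#' Average, Good, Excellent.
#'
#' @param score numeric weighted score(s).
#' @param standard a [composite_standard()].
#' @param which which column to rate: a primary id or `"comprehensive"`.
#' @return character vector of rating labels.
#' @export
#' @examples
#' cs <- composite_standard("male", list(
#'   comprehensive = c(p10 = 2.80, p25 = 2.85, p75 = 3.32, p90 = 3.53)))
#' rate(4.11, cs)  # Excellent
rate <- function(score, standard, which = "comprehensive") {
  stopifnot(inherits(standard, "composite_standard"))
  col <- standard$columns[[which]]
  if (is.null(col)) stop("composite standard has no column '", which, "'")
  RATING_LEVELS[score_index(score, col)]
}

#' Add rating labels to a score report
#'
#' @param reports a `score_report` data.frame.
#' @param standard a [composite_standard()] covering the report's primary
#'   and comprehensive columns.
#' @return the reports with `<column>_rating` character columns appended.
#' @export
rate_reports <- function(reports, standard) {
  for (nm in names(standard$columns)) {
    if (is.null(reports[[nm]])) stop("reports lack column '", nm, "'")
    reports[[paste0(nm, "_rating")]] <- rate(reports[[nm]], standard, nm)
  }
  reports
}

#' General fitness model: cohort mean and SD per representative index
#'
#' @param measurements a `measurement_table` with a `sex` column.
#' @param representatives character vector of representative index ids.
#' @param sex which sex's athletes enter the model (>= 2 required).
#' @return data.frame of class `fitness_profile` (kind `"general"`) with
#'   columns `index`, `mean`, `sd`, `n`.
#' @export
build_general_model <- function(measurements, representatives, sex) {
  sex <- match.arg(sex, SEXES)
  x <- as.data.frame(measurements)
  x <- x[x$sex == sex, , drop = FALSE]
  if (nrow(x) < 2) stop("need at least 2 athletes of sex '", sex, "'")
  miss <- setdiff(representatives, names(x))
  if (length(miss)) stop("measurements lack index '", miss[1], "'")
  out <- data.frame(index = representatives,
                    mean = vapply(representatives,
                                  function(i) mean(x[[i]], na.rm = TRUE), 0),
                    sd = vapply(representatives,
                                function(i) sd(x[[i]], na.rm = TRUE), 0),
                    n = vapply(representatives,
                               function(i) sum(!is.na(x[[i]])), 0),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, kind = "general", sex = sex,
            class = c("fitness_profile", "data.frame"))
}

#' Ideal fitness model: directional 90th-percentile targets
#'
#' The ideal profile takes, per representative index, the boundary of
#' the excellent band of the cohort's scoring standard: the P90 cutoff
#' with a `>=` target for high-optimal indexes, and the P10 cutoff with
#' a `<=` target for low-optimal indexes (e.g. sprint time).
#'
#' @param standards named list of [scoring_standard()]s.
#' @return data.frame of class `fitness_profile` (kind `"ideal"`) with
#'   columns `index`, `threshold`, `inequality`.
#' @export
build_ideal_model <- function(standards) {
  if (!length(standards)) stop("no scoring standards supplied")
  rows <- lapply(standards, function(s) {
    stopifnot(inherits(s, "scoring_standard"))
    if (s$direction == "high_optimal")
      data.frame(index = s$index, threshold = s$cutoffs[["p90"]],
                 inequality = ">=", stringsAsFactors = FALSE)
    else
      data.frame(index = s$index, threshold = s$cutoffs[["p10"]],
                 inequality = "<=", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  structure(out, kind = "ideal", sex = standards[[1]]$sex,
            class = c("fitness_profile", "data.frame"))
}
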