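# Accessors for the bundled freestyle-skiing-aerials reference system.
# The study's raw athlete measurements were never deposited; what the
# publication prints -- per-index cutoffs, composite cutoffs, weights,
# per-athlete weighted scores and ratings, general/ideal model values,
# rating frequencies -- ships here as plain-text fixtures.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "fitindex")
  if (path == "") stop("bundled fixture '", file, "' not found")
  path
}

#' Published per-index scoring standards
#'
#' The reference cutoffs (P10/P25/P75/P90) for the eleven representative
#' indexes, per sex. These are literal published values: the source
#' cohort's raw data are unavailable, so they cannot be rebuilt with
#' [build_scoring_standard()].
#'
#' @param sex `"male"` or `"female"`.
#' @return named list of [scoring_standard()]s keyed by index id.
#' @export
aerials_standards <- function(sex = "male") {
  sex <- match.arg(sex, SEXES)
  tab <- read.csv(.extdata("single_index_standards.csv"),
                  stringsAsFactors = FALSE)
  tab <- tab[tab$sex == sex, ]
  out <- lapply(seq_len(nrow(tab)), function(i)
    scoring_standard(tab$index[i], sex, tab$direction[i],
                     p10 = tab$p10[i], p25 = tab$p25[i],
                     p75 = tab$p75[i], p90 = tab$p90[i], units = tab$units[i]))
  names(out) <- tab$index
  out
}

#' Published composite (primary + comprehensive) standard
#'
#' @inheritParams aerials_standards
#' @return a [composite_standard()].
#' @export
aerials_composite_standard <- function(sex = "male") {
  sex <- match.arg(sex, SEXES)
  tab <- read.csv(.extdata("composite_standards.csv"), stringsAsFactors = FALSE)
  tab <- tab[tab$sex == sex, ]
  cols <- lapply(seq_len(nrow(tab)), function(i)
    c(p10 = tab$p10[i], p25 = tab$p25[i], p75 = tab$p75[i], p90 = tab$p90[i]))
  names(cols) <- tab$column
  composite_standard(sex, cols)
}

#' Published per-athlete weighted scores
#'
#' The 29 athletes' primary weighted scores and comprehensive scores
#' (both tiers, both sexes) as printed, at 2-decimal precision. The
#' added logical column `consistent` flags rows whose three primary
#' weighted scores sum (rounded half away from zero to 2 decimals) to
#' the printed comprehensive value; the remaining rows carry up to
#' 0.13 of rounding drift and are excluded from exact reproduction
#' checks.
#'
#' @return data.frame with columns `athlete_id`, `label`, `sex`, `tier`,
#'   the three primary weighted scores, `comprehensive`, `consistent`.
#' @export
aerials_weighted_scores <- function() {
  tab <- read.csv(.extdata("published_weighted_scores.csv"),
                  stringsAsFactors = FALSE)
  prims <- c("body_form", "physiological_function", "physical_quality")
  s <- round_display(rowSums(tab[, prims]), 2)
  tab$consistent <- abs(s - tab$comprehensive) < 1e-9
  attr(tab, "primaries") <- prims
  tab
}

#' Published per-athlete rating labels
#'
#' The printed rating table for all 29 athletes. Nine cells conflict
#' with the published composite cutoffs themselves (the source rated
#' unrounded weighted scores); [aerials_nonverifiable_ratings()] lists
#' them.
#'
#' @return data.frame with columns `athlete_id`, `sex`, `tier` and a
#'   rating label per primary column and `comprehensive`.
#' @export
aerials_published_ratings <- function() {
  read.csv(.extdata("published_ratings.csv"), stringsAsFactors = FALSE)
}

#' Rating cells irreproducible from the published cutoffs
#'
#' Cells of the published rating tables whose label conflicts with the
#' published composite cutoff bands applied to the published (2-decimal)
#' weighted scores. Decisive evidence the source rated unrounded scores:
#' the printed male physiological-function score 1.31 appears three
#' times with ratings Excellent, Good and Good. The first three cells
#' are the documented elite-male inconsistencies; the remaining six are
#' additional conflicts of the same kind.
#'
#' @return data.frame with columns `athlete_id`, `column`, `printed`,
#'   `band_derived`, `documented` (whether the source itself flags the
#'   cell as inconsistent).
#' @export
aerials_nonverifiable_ratings <- function() {
  data.frame(
    athlete_id = c("M02", "M06", "M04",
                   "M02", "M05", "F02", "F04", "F05", "M15"),
    column = c("body_form", "body_form", "comprehensive",
               "physiological_function", "physical_quality",
               "physical_quality", "physiological_function", "body_form",
               "physical_quality"),
    printed = c("Excellent", "Good", "Good",
                "Excellent", "Good", "Good", "Good", "Good", "Poor"),
    band_derived = c("Average", "Average", "Average",
                     "Good", "Average", "Excellent", "Excellent", "Average",
                     "Fail"),
    documented = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Published general fitness model (mean and SD per index)
#'
#' @inheritParams aerials_standards
#' @return `fitness_profile` data.frame (kind `"general"`) with columns
#'   `index`, `mean`, `sd`.
#' @export
aerials_general_model <- function(sex = "male") {
  sex <- match.arg(sex, SEXES)
  tab <- read.csv(.extdata("general_model.csv"), stringsAsFactors = FALSE)
  tab <- tab[tab$sex == sex, c("index", "mean", "sd")]
  rownames(tab) <- NULL
  structure(tab, kind = "general", sex = sex,
            class = c("fitness_profile", "data.frame"))
}

#' Published ideal fitness model (directional 90th-percentile targets)
#'
#' @inheritParams aerials_standards
#' @return `fitness_profile` data.frame (kind `"ideal"`) with columns
#'   `index`, `threshold`, `inequality`.
#' @export
aerials_ideal_model <- function(sex = "male") {
  sex <- match.arg(sex, SEXES)
  tab <- read.csv(.extdata("ideal_model.csv"), stringsAsFactors = FALSE)
  tab <- tab[tab$sex == sex, c("index", "threshold", "inequality")]
  rownames(tab) <- NULL
  structure(tab, kind = "ideal", sex = sex,
            class = c("fitness_profile", "data.frame"))
}

#' Published comprehensive-rating frequency table
#'
#' @inheritParams aerials_standards
#' @return a `rating_contingency` matrix (5 ratings x elite/excellent).
#' @export
aerials_rating_frequencies <- function(sex = "male") {
  sex <- match.arg(sex, SEXES)
  tab <- read.csv(.extdata("rating_frequencies.csv"), stringsAsFactors = FALSE)
  tab <- tab[tab$sex == sex, ]
  m <- as.matrix(tab[, c("elite", "excellent")])
  storage.mode(m) <- "integer"
  dimnames(m) <- list(rating = tab$rating, group = c("elite", "excellent"))
  m <- m[RATING_LEVELS, ]
  structure(m, class = c("rating_contingency", class(m)))
}
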