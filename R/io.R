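#' Round half away from zero
#'
#' Display rounding used throughout published fitness tables (2.005 ->
#' 2.01, -2.005 -> -2.01), unlike [base::round()]'s round-half-even.
#' Internal arithmetic is never rounded; this is applied only when
#' rendering.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return rounded numeric vector.
#' @export
round_display <- function(x, digits = 2) {
  m <- 10^digits
  # the 1e-9 guard keeps exact halves (stored just below .5 in binary,
  # e.g. 2.675) rounding up as they do in print
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Read an athlete measurement table
#'
#' Comma-separated, UTF-8, `.` decimal mark, `NA` for missing. The header
#' must name `athlete_id`, `sex`, optionally `tier`, and tertiary index
#' ids declared in the hierarchy. Sex labels must be lowercase
#' `male`/`female`; tier labels `elite`/`excellent`. Unknown columns are
#' kept but reported as a warning; missing values stay `NA`, never zero.
#'
#' @param path CSV file path.
#' @param hierarchy an [index_hierarchy()] the index columns must belong to.
#' @return `data.frame` of class `measurement_table`.
#' @export
read_measurements <- function(path, hierarchy) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  fileEncoding = "UTF-8")
  as_measurement_table(raw, hierarchy)
}

#' Validate a data.frame as a measurement table
#'
#' @param x data.frame with `athlete_id`, `sex`, optional `tier`, and one
#'   column per tertiary index (numeric or character-numeric).
#' @inheritParams read_measurements
#' @return `data.frame` of class `measurement_table`.
#' @export
as_measurement_table <- function(x, hierarchy) {
  stopifnot(is.data.frame(x))
  if (!all(c("athlete_id", "sex") %in% names(x)))
    stop("measurement table needs 'athlete_id' and 'sex' columns")
  x$athlete_id <- as.character(x$athlete_id)
  if (anyDuplicated(x$athlete_id))
    stop("duplicated athlete_id: ",
         paste(unique(x$athlete_id[duplicated(x$athlete_id)]), collapse = ", "))
  bad <- setdiff(unique(x$sex), SEXES)
  if (length(bad))
    stop("sex must be one of {male, female}; got '", bad[1], "'")
  if ("tier" %in% names(x)) {
    bad <- setdiff(unique(x$tier), c("elite", "excellent"))
    if (length(bad))
      stop("tier must be one of {elite, excellent}; got '", bad[1], "'")
  }
  terts <- tertiary_ids(hierarchy)
  idx_cols <- intersect(names(x), terts)
  meta <- c("athlete_id", "sex", "tier")
  unknown <- setdiff(names(x), c(meta, terts))
  if (length(unknown))
    warning("columns not declared in the hierarchy: ",
            paste(unknown, collapse = ", "))
  for (col in idx_cols) {
    v <- x[[col]]
    if (is.character(v)) {
      miss <- is.na(v) | v == "NA" | v == ""
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!miss & is.na(num))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                     v[bad[1]], col, bad[1]))
      num[miss] <- NA_real_
      x[[col]] <- num
    } else {
      x[[col]] <- as.numeric(v)
    }
  }
  class(x) <- c("measurement_table", "data.frame")
  x
}

#' Write a measurement table
#'
#' Full-precision CSV writer; [read_measurements()] of the result
#' round-trips values bit-identically (numbers are serialized with 17
#' significant digits).
#'
#' @param x a `measurement_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(x, path) {
  out <- as.data.frame(x)
  for (col in names(out))
    if (is.numeric(out[[col]]))
      out[[col]] <- ifelse(is.na(out[[col]]), NA,
                           sprintf("%.17g", out[[col]]))
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA",
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Write athlete score reports
#'
#' Two renderings: a delimited-text file with displayed numbers rounded
#' to 2 decimals (half away from zero, as published tables print them),
#' and a JSON sidecar (same path with extension `.json`) keeping every
#' stored number at full precision.
#'
#' @param reports a `score_report` data.frame (see [aggregate_scores()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(reports, path) {
  if (!is.data.frame(reports) || nrow(reports) == 0)
    stop("reports must be a non-empty data.frame")
  disp <- as.data.frame(reports)
  for (col in names(disp))
    if (is.numeric(disp[[col]])) disp[[col]] <- round_display(disp[[col]], 2)
  tryCatch(
    write.csv(disp, path, row.names = FALSE, quote = FALSE, na = "NA",
              fileEncoding = "UTF-8"),
    error = function(e) stop("cannot write report to '", path, "': ",
                             conditionMessage(e)))
  json_path <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(as.data.frame(reports), json_path, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
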