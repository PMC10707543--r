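#' Construct an evaluation-index hierarchy
#'
#' An index hierarchy is a forest of evaluation indexes on up to three
#' levels (primary, secondary, tertiary). Athlete measurements attach to
#' tertiary indexes; weights are normalized within sibling sets (the
#' tertiary children of one primary, and the set of primaries). The
#' secondary level may be collapsed: a tertiary index may hang directly
#' off a primary, as published weight tables usually print it.
#'
#' @param nodes data.frame with columns `id`, `level` and optionally
#'   `name`, `parent_id`, `direction`, `units`. `direction` defaults to
#'   `"high_optimal"`; `"low_optimal"` (smaller is better, e.g. sprint
#'   time) must be declared explicitly.
#' @param weights optional named list keyed by sex (`"male"`, `"female"`),
#'   each a named numeric vector of weights over index ids. Within every
#'   sibling set weights must be non-negative and sum to 1 within 0.005
#'   (published tables are rounded to 2 decimals).
#' @return object of class `index_hierarchy`: list with elements `nodes`
#'   (validated data.frame) and `weights`.
#' @seealso [load_hierarchy()], [aerials_hierarchy()]
#' @export
#' @examples
#' h <- index_hierarchy(data.frame(
#'   id = c("form", "height"), level = c("primary", "tertiary"),
#'   parent_id = c(NA, "form")))
#' level_ids(h, "tertiary")
index_hierarchy <- function(nodes, weights = NULL) {
  stopifnot(is.data.frame(nodes))
  if (!all(c("id", "level") %in% names(nodes)))
    stop("hierarchy nodes need at least 'id' and 'level' columns")
  nodes$id <- as.character(nodes$id)
  nodes$level <- as.character(nodes$level)
  if (is.null(nodes$name)) nodes$name <- nodes$id
  if (is.null(nodes$parent_id)) nodes$parent_id <- NA_character_
  nodes$parent_id <- as.character(nodes$parent_id)
  nodes$parent_id[!is.na(nodes$parent_id) & nodes$parent_id == ""] <- NA_character_
  if (is.null(nodes$direction)) nodes$direction <- "high_optimal"
  nodes$direction[is.na(nodes$direction) | nodes$direction == ""] <- "high_optimal"
  if (is.null(nodes$units)) nodes$units <- ""
  nodes <- nodes[, c("id", "name", "level", "parent_id", "direction", "units")]

  if (anyDuplicated(nodes$id))
    stop("duplicated index id: ", paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  bad <- setdiff(nodes$level, LEVELS)
  if (length(bad)) stop("unknown level '", bad[1], "' (node '",
                        nodes$id[match(bad[1], nodes$level)], "')")
  bad <- setdiff(nodes$direction, DIRECTIONS)
  if (length(bad)) stop("unknown direction '", bad[1], "'")
  if (!any(nodes$level == "primary")) stop("hierarchy has no primary node")

  depth <- match(nodes$level, LEVELS)
  for (i in seq_len(nrow(nodes))) {
    p <- nodes$parent_id[i]
    if (nodes$level[i] == "primary") {
      if (!is.na(p)) stop("primary node '", nodes$id[i], "' must not have a parent")
      next
    }
    if (is.na(p)) stop("node '", nodes$id[i], "' (", nodes$level[i],
                       ") has no parent_id")
    j <- match(p, nodes$id)
    if (is.na(j)) stop("node '", nodes$id[i], "' references unknown parent '", p, "'")
    if (depth[j] >= depth[i])
      stop("parent of '", nodes$id[i], "' must be at a higher level, got '",
           nodes$level[j], "'")
  }

  h <- structure(list(nodes = nodes, weights = NULL), class = "index_hierarchy")
  if (!is.null(weights)) h <- set_weights(h, weights)
  h
}

#' Read an index hierarchy from a YAML/JSON configuration document
#'
#' The document holds an `indexes` sequence (fields `id`, `name`, `level`,
#' `parent`, `direction`, `units`) and optionally a `weights` mapping keyed
#' by sex. See `system.file("extdata", "aerials_hierarchy.yaml",
#' package = "fitindex")` for the schema by example.
#'
#' @param path path to a YAML (or JSON, which YAML subsumes) file, or a
#'   literal document passed via `text`.
#' @param text optional literal configuration text.
#' @return an [index_hierarchy()].
#' @export
load_hierarchy <- function(path, text = NULL) {
  doc <- if (!is.null(text)) yaml::yaml.load(text) else yaml::read_yaml(path)
  if (is.null(doc$indexes)) stop("configuration has no 'indexes' section")
  nodes <- do.call(rbind, lapply(doc$indexes, function(x) {
    if (is.null(x$id)) stop("an index entry is missing 'id'")
    data.frame(id = x$id, name = x$name %||% x$id, level = x$level %||% NA_character_,
               parent_id = x$parent %||% NA_character_,
               direction = x$direction %||% "high_optimal",
               units = x$units %||% "", stringsAsFactors = FALSE)
  }))
  if (anyNA(nodes$level)) stop("index '", nodes$id[which(is.na(nodes$level))[1]],
                               "' is missing 'level'")
  w <- NULL
  if (!is.null(doc$weights))
    w <- lapply(doc$weights, function(x) unlist(x))
  index_hierarchy(nodes, weights = w)
}

#' Attach sex-specific weights to a hierarchy
#'
#' @param hierarchy an [index_hierarchy()].
#' @param weights named list keyed by sex of named numeric vectors
#'   (index id -> weight).
#' @param tol tolerance on sibling-set weight sums (default 0.005,
#'   accommodating 2-decimal published rounding).
#' @return the hierarchy with validated weights attached.
#' @export
set_weights <- function(hierarchy, weights, tol = 0.005) {
  stopifnot(inherits(hierarchy, "index_hierarchy"), is.list(weights))
  bad <- setdiff(names(weights), SEXES)
  if (length(bad)) stop("weight maps must be keyed by sex, got '", bad[1], "'")
  for (sex in names(weights)) {
    w <- weights[[sex]]
    unknown <- setdiff(names(w), hierarchy$nodes$id)
    if (length(unknown))
      stop("weight for unknown index '", unknown[1], "' (", sex, ")")
    if (any(w < 0)) stop("negative weight (", sex, ")")
    for (set in sibling_sets(hierarchy)) {
      have <- intersect(set, names(w))
      if (!length(have)) next
      if (length(have) < length(set))
        stop("incomplete weights for sibling set {", paste(set, collapse = ", "),
             "} (", sex, ")")
      s <- sum(w[set])
      if (abs(s - 1) > tol)
        stop(sprintf("weights of sibling set {%s} sum to %.4f, not 1 (%s)",
                     paste(set, collapse = ", "), s, sex))
    }
  }
  hierarchy$weights <- weights
  hierarchy
}

#' Sibling sets of a hierarchy
#'
#' The groups within which weights are normalized: the set of primary
#' indexes, and the scored children of each primary (tertiary indexes,
#' via their secondary parent when one is declared).
#'
#' @param hierarchy an [index_hierarchy()].
#' @return list of character vectors of index ids.
#' @export
sibling_sets <- function(hierarchy) {
  n <- hierarchy$nodes
  out <- list(n$id[n$level == "primary"])
  for (p in out[[1]]) {
    kids <- scored_children(hierarchy, p)
    if (length(kids)) out <- c(out, list(kids))
  }
  out
}

#' @rdname level_ids
#' @export
primary_ids <- function(hierarchy) level_ids(hierarchy, "primary")

#' @rdname level_ids
#' @export
tertiary_ids <- function(hierarchy) level_ids(hierarchy, "tertiary")

#' Index ids at one hierarchy level
#' @param hierarchy an [index_hierarchy()].
#' @param level one of `"primary"`, `"secondary"`, `"tertiary"`.
#' @return character vector of ids, in declaration order.
#' @export
level_ids <- function(hierarchy, level) {
  level <- match.arg(level, LEVELS)
  hierarchy$nodes$id[hierarchy$nodes$level == level]
}

# tertiary descendants of a primary (skipping a collapsed secondary level)
scored_children <- function(hierarchy, primary) {
  n <- hierarchy$nodes
  direct <- n$id[!is.na(n$parent_id) & n$parent_id == primary]
  terts <- character()
  for (id in direct) {
    if (n$level[n$id == id] == "tertiary") terts <- c(terts, id)
    else terts <- c(terts, scored_children(hierarchy, id))
  }
  terts
}

# primary ancestor of any node
primary_of <- function(hierarchy, id) {
  n <- hierarchy$nodes
  while (n$level[n$id == id] != "primary") id <- n$parent_id[n$id == id]
  id
}

#' Optimality direction of an index
#' @param hierarchy an [index_hierarchy()].
#' @param id index id.
#' @return `"high_optimal"` or `"low_optimal"`.
#' @export
index_direction <- function(hierarchy, id) {
  i <- match(id, hierarchy$nodes$id)
  if (anyNA(i)) stop("unknown index '", id[which(is.na(i))[1]], "'")
  hierarchy$nodes$direction[i]
}

# weights for one sex; errors if absent
hierarchy_weights <- function(hierarchy, sex) {
  sex <- match.arg(sex, SEXES)
  w <- hierarchy$weights[[sex]]
  if (is.null(w)) stop("hierarchy carries no weights for sex '", sex, "'")
  w
}

#' @export
print.index_hierarchy <- function(x, ...) {
  n <- x$nodes
  cat("Index hierarchy:", sum(n$level == "primary"), "primary,",
      sum(n$level == "secondary"), "secondary,",
      sum(n$level == "tertiary"), "tertiary indexes\n")
  if (!is.null(x$weights))
    cat("Weights attached for:", paste(names(x$weights), collapse = ", "), "\n")
  invisible(x)
}

#' The published freestyle-skiing-aerials index hierarchy and weights
#'
#' Three primary domains (body form, physiological function, physical
#' quality) over eleven representative tertiary indexes, with the
#' published expert-derived weights for both sexes. Squat on the balance
#' pad and the 30-metre sprint are low-optimal (smaller is better).
#'
#' @return an [index_hierarchy()] with weights attached.
#' @export
aerials_hierarchy <- function() {
  nodes <- data.frame(
    id = c("body_form", "physiological_function", "physical_quality",
           "achilles_tendon_length", "pelvis_width", "waist_circumference",
           "quetelet_index",
           "rel_max_anaerobic_power", "rel_max_oxygen_uptake", "hemoglobin",
           "power_clean", "squat_balance_pad", "sprint_30m", "run_12min"),
    name = c("Body form", "Physiological function", "Physical quality",
             "Achilles tendon length", "Pelvis width", "Waist circumference",
             "Quetelet index",
             "Relative maximum anaerobic power", "Relative maximum oxygen uptake",
             "Hemoglobin",
             "Power clean", "Squat on the balance pad with the barbell raising",
             "30-meter sprint", "12-minute run"),
    level = c(rep("primary", 3), rep("tertiary", 11)),
    parent_id = c(rep(NA, 3), rep("body_form", 4),
                  rep("physiological_function", 3), rep("physical_quality", 4)),
    direction = c(rep("high_optimal", 11), "low_optimal", "low_optimal",
                  "high_optimal"),
    units = c("", "", "", "cm", "cm", "cm", "g/cm", "W/kg", "ml/kg/min", "g/L",
              "kg", "s", "s", "m"),
    stringsAsFactors = FALSE)
  weights <- list(
    male = c(body_form = 0.25, physiological_function = 0.33,
             physical_quality = 0.42,
             achilles_tendon_length = 0.24, pelvis_width = 0.23,
             waist_circumference = 0.31, quetelet_index = 0.22,
             rel_max_anaerobic_power = 0.35, rel_max_oxygen_uptake = 0.31,
             hemoglobin = 0.34,
             power_clean = 0.30, squat_balance_pad = 0.29,
             sprint_30m = 0.20, run_12min = 0.21),
    female = c(body_form = 0.27, physiological_function = 0.32,
               physical_quality = 0.41,
               achilles_tendon_length = 0.23, pelvis_width = 0.22,
               waist_circumference = 0.30, quetelet_index = 0.25,
               rel_max_anaerobic_power = 0.36, rel_max_oxygen_uptake = 0.29,
               hemoglobin = 0.35,
               power_clean = 0.27, squat_balance_pad = 0.28,
               sprint_30m = 0.20, run_12min = 0.25))
  index_hierarchy(nodes, weights = weights)
}
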