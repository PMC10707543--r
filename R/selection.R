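#' R-type (variable) hierarchical clustering of indexes
#'
#' Clusters the columns (indexes), not the athletes, by correlation-based
#' dissimilarity, and cuts the tree to a caller-supplied number of
#' groups. The default dissimilarity 1 - |r| with average linkage makes
#' the partition invariant to affine rescaling (including sign flips) of
#' any index; `1 - r` treats negatively correlated indexes as distant and
#' is offered for inspection.
#'
#' @param measurements a `measurement_table` (sexes pooled, as reference
#'   cohorts are typically analysed; subset beforehand for per-sex runs).
#' @param indexes character vector of tertiary index ids to cluster.
#' @param n_clusters number of groups to cut to (<= number of indexes).
#' @param metric `"abs_correlation"` (1 - |r|, default) or
#'   `"correlation"` (1 - r).
#' @param linkage agglomeration method passed to [stats::hclust()]:
#'   `"average"` (default), `"complete"`, or `"ward.D2"`.
#' @return list of class `variable_clustering`: `clusters` (named list of
#'   id vectors, partitioning `indexes`), `tree` (the `hclust` object),
#'   `k`, `metric`, `linkage`.
#' @export
cluster_variables <- function(measurements, indexes, n_clusters,
                              metric = c("abs_correlation", "correlation"),
                              linkage = c("average", "complete", "ward.D2")) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  missing_cols <- setdiff(indexes, names(measurements))
  if (length(missing_cols)) stop("unknown index '", missing_cols[1], "'")
  x <- as.matrix(as.data.frame(measurements)[, indexes, drop = FALSE])
  if (anyNA(x)) {
    bad <- indexes[colSums(is.na(x)) > 0]
    stop("missing values in index: ", paste(bad, collapse = ", "),
         " (imputation is out of scope)")
  }
  if (nrow(x) < 3) stop("need at least 3 athletes with complete data")
  if (n_clusters < 1 || n_clusters > length(indexes))
    stop("n_clusters must lie in 1..", length(indexes))
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop("constant column (zero variance): ",
         paste(indexes[sds == 0], collapse = ", "))
  r <- cor(x)
  d <- if (metric == "abs_correlation") 1 - abs(r) else 1 - r
  tree <- hclust(as.dist(d), method = linkage)
  grp <- cutree(tree, k = n_clusters)
  clusters <- split(names(grp), grp)
  names(clusters) <- paste0("cluster", seq_along(clusters))
  structure(list(clusters = clusters, tree = tree, k = n_clusters,
                 metric = metric, linkage = linkage),
            class = "variable_clustering")
}

#' @export
print.variable_clustering <- function(x, ...) {
  cat("Variable clustering (", x$metric, ", ", x$linkage, " linkage), k = ",
      x$k, "\n", sep = "")
  for (nm in names(x$clusters))
    cat("  ", nm, ": ", paste(x$clusters[[nm]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Representative index of a cluster by coefficient of determination
#'
#' Forced-entry (all predictors simultaneously, no stepwise selection)
#' ordinary least squares of each cluster member on all other members;
#' the member with the largest R-squared — the one best explained by its
#' cluster mates — is chosen as representative. Ties are broken by the
#' larger mean absolute correlation with the cluster mates, then by id
#' order within `cluster`.
#'
#' @param cluster character vector of >= 3 index ids.
#' @param measurements a `measurement_table` with >= length(cluster) + 2
#'   complete athletes on those indexes.
#' @return list of class `representative_choice`: `cluster` (ids),
#'   `chosen`, `rule = "max_r2"`, `r2` (named vector).
#' @export
representative_by_r2 <- function(cluster, measurements) {
  if (length(cluster) < 3)
    stop("cluster has fewer than 3 members; use the singleton or ",
         "domain-override rules")
  x <- as.data.frame(measurements)[, cluster, drop = FALSE]
  if (anyNA(x)) stop("missing values among cluster indexes")
  if (nrow(x) < length(cluster) + 2)
    stop("need at least ", length(cluster) + 2, " athletes to fit the regressions")
  r2 <- setNames(numeric(length(cluster)), cluster)
  for (dep in cluster) {
    preds <- setdiff(cluster, dep)
    fit <- lm(reformulate(preds, response = dep), data = x)
    if (fit$rank < length(preds) + 1 || anyNA(coef(fit))) {
      aliased <- names(coef(fit))[is.na(coef(fit))]
      stop("perfect collinearity among predictors for '", dep, "': ",
           paste(aliased, collapse = ", "))
    }
    r2[dep] <- summary(fit)$r.squared
  }
  best <- r2[r2 >= max(r2) - 1e-12]
  chosen <- names(best)[1]
  if (length(best) > 1) {
    rmat <- abs(cor(x))
    diag(rmat) <- NA
    mac <- rowMeans(rmat[names(best), cluster, drop = FALSE], na.rm = TRUE)
    chosen <- names(best)[order(-mac, match(names(best), cluster))][1]
  }
  structure(list(cluster = cluster, chosen = chosen, rule = "max_r2", r2 = r2),
            class = "representative_choice")
}

#' Select one representative index per cluster
#'
#' Applies the published three-way rule: a singleton cluster represents
#' itself; a 2-member cluster is resolved by a caller-supplied
#' domain-knowledge override (e.g. pelvis width over shoulder width,
#' relative over absolute power and oxygen uptake); clusters of 3 or
#' more delegate to [representative_by_r2()].
#'
#' @param clustering a [cluster_variables()] result.
#' @param measurements the `measurement_table` the clustering used.
#' @param overrides named list or vector mapping cluster name -> chosen
#'   index id; required for every 2-member cluster.
#' @return list of `representative_choice` objects, one per cluster.
#' @export
select_representatives <- function(clustering, measurements, overrides = NULL) {
  stopifnot(inherits(clustering, "variable_clustering"))
  out <- list()
  for (nm in names(clustering$clusters)) {
    members <- clustering$clusters[[nm]]
    if (length(members) == 1) {
      out[[nm]] <- structure(list(cluster = members, chosen = members,
                                  rule = "singleton", r2 = NULL),
                             class = "representative_choice")
    } else if (length(members) == 2) {
      choice <- overrides[[nm]]
      if (is.null(choice))
        stop("no override supplied for 2-member cluster ", nm, " {",
             paste(members, collapse = ", "), "}")
      if (!choice %in% members)
        stop("override '", choice, "' is not a member of ", nm)
      out[[nm]] <- structure(list(cluster = members, chosen = choice,
                                  rule = "domain_override", r2 = NULL),
                             class = "representative_choice")
    } else {
      out[[nm]] <- representative_by_r2(members, measurements)
    }
  }
  out
}

#' @export
print.representative_choice <- function(x, ...) {
  cat("Representative '", x$chosen, "' (rule: ", x$rule, ") of {",
      paste(x$cluster, collapse = ", "), "}\n", sep = "")
  if (!is.null(x$r2)) {
    cat("  R2:", paste(sprintf("%s=%.3f", names(x$r2), x$r2), collapse = ", "),
        "\n")
  }
  invisible(x)
}
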