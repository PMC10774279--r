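#' Configuration for region-based feature selection
#'
#' @param alpha significance threshold for the sequential admission rule
#'   (default 0.05).
#' @param n_trees trees in the importance ensemble (default 100).
#' @param rng_seed seed for the ensemble's bootstrap/split randomness.
#' @return A `selection_config`.
#' @export
selection_config <- function(alpha = 0.05, n_trees = 100L, rng_seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_trees < 1L) stop("n_trees must be positive")
  structure(list(alpha = alpha, n_trees = as.integer(n_trees),
                 rng_seed = as.integer(rng_seed)),
            class = "selection_config")
}

#' Voxelwise impurity importance from a randomized tree ensemble
#'
#' Mean-decrease-impurity score per voxel from a random forest (Gini
#' impurity, bootstrap resampling, `floor(sqrt(p))` candidate features per
#' split), normalized to sum to one. Voxels never used in a split score
#' exactly zero, so non-zero scores mark the voxels the ensemble found
#' informative.
#'
#' @param values subjects x voxels numeric matrix.
#' @param labels binary group labels (factor or character/numeric with
#'   exactly two levels).
#' @param config a [selection_config()].
#' @return Non-negative numeric vector, one score per voxel, summing to 1.
#' @export
voxelwise_tree_importance <- function(values, labels, config = selection_config()) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop("labels must contain exactly 2 classes, got ", nlevels(labels))
  if (min(table(labels)) < 2L) stop("need >= 2 subjects per class")
  if (ncol(values) < 1L) stop("need at least one voxel")
  x <- values
  colnames(x) <- paste0("v", seq_len(ncol(x)))
  fit <- ranger::ranger(x = x, y = labels,
                        num.trees = config$n_trees,
                        importance = "impurity",
                        num.threads = 1L,
                        seed = config$rng_seed)
  imp <- unname(fit$variable.importance)
  imp[imp < 0] <- 0    # guard against tiny negative rounding
  tot <- sum(imp)
  if (tot == 0) {
    warning("ensemble produced all-zero importance")
    return(imp)
  }
  imp / tot
}

#' Aggregate voxel importance into a ranked region table
#'
#' A region's importance is the sum of its member voxels' scores; regions are
#' ranked in descending order of importance, ties broken by ascending region
#' id. Total importance is conserved.
#'
#' @param importance numeric vector, one score per registry row.
#' @param registry a [voxel_registry()].
#' @param region_names optional named character vector (id -> name).
#' @return A `region_score_table` data.frame sorted by rank, with columns
#'   `region_id, region_name, importance, rank, u_stat, p_value, selected`.
#' @export
aggregate_importance_by_region <- function(importance, registry,
                                           region_names = NULL) {
  if (length(importance) != nrow(registry))
    stop("importance length does not match registry")
  if (any(is.na(registry$region)) || any(registry$region < 1L))
    stop("registry contains voxels with unknown region labels")
  ids <- sort(unique(registry$region))
  imp <- vapply(ids, function(id)
    sum(importance[registry$region == id]), numeric(1))
  nm <- if (is.null(region_names)) sprintf("region_%02d", ids)
        else unname(region_names[as.character(ids)])
  tab <- data.frame(region_id = ids, region_name = nm, importance = imp,
                    stringsAsFactors = FALSE)
  ord <- order(-tab$importance, tab$region_id)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab$u_stat <- NA_real_
  tab$p_value <- NA_real_
  tab$selected <- FALSE
  rownames(tab) <- NULL
  class(tab) <- c("region_score_table", "data.frame")
  tab
}

#' Per-subject mean connectivity of one region
#'
#' @param values subjects x voxels matrix.
#' @param registry a [voxel_registry()].
#' @param region_id region label.
#' @return Numeric vector, one mean per subject.
#' @export
mean_region_fc <- function(values, registry, region_id) {
  cols <- which(registry$region == region_id)
  if (length(cols) == 0L) stop("region ", region_id, " has no voxels")
  rowMeans(values[, cols, drop = FALSE])
}

#' Two-sided Mann-Whitney U test
#'
#' Reports the U statistic of the first sample. The exact null distribution
#' is used when the combined sample has at most 12 observations and no ties;
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param a,b numeric vectors, both non-empty.
#' @return List with `u_stat`, `p_value`, and `method` (`"exact"` or
#'   `"normal_approx"`).
#' @export
mann_whitney_u <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) stop("both groups must be non-empty")
  all_v <- c(a, b)
  rk <- rank(all_v)
  u <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  ties <- anyDuplicated(all_v) > 0L
  if (na + nb <= 12L && !ties) {
    p <- if (u > mu) 2 * stats::pwilcox(u - 1, na, nb, lower.tail = FALSE)
         else if (u < mu) 2 * stats::pwilcox(u, na, nb)
         else 1
    return(list(u_stat = u, p_value = min(p, 1), method = "exact"))
  }
  n <- na + nb
  tie_tab <- table(all_v)
  sigma2 <- (na * nb / 12) * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(u_stat = u, p_value = 1,
                               method = "normal_approx"))
  z <- (u - mu - 0.5 * sign(u - mu)) / sqrt(sigma2)
  list(u_stat = u, p_value = min(2 * stats::pnorm(-abs(z)), 1),
       method = "normal_approx")
}

#' Sequential admission of ranked regions by the U-test rule
#'
#' Walks the region table in rank order; for each region the per-subject
#' mean connectivity is compared between the two groups with a two-sided
#' Mann-Whitney U test. Regions are admitted while `p < alpha`; the first
#' region with `p >= alpha` stops the walk and it and all later regions stay
#' unselected, so the selected set is always a prefix of the ranking. U and p
#' are recorded for every region for reporting.
#'
#' @param table a ranked `region_score_table`.
#' @param values subjects x voxels matrix.
#' @param labels binary group labels.
#' @param registry a [voxel_registry()].
#' @param config a [selection_config()] (supplies `alpha`).
#' @return The table with `u_stat`, `p_value`, `selected` filled.
#' @export
sequential_region_selection <- function(table, values, labels, registry,
                                        config = selection_config()) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("labels must contain exactly 2 classes")
  ga <- labels == levels(labels)[1]
  stopped <- FALSE
  for (i in seq_len(nrow(table))) {
    mfc <- mean_region_fc(values, registry, table$region_id[i])
    ut <- mann_whitney_u(mfc[ga], mfc[!ga])
    table$u_stat[i] <- ut$u_stat
    table$p_value[i] <- ut$p_value
    if (!stopped && ut$p_value < config$alpha) {
      table$selected[i] <- TRUE
    } else {
      stopped <- TRUE
      table$selected[i] <- FALSE
    }
  }
  if (!any(table$selected))
    stop(errorCondition(
      "empty selection: the top-ranked region already has p >= alpha",
      class = c("limbicscreen_empty_selection", "error")))
  table
}

#' Final voxel mask of the selection
#'
#' The retained features are exactly the voxels with non-zero importance
#' lying in a selected region.
#'
#' @param table a `region_score_table` with `selected` filled.
#' @param importance voxelwise importance vector.
#' @param registry a [voxel_registry()].
#' @return Sorted integer vector of registry indices.
#' @export
build_feature_mask <- function(table, importance, registry) {
  sel_regions <- table$region_id[table$selected]
  if (length(sel_regions) == 0L) stop("no selected regions")
  idx <- which(registry$region %in% sel_regions & importance > 0)
  if (length(idx) == 0L)
    stop(errorCondition(
      "empty mask: no non-zero-importance voxel in the selected regions",
      class = c("limbicscreen_empty_selection", "error")))
  sort(idx)
}

#' Top regions by importance
#'
#' @param table a ranked `region_score_table`.
#' @param k number of leading regions (default 10, capped at the table size).
#' @return data.frame `region_name, importance` in rank order.
#' @export
top_regions_report <- function(table, k = 10L) {
  if (k > nrow(table)) stop("k exceeds the number of regions")
  utils::head(table[order(table$rank), c("region_name", "importance")], k)
}

#' Run the full two-stage feature selection
#'
#' Impurity importance, region aggregation and ranking, sequential U-test
#' admission, and the final non-zero-importance voxel mask -- computed on
#' (and only on) the data supplied, so callers control training/test
#' separation.
#'
#' @param values subjects x voxels matrix (training data only).
#' @param labels binary group labels.
#' @param registry a [voxel_registry()].
#' @param config a [selection_config()].
#' @param region_names optional id -> name map.
#' @return List with `mask` (voxel indices), `table` (region score table),
#'   `importance` (voxel scores).
#' @export
select_features <- function(values, labels, registry,
                            config = selection_config(),
                            region_names = NULL) {
  importance <- voxelwise_tree_importance(values, labels, config)
  tab <- aggregate_importance_by_region(importance, registry, region_names)
  tab <- sequential_region_selection(tab, values, labels, registry, config)
  mask <- build_feature_mask(tab, importance, registry)
  list(mask = mask, table = tab, importance = importance)
}

#' Write a region score table as TSV
#'
#' @param table a `region_score_table`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_region_table <- function(table, path) {
  utils::write.table(format(as.data.frame(table), digits = 12, trim = TRUE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
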