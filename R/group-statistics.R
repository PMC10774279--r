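.stat_result <- function(statistic, df, p_value, method, extra = NULL) {
  out <- c(list(statistic = unname(statistic), df = unname(df),
                p_value = unname(p_value), method = method), extra)
  class(out) <- "stat_result"
  out
}

#' One-way analysis of variance
#'
#' Classical fixed-effects F test (`F = MSB/MSW`, df `k-1`, `N-k`).
#'
#' @param groups list of numeric vectors, one per group (each n >= 2).
#' @return A `stat_result` with `statistic` (F), `df` (length 2), `p_value`.
#' @export
oneway_anova <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("every group needs n >= 2")
  y <- unlist(groups, use.names = FALSE)
  if (stats::var(y) == 0) stop("degenerate input: all values identical")
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  .stat_result(ft$statistic, unname(ft$parameter), ft$p.value, "anova")
}

#' One-way ANOVA from per-group summary statistics
#'
#' Computes F from `(n, mean, sd)` alone: between-group sum of squares from
#' the means, within-group mean square from the SDs. Agrees with the
#' raw-data F when summaries are exact.
#'
#' @param n,means,sds numeric vectors of per-group size, mean, SD.
#' @return A `stat_result`.
#' @export
anova_from_summary <- function(n, means, sds) {
  if (length(unique(c(length(n), length(means), length(sds)))) != 1L)
    stop("n, means, sds must have equal length")
  if (any(n < 2)) stop("every group needs n >= 2")
  k <- length(n); N <- sum(n)
  gm <- sum(n * means) / N
  msb <- sum(n * (means - gm)^2) / (k - 1)
  msw <- sum((n - 1) * sds^2) / (N - k)
  if (msw == 0) stop("degenerate input: zero within-group variance")
  f <- msb / msw
  .stat_result(f, c(k - 1, N - k),
               stats::pf(f, k - 1, N - k, lower.tail = FALSE), "anova")
}

#' Levene's test for homogeneity of variance
#'
#' ANOVA on the absolute deviations from the group means (the classical
#' mean-centered variant); used to route post-hoc comparisons to the
#' equal-variance or unequal-variance procedure.
#'
#' @param groups list of numeric vectors.
#' @return A `stat_result` with method `"levene"`.
#' @export
levene_test <- function(groups) {
  devs <- lapply(groups, function(g) abs(g - mean(g)))
  out <- oneway_anova(devs)
  out$method <- "levene"
  out
}

#' Pairwise post-hoc comparisons after ANOVA
#'
#' With homogeneous variances: pairwise t tests on the pooled within-group
#' mean square (df `N - k`), p values Bonferroni-multiplied by the number of
#' pairs (capped at 1). Otherwise: Tamhane's T2 -- Welch t per pair with
#' Sidak-style correction `1 - (1-p)^m`.
#'
#' @param groups named list of numeric vectors.
#' @param homogeneous logical, typically `levene_test(...)$p_value >= 0.05`.
#' @return data.frame `pair, statistic, df, p_raw, p_adjusted, method`.
#' @export
posthoc_pairwise <- function(groups, homogeneous = TRUE) {
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  n <- vapply(groups, length, integer(1))
  if (homogeneous) {
    msw <- sum((n - 1) * vapply(groups, stats::var, numeric(1))) / (sum(n) - k)
    df_pool <- sum(n) - k
  }
  rows <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    a <- groups[[i1]]; b <- groups[[i2]]
    if (homogeneous) {
      se <- sqrt(msw * (1 / n[i1] + 1 / n[i2]))
      tt <- (mean(a) - mean(b)) / se
      df <- df_pool
      p_raw <- 2 * stats::pt(-abs(tt), df)
      p_adj <- min(p_raw * m, 1)
      meth <- "bonferroni"
    } else {
      v1 <- stats::var(a) / n[i1]; v2 <- stats::var(b) / n[i2]
      tt <- (mean(a) - mean(b)) / sqrt(v1 + v2)
      df <- (v1 + v2)^2 / (v1^2 / (n[i1] - 1) + v2^2 / (n[i2] - 1))
      p_raw <- 2 * stats::pt(-abs(tt), df)
      p_adj <- 1 - (1 - p_raw)^m
      meth <- "tamhane_t2"
    }
    data.frame(pair = paste(names(groups)[i1], "vs", names(groups)[i2]),
               statistic = tt, df = df, p_raw = p_raw,
               p_adjusted = max(p_adj, p_raw), method = meth,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Kruskal-Wallis rank test
#'
#' @param groups list of numeric vectors (total N >= 3).
#' @return A `stat_result` with `statistic` (H, tie-corrected), chi-square
#'   df `k - 1`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  y <- unlist(groups, use.names = FALSE)
  if (length(y) < 3L) stop("need total N >= 3")
  if (length(unique(y)) == 1L) stop("degenerate input: all values identical")
  kt <- stats::kruskal.test(groups)
  .stat_result(kt$statistic, unname(kt$parameter), kt$p.value,
               "kruskal_wallis")
}

#' Pearson chi-square test on an r x c contingency table
#'
#' `chi^2 = sum (O - E)^2 / E` with expectations from the margins, df
#' `(r-1)(c-1)`, no continuity correction (the convention that reproduces
#' SPSS's printed Pearson chi-square).
#'
#' @param counts non-negative integer matrix; all margins must be positive.
#' @return A `stat_result`.
#' @export
pearson_chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin in contingency table")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  .stat_result(ct$statistic, unname(ct$parameter), ct$p.value, "chi_square")
}

#' Exact conditional test for an r x c contingency table
#'
#' Freeman-Halton extension of Fisher's exact test: with margins fixed, the
#' p value is the total probability of tables no more probable than the
#' observed one. Tables with more than 200 observations fall back to a
#' Monte-Carlo estimate.
#'
#' @param counts non-negative integer matrix.
#' @param mc_replicates Monte-Carlo replicates for the fallback.
#' @return A `stat_result` with method `"fisher_exact"`; `statistic` and
#'   `df` are `NA` (the test is conditional, not chi-square distributed).
#'   The fallback records `mc = TRUE`.
#' @export
freeman_halton_exact <- function(counts, mc_replicates = 1e5) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin in contingency table")
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    return(.stat_result(NA_real_, NA_real_, 1, "fisher_exact",
                        list(mc = FALSE)))
  if (sum(counts) <= 200) {
    ft <- stats::fisher.test(counts, workspace = 2e7)
    .stat_result(NA_real_, NA_real_, ft$p.value, "fisher_exact",
                 list(mc = FALSE))
  } else {
    ft <- stats::fisher.test(counts, simulate.p.value = TRUE,
                             B = mc_replicates)
    .stat_result(NA_real_, NA_real_, ft$p.value, "fisher_exact",
                 list(mc = TRUE, mc_replicates = mc_replicates))
  }
}

#' Pearson correlation with t-distributed significance
#'
#' @param x,y numeric vectors of equal length >= 3, both non-constant.
#' @return A `stat_result` with `statistic` = r, `df` = n - 2.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: constant vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  .stat_result(unname(ct$estimate), unname(ct$parameter), ct$p.value,
               "pearson_r")
}

#' Benjamini-Hochberg step-up false discovery rate control
#'
#' Rejects the hypotheses with the `i0` smallest p values, where `i0` is the
#' largest `i` with `p_(i) <= (i/m) q`; adjusted p values are the standard
#' step-up values with monotonicity enforced (`p.adjust` BH).
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param q target false discovery rate (default 0.05).
#' @return List with `rejected` (logical, original order) and `p_adjusted`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1)) stop("p values must lie in [0, 1]")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  m <- length(p_values)
  ord <- order(p_values)
  thresh <- seq_len(m) / m * q
  ok <- which(p_values[ord] <= thresh)
  rejected <- logical(m)
  if (length(ok) > 0) rejected[ord[seq_len(max(ok))]] <- TRUE
  list(rejected = rejected,
       p_adjusted = stats::p.adjust(p_values, method = "BH"))
}

#' Three-group regional connectivity comparison with routed post-hocs
#'
#' For each of the top-importance regions: per-subject mean connectivity,
#' one-way ANOVA across the three diagnostic groups, Levene's test, and
#' pairwise post-hocs (pooled-variance Bonferroni when variances are
#' homogeneous at 0.05, Tamhane T2 otherwise).
#'
#' @param values subjects x voxels matrix (all three groups).
#' @param registry a [voxel_registry()].
#' @param groups group label per subject (three levels).
#' @param region_table ranked `region_score_table` (training selection).
#' @param k number of top regions to compare (default 10, capped).
#' @return data.frame, one row per region: `region_id, region_name, f_stat,
#'   df1, df2, p_value, levene_p, posthoc_method`, then one adjusted-p
#'   column per group pair.
#' @export
table2_analysis <- function(values, registry, groups, region_table, k = 10L) {
  canon <- c("UD", "tBD", "BD")
  groups <- if (all(unique(groups) %in% canon))
    factor(groups, levels = intersect(canon, unique(groups)))
  else factor(groups)
  if (nlevels(groups) != 3L) stop("need exactly three groups")
  k <- min(k, nrow(region_table))
  top <- region_table[order(region_table$rank), ][seq_len(k), ]
  rows <- lapply(seq_len(k), function(i) {
    mfc <- mean_region_fc(values, registry, top$region_id[i])
    gl <- split(mfc, groups)
    an <- oneway_anova(gl)
    lv <- levene_test(gl)
    ph <- posthoc_pairwise(gl, homogeneous = lv$p_value >= 0.05)
    out <- data.frame(region_id = top$region_id[i],
                      region_name = top$region_name[i],
                      f_stat = an$statistic, df1 = an$df[1], df2 = an$df[2],
                      p_value = an$p_value, levene_p = lv$p_value,
                      posthoc_method = ph$method[1],
                      stringsAsFactors = FALSE)
    for (j in seq_len(nrow(ph)))
      out[[paste0("p_", gsub(" ", "_", ph$pair[j]))]] <- ph$p_adjusted[j]
    out
  })
  do.call(rbind, rows)
}

#' Region-scale correlation screen with FDR correction
#'
#' Pearson correlation between each region's mean connectivity and each
#' clinician scale, within each diagnostic group, with Benjamini-Hochberg
#' correction across the whole screen.
#'
#' @param values subjects x voxels matrix.
#' @param registry a [voxel_registry()].
#' @param subjects metadata data.frame with `group` and the scale columns.
#' @param region_table ranked `region_score_table`.
#' @param scales scale column names (default `hamd17, hama, ymrs`).
#' @param k top regions to screen (default 10, capped).
#' @param q false discovery rate (default 0.05).
#' @return data.frame `group, region_name, scale, r, p_value, p_adjusted,
#'   significant`.
#' @export
fc_scale_correlations <- function(values, registry, subjects, region_table,
                                  scales = c("hamd17", "hama", "ymrs"),
                                  k = 10L, q = 0.05) {
  k <- min(k, nrow(region_table))
  top <- region_table[order(region_table$rank), ][seq_len(k), ]
  rows <- list()
  for (g in unique(subjects$group)) {
    in_g <- subjects$group == g
    for (i in seq_len(k)) {
      mfc <- mean_region_fc(values[in_g, , drop = FALSE], registry,
                            top$region_id[i])
      for (sc in scales) {
        y <- subjects[[sc]][in_g]
        res <- tryCatch(pearson_correlation(mfc, y), error = function(e) NULL)
        if (is.null(res)) next
        rows[[length(rows) + 1L]] <-
          data.frame(group = g, region_name = top$region_name[i], scale = sc,
                     r = res$statistic, p_value = res$p_value,
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  fdr <- bh_fdr(out$p_value, q)
  out$p_adjusted <- fdr$p_adjusted
  out$significant <- fdr$rejected
  out
}
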