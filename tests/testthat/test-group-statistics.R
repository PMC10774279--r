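test_that("one-way ANOVA matches the direct-formula oracle", {
  set.seed(30)
  for (i in 1:10) {
    groups <- lapply(sample(3:6, 3, replace = TRUE) + 2, rnorm)
    res <- oneway_anova(groups)
    # textbook computation
    k <- length(groups); N <- sum(lengths(groups))
    gm <- mean(unlist(groups))
    msb <- sum(lengths(groups) *
                 (vapply(groups, mean, numeric(1)) - gm)^2) / (k - 1)
    msw <- sum(vapply(groups, function(g)
      sum((g - mean(g))^2), numeric(1))) / (N - k)
    expect_equal(res$statistic, msb / msw, tolerance = 1e-10)
    expect_equal(res$df, c(k - 1, N - k))
    expect_equal(res$p_value,
                 pf(msb / msw, k - 1, N - k, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  # two groups: F equals the squared pooled-variance t
  a <- rnorm(12); b <- rnorm(15, 0.5)
  f2 <- oneway_anova(list(a, b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(f2$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  # equal values within and across groups degenerate
  expect_error(oneway_anova(list(c(1, 1), c(1, 1))), "degenerate")
  expect_equal(oneway_anova(list(c(1, 2, 3), c(2, 1, 3)))$statistic, 0,
               tolerance = 1e-12)
})

test_that("summary-statistic ANOVA reproduces the published severity F", {
  res <- anova_from_summary(n = c(69, 23, 48), means = c(24.6, 24.3, 15.6),
                            sds = c(8.1, 6.7, 7.3))
  expect_lt(abs(res$statistic - 21.627) / 21.627, 0.005)
  expect_equal(res$df, c(2, 137))
  expect_lt(res$p_value, 1e-6)
  # agrees with raw-data F when summaries are exact
  set.seed(31)
  gs <- list(rnorm(10), rnorm(12, 1), rnorm(9, -1))
  raw <- oneway_anova(gs)
  smry <- anova_from_summary(lengths(gs), vapply(gs, mean, numeric(1)),
                             vapply(gs, sd, numeric(1)))
  expect_equal(smry$statistic, raw$statistic, tolerance = 1e-10)
  expect_equal(smry$p_value, raw$p_value, tolerance = 1e-10)
  # identical groups -> F = 0
  expect_equal(anova_from_summary(c(5, 5), c(2, 2), c(1, 1))$statistic, 0)
})

test_that("Levene gate is calibrated and detects scale differences", {
  set.seed(32)
  # identical groups: statistic ~ 0
  g <- rnorm(20)
  expect_lt(levene_test(list(g, g))$statistic, 1e-10)
  # calibration under equal variances
  rej <- mean(vapply(1:200, function(i) {
    gl <- list(rnorm(20), rnorm(20), rnorm(20))
    levene_test(gl)$p_value < 0.05
  }, logical(1)))
  expect_gt(rej, 0.005)
  expect_lt(rej, 0.12)
  # power: one group scaled x10 at n = 50
  hits <- mean(vapply(1:20, function(i) {
    levene_test(list(rnorm(50), rnorm(50, sd = 10)))$p_value < 0.05
  }, logical(1)))
  expect_gte(hits, 0.95)
  # agreement with the mean-centered reference implementation
  gl <- list(rnorm(15), rnorm(20, sd = 3), rnorm(10))
  ref <- car::leveneTest(unlist(gl),
                         factor(rep(seq_along(gl), lengths(gl))),
                         center = "mean")
  expect_equal(levene_test(gl)$statistic, ref$`F value`[1],
               tolerance = 1e-10)
  expect_equal(levene_test(gl)$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("post-hoc comparisons route by homogeneity and stay conservative", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  ph <- posthoc_pairwise(g, homogeneous = TRUE)
  expect_equal(ph$p_adjusted, rep(1, 3))
  pht <- posthoc_pairwise(g, homogeneous = FALSE)
  expect_equal(pht$p_adjusted, rep(1, 3))
  expect_identical(unique(pht$method), "tamhane_t2")
  # Bonferroni multiplies by the number of pairs
  set.seed(33)
  g2 <- list(a = rnorm(10), b = rnorm(10, 1.3), c = rnorm(10, 0.5))
  ph2 <- posthoc_pairwise(g2, homogeneous = TRUE)
  expect_equal(ph2$p_adjusted, pmin(pmax(ph2$p_raw * 3, ph2$p_raw), 1),
               tolerance = 1e-12)
  # adjusted never below raw, both branches
  ph3 <- posthoc_pairwise(g2, homogeneous = FALSE)
  expect_true(all(ph2$p_adjusted >= ph2$p_raw))
  expect_true(all(ph3$p_adjusted >= ph3$p_raw))
  # pooled t against the reference pairwise test
  ref <- pairwise.t.test(unlist(g2), rep(names(g2), lengths(g2)),
                         p.adjust.method = "bonferroni", pool.sd = TRUE)
  expect_equal(ph2$p_adjusted[1], ref$p.value["b", "a"], tolerance = 1e-10)
})

test_that("Kruskal-Wallis handles ties and monotone invariance", {
  res <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(res$statistic, 32 / 7, tolerance = 1e-12)
  expect_equal(res$df, 2)
  # identical values across groups: H ~ 0 after permuting
  set.seed(34)
  v <- rnorm(30)
  gl <- split(v, rep(1:3, 10))
  ref <- kruskal.test(gl)
  expect_equal(kruskal_wallis(gl)$statistic, unname(ref$statistic))
  # invariant to monotone transformation
  gl_exp <- lapply(gl, exp)
  expect_equal(kruskal_wallis(gl_exp)$statistic,
               kruskal_wallis(gl)$statistic, tolerance = 1e-12)
  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))), "degenerate")
})

test_that("Pearson chi-square reproduces the published cohort tables", {
  sex <- pearson_chi_square(rbind(c(43, 26), c(14, 9), c(30, 18)))
  expect_equal(round(sex$statistic, 3), 0.019)
  expect_equal(round(sex$p_value, 3), 0.990)
  expect_equal(sex$df, 2)
  med <- pearson_chi_square(rbind(c(24, 45), c(8, 15), c(34, 14)))
  expect_equal(round(med$statistic, 3), 16.452)
  expect_lt(med$p_value, 0.001)
  # proportional rows -> statistic 0
  expect_equal(pearson_chi_square(rbind(c(10, 20), c(5, 10)))$statistic, 0,
               tolerance = 1e-12)
  # 2x2 identity: chi2 = N * phi^2
  tab <- rbind(c(12, 5), c(7, 9))
  phi2 <- (det(tab) / sqrt(prod(rowSums(tab)) * prod(colSums(tab))))^2
  expect_equal(pearson_chi_square(tab)$statistic, sum(tab) * phi2,
               tolerance = 1e-10)
  expect_error(pearson_chi_square(rbind(c(0, 0), c(1, 2))), "zero margin")
})

test_that("exact r x c test matches hypergeometric enumeration", {
  res <- freeman_halton_exact(rbind(c(1, 9), c(11, 3)))
  expect_equal(round(res$p_value, 6), 0.002759)
  expect_equal(res$p_value, oracle_freeman_halton(rbind(c(1, 9), c(11, 3))),
               tolerance = 1e-10)
  # single-row / single-column tables are the whole reference set
  expect_equal(freeman_halton_exact(matrix(c(3, 4, 5), 1))$p_value, 1)
  # Monte-Carlo fallback for large tables stays close to the chi-square p
  big <- rbind(c(80, 40), c(50, 80))
  mc <- freeman_halton_exact(big, mc_replicates = 2e4)
  expect_true(isTRUE(mc$mc))
  expect_lt(mc$p_value, 0.01)
})

test_that("Pearson correlation matches its closed form", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1)$statistic, 1)
  set.seed(35)
  a <- rnorm(25); b <- rnorm(25)
  b_perp <- residuals(lm(b ~ a))
  resp <- pearson_correlation(a, b_perp)
  expect_lt(abs(resp$statistic), 1e-10)
  expect_gt(resp$p_value, 0.99)
  # direct-formula oracle
  r_direct <- cov(a, b) / (sd(a) * sd(b))
  res <- pearson_correlation(a, b)
  expect_equal(res$statistic, r_direct, tolerance = 1e-12)
  tt <- r_direct * sqrt((25 - 2) / (1 - r_direct^2))
  expect_equal(res$p_value, 2 * pt(-abs(tt), 23), tolerance = 1e-12)
  expect_error(pearson_correlation(a, rep(1, 25)), "degenerate")
})

test_that("BH step-up rejects the documented sets and bounds the raw p", {
  r1 <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r1$rejected))
  r2 <- bh_fdr(c(0.04, 0.2, 0.5), q = 0.05)
  expect_false(any(r2$rejected))
  # m = 1 reduces to the raw test
  expect_true(bh_fdr(0.04, q = 0.05)$rejected)
  expect_false(bh_fdr(0.06, q = 0.05)$rejected)
  # adjusted p never below raw; rejections monotone in q
  set.seed(36)
  for (i in 1:10) {
    p <- runif(sample(2:8, 1))
    got <- bh_fdr(p, q = 0.05)
    orc <- oracle_bh(p, 0.05)
    expect_identical(got$rejected, orc$rejected)
    expect_equal(got$p_adjusted, orc$p_adjusted, tolerance = 1e-12)
    expect_true(all(got$p_adjusted >= p - 1e-12))
    expect_true(all(bh_fdr(p, q = 0.2)$rejected >= got$rejected))
  }
})

test_that("three-group regional comparison reproduces the expected pattern", {
  # constructed features: 2 planted regions with UD < tBD = BD, 2 null
  set.seed(39)
  n <- 30
  groups <- rep(c("UD", "tBD", "BD"), each = n)
  shift <- ifelse(groups == "UD", 0, 0.5)
  vals <- cbind(matrix(shift + rnorm(3 * n * 2, sd = 0.3), 3 * n),
                matrix(rnorm(3 * n * 2, sd = 0.3), 3 * n))
  reg <- data.frame(index = 1:4, linear = 1:4, x = 1:4, y = 1, z = 1,
                    region = c(1L, 1L, 2L, 2L))
  tab <- data.frame(region_id = c(1, 2), region_name = c("planted", "null"),
                    importance = c(0.8, 0.2), rank = 1:2,
                    u_stat = 0, p_value = 0.01, selected = c(TRUE, FALSE))
  out <- table2_analysis(vals, reg, groups, tab, k = 2)
  expect_identical(nrow(out), 2L)
  expect_identical(sum(grepl("_vs_", names(out))), 3L)
  planted <- out[out$region_name == "planted", ]
  expect_lt(planted$p_value, 0.001)
  expect_lt(planted$p_UD_vs_BD, 0.05)
  expect_lt(planted$p_UD_vs_tBD, 0.05)
  expect_gt(planted$p_tBD_vs_BD, 0.05)
  nullr <- out[out$region_name == "null", ]
  expect_gt(nullr$p_value, 0.05)
})

test_that("scale correlation screen applies FDR across the whole grid", {
  set.seed(38)
  n <- 40
  subjects <- data.frame(
    subject_id = sprintf("s%02d", 1:n),
    group = rep(c("BD", "UD"), each = n / 2),
    hamd17 = rpois(n, 20), hama = rpois(n, 15), ymrs = rpois(n, 3))
  vals <- matrix(rnorm(n * 4), n)
  # plant one strong correlation in the BD group, region 1 x hamd17
  vals[subjects$group == "BD", 1:2] <-
    subjects$hamd17[subjects$group == "BD"] * 0.2 +
    rnorm(n, sd = 0.05)
  reg <- data.frame(index = 1:4, linear = 1:4, x = 1:4, y = 1, z = 1,
                    region = c(1L, 1L, 2L, 2L))
  tab <- data.frame(region_id = c(1, 2), region_name = c("r1", "r2"),
                    importance = c(0.8, 0.2), rank = 1:2,
                    u_stat = 0, p_value = 0.01, selected = c(TRUE, TRUE))
  out <- fc_scale_correlations(vals, reg, subjects, tab, k = 2)
  expect_identical(nrow(out), 12L)   # 2 groups x 2 regions x 3 scales
  expect_true(all(out$p_adjusted >= out$p_value - 1e-12))
  hit <- out[out$group == "BD" & out$region_name == "r1" &
               out$scale == "hamd17", ]
  expect_true(hit$significant)
})
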