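test_that("exact Mann-Whitney matches the enumeration oracle and wilcox.test", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$u, 0)
  expect_equal(mw$p_value, 2 / choose(4, 2))
  expect_equal(mw$method, "exact")

  set.seed(7)
  for (rep in 1:10) {
    vals <- sample(100, 8)
    x <- vals[1:4]; y <- vals[5:8]
    mine <- mann_whitney(x, y)
    oracle <- mw_enumeration_oracle(x, y)
    expect_equal(mine$u, oracle$u)
    expect_equal(mine$p_value, oracle$p_value, tolerance = 1e-12)
    wt <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(mine$p_value, unname(wt$p.value), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney identities and degenerate input", {
  set.seed(8)
  for (rep in 1:5) {
    x <- stats::rnorm(6); y <- stats::rnorm(9)
    expect_equal(mann_whitney(x, y)$u + mann_whitney(y, x)$u, 6 * 9)
  }
  sym <- mann_whitney(c(1, 5, 9), c(1, 5, 9))
  expect_equal(sym$u, 4.5)
  expect_equal(sym$p_value, 1)
  expect_warning(res <- mann_whitney(rep(2, 3), rep(2, 4)), "identical")
  expect_equal(res$p_value, 1)
})

test_that("Cohen's d matches hand computation and is antisymmetric", {
  expect_equal(cohens_d(c(1, 2, 3), c(4, 5, 6))$d, -3)
  expect_equal(cohens_d(c(5, 6, 7), c(5, 6, 7))$d, 0)
  a <- c(1.2, 3.4, 2.2, 5.0); b <- c(2.0, 4.4, 6.1)
  d1 <- cohens_d(a, b); d2 <- cohens_d(b, a)
  expect_equal(d1$d, -d2$d)
  expect_equal(d1$ci_low, -d2$ci_high)
  expect_equal(d1$ci_high, -d2$ci_low)
  expect_true(d1$ci_low <= d1$d && d1$d <= d1$ci_high)
  # affine re-scaling of the measurement units leaves d unchanged
  expect_equal(cohens_d(10 * a + 3, 10 * b + 3)$d, d1$d)
  expect_true(cohens_d(c(1, 1, 1), c(1, 1, 1))$undefined)
})

test_that("Cohen's f-squared closed form", {
  expect_equal(cohens_f2(0), 0)
  expect_equal(cohens_f2(0.5), 1)
  expect_equal(cohens_f2(0.847), 0.847 / 0.153)
  expect_equal(cohens_f2(1), Inf)
})

test_that("PCA recovers planted orthogonal factors and rotation preserves variance", {
  set.seed(21)
  n <- 100
  f1 <- stats::rnorm(n); f2 <- stats::rnorm(n)
  # two variable blocks, one per latent factor, small noise
  X <- cbind(sapply(1:4, function(i) f1 + 0.1 * stats::rnorm(n)),
             sapply(1:4, function(i) f2 + 0.1 * stats::rnorm(n)))
  colnames(X) <- paste0("v", 1:8)
  groups <- rep(c("a", "b"), each = n / 2)
  res <- pca_signature(X, groups, n_components = 2)
  expect_gt(sum(res$variance_fraction), 0.95)
  # rotated loadings separate the blocks
  assign1 <- apply(abs(res$loadings), 1, which.max)
  expect_equal(length(unique(assign1[1:4])), 1)
  expect_equal(length(unique(assign1[5:8])), 1)
  expect_false(assign1[1] == assign1[5])
  # rotation preserves total retained variance
  expect_equal(sum(res$loadings^2),
               sum(res$eigenvalues[1:2]), tolerance = 1e-8)
  # scores have zero column mean
  expect_equal(colMeans(res$scores), c(PC1 = 0, PC2 = 0), tolerance = 1e-10)
  # eigenvalue fractions over all components sum to 1
  expect_equal(sum(res$eigenvalues) / ncol(X), 1, tolerance = 1e-8)
})

test_that("factor-score ANOVA flags only the component carrying a group offset", {
  set.seed(22)
  n <- 50
  f1 <- stats::rnorm(2 * n)
  offset <- rep(c(0, 2), each = n)   # group shift on factor 2 only
  f2 <- stats::rnorm(2 * n) + offset
  X <- cbind(sapply(1:3, function(i) f1 + 0.15 * stats::rnorm(2 * n)),
             sapply(1:3, function(i) f2 + 0.15 * stats::rnorm(2 * n)))
  groups <- rep(c("NSL", "ALS"), each = n)
  res <- pca_signature(X, groups, n_components = 2)
  shifted <- which.max(abs(colSums(res$loadings[4:6, , drop = FALSE])))
  expect_lt(res$anova_p[shifted], 0.01)
  expect_gt(res$anova_p[-shifted], 0.1)
})

test_that("pca_signature drops constant variables with a warning", {
  set.seed(23)
  X <- cbind(a = stats::rnorm(20), b = stats::rnorm(20), c = rep(1, 20))
  expect_warning(res <- pca_signature(X, rep(c("x", "y"), 10)), "constant")
  expect_equal(res$dropped, "c")
  expect_equal(nrow(res$loadings), 2)
})

test_that("two perfectly correlated variables load on one component", {
  x <- seq(1, 20)
  X <- cbind(a = x, b = 2 * x + 5)
  res <- suppressWarnings(pca_signature(X, rep(c("g1", "g2"), 10),
                                        n_components = 1))
  expect_equal(res$variance_fraction[1], 1, tolerance = 1e-12)
})

test_that("correlation heatmap: R-squared cells equal squared r, q on Fisher scale", {
  co <- as_raft_cohort(toy_cohort_df())
  hm <- correlation_heatmap(co, row_vars = c("PE", "PC"),
                            col_vars = c("20:4n-6", "18:1n-9"))
  for (g in c("NSL", "ALS")) {
    expect_equal(hm$r_squared[[g]], hm$r[[g]]^2)
  }
  expect_equal(hm$q_diff,
               abs(atanh(pmin(pmax(hm$r$NSL, -0.999999), 0.999999)) -
                   atanh(pmin(pmax(hm$r$ALS, -0.999999), 0.999999))))
  # exact linear dependence gives r = 1
  co2 <- co
  co2$PE <- 2 * co2[["20:4n-6"]]
  hm2 <- correlation_heatmap(co2, "PE", "20:4n-6")
  expect_equal(unname(hm2$r$NSL[1, 1]), 1, tolerance = 1e-12)
  expect_equal(unname(hm2$r_squared$NSL[1, 1]), 1, tolerance = 1e-12)
})

test_that("independent pairs yield small correlations at n = 500", {
  set.seed(29)
  n <- 500
  df <- data.frame(group = rep(c("NSL", "ALS"), each = n / 2),
                   a = stats::rnorm(n), b = stats::rnorm(n),
                   c = stats::rnorm(n), d = stats::rnorm(n))
  hm <- correlation_heatmap(df, c("a", "b"), c("c", "d"))
  rs <- abs(c(hm$r$NSL, hm$r$ALS))
  expect_gte(mean(rs < 0.1), 0.75)
  expect_true(all(rs < 0.2))
})

test_that("slope comparison recovers planted heterogeneous slopes", {
  set.seed(33)
  n <- 20
  x <- c(stats::runif(n, 20, 40), stats::runif(n, 20, 40))
  groups <- rep(c("ALS", "NSL"), each = n)
  beta <- ifelse(groups == "ALS", -2.59, -0.07)
  y <- 10 + beta * x + stats::rnorm(2 * n, sd = 1)
  res <- compare_slopes(x, y, groups)
  expect_lt(res$p_value, 0.01)
  expect_equal(unname(res$beta_by_group["ALS"]), -2.59, tolerance = 0.1 * 2.59)
  expect_lt(abs(res$beta_by_group[["NSL"]] - (-0.07)), 0.1)
  expect_equal(res$df[1], 1)
  expect_equal(res$df[2], 2 * n - 4)
  # doubling y doubles both betas, leaves the test untouched
  res2 <- compare_slopes(x, 2 * y, groups)
  expect_equal(unname(res2$beta_by_group), unname(2 * res$beta_by_group))
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-10)
  # identical data in both groups: no heterogeneity
  res3 <- compare_slopes(rep(x[1:n], 2), rep(y[1:n], 2), groups)
  expect_lt(res3$f_stat, 1e-10)
  expect_gt(res3$p_value, 0.99)
})

test_that("compare_slopes rejects degenerate designs naming the group", {
  expect_error(compare_slopes(c(1, 1, 1, 1, 2, 3), 1:6,
                              rep(c("a", "b"), each = 3)),
               "no variance within group a")
})

test_that("forest table flags large effects with the NSL-minus-ALS convention", {
  co <- as_raft_cohort(toy_cohort_df())
  ft <- forest_table(co)
  # SE rises in ALS -> negative d; CHO falls -> positive d
  expect_lt(ft$d[ft$token == "SE"], -0.8)
  expect_gt(ft$d[ft$token == "CHO"], 0.8)
  expect_true(ft$large_effect[ft$token == "SE"])
  expect_equal(ft$pct_change[ft$token == "SE"], 100 * (12 / 5 - 1),
               tolerance = 1e-9)
  # equal groups: d = 0, not flagged
  same <- co; same[4:6, fa_cols(co)] <- same[1:3, fa_cols(co)]
  ft2 <- forest_table(same, tokens = "16:0", include_indexes = FALSE)
  expect_equal(ft2$d, 0)
  expect_false(ft2$large_effect)
  # Benjamini-Hochberg helper is monotone and bounded
  adj <- adjust_forest_fdr(ft)
  expect_true(all(adj$p_adjusted >= adj$p_value - 1e-12))
  expect_true(all(adj$p_adjusted <= 1))
})
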