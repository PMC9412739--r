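make_toy_table <- function(seed = 1, n = 6, p = 30, m = 5, fc = 2,
                           sigma = 0.25) {
  make_feature_table(sim_config(seed = seed, n_per_group = n, n_features = p,
                                n_markers = m, log2_fc = fc, sigma = sigma))
}

test_that("preprocessing centers, scales and drops constant features", {
  sim <- make_toy_table(seed = 2)
  pr <- preprocess(sim$table, scaling = "uv")
  expect_equal(unname(colMeans(pr$X)), rep(0, ncol(pr$X)), tolerance = 1e-12)
  expect_equal(unname(apply(pr$X, 2, sd)), rep(1, ncol(pr$X)),
               tolerance = 1e-12)

  X <- sim$table$X
  X[, 3] <- 5  # constant feature
  tab <- feature_table(X, sim$table$groups)
  expect_warning(pr2 <- preprocess(tab, scaling = "uv"), "zero-variance")
  expect_equal(pr2$dropped, colnames(X)[3])

  pr3 <- preprocess(sim$table, scaling = "ctr")
  expect_lt(max(abs(colMeans(pr3$X))), 1e-8)
  expect_false(isTRUE(all.equal(unname(apply(pr3$X, 2, sd)),
                                rep(1, ncol(pr3$X)))))
})

test_that("pca matches the SVD oracle and explains rank-1 data fully", {
  # rank-1 matrix
  X1 <- outer(1:6, seq(0.5, 2, length.out = 10))
  p1 <- pca(feature_table(X1, rep(c("a", "b"), 3)), 1, scaling = "ctr",
            cv_folds = 0)
  expect_equal(p1$r2x_cum[1], 1.0, tolerance = 1e-10)

  set.seed(9)
  X <- matrix(rnorm(12 * 20), 12, 20)
  tab <- feature_table(X, rep(c("a", "b"), each = 6))
  pc <- pca(tab, 3, scaling = "ctr", cv_folds = 0)
  sv <- svd(scale(X, scale = FALSE))
  for (k in 1:3) {
    expect_equal(abs(cor(pc$scores[, k], sv$u[, k])), 1, tolerance = 1e-8)
    expect_equal(abs(sum(pc$loadings[, k] * sv$v[, k])), 1, tolerance = 1e-8)
  }
  expect_true(all(diff(pc$r2x_cum) >= 0))
  expect_warning(pca(tab, 50, cv_folds = 0), "rank")
})

test_that("pca separates strongly shifted groups along PC1", {
  sim <- make_toy_table(seed = 4, m = 15, fc = 3)
  pc <- pca(sim$table, 2, log_transform = TRUE, seed = 4)
  t1 <- pc$scores[, 1]
  g <- sim$table$groups
  gap <- abs(mean(t1[g == "GH"]) - mean(t1[g == "GSW"]))
  spread <- sd(t1[g == "GH"]) + sd(t1[g == "GSW"])
  expect_gt(gap, spread)
  expect_gt(pc$q2, 0)
})

test_that("a single perfectly separating feature dominates OPLS-DA", {
  set.seed(5)
  X <- matrix(rnorm(12 * 10, sd = 0.1), 12, 10)
  X[, 1] <- rep(c(5, 0), each = 6) + rnorm(12, sd = 0.01)
  tab <- feature_table(X, rep(c("GH", "GSW"), each = 6))
  m <- fit_oplsda(tab, scaling = "ctr", cv_folds = 0)
  expect_gt(m$r2y, 0.99)
  expect_equal(which.max(vip(m)), 1, ignore_attr = TRUE)
})

test_that("OPLS-DA with zero orthogonal components equals 1-component PLS", {
  sim <- make_toy_table(seed = 6)
  m <- fit_oplsda(sim$table, n_orthogonal = 0, log_transform = TRUE,
                  scaling = "uv", cv_folds = 0)
  y <- as.numeric(sim$table$groups == "GH")
  orc <- pls1_oracle(log2(sim$table$X + 1), y)
  sgn <- sign(sum(m$w * orc$w))
  expect_equal(m$w, sgn * orc$w, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(m$t, sgn * orc$t, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(m$r2y, orc$r2y, tolerance = 1e-10)
})

test_that("model statistics respect their defining bounds", {
  sim <- make_toy_table(seed = 8)
  m <- fit_oplsda(sim$table, log_transform = TRUE, seed = 8)
  expect_gte(m$r2x, 0); expect_lte(m$r2x, 1)
  expect_lte(m$r2y, 1)
  expect_lte(m$q2, m$r2y + 1e-9)
  # orthogonal scores are uncorrelated with the class vector
  y <- as.numeric(sim$table$groups == "GH")
  expect_lt(abs(cor(m$T_o[, 1], y)), 1e-8)
  expect_error(fit_oplsda(sim$table, labels = rep("a", 12)), "two classes")
})

test_that("VIP normalization and degenerate cases hold", {
  sim <- make_toy_table(seed = 10)
  m <- fit_oplsda(sim$table, log_transform = TRUE, cv_folds = 0)
  expect_equal(mean(vip(m)^2), 1, tolerance = 1e-6)

  # p = 1 forces VIP = 1
  one <- feature_table(matrix(c(rnorm(6, 10), rnorm(6, 0)), ncol = 1),
                       rep(c("a", "b"), each = 6))
  expect_equal(unname(vip(fit_oplsda(one, cv_folds = 0))), 1)

  # identical features share the weight equally
  set.seed(10)
  base <- rep(c(1, 0), each = 6) + rnorm(12, sd = 0.1)
  same <- feature_table(matrix(base, 12, 8), rep(c("a", "b"), each = 6))
  expect_equal(unname(vip(fit_oplsda(same, cv_folds = 0))), rep(1, 8),
               tolerance = 1e-8)

  expect_error(vip(structure(list(), class = "lm")), "opls_model")
})

test_that("Q2 is negative in expectation when labels are permuted", {
  q2s <- vapply(1:10, function(s) {
    sim <- make_feature_table(sim_config(seed = s, n_features = 200,
                                         n_markers = 10, log2_fc = 0))
    fit_oplsda(sim$table, log_transform = TRUE, seed = s)$q2
  }, numeric(1))
  expect_lt(mean(q2s), 0)
})

test_that("spiked markers occupy the top VIP ranks", {
  sim <- make_feature_table(sim_config(seed = 12, n_features = 96,
                                       n_markers = 10, log2_fc = 2))
  m <- fit_oplsda(sim$table, log_transform = TRUE, scaling = "ctr",
                  cv_folds = 0)
  top10 <- names(sort(vip(m), decreasing = TRUE))[1:10]
  expect_setequal(top10, sim$truth$markers)
})

test_that("permutation test separates real from scrambled structure", {
  sim <- make_toy_table(seed = 14, p = 50, m = 10, fc = 2)
  pt <- permutation_test(sim$table, n_permutations = 60,
                         log_transform = TRUE, seed = 14)
  expect_lte(pt$p_value, 2 / 61)
  expect_true(all(pt$perm$q2 < pt$q2))
  # identity relabeling reproduces the observed statistics
  m0 <- fit_oplsda(sim$table, log_transform = TRUE, seed = 99)
  m1 <- fit_oplsda(sim$table, sim$table$groups, log_transform = TRUE,
                   seed = 99)
  expect_identical(m0$q2, m1$q2)
  expect_warning(permutation_test(sim$table, n_permutations = 5,
                                  log_transform = TRUE, seed = 1),
                 "20 permutations")
})

test_that("welch t matches the closed form and the null is calibrated", {
  sim <- make_toy_table(seed = 16, p = 10, m = 2)
  tt <- univariate(sim$table, "welch_t")
  g <- sim$table$groups
  for (j in c(1, 5, 10)) {
    orc <- welch_oracle(sim$table$X[g == "GH", j],
                        sim$table$X[g == "GSW", j])
    expect_equal(tt$statistic[j], orc$t, tolerance = 1e-10)
    expect_equal(tt$df[j], orc$df, tolerance = 1e-10)
    expect_equal(tt$p[j], orc$p, tolerance = 1e-10)
  }
  # identical groups: t = 0, p = 1
  X <- matrix(rnorm(6), ncol = 1)
  same <- feature_table(rbind(X, X), rep(c("a", "b"), each = 6))
  tt2 <- univariate(same, "welch_t")
  expect_equal(tt2$statistic, 0)
  expect_equal(tt2$p, 1)
})

test_that("three-group ANOVA keeps nominal type-I error", {
  set.seed(18)
  rej <- mean(replicate(400, {
    tab <- feature_table(matrix(rnorm(12), ncol = 1),
                         rep(c("a", "b", "c"), each = 4))
    univariate(tab, "anova_tukey")$p < 0.05
  }))
  expect_gt(rej, 0.02); expect_lt(rej, 0.09)
  # Tukey output is attached per feature
  tab <- feature_table(matrix(rnorm(24), ncol = 2),
                       rep(c("a", "b", "c"), each = 4))
  an <- univariate(tab, "anova_tukey")
  expect_length(attr(an, "tukey"), 2)
  expect_equal(rownames(attr(an, "tukey")[[1]]), c("b-a", "c-a", "c-b"))
})

test_that("marker selection applies strict VIP and p thresholds", {
  sim <- make_toy_table(seed = 20)
  m <- fit_oplsda(sim$table, log_transform = TRUE, scaling = "ctr",
                  cv_folds = 0)
  tt <- univariate(sim$table, "welch_t")
  none <- select_markers(m, tt, vip_threshold = Inf, alpha = 0)
  expect_equal(sum(none$selected), 0)
  # boundary: VIP exactly at the threshold is NOT selected
  mk <- select_markers(m, tt, vip_threshold = max(m$vip), alpha = 1)
  expect_false(mk$selected[1])
  expect_error(select_markers(m, tt$p[1:3]), "length mismatch")
})

test_that("percent change is exact arithmetic on group means", {
  X <- rbind(matrix(2, 3, 2), matrix(1, 3, 2))
  X[, 2] <- rep(c(3, 3), each = 3)
  tab <- feature_table(X, factor(rep(c("GH", "GSW"), each = 3),
                                 levels = c("GH", "GSW")))
  pc <- percent_change(tab)
  expect_equal(pc$percent_change[1], 100)   # means 2 vs 1
  expect_equal(pc$percent_change[2], 0)     # equal means
  # zero reference mean flagged as undefined
  X0 <- cbind(c(1, 1, 1, 0, 0, 0))
  pc0 <- percent_change(feature_table(X0, rep(c("GH", "GSW"), each = 3)))
  expect_true(pc0$undefined[1])
})

test_that("hierarchical clustering is exact on toy data", {
  # identical samples merge at height zero
  X <- rbind(c(1, 2, 3), c(1, 2, 3), c(5, 6, 7), c(9, 9, 9))
  h <- hca(X, linkage = "complete", scale_features = FALSE)
  expect_equal(min(h$samples$height), 0)
  expect_true(all(diff(h$samples$height) >= 0))

  # 1-D complete linkage, hand-computed merge heights 1, 3, 7
  pts <- matrix(c(0, 1, 3, 7, 0, 1, 3, 7), ncol = 2)
  h2 <- hca(pts, linkage = "complete", scale_features = FALSE)
  expect_equal(h2$samples$height, sqrt(2) * c(1, 3, 7), tolerance = 1e-10)

  # two well-separated groups split at the top
  sim <- make_toy_table(seed = 22, m = 20, fc = 4)
  logt <- feature_table(log2(sim$table$X), sim$table$groups)
  h3 <- hca(logt, linkage = "ward")
  top_split <- cutree(h3$samples, 2)
  expect_equal(length(unique(top_split[sim$table$groups == "GH"])), 1)
  expect_equal(length(unique(top_split[sim$table$groups == "GSW"])), 1)

  expect_error(hca(X[1, , drop = FALSE]), ">= 2")
})

test_that("Hotelling T2 flags a gross outlier and spares the bulk", {
  set.seed(24)
  S <- matrix(rnorm(40, sd = 1), 20, 2)
  S[1, ] <- c(30, 30)
  fl <- hotelling_t2(S)
  expect_true(fl[1])
  expect_lt(mean(fl[-1]), 0.2)
})

test_that("feature table csv i/o round-trips", {
  sim <- make_toy_table(seed = 26, p = 5)
  tmp <- tempfile(fileext = ".csv")
  write_feature_table(sim$table, tmp)
  back <- read_feature_table(tmp)
  expect_equal(back$X, sim$table$X, tolerance = 1e-6)
  expect_equal(as.character(back$groups), as.character(sim$table$groups))
})
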