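test_that("Kaplan-Meier reproduces the hand product-limit", {
  km <- km_curve(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  # no events: survival identically 1 with defined limits
  km0 <- km_curve(c(1, 2, 3), c(FALSE, FALSE, FALSE))
  expect_true(all(km0$survival == 1))
  expect_true(all(km0$ci_low == 1 & km0$ci_high == 1))
  # oracle equivalence on 200 random small samples, including Greenwood CIs
  set.seed(31)
  for (i in 1:200) {
    s <- random_surv_sample(sample(3:25, 1))
    got <- km_curve(s$time, s$event)
    want <- oracle_km_ci(s$time, s$event)
    expect_equal(got$survival, want$survival, tolerance = 1e-12)
    expect_equal(got$ci_low, want$low, tolerance = 1e-10)
    expect_equal(got$ci_high, want$high, tolerance = 1e-10)
  }
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(32)
  time <- sample(1:6, 60, replace = TRUE)
  km <- km_curve(time, rep(TRUE, 60))
  ecdf_surv <- vapply(km$time, function(t) mean(time > t), numeric(1))
  expect_equal(km$survival, ecdf_surv, tolerance = 1e-12)
  expect_true(all(diff(km$survival) <= 0))
})

test_that("log-rank matches the observed-minus-expected oracle", {
  # hand-computable 6-subject example, distinct times
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  group <- c("a", "b", "a", "b", "a", "b")
  got <- logrank_test(time, event, group)
  want <- oracle_logrank(time, event, group)
  expect_equal(got$chisq, want$chisq, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  # identical event patterns in both groups: statistic 0, p = 1
  sym <- logrank_test(c(1, 2, 3, 1, 2, 3), rep(TRUE, 6), rep(c("a", "b"), each = 3))
  expect_equal(sym$chisq, 0, tolerance = 1e-12)
  expect_equal(sym$p, 1)
  expect_error(logrank_test(1:3, c(TRUE, TRUE, TRUE), c("a", "a", "a")), "two")
})

test_that("log-rank holds its size under permuted labels", {
  set.seed(33)
  s <- random_surv_sample(40, p_event = 0.5, tmax = 3)
  group <- rep(c(0, 1), each = 20)
  rej <- 0
  nperm <- 2000
  for (i in seq_len(nperm)) {
    rej <- rej + (logrank_test(s$time, s$event, sample(group))$p < 0.05)
  }
  expect_gte(rej / nperm, 0.03)
  expect_lte(rej / nperm, 0.07)
})

test_that("Cox coefficient matches grid-search partial-likelihood maximization", {
  d <- data.frame(
    time = c(1, 2, 3, 4, 5, 6, 7, 8),
    event = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
    x = c(1, 0, 1, 1, 0, 1, 0, 0)
  )
  fit <- cox_fit(d, covariates = "x")
  expect_equal(fit$beta, oracle_cox_beta(d$time, d$event, d$x), tolerance = 1e-6)
  expect_equal(fit$hr, exp(fit$beta))
  expect_true(fit$ci_low < fit$hr && fit$hr < fit$ci_high)
})

test_that("Cox rejects degenerate designs and is invariant to time recoding", {
  d <- data.frame(time = 1:8, event = rep(c(TRUE, FALSE), 4),
    x = c(1, 0, 1, 1, 0, 1, 0, 0), z = rep(2, 8))
  expect_error(cox_fit(d, covariates = "z"), "constant.*z")
  expect_error(cox_fit(d, covariates = "missing_col"), "not found")
  # affine order-preserving recoding of event times leaves the HR unchanged
  f1 <- cox_fit(d, covariates = "x")
  d2 <- d; d2$time <- 10 + 3 * d$time
  f2 <- cox_fit(d2, covariates = "x")
  expect_equal(f1$beta, f2$beta, tolerance = 1e-12)
  # a single stratum equals the unstratified fit
  d$one <- 1L
  f3 <- cox_fit(d, covariates = "x", strata = "one")
  expect_equal(f1$beta, f3$beta, tolerance = 1e-12)
  expect_equal(f1$se, f3$se, tolerance = 1e-12)
})

test_that("ANCOVA adjusted means agree with the normal-equation oracle", {
  set.seed(34)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    g <- factor(sample(c("a", "b"), n, replace = TRUE))
    if (length(unique(g)) < 2) next
    age <- runif(n, 30, 70)
    y <- 7 + 0.02 * age + 0.3 * (g == "b") + rnorm(n, 0, 0.5)
    res <- ancova_adjusted_means(y, g, age)
    X <- cbind(1, as.integer(g == "b"), age)
    beta <- oracle_lm_coef(X, y)
    expect_equal(res$difference, beta[2], tolerance = 1e-8,
      label = "adjusted difference equals the group coefficient")
    adj_a <- beta[1] + beta[3] * mean(age)
    expect_equal(res$groups$adjusted_mean, c(adj_a, adj_a + beta[2]),
      tolerance = 1e-8)
  }
})

test_that("ANCOVA removes a purely age-driven group difference", {
  set.seed(35)
  # group b is simply older; CAVI depends on age only
  age <- c(runif(100, 40, 50), runif(100, 60, 70))
  g <- factor(rep(c("a", "b"), each = 100))
  y <- 5 + 0.05 * age + rnorm(200, 0, 0.1)
  raw_diff <- mean(y[g == "b"]) - mean(y[g == "a"])
  res <- ancova_adjusted_means(y, g, age)
  expect_gt(raw_diff, 0.5)
  expect_lt(abs(res$difference), 0.1)
  # null effect at large n: adjusted means nearly equal
  y0 <- 8 + 0.05 * age + rnorm(200, 0, 0.1)
  res0 <- ancova_adjusted_means(y0, factor(sample(rep(c("a", "b"), 100))), age)
  expect_lt(abs(res0$difference), 0.2)
  # Bonferroni multiplies and caps the p-value
  expect_equal(ancova_adjusted_means(y0, g, age, n_comparisons = 6)$p_bonferroni,
    min(1, 6 * ancova_adjusted_means(y0, g, age)$p_raw))
  expect_error(ancova_adjusted_means(y, g, rep(50, 200)), "constant")
})

test_that("ROC AUC equals the Mann-Whitney identity; Youden cutoff recovered", {
  # perfect separation
  r <- roc_youden(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 1)
  expect_true(r$cutoff > 3 && r$cutoff <= 10)
  expect_equal(r$youden, 1)
  # U-statistic identity on 500 random datasets (with ties)
  set.seed(36)
  for (i in 1:500) {
    n <- sample(8:40, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    expect_equal(roc_youden(scores, labels)$auc, oracle_auc(scores, labels),
      tolerance = 1e-12)
  }
  expect_error(roc_youden(1:5, c(1, 1, 1, 1, 1)), "both classes")
})

test_that("Youden cutoff recovers a constructed optimal threshold", {
  set.seed(37)
  grid <- seq(0.070, 0.090, by = 0.0005)
  scores <- sample(grid, 4000, replace = TRUE)
  labels <- runif(4000) < ifelse(scores >= 0.080, 0.6, 0.1)
  r <- roc_youden(scores, labels)
  expect_lte(abs(r$cutoff - 0.080), 0.0005) # within one grid step
  # ties in J break toward the lower score value
  s <- c(1, 2, 3, 4)
  y <- c(0, 0, 1, 1)
  expect_equal(roc_youden(s, y)$cutoff, 3)
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(38)
  scores <- rnorm(200)
  labels <- runif(200) < plogis(scores)
  if (any(labels) && !all(labels)) {
    got <- roc_youden(scores, labels)
    ref <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
    expect_equal(got$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  }
})
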