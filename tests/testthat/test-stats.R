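test_that("OLS matches the normal-equations oracle and flags rank deficiency", {
  set.seed(101)
  n <- 40
  X <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- 2 + 1.5 * X[, "a"] - 0.7 * X[, "b"] + rnorm(n)
  fit <- ols_fit(X, y)
  Xi <- cbind(1, X)
  beta <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
  expect_equal(fit$coefficients$estimate, as.vector(beta), tolerance = 1e-10)
  ref <- summary(lm(y ~ X))
  expect_equal(fit$r_squared, ref$r.squared, tolerance = 1e-12)
  expect_equal(fit$coefficients$p, unname(ref$coefficients[, 4]),
               tolerance = 1e-12)

  # exact linear response
  y2 <- 1 + X %*% c(1, 2, 3)
  fit2 <- ols_fit(X, drop(y2))
  expect_equal(fit2$r_squared, 1)
  expect_lt(max(abs(fit2$residuals)), 1e-10)

  # response orthogonal to centred regressors has zero slopes
  Xc <- scale(X, scale = FALSE)
  y3 <- rnorm(n)
  y3 <- drop(y3 - Xc %*% solve(crossprod(Xc), crossprod(Xc, y3)))
  fit3 <- ols_fit(X, y3)
  expect_lt(max(abs(fit3$coefficients$estimate[-1])), 1e-10)

  Xbad <- cbind(X, d = X[, "a"] + X[, "b"])
  expect_error(ols_fit(Xbad, y), "rank deficient")
})

test_that("exact LMG equals the brute-force all-orderings average", {
  set.seed(202)
  for (p in 3:5) {
    n <- 50
    S <- matrix(0.4, p, p); diag(S) <- 1
    X <- t(data_with_exact_correlation(S, n, seed = p))
    colnames(X) <- paste0("x", seq_len(p))
    y <- drop(X %*% runif(p, 0.2, 1)) + rnorm(n)
    res <- lmg_decomposition(X, y)
    expect_equal(res$mode, "exact")
    expect_equal(res$shares$share_raw, oracle_lmg(X, y), tolerance = 1e-10)
    expect_equal(sum(res$shares$share_raw), res$r_squared, tolerance = 1e-10)
    expect_equal(sum(res$shares$share_fraction), 1, tolerance = 1e-12)
    expect_true(all(res$shares$share_raw > -1e-12))
    # permutation invariance of regressor input order
    perm <- sample(p)
    res2 <- lmg_decomposition(X[, perm], y)
    expect_equal(res2$shares$share_raw[match(colnames(X), res2$shares$term)],
                 res$shares$share_raw, tolerance = 1e-10)
  }
})

test_that("LMG closed forms: single regressor and orthogonal designs", {
  set.seed(33)
  n <- 30
  x1 <- rnorm(n)
  y <- 2 * x1 + rnorm(n)
  res1 <- lmg_decomposition(cbind(x1 = x1), y)
  expect_equal(res1$shares$share_raw, res1$r_squared)

  # exactly orthogonal centred regressors: share_j = squared simple correlation
  X <- t(data_with_exact_correlation(diag(3), n, seed = 9))
  colnames(X) <- c("a", "b", "c")
  y2 <- drop(X %*% c(1, -0.5, 0.25)) + rnorm(n)
  res2 <- lmg_decomposition(X, y2)
  simple <- vapply(1:3, function(j) cor(X[, j], y2)^2, numeric(1))
  expect_equal(res2$shares$share_raw, simple, tolerance = 1e-10)
})

test_that("sampled LMG converges to the exact decomposition", {
  set.seed(404)
  n <- 60; p <- 5
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", 1:p)))
  X[, 2] <- X[, 1] * 0.6 + X[, 2] * 0.8
  y <- drop(X %*% runif(p)) + rnorm(n)
  exact <- lmg_decomposition(X, y)
  sampled <- lmg_decomposition(X, y, max_exact = 2, n_orderings = 4000,
                               seed = 5)
  expect_equal(sampled$mode, "sampled")
  expect_equal(sampled$shares$share_raw, exact$shares$share_raw,
               tolerance = 0.02)
  expect_error(lmg_decomposition(X, y, max_exact = 2), "seed")
})

test_that("LMG recovers the generating shares of a stroke + anticoagulant model", {
  # composite = b1 * stroke + b2 * anticoagulant + noise, with the
  # anticoagulant prevalence depending on class; analytic shares come from
  # the population covariance via the same subset formula.
  b1 <- 1.5; b2 <- 0.4
  pi1 <- 39 / 63; p0 <- 0.04; p1 <- 0.51
  vS <- pi1 * (1 - pi1)
  q <- pi1 * p1 + (1 - pi1) * p0
  C <- matrix(0, 3, 3, dimnames = rep(list(c("y", "stroke", "anticoag")), 2))
  C["stroke", "stroke"] <- vS
  C["anticoag", "anticoag"] <- q * (1 - q)
  C["stroke", "anticoag"] <- C["anticoag", "stroke"] <- vS * (p1 - p0)
  C["y", "stroke"] <- C["stroke", "y"] <- b1 * vS + b2 * C["stroke", "anticoag"]
  C["y", "anticoag"] <- C["anticoag", "y"] <-
    b1 * C["stroke", "anticoag"] + b2 * C["anticoag", "anticoag"]
  C["y", "y"] <- 1 + b1^2 * vS + b2^2 * C["anticoag", "anticoag"] +
    2 * b1 * b2 * C["stroke", "anticoag"]
  analytic <- lmg_from_covariance(C)$share_fraction

  set.seed(515)
  fracs <- matrix(NA_real_, 50, 2)
  for (r in 1:50) {
    n <- 63 * 4
    S <- rbinom(n, 1, pi1)
    A <- rbinom(n, 1, ifelse(S == 1, p1, p0))
    y <- b1 * S + b2 * A + rnorm(n)
    fit <- lmg_decomposition(cbind(stroke = S, anticoag = A), y)
    fracs[r, ] <- fit$shares$share_fraction
  }
  expect_lt(max(abs(colMeans(fracs) - analytic)), 0.05)
})

test_that("Welch t reproduces published summary statistics and matches t.test", {
  # severity score, 0 +/- 0.0 (n=24) vs 5.3 +/- 6.4 (n=39): t = 5.17, df = 38
  tr <- welch_t(summary_stats(0, 0, 24), summary_stats(5.3, 6.4, 39))
  expect_equal(round(abs(unname(tr$statistic)), 2), 5.17)
  expect_equal(tr$df, 38)

  # validation ages, 51.5 +/- 14.3 (30) vs 73.1 +/- 13.3 (39): |t| = 6.41
  tr2 <- welch_t(summary_stats(51.5, 14.3, 30), summary_stats(73.1, 13.3, 39))
  expect_equal(round(abs(unname(tr2$statistic)), 2), 6.41)

  set.seed(61)
  x <- rnorm(15, 3, 2); y <- rnorm(20, 4, 3)
  ours <- welch_t(x, y)
  ref <- t.test(x, y)
  expect_equal(unname(ours$statistic), unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  oursp <- welch_t(x, y, pooled = TRUE)
  refp <- t.test(x, y, var.equal = TRUE)
  expect_equal(unname(oursp$statistic), unname(refp$statistic), tolerance = 1e-12)

  same <- welch_t(x, x)
  expect_equal(unname(same$statistic), 0)
  deg <- welch_t(summary_stats(2, 0, 5), summary_stats(2, 0, 9))
  expect_equal(unname(deg$statistic), 0)
  expect_equal(deg$p, 1)
  expect_match(deg$flags, "degenerate")
  deg2 <- welch_t(summary_stats(2, 0, 5), summary_stats(3, 0, 9))
  expect_equal(unname(deg2$statistic), -Inf)
  expect_equal(deg2$p, 0)
})

test_that("chi-square reproduces published table entries and is symmetric", {
  # dyslipidaemia 0/24 vs 18/39
  expect_equal(round(unname(pearson_chi_square(
    counts_2x2(0, 24, 18, 39))$statistic), 1), 15.5)
  # rtPA 0/24 vs 9/39
  expect_equal(round(unname(pearson_chi_square(
    counts_2x2(0, 24, 9, 39))$statistic), 2), 6.46)
  # identical proportions
  expect_equal(unname(pearson_chi_square(counts_2x2(10, 20, 10, 20))$statistic), 0)

  # hand formula N(ad-bc)^2 / (r1 r2 c1 c2)
  tab <- counts_2x2(7, 24, 25, 39)
  hand <- 63 * (7 * 14 - 17 * 25)^2 / (24 * 39 * 32 * 31)
  expect_equal(unname(pearson_chi_square(tab)$statistic), hand,
               tolerance = 1e-12)
  # row and column swaps leave the statistic unchanged
  expect_equal(pearson_chi_square(tab[2:1, ])$statistic,
               pearson_chi_square(tab)$statistic)
  expect_equal(pearson_chi_square(tab[, 2:1])$statistic,
               pearson_chi_square(tab)$statistic)
  expect_error(pearson_chi_square(counts_2x2(0, 24, 0, 39)), "zero margin")
})

test_that("Spearman rho follows the rank-then-Pearson definition", {
  expect_equal(unname(spearman_test(1:10, (1:10)^3)$statistic), 1)
  expect_equal(unname(spearman_test(1:10, -(1:10))$statistic), -1)
  set.seed(71)
  x <- sample(1:5, 30, replace = TRUE)  # heavy ties
  y <- x + rnorm(30)
  st <- spearman_test(x, y)
  expect_equal(unname(st$statistic), cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_equal(unname(st$statistic),
               cor(x, y, method = "spearman"), tolerance = 1e-12)
  cst <- spearman_test(rep(1, 10), rnorm(10))
  expect_true(is.na(cst$statistic))
  expect_match(cst$flags, "degenerate")
})

test_that("Holm adjustment matches the stepwise formula and its properties", {
  expect_equal(holm_adjust(0.04), 0.04)
  expect_equal(holm_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(rep(1, 5)), rep(1, 5))
  set.seed(81)
  for (rep in 1:5) {
    p <- runif(sample(3:12, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, oracle_holm(p), tolerance = 1e-15)
    expect_true(all(adj >= p))
    perm <- sample(length(p))
    expect_equal(holm_adjust(p[perm])[order(perm)], adj)
  }
})

test_that("cohort table dispatches tests by variable type", {
  set.seed(91)
  md <- data.frame(
    sample_id = sprintf("S%02d", 1:63),
    class_label = factor(c(rep("control", 24), rep("AIS", 39)),
                         levels = c("control", "mimic", "AIS")),
    age = c(rnorm(24, 60, 10), rnorm(39, 73, 14)),
    hypertension_medication = c(rep(1, 8), rep(0, 16), rep(1, 29), rep(0, 10)),
    never_seen = c(rep(0, 24), rep(0, 39)))
  tab <- suppressWarnings(cohort_table(md, c("control", "AIS")))
  htn <- tab[tab$variable == "hypertension_medication", ]
  expect_equal(round(htn$statistic, 1), 10.3)  # published value for 8/24 vs 29/39
  agerow <- tab[tab$variable == "age", ]
  ref <- t.test(md$age[md$class_label == "control"],
                md$age[md$class_label == "AIS"])
  expect_equal(agerow$statistic, unname(ref$statistic), tolerance = 1e-12)
  # zero-margin variable is skipped with a warning
  expect_warning(cohort_table(md, c("control", "AIS")), "zero margin")
  # two compositionally identical groups give null statistics
  md2 <- data.frame(
    sample_id = sprintf("T%02d", 1:40),
    class_label = factor(rep(c("control", "AIS"), each = 20),
                         levels = c("control", "mimic", "AIS")),
    age = rep(c(48, 52), 20),
    hypertension_medication = rep(rep(c(0, 1), 10), 2))
  tab2 <- cohort_table(md2, c("control", "AIS"))
  expect_equal(tab2$statistic[tab2$variable == "hypertension_medication"], 0)
  expect_equal(tab2$statistic[tab2$variable == "age"], 0)
})

test_that("published cohort tables recompute exactly where flagged reproducible", {
  pub <- published_cohort_characteristics()
  for (nm in names(pub)) {
    rec <- recompute_cohort_table(pub[[nm]])
    rep_rows <- rec[rec$reproducible, ]
    printed <- abs(rep_rows$published_statistic)
    # match at the precision the table prints (3 significant-ish digits)
    digits <- ifelse(printed >= 10, 1, 2)
    expect_equal(round(abs(rep_rows$statistic), digits),
                 round(printed, digits),
                 info = nm)
  }
})
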