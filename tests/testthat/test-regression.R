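make_features <- function(S, y, location = NULL) {
  location <- location %||% rep("prm", ncol(S))
  structure(
    list(gene_ids = rownames(S), feature_names = colnames(S),
         location = stats::setNames(location, colnames(S)),
         S = S, y = stats::setNames(y, rownames(S)),
         model_kind = "B", condition = "c1", randomized = FALSE),
    class = "regdom_features")
}

random_design <- function(n, p, seed = 1) {
  withr::with_seed(seed, {
    S <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("g%03d", 1:n), sprintf("f%02d", 1:p)))
    S
  })
}

test_that("exact linear data is fitted exactly", {
  S <- random_design(50, 3)
  y <- drop(S %*% c(2, -1, 0.5)) + 4
  fit <- fit_linear(make_features(S, y))
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-10)
  expect_equal(fit$rse, 0, tolerance = 1e-10)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients), c(2, -1, 0.5), tolerance = 1e-10)

  # identity regression: single feature equal to the response
  S1 <- matrix(y, ncol = 1, dimnames = list(rownames(S), "f"))
  fit1 <- fit_linear(make_features(S1, y))
  expect_equal(unname(fit1$coefficients), 1, tolerance = 1e-12)
  expect_equal(fit1$intercept, 0, tolerance = 1e-10)
})

test_that("OLS matches the closed-form normal-equations oracle", {
  for (seed in 1:3) {
    S <- random_design(50, 8, seed = seed)
    y <- withr::with_seed(seed + 100,
                          drop(S %*% rnorm(8)) + 1 + rnorm(50, 0, 0.5))
    fit <- fit_linear(make_features(S, y))
    X <- cbind(1, S)
    beta <- solve(t(X) %*% X, t(X) %*% y) # independent closed form
    expect_equal(unname(c(fit$intercept, fit$coefficients)),
                 unname(drop(beta)), tolerance = 1e-8)
    # RSE uses df = n - 2 regardless of p
    expect_equal(fit$rse, sqrt(sum(fit$residuals^2) / (50 - 2)),
                 tolerance = 1e-12)
  }
})

test_that("singular designs are rejected with the offending column named", {
  S <- random_design(30, 2)
  S <- cbind(S, bad = S[, 1] + S[, 2])
  y <- rnorm(30)
  expect_error(regdom:::ols_fit(S, y, colnames(S)), "bad")
})

test_that("stepwise keeps planted effects and matches stepAIC", {
  withr::with_seed(11, {
    S <- random_design(300, 10, seed = 42)
    y <- 5 * 0.3 * S[, 4] + rnorm(300, 0, 0.3) # effect 5x noise sd
  })
  m1 <- stepwise_aic(make_features(S, y))
  expect_true("f04" %in% m1$fit$feature_names)

  # dual route: MASS::stepAIC backward from the full lm reaches the same set
  df <- data.frame(y = y, S)
  full <- stats::lm(y ~ ., data = df)
  ref <- MASS::stepAIC(full, direction = "backward", trace = 0)
  ref_feats <- sub("^S", "", setdiff(names(coef(ref)), "(Intercept)"))
  expect_setequal(m1$fit$feature_names, ref_feats)
})

test_that("stepwise with one feature reduces to a direct AIC comparison", {
  S <- random_design(100, 1)
  y <- withr::with_seed(2, rnorm(100)) # pure noise: null model should win
  fm <- make_features(S, y)
  m1 <- stepwise_aic(fm)
  n <- 100
  rss_full <- sum(fit_linear(fm)$residuals^2)
  rss_null <- sum((y - mean(y))^2)
  aic_full <- n * log(rss_full / n) + 2 * 2
  aic_null <- n * log(rss_null / n) + 2 * 1
  expect_equal(length(m1$fit$feature_names) == 1, aic_full < aic_null)
})

test_that("pure-noise designs retain almost nothing", {
  retained <- vapply(1:10, function(s) {
    S <- random_design(200, 8, seed = s)
    y <- withr::with_seed(s + 500, rnorm(200))
    length(stepwise_aic(make_features(S, y))$fit$feature_names)
  }, numeric(1))
  expect_gte(mean(retained <= 2), 0.6)
})

test_that("greedy reintroduction only ever improves AIC and CV-RSE", {
  S <- random_design(200, 12, seed = 3)
  y <- withr::with_seed(33, drop(S[, 1:4] %*% c(1, -1, 0.8, 0.5)) +
                          rnorm(200, 0, 1.5))
  m1 <- stepwise_aic(make_features(S, y))
  final <- greedy_reintroduction(m1, seed = 7)
  m1_at7 <- fit_linear(m1$fm, m1$fit$feature_names, cv_seed = 7)
  expect_lte(final$aic, m1_at7$aic)
  expect_lte(final$cv_rse, m1_at7$cv_rse)
  # with nothing removed, greedy returns M1 unchanged
  none <- list(fit = m1$fit, removed = character(0), fm = m1$fm)
  expect_identical(greedy_reintroduction(none, seed = 1)$feature_names,
                   m1$fit$feature_names)
})

test_that("ensembles are deterministic and zero-fill unselected features", {
  st <- generate_study(n_genes = 150, n_motifs = 8, n_prm_informative = 4,
                       n_lrc_informative = 2, seed = 21)
  fm <- study_matrices(st, "BHL")[[1]]
  e1 <- run_ensemble(fm, n_runs = 3, base_seed = 5)
  e2 <- run_ensemble(fm, n_runs = 3, base_seed = 5)
  expect_equal(e1$rcs, e2$rcs)
  expect_equal(attr(e1, "mean_rse"), attr(e2, "mean_rse"))
  unsel <- e1[e1$n_selected == 0, ]
  expect_true(all(vapply(unsel$rcs, function(r) all(r == 0), logical(1))))
  expect_true(all(unsel$mean_rc == 0))
})

test_that("ensemble t-tests behave under null, constant and random RCs", {
  zero <- toy_ensemble("f1", "prm", 0, rcs = list(rep(0, 10)))
  tz <- test_rc_significance(zero)
  expect_equal(tz$p_value, 1)
  expect_false(tz$significant)

  const <- toy_ensemble("f1", "prm", 0.5, rcs = list(rep(0.5, 10)))
  expect_true(test_rc_significance(const)$significant)

  # N(0,1) RCs over 100 features: ~5% nominal, ~0 after Bonferroni
  reps <- withr::with_seed(99, {
    vapply(1:30, function(r) {
      rcs <- lapply(1:100, function(i) rnorm(10))
      ens <- toy_ensemble(sprintf("f%03d", 1:100), "prm",
                          vapply(rcs, mean, numeric(1)), rcs = rcs)
      tt <- test_rc_significance(ens)
      c(raw = mean(tt$p_value < 0.05), adj = sum(tt$significant))
    }, numeric(2))
  })
  expect_lt(mean(reps["raw", ]), 0.08)
  expect_lt(mean(reps["adj", ]), 0.2)

  single <- toy_ensemble("f1", "prm", 0.5, rcs = list(0.5), n_runs = 1)
  expect_error(test_rc_significance(single), "2 runs")
})

test_that("constant and duplicate columns are dropped before fitting", {
  S <- random_design(50, 3)
  S <- cbind(S, const = rep(2, 50), dup = S[, 2])
  y <- rnorm(50)
  expect_warning(fm <- dedup_features(make_features(S, y)), "const")
  expect_setequal(attr(fm, "dropped"), c("const", "dup"))
  expect_equal(ncol(fm$S), 3)
})
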