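test_that("the five models carry exactly the canonical predictor sets", {
  expect_equal(model_terms(1), c("(Intercept)", "p1", "p2"))
  expect_equal(model_terms(2), c("(Intercept)", "p1", "p2", "pre"))
  expect_equal(model_terms(3), c("(Intercept)", "p1", "p2", "pre", "group"))
  expect_equal(model_terms(4),
               c("(Intercept)", "p1", "p2", "pre", "group",
                 "p1:group", "p2:group"))
  expect_equal(model_terms(5),
               c("(Intercept)", "p1", "p2", "group",
                 "p1:group", "p2:group"))
  expect_error(model_terms(6), "1..5")
})

test_that("design matrices center, dummy-code, and cross as specified", {
  obs <- small_observed(n = 60, seed = 4)
  d <- build_design(obs, "absolute_change", 4)
  expect_equal(colnames(d$X), model_terms(4))
  expect_equal(unname(d$X[, "(Intercept)"]), rep(1, 60))
  for (col in c("p1", "p2", "pre")) {
    expect_equal(sum(d$X[, col]), 0, tolerance = 1e-9)
  }
  expect_setequal(unique(d$X[, "group"]), c(0, 1))
  ctl <- obs$group == "control"
  expect_true(all(d$X[ctl, "p1:group"] == 0))
  expect_true(all(d$X[ctl, "p2:group"] == 0))
  expect_equal(d$X[!ctl, "p1:group"], d$X[!ctl, "p1"])
  expect_equal(d$mean_pre_nc, mean(obs$pre_obs))
  # response is computed on UNcentered scores
  expect_equal(d$y, obs$post_obs - obs$pre_obs)
})

test_that("degenerate predictor columns are named in the error", {
  obs <- small_observed(n = 30, seed = 5)
  obs$p2_obs <- rep(7, 30)
  expect_error(build_design(obs, "post_test", 2), "p2")
})

test_that("ols_fit matches closed forms and the normal-equations oracle", {
  # simple regression with a known closed form
  fit <- ols_fit(cbind("(Intercept)" = 1, x = 0:3), c(1, 2, 3, 4))
  expect_equal(fit$coef$estimate, c(1, 1))
  # exact recovery of a noiseless linear function
  X <- cbind("(Intercept)" = 1, a = rnorm(12), b = rnorm(12))
  y <- 2 - 3 * X[, "a"] + 0.5 * X[, "b"]
  fit <- ols_fit(X, y)
  expect_equal(fit$coef$estimate, c(2, -3, 0.5), tolerance = 1e-10)
  expect_lt(fit$sigma, 1e-10)
  # independent oracle on small random designs, estimates / SEs / p-values
  set.seed(42)
  for (i in 1:5) {
    n <- sample(9:12, 1)
    X <- cbind(1, matrix(rnorm(3 * n), n))
    colnames(X) <- c("(Intercept)", "a", "b", "c")
    y <- rnorm(n)
    fit <- ols_fit(X, y)
    oracle <- ols_normal_equations(X, y)
    expect_equal(fit$coef$estimate, unname(oracle$estimate),
                 tolerance = 1e-8)
    expect_equal(fit$coef$std_error, unname(oracle$std_error),
                 tolerance = 1e-8)
    expect_equal(fit$coef$p_value, unname(oracle$p_value), tolerance = 1e-8)
    expect_equal(fit$df_residual, oracle$df)
  }
})

test_that("fit_cell agrees with stats::lm on the same design", {
  obs <- small_observed(n = 80, seed = 6)
  for (m in c(1, 3, 4, 5)) {
    for (cr in c("post_test", "absolute_change", "relative_change")) {
      fit <- fit_cell(obs, cr, m)
      d <- build_design(obs, cr, m)
      ref <- summary(stats::lm(d$y ~ d$X - 1))$coefficients
      expect_equal(fit$coef$estimate, unname(ref[, 1]), tolerance = 1e-10)
      expect_equal(fit$coef$std_error, unname(ref[, 2]), tolerance = 1e-10)
      expect_equal(fit$coef$p_value, unname(ref[, 4]), tolerance = 1e-10)
    }
  }
})

test_that("estimates are invariant to subject order", {
  obs <- small_observed(n = 50, seed = 7)
  fit1 <- fit_cell(obs, "absolute_change", 4)
  set.seed(1)
  perm <- sample(50)
  shuffled <- obs[perm, ]
  attr(shuffled, "truth") <- attr(obs, "truth")[perm, ]
  class(shuffled) <- class(obs)
  fit2 <- fit_cell(shuffled, "absolute_change", 4)
  expect_equal(fit1$coef$estimate, fit2$coef$estimate, tolerance = 1e-10)
})

test_that("rank deficiency and exhausted degrees of freedom error out", {
  X <- cbind("(Intercept)" = 1, a = 1:8, b = 2 * (1:8))
  expect_error(ols_fit(X, rnorm(8)), "singular")
  expect_error(ols_fit(cbind("(Intercept)" = rep(1, 2), a = 1:2 + 0.5),
                       rnorm(2)), "degrees of freedom|singular")
})

test_that("true-source fits run the same pipeline on noise-free scores", {
  eff <- default_effects()
  truth <- generate_true_dataset(eff, 100000, seed = 9)
  obs <- apply_noise(truth, 0.8, seed = 10)
  fit <- fit_cell(obs, "post_test", 2, source = "true")
  # cov(T1, T2)_true = var(T1)_true, so the true pre-test slope is 1
  pre_b <- fit$coef$estimate[fit$coef$term == "pre"]
  expect_close(pre_b, 1, 0.01)
  expect_identical(fit$data_source, "true")
})

test_that("residual-score criterion nullifies the pre-test predictor", {
  # the pooled residual is orthogonal to pre by construction, so across
  # replicates the pre term is essentially never significant
  eff <- default_effects()
  pvals <- vapply(1:40, function(i) {
    obs <- small_observed(n = 200, seed = 100 + i, effects = eff)
    fit <- fit_cell(obs, "residual_score", 2)
    fit$coef$p_value[fit$coef$term == "pre"]
  }, numeric(1))
  expect_lt(significance_rate(pvals, 0.05), 0.05)
  expect_gt(mean(pvals), 0.5)
})

test_that("null-predictor p-values are uniform under resampling", {
  eff <- default_effects()
  pvals <- vapply(1:200, function(i) {
    obs <- small_observed(n = 100, seed = 3000 + i, effects = eff)
    fit <- fit_cell(obs, "absolute_change", 3)
    fit$coef$p_value[fit$coef$term == "p2"]
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})
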