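# Shared fixtures: everything is generated in code at test time.

# Absolute-tolerance comparison for statistical quantities (expect_equal's
# tolerance is relative for values away from zero).
expect_close <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)), tol)
}

default_effects <- function() calibrate_true_effects(true_model_spec())

# A small observed dataset for exact-algebra tests.
small_observed <- function(n = 60, seed = 1, reliability = 0.8,
                           effects = default_effects()) {
  truth <- generate_true_dataset(effects, n, seed)
  apply_noise(truth, reliability, seed + 1000L)
}

# Independent OLS oracle: explicit normal-equations solve with classical
# homoskedastic standard errors. Deliberately naive; used only on small,
# well-conditioned designs.
ols_normal_equations <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))[, 1]
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- beta / se
  list(estimate = beta, std_error = se,
       p_value = 2 * stats::pt(-abs(tval), df), df = df)
}
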