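test_that("significance_rate counts strict p < alpha", {
  expect_equal(significance_rate(c(0.01, 0.2, 0.04, 0.9), 0.05), 0.5)
  expect_equal(significance_rate(rep(1, 10), 0.05), 0)
  expect_equal(significance_rate(c(0.05, 0.049), 0.05), 0.5)  # strict
  set.seed(8)
  expect_close(significance_rate(runif(1000), 0.05), 0.05, 0.02)
  expect_error(significance_rate(numeric(0)), "empty")
  expect_error(significance_rate(c(0.5, 1.2)), "0, 1")
})

test_that("studentized_bias implements mean bias over SD times sqrt(n)", {
  expect_equal(studentized_bias(c(1, 2, 3), c(1, 2, 3), 100), 0)
  obs <- c(1.2, 1.4, 1.6, 1.1)
  tru <- obs - 0.3  # constant offset d
  expect_equal(studentized_bias(obs, tru, 25), 0.3 / (sd(obs) * 5))
  expect_equal(studentized_bias(obs, tru, 50),
               studentized_bias(obs, tru, 25) / sqrt(2))
  expect_error(studentized_bias(1:3, 1:4, 10), "equal length")
  expect_error(studentized_bias(rep(1, 5), rep(0, 5), 10), "undefined")
})

test_that("count_planned_fits multiplies the grid out", {
  expect_equal(count_planned_fits(study_config()), 1280000)
  expect_equal(count_planned_fits(
    study_config(n_grid = 50, reliability_grid = 0.8, replications = 1,
                 model_ids = 1, criteria = "post_test")), 2)
  expect_equal(count_planned_fits(
    study_config(n_grid = 100, reliability_grid = 0.8,
                 replications = 1000)), 40000)
  expect_equal(count_planned_fits(
    study_config(n_grid = 100, reliability_grid = 0.8, replications = 100)),
    4000)
})

test_that("study_config validates its grids", {
  expect_error(study_config(replications = 0), "replications")
  expect_error(study_config(n_grid = c(100, 201)), "even")
  expect_error(study_config(n_grid = integer(0)), "non-empty")
  expect_error(study_config(reliability_grid = 1.2), "0, 1")
  expect_error(study_config(alpha = 0), "alpha")
  expect_error(study_config(model_ids = 7), "1:5")
})

test_that("run_cell aggregates coefficient distributions per term", {
  eff <- default_effects()
  cfg <- study_config(n_grid = 100, reliability_grid = 0.8,
                      replications = 60, master_seed = 11,
                      model_ids = c(2, 4), criteria = c("absolute_change",
                                                        "post_test"))
  cell <- run_cell(cfg, eff, 100, 0.8)
  s <- cell$summary
  expect_setequal(unique(s$model_id), c(2, 4))
  expect_setequal(unique(s$source), c("observed", "true"))
  expect_equal(nrow(s), 2 * 2 * (length(model_terms(2)) +
                                   length(model_terms(4))))
  expect_true(all(s$SE >= 0))
  expect_true(all(s$P >= 0 & s$P <= 1))
  # P * replications is an integer count
  expect_equal(s$P * s$n_ok, round(s$P * s$n_ok))
  expect_equal(cell$n_failed, 0)
  # bias table covers observed-model terms only
  expect_equal(nrow(cell$bias),
               2 * (length(model_terms(2)) + length(model_terms(4))))
  expect_true(all(is.finite(cell$bias$studentized_bias)))
  # determinism under the master seed
  cell2 <- run_cell(cfg, eff, 100, 0.8)
  expect_identical(cell$summary, cell2$summary)
})

test_that("true-data fits recover the calibrated interaction slope", {
  eff <- default_effects()
  cfg <- study_config(n_grid = 400, reliability_grid = 0.8,
                      replications = 120, master_seed = 5,
                      model_ids = 4, criteria = "absolute_change")
  cell <- run_cell(cfg, eff, 400, 0.8)
  tru <- cell$summary[cell$summary$source == "true" &
                        cell$summary$term == "p1:group", ]
  expect_close(tru$M, eff$beta_true_p1, 0.02)
  # observed estimates attenuate toward rel * beta (error on P-I inflates
  # the predictor variance by 1/rel while the covariance is preserved)
  obs <- cell$summary[cell$summary$source == "observed" &
                        cell$summary$term == "p1:group", ]
  expect_close(obs$M, 0.8 * eff$beta_true_p1, 0.02)
})

test_that("run_study emits one deterministic tidy row per cell and term", {
  eff <- default_effects()
  cfg <- study_config(n_grid = c(50, 100), reliability_grid = c(0.6, 0.9),
                      replications = 25, master_seed = 3,
                      model_ids = 3, criteria = "absolute_change")
  res <- run_study(cfg, eff)
  expect_s3_class(res, "tbl_df")
  expect_equal(names(res),
               c("model_id", "criterion", "n", "reliability", "term",
                 "M", "SE", "P", "studentized_bias", "n_ok"))
  expect_equal(nrow(res), 2 * 2 * length(model_terms(3)))
  expect_true(all(res$n_ok == 25))
  res2 <- run_study(cfg, eff)
  expect_identical(res, res2)
  # SE shrinks roughly like 1/sqrt(n) across the n grid
  se50 <- res$SE[res$n == 50 & res$term == "p1" & res$reliability == 0.9]
  se100 <- res$SE[res$n == 100 & res$term == "p1" & res$reliability == 0.9]
  expect_close(se100 / se50, 1 / sqrt(2), 0.25)
})

test_that("alpha is calibrated for null effects at reliability 1", {
  # all true effects zero: every term's significance rate sits near alpha
  eff <- default_effects()
  eff$mu_delta_exp <- 0
  eff$mu_delta_ctl <- 0
  eff$beta_true_p1 <- 0
  eff$r_true_p1 <- 0
  eff$var_delta_exp <- 0  # no treatment-induced spread either
  cfg <- study_config(n_grid = 100, reliability_grid = 1.0,
                      replications = 400, master_seed = 17,
                      model_ids = 1, criteria = "post_test")
  cell <- run_cell(cfg, eff, 100, 1.0)
  obs <- cell$summary[cell$summary$source == "observed" &
                        cell$summary$term %in% c("p1", "p2"), ]
  expect_true(all(obs$P >= 0.02 & obs$P <= 0.08))
})
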