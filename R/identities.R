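#' Algebraic identities linking post-test and change-score regressions
#'
#' When the centered pre-test score is a predictor, the post-test
#' regression and the absolute-change regression on the same dataset are
#' linear transformations of each other: the pre-test slope differs by
#' exactly one (`b_pre = c_pre + 1`), every other slope is identical
#' (`b_k = c_k`), and the intercepts differ by the mean uncentered
#' pre-test score (`b_0 = c_0 + mean(pre)`). These are exact finite-sample
#' OLS facts, not asymptotic approximations — a direct consequence of the
#' change score being the post score minus a linear function of a
#' predictor already in the model. [verify_change_identities()] checks
#' them on a pair of fitted models.
#'
#' One corollary: since the post-test pre-slope estimates the test-retest
#' reliability (at most 1), the change-score pre-slope is negative
#' whenever measurement is imperfect — more negative the lower the
#' reliability — without any true compensation effect in the data.
#'
#' @param fit_post An [`ols_fit`][fit_cell()] with criterion
#'   `"post_test"`, pre-test term included.
#' @param fit_change The matching fit with criterion `"absolute_change"`,
#'   same dataset and model.
#' @param mean_pre_nc Mean of the uncentered pre-test score used in the
#'   fits; defaults to the value stored on `fit_post`.
#' @param tolerance Absolute tolerance for each discrepancy (default
#'   1e-8).
#' @return A tibble of class `identity_report`: one row per term with the
#'   post-test estimate `b`, change estimate `c`, the identity's expected
#'   `b`, the discrepancy, and a pass flag. Attribute `"pass"` is the
#'   overall verdict.
#' @export
#' @examples
#' eff <- calibrate_true_effects(true_model_spec())
#' obs <- apply_noise(generate_true_dataset(eff, 100, 1), 0.8, 2)
#' verify_change_identities(fit_cell(obs, "post_test", 4),
#'                          fit_cell(obs, "absolute_change", 4))
verify_change_identities <- function(fit_post, fit_change,
                                     mean_pre_nc = fit_post$mean_pre_nc,
                                     tolerance = 1e-8) {
  stopifnot(inherits(fit_post, "ols_fit"), inherits(fit_change, "ols_fit"))
  if (!identical(fit_post$coef$term, fit_change$coef$term)) {
    stop("the two fits use different model terms", call. = FALSE)
  }
  if (!"pre" %in% fit_post$coef$term) {
    stop("the identities require the pre-test score as a predictor",
         call. = FALSE)
  }
  if (!is.null(fit_post$criterion) && fit_post$criterion != "post_test") {
    stop("`fit_post` must use the post_test criterion", call. = FALSE)
  }
  if (!is.null(fit_change$criterion) &&
      fit_change$criterion != "absolute_change") {
    stop("`fit_change` must use the absolute_change criterion", call. = FALSE)
  }
  if (!is.null(fit_post$n) && !is.null(fit_change$n) &&
      fit_post$n != fit_change$n) {
    stop("the two fits come from datasets of different size", call. = FALSE)
  }
  if (is.null(mean_pre_nc)) {
    stop("`mean_pre_nc` is required (not stored on `fit_post`)", call. = FALSE)
  }
  terms <- fit_post$coef$term
  b <- fit_post$coef$estimate
  cc <- fit_change$coef$estimate
  expected_b <- cc +
    ifelse(terms == "pre", 1, ifelse(terms == "(Intercept)", mean_pre_nc, 0))
  rpt <- tibble::tibble(
    term = terms,
    b = b,
    c = cc,
    expected_b = expected_b,
    discrepancy = b - expected_b,
    pass = abs(b - expected_b) <= tolerance
  )
  attr(rpt, "pass") <- all(rpt$pass)
  attr(rpt, "mean_pre_nc") <- mean_pre_nc
  class(rpt) <- c("identity_report", class(rpt))
  rpt
}

#' @export
print.identity_report <- function(x, ...) {
  cat("Post-test vs absolute-change regression identities",
      sprintf("(mean pre = %.4f)\n", attr(x, "mean_pre_nc")))
  print(as.data.frame(x[, c("term", "b", "c", "discrepancy", "pass")]),
        digits = 6, row.names = FALSE)
  cat(if (isTRUE(attr(x, "pass"))) "All identities hold.\n" else
    "IDENTITY VIOLATION.\n")
  invisible(x)
}

#' Criterion equivalence of slopes when the pre-test is in the model
#'
#' With the pre-test score as a predictor, the slope estimates of all
#' *other* predictors (P-I, P-II, group, interactions) are identical
#' whether the criterion is the post-test score, the absolute change, or
#' the residualized change — the three criteria differ only by linear
#' functions of predictors already in the model (the relative change is
#' on another scale and is exempt). Checks all pairwise agreements.
#'
#' @param fit_post,fit_change,fit_residual [`ols_fit`][fit_cell()]s of
#'   the same model (pre-test included) on one dataset, with criteria
#'   post-test, absolute change, and residual score respectively.
#' @param tolerance Absolute tolerance (default 1e-8).
#' @return A tibble: one row per non-pre slope term with the three
#'   estimates, the maximum pairwise discrepancy, and a pass flag;
#'   attribute `"pass"` is the overall verdict.
#' @export
verify_criterion_equivalence <- function(fit_post, fit_change, fit_residual,
                                         tolerance = 1e-8) {
  fits <- list(post_test = fit_post, absolute_change = fit_change,
               residual_score = fit_residual)
  for (f in fits) stopifnot(inherits(f, "ols_fit"))
  terms <- fit_post$coef$term
  if (!"pre" %in% terms) {
    stop("criterion equivalence only applies to models that include the ",
         "pre-test score as a predictor", call. = FALSE)
  }
  if (!identical(terms, fit_change$coef$term) ||
      !identical(terms, fit_residual$coef$term)) {
    stop("the three fits use different model terms", call. = FALSE)
  }
  for (nm in names(fits)) {
    crit <- fits[[nm]]$criterion
    if (!is.null(crit) && crit != nm) {
      stop("fit supplied for ", nm, " was computed with criterion ", crit,
           call. = FALSE)
    }
  }
  keep <- !terms %in% c("(Intercept)", "pre")
  est <- cbind(post_test = fit_post$coef$estimate,
               absolute_change = fit_change$coef$estimate,
               residual_score = fit_residual$coef$estimate)[keep, , drop = FALSE]
  spread <- apply(est, 1, function(v) max(v) - min(v))
  out <- tibble::tibble(
    term = terms[keep],
    post_test = est[, "post_test"],
    absolute_change = est[, "absolute_change"],
    residual_score = est[, "residual_score"],
    max_discrepancy = spread,
    pass = spread <= tolerance
  )
  attr(out, "pass") <- all(out$pass)
  out
}
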