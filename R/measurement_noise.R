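#' Impose classical-test-theory measurement error
#'
#' Adds independent zero-mean Gaussian noise to every measure of a true
#' dataset so that each observed measure has the requested reliability
#' (true variance / observed variance). Each measure's error SD is based
#' on its own true-score SD: the pre-test and both predictors use the
#' pre-test/predictor SD, the experimental post-test uses its larger SD,
#' the control post-test its own. Noise draws are independent across
#' subjects and measures.
#'
#' @param truth A [generate_true_dataset()] result.
#' @param reliability Reliability in (0, 1] applied to all six measures;
#'   at 1 the observed scores equal the true scores exactly.
#' @param seed Integer seed for the noise draws.
#' @return A tibble of class `observed_dataset` with columns `subject_id`,
#'   `group`, `pre_obs`, `post_obs`, `p1_obs`, `p2_obs`; the source
#'   dataset and reliability are attached as attributes `"truth"` and
#'   `"reliability"`.
#' @export
#' @examples
#' eff <- calibrate_true_effects(true_model_spec())
#' truth <- generate_true_dataset(eff, 200, seed = 1)
#' obs <- apply_noise(truth, reliability = 0.8, seed = 2)
apply_noise <- function(truth, reliability, seed) {
  stopifnot(inherits(truth, "true_dataset"))
  if (length(reliability) != 1L || reliability <= 0 || reliability > 1) {
    stop("`reliability` must be a single value in (0, 1]", call. = FALSE)
  }
  spec <- attr(truth, "spec")
  n <- nrow(truth)
  is_exp <- truth$group == "experimental"
  sd_post_true <- ifelse(is_exp, spec$sd_post_exp, spec$sd_post_ctl)

  if (reliability == 1) {
    noise_pre <- noise_post <- noise_p1 <- noise_p2 <- numeric(n)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    noise_pre <- stats::rnorm(n, 0, error_sd(spec$sd_pre, reliability))
    noise_post <- stats::rnorm(n) * error_sd(sd_post_true, reliability)
    noise_p1 <- stats::rnorm(n, 0, error_sd(spec$sd_p, reliability))
    noise_p2 <- stats::rnorm(n, 0, error_sd(spec$sd_p, reliability))
  }

  out <- tibble::tibble(
    subject_id = truth$subject_id,
    group = truth$group,
    pre_obs = truth$t1_true + noise_pre,
    post_obs = truth$t2_true + noise_post,
    p1_obs = truth$p1_true + noise_p1,
    p2_obs = truth$p2_true + noise_p2
  )
  attr(out, "truth") <- truth
  attr(out, "reliability") <- reliability
  class(out) <- c("observed_dataset", class(out))
  out
}

#' Empirical reliability of an observed measure
#'
#' The squared Pearson correlation between true and observed scores; under
#' the classical test model this estimates the reliability (the share of
#' observed variance that is true variance).
#'
#' @param truth_values True scores.
#' @param observed_values Observed scores, same length (>= 3).
#' @return A single value in \[0, 1\].
#' @export
empirical_reliability <- function(truth_values, observed_values) {
  if (length(truth_values) != length(observed_values)) {
    stop("true and observed vectors must have equal length", call. = FALSE)
  }
  if (length(truth_values) < 3L) {
    stop("need at least 3 observations", call. = FALSE)
  }
  if (stats::sd(truth_values) == 0 || stats::sd(observed_values) == 0) {
    stop("reliability is undefined when either vector has zero variance",
         call. = FALSE)
  }
  stats::cor(truth_values, observed_values)^2
}
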