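#' Specify the true-score generative model
#'
#' Defines the noise-free ("true") generative model of a 2 (group:
#' control/experimental) x 2 (pre/post) intervention design with two
#' external continuous predictors. Both groups share the pre-test
#' distribution; the experimental group gains more on average and with
#' larger post-test spread; one predictor (P-I) is correlated with the
#' experimental gain, the other (P-II) with nothing.
#'
#' The standardized-change (`dz`) and predictor-gain correlation targets
#' are *observed-score* targets, defined at `reference_reliability`: the
#' true effects backed out of them by [calibrate_true_effects()] are held
#' constant across all reliability conditions, so observed effect sizes
#' attenuate as reliability drops while the underlying truth does not move.
#'
#' @param mean_pre Mean of the true pre-test score in both groups (T-scale
#'   default 50).
#' @param sd_pre SD of the true pre-test score (default 10).
#' @param sd_post_exp SD of the experimental-group true post-test score
#'   (default 13); must be at least `sd_pre` because the gain-variance
#'   decomposition `var(gain) = sd_post_exp^2 - sd_pre^2` requires it.
#' @param sd_post_ctl SD of the control-group true post-test score
#'   (default 10).
#' @param dz_exp Target observed standardized mean change (mean change /
#'   SD of change) in the experimental group at the reference reliability
#'   (default 0.50).
#' @param dz_ctl Same for the control group (default 0.05).
#' @param r_p1_gain Target observed Pearson correlation between P-I and
#'   the experimental-group change score at the reference reliability
#'   (default 0.30).
#' @param r_p2_gain Target correlation for P-II (default 0; P-II is the
#'   null predictor and receives no pathway).
#' @param mean_p,sd_p Mean and SD of both predictors (defaults 50, 10).
#' @param reference_reliability Reliability at which the observed-score
#'   targets are defined (default 0.80).
#'
#' @return An object of class `true_model_spec`.
#' @seealso [calibrate_true_effects()], [generate_true_dataset()]
#' @export
#' @examples
#' spec <- true_model_spec()
#' spec
true_model_spec <- function(mean_pre = 50, sd_pre = 10,
                            sd_post_exp = 13, sd_post_ctl = 10,
                            dz_exp = 0.50, dz_ctl = 0.05,
                            r_p1_gain = 0.30, r_p2_gain = 0,
                            mean_p = 50, sd_p = 10,
                            reference_reliability = 0.80) {
  stopifnot(
    is.numeric(mean_pre), length(mean_pre) == 1L,
    is.numeric(mean_p), length(mean_p) == 1L
  )
  if (sd_pre <= 0 || sd_post_exp <= 0 || sd_post_ctl <= 0 || sd_p <= 0) {
    stop("all standard deviations must be strictly positive", call. = FALSE)
  }
  if (sd_post_exp < sd_pre) {
    stop("`sd_post_exp` must be >= `sd_pre`: the experimental gain variance ",
         "is sd_post_exp^2 - sd_pre^2 and cannot be negative", call. = FALSE)
  }
  if (reference_reliability <= 0 || reference_reliability > 1) {
    stop("`reference_reliability` must lie in (0, 1]", call. = FALSE)
  }
  if (abs(r_p1_gain) >= 1 || abs(r_p2_gain) >= 1) {
    stop("target correlations must lie in (-1, 1)", call. = FALSE)
  }
  if (r_p2_gain != 0) {
    stop("P-II is the null predictor: `r_p2_gain` must be 0", call. = FALSE)
  }
  structure(
    list(
      mean_pre = mean_pre, sd_pre = sd_pre,
      sd_post_exp = sd_post_exp, sd_post_ctl = sd_post_ctl,
      dz_exp = dz_exp, dz_ctl = dz_ctl,
      r_p1_gain = r_p1_gain, r_p2_gain = r_p2_gain,
      mean_p = mean_p, sd_p = sd_p,
      reference_reliability = reference_reliability
    ),
    class = "true_model_spec"
  )
}

#' @export
print.true_model_spec <- function(x, ...) {
  cat("True-score model for a 2 (group) x 2 (pre/post) design\n")
  cat(sprintf("  pre-test:      mean %.4g, SD %.4g (both groups)\n",
              x$mean_pre, x$sd_pre))
  cat(sprintf("  post-test SD:  %.4g (experimental), %.4g (control)\n",
              x$sd_post_exp, x$sd_post_ctl))
  cat(sprintf("  predictors:    mean %.4g, SD %.4g\n", x$mean_p, x$sd_p))
  cat(sprintf("  observed targets at reliability %.2f:\n",
              x$reference_reliability))
  cat(sprintf("    dz = %.2f (exp), %.2f (ctl); r(P-I, gain) = %.2f\n",
              x$dz_exp, x$dz_ctl, x$r_p1_gain))
  invisible(x)
}

#' Measurement-error SD implied by a reliability
#'
#' Under Classical Test Theory, observed = true + independent zero-mean
#' Gaussian noise, and reliability is the ratio of true to observed
#' variance. This returns the noise SD that yields a given reliability
#' for a measure whose true-score SD is `sd_true`:
#' `sd_true * sqrt((1 - reliability) / reliability)`.
#'
#' @param sd_true True-score SD (> 0). Vectorized.
#' @param reliability Reliability in (0, 1]. Vectorized.
#' @return The error SD, in the same units as `sd_true`.
#' @export
#' @examples
#' error_sd(10, 0.80)  # 5: 100 / (100 + 25) = 0.80
error_sd <- function(sd_true, reliability) {
  if (any(sd_true <= 0)) stop("`sd_true` must be > 0", call. = FALSE)
  if (any(reliability <= 0 | reliability > 1)) {
    stop("`reliability` must lie in (0, 1]", call. = FALSE)
  }
  sd_true * sqrt((1 - reliability) / reliability)
}

#' Attenuate a true correlation for unreliability
#'
#' The observed correlation between two imperfectly measured variables is
#' the true-score correlation shrunk by the square root of the product of
#' the two reliabilities (Spearman's attenuation formula).
#'
#' @param r_true True-score correlation, |r| <= 1.
#' @param rel_x,rel_y Reliabilities of the two measures, each in (0, 1].
#' @return The expected observed correlation.
#' @export
#' @examples
#' attenuate(0.50, 0.60, 0.60)  # 0.30
#' attenuate(0.50, 0.90, 0.90)  # 0.45
attenuate <- function(r_true, rel_x, rel_y) {
  if (any(abs(r_true) > 1)) stop("|r_true| must be <= 1", call. = FALSE)
  if (any(rel_x <= 0 | rel_x > 1) || any(rel_y <= 0 | rel_y > 1)) {
    stop("reliabilities must lie in (0, 1]", call. = FALSE)
  }
  r_true * sqrt(rel_x * rel_y)
}

#' Calibrate constant true effects from observed-score targets
#'
#' Backs out the true (noise-free) effects that reproduce the observed
#' effect-size targets of a [true_model_spec()] at its reference
#' reliability. These true effects are then held constant across all
#' reliability conditions of a study.
#'
#' The calibration is closed-form:
#' * experimental true-gain variance: `sd_post_exp^2 - sd_pre^2`
#'   (true pre score and true gain are uncorrelated by construction);
#' * the true P-I/gain correlation disattenuates the target by
#'   `sqrt(rel_p * rel_gain)`, where `rel_gain` is the reliability of the
#'   observed change-score composite (true gain variance over true gain
#'   variance plus the pre and post error variances);
#' * experimental true mean gain: `dz_exp` times the observed change-score
#'   SD at the reference reliability;
#' * control true gain is a deterministic shift (`SD_C2 = SD_C1` leaves it
#'   no variance), sized so `dz_ctl` holds on the purely noise-driven
#'   observed change.
#'
#' @param spec A [true_model_spec()].
#' @return An object of class `calibrated_effects`: a list with elements
#'   `mu_delta_exp`, `mu_delta_ctl`, `var_delta_exp`, `r_true_p1`,
#'   `beta_true_p1` (raw units of gain per raw unit of P-I) and the
#'   generating `spec`.
#' @export
#' @examples
#' eff <- calibrate_true_effects(true_model_spec())
#' eff$var_delta_exp  # 13^2 - 10^2 = 69
calibrate_true_effects <- function(spec) {
  stopifnot(inherits(spec, "true_model_spec"))
  rel <- spec$reference_reliability
  var_delta_exp <- spec$sd_post_exp^2 - spec$sd_pre^2
  e_pre <- error_sd(spec$sd_pre, rel)
  e_post_exp <- error_sd(spec$sd_post_exp, rel)
  e_post_ctl <- error_sd(spec$sd_post_ctl, rel)

  # observed change = true gain + post noise - pre noise
  var_gain_obs_exp <- var_delta_exp + e_pre^2 + e_post_exp^2
  rel_gain_obs <- var_delta_exp / var_gain_obs_exp
  r_true_p1 <- spec$r_p1_gain / sqrt(rel * rel_gain_obs)
  if (!is.finite(r_true_p1) || abs(r_true_p1) >= 1) {
    stop("calibration infeasible: disattenuated P-I/gain correlation ",
         sprintf("(%.3f) falls outside (-1, 1); ", r_true_p1),
         "lower `r_p1_gain` or raise the reliability/gain variance",
         call. = FALSE)
  }
  structure(
    list(
      mu_delta_exp = spec$dz_exp * sqrt(var_gain_obs_exp),
      mu_delta_ctl = spec$dz_ctl * sqrt(e_pre^2 + e_post_ctl^2),
      var_delta_exp = var_delta_exp,
      r_true_p1 = r_true_p1,
      beta_true_p1 = r_true_p1 * sqrt(var_delta_exp) / spec$sd_p,
      spec = spec
    ),
    class = "calibrated_effects"
  )
}

#' @export
print.calibrated_effects <- function(x, ...) {
  cat("Calibrated constant true effects (observed targets at reliability",
      sprintf("%.2f)\n", x$spec$reference_reliability))
  cat(sprintf("  true mean gain:     %.4f (experimental), %.4f (control)\n",
              x$mu_delta_exp, x$mu_delta_ctl))
  cat(sprintf("  true gain variance: %.4f (experimental), 0 (control)\n",
              x$var_delta_exp))
  cat(sprintf("  r_true(P-I, gain):  %.4f  ->  slope %.4f per raw unit\n",
              x$r_true_p1, x$beta_true_p1))
  invisible(x)
}

#' Generate a true (noise-free) dataset
#'
#' Draws `n_total` subjects, split equally into control and experimental
#' groups. True pre-test scores and both predictors are independent
#' Gaussians. The control group's true gain is the constant
#' `mu_delta_ctl`; the experimental group's true gain is
#' `mu_delta_exp + beta_true_p1 * (P-I - mean_p) + e`, with `e` Gaussian
#' and scaled so the total true gain variance equals `var_delta_exp`.
#'
#' @param effects A [calibrate_true_effects()] result (carries its spec).
#' @param n_total Total sample size, even, >= 8; split equally across
#'   groups.
#' @param seed Integer seed; identical inputs give identical datasets.
#' @return A tibble of class `true_dataset` with columns `subject_id`,
#'   `group` (factor control/experimental), `t1_true`, `delta_true`,
#'   `t2_true`, `p1_true`, `p2_true`. The generating spec is attached as
#'   attribute `"spec"`.
#' @export
#' @examples
#' eff <- calibrate_true_effects(true_model_spec())
#' truth <- generate_true_dataset(eff, n_total = 200, seed = 1)
generate_true_dataset <- function(effects, n_total, seed) {
  stopifnot(inherits(effects, "calibrated_effects"))
  if (n_total %% 2L != 0L) {
    stop("`n_total` must be even (groups are split equally; no silent ",
         "rounding)", call. = FALSE)
  }
  if (n_total < 8L) stop("`n_total` must be >= 8", call. = FALSE)
  spec <- effects$spec
  n_half <- n_total %/% 2L

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  group <- factor(rep(c("control", "experimental"), each = n_half),
                  levels = c("control", "experimental"))
  t1 <- stats::rnorm(n_total, spec$mean_pre, spec$sd_pre)
  p1 <- stats::rnorm(n_total, spec$mean_p, spec$sd_p)
  p2 <- stats::rnorm(n_total, spec$mean_p, spec$sd_p)

  exp_idx <- (n_half + 1L):n_total
  resid_sd <- sqrt(effects$var_delta_exp * (1 - effects$r_true_p1^2))
  delta <- rep(effects$mu_delta_ctl, n_total)
  delta[exp_idx] <- effects$mu_delta_exp +
    effects$beta_true_p1 * (p1[exp_idx] - spec$mean_p) +
    stats::rnorm(n_half, 0, resid_sd)

  out <- tibble::tibble(
    subject_id = seq_len(n_total),
    group = group,
    t1_true = t1,
    delta_true = delta,
    t2_true = t1 + delta,
    p1_true = p1,
    p2_true = p2
  )
  attr(out, "spec") <- spec
  class(out) <- c("true_dataset", class(out))
  out
}

# Save/restore .Random.seed so generation functions are pure under `seed`
# without clobbering the caller's RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
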