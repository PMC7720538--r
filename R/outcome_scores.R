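#' Criterion variables for treatment-success regressions
#'
#' Four ways of scoring the outcome of a pre-post design, used as the
#' dependent variable in the regression models: the raw post-test score,
#' the absolute change (post minus pre), the relative change (percent of
#' the pre score), and the residualized change (post-test residual after a
#' pooled least-squares adjustment for the pre-test).
#'
#' @format `criterion_kinds` is the character vector of the four
#'   recognized criterion names: `"post_test"`, `"absolute_change"`,
#'   `"relative_change"`, `"residual_score"`.
#' @name outcome_scores
NULL

#' @rdname outcome_scores
#' @export
criterion_kinds <- c("post_test", "absolute_change", "relative_change",
                     "residual_score")

#' @describeIn outcome_scores Elementwise `post - pre` in raw units.
#' @param pre,post Equal-length numeric vectors of pre- and post-test
#'   scores (uncentered raw scores).
#' @export
absolute_change <- function(pre, post) {
  if (length(pre) != length(post)) {
    stop("`pre` and `post` must have equal length", call. = FALSE)
  }
  post - pre
}

#' @describeIn outcome_scores Percent change, `100 * (post - pre) / pre`.
#'   Errors if any pre score is zero (the ratio is undefined there).
#' @export
relative_change <- function(pre, post) {
  if (length(pre) != length(post)) {
    stop("`pre` and `post` must have equal length", call. = FALSE)
  }
  zero <- which(pre == 0)
  if (length(zero)) {
    stop("relative change undefined: pre-test score is zero for subject(s) ",
         paste(utils::head(zero, 5L), collapse = ", "), call. = FALSE)
  }
  100 * (post - pre) / pre
}

#' @describeIn outcome_scores Residuals of one simple regression of post
#'   on pre fitted to the pooled sample (both groups together, within this
#'   dataset). The residuals have mean exactly zero and zero sample
#'   correlation with `pre`.
#' @export
residual_score <- function(pre, post) {
  if (length(pre) != length(post)) {
    stop("`pre` and `post` must have equal length", call. = FALSE)
  }
  if (length(pre) < 3L) stop("need at least 3 subjects", call. = FALSE)
  pre_c <- pre - mean(pre)
  ss_pre <- sum(pre_c^2)
  if (ss_pre == 0) {
    stop("pre-test scores have zero variance; residualization undefined",
         call. = FALSE)
  }
  slope <- sum(pre_c * post) / ss_pre
  post - mean(post) - slope * pre_c
}

# Criterion response for a dataset, on UNcentered scores. `source` picks
# the observed or the noise-free columns.
criterion_response <- function(data, criterion, source = c("observed", "true")) {
  source <- match.arg(source)
  criterion <- match.arg(criterion, criterion_kinds)
  if (source == "observed") {
    if (!inherits(data, "observed_dataset")) {
      stop("observed-source criteria need an `observed_dataset`", call. = FALSE)
    }
    pre <- data$pre_obs
    post <- data$post_obs
  } else {
    truth <- if (inherits(data, "true_dataset")) data else attr(data, "truth")
    if (is.null(truth)) {
      stop("no true dataset available for a true-source fit", call. = FALSE)
    }
    pre <- truth$t1_true
    post <- truth$t2_true
  }
  switch(criterion,
    post_test = post,
    absolute_change = absolute_change(pre, post),
    relative_change = relative_change(pre, post),
    residual_score = residual_score(pre, post)
  )
}
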