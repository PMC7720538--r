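#' Predictor sets of the five canonical regression models
#'
#' The five models differ only in which predictors enter:
#' Model 1 the external predictors P-I and P-II only; Model 2 adds the
#' pre-test score; Model 3 adds the group dummy; Model 4 adds the
#' predictor-by-group interactions; Model 5 is Model 4 without the
#' pre-test score.
#'
#' @param model_id Integer 1 to 5.
#' @return Character vector of term names in design-matrix order
#'   (`"(Intercept)"`, `"p1"`, `"p2"`, `"pre"`, `"group"`, `"p1:group"`,
#'   `"p2:group"` as applicable).
#' @export
#' @examples
#' model_terms(3)
model_terms <- function(model_id) {
  if (!model_id %in% 1:5) stop("`model_id` must be 1..5", call. = FALSE)
  switch(model_id,
    c("(Intercept)", "p1", "p2"),
    c("(Intercept)", "p1", "p2", "pre"),
    c("(Intercept)", "p1", "p2", "pre", "group"),
    c("(Intercept)", "p1", "p2", "pre", "group", "p1:group", "p2:group"),
    c("(Intercept)", "p1", "p2", "group", "p1:group", "p2:group")
  )
}

# Raw predictor columns for a dataset/source, as plain numeric vectors.
# p2 may be absent (audit data with a single predictor); then it is NULL.
predictor_columns <- function(data, source = c("observed", "true")) {
  source <- match.arg(source)
  if (source == "observed") {
    if (!inherits(data, "observed_dataset")) {
      stop("observed-source fits need an `observed_dataset`", call. = FALSE)
    }
    list(pre = data$pre_obs, p1 = data$p1_obs, p2 = data[["p2_obs"]],
         group = as.integer(data$group == "experimental"))
  } else {
    truth <- if (inherits(data, "true_dataset")) data else attr(data, "truth")
    if (is.null(truth)) {
      stop("no true dataset available for a true-source fit", call. = FALSE)
    }
    list(pre = truth$t1_true, p1 = truth$p1_true, p2 = truth$p2_true,
         group = as.integer(truth$group == "experimental"))
  }
}

# Assemble the design matrix for one model from raw predictor columns.
# Continuous predictors are centered at their full-sample means; the
# group dummy is 0 = control, 1 = experimental; interaction columns are
# (centered predictor) * dummy. Returns list(X, terms, mean_pre_nc).
design_from_columns <- function(cols, model_id) {
  terms <- model_terms(model_id)
  if (is.null(cols$p2)) terms <- setdiff(terms, c("p2", "p2:group"))
  n <- length(cols$p1)
  blocks <- list("(Intercept)" = rep(1, n))
  center <- function(x) x - mean(x)
  if ("p1" %in% terms) blocks$p1 <- center(cols$p1)
  if ("p2" %in% terms) blocks$p2 <- center(cols$p2)
  if ("pre" %in% terms) blocks$pre <- center(cols$pre)
  if ("group" %in% terms) blocks$group <- cols$group
  if ("p1:group" %in% terms) blocks$`p1:group` <- blocks$p1 * cols$group
  if ("p2:group" %in% terms) blocks$`p2:group` <- blocks$p2 * cols$group
  X <- do.call(cbind, blocks[terms])
  colnames(X) <- terms
  zero_var <- terms != "(Intercept)" &
    apply(X, 2, function(col) all(col == col[1]))
  if (any(zero_var)) {
    stop("degenerate (zero-variance) predictor column(s): ",
         paste(terms[zero_var], collapse = ", "), call. = FALSE)
  }
  list(X = X, terms = terms, mean_pre_nc = mean(cols$pre))
}

#' Build the design matrix and response for one model and criterion
#'
#' Continuous predictors (P-I, P-II, pre-test) are centered at their
#' full-sample means within the dataset; the group dummy is coded
#' 0 = control, 1 = experimental; interaction columns are the centered
#' predictor times the dummy. The response is computed by the criterion
#' functions on *uncentered* scores. The first column is an all-ones
#' intercept.
#'
#' @param data An `observed_dataset` (or, for `source = "true"`, either a
#'   `true_dataset` or an observed one carrying its truth).
#' @param criterion One of [criterion_kinds].
#' @param model_id Integer 1 to 5 (see [model_terms()]).
#' @param source Fit the observed scores (default) or the noise-free true
#'   scores.
#' @return A list with the design matrix `X` (named columns), response
#'   `y`, `terms`, and `mean_pre_nc` (mean of the uncentered pre score,
#'   needed by the post-test/change intercept identity).
#' @export
build_design <- function(data, criterion, model_id,
                         source = c("observed", "true")) {
  source <- match.arg(source)
  cols <- predictor_columns(data, source)
  d <- design_from_columns(cols, model_id)
  y <- criterion_response(data, criterion, source)
  if (nrow(d$X) < length(d$terms) + 2L) {
    stop("too few subjects for ", length(d$terms), " terms", call. = FALSE)
  }
  c(d, list(y = y))
}

# QR-based OLS engine. qr once per design; solve cheaply per response.
ols_engine <- function(X) {
  qx <- qr(X)
  p <- ncol(X)
  if (qx$rank < p) {
    stop("singular design matrix (rank ", qx$rank, " < ", p, " columns)",
         call. = FALSE)
  }
  Rinv <- backsolve(qr.R(qx), diag(p))
  xtx_inv_diag <- rowSums(Rinv^2)[order(qx$pivot)]
  list(qx = qx, xtx_inv_diag = xtx_inv_diag, n = nrow(X), p = p,
       terms = colnames(X))
}

# One response through a prepared engine; returns plain numeric vectors.
ols_solve <- function(engine, y) {
  df <- engine$n - engine$p
  if (df <= 0) stop("non-positive residual degrees of freedom", call. = FALSE)
  coef <- qr.coef(engine$qx, y)[engine$terms]
  rss <- sum(qr.resid(engine$qx, y)^2)
  sigma2 <- rss / df
  se <- sqrt(sigma2 * engine$xtx_inv_diag)
  tval <- coef / se
  list(estimate = coef, std_error = se, statistic = tval,
       p_value = 2 * stats::pt(-abs(tval), df), df_residual = df,
       sigma = sqrt(sigma2))
}

#' Ordinary least squares with classical inference
#'
#' Fits `y = X b + e` by least squares and reports coefficient estimates,
#' classical homoskedastic standard errors (residual variance RSS/df), and
#' two-sided t-test p-values with `df = n - ncol(X)`.
#'
#' @param X Design matrix with named columns (including the intercept).
#' @param y Response vector.
#' @param terms Optional term names; defaults to `colnames(X)`.
#' @return An object of class `ols_fit`: a list with a `coef` tibble
#'   (term, estimate, std_error, statistic, p_value), `df_residual`,
#'   `sigma`, and `n`.
#' @export
#' @examples
#' X <- cbind("(Intercept)" = 1, x = 0:3)
#' ols_fit(X, c(1, 2, 3, 4))
ols_fit <- function(X, y, terms = colnames(X)) {
  X <- as.matrix(X)
  if (is.null(terms)) terms <- paste0("x", seq_len(ncol(X)))
  colnames(X) <- terms
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)", call. = FALSE)
  engine <- ols_engine(X)
  sol <- ols_solve(engine, y)
  structure(
    list(
      coef = tibble::tibble(
        term = terms,
        estimate = unname(sol$estimate),
        std_error = unname(sol$std_error),
        statistic = unname(sol$statistic),
        p_value = unname(sol$p_value)
      ),
      df_residual = sol$df_residual,
      sigma = sol$sigma,
      n = nrow(X)
    ),
    class = "ols_fit"
  )
}

#' @export
print.ols_fit <- function(x, ...) {
  hdr <- c()
  if (!is.null(x$model_id)) hdr <- c(hdr, paste0("Model ", x$model_id))
  if (!is.null(x$criterion)) hdr <- c(hdr, x$criterion)
  if (!is.null(x$data_source)) hdr <- c(hdr, paste0(x$data_source, " scores"))
  if (length(hdr)) cat(paste(hdr, collapse = ", "), "\n")
  cat(sprintf("OLS fit: n = %d, residual df = %d, sigma = %.4g\n",
              x$n, x$df_residual, x$sigma))
  print(as.data.frame(x$coef), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Fit one model/criterion cell on a dataset
#'
#' Composes [build_design()] and [ols_fit()]: computes the criterion
#' response, builds the centered design for the requested model, and fits
#' OLS, on either the observed or the noise-free true scores.
#'
#' @inheritParams build_design
#' @return An `ols_fit` with metadata fields `model_id`, `criterion`,
#'   `data_source`, and `mean_pre_nc` (mean uncentered pre score).
#' @export
#' @examples
#' eff <- calibrate_true_effects(true_model_spec())
#' obs <- apply_noise(generate_true_dataset(eff, 200, 1), 0.8, 2)
#' fit_cell(obs, "absolute_change", model_id = 4)
fit_cell <- function(data, criterion, model_id,
                     source = c("observed", "true")) {
  source <- match.arg(source)
  criterion <- match.arg(criterion, criterion_kinds)
  d <- build_design(data, criterion, model_id, source)
  fit <- ols_fit(d$X, d$y, d$terms)
  fit$model_id <- model_id
  fit$criterion <- criterion
  fit$data_source <- source
  fit$mean_pre_nc <- d$mean_pre_nc
  fit
}
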