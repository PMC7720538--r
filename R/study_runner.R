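#' Configure a simulation study
#'
#' Defines the factorial grid of a Monte-Carlo study: total sample sizes,
#' reliabilities, replications per cell, the significance level, and the
#' master seed from which every replicate's seed is derived. Defaults are
#' the canonical grid: eight sample sizes from 50 to 500, four
#' reliabilities from .60 to .90, 1000 replications, alpha = .05.
#'
#' @param n_grid Even total sample sizes (split equally across groups).
#' @param reliability_grid Reliabilities in (0, 1].
#' @param replications Independent datasets per cell (>= 1).
#' @param alpha Two-sided significance level in (0, 1).
#' @param master_seed Integer master seed.
#' @param model_ids Subset of 1:5 (see [model_terms()]).
#' @param criteria Subset of [criterion_kinds].
#' @return An object of class `study_config`.
#' @export
#' @examples
#' study_config(n_grid = 200, reliability_grid = 0.8, replications = 100)
study_config <- function(n_grid = c(50, 100, 150, 200, 250, 300, 400, 500),
                         reliability_grid = c(0.60, 0.70, 0.80, 0.90),
                         replications = 1000,
                         alpha = 0.05,
                         master_seed = 1,
                         model_ids = 1:5,
                         criteria = criterion_kinds) {
  if (length(n_grid) == 0 || length(reliability_grid) == 0) {
    stop("`n_grid` and `reliability_grid` must be non-empty", call. = FALSE)
  }
  if (any(n_grid %% 2 != 0) || any(n_grid < 8)) {
    stop("every `n_grid` entry must be an even total sample size >= 8",
         call. = FALSE)
  }
  if (any(reliability_grid <= 0 | reliability_grid > 1)) {
    stop("reliabilities must lie in (0, 1]", call. = FALSE)
  }
  if (replications < 1) stop("`replications` must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)", call. = FALSE)
  if (!all(model_ids %in% 1:5) || length(model_ids) == 0) {
    stop("`model_ids` must be a non-empty subset of 1:5", call. = FALSE)
  }
  criteria <- match.arg(criteria, criterion_kinds, several.ok = TRUE)
  structure(
    list(
      n_grid = as.integer(sort(unique(n_grid))),
      reliability_grid = sort(unique(reliability_grid)),
      replications = as.integer(replications),
      alpha = alpha,
      master_seed = as.integer(master_seed),
      model_ids = as.integer(sort(unique(model_ids))),
      criteria = criteria
    ),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("Simulation study configuration\n")
  cat("  n grid:        ", paste(x$n_grid, collapse = ", "), "\n")
  cat("  reliabilities: ", paste(format(x$reliability_grid), collapse = ", "), "\n")
  cat(sprintf("  replications:  %d per cell, alpha = %.3g, master seed = %d\n",
              x$replications, x$alpha, x$master_seed))
  cat("  models:        ", paste(x$model_ids, collapse = ", "),
      "; criteria: ", paste(x$criteria, collapse = ", "), "\n", sep = "")
  cat("  planned fits:  ", format(count_planned_fits(x), big.mark = ","), "\n")
  invisible(x)
}

#' Total regression fits a configuration plans
#'
#' `models x criteria x sample sizes x reliabilities x replications x 2`
#' (each replicate is fitted on both the observed and the true scores).
#'
#' @param config A [study_config()].
#' @return Integer count.
#' @export
#' @examples
#' count_planned_fits(study_config())  # 1,280,000
count_planned_fits <- function(config) {
  stopifnot(inherits(config, "study_config"))
  length(config$model_ids) * length(config$criteria) *
    length(config$n_grid) * length(config$reliability_grid) *
    config$replications * 2
}

# Deterministic 32-bit seed stream: Lehmer-style mixing of the cell key.
# All arithmetic stays below 2^53 so double precision is exact.
MOD31 <- 2147483629  # prime < 2^31
cell_seed <- function(master_seed, n, reliability, replicate, stream) {
  h <- as.numeric(master_seed) %% MOD31
  for (k in c(n, round(reliability * 1000), replicate, stream)) {
    h <- (h * 48271 + as.numeric(k) + 1) %% MOD31
  }
  as.integer(h)
}

#' Proportion of significant p-values
#'
#' Strict inequality `p < alpha`, the count divided by the total. When a
#' true effect exists this estimates power; under the null it estimates
#' the type-I error rate.
#'
#' @param p_values Non-empty vector of p-values in \[0, 1\].
#' @param alpha Significance level.
#' @return Proportion in \[0, 1\].
#' @export
significance_rate <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) stop("empty p-value vector", call. = FALSE)
  if (any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  mean(p_values < alpha)
}

#' Studentized bias of coefficient estimates
#'
#' Mean paired difference between observed-score and true-score
#' coefficient estimates, divided by the SD of the observed estimates
#' times `sqrt(n_sample)`. The scaling makes biases comparable across
#' criteria measured in different units and across sample sizes; the
#' result is in standard-deviation units.
#'
#' @param observed_estimates,true_estimates Equal-length vectors of
#'   estimates, paired by replicate dataset.
#' @param n_sample Total sample size of each replicate.
#' @return A single studentized bias.
#' @export
studentized_bias <- function(observed_estimates, true_estimates, n_sample) {
  if (length(observed_estimates) != length(true_estimates)) {
    stop("estimate vectors must have equal length", call. = FALSE)
  }
  if (length(observed_estimates) < 2) {
    stop("need at least 2 replicates", call. = FALSE)
  }
  s <- stats::sd(observed_estimates)
  if (s == 0) stop("SD of observed estimates is zero; studentized bias ",
                   "undefined", call. = FALSE)
  mean(observed_estimates - true_estimates) / (s * sqrt(n_sample))
}

#' Run one (n, reliability) cell of the study
#'
#' Generates `replications` independent true datasets (each replicate's
#' seed derived deterministically from the master seed and cell key),
#' imposes measurement noise, fits every requested model x criterion
#' combination on both the observed and the true scores, and aggregates:
#' per term, the mean estimate `M`, the SD of estimates across
#' replications `SE` (an estimate of the coefficient's standard error),
#' the proportion significant `P` (strict `p < alpha`), and the
#' studentized bias of observed vs. paired true estimates.
#'
#' Replicates in which any fit fails (singular design; vanishingly rare
#' at these sample sizes) are dropped and counted; more than 1% failures
#' aborts the cell.
#'
#' @param config A [study_config()] (supplies replications, alpha, seeds,
#'   model/criterion subsets).
#' @param effects A [calibrate_true_effects()] result.
#' @param n Total sample size for this cell.
#' @param reliability Reliability for this cell.
#' @return A list with `summary` (tibble: model_id, criterion, source,
#'   term, M, SE, P, n_ok), `bias` (tibble: model_id, criterion, term,
#'   studentized_bias, bias_spread), and `n_failed`.
#' @export
run_cell <- function(config, effects, n, reliability) {
  stopifnot(inherits(config, "study_config"),
            inherits(effects, "calibrated_effects"))
  reps <- config$replications
  sources <- c("observed", "true")
  slots <- vector("list", 0)
  for (m in config$model_ids) {
    terms <- model_terms(m)
    for (cr in config$criteria) {
      for (src in sources) {
        key <- paste(m, cr, src, sep = ".")
        slots[[key]] <- list(
          model_id = m, criterion = cr, source = src, terms = terms,
          est = matrix(NA_real_, reps, length(terms),
                       dimnames = list(NULL, terms)),
          pval = matrix(NA_real_, reps, length(terms),
                        dimnames = list(NULL, terms))
        )
      }
    }
  }

  ok <- rep(TRUE, reps)
  for (r in seq_len(reps)) {
    res <- tryCatch({
      truth <- generate_true_dataset(
        effects, n, cell_seed(config$master_seed, n, reliability, r, 1L))
      obs <- apply_noise(
        truth, reliability, cell_seed(config$master_seed, n, reliability, r, 2L))
      out <- list()
      for (src in sources) {
        data <- if (src == "observed") obs else truth
        cols <- predictor_columns(data, src)
        responses <- lapply(config$criteria, function(cr) {
          criterion_response(data, cr, src)
        })
        names(responses) <- config$criteria
        for (m in config$model_ids) {
          d <- design_from_columns(cols, m)
          engine <- ols_engine(d$X)
          for (cr in config$criteria) {
            sol <- ols_solve(engine, responses[[cr]])
            out[[paste(m, cr, src, sep = ".")]] <-
              list(est = sol$estimate, pval = sol$p_value)
          }
        }
      }
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      ok[r] <- FALSE
    } else {
      for (key in names(res)) {
        slots[[key]]$est[r, ] <- res[[key]]$est
        slots[[key]]$pval[r, ] <- res[[key]]$pval
      }
    }
  }

  n_failed <- sum(!ok)
  if (n_failed > 0.01 * reps) {
    stop(sprintf("cell (n=%d, reliability=%.2f): %d of %d replicates failed",
                 n, reliability, n_failed, reps), call. = FALSE)
  }

  summary_rows <- lapply(slots, function(s) {
    est <- s$est[ok, , drop = FALSE]
    pval <- s$pval[ok, , drop = FALSE]
    tibble::tibble(
      model_id = s$model_id, criterion = s$criterion, source = s$source,
      term = s$terms,
      M = colMeans(est),
      SE = apply(est, 2, stats::sd),
      P = colMeans(pval < config$alpha),
      n_ok = nrow(est)
    )
  })
  summary <- dplyr::bind_rows(summary_rows)

  bias_rows <- lapply(slots[vapply(slots, function(s) s$source == "observed",
                                   logical(1))], function(s) {
    est_obs <- s$est[ok, , drop = FALSE]
    est_true <- slots[[paste(s$model_id, s$criterion, "true",
                             sep = ".")]]$est[ok, , drop = FALSE]
    sb <- vapply(seq_along(s$terms), function(j) {
      studentized_bias(est_obs[, j], est_true[, j], n)
    }, numeric(1))
    spread <- vapply(seq_along(s$terms), function(j) {
      stats::sd((est_obs[, j] - est_true[, j]) /
                  (stats::sd(est_obs[, j]) * sqrt(n)))
    }, numeric(1))
    tibble::tibble(
      model_id = s$model_id, criterion = s$criterion, term = s$terms,
      studentized_bias = sb, bias_spread = spread
    )
  })
  bias <- dplyr::bind_rows(bias_rows)

  list(summary = summary, bias = bias, n_failed = n_failed)
}

#' Run the full factorial study grid
#'
#' Iterates [run_cell()] over every (n, reliability) combination of the
#' configuration and returns one tidy table: one row per (model,
#' criterion, n, reliability, term), with observed-score `M`, `SE`, `P`,
#' the studentized bias against the paired true-score fits, and the
#' replicate count. Deterministic under `master_seed`.
#'
#' @param config A [study_config()].
#' @param effects A [calibrate_true_effects()] result; defaults to the
#'   calibration of the default [true_model_spec()].
#' @param verbose Print per-cell progress (replications and failures).
#' @return A tibble with columns `model_id`, `criterion`, `n`,
#'   `reliability`, `term`, `M`, `SE`, `P`, `studentized_bias`, `n_ok`.
#' @export
run_study <- function(config,
                      effects = calibrate_true_effects(true_model_spec()),
                      verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  out <- list()
  for (rel in config$reliability_grid) {
    for (n in config$n_grid) {
      cell <- run_cell(config, effects, n, rel)
      if (verbose) {
        message(sprintf("cell n=%d reliability=%.2f: %d replicates, %d failed",
                        n, rel, config$replications, cell$n_failed))
      }
      obs <- cell$summary[cell$summary$source == "observed",
                          setdiff(names(cell$summary), "source")]
      merged <- dplyr::left_join(
        obs, cell$bias, by = c("model_id", "criterion", "term"))
      merged$n <- n
      merged$reliability <- rel
      out[[length(out) + 1L]] <- merged
    }
  }
  res <- dplyr::bind_rows(out)
  dplyr::select(res, "model_id", "criterion", "n", "reliability", "term",
                "M", "SE", "P", "studentized_bias", "n_ok")
}
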