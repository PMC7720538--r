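#' Load a study configuration from a YAML file
#'
#' Flat key-value YAML; every key is optional and unspecified keys take
#' the canonical defaults of [study_config()]. Recognized keys:
#' `n_grid`, `reliability_grid`, `replications`, `alpha`, `master_seed`,
#' `model_ids`, `criteria`. Unknown keys are an error.
#'
#' @param path Path to the YAML file.
#' @return A validated [study_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("n_grid", "reliability_grid", "replications", "alpha",
             "master_seed", "model_ids", "criteria")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; recognized keys are: ", paste(known, collapse = ", "),
         call. = FALSE)
  }
  do.call(study_config, raw)
}

#' Write / read study results at full precision
#'
#' Results are stored as one tidy CSV (numbers at full precision;
#' rounding happens only at render time) that round-trips exactly through
#' [read_results()].
#'
#' @param results A [run_study()] results tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly (for `write_results`); the results tibble
#'   (for `read_results`).
#' @export
write_results <- function(results, path) {
  readr::write_csv(results, path)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      model_id = readr::col_integer(),
      criterion = readr::col_character(),
      n = readr::col_integer(),
      reliability = readr::col_double(),
      term = readr::col_character(),
      .default = readr::col_double()
    )
  )
}

#' Run manifest for reproducibility
#'
#' Captures everything needed to reproduce a run bit-identically with the
#' same implementation version: the full configuration, the calibrated
#' effects, the seed-derivation scheme, package version, timestamps, and
#' per-cell failure counts.
#'
#' @param config A [study_config()].
#' @param effects A [calibrate_true_effects()] result.
#' @param started,finished POSIXct timestamps.
#' @param failures Optional named list/vector of per-cell failure counts.
#' @return A list suitable for [write_manifest()].
#' @export
run_manifest <- function(config, effects, started = Sys.time(),
                         finished = Sys.time(), failures = NULL) {
  list(
    config = unclass(config),
    calibrated_effects = unclass(effects)[
      c("mu_delta_exp", "mu_delta_ctl", "var_delta_exp",
        "r_true_p1", "beta_true_p1")],
    true_model_spec = unclass(effects$spec),
    seed_scheme = paste(
      "replicate seed = Lehmer mix (mod 2147483629, multiplier 48271) of",
      "(master_seed, n, round(1000*reliability), replicate, stream);",
      "stream 1 = true scores, stream 2 = measurement noise"),
    package_version = as.character(utils::packageVersion("prepostsim")),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
    cell_failures = failures
  )
}

#' @rdname run_manifest
#' @param manifest A [run_manifest()] list.
#' @param path Output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# half-even rounding to 2 decimals, rendered with a fixed width
fmt2 <- function(x) {
  ifelse(is.na(x), "", sprintf("%.2f", round(x, 2)))
}

#' Render one (reliability, n) slice as a summary table
#'
#' Lays out the cell the way simulation summaries are conventionally
#' tabulated: four criterion blocks as rows, the five models as column
#' groups, each showing M / SE / P rounded (half-even) to two decimals.
#'
#' @param results A [run_study()] tibble.
#' @param reliability,n The cell to render; must exist in `results`.
#' @return A single character string (aligned text, UTF-8); printing it
#'   with `cat()` reproduces the table.
#' @export
render_table <- function(results, reliability, n) {
  slice <- results[results$n == n &
                     abs(results$reliability - reliability) < 1e-9, ]
  if (nrow(slice) == 0) {
    cells <- unique(results[, c("reliability", "n")])
    stop("no results for reliability=", reliability, ", n=", n,
         "; available cells: ",
         paste(sprintf("(%.2f, %d)", cells$reliability, cells$n),
               collapse = " "), call. = FALSE)
  }
  term_order <- c("(Intercept)", "p1", "p2", "pre", "group",
                  "p1:group", "p2:group")
  term_label <- c("(Intercept)" = "Intercept", p1 = "P-I", p2 = "P-II",
                  pre = "Pre-test score", group = "Group",
                  "p1:group" = "P-I x Group", "p2:group" = "P-II x Group")
  crit_label <- c(post_test = "Post-test score",
                  absolute_change = "Absolute change score",
                  relative_change = "Relative change score",
                  residual_score = "Residual score")
  models <- sort(unique(slice$model_id))
  lines <- c(
    sprintf("Simulation results for reliability %.2f, total n = %d",
            reliability, n),
    paste0(formatC("Coefficient", width = -16),
           paste(vapply(models, function(m) {
             formatC(paste0("Model ", m), width = -24)
           }, character(1)), collapse = "")),
    paste0(formatC("", width = 16),
           paste(rep(formatC(paste(formatC(c("M", "SE", "P"), width = -8),
                                   collapse = "")), length(models)),
                 collapse = ""))
  )
  for (cr in intersect(names(crit_label), unique(slice$criterion))) {
    lines <- c(lines, crit_label[[cr]])
    blk <- slice[slice$criterion == cr, ]
    for (tm in intersect(term_order, unique(blk$term))) {
      row <- formatC(paste0("  ", term_label[[tm]]), width = -16)
      for (m in models) {
        hit <- blk[blk$model_id == m & blk$term == tm, ]
        if (nrow(hit) == 1) {
          row <- paste0(row, formatC(fmt2(hit$M), width = -8),
                        formatC(fmt2(hit$SE), width = -8),
                        formatC(fmt2(hit$P), width = -8))
        } else {
          row <- paste0(row, formatC("", width = 24))
        }
      }
      lines <- c(lines, row)
    }
  }
  paste(lines, collapse = "\n")
}

#' Export a dataset as delimited text (audit/debug mode)
#'
#' @param data An `observed_dataset`.
#' @param path Output CSV path; columns `subject_id`, `group`, `pre`,
#'   `post`, `p1`, `p2`.
#' @return `path`, invisibly.
#' @export
export_dataset <- function(data, path) {
  stopifnot(inherits(data, "observed_dataset"))
  out <- tibble::tibble(
    subject_id = data$subject_id,
    group = as.character(data$group),
    pre = data$pre_obs, post = data$post_obs,
    p1 = data$p1_obs, p2 = data$p2_obs
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Fit a model to a user-supplied dataset (audit mode)
#'
#' Reads a comma-separated file with a header row `group, pre, post, p1`
#' and optionally `p2` (group coded 0/1 or control/experimental), runs it
#' through the same centering, coding, criterion and OLS machinery as the
#' simulations, and returns the fit. When `p2` is absent the P-II terms
#' are dropped from the requested model.
#'
#' @param path CSV file path.
#' @param criterion One of [criterion_kinds].
#' @param model_id Integer 1 to 5.
#' @return An [`ols_fit`][fit_cell()].
#' @export
audit_fit <- function(path, criterion, model_id) {
  criterion <- match.arg(criterion, criterion_kinds)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "pre", "post", "p1")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("audit file lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  g <- as.character(df$group)
  valid <- g %in% c("0", "1", "control", "experimental")
  if (!all(valid)) {
    stop("`group` values must be 0/1 or control/experimental; offending ",
         "value(s): ", paste(unique(g[!valid]), collapse = ", "),
         call. = FALSE)
  }
  group <- factor(ifelse(g %in% c("1", "experimental"),
                         "experimental", "control"),
                  levels = c("control", "experimental"))
  data <- tibble::tibble(
    subject_id = seq_len(nrow(df)),
    group = group,
    pre_obs = as.numeric(df$pre),
    post_obs = as.numeric(df$post),
    p1_obs = as.numeric(df$p1),
    p2_obs = if ("p2" %in% names(df)) as.numeric(df$p2) else NULL
  )
  class(data) <- c("observed_dataset", class(data))
  fit <- fit_cell(data, criterion, model_id, source = "observed")
  fit
}
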