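#' Configure a full planning run
#'
#' Bundles the inputs of an end-to-end analysis: where the case-mix comes
#' from (a participant table file or a predictor specification file), how the
#' core model is defined (explicit coefficients, a precomputed
#' linear-predictor column, or relative weights plus prevalence and
#' C-statistic to trigger calibration), which sample sizes, thresholds and
#' precision targets to evaluate, and where to write artifacts. Exactly one
#' core-model source must be given, and at least one of `sample_sizes` or
#' `target_width` must be requested.
#'
#' @param table_path Path to a delimited participant table, or `NULL`.
#' @param spec_path Path to a YAML predictor specification, or `NULL`
#'   (exactly one of the two).
#' @param predictors Character vector of core predictor column names (required
#'   with `table_path`; implied by the spec otherwise).
#' @param model Optional explicit [core_model()].
#' @param lp_column Optional name of a column holding each row's true logit
#'   risk (alternative core-model source).
#' @param relative_betas,prevalence,c_statistic Calibration source: named
#'   relative weights plus targets for [calibrate_core_model()].
#' @param sample_sizes Integer vector of sample sizes for the precision
#'   analysis ([stability_report()]), possibly empty.
#' @param thresholds Clinical risk thresholds for classification instability.
#' @param target_width Optional target interval width triggering the sample
#'   size inversion ([required_sample_size()]).
#' @param risk_bands Optional representative risks for banded targets.
#' @param var_increment Variance grid step, default 0.0005.
#' @param tolerance Calibration tolerance, default 0.001.
#' @param subgroups Subgroup column names for fairness summaries.
#' @param n_synthetic Cohort size when generating from a spec.
#' @param seed Seed recorded in (and used by) every stochastic step.
#' @param out_dir Output directory for artifacts.
#' @param plots Write figure files (default TRUE).
#' @return A `run_config` list, validated.
#' @seealso [run_stability()]
#' @export
run_config <- function(table_path = NULL, spec_path = NULL, predictors = NULL,
                       model = NULL, lp_column = NULL, relative_betas = NULL,
                       prevalence = NULL, c_statistic = NULL,
                       sample_sizes = integer(), thresholds = numeric(),
                       target_width = NULL, risk_bands = NULL,
                       var_increment = 5e-4, tolerance = 1e-3,
                       subgroups = NULL, n_synthetic = 10000, seed = 1,
                       out_dir = tempfile("pmprecision_run_"), plots = TRUE) {
  if (is.null(table_path) == is.null(spec_path)) {
    stop("supply exactly one of `table_path` or `spec_path`", call. = FALSE)
  }
  sources <- c(explicit = !is.null(model), lp = !is.null(lp_column),
               calibrate = !is.null(relative_betas))
  if (sum(sources) != 1) {
    stop("supply exactly one core-model source: explicit `model`, `lp_column`, ",
         "or `relative_betas` (+ prevalence + c_statistic)", call. = FALSE)
  }
  if (sources[["calibrate"]] && (is.null(prevalence) || is.null(c_statistic))) {
    stop("`relative_betas` requires `prevalence` and `c_statistic`", call. = FALSE)
  }
  if (!length(sample_sizes) && is.null(target_width)) {
    stop("request at least one analysis: `sample_sizes` and/or `target_width`",
         call. = FALSE)
  }
  structure(
    list(table_path = table_path, spec_path = spec_path, predictors = predictors,
         model = model, lp_column = lp_column, relative_betas = relative_betas,
         prevalence = prevalence, c_statistic = c_statistic,
         sample_sizes = as.integer(sample_sizes), thresholds = thresholds,
         target_width = target_width, risk_bands = risk_bands,
         var_increment = var_increment, tolerance = tolerance,
         subgroups = subgroups, n_synthetic = n_synthetic,
         seed = as.integer(seed), out_dir = out_dir, plots = isTRUE(plots)),
    class = "run_config"
  )
}

#' Run a full planning analysis and write its artifacts
#'
#' Executes the configured workflow: loads or generates the case-mix, resolves
#' the core model (calibrating it if requested), forms the unit information
#' matrix, runs the precision analysis at each requested sample size and the
#' sample size inversion for any target width, and writes everything to
#' `out_dir` as delimited text: per-individual tables and summary tables (one
#' pair per sample size, suffixed `_n<k>`), a sample-size table, the smoothed
#' plot series, the unit information matrix, figure files (PDF) when
#' requested, and a JSON run manifest recording inputs, seed, case-mix mode
#' and achieved calibration. Every number in a figure is also present in a
#' delimited table. Identical configurations with identical seeds produce
#' byte-identical tables.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the loaded `data`, resolved `model`,
#'   `info`, the list of `stability` reports, any `samplesize` report, and
#'   the `manifest`.
#' @export
run_stability <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # -- case-mix -------------------------------------------------------------
  if (!is.null(config$spec_path)) {
    spec <- read_predictor_spec(config$spec_path)
    data <- sample_cohort(spec, n = config$n_synthetic, seed = config$seed)
    predictors <- spec$predictor_names
    casemix_mode <- "sampled_from_spec"
  } else {
    data <- read_participant_table(config$table_path,
                                   predictors = config$predictors)
    predictors <- config$predictors %||%
      names(data)[vapply(data, is.numeric, logical(1))]
    casemix_mode <- "observed_table"
  }

  # -- core model -----------------------------------------------------------
  calibration <- NULL
  if (!is.null(config$model)) {
    model <- config$model
  } else if (!is.null(config$lp_column)) {
    # recover the implied coefficients by exact least squares of the supplied
    # logit risks on the design columns (they are linear by construction)
    lp <- data[[config$lp_column]]
    if (is.null(lp)) stop("column `", config$lp_column, "` not found", call. = FALSE)
    X <- cbind(1, as.matrix(data[predictors]))
    coef <- stats::lm.fit(X, lp)$coefficients
    if (max(abs(X %*% coef - lp)) > 1e-6) {
      stop("`", config$lp_column, "` is not a linear function of the core predictors",
           call. = FALSE)
    }
    model <- core_model(alpha = coef[1],
                        betas = stats::setNames(coef[-1], predictors))
  } else {
    model <- calibrate_core_model(data, config$relative_betas,
                                  prevalence = config$prevalence,
                                  c_statistic = config$c_statistic,
                                  tolerance = config$tolerance)
    calibration <- attr(model, "calibration")
  }

  info <- unit_information(data[predictors], model)
  write_delim_plain(tidy(info), file.path(config$out_dir, "unit_information.csv"))

  # -- option A: precision at given sample sizes ----------------------------
  stability <- list()
  for (n in config$sample_sizes) {
    rep_n <- stability_report(data, model, n = n, info = info,
                              thresholds = config$thresholds,
                              subgroups = config$subgroups,
                              seed = config$seed)
    tag <- sprintf("n%d", n)
    write_delim_plain(tidy(rep_n),
                      file.path(config$out_dir, sprintf("individuals_%s.csv", tag)))
    write_delim_plain(rep_n$summary,
                      file.path(config$out_dir, sprintf("summary_%s.csv", tag)))
    write_delim_plain(rep_n$curves,
                      file.path(config$out_dir, sprintf("envelopes_%s.csv", tag)))
    if (config$plots) {
      ggplot2::ggsave(file.path(config$out_dir, sprintf("prediction_instability_%s.pdf", tag)),
                      plot_prediction_instability(rep_n), width = 6, height = 5)
      for (t in config$thresholds) {
        ggplot2::ggsave(
          file.path(config$out_dir,
                    sprintf("classification_instability_%s_t%g.pdf", tag, t)),
          plot_classification_instability(rep_n, t), width = 6, height = 5)
      }
    }
    stability[[tag]] <- rep_n
  }

  # -- option B: sample size for a target width -----------------------------
  samplesize <- NULL
  if (!is.null(config$target_width)) {
    samplesize <- required_sample_size(
      data[predictors], model, target_width = config$target_width,
      info = info, risk_bands = config$risk_bands,
      increment = config$var_increment)
    write_delim_plain(tidy(samplesize),
                      file.path(config$out_dir, "required_n_individuals.csv"))
    write_delim_plain(glance(samplesize),
                      file.path(config$out_dir, "required_n.csv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("pmprecision")),
    seed = config$seed,
    casemix_mode = casemix_mode,
    n_rows = nrow(data),
    predictors = predictors,
    model = list(alpha = model$alpha, delta = model$delta,
                 betas = as.list(model$betas)),
    calibration = if (!is.null(calibration)) as.list(calibration),
    sample_sizes = config$sample_sizes,
    thresholds = config$thresholds,
    target_width = config$target_width
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(data = data, model = model, info = info,
                 stability = stability, samplesize = samplesize,
                 manifest = manifest, out_dir = config$out_dir))
}

# CSV writer with stable formatting so identical runs are byte-identical.
write_delim_plain <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
}
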