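#' Wald uncertainty interval for an individual's risk
#'
#' Built on the logit scale and back-transformed: with \eqn{z} the
#' standard-normal quantile for the coverage level (1.96 at 95%),
#' \deqn{\mathrm{invlogit}\left[\mathrm{logit}(p) \pm z\sqrt{\mathrm{var}(\mathrm{logit}\,\hat p)}\right].}
#' The logit construction keeps the bounds inside (0, 1) and makes intervals
#' asymmetric on the risk scale, as risks near 0 or 1 require.
#'
#' @param true_risk Risk(s) strictly inside (0, 1).
#' @param var_logit Variance(s) of the logit risk (>= 0); recycled.
#' @param level Coverage level, default 0.95.
#' @return A tibble with columns `lower`, `upper`, `width`.
#' @examples
#' uncertainty_interval(0.135, 0.103)  # width about 0.15
#' @export
uncertainty_interval <- function(true_risk, var_logit, level = 0.95) {
  stopifnot(level > 0, level < 1)
  if (any(true_risk <= 0 | true_risk >= 1)) {
    stop("`true_risk` of 0 or 1 has an infinite logit; intervals are undefined",
         call. = FALSE)
  }
  if (any(var_logit < 0)) stop("`var_logit` must be non-negative", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  lp <- logit(true_risk)
  half <- z * sqrt(var_logit)
  tibble::tibble(
    lower = invlogit(lp - half),
    upper = invlogit(lp + half),
    width = invlogit(lp + half) - invlogit(lp - half)
  )
}

#' Probability of misclassification at a risk threshold
#'
#' The mass of an individual's uncertainty distribution lying on the opposite
#' side of a clinical risk threshold from their true risk. The uncertainty
#' distribution is Normal(logit(p), var) on the logit scale, consistent with
#' the Wald interval construction, so the closed form is a single normal tail
#' probability; it is capped at 0.5 by construction (exactly 0.5 when the true
#' risk sits on the threshold).
#'
#' @param true_risk Risk(s) in (0, 1).
#' @param var_logit Logit-scale variance(s); recycled.
#' @param threshold Clinical risk threshold in (0, 1).
#' @return Probabilities in \[0, 0.5\]. With `var_logit = 0` and
#'   `true_risk != threshold` the value is 0 (a point mass on the correct
#'   side).
#' @examples
#' misclassification_probability(0.13, 0.02, threshold = 0.06)
#' @export
misclassification_probability <- function(true_risk, var_logit, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  if (any(true_risk <= 0 | true_risk >= 1)) {
    stop("`true_risk` must be strictly inside (0, 1)", call. = FALSE)
  }
  if (any(var_logit < 0)) stop("`var_logit` must be non-negative", call. = FALSE)
  k <- max(length(true_risk), length(var_logit))
  p <- rep_len(true_risk, k)
  v <- rep_len(var_logit, k)
  d <- logit(threshold) - logit(p)
  out <- ifelse(
    p == threshold, 0.5,
    ifelse(v == 0, 0,
           ifelse(p > threshold,
                  stats::pnorm(d / sqrt(pmax(v, .Machine$double.xmin))),
                  stats::pnorm(d / sqrt(pmax(v, .Machine$double.xmin)),
                               lower.tail = FALSE)))
  )
  unname(out)
}

#' Mean absolute prediction error from the uncertainty distribution
#'
#' For each individual, draws from Normal(logit(p), var) on the logit scale,
#' maps through the inverse logit, and averages the absolute deviation from
#' the true risk. Each row uses a seed derived from (`seed`, row index), so a
#' row's value does not depend on how many or which other rows are present.
#'
#' @inheritParams misclassification_probability
#' @param n_samples Draws per individual (default 1000).
#' @param seed Global seed from which per-row seeds are derived.
#' @return Numeric vector of per-individual MAPE values (>= 0; exactly 0 when
#'   `var_logit` is 0).
#' @export
mape <- function(true_risk, var_logit, n_samples = 1000, seed = 1) {
  stopifnot(n_samples >= 1)
  k <- max(length(true_risk), length(var_logit))
  p <- rep_len(true_risk, k)
  v <- rep_len(var_logit, k)
  if (any(p <= 0 | p >= 1)) stop("`true_risk` must be strictly inside (0, 1)", call. = FALSE)
  if (any(v < 0)) stop("`var_logit` must be non-negative", call. = FALSE)
  lp <- logit(p)
  purrr::map_dbl(seq_len(k), function(i) {
    if (v[i] == 0) return(0)
    with_seed(row_seed(seed, i), {
      mean(abs(invlogit(lp[i] + stats::rnorm(n_samples) * sqrt(v[i])) - p[i]))
    })
  })
}

#' Anticipated precision of individual predictions at a given sample size
#'
#' The "given n" analysis: for every individual in the case-mix table,
#' computes the true risk under the core model, the variance of the logit
#' risk at development sample size `n`, the 95% (or `level`) uncertainty
#' interval, the misclassification probability at each clinical risk
#' threshold, and the Monte-Carlo mean absolute prediction error. Summaries
#' (mean, min, median, max of each metric) are produced overall and within
#' each requested subgroup, along with smoothed envelope curves through the
#' interval bounds for the prediction instability plot.
#'
#' @param data Participant table; rows are individuals (or distinct predictor
#'   combinations when `weights` gives their probabilities).
#' @param model A [core_model()].
#' @param n Development sample size under evaluation.
#' @param info Optional precomputed [unit_information()]; derived from
#'   (`data`, `model`, `weights`) when omitted.
#' @param thresholds Numeric vector of clinical risk thresholds (possibly
#'   empty) at which classification instability is evaluated.
#' @param subgroups Character vector of column names in `data` defining
#'   subgroup summaries (e.g. one predictor, sex, ethnicity).
#' @param level Interval coverage, default 0.95.
#' @param seed Seed for the MAPE draws.
#' @param n_samples MAPE draws per individual, default 1000.
#' @param weights Optional row weights (cell probabilities); used in the
#'   information matrix and in all weighted summaries.
#' @return A `stability_report`: list with `individuals` (a tibble with
#'   `true_risk`, `var_logit`, `lower`, `upper`, `width`, `mape`, one
#'   `misclass_<t>` column per threshold, and the subgroup columns),
#'   `summary` (overall and per-subgroup mean/min/median/max of every
#'   metric), `curves` (smoothed lower/upper envelopes), plus `n`,
#'   `thresholds` and `level`. `tidy()` returns the per-individual table,
#'   `glance()` the overall summary row.
#' @seealso [plot_prediction_instability()], [plot_classification_instability()],
#'   [required_sample_size()] for the inverse problem.
#' @examples
#' m <- core_model(alpha = -2, betas = c(x = 1))
#' d <- data.frame(x = rep(0:1, c(70, 30)))
#' rep <- stability_report(d, m, n = 500, thresholds = 0.1)
#' glance(rep)
#' @export
stability_report <- function(data, model, n, info = NULL, thresholds = numeric(),
                             subgroups = NULL, level = 0.95, seed = 1,
                             n_samples = 1000, weights = NULL) {
  stopifnot(inherits(model, "core_model"), n >= 1)
  if (is.null(info)) info <- unit_information(data, model, weights = weights)
  p <- predict_risk(model, data)
  v <- variance_logit(tibble::as_tibble(data), info, n)
  ui <- uncertainty_interval(p, v, level = level)

  ind <- tibble::tibble(true_risk = p, var_logit = v) |>
    dplyr::bind_cols(ui)
  for (t in thresholds) {
    ind[[sprintf("misclass_%g", t)]] <- misclassification_probability(p, v, t)
  }
  ind$mape <- mape(p, v, n_samples = n_samples, seed = seed)
  ind$.weight <- weights %||% rep(1, nrow(ind))
  for (sg in subgroups %||% character()) {
    if (!sg %in% names(data)) stop("subgroup column `", sg, "` not in table", call. = FALSE)
    ind[[sg]] <- data[[sg]]
  }

  metrics <- c("width", grep("^misclass_", names(ind), value = TRUE), "mape")
  summarize_block <- function(d, label) {
    purrr::map_dfr(metrics, function(m) {
      tibble::tibble(
        subgroup = label,
        metric = m,
        mean = stats::weighted.mean(d[[m]], d$.weight),
        min = min(d[[m]]),
        median = weighted_median(d[[m]], d$.weight),
        max = max(d[[m]]),
        n_individuals = nrow(d),
        weight_share = sum(d$.weight) / sum(ind$.weight)
      )
    })
  }
  summary <- summarize_block(ind, "overall")
  for (sg in subgroups %||% character()) {
    for (val in sort(unique(ind[[sg]]))) {
      summary <- dplyr::bind_rows(
        summary,
        summarize_block(ind[ind[[sg]] == val, ], sprintf("%s=%s", sg, val)))
    }
  }

  structure(
    list(individuals = ind, summary = summary,
         curves = envelope_curves(ind), n = as.integer(n),
         thresholds = thresholds, level = level, info = info, model = model),
    class = "stability_report"
  )
}

# Weighted median via the weighted empirical CDF.
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

# Smoothed envelopes through (true_risk, bound) pairs -- the "typical"
# interval at each risk. Local linear smoother, bandwidth fraction 0.3;
# presentational only, never feeds any reported number.
envelope_curves <- function(ind) {
  if (nrow(ind) < 3 || length(unique(ind$true_risk)) < 3) {
    return(tibble::tibble(true_risk = ind$true_risk,
                          lower_smooth = ind$lower, upper_smooth = ind$upper))
  }
  lo <- stats::lowess(ind$true_risk, ind$lower, f = 0.3)
  hi <- stats::lowess(ind$true_risk, ind$upper, f = 0.3)
  tibble::tibble(true_risk = lo$x,
                 lower_smooth = pmin(pmax(lo$y, 0), 1),
                 upper_smooth = pmin(pmax(hi$y, 0), 1))
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report> n =", x$n, "over", nrow(x$individuals), "individuals\n")
  ov <- x$summary[x$summary$subgroup == "overall", ]
  print(as.data.frame(ov[, c("metric", "mean", "min", "median", "max")]),
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
tidy.stability_report <- function(x, ...) {
  dplyr::select(x$individuals, -".weight")
}

#' @export
glance.stability_report <- function(x, ...) {
  ov <- x$summary[x$summary$subgroup == "overall", ]
  wide <- stats::setNames(ov$mean, paste0("mean_", ov$metric))
  dplyr::bind_cols(
    tibble::tibble(n = x$n, n_individuals = nrow(x$individuals),
                   level = x$level),
    tibble::as_tibble(as.list(wide)),
    tibble::tibble(min_width = ov$min[ov$metric == "width"],
                   max_width = ov$max[ov$metric == "width"])
  )
}

#' Prediction instability plot
#'
#' Each individual's true risk against their uncertainty interval, with
#' smoothed curves through the lower and upper bounds depicting the "typical"
#' interval at each risk.
#'
#' @param report A [stability_report()].
#' @return A ggplot object.
#' @export
plot_prediction_instability <- function(report) {
  stopifnot(inherits(report, "stability_report"))
  ind <- report$individuals
  ggplot2::ggplot(ind, ggplot2::aes(x = .data$true_risk)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                           width = 0, alpha = 0.4, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$true_risk), size = 0.8) +
    ggplot2::geom_line(data = report$curves,
                       ggplot2::aes(y = .data$lower_smooth), linetype = 2) +
    ggplot2::geom_line(data = report$curves,
                       ggplot2::aes(y = .data$upper_smooth), linetype = 2) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "True risk (core model)",
                  y = sprintf("%d%% uncertainty interval", round(report$level * 100)),
                  title = sprintf("Prediction instability at n = %d", report$n)) +
    ggplot2::theme_minimal()
}

#' Classification instability plot
#'
#' Each individual's true risk against the probability that their uncertainty
#' distribution falls on the opposite side of the clinical risk threshold.
#'
#' @param report A [stability_report()] computed with at least one threshold.
#' @param threshold Which threshold to plot; defaults to the first.
#' @return A ggplot object.
#' @export
plot_classification_instability <- function(report, threshold = NULL) {
  stopifnot(inherits(report, "stability_report"))
  if (!length(report$thresholds)) {
    stop("report was computed without thresholds", call. = FALSE)
  }
  threshold <- threshold %||% report$thresholds[1]
  col <- sprintf("misclass_%g", threshold)
  if (!col %in% names(report$individuals)) {
    stop("threshold ", threshold, " not present in this report", call. = FALSE)
  }
  ggplot2::ggplot(report$individuals,
                  ggplot2::aes(x = .data$true_risk, y = .data[[col]])) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2, colour = "grey50") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 0.5)) +
    ggplot2::labs(x = "True risk (core model)",
                  y = "Probability of misclassification",
                  title = sprintf("Classification instability at n = %d (threshold %g)",
                                  report$n, threshold)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.stability_report <- function(object, type = c("prediction", "classification"),
                                      ...) {
  type <- match.arg(type)
  if (type == "prediction") plot_prediction_instability(object)
  else plot_classification_instability(object, ...)
}
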