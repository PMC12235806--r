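#' Maximum logit-variance compatible with a target interval width
#'
#' Inverts the Wald interval: finds the largest variance of the logit risk
#' such that the uncertainty interval at a given true risk is no wider than
#' the target width on the risk scale. Interval width is strictly increasing
#' in the variance for a fixed risk, so the solution is well defined. The
#' default search walks a variance grid (step `increment`) and returns the
#' largest grid point whose width does not exceed the target, mirroring how
#' practitioners tabulate variance targets per risk band; `method =
#' "bisection"` refines to a continuous solution. If even the first grid
#' point is too wide, a sub-increment bisection is used and a message is
#' emitted.
#'
#' @param true_risk Risk in (0, 1) at which the target applies.
#' @param target_width Desired maximum interval width on the risk scale, in
#'   (0, 1).
#' @param level Interval coverage, default 0.95.
#' @param increment Variance grid step, default 0.0005.
#' @param method `"grid"` (default) or `"bisection"`.
#' @return The target variance (a positive scalar).
#' @examples
#' width_to_variance(0.135, 0.15)  # about 0.103
#' @export
width_to_variance <- function(true_risk, target_width, level = 0.95,
                              increment = 5e-4, method = c("grid", "bisection")) {
  method <- match.arg(method)
  stopifnot(true_risk > 0, true_risk < 1,
            target_width > 0, target_width < 1, increment > 0)
  z <- stats::qnorm(1 - (1 - level) / 2)
  lp <- logit(true_risk)
  width_at <- function(v) invlogit(lp + z * sqrt(v)) - invlogit(lp - z * sqrt(v))

  bisect <- function(lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (width_at(mid) <= target_width) lo <- mid else hi <- mid
      if (hi - lo < 1e-12 * max(1, hi)) break
    }
    lo
  }

  if (width_at(increment) > target_width) {
    message("target width narrower than the first grid point; refining below one increment")
    return(bisect(0, increment))
  }
  # grow the grid geometrically to bracket, then scan the last block linearly
  k <- 1
  while (width_at(increment * 2^k) <= target_width) {
    k <- k + 1
    if (increment * 2^k > 1e6) break
  }
  grid <- seq(increment, increment * 2^k, by = increment)
  v_grid <- grid[findInterval(target_width, width_at(grid))]
  if (method == "grid") v_grid else bisect(v_grid, v_grid + increment)
}

#' Required sample size for a target logit-variance
#'
#' Rearranges the variance decomposition: to attain
#' \eqn{\mathrm{var}(\mathrm{logit}(\hat p_{new}))} no larger than a target
#' value for an individual with design row \eqn{x_{new}},
#' \deqn{n = \mathrm{var}(\mathrm{logit}(p_{new}))^{-1}\, x_{new} \mathbf{I}^{-1} x_{new}',}
#' rounded up to an integer.
#'
#' @param x_new Design row(s) or a data frame of predictor values (see
#'   [variance_logit()]).
#' @param info A [unit_information()].
#' @param target_variance Target variance(s) of the logit risk, recycled
#'   across rows.
#' @return Integer vector of required sample sizes (>= 1).
#' @export
required_n <- function(x_new, info, target_variance) {
  if (any(target_variance <= 0)) stop("`target_variance` must be positive", call. = FALSE)
  q <- quad_form_inv(info, as_design_rows(x_new, info))
  pmax(1L, as.integer(ceiling(q / target_variance)))
}

#' Sample size achieving target interval widths across a case-mix
#'
#' The "target precision" analysis: assigns every individual a target
#' interval width -- either one common width, or per-risk-band widths with
#' each individual mapped to the band whose representative risk is closest to
#' their own (ties broken toward the lower band) -- converts widths to
#' logit-variance targets at the band's representative risk (or, for a single
#' common width, at each individual's own risk), applies the sample size
#' inversion to every individual, and reports the maximum: the sample size at
#' which *every* combination of predictor values attains its target.
#'
#' @param data Participant table (case-mix).
#' @param model A [core_model()].
#' @param target_width A single width, or a vector with one width per row of
#'   `risk_bands`.
#' @param info Optional precomputed [unit_information()].
#' @param risk_bands Optional numeric vector of representative risks. Use
#'   [default_risk_bands()] for the conventional ladder; `NULL` (default)
#'   applies `target_width` at each individual's own true risk.
#' @param level Interval coverage, default 0.95.
#' @param increment Variance grid step for [width_to_variance()].
#' @param scope Optional logical vector selecting the individuals over which
#'   the maximum is taken (e.g. a subgroup); defaults to all.
#' @param weights Optional row weights for the information matrix.
#' @return A `samplesize_report`: list with `n_required` (the overall
#'   maximum), `individuals` (per-row tibble of true risk, band, target
#'   variance and required n), and `driver` (the row(s) attaining the
#'   maximum). `tidy()` returns the per-individual table; `glance()` a
#'   one-row summary.
#' @examples
#' m <- core_model(alpha = -2, betas = c(x = 1))
#' d <- data.frame(x = rep(0:1, c(70, 30)))
#' required_sample_size(d, m, target_width = 0.1)
#' @export
required_sample_size <- function(data, model, target_width, info = NULL,
                                 risk_bands = NULL, level = 0.95,
                                 increment = 5e-4, scope = NULL,
                                 weights = NULL) {
  stopifnot(inherits(model, "core_model"))
  if (is.null(info)) info <- unit_information(data, model, weights = weights)
  p <- predict_risk(model, data)
  scope <- scope %||% rep(TRUE, length(p))
  if (!any(scope)) stop("`scope` selects no individuals", call. = FALSE)

  if (is.null(risk_bands)) {
    if (length(target_width) != 1) {
      stop("without `risk_bands`, `target_width` must be a single width", call. = FALSE)
    }
    band <- p
    p_unique <- unique(p)
    v_unique <- vapply(p_unique, width_to_variance, numeric(1),
                       target_width = target_width, level = level,
                       increment = increment)
    v_target <- v_unique[match(p, p_unique)]
  } else {
    stopifnot(is.numeric(risk_bands), all(risk_bands > 0 & risk_bands < 1),
              !is.unsorted(risk_bands))
    widths <- rep_len(target_width, length(risk_bands))
    # nearest representative risk; ties go to the lower band
    idx <- vapply(p, function(pi) {
      d <- abs(risk_bands - pi)
      which(d <= min(d) + 1e-15)[1]
    }, integer(1))
    band <- risk_bands[idx]
    v_band <- vapply(seq_along(risk_bands), function(i) {
      width_to_variance(risk_bands[i], widths[i], level = level,
                        increment = increment)
    }, numeric(1))
    v_target <- v_band[idx]
  }

  n_i <- required_n(tibble::as_tibble(data), info, v_target)
  ind <- tibble::tibble(true_risk = p, band = band,
                        target_variance = v_target, n_required = n_i)
  in_scope <- ind[scope, ]
  n_req <- max(in_scope$n_required)
  driver_rows <- which(scope)[in_scope$n_required == n_req]
  driver <- dplyr::distinct(dplyr::bind_cols(
    tibble::as_tibble(data)[driver_rows, , drop = FALSE],
    ind[driver_rows, c("true_risk", "target_variance", "n_required")]))

  structure(
    list(n_required = n_req, individuals = ind, driver = driver,
         target_width = target_width, risk_bands = risk_bands,
         level = level, info = info),
    class = "samplesize_report"
  )
}

#' Conventional ladder of representative risks for banded targets
#'
#' Fine steps at low risks (0.01, 0.025, 0.05) where intervals are naturally
#' asymmetric, then 0.05 steps from 0.10 to 0.95.
#'
#' @return Numeric vector of representative risks.
#' @export
default_risk_bands <- function() {
  c(0.01, 0.025, 0.05, seq(0.10, 0.95, by = 0.05))
}

#' @export
print.samplesize_report <- function(x, ...) {
  cat("<samplesize_report> required n =", x$n_required, "\n")
  cat("driven by:\n")
  print(as.data.frame(x$driver), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
tidy.samplesize_report <- function(x, ...) x$individuals

#' @export
glance.samplesize_report <- function(x, ...) {
  tibble::tibble(
    n_required = x$n_required,
    driver_risk = x$driver$true_risk[1],
    target_variance_at_driver = x$driver$target_variance[1],
    n_individuals = nrow(x$individuals)
  )
}
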