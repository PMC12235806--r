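#' Define a core model
#'
#' The core model is the assumed logistic regression that maps an individual's
#' core predictor values to their "true" risk, before any data are collected:
#'
#' \deqn{\mathrm{logit}(p_i) = \alpha + \delta(\beta_1 x_{1i} + \dots + \beta_P x_{Pi})}
#'
#' `alpha` is the intercept, `betas` the (possibly only *relative*) predictor
#' weights, and `delta` a common multiplicative factor on the weighted sum.
#' When intercept and coefficients are taken from an existing published model,
#' set `delta = 1`; when only relative weights are known, leave `delta` to be
#' found by [calibrate_core_model()] together with `alpha`.
#'
#' @param alpha Intercept on the logit scale.
#' @param betas Named numeric vector of coefficients, one per design column.
#' @param delta Multiplicative factor on the weighted predictor sum (default 1).
#' @param standardization Optional standardization metadata (tibble of
#'   predictor, mean, sd) recorded when coefficients apply to standardized
#'   predictors; see [standardize_predictors()].
#' @return An object of class `core_model`.
#' @examples
#' m <- core_model(alpha = -3.81,
#'                 betas = c(mono = 1.11, pulse = 0.70, history = 1.95))
#' predict_risk(m, data.frame(mono = 1, pulse = 1, history = 1))
#' @export
core_model <- function(alpha, betas = NULL, delta = 1, standardization = NULL) {
  betas <- betas %||% stats::setNames(numeric(0), character(0))
  stopifnot(is.numeric(alpha), length(alpha) == 1, is.finite(alpha),
            is.numeric(betas), all(is.finite(betas)),
            is.numeric(delta), length(delta) == 1, is.finite(delta))
  if (length(betas) && (is.null(names(betas)) || any(names(betas) == ""))) {
    stop("`betas` must be a fully named vector (one name per design column)",
         call. = FALSE)
  }
  structure(
    list(alpha = alpha, betas = betas, delta = delta,
         predictor_names = names(betas), standardization = standardization),
    class = "core_model"
  )
}

#' @export
print.core_model <- function(x, ...) {
  cat("<core_model> logit(p) =", format(x$alpha, digits = 4), "+",
      format(x$delta, digits = 4), "* (",
      paste(sprintf("%s*%s", format(x$betas, digits = 4), x$predictor_names),
            collapse = " + "), ")\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.core_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$predictor_names),
    estimate = c(x$alpha, x$delta * x$betas),
    relative_weight = c(NA_real_, x$betas)
  )
}

#' @importFrom generics glance
#' @export
glance.core_model <- function(x, data = NULL, ...) {
  out <- tibble::tibble(alpha = x$alpha, delta = x$delta,
                        n_predictors = length(x$betas))
  if (!is.null(data)) {
    out$mean_risk <- mean_risk(x, data)
    out$expected_c <- expected_c_statistic(x, data)
  }
  out
}

# Design matrix (with leading intercept column) aligned to the model.
design_matrix <- function(model, data) {
  missing_cols <- setdiff(model$predictor_names, names(data))
  if (length(missing_cols)) {
    stop("table lacks core predictor columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(tibble::as_tibble(data)[model$predictor_names])
  if (length(model$predictor_names) && !is.numeric(X)) {
    stop("core predictor columns must be numeric", call. = FALSE)
  }
  cbind(`(Intercept)` = rep(1, nrow(data)), X)
}

#' Linear predictor and true risk under a core model
#'
#' @param model A [core_model()].
#' @param data Participant table whose columns include the model's predictors.
#' @return `linear_predictor()` returns the vector of logit-risks
#'   \eqn{\alpha + \delta \sum_j \beta_j x_{ji}}; `predict_risk()` its
#'   inverse-logit, the true risk per individual.
#' @export
linear_predictor <- function(model, data) {
  stopifnot(inherits(model, "core_model"))
  X <- design_matrix(model, data)
  drop(X %*% c(model$alpha, model$delta * model$betas))
}

#' @rdname linear_predictor
#' @export
predict_risk <- function(model, data) {
  invlogit(linear_predictor(model, data))
}

#' Overall (mean) outcome risk implied by a core model
#'
#' @inheritParams linear_predictor
#' @param weights Optional non-negative row weights (e.g. cell probabilities
#'   when `data` lists distinct predictor combinations).
#' @return The weighted mean of the individual risks: the model-implied
#'   prevalence over this case-mix.
#' @export
mean_risk <- function(model, data, weights = NULL) {
  if (nrow(data) < 1) stop("table is empty", call. = FALSE)
  p <- predict_risk(model, data)
  if (is.null(weights)) mean(p) else stats::weighted.mean(p, weights)
}

#' Model-implied concordance (expected C-statistic)
#'
#' The concordance probability (equivalently the area under the ROC curve) the
#' core model would attain over this case-mix, computed without simulating
#' outcomes: every ordered pair of individuals (i, j) contributes its
#' probability \eqn{p_i(1-p_j)} of being an (event, non-event) pair, counted
#' as concordant when \eqn{lp_i > lp_j} and half when tied,
#'
#' \deqn{C = \frac{\sum_{i \ne j} p_i(1-p_j)\,[\mathbf{1}(lp_i > lp_j) + \tfrac12 \mathbf{1}(lp_i = lp_j)]}{\sum_{i \ne j} p_i (1-p_j)}.}
#'
#' Removing the outcome simulation removes Monte-Carlo noise from the
#' calibration loop; a rank-based simulated C converges to this value.
#' Computed in O(n log n) via a sort and prefix sums.
#'
#' @inheritParams mean_risk
#' @return Concordance probability in \[0.5, 1\] for risks monotone in the
#'   linear predictor.
#' @export
expected_c_statistic <- function(model, data, weights = NULL) {
  if (nrow(data) < 2) stop("need at least 2 rows to form pairs", call. = FALSE)
  lp <- linear_predictor(model, data)
  p <- invlogit(lp)
  w <- weights %||% rep(1, length(lp))
  concordance_expected(lp, p, w)
}

# Expected pairwise concordance for given (lp, p, w); ties in lp count 1/2.
concordance_expected <- function(lp, p, w) {
  o <- order(lp)
  lp <- lp[o]; p <- p[o]; w <- w[o]
  wp <- w * p
  wq <- w * (1 - p)
  total <- sum(wp) * sum(wq) - sum(wp * wq)
  if (total <= 0) return(NaN)
  grp <- cumsum(!duplicated(lp))
  cum_wq <- c(0, cumsum(wq))
  num <- 0
  for (g in split(seq_along(lp), grp)) {
    lo <- g[1]; hi <- g[length(g)]
    below <- cum_wq[lo]                       # mass with strictly smaller lp
    within <- cum_wq[hi + 1] - cum_wq[lo]     # tied mass (incl. self, removed below)
    sp <- sum(wp[g])
    num <- num + sp * below + 0.5 * (sp * within - sum(wp[g] * wq[g]))
  }
  num / total
}

#' Calibrate a core model to a target prevalence and C-statistic
#'
#' Given only *relative* predictor weights, finds the intercept \eqn{\alpha}
#' and multiplicative factor \eqn{\delta} so that the core model attains a
#' specified overall outcome risk and C-statistic over the supplied case-mix
#' (the iterative constrained-calibration approach). Two monotonicities make
#' the search well-posed: for fixed \eqn{\delta} the mean risk is strictly
#' increasing in \eqn{\alpha}, and the model-implied C is non-decreasing in
#' \eqn{\delta \ge 0}. The implementation therefore runs an outer bisection on
#' \eqn{\delta} (bracket grown by doubling) with, at each \eqn{\delta}, an
#' inner one-dimensional root-find of \eqn{\alpha} for the prevalence.
#'
#' @param data Participant table representing the case-mix (typically a large
#'   synthetic cohort from [sample_cohort()]).
#' @param relative_betas Named numeric vector of relative weights, not all
#'   zero. For the equal-weights variant, standardize the continuous columns
#'   first ([standardize_predictors()]) and pass all weights equal to 1.
#' @param prevalence Target overall outcome risk, strictly inside (0, 1).
#' @param c_statistic Target C-statistic, strictly inside (0.5, 1).
#' @param tolerance Convergence margin on both targets (default 0.001).
#' @param max_iterations Cap on outer bisection steps (default 200).
#' @param weights Optional row weights (cell probabilities).
#' @return A [core_model()] whose implied mean risk and C are each within
#'   `tolerance` of target; its `calibration` attribute records the achieved
#'   values and iteration count.
#' @examples
#' \donttest{
#' spec <- predictor_spec(means = c(a = 0, b = 0), sds = c(a = 1, b = 1))
#' cohort <- sample_cohort(spec, n = 2000, seed = 1)
#' m <- calibrate_core_model(cohort, c(a = 1, b = 1),
#'                           prevalence = 0.2, c_statistic = 0.75)
#' glance(m, cohort)
#' }
#' @export
calibrate_core_model <- function(data, relative_betas, prevalence, c_statistic,
                                 tolerance = 0.001, max_iterations = 200,
                                 weights = NULL) {
  stopifnot(is.numeric(relative_betas), length(relative_betas) >= 1)
  if (all(relative_betas == 0)) stop("relative weights are all zero", call. = FALSE)
  if (!(prevalence > 0 && prevalence < 1)) {
    stop("`prevalence` must be strictly inside (0, 1)", call. = FALSE)
  }
  if (!(c_statistic > 0.5 && c_statistic < 1)) {
    stop("`c_statistic` must be strictly inside (0.5, 1)", call. = FALSE)
  }
  stopifnot(tolerance > 0)
  if (is.null(names(relative_betas))) {
    stop("`relative_betas` must be named", call. = FALSE)
  }

  skeleton <- core_model(alpha = 0, betas = relative_betas, delta = 1)
  X <- design_matrix(skeleton, data)
  xb <- drop(X[, -1, drop = FALSE] %*% relative_betas)
  w <- weights %||% rep(1, length(xb))

  solve_alpha <- function(delta) {
    f <- function(a) stats::weighted.mean(invlogit(a + delta * xb), w) - prevalence
    stats::uniroot(f, interval = c(-50, 50), tol = 1e-12)$root
  }
  c_at <- function(delta) {
    a <- solve_alpha(delta)
    lp <- a + delta * xb
    list(alpha = a, c = concordance_expected(lp, invlogit(lp), w))
  }

  # grow the delta bracket until the target C is straddled
  lo <- 0; hi <- 1
  hi_c <- c_at(hi)
  grow <- 0
  while (hi_c$c < c_statistic) {
    lo <- hi
    hi <- hi * 2
    hi_c <- c_at(hi)
    grow <- grow + 1
    if (grow > 60) {
      stop(sprintf(paste0("target C-statistic %.3f unreachable for this case-mix: ",
                          "at delta = %.3g achieved C = %.4f, mean risk = %.4f"),
                   c_statistic, hi, hi_c$c, prevalence), call. = FALSE)
    }
  }

  iter <- 0
  mid_c <- NULL
  repeat {
    iter <- iter + 1
    mid <- (lo + hi) / 2
    mid_c <- c_at(mid)
    if (abs(mid_c$c - c_statistic) <= tolerance) break
    if (mid_c$c < c_statistic) lo <- mid else hi <- mid
    if (iter >= max_iterations) {
      stop(sprintf(paste0("calibration did not converge in %d iterations: ",
                          "last alpha = %.4f, delta = %.4f, mean risk = %.4f, C = %.4f"),
                   max_iterations, mid_c$alpha, mid,
                   stats::weighted.mean(invlogit(mid_c$alpha + mid * xb), w),
                   mid_c$c), call. = FALSE)
    }
  }

  out <- core_model(alpha = mid_c$alpha, betas = relative_betas, delta = mid,
                    standardization = attr(data, "standardization"))
  attr(out, "calibration") <- tibble::tibble(
    target_prevalence = prevalence, target_c = c_statistic,
    achieved_prevalence = stats::weighted.mean(invlogit(mid_c$alpha + mid * xb), w),
    achieved_c = mid_c$c, iterations = iter, tolerance = tolerance
  )
  out
}
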