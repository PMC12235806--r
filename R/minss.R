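#' Convert an anticipated C-statistic to a Cox-Snell R-squared
#'
#' The established minimum-sample-size criteria are driven by the Cox-Snell
#' \eqn{R^2}, but investigators usually know an anticipated C-statistic
#' instead. The conversion simulates a large population in which the linear
#' predictor is standard normal among non-events and Normal(\eqn{\sqrt{2}\,
#' \Phi^{-1}(C)}, 1) among events (the binormal model whose theoretical AUROC
#' is exactly C), fits the univariable logistic regression of outcome on that
#' linear predictor, and returns \eqn{1 - \exp(-\mathrm{LR}/N)} from the
#' likelihood-ratio statistic. At the default `sim_size` the estimate is
#' stable to about three decimals across seeds.
#'
#' @param c_statistic Anticipated C-statistic, strictly inside (0.5, 1).
#' @param prevalence Overall outcome risk in (0, 1).
#' @param sim_size Simulated population size (default 1,000,000).
#' @param seed Seed for the simulation.
#' @return Cox-Snell R-squared, in (0, `max_r2cs(prevalence)`).
#' @seealso [max_r2cs()], [minimum_sample_size()]
#' @export
cstat_to_r2cs <- function(c_statistic, prevalence, sim_size = 1e6, seed = 1) {
  if (!(c_statistic > 0.5 && c_statistic < 1)) {
    stop("`c_statistic` must be strictly inside (0.5, 1)", call. = FALSE)
  }
  stopifnot(prevalence > 0, prevalence < 1, sim_size >= 100)
  with_seed(seed, {
    y <- stats::rbinom(sim_size, 1, prevalence)
    mu <- sqrt(2) * stats::qnorm(c_statistic)
    x <- stats::rnorm(sim_size, mean = ifelse(y == 1, mu, 0))
    fit <- stats::glm.fit(cbind(1, x), y, family = stats::binomial())
    lr <- fit$null.deviance - fit$deviance
    1 - exp(-lr / sim_size)
  })
}

#' Upper bound of the Cox-Snell R-squared for a binary outcome
#'
#' @param prevalence Overall outcome risk in (0, 1).
#' @return \eqn{1 - (\phi^\phi (1-\phi)^{1-\phi})^2}, the maximum attainable
#'   Cox-Snell R-squared at prevalence \eqn{\phi}.
#' @export
max_r2cs <- function(prevalence) {
  stopifnot(prevalence > 0, prevalence < 1)
  phi <- prevalence
  1 - (phi^phi * (1 - phi)^(1 - phi))^2
}

#' Minimum sample size criteria for developing a risk prediction model
#'
#' The established population-level criteria against which individual-level
#' precision analyses are compared:
#'
#' * **criterion (i)** -- estimate the overall outcome risk precisely:
#'   \eqn{n \ge z_{0.975}^2\, \phi(1-\phi) / \mathrm{margin}^2};
#' * **criterion (ii)** -- small overfitting of predictor effects, targeting
#'   a global shrinkage factor \eqn{S} (default 0.9):
#'   \eqn{n \ge P / [(S-1)\ln(1 - R^2_{CS}/S)]};
#' * **criterion (iii)** -- small optimism in apparent fit: the same form
#'   with \eqn{S = R^2_{CS} / (R^2_{CS} + \delta \cdot \max R^2_{CS})}
#'   (\eqn{\delta} = 0.05), floored at 0.9 so it never loosens criterion (ii).
#'
#' The overall minimum is the maximum of the three, each rounded up to an
#' integer first; the implied event count is \eqn{\lceil n\phi \rceil}.
#'
#' @param prevalence Overall outcome risk \eqn{\phi} in (0, 1).
#' @param n_parameters Number of candidate predictor parameters P (>= 1).
#' @param c_statistic Anticipated C-statistic; converted to a Cox-Snell
#'   R-squared via [cstat_to_r2cs()] unless `r2_cs` is given directly.
#' @param r2_cs Anticipated Cox-Snell R-squared (overrides `c_statistic`).
#' @param shrinkage Target shrinkage factor S for criterion (ii), default 0.9.
#' @param r2_margin Optimism margin \eqn{\delta} for criterion (iii), default
#'   0.05.
#' @param prevalence_margin Half-width of the 95% CI for the overall risk in
#'   criterion (i), default 0.05.
#' @param sim_size,seed Passed to [cstat_to_r2cs()].
#' @return A `minss_result`: tibble with one row per criterion plus the
#'   overall row (columns `criterion`, `n`, `events`), carrying the
#'   `r2_cs` used as an attribute.
#' @examples
#' \donttest{
#' minimum_sample_size(prevalence = 0.059, c_statistic = 0.77, n_parameters = 3)
#' }
#' @export
minimum_sample_size <- function(prevalence, n_parameters,
                                c_statistic = NULL, r2_cs = NULL,
                                shrinkage = 0.9, r2_margin = 0.05,
                                prevalence_margin = 0.05,
                                sim_size = 1e6, seed = 1) {
  stopifnot(prevalence > 0, prevalence < 1, n_parameters >= 1,
            shrinkage > 0, shrinkage < 1)
  if (is.null(r2_cs)) {
    if (is.null(c_statistic)) {
      stop("supply either `c_statistic` or `r2_cs`", call. = FALSE)
    }
    r2_cs <- cstat_to_r2cs(c_statistic, prevalence, sim_size = sim_size, seed = seed)
  }
  if (r2_cs >= shrinkage) {
    stop(sprintf("R2_CS (%.3f) >= shrinkage target (%.2f): criterion (ii) infeasible",
                 r2_cs, shrinkage), call. = FALSE)
  }
  phi <- prevalence
  z <- stats::qnorm(0.975)

  n1 <- ceiling(z^2 * phi * (1 - phi) / prevalence_margin^2)
  n2 <- ceiling(n_parameters / ((shrinkage - 1) * log(1 - r2_cs / shrinkage)))
  s3 <- max(shrinkage, r2_cs / (r2_cs + r2_margin * max_r2cs(phi)))
  n3 <- ceiling(n_parameters / ((s3 - 1) * log(1 - r2_cs / s3)))
  overall <- max(n1, n2, n3)

  out <- tibble::tibble(
    criterion = c("(i) overall risk precision",
                  "(ii) shrinkage / overfitting",
                  "(iii) optimism in apparent fit",
                  "overall"),
    n = c(n1, n2, n3, overall),
    events = ceiling(c(n1, n2, n3, overall) * phi)
  )
  attr(out, "r2_cs") <- r2_cs
  attr(out, "shrinkage_iii") <- s3
  class(out) <- c("minss_result", class(out))
  out
}

#' @export
glance.minss_result <- function(x, ...) {
  tibble::tibble(
    n_overall = x$n[x$criterion == "overall"],
    events = x$events[x$criterion == "overall"],
    r2_cs = attr(x, "r2_cs")
  )
}
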