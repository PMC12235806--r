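#' Worked example: diabetic foot ulcer risk model
#'
#' A fully specified planning scenario built around a published three-predictor
#' prediction model for the 2-year risk of foot ulcer in people with diabetes.
#' The three binary core predictors are `mono` (insensitivity to
#' monofilament), `pulse` (missing at least one foot pulse) and `history`
#' (previous ulcer or amputation). The case-mix is the cross-tabulation of the
#' three predictors reported for the original development data; the published
#' cell percentages sum to 100.2% (rounding), so they are renormalized to
#' probabilities. The core model uses the published intercept and
#' coefficients.
#'
#' @return A list with components `spec` (a [predictor_spec()] over the 8
#'   cells) and `model` (a [core_model()] with intercept -3.81 and
#'   coefficients 1.11, 0.70, 1.95).
#' @examples
#' ex <- example_foot_ulcer()
#' cohort <- sample_cohort(ex$spec, n = 1000, seed = 1)
#' summary(predict_risk(ex$model, cohort))
#' @export
example_foot_ulcer <- function() {
  cells <- tibble::tibble(
    mono    = c(0, 1, 1, 1, 1, 0, 0, 0),
    pulse   = c(0, 1, 1, 0, 0, 1, 1, 0),
    history = c(0, 1, 0, 1, 0, 1, 0, 1),
    prob    = c(0.563, 0.021, 0.062, 0.032, 0.115, 0.012, 0.177, 0.020)
  )
  list(
    spec = predictor_spec(cells = cells, normalize = TRUE),
    model = core_model(alpha = -3.81,
                       betas = c(mono = 1.11, pulse = 0.70, history = 1.95))
  )
}
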