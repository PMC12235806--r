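# Shared fixtures: the fully-specified three-binary-predictor case-mix and
# published core model used across module tests.
fu <- example_foot_ulcer()
fu_cells <- fu$spec$cells
fu_pred <- fu_cells[c("mono", "pulse", "history")]
fu_weights <- fu_cells$prob
fu_model <- fu$model
fu_info <- unit_information(fu_pred, fu_model, weights = fu_weights)

expect_within <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("%g within %g of %g", object, tol, expected))
}
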