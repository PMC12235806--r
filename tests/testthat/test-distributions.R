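test_that("categorical sampling matches cell probabilities and is reproducible", {
  n <- 10000
  tab <- sample_categorical(fu$spec, n = n, seed = 11)
  expect_equal(nrow(tab), n)
  expect_identical(names(tab), c("mono", "pulse", "history"))

  # observed cell proportions within 4 binomial SEs of their probabilities
  key <- paste(tab$mono, tab$pulse, tab$history)
  cell_key <- paste(fu_cells$mono, fu_cells$pulse, fu_cells$history)
  obs <- as.numeric(table(factor(key, levels = cell_key))) / n
  se <- sqrt(fu_weights * (1 - fu_weights) / n)
  expect_true(all(abs(obs - fu_weights) <= 4 * se))

  # identical (spec, n, seed) triples give identical tables
  expect_identical(tab, sample_categorical(fu$spec, n = n, seed = 11))
  expect_false(identical(tab, sample_categorical(fu$spec, n = n, seed = 12)))
})

test_that("a degenerate single-cell distribution yields identical rows", {
  spec <- predictor_spec(cells = data.frame(a = 1, b = 0, prob = 1))
  tab <- sample_cohort(spec, n = 5, seed = 3)
  expect_equal(nrow(tab), 5)
  expect_true(all(tab$a == 1) && all(tab$b == 0))
})

test_that("two-cell sampling passes a goodness-of-fit check against a brute-force tally", {
  spec <- predictor_spec(cells = data.frame(x = c(0, 1), prob = c(0.5, 0.5)))
  n <- 100000
  tab <- sample_cohort(spec, n = n, seed = 21)
  # independent tally: loop over rows, no table()/dplyr shortcut
  counts <- c(0, 0)
  for (v in tab$x) counts[v + 1] <- counts[v + 1] + 1
  expect_equal(sum(counts), n)
  p <- stats::chisq.test(counts, p = c(0.5, 0.5))$p.value
  expect_gt(p, 1e-4)
})

test_that("continuous sampling reproduces the declared moments and correlations", {
  for (rho in c(0, 0.8)) {
    spec <- predictor_spec(means = c(u = 0, v = 0), sds = c(u = 1, v = 1),
                           correlation = matrix(c(1, rho, rho, 1), 2))
    tab <- sample_continuous(spec, n = 100000, seed = 31)
    expect_within(cor(tab$u, tab$v), rho, 0.01)
    expect_within(mean(tab$u), 0, 0.02)
    expect_within(sd(tab$v), 1, 0.02)
  }
})

test_that("independent continuous predictors stay uncorrelated", {
  spec <- predictor_spec(means = c(a = 0, b = 5, c = -2),
                         sds = c(a = 1, b = 2, c = 0.5))
  tab <- sample_continuous(spec, n = 100000, seed = 41)
  cm <- cor(as.matrix(tab))
  expect_true(all(abs(cm[upper.tri(cm)]) < 0.02))
})

test_that("a single continuous draw is reproducible under a fixed seed", {
  spec <- predictor_spec(means = c(x = 10), sds = c(x = 1))
  one <- sample_continuous(spec, n = 1, seed = 5)
  expect_identical(one, sample_continuous(spec, n = 1, seed = 5))
  expect_equal(nrow(one), 1)
})

test_that("specification invariants are enforced", {
  expect_error(predictor_spec(cells = data.frame(x = c(0, 1), prob = c(0.6, 0.5))),
               "sum to")
  # rounded published percentages can be renormalized explicitly
  spec <- predictor_spec(cells = data.frame(x = c(0, 1), prob = c(0.6, 0.5)),
                         normalize = TRUE)
  expect_equal(sum(spec$cells$prob), 1)

  bad_cor <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3)
  expect_error(
    predictor_spec(means = c(a = 0, b = 0, c = 0), sds = c(a = 1, b = 1, c = 1),
                   correlation = bad_cor),
    "positive semi-definite.*eigenvalue")
  expect_error(predictor_spec(means = c(x = 0), sds = c(x = 0)), "positive")
  expect_error(
    predictor_spec(cells = data.frame(x = c(0, 1), prob = c(0.5, 0.5)),
                   means = c(x = 0), sds = c(x = 1)),
    "unique")
  expect_error(sample_cohort(fu$spec, n = 0), "positive")
})

test_that("standardization centres and scales, stores invertible metadata", {
  tab <- tibble::tibble(x = c(1, 2, 3), z = c(0, 1, 0))
  out <- standardize_predictors(tab, "x")
  expect_equal(out$x, c(-1, 0, 1))
  expect_equal(mean(out$x), 0, tolerance = 1e-10)
  expect_equal(sd(out$x), 1, tolerance = 1e-10)
  expect_identical(out$z, tab$z)  # untouched binary column passes through

  # idempotent on already-standardized values
  again <- standardize_predictors(out, "x")
  expect_equal(again$x, out$x, tolerance = 1e-10)

  # metadata round-trips new individuals
  meta <- attr(out, "standardization")
  new <- tibble::tibble(x = c(10, -4))
  back <- apply_standardization(apply_standardization(new, meta), meta,
                                invert = TRUE)
  expect_equal(back$x, new$x, tolerance = 1e-12)

  expect_error(standardize_predictors(tibble::tibble(x = c(2, 2)), "x"),
               "degenerate")
})

test_that("participant tables reject missing values in core predictors", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = c(1, NA), b = c(0, 1)), path, row.names = FALSE)
  expect_error(read_participant_table(path, predictors = c("a", "b")),
               "missing values")
  ok <- read_participant_table(path, predictors = "b")
  expect_equal(nrow(ok), 2)
  expect_identical(attr(ok, "provenance"), "observed")
})

test_that("predictor specs round-trip through YAML config files", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "normalize: true",
    "n_default: 500",
    "cells:",
    "  - {x: 0, grp: 0, prob: 0.5}",
    "  - {x: 1, grp: 1, prob: 0.5}",
    "continuous:",
    "  means: {age: 60}",
    "  sds: {age: 10}"
  ), path)
  spec <- read_predictor_spec(path)
  expect_identical(spec$predictor_names, c("x", "grp", "age"))
  expect_equal(spec$n_default, 500L)
  tab <- sample_cohort(spec, n = 50, seed = 2)
  expect_identical(names(tab), c("x", "grp", "age"))
})
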