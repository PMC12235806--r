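test_that("linear predictor reproduces the published model's risks", {
  # all three predictors present: lp = -3.81 + 1.11 + 0.70 + 1.95 = -0.05
  lp <- linear_predictor(fu_model, data.frame(mono = 1, pulse = 1, history = 1))
  expect_equal(lp, -0.05)
  expect_within(invlogit(lp), 0.49, 0.005)

  # history only: lp = -3.81 + 1.95 = -1.86, risk ~= 0.13
  lp2 <- linear_predictor(fu_model, data.frame(mono = 0, pulse = 0, history = 1))
  expect_equal(lp2, -1.86)
  expect_within(invlogit(lp2), 0.13, 0.005)

  # all-zero betas collapse to the intercept regardless of delta
  m0 <- core_model(alpha = -1.2, betas = c(a = 0, b = 0), delta = 7)
  expect_equal(linear_predictor(m0, data.frame(a = rnorm(5), b = rnorm(5))),
               rep(-1.2, 5))

  expect_error(linear_predictor(fu_model, data.frame(mono = 1)), "lacks")
})

test_that("expected concordance handles the degenerate and hand-computable cases", {
  d <- data.frame(x = c(0, 0.5, 1, 2))
  # delta = 0: every pair tied, C = 0.5 exactly
  m_flat <- core_model(alpha = -1, betas = c(x = 1), delta = 0)
  expect_equal(expected_c_statistic(m_flat, d), 0.5)

  # two rows with risks 0.9 and 0.1, by hand: the (event from row 1,
  # non-event from row 2) pairing has weight 0.9*0.9 and is concordant; the
  # reverse pairing has weight 0.1*0.1 and is discordant, so C = 81/82
  m2 <- core_model(alpha = 0, betas = c(x = 1))
  d2 <- data.frame(x = logit(c(0.9, 0.1)))
  expect_equal(expected_c_statistic(m2, d2), 81 / 82)

  expect_error(expected_c_statistic(m2, d2[1, , drop = FALSE]), "2 rows")
})

test_that("fast concordance equals the brute-force pair sum", {
  set.seed(71)
  for (rep in 1:3) {
    n <- sample(50:200, 1)
    d <- data.frame(x = round(rnorm(n), 1))  # rounding induces ties
    m <- core_model(alpha = -0.5, betas = c(x = 0.8))
    lp <- linear_predictor(m, d)
    p <- invlogit(lp)
    num <- den <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      w <- p[i] * (1 - p[j])
      den <- den + w
      num <- num + w * (if (lp[i] > lp[j]) 1 else if (lp[i] == lp[j]) 0.5 else 0)
    }
    expect_equal(expected_c_statistic(m, d), num / den, tolerance = 1e-12)
  }
})

test_that("expected concordance agrees with simulated-outcome AUROC", {
  set.seed(72)
  d <- data.frame(x = rnorm(400))
  m <- core_model(alpha = -1, betas = c(x = 1.2))
  p <- predict_risk(m, d)
  lp <- linear_predictor(m, d)
  cc <- expected_c_statistic(m, d)
  sims <- replicate(50, {
    y <- rbinom(length(p), 1, p)
    if (sum(y) == 0 || sum(y) == length(y)) return(NA_real_)
    pos <- lp[y == 1]; neg <- lp[y == 0]
    mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  })
  mc <- mean(sims, na.rm = TRUE)
  se <- sd(sims, na.rm = TRUE) / sqrt(sum(!is.na(sims)))
  expect_within(cc, mc, 3 * se + 0.005)  # small-n AUROC is a ratio estimate
})

test_that("mean risk behaves as a weighted mean of model risks", {
  m_int <- core_model(alpha = logit(0.059), betas = c(x = 0))
  expect_equal(mean_risk(m_int, data.frame(x = rnorm(10))), 0.059)

  # the published case-mix implies roughly the published overall risk
  expect_within(mean_risk(fu_model, fu_pred, weights = fu_weights), 0.059, 0.005)

  # monotone in alpha, vanishing in the -Inf limit
  risks <- sapply(c(-10, -5, -2, 0, 2), function(a) {
    mean_risk(core_model(alpha = a, betas = c(x = 1)), data.frame(x = rnorm(50)))
  })
  expect_true(all(diff(risks) > 0))
  expect_lt(risks[1], 1e-3)
  expect_error(mean_risk(fu_model, fu_pred[0, ]), "empty")
})

test_that("calibration hits the target prevalence and C-statistic", {
  spec <- predictor_spec(means = stats::setNames(rep(0, 9), paste0("z", 1:9)),
                        sds = stats::setNames(rep(1, 9), paste0("z", 1:9)))
  cohort <- sample_cohort(spec, n = 4000, seed = 81)
  betas <- stats::setNames(rep(1, 9), paste0("z", 1:9))
  m <- calibrate_core_model(cohort, betas, prevalence = 0.174,
                            c_statistic = 0.78, tolerance = 0.001)
  expect_within(mean_risk(m, cohort), 0.174, 0.001)
  expect_within(expected_c_statistic(m, cohort), 0.78, 0.001)
  expect_gte(m$delta, 0)

  cal <- attr(m, "calibration")
  expect_within(cal$achieved_prevalence, 0.174, 0.001)
  expect_within(cal$achieved_c, 0.78, 0.001)
})

test_that("a near-null discrimination target collapses to the intercept-only model", {
  d <- data.frame(x = rnorm(500, sd = 2))
  m <- calibrate_core_model(d, c(x = 1), prevalence = 0.3, c_statistic = 0.501)
  expect_lt(m$delta, 0.05)
  expect_within(m$alpha, logit(0.3), 0.05)
})

test_that("calibration is invariant to rescaling the relative weights", {
  set.seed(83)
  d <- data.frame(a = rnorm(1500), b = rbinom(1500, 1, 0.3))
  m1 <- calibrate_core_model(d, c(a = 1, b = 2), prevalence = 0.2,
                             c_statistic = 0.7, tolerance = 1e-4)
  m2 <- calibrate_core_model(d, c(a = 2, b = 4), prevalence = 0.2,
                             c_statistic = 0.7, tolerance = 1e-4)
  # delta absorbs the rescaling; the delta*beta products are invariant
  expect_equal(m2$delta * 2, m1$delta, tolerance = 0.02 * m1$delta)
  expect_equal(m2$alpha, m1$alpha, tolerance = 0.01)
})

test_that("calibration validates its targets and reports unreachable ones", {
  d <- data.frame(x = rnorm(100))
  expect_error(calibrate_core_model(d, c(x = 0), 0.2, 0.7), "all zero")
  expect_error(calibrate_core_model(d, c(x = 1), 1.2, 0.7), "prevalence")
  expect_error(calibrate_core_model(d, c(x = 1), 0.2, 0.5), "c_statistic")
  # a binary predictor with tiny variation cannot reach C = 0.99
  d2 <- data.frame(x = c(rep(0, 99), 1))
  expect_error(
    calibrate_core_model(d2, c(x = 1), prevalence = 0.2, c_statistic = 0.99),
    "unreachable")
})

test_that("mean risk is increasing in alpha and C non-decreasing in delta on a grid", {
  set.seed(85)
  d <- data.frame(x = rnorm(300), y = rbinom(300, 1, 0.4))
  bet <- c(x = 1, y = 0.5)
  xb <- as.matrix(d) %*% bet
  for (delta in c(0.2, 1, 3)) {
    risks <- sapply(seq(-3, 3, length.out = 7), function(a) {
      mean(invlogit(a + delta * xb))
    })
    expect_true(all(diff(risks) > 0))
  }
  cs <- sapply(c(0, 0.25, 0.5, 1, 2, 4), function(delta) {
    m <- core_model(alpha = -1, betas = bet, delta = delta)
    expected_c_statistic(m, d)
  })
  expect_true(all(diff(cs) >= -1e-12))
})
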