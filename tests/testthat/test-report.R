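write_fu_spec_yaml <- function(path) {
  lines <- c("normalize: true",
             "cells:",
             sprintf("  - {mono: %d, pulse: %d, history: %d, prob: %.3f}",
                     fu_cells$mono, fu_cells$pulse, fu_cells$history,
                     c(0.563, 0.021, 0.062, 0.032, 0.115, 0.012, 0.177, 0.020)))
  writeLines(lines, path)
  path
}

test_that("run configuration enforces one model source and one analysis", {
  spec_path <- write_fu_spec_yaml(withr::local_tempfile(fileext = ".yaml"))
  expect_error(run_config(), "exactly one of")
  expect_error(run_config(spec_path = spec_path, model = fu_model,
                          lp_column = "lp", sample_sizes = 100),
               "exactly one core-model source")
  expect_error(run_config(spec_path = spec_path, model = fu_model),
               "at least one analysis")
  expect_error(run_config(spec_path = spec_path,
                          relative_betas = c(mono = 1), sample_sizes = 100),
               "requires")
  cfg <- run_config(spec_path = spec_path, model = fu_model, sample_sizes = 100)
  expect_s3_class(cfg, "run_config")
})

test_that("an end-to-end run writes recomputable artifacts for each sample size", {
  spec_path <- write_fu_spec_yaml(withr::local_tempfile(fileext = ".yaml"))
  out_dir <- withr::local_tempdir()
  cfg <- run_config(spec_path = spec_path, model = fu_model,
                    sample_sizes = c(453, 9126), thresholds = 0.06,
                    subgroups = "pulse", target_width = 0.1,
                    n_synthetic = 2000, seed = 7, out_dir = out_dir,
                    plots = FALSE)
  res <- run_stability(cfg)

  for (f in c("individuals_n453.csv", "summary_n453.csv", "envelopes_n453.csv",
              "individuals_n9126.csv", "summary_n9126.csv",
              "required_n_individuals.csv", "required_n.csv",
              "unit_information.csv", "manifest.json")) {
    expect_true(file.exists(file.path(out_dir, f)), label = f)
  }
  expect_length(res$stability, 2)

  # every summary cell recomputable from the per-individual table
  ind <- utils::read.csv(file.path(out_dir, "individuals_n453.csv"))
  smry <- utils::read.csv(file.path(out_dir, "summary_n453.csv"))
  expect_equal(smry$mean[smry$subgroup == "overall" & smry$metric == "width"],
               mean(ind$width), tolerance = 1e-9)

  # the batch's larger sample size yields uniformly narrower intervals
  ind2 <- utils::read.csv(file.path(out_dir, "individuals_n9126.csv"))
  expect_true(all(ind2$width < ind$width))

  manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  expect_equal(manifest$seed, 7)
  expect_equal(manifest$casemix_mode, "sampled_from_spec")
  expect_equal(manifest$model$alpha, -3.81)
})

test_that("identical configurations with identical seeds are byte-identical", {
  spec_path <- write_fu_spec_yaml(withr::local_tempfile(fileext = ".yaml"))
  runs <- lapply(1:2, function(i) {
    out <- file.path(withr::local_tempdir(.local_envir = parent.frame(2)),
                     paste0("run", i))
    cfg <- run_config(spec_path = spec_path, model = fu_model,
                      sample_sizes = 453, thresholds = 0.06,
                      n_synthetic = 500, seed = 42, out_dir = out, plots = FALSE)
    run_stability(cfg)
    out
  })
  for (f in c("individuals_n453.csv", "summary_n453.csv", "unit_information.csv")) {
    expect_identical(readLines(file.path(runs[[1]], f)),
                     readLines(file.path(runs[[2]], f)), label = f)
  }
})

test_that("a true-logit-risk column in an observed table recovers the core model", {
  tab <- sample_categorical(fu$spec, n = 400, seed = 13)
  tab$lp_true <- linear_predictor(fu_model, tab)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  out_dir <- withr::local_tempdir()
  cfg <- run_config(table_path = path,
                    predictors = c("mono", "pulse", "history"),
                    lp_column = "lp_true", sample_sizes = 453,
                    seed = 1, out_dir = out_dir, plots = FALSE)
  res <- run_stability(cfg)
  expect_equal(unname(res$model$alpha), -3.81, tolerance = 1e-8)
  expect_equal(unname(res$model$delta * res$model$betas),
               c(mono = 1.11, pulse = 0.70, history = 1.95) |> unname(),
               tolerance = 1e-8)
  expect_equal(jsonlite::read_json(file.path(out_dir, "manifest.json"))$casemix_mode,
               "observed_table")
})

test_that("calibration-sourced runs record the achieved targets in the manifest", {
  tab <- tibble::tibble(z1 = rnorm(800), z2 = rnorm(800))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  out_dir <- withr::local_tempdir()
  cfg <- run_config(table_path = path, predictors = c("z1", "z2"),
                    relative_betas = c(z1 = 1, z2 = 1),
                    prevalence = 0.2, c_statistic = 0.7,
                    sample_sizes = 500, seed = 5, out_dir = out_dir,
                    plots = FALSE)
  res <- run_stability(cfg)
  cal <- res$manifest$calibration
  expect_within(cal$achieved_prevalence, 0.2, 0.001)
  expect_within(cal$achieved_c, 0.7, 0.001)
})
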