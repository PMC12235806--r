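#' Declare the joint distribution of core predictors
#'
#' A predictor specification is the declarative description of the case-mix:
#' the joint distribution of the core predictor values in the target
#' population. It is the second step of the planning workflow, after the core
#' predictors themselves have been chosen. Two blocks are supported, alone or
#' together:
#'
#' * a **categorical block**: a table of value combinations (one column per
#'   predictor, already encoded as numeric design columns, e.g. 0/1 dummies)
#'   with a `prob` column of cell probabilities summing to 1;
#' * a **continuous block**: per-predictor means and standard deviations plus
#'   a correlation matrix, realised by drawing from a multivariate normal and
#'   rescaling to the requested moments (a Gaussian-copula-style
#'   construction).
#'
#' When both blocks are present they are sampled independently: published
#' summaries almost always give a cross-tabulation of the categorical
#' predictors and marginal moments (plus, at best, correlations) for the
#' continuous ones, not their joint law.
#'
#' @param cells Data frame with one numeric column per categorical predictor
#'   and a `prob` column of cell probabilities, or `NULL`.
#' @param means,sds Named numeric vectors of continuous predictor means and
#'   standard deviations (same units as the predictor), or `NULL`.
#' @param correlation Correlation matrix for the continuous block; identity if
#'   omitted. Must be symmetric, unit-diagonal and positive semi-definite.
#' @param n_default Cohort size used by [sample_cohort()] when `n` is not
#'   given. Defaults to 10,000, a size at which sampling noise in downstream
#'   information-matrix entries is small relative to typical reporting
#'   precision.
#' @param normalize If `TRUE`, cell probabilities that do not sum to 1 (as
#'   happens with rounded published percentages) are rescaled to sum to 1
#'   instead of raising an error.
#' @return An object of class `predictor_spec`.
#' @seealso [sample_cohort()], [read_predictor_spec()]
#' @examples
#' spec <- predictor_spec(
#'   cells = data.frame(x = c(0, 1), prob = c(0.7, 0.3))
#' )
#' sample_cohort(spec, n = 5, seed = 1)
#' @export
predictor_spec <- function(cells = NULL, means = NULL, sds = NULL,
                           correlation = NULL, n_default = 10000,
                           normalize = FALSE) {
  if (is.null(cells) && is.null(means)) {
    stop("supply a categorical `cells` table and/or a continuous block", call. = FALSE)
  }
  stopifnot(is.numeric(n_default), length(n_default) == 1, n_default >= 1)

  cat_names <- character()
  if (!is.null(cells)) {
    cells <- tibble::as_tibble(cells)
    if (!"prob" %in% names(cells)) {
      stop("`cells` must contain a `prob` column", call. = FALSE)
    }
    cat_names <- setdiff(names(cells), "prob")
    if (length(cat_names) == 0) stop("`cells` has no predictor columns", call. = FALSE)
    if (!all(vapply(cells[cat_names], is.numeric, logical(1)))) {
      stop("categorical predictors must arrive pre-encoded as numeric design columns",
           call. = FALSE)
    }
    p <- cells$prob
    if (any(p < 0 | p > 1)) {
      stop("cell probabilities must lie in [0, 1]", call. = FALSE)
    }
    if (abs(sum(p) - 1) > 1e-9) {
      if (normalize) {
        cells$prob <- p / sum(p)
      } else {
        stop(sprintf("cell probabilities sum to %.6f, not 1 (use normalize = TRUE for rounded published percentages)",
                     sum(p)), call. = FALSE)
      }
    }
  }

  cont_names <- character()
  if (!is.null(means)) {
    if (is.null(sds)) stop("continuous block needs both `means` and `sds`", call. = FALSE)
    if (is.null(names(means)) || is.null(names(sds))) {
      stop("`means` and `sds` must be named vectors", call. = FALSE)
    }
    if (!identical(names(means), names(sds))) {
      stop("`means` and `sds` must name the same predictors in the same order", call. = FALSE)
    }
    if (any(sds <= 0)) stop("standard deviations must be strictly positive", call. = FALSE)
    cont_names <- names(means)
    k <- length(cont_names)
    if (is.null(correlation)) correlation <- diag(k)
    correlation <- as.matrix(correlation)
    if (!isTRUE(all.equal(dim(correlation), c(k, k)))) {
      stop("correlation matrix dimension does not match the continuous block", call. = FALSE)
    }
    if (max(abs(correlation - t(correlation))) > 1e-8 ||
        max(abs(diag(correlation) - 1)) > 1e-8) {
      stop("correlation matrix must be symmetric with unit diagonal", call. = FALSE)
    }
    ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop(sprintf("correlation matrix is not positive semi-definite (smallest eigenvalue %.3g)",
                   min(ev)), call. = FALSE)
    }
    dimnames(correlation) <- list(cont_names, cont_names)
  }

  predictor_names <- c(cat_names, cont_names)
  if (anyDuplicated(predictor_names)) {
    stop("predictor names must be unique across blocks", call. = FALSE)
  }

  structure(
    list(cells = cells, means = means, sds = sds, correlation = correlation,
         predictor_names = predictor_names, n_default = as.integer(n_default)),
    class = "predictor_spec"
  )
}

#' @export
print.predictor_spec <- function(x, ...) {
  cat("<predictor_spec>", length(x$predictor_names), "predictors:",
      paste(x$predictor_names, collapse = ", "), "\n")
  if (!is.null(x$cells)) cat("  categorical block:", nrow(x$cells), "cells\n")
  if (!is.null(x$means)) cat("  continuous block:", length(x$means), "predictors\n")
  invisible(x)
}

#' Generate a synthetic cohort from a predictor specification
#'
#' Draws `n` individuals whose predictor values follow the declared joint
#' distribution: categorical cells are sampled with their cell probabilities,
#' and the continuous block from a multivariate normal with the declared
#' moments and correlations. Generation is reproducible: the same
#' (spec, n, seed) triple always yields the same table.
#'
#' @param spec A [predictor_spec()].
#' @param n Number of individuals; defaults to `spec$n_default`.
#' @param seed Integer seed for the draw.
#' @return A tibble with one row per individual and one column per predictor,
#'   carrying a `"provenance"` attribute of `"synthetic"`.
#' @examples
#' spec <- predictor_spec(cells = data.frame(x = c(0, 1), prob = c(0.5, 0.5)))
#' sample_cohort(spec, n = 4, seed = 7)
#' @export
sample_cohort <- function(spec, n = NULL, seed = 1) {
  stopifnot(inherits(spec, "predictor_spec"))
  n <- n %||% spec$n_default
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)

  parts <- list()
  with_seed(seed, {
    if (!is.null(spec$cells)) {
      cat_names <- setdiff(names(spec$cells), "prob")
      idx <- sample.int(nrow(spec$cells), n, replace = TRUE, prob = spec$cells$prob)
      parts$categorical <- spec$cells[idx, cat_names, drop = FALSE]
    }
    if (!is.null(spec$means)) {
      k <- length(spec$means)
      z <- MASS::mvrnorm(n, mu = rep(0, k), Sigma = spec$correlation)
      z <- matrix(z, nrow = n)  # mvrnorm drops to a vector when n = 1
      x <- sweep(sweep(z, 2, spec$sds, `*`), 2, spec$means, `+`)
      colnames(x) <- names(spec$means)
      parts$continuous <- tibble::as_tibble(x)
    }
  })
  out <- tibble::as_tibble(dplyr::bind_cols(parts))
  out <- out[spec$predictor_names]
  attr(out, "provenance") <- "synthetic"
  out
}

#' @rdname sample_cohort
#' @export
sample_categorical <- function(spec, n = NULL, seed = 1) {
  stopifnot(inherits(spec, "predictor_spec"))
  if (is.null(spec$cells)) stop("spec has no categorical block", call. = FALSE)
  spec$means <- spec$sds <- spec$correlation <- NULL
  spec$predictor_names <- setdiff(names(spec$cells), "prob")
  sample_cohort(spec, n = n, seed = seed)
}

#' @rdname sample_cohort
#' @export
sample_continuous <- function(spec, n = NULL, seed = 1) {
  stopifnot(inherits(spec, "predictor_spec"))
  if (is.null(spec$means)) stop("spec has no continuous block", call. = FALSE)
  spec$cells <- NULL
  spec$predictor_names <- names(spec$means)
  sample_cohort(spec, n = n, seed = seed)
}

#' Standardize continuous predictor columns
#'
#' Centres and scales the named columns to mean 0 and (sample) SD 1, as used
#' when a core model assumes equal weights on standardized continuous
#' predictors. The marginal means and SDs are stored so the same transform can
#' be re-applied to new individuals or inverted.
#'
#' @param data Participant table (data frame).
#' @param which Character vector of column names to standardize.
#' @return The table with the named columns standardized; the
#'   `"standardization"` attribute holds a tibble of (predictor, mean, sd).
#' @seealso [apply_standardization()]
#' @examples
#' out <- standardize_predictors(data.frame(a = c(1, 2, 3)), "a")
#' attr(out, "standardization")
#' @export
standardize_predictors <- function(data, which) {
  stopifnot(is.data.frame(data), is.character(which))
  missing_cols <- setdiff(which, names(data))
  if (length(missing_cols)) {
    stop("columns not in table: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  meta <- purrr::map_dfr(which, function(nm) {
    x <- data[[nm]]
    if (!is.numeric(x)) stop("column `", nm, "` is not numeric", call. = FALSE)
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop("column `", nm, "` is degenerate (zero SD); cannot standardize", call. = FALSE)
    }
    tibble::tibble(predictor = nm, mean = mean(x), sd = s)
  })
  out <- tibble::as_tibble(data)
  for (i in seq_len(nrow(meta))) {
    nm <- meta$predictor[i]
    out[[nm]] <- (out[[nm]] - meta$mean[i]) / meta$sd[i]
  }
  attr(out, "standardization") <- meta
  attr(out, "provenance") <- attr(data, "provenance") %||% "observed"
  out
}

#' Apply or invert a stored standardization
#'
#' @param data Table of new individuals.
#' @param meta The `"standardization"` attribute produced by
#'   [standardize_predictors()] (a tibble with columns predictor, mean, sd).
#' @param invert If `TRUE`, maps standardized values back to the original scale.
#' @return The transformed tibble.
#' @export
apply_standardization <- function(data, meta, invert = FALSE) {
  stopifnot(is.data.frame(data), is.data.frame(meta))
  out <- tibble::as_tibble(data)
  for (i in seq_len(nrow(meta))) {
    nm <- meta$predictor[i]
    if (!nm %in% names(out)) stop("column `", nm, "` missing", call. = FALSE)
    out[[nm]] <- if (invert) {
      out[[nm]] * meta$sd[i] + meta$mean[i]
    } else {
      (out[[nm]] - meta$mean[i]) / meta$sd[i]
    }
  }
  out
}

#' Read and validate a participant table
#'
#' Reads a delimited text file (comma by default, tab accepted) with a header
#' row into a participant table, and checks the core predictor columns are
#' numeric with no missing values. Missing values are rejected, not imputed:
#' the planning calculations assume a complete case-mix.
#'
#' @param path File path.
#' @param predictors Character vector of core predictor column names to
#'   validate; by default all numeric columns are accepted as-is.
#' @param sep Field separator (`","` or `"\t"`).
#' @return A tibble with a `"provenance"` attribute of `"observed"`.
#' @export
read_participant_table <- function(path, predictors = NULL, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  out <- tibble::as_tibble(raw)
  if (nrow(out) < 1) stop("participant table is empty", call. = FALSE)
  if (!is.null(predictors)) {
    missing_cols <- setdiff(predictors, names(out))
    if (length(missing_cols)) {
      stop("missing core predictor columns: ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    }
    for (nm in predictors) {
      if (!is.numeric(out[[nm]])) {
        stop("core predictor `", nm, "` is not numeric; encode it as design columns first",
             call. = FALSE)
      }
      if (anyNA(out[[nm]])) {
        stop("core predictor `", nm, "` contains missing values", call. = FALSE)
      }
    }
  }
  attr(out, "provenance") <- "observed"
  out
}

#' Read a predictor specification from a YAML config
#'
#' The config mirrors [predictor_spec()]: an optional `cells` list (each entry
#' a named list of predictor values plus `prob`), an optional `continuous`
#' block with `means`, `sds` and an optional `correlation` matrix (list of
#' rows), plus optional `n_default` and `normalize` keys.
#'
#' @param path Path to a YAML file.
#' @return A [predictor_spec()].
#' @export
read_predictor_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  cells <- NULL
  if (!is.null(cfg$cells)) {
    cells <- purrr::map_dfr(cfg$cells, tibble::as_tibble)
  }
  means <- sds <- correlation <- NULL
  if (!is.null(cfg$continuous)) {
    means <- unlist(cfg$continuous$means)
    sds <- unlist(cfg$continuous$sds)
    if (!is.null(cfg$continuous$correlation)) {
      correlation <- do.call(rbind, cfg$continuous$correlation)
    }
  }
  predictor_spec(cells = cells, means = means, sds = sds,
                 correlation = correlation,
                 n_default = cfg$n_default %||% 10000,
                 normalize = isTRUE(cfg$normalize))
}
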