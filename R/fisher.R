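#' Fisher's unit information matrix over a case-mix
#'
#' The variance-covariance matrix of logistic regression estimates decomposes
#' into the sample size and a per-participant ("unit") expected information
#' matrix,
#' \deqn{\mathrm{var}(\hat\beta) = n^{-1} \mathbf{I}^{-1}, \qquad
#'       \mathbf{I} = E\left[p(1-p)\, \mathbf{x}'\mathbf{x}\right],}
#' with \eqn{\mathbf{x} = (1, x_1, \dots, x_P)} an individual's design row and
#' \eqn{p} their risk under the core model. The expectation is over the joint
#' predictor distribution: entry (j, k) is the (weighted) mean over rows of
#' \eqn{p(1-p) x_j x_k}.
#'
#' Two modes are supported. The default takes `data` as a (large, typically
#' simulated) cohort and averages with equal weights. When the case-mix is a
#' finite table of distinct predictor combinations, pass the cell
#' probabilities as `weights` for the exact expectation, free of simulation
#' noise.
#'
#' @param data Participant table (rows are individuals or distinct cells).
#' @param model A [core_model()] aligned to the table's columns.
#' @param weights Optional non-negative row weights (cell probabilities).
#' @return An object of class `unit_information`: the (P+1) x (P+1) symmetric
#'   matrix with a leading intercept row/column, plus the predictor ordering
#'   and the number of rows used. A warning is attached (and raised) when the
#'   design is numerically rank-deficient (condition number > 1e10).
#' @examples
#' m <- core_model(alpha = 0, betas = c(x = 0))
#' unit_information(data.frame(x = 0), m)  # p = 0.5, so I = [0.25, ...]
#' @export
unit_information <- function(data, model, weights = NULL) {
  stopifnot(inherits(model, "core_model"))
  if (nrow(data) < 1) stop("table is empty", call. = FALSE)
  X <- design_matrix(model, data)
  p <- invlogit(drop(X %*% c(model$alpha, model$delta * model$betas)))
  w <- weights %||% rep(1 / nrow(X), nrow(X))
  if (length(w) != nrow(X)) stop("`weights` length must match rows", call. = FALSE)
  if (any(w < 0)) stop("`weights` must be non-negative", call. = FALSE)
  w <- w / sum(w)
  I <- crossprod(X, X * (w * p * (1 - p)))
  I <- (I + t(I)) / 2  # enforce exact symmetry against float round-off
  out <- structure(
    list(matrix = I, predictor_names = colnames(X), n_source = nrow(X)),
    class = "unit_information"
  )
  kappa_I <- kappa(I, exact = TRUE)
  if (!is.finite(kappa_I) || kappa_I > 1e10) {
    ev <- eigen(I, symmetric = TRUE)
    null_dir <- ev$vectors[, which.min(ev$values)]
    culprit <- paste(colnames(X)[order(-abs(null_dir))][1:2], collapse = ", ")
    attr(out, "rank_warning") <- sprintf(
      "unit information is near-singular (condition number %.3g); check columns: %s",
      kappa_I, culprit)
    warning(attr(out, "rank_warning"), call. = FALSE)
  }
  out
}

#' @export
print.unit_information <- function(x, ...) {
  cat("<unit_information> formed from", x$n_source, "rows\n")
  print(round(x$matrix, 6))
  invisible(x)
}

#' @export
tidy.unit_information <- function(x, ...) {
  m <- x$matrix
  tibble::as_tibble(as.data.frame(m), rownames = "term")
}

# Cholesky factor cached on first use; quadratic forms x' I^{-1} x are then
# two triangular solves per batch, never forming the inverse.
info_chol <- function(info) {
  stopifnot(inherits(info, "unit_information"))
  ev <- eigen(info$matrix, symmetric = TRUE)
  if (min(ev$values) <= 1e-10 * max(ev$values)) {
    dir <- ev$vectors[, which.min(ev$values)]
    names(dir) <- info$predictor_names
    stop(sprintf("unit information matrix is singular; null-space direction loads on: %s",
                 paste(sprintf("%s (%.2f)", names(dir), dir), collapse = ", ")),
         call. = FALSE)
  }
  chol(info$matrix)
}

# x I^{-1} x' for each row of X (matrix or vector), via the Cholesky factor.
quad_form_inv <- function(info, X) {
  X <- rbind(X)
  if (ncol(X) != nrow(info$matrix)) {
    stop("design row length does not match the information matrix", call. = FALSE)
  }
  R <- info_chol(info)
  Z <- backsolve(R, t(X), transpose = TRUE)
  colSums(Z^2)
}

#' Variance of an individual's logit risk estimate
#'
#' For a development sample of size `n`, the anticipated variance of the
#' estimated logit risk for an individual with design row \eqn{x_{new}} is
#' \deqn{\mathrm{var}(\mathrm{logit}(\hat p_{new})) = n^{-1}\, x_{new} \mathbf{I}^{-1} x_{new}'.}
#' It scales exactly as 1/n and is the quantity driving all interval widths
#' and instability metrics.
#'
#' @param x_new A design row `(1, x1, ..., xP)`, a matrix of such rows, or a
#'   data frame of predictor values (the intercept column is added using the
#'   ordering stored in `info`).
#' @param info A [unit_information()].
#' @param n Development sample size (>= 1).
#' @return Numeric vector of variances, one per row of `x_new`.
#' @examples
#' m <- core_model(alpha = 0, betas = c(x = 0))
#' info <- unit_information(data.frame(x = 0), m)
#' variance_logit(c(1, 0), info, n = 100)  # 1 / (100 * 0.25)
#' @export
variance_logit <- function(x_new, info, n) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  X <- as_design_rows(x_new, info)
  quad_form_inv(info, X) / n
}

as_design_rows <- function(x_new, info) {
  P1 <- nrow(info$matrix)
  if (is.data.frame(x_new)) {
    nm <- setdiff(info$predictor_names, "(Intercept)")
    missing_cols <- setdiff(nm, names(x_new))
    if (length(missing_cols)) {
      stop("missing predictor columns: ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    }
    return(cbind(1, as.matrix(tibble::as_tibble(x_new)[nm])))
  }
  X <- rbind(x_new)
  if (ncol(X) == P1 - 1) X <- cbind(1, X)
  if (ncol(X) != P1) {
    stop("design row has wrong length for this information matrix", call. = FALSE)
  }
  X
}

#' Anticipated variance-covariance matrix of model coefficients
#'
#' @param info A [unit_information()].
#' @param n Development sample size.
#' @return The (P+1) x (P+1) matrix \eqn{n^{-1}\mathbf{I}^{-1}}: the
#'   anticipated covariance of maximum-likelihood estimates were the core
#'   model fitted to `n` participants drawn from this case-mix.
#' @export
vcov_beta <- function(info, n) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  R <- info_chol(info)
  V <- chol2inv(R) / n
  dimnames(V) <- list(info$predictor_names, info$predictor_names)
  V
}
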