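#' Logit and inverse-logit
#'
#' Convenience link functions used throughout: risks live on the probability
#' scale, uncertainty is propagated on the logit scale.
#'
#' @param p Probability in (0, 1).
#' @param x Real number.
#' @return `logit()` returns `log(p / (1 - p))`; `invlogit()` its inverse.
#' @examples
#' invlogit(logit(0.2))
#' @export
logit <- function(p) {
  stopifnot(is.numeric(p))
  log(p / (1 - p))
}

#' @rdname logit
#' @export
invlogit <- function(x) {
  stopifnot(is.numeric(x))
  1 / (1 + exp(-x))
}

# Run `expr` under a locally-set RNG seed, restoring global state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a per-row seed from a global seed and a row index, kept within the
# 32-bit range R accepts, so one row's draws never depend on another row's.
row_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(i) * 7919) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
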