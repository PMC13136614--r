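#' Evaluate a sum of logistic (sigmoid) basis functions
#'
#' `f(t) = offset + sum_k A_k * plogis((t - m_k) / s_k)`. Negative slopes
#' `s_k` give decreasing sigmoids. This basis is shared by the growth-rate
#' baseline interpolator, the synthetic ground-truth growth profile, and the
#' pseudo-concentration basis fits.
#'
#' @param par parameter vector `c(A1, m1, s1, ..., Ak, mk, sk, offset)`.
#' @param t evaluation times (days).
#' @return numeric vector `f(t)`.
#' @export
sigmoid_sum <- function(par, t) {
  k <- (length(par) - 1L) %/% 3L
  stopifnot(length(par) == 3L * k + 1L)
  out <- rep(par[3L * k + 1L], length(t))
  for (i in seq_len(k)) {
    A <- par[3L * i - 2L]; m <- par[3L * i - 1L]; s <- par[3L * i]
    out <- out + A * stats::plogis((t - m) / s)
  }
  out
}

#' Analytic time derivative of a sigmoid sum
#'
#' @inheritParams sigmoid_sum
#' @return numeric vector `f'(t)`.
#' @export
sigmoid_sum_deriv <- function(par, t) {
  k <- (length(par) - 1L) %/% 3L
  out <- numeric(length(t))
  for (i in seq_len(k)) {
    A <- par[3L * i - 2L]; m <- par[3L * i - 1L]; s <- par[3L * i]
    p <- stats::plogis((t - m) / s)
    out <- out + A * p * (1 - p) / s
  }
  out
}

# Run expr with a local RNG state; restores the caller's state after.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
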