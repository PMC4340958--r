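#' Hill activation and repression factors
#'
#' Saturating regulatory factors used in Hill-modulated propensities.
#' `hill_activation()` returns \eqn{x^n / (K^n + x^n)}, the fractional
#' activation of a promoter by `x` copies of a transcription factor with
#' dissociation constant `K` and Hill coefficient `n`. `hill_repression()`
#' returns \eqn{1 / (1 + (x/K)^n)}, the fraction of unrepressed activity
#' remaining at `x` copies of a repressor (here, a microRNA acting on its
#' target mRNA); the two are complementary,
#' `hill_repression(x, K, n) == 1 - hill_activation(x, K, n)`.
#'
#' @param x Copy number (or concentration) of the regulator; vectorised,
#'   must be non-negative.
#' @param K Dissociation constant, same units as `x`; must be positive.
#' @param n Hill coefficient; must be positive.
#' @return A numeric vector of factors in `[0, 1]`.
#' @examples
#' hill_activation(200, K = 200, n = 2)  # half-saturation
#' hill_repression(42, K = 60, n = 2)
#' @export
hill_activation <- function(x, K, n) {
  check_hill_args(x, K, n)
  u <- (x / K)^n
  u / (1 + u)
}

#' @rdname hill_activation
#' @export
hill_repression <- function(x, K, n) {
  check_hill_args(x, K, n)
  1 / (1 + (x / K)^n)
}

check_hill_args <- function(x, K, n) {
  if (!is.numeric(x) || any(x < 0)) {
    abort("`x` must be a non-negative copy number.")
  }
  if (!is.numeric(K) || length(K) != 1L || K <= 0) {
    abort("`K` must be a single positive dissociation constant.")
  }
  if (!is.numeric(n) || length(n) != 1L || n <= 0) {
    abort("`n` must be a single positive Hill coefficient.")
  }
  invisible(NULL)
}
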