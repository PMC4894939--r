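#' Numerical inverse Laplace transform (fixed Talbot)
#'
#' Abate-Valko fixed-Talbot inversion of a transform `F(s)` that can be
#' evaluated at complex `s` (closed forms or analytic continuations).  The
#' contour crosses the real axis at `r = 2N/(5t) + shift`; all singularities
#' of `F` must lie to the left of this crossing, so transforms with a
#' rightmost real singularity `s*` need `shift` only when `2N/(5t) <= s*`.
#'
#' @param F function of one complex argument.
#' @param t positive times (vectorized).
#' @param N number of contour nodes (32 by default; accuracy is roughly
#'   `0.6 N` significant digits for smooth transforms).
#' @param shift real shift `c`: inverts `F(s + c)` and multiplies by
#'   `exp(c t)`, moving the contour right of singularities with positive real
#'   part.
#' @return Numeric vector of inverse-transform values.
#' @export
invert_talbot <- function(F, t, N = 32L, shift = 0) {
  vapply(t, function(tt) {
    stopifnot(tt > 0)
    r <- 2 * N / (5 * tt)
    theta <- pi * seq_len(N - 1) / N
    s <- r * theta * (1 / tan(theta) + 1i)
    sigma <- theta + (theta / tan(theta) - 1) / tan(theta)
    Fv <- vapply(s + shift, F, complex(1))
    term0 <- 0.5 * exp(r * tt) * Re(F(r + shift))
    terms <- Re(exp(tt * s) * Fv * (1 + 1i * sigma))
    exp(shift * tt) * (r / N) * (term0 + sum(terms))
  }, numeric(1))
}

#' Numerical inverse Laplace transform (Gaver-Stehfest)
#'
#' Stehfest inversion using only real, positive transform evaluations
#' `F(k log(2)/t)`.  Suited to transforms that are defined by numerical
#' integration and therefore cannot be continued into the complex plane.
#' Accuracy in double precision peaks around `n = 12`--`16` terms (roughly
#' 6--8 significant digits for smooth targets).
#'
#' @param F function of one real positive argument.
#' @param t positive times (vectorized).
#' @param n even number of terms.
#' @return Numeric vector of inverse-transform values.
#' @export
invert_stehfest <- function(F, t, n = 14L) {
  stopifnot(n %% 2 == 0)
  V <- stehfest_weights(n)
  vapply(t, function(tt) {
    stopifnot(tt > 0)
    a <- log(2) / tt
    a * sum(V * vapply(seq_len(n) * a, F, numeric(1)))
  }, numeric(1))
}

stehfest_weights <- function(n) {
  m <- n / 2
  V <- numeric(n)
  for (k in seq_len(n)) {
    j0 <- floor((k + 1) / 2)
    s <- 0
    for (j in j0:min(k, m)) {
      s <- s + j^m * factorial(2 * j) /
        (factorial(m - j) * factorial(j) * factorial(j - 1) *
         factorial(k - j) * factorial(2 * j - k))
    }
    V[k] <- (-1)^(k + m) * s
  }
  V
}
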