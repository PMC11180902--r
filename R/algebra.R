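# Operational laws, score/accuracy, comparison and distance for linguistic
# interval-valued q-rung orthopair fuzzy evaluations. All arithmetic runs on
# tau-normalized reals in [0, 1]; intermediate probabilities are clamped to
# [0, 1] to guard q-th roots against floating-point underflow.

clamp01 <- function(p) pmin(pmax(p, 0), 1)

# unit-scale components as a named list of four vectors
unit_components <- function(x, tau) {
  lapply(as.list(x[fz_cols]), function(v) v / tau)
}

rebuild <- function(mu_lo, mu_hi, nu_lo, nu_hi, tau) {
  tibble::tibble(
    mu_lo = tau * clamp01(mu_lo), mu_hi = tau * clamp01(mu_hi),
    nu_lo = tau * clamp01(nu_lo), nu_hi = tau * clamp01(nu_hi)
  )
}

# probabilistic sum under the q-power transform: (a^q + b^q - a^q b^q)^(1/q),
# i.e. (1 - (1-a^q)(1-b^q))^(1/q), in log space to avoid cancellation for
# small endpoints
q_prob_sum <- function(a, b, q) {
  (-expm1(log1p(-clamp01(a^q)) + log1p(-clamp01(b^q))))^(1 / q)
}

# elementwise 1 - (1 - b)^e on probabilities b, stable for small b; e = 0
# yields exactly 0 even at b = 1 (where log1p(-b) is -Inf)
one_minus_pow <- function(b, e) {
  out <- -expm1(e * log1p(-clamp01(b)))
  out[e == 0] <- 0
  out
}

#' Score of a fuzzy evaluation
#'
#' The score summarizes an evaluation as a single number on the unit scale,
#' \deqn{K = \tfrac14\left[(1 + a^q - c^q) + (1 + b^q - d^q)\right]}
#' where \eqn{a, b} are the tau-normalized membership endpoints and
#' \eqn{c, d} the non-membership endpoints. Larger is better; the score of
#' the swapped (complement) evaluation is `1 - K`.
#'
#' @param x A tibble of evaluations (see [tlivq()]).
#' @param q Rung parameter.
#' @param tau Scale granularity.
#' @param as_two_tuple If `TRUE`, return the score re-expressed on the term
#'   scale as a 2-tuple tibble (`index`, `offset`) of `tau * K` instead of
#'   the unit-scale numeric.
#' @return Numeric vector in `[0, 1]`, or a 2-tuple tibble.
#' @examples
#' fz_score(tlivq(3.4154, 4.1953, 5.2148, 6.0315, tau = 8), q = 6, tau = 8)
#' @export
fz_score <- function(x, q, tau, as_two_tuple = FALSE) {
  check_q(q)
  check_tlivq(x, tau)
  u <- unit_components(x, tau)
  k <- 0.25 * ((1 + u$mu_lo^q - u$nu_lo^q) + (1 + u$mu_hi^q - u$nu_hi^q))
  if (as_two_tuple) tl_delta(tau * k, tau) else k
}

#' Accuracy of a fuzzy evaluation
#'
#' The mean of the q-th powers of all four tau-normalized endpoints,
#' \eqn{F = \tfrac14(a^q + b^q + c^q + d^q)}; used as the tiebreaker when
#' scores coincide.
#'
#' @inheritParams fz_score
#' @return Numeric vector in `[0, 1]`, or a 2-tuple tibble.
#' @export
fz_accuracy <- function(x, q, tau, as_two_tuple = FALSE) {
  check_q(q)
  check_tlivq(x, tau)
  u <- unit_components(x, tau)
  f <- 0.25 * (u$mu_lo^q + u$mu_hi^q + u$nu_lo^q + u$nu_hi^q)
  if (as_two_tuple) tl_delta(tau * f, tau) else f
}

#' Compare fuzzy evaluations
#'
#' Orders evaluations by score; scores within `tol` of each other are broken
#' by accuracy; a tie on both yields 0.
#'
#' @param x,y Tibbles of evaluations (rows recycled to a common length).
#' @inheritParams fz_score
#' @param tol Absolute tolerance below which two scores (or accuracies)
#'   count as equal.
#' @return Integer vector: `1` where `x > y`, `-1` where `x < y`, `0` on ties.
#' @export
fz_compare <- function(x, y, q, tau, tol = 1e-9) {
  check_tlivq(x, tau); check_tlivq(y, tau)
  check_same_shape(x, y)
  xy <- recycle2(x, y)
  ds <- fz_score(xy[[1]], q, tau) - fz_score(xy[[2]], q, tau)
  da <- fz_accuracy(xy[[1]], q, tau) - fz_accuracy(xy[[2]], q, tau)
  out <- sign(ds) * (abs(ds) > tol)
  tie <- out == 0
  out[tie] <- sign(da[tie]) * (abs(da[tie]) > tol)
  as.integer(out)
}

#' Sum of fuzzy evaluations
#'
#' The addition law: membership endpoints combine by the probabilistic sum
#' under the q-power transform, non-membership endpoints multiply (on the
#' unit scale). The evaluation `([J0, J0], [Jtau, Jtau])` is the additive
#' identity.
#'
#' @inheritParams fz_compare
#' @return A tibble of evaluations.
#' @export
fz_add <- function(x, y, q, tau) {
  check_q(q)
  check_tlivq(x, tau); check_tlivq(y, tau)
  check_same_shape(x, y)
  xy <- recycle2(x, y)
  u <- unit_components(xy[[1]], tau); v <- unit_components(xy[[2]], tau)
  rebuild(
    q_prob_sum(u$mu_lo, v$mu_lo, q), q_prob_sum(u$mu_hi, v$mu_hi, q),
    u$nu_lo * v$nu_lo, u$nu_hi * v$nu_hi, tau
  )
}

#' Product of fuzzy evaluations
#'
#' The multiplication law, dual to [fz_add()]: membership endpoints multiply,
#' non-membership endpoints combine by the q-power probabilistic sum. The
#' evaluation `([Jtau, Jtau], [J0, J0])` is the multiplicative identity.
#'
#' @inheritParams fz_compare
#' @return A tibble of evaluations.
#' @export
fz_mul <- function(x, y, q, tau) {
  check_q(q)
  check_tlivq(x, tau); check_tlivq(y, tau)
  check_same_shape(x, y)
  xy <- recycle2(x, y)
  u <- unit_components(xy[[1]], tau); v <- unit_components(xy[[2]], tau)
  rebuild(
    u$mu_lo * v$mu_lo, u$mu_hi * v$mu_hi,
    q_prob_sum(u$nu_lo, v$nu_lo, q), q_prob_sum(u$nu_hi, v$nu_hi, q), tau
  )
}

#' Scalar multiple of a fuzzy evaluation
#'
#' The law for \eqn{\varepsilon R}: membership endpoints map to
#' \eqn{(1 - (1 - a^q)^\varepsilon)^{1/q}}, non-membership endpoints to
#' \eqn{a^\varepsilon}. This is the single-element weighting step of the
#' MABAC pipeline.
#'
#' @param eps Non-negative scalar multiplier (recycled over rows of `x`).
#' @inheritParams fz_score
#' @return A tibble of evaluations.
#' @examples
#' fz_scalar_mul(0.2480, tlivq(4.3023, 5.2651, 1.4246, 2.5614, tau = 8),
#'               q = 6, tau = 8)
#' @export
fz_scalar_mul <- function(eps, x, q, tau) {
  check_q(q)
  if (any(!is.finite(eps)) || any(eps < 0)) {
    rlang::abort("`eps` must be non-negative and finite.")
  }
  check_tlivq(x, tau)
  u <- unit_components(x, tau)
  rebuild(
    one_minus_pow(u$mu_lo^q, eps)^(1 / q),
    one_minus_pow(u$mu_hi^q, eps)^(1 / q),
    u$nu_lo^eps, u$nu_hi^eps, tau
  )
}

#' Power of a fuzzy evaluation
#'
#' The law for \eqn{R^\varepsilon}, dual to [fz_scalar_mul()]: membership
#' endpoints map to \eqn{a^\varepsilon}, non-membership endpoints to
#' \eqn{(1 - (1 - c^q)^\varepsilon)^{1/q}}.
#'
#' @inheritParams fz_scalar_mul
#' @return A tibble of evaluations.
#' @export
fz_power <- function(x, eps, q, tau) {
  check_q(q)
  if (any(!is.finite(eps)) || any(eps < 0)) {
    rlang::abort("`eps` must be non-negative and finite.")
  }
  check_tlivq(x, tau)
  u <- unit_components(x, tau)
  rebuild(
    u$mu_lo^eps, u$mu_hi^eps,
    one_minus_pow(u$nu_lo^q, eps)^(1 / q),
    one_minus_pow(u$nu_hi^q, eps)^(1 / q), tau
  )
}

#' Complement of a fuzzy evaluation
#'
#' Swaps the membership and non-membership intervals; an involution. This is
#' also the cost-attribute normalization of the MABAC pipeline, and it links
#' the dual operational laws: `fz_mul` is `fz_add` conjugated by the
#' complement, and likewise `fz_power` and `fz_scalar_mul`.
#'
#' @inheritParams fz_score
#' @return A tibble of evaluations.
#' @export
fz_complement <- function(x, tau) {
  check_tlivq(x, tau)
  tibble::tibble(mu_lo = x$nu_lo, mu_hi = x$nu_hi,
                 nu_lo = x$mu_lo, nu_hi = x$mu_hi)
}

#' Normalized Hamming distance between fuzzy evaluations
#'
#' \deqn{d = \tfrac14 \sum |x_1^q - x_2^q|} over the four tau-normalized
#' endpoints. A metric on evaluations with values in `[0, 1]`.
#'
#' @inheritParams fz_compare
#' @param as_two_tuple If `TRUE`, return `tau * d` re-encoded as a 2-tuple
#'   tibble.
#' @return Numeric vector in `[0, 1]`, or a 2-tuple tibble.
#' @export
fz_hamming <- function(x, y, q, tau, as_two_tuple = FALSE) {
  check_q(q)
  check_tlivq(x, tau); check_tlivq(y, tau)
  check_same_shape(x, y)
  xy <- recycle2(x, y)
  u <- unit_components(xy[[1]], tau); v <- unit_components(xy[[2]], tau)
  d <- 0.25 * (abs(u$mu_lo^q - v$mu_lo^q) + abs(u$mu_hi^q - v$mu_hi^q) +
                 abs(u$nu_lo^q - v$nu_lo^q) + abs(u$nu_hi^q - v$nu_hi^q))
  if (as_two_tuple) tl_delta(tau * d, tau) else d
}
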