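# Weighted averaging and weighted geometric aggregation of fuzzy
# evaluations, in closed form and as folds over the operational laws.

#' Resolve an aggregation weight vector
#'
#' Weights must be non-negative reals in `[0, 1]`. The theory requires them
#' to sum to one, but published weight vectors do not always comply, so three
#' policies are offered: `"as-given"` (default) uses the weights verbatim and
#' warns when the sum deviates from 1 by more than `tol`; `"renormalize"`
#' divides by the sum; `"strict"` errors on deviation.
#'
#' @param w Numeric weight vector.
#' @param policy One of `"as-given"`, `"renormalize"`, `"strict"`.
#' @param tol Allowed deviation of `sum(w)` from 1.
#' @return The resolved numeric weight vector.
#' @export
resolve_weights <- function(w, policy = c("as-given", "renormalize", "strict"),
                            tol = 1e-6) {
  policy <- match.arg(policy)
  if (!is.numeric(w) || !length(w) || any(!is.finite(w)) ||
      any(w < 0) || any(w > 1)) {
    rlang::abort("weights must be numeric values in [0, 1].")
  }
  dev <- abs(sum(w) - 1)
  if (dev > tol) {
    msg <- sprintf("weights sum to %.4f, not 1 (deviation %.2g)", sum(w), dev)
    switch(policy,
      "as-given" = rlang::warn(paste0(msg, "; using them verbatim.")),
      "renormalize" = return(w / sum(w)),
      "strict" = rlang::abort(msg)
    )
  }
  w
}

agg_checks <- function(x, w, q, tau) {
  check_q(q)
  check_tlivq(x, tau)
  if (nrow(x) == 0) rlang::abort("cannot aggregate an empty set of evaluations.")
  if (length(w) != nrow(x)) {
    rlang::abort(sprintf(
      "got %d weights for %d evaluations.", length(w), nrow(x)
    ))
  }
}

# weighted product with 0^0 = 1 so that zero-weight elements never contribute
wprod <- function(a, w) prod(a^w)

# 1 - prod((1 - b_j)^(w_j)) over probabilities b, in log space; zero-weight
# terms are dropped so that b = 1 there cannot poison the sum
one_minus_wprod <- function(b, w) {
  keep <- w != 0
  if (!any(keep)) return(0)
  -expm1(sum(w[keep] * log1p(-clamp01(b[keep]))))
}

#' Weighted averaging aggregation
#'
#' Aggregates a set of evaluations into one: membership endpoints combine as
#' \eqn{(1 - \prod_j (1 - a_j^q)^{w_j})^{1/q}}, non-membership endpoints as
#' \eqn{\prod_j c_j^{w_j}}. This closed form equals the fold
#' \eqn{\oplus_j w_j R_j} of the operational laws ([fz_add()],
#' [fz_scalar_mul()]); `method = "fold"` computes that fold instead, which is
#' useful as an independent cross-check. The operator is idempotent,
#' monotone, and bounded when the weights sum to one.
#'
#' @param x A tibble of evaluations, one row per element to aggregate.
#' @param w Weight vector, one weight per row of `x`.
#' @param q Rung parameter.
#' @param tau Scale granularity.
#' @param policy Weight policy, see [resolve_weights()].
#' @param method `"closed"` (default) or `"fold"`.
#' @return A single-row tibble of evaluations.
#' @examples
#' x <- tlivq(c(2, 3), c(3, 5), c(4, 2), c(5, 4), tau = 8)
#' fz_wa(x, c(0.5, 0.5), q = 6, tau = 8)
#' @export
fz_wa <- function(x, w, q, tau, policy = "as-given",
                  method = c("closed", "fold")) {
  method <- match.arg(method)
  agg_checks(x, w, q, tau)
  w <- resolve_weights(w, policy)
  if (method == "fold") {
    terms <- purrr::map(seq_len(nrow(x)),
                        function(j) fz_scalar_mul(w[[j]], x[j, ], q, tau))
    return(purrr::reduce(terms, fz_add, q = q, tau = tau))
  }
  u <- unit_components(x, tau)
  rebuild(
    one_minus_wprod(u$mu_lo^q, w)^(1 / q),
    one_minus_wprod(u$mu_hi^q, w)^(1 / q),
    wprod(u$nu_lo, w), wprod(u$nu_hi, w), tau
  )
}

#' Weighted geometric aggregation
#'
#' The geometric dual of [fz_wa()]: membership endpoints combine as
#' \eqn{\prod_j a_j^{w_j}}, non-membership endpoints as
#' \eqn{(1 - \prod_j (1 - c_j^q)^{w_j})^{1/q}}. Equals the fold
#' \eqn{\otimes_j R_j^{w_j}} and the complement-conjugate of [fz_wa()].
#' (In the source literature this operator appears under both the "WG" and
#' "WJ" names.)
#'
#' @inheritParams fz_wa
#' @return A single-row tibble of evaluations.
#' @export
fz_wg <- function(x, w, q, tau, policy = "as-given",
                  method = c("closed", "fold")) {
  method <- match.arg(method)
  agg_checks(x, w, q, tau)
  w <- resolve_weights(w, policy)
  if (method == "fold") {
    terms <- purrr::map(seq_len(nrow(x)),
                        function(j) fz_power(x[j, ], w[[j]], q, tau))
    return(purrr::reduce(terms, fz_mul, q = q, tau = tau))
  }
  u <- unit_components(x, tau)
  rebuild(
    wprod(u$mu_lo, w), wprod(u$mu_hi, w),
    one_minus_wprod(u$nu_lo^q, w)^(1 / q),
    one_minus_wprod(u$nu_hi^q, w)^(1 / q), tau
  )
}

#' Equal-weight geometric mean of evaluations
#'
#' [fz_wg()] with uniform weights `1/n`; the border approximation area of
#' the MABAC pipeline is this mean taken over alternatives.
#'
#' @inheritParams fz_wa
#' @return A single-row tibble of evaluations.
#' @export
fz_geometric_mean <- function(x, q, tau) {
  if (nrow(x) == 0) rlang::abort("cannot aggregate an empty set of evaluations.")
  fz_wg(x, rep(1 / nrow(x), nrow(x)), q, tau, policy = "strict")
}
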