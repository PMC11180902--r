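#' Construct linguistic interval-valued fuzzy evaluations
#'
#' An evaluation is an interval-valued q-rung orthopair fuzzy number whose
#' four interval endpoints are expressed on a linguistic term scale: a
#' membership interval `[mu_lo, mu_hi]` and a non-membership interval
#' `[nu_lo, nu_hi]`, each endpoint a real in `[0, tau]` (the numeric value of
#' a linguistic 2-tuple). `tlivq()` builds a tibble of such evaluations, one
#' per row; every algebra function in the package operates row-wise on
#' tibbles of this shape, so evaluations compose freely with dplyr verbs.
#'
#' Interval ordering (`mu_lo <= mu_hi`, `nu_lo <= nu_hi`) is always enforced.
#' The rung constraint \eqn{(\mu_{hi}/\tau)^q + (\nu_{hi}/\tau)^q \le 1} is
#' checked by [fz_validate()] according to a validation mode.
#'
#' @param mu_lo,mu_hi Lower/upper membership endpoints on the `[0, tau]`
#'   scale (numeric vectors, recycled to a common length).
#' @param nu_lo,nu_hi Lower/upper non-membership endpoints.
#' @param tau Scale granularity.
#'
#' @return A tibble with numeric columns `mu_lo`, `mu_hi`, `nu_lo`, `nu_hi`.
#' @examples
#' tlivq(1, 7, 2, 4, tau = 8)
#' @export
tlivq <- function(mu_lo, mu_hi, nu_lo, nu_hi, tau) {
  n <- max(length(mu_lo), length(mu_hi), length(nu_lo), length(nu_hi))
  x <- tibble::tibble(
    mu_lo = rep_len(as.numeric(mu_lo), n),
    mu_hi = rep_len(as.numeric(mu_hi), n),
    nu_lo = rep_len(as.numeric(nu_lo), n),
    nu_hi = rep_len(as.numeric(nu_hi), n)
  )
  check_tlivq(x, tau)
  x
}

fz_cols <- c("mu_lo", "mu_hi", "nu_lo", "nu_hi")

# structural checks: presence of the four columns, range, interval ordering
check_tlivq <- function(x, tau, where = "evaluation") {
  missing <- setdiff(fz_cols, names(x))
  if (length(missing)) {
    rlang::abort(paste0(
      "expected columns mu_lo, mu_hi, nu_lo, nu_hi; missing: ",
      paste(missing, collapse = ", ")
    ))
  }
  vals <- as.matrix(x[fz_cols])
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > tau)) {
    bad <- which(rowSums(!is.finite(vals) | vals < 0 | vals > tau) > 0)
    rlang::abort(sprintf(
      "%s endpoints must lie in [0, %d]; offending row(s): %s",
      where, tau, paste(bad, collapse = ", ")
    ))
  }
  if (any(x$mu_lo > x$mu_hi) || any(x$nu_lo > x$nu_hi)) {
    bad <- which(x$mu_lo > x$mu_hi | x$nu_lo > x$nu_hi)
    rlang::abort(sprintf(
      "interval ordering violated (lower endpoint > upper) in row(s): %s",
      paste(bad, collapse = ", ")
    ))
  }
  invisible(x)
}

#' Validate evaluations against the rung constraint
#'
#' Checks each evaluation against the defining constraint of the fuzzy
#' number family, \eqn{(\mu_{hi}/\tau)^q + (\nu_{hi}/\tau)^q \le 1}. The scale
#' range and interval ordering are always enforced; the rung constraint is
#' handled per `mode`: `"strict"` raises an error naming the offending rows,
#' `"warn"` (the default) emits a warning and passes, `"off"` skips the check.
#' The warn default reflects that published data sets are not always
#' constraint-feasible at every rung, notably for `q < 1`.
#'
#' @param x A tibble of evaluations (see [tlivq()]).
#' @param q Rung parameter (positive real).
#' @param tau Scale granularity.
#' @param mode One of `"warn"`, `"strict"`, `"off"`.
#'
#' @return `x`, invisibly, with a tibble of violations (columns `row`,
#'   `mu_hi`, `nu_hi`, `excess`) attached as attribute `"violations"`.
#' @examples
#' x <- tlivq(1, 7, 2, 4, tau = 8)
#' fz_validate(x, q = 6, tau = 8)
#' @export
fz_validate <- function(x, q, tau, mode = c("warn", "strict", "off")) {
  mode <- match.arg(mode)
  check_q(q)
  check_tlivq(x, tau)
  viol <- tibble::tibble(row = integer(), mu_hi = numeric(),
                         nu_hi = numeric(), excess = numeric())
  if (mode != "off") {
    lhs <- (x$mu_hi / tau)^q + (x$nu_hi / tau)^q
    bad <- which(lhs > 1 + 1e-12)
    if (length(bad)) {
      viol <- tibble::tibble(
        row = bad, mu_hi = x$mu_hi[bad], nu_hi = x$nu_hi[bad],
        excess = lhs[bad] - 1
      )
      msg <- sprintf(
        "rung constraint (mu_hi/tau)^q + (nu_hi/tau)^q <= 1 violated at q = %g in %d row(s): %s",
        q, length(bad), paste(utils::head(bad, 10), collapse = ", ")
      )
      if (mode == "strict") rlang::abort(msg) else rlang::warn(msg)
    }
  }
  attr(x, "violations") <- viol
  invisible(x)
}

check_q <- function(q) {
  if (!is.numeric(q) || length(q) != 1 || !is.finite(q) || q <= 0) {
    rlang::abort("`q` must be a single positive real.")
  }
}

check_same_shape <- function(x, y) {
  if (nrow(x) != nrow(y) && nrow(x) != 1 && nrow(y) != 1) {
    rlang::abort("operands must have the same number of rows (or one row).")
  }
}

recycle2 <- function(x, y) {
  n <- max(nrow(x), nrow(y))
  list(x[rep_len(seq_len(nrow(x)), n), fz_cols],
       y[rep_len(seq_len(nrow(y)), n), fz_cols])
}

#' Express evaluations as linguistic 2-tuples
#'
#' Expands the four numeric endpoints of each evaluation into (term index,
#' symbolic translation) pairs, the form in which results are conventionally
#' reported.
#'
#' @inheritParams fz_validate
#' @return A tibble with eight columns `<endpoint>_index`,
#'   `<endpoint>_offset` for each of `mu_lo`, `mu_hi`, `nu_lo`, `nu_hi`.
#' @examples
#' as_two_tuples(tlivq(3.4154, 4.1953, 5.2148, 6.0315, tau = 8), tau = 8)
#' @export
as_two_tuples <- function(x, tau) {
  check_tlivq(x, tau)
  out <- purrr::map(fz_cols, function(col) {
    tt <- tl_delta(x[[col]], tau)
    names(tt) <- paste0(col, c("_index", "_offset"))
    tt
  })
  dplyr::bind_cols(out)
}

#' Format evaluations in the conventional bracket notation
#'
#' @inheritParams fz_validate
#' @param digits Display digits for symbolic translations.
#' @return Character vector like
#'   `"([(J3, 0.4154), (J4, 0.1953)], [(J5, 0.2148), (J6, 0.0315)])"`.
#' @export
format_tlivq <- function(x, tau, digits = 4) {
  check_tlivq(x, tau)
  f <- function(col) format_two_tuple(x[[col]], tau, digits = digits)
  sprintf("([%s, %s], [%s, %s])",
          f("mu_lo"), f("mu_hi"), f("nu_lo"), f("nu_hi"))
}
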