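#' Define a linguistic term scale
#'
#' A linguistic term set \eqn{\{J_0, \dots, J_\tau\}} on which all fuzzy
#' evaluations live. Term indices are 0-based, so a scale of granularity
#' `tau` has `tau + 1` terms.
#'
#' @param tau Integer granularity bound (>= 2); terms run from `J0` to
#'   `J<tau>`.
#' @param labels Optional character vector of `tau + 1` term names, ordered
#'   from the lowest term to the highest.
#'
#' @return An object of class `linguistic_scale`: a list with elements
#'   `tau` and `labels`.
#' @examples
#' linguistic_scale(8)
#' @export
linguistic_scale <- function(tau, labels = NULL) {
  if (!is.numeric(tau) || length(tau) != 1 || tau != round(tau) || tau < 2) {
    rlang::abort("`tau` must be a single integer >= 2.")
  }
  tau <- as.integer(tau)
  if (!is.null(labels) && length(labels) != tau + 1L) {
    rlang::abort(sprintf(
      "`labels` must have exactly tau + 1 = %d entries, got %d.",
      tau + 1L, length(labels)
    ))
  }
  structure(list(tau = tau, labels = labels), class = "linguistic_scale")
}

#' @export
print.linguistic_scale <- function(x, ...) {
  cat(sprintf("<linguistic_scale> %d terms (J0..J%d)\n", x$tau + 1L, x$tau))
  if (!is.null(x$labels)) {
    cat(paste0("  J", seq_along(x$labels) - 1L, ": ", x$labels, collapse = "\n"), "\n")
  }
  invisible(x)
}

# round half away from zero toward the larger index; all scale values are
# non-negative here so this is plain half-up
round_half_up <- function(x) floor(x + 0.5)

#' Convert a numeric scale value to a linguistic 2-tuple
#'
#' The 2-tuple representation model maps a real \eqn{\xi \in [0, \tau]} to a
#' pair (term index, symbolic translation): the index is the nearest term
#' (half-way points round up) and the symbolic translation is the remainder,
#' which always lies in \eqn{[-0.5, 0.5)}. At \eqn{\xi = \tau} the index is
#' `tau` and the translation is 0.
#'
#' @param xi Numeric vector of values in `[0, tau]`.
#' @param tau Scale granularity (see [linguistic_scale()]).
#'
#' @return A tibble with integer column `index` and numeric column `offset`
#'   (the symbolic translation), one row per element of `xi`.
#' @seealso [tl_delta_inv()] for the inverse conversion.
#' @examples
#' tl_delta(c(3.4154, 4.5, 0), tau = 8)
#' @export
tl_delta <- function(xi, tau) {
  if (!is.numeric(xi)) rlang::abort("`xi` must be numeric.")
  bad <- which(xi < 0 | xi > tau)
  if (length(bad)) {
    rlang::abort(sprintf(
      "`xi` must lie in [0, %s]; offending value(s): %s",
      format(tau), paste(format(xi[bad]), collapse = ", ")
    ))
  }
  idx <- pmin(round_half_up(xi), tau)
  tibble::tibble(index = as.integer(idx), offset = xi - idx)
}

#' Convert a linguistic 2-tuple back to its numeric scale value
#'
#' @param index Integer term indices in `0:tau`.
#' @param offset Symbolic translations in `[-0.5, 0.5)`.
#' @param tau Scale granularity.
#'
#' @return Numeric vector `index + offset`, guaranteed to lie in `[0, tau]`.
#' @examples
#' tl_delta_inv(3, 0.4154, tau = 8)
#' @export
tl_delta_inv <- function(index, offset = 0, tau) {
  n <- max(length(index), length(offset))
  index <- rep_len(index, n)
  offset <- rep_len(offset, n)
  if (any(index != round(index) | index < 0 | index > tau)) {
    rlang::abort(sprintf("`index` must be an integer in 0..%d.", tau))
  }
  if (any(offset < -0.5 | offset >= 0.5)) {
    rlang::abort("`offset` must lie in [-0.5, 0.5).")
  }
  xi <- index + offset
  if (any(xi < 0 | xi > tau)) {
    rlang::abort(sprintf("index + offset must lie in [0, %d].", tau))
  }
  xi
}

#' Format scale values as 2-tuple strings
#'
#' Renders numeric scale values in the conventional `(J3, 0.4154)` form;
#' crisp terms (zero symbolic translation) are shortened to `J3`.
#'
#' @param xi Numeric vector of values in `[0, tau]`.
#' @param tau Scale granularity.
#' @param digits Display digits for the symbolic translation.
#' @param crisp_short Shorten exact terms to `J<k>`? Default `TRUE`.
#' @return Character vector.
#' @examples
#' format_two_tuple(c(3.4154, 2), tau = 8)
#' @export
format_two_tuple <- function(xi, tau, digits = 4, crisp_short = TRUE) {
  tt <- tl_delta(xi, tau)
  out <- sprintf(paste0("(J%d, %.", digits, "f)"), tt$index, tt$offset)
  if (crisp_short) {
    crisp <- abs(tt$offset) < 10^(-digits) / 2
    out[crisp] <- sprintf("J%d", tt$index[crisp])
  }
  out
}

# parse "J3" / "(J3, 0.4154)" / plain numbers into scale values
parse_two_tuple <- function(s, tau) {
  s <- gsub("−", "-", trimws(s)) # normalize unicode minus
  out <- numeric(length(s))
  for (i in seq_along(s)) {
    x <- s[[i]]
    if (grepl("^J-?[0-9]+$", x)) {
      idx <- as.numeric(sub("^J", "", x))
      if (idx != round(idx) || idx < 0 || idx > tau) {
        rlang::abort(sprintf("term '%s' is outside the scale J0..J%d", x, tau))
      }
      out[[i]] <- idx
    } else if (grepl("^\\(", x)) {
      parts <- strsplit(gsub("[()J ]", "", x), ",")[[1]]
      if (length(parts) != 2) rlang::abort(sprintf("cannot parse 2-tuple '%s'", x))
      idx <- as.numeric(parts[[1]])
      off <- as.numeric(parts[[2]])
      out[[i]] <- tl_delta_inv(idx, off, tau)
    } else {
      v <- suppressWarnings(as.numeric(x))
      if (is.na(v)) rlang::abort(sprintf("cannot parse 2-tuple '%s'", x))
      if (v < 0 || v > tau) {
        rlang::abort(sprintf("value %s is outside [0, %d]", x, tau))
      }
      out[[i]] <- v
    }
  }
  out
}
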