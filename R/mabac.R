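# The extended MABAC group-decision pipeline: expert aggregation,
# benefit/cost normalization, attribute weighting, border approximation
# area, signed distances, cumulative assessment, ranking, and rung sweeps.

#' Configure a MABAC decision problem
#'
#' Collects the parameters of a linguistic group-decision problem: the rung
#' `q`, the term-scale granularity `tau`, the expert and attribute weight
#' vectors, the benefit/cost orientation of each attribute, and the weight
#' and validation policies.
#'
#' @param q Rung parameter (positive real).
#' @param tau Scale granularity.
#' @param expert_weights Numeric weights, one per expert (may be `NULL` when
#'   the pipeline is entered at the aggregated stage). Optionally named by
#'   expert id.
#' @param attribute_weights Numeric weights, one per attribute. Optionally
#'   named by attribute id.
#' @param attribute_kinds Character vector of `"benefit"` / `"cost"`, one
#'   per attribute, optionally named; default all-benefit.
#' @param weight_policy Weight-sum policy, see [resolve_weights()].
#' @param validation Rung-constraint validation mode, see [fz_validate()].
#' @param labels Optional term labels for the scale.
#' @return An object of class `mabac_config`.
#' @export
mabac_config <- function(q = 6, tau = 8, expert_weights = NULL,
                         attribute_weights = NULL, attribute_kinds = NULL,
                         weight_policy = c("as-given", "renormalize", "strict"),
                         validation = c("warn", "strict", "off"),
                         labels = NULL) {
  check_q(q)
  structure(list(
    q = q,
    scale = linguistic_scale(tau, labels),
    expert_weights = expert_weights,
    attribute_weights = attribute_weights,
    attribute_kinds = attribute_kinds,
    weight_policy = match.arg(weight_policy),
    validation = match.arg(validation)
  ), class = "mabac_config")
}

#' @export
print.mabac_config <- function(x, ...) {
  cat(sprintf("<mabac_config> q = %g, tau = %d\n", x$q, x$scale$tau))
  cat("  expert weights:   ", paste(format(x$expert_weights), collapse = " "), "\n")
  cat("  attribute weights:", paste(format(x$attribute_weights), collapse = " "), "\n")
  kinds <- x$attribute_kinds %||% "all benefit"
  cat("  kinds:", paste(kinds, collapse = " "),
      "| weight policy:", x$weight_policy,
      "| validation:", x$validation, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# first-appearance ordering of an id column
id_levels <- function(x) unique(as.character(x))

# align a (possibly named) weight/kind vector with the ids found in the data
align_by_id <- function(values, ids, what) {
  if (is.null(values)) rlang::abort(sprintf("`%s` is required here.", what))
  if (length(values) != length(ids)) {
    rlang::abort(sprintf("`%s` has length %d but the data has %d %s.",
                         what, length(values), length(ids),
                         sub("_.*", "s", what)))
  }
  if (!is.null(names(values)) && all(nzchar(names(values)))) {
    missing <- setdiff(ids, names(values))
    if (length(missing)) {
      rlang::abort(sprintf("`%s` has no entry for: %s", what,
                           paste(missing, collapse = ", ")))
    }
    values <- values[ids]
  }
  values
}

check_rectangular <- function(data, dims) {
  counts <- dplyr::count(data, dplyr::across(dplyr::all_of(dims)))
  if (dplyr::n_distinct(counts$n) != 1 ||
      nrow(counts) != prod(purrr::map_int(dims, ~ dplyr::n_distinct(data[[.x]])))) {
    rlang::abort(sprintf(
      "decision data must be rectangular over (%s): every combination exactly once.",
      paste(dims, collapse = ", ")
    ))
  }
  invisible(data)
}

#' Aggregate per-expert evaluations into a group matrix
#'
#' Pools the experts' evaluation matrices into one alternative-by-attribute
#' matrix with the weighted averaging operator ([fz_wa()]) under the
#' configured expert weights and weight policy.
#'
#' @param data Long-format decision data: a tibble with id columns `expert`,
#'   `alternative`, `attribute` and evaluation columns `mu_lo`, `mu_hi`,
#'   `nu_lo`, `nu_hi`, one row per (expert, alternative, attribute).
#' @param config A [mabac_config()].
#' @return A tibble with one row per (alternative, attribute) and the four
#'   evaluation columns.
#' @export
aggregate_experts <- function(data, config) {
  check_tlivq(data, config$scale$tau)
  check_rectangular(data, c("expert", "alternative", "attribute"))
  experts <- id_levels(data$expert)
  w <- align_by_id(config$expert_weights, experts, "expert_weights")
  w <- resolve_weights(w, config$weight_policy)
  q <- config$q; tau <- config$scale$tau
  data |>
    dplyr::mutate(.expert_ord = match(as.character(.data$expert), experts)) |>
    dplyr::arrange(match(as.character(.data$alternative),
                         id_levels(data$alternative)),
                   match(as.character(.data$attribute),
                         id_levels(data$attribute)),
                   .data$.expert_ord) |>
    dplyr::group_by(.data$alternative, .data$attribute) |>
    dplyr::group_modify(function(g, key) wa_closed(g, w, q, tau)) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(as.character(.data$alternative),
                         id_levels(data$alternative)),
                   match(as.character(.data$attribute),
                         id_levels(data$attribute)))
}

# closed-form WA without re-resolving weights (stage-level resolution)
wa_closed <- function(x, w, q, tau) {
  u <- unit_components(x, tau)
  rebuild(
    one_minus_wprod(u$mu_lo^q, w)^(1 / q),
    one_minus_wprod(u$mu_hi^q, w)^(1 / q),
    wprod(u$nu_lo, w), wprod(u$nu_hi, w), tau
  )
}

#' Normalize an aggregated matrix by attribute orientation
#'
#' Benefit attributes pass through unchanged; cost attributes are replaced
#' by their complement (membership and non-membership intervals swapped), so
#' that "larger is better" holds in every column afterwards.
#'
#' @param matrix A tibble with `alternative`, `attribute` and evaluation
#'   columns (the output of [aggregate_experts()]).
#' @param config A [mabac_config()]; `attribute_kinds` of `NULL` means
#'   all-benefit.
#' @return A tibble of the same shape.
#' @export
normalize_attributes <- function(matrix, config) {
  tau <- config$scale$tau
  check_tlivq(matrix, tau)
  attrs <- id_levels(matrix$attribute)
  kinds <- config$attribute_kinds %||% rep("benefit", length(attrs))
  kinds <- align_by_id(kinds, attrs, "attribute_kinds")
  if (!all(kinds %in% c("benefit", "cost"))) {
    rlang::abort("`attribute_kinds` entries must be \"benefit\" or \"cost\".")
  }
  is_cost <- kinds[match(as.character(matrix$attribute), attrs)] == "cost"
  out <- matrix
  out[is_cost, fz_cols] <- fz_complement(matrix[is_cost, ], tau)
  out
}

#' Apply attribute weights to a normalized matrix
#'
#' Scales every column by its attribute weight through the scalar
#' multiplication law ([fz_scalar_mul()]).
#'
#' @inheritParams normalize_attributes
#' @return A tibble of the same shape.
#' @export
weight_attributes <- function(matrix, config) {
  tau <- config$scale$tau
  check_tlivq(matrix, tau)
  attrs <- id_levels(matrix$attribute)
  w <- align_by_id(config$attribute_weights, attrs, "attribute_weights")
  eps <- w[match(as.character(matrix$attribute), attrs)]
  out <- matrix
  out[fz_cols] <- fz_scalar_mul(eps, matrix, config$q, tau)
  out
}

#' Border approximation area of a weighted matrix
#'
#' For each attribute, the border approximation area (BAA) element is the
#' equal-weight geometric mean over alternatives ([fz_geometric_mean()] with
#' exponent `1/alpha`). It separates above-border from below-border
#' performance in that attribute.
#'
#' @inheritParams normalize_attributes
#' @return A tibble with one row per attribute: the BAA evaluation plus its
#'   unit-scale `score`.
#' @export
compute_baa <- function(matrix, config) {
  tau <- config$scale$tau
  check_tlivq(matrix, tau)
  if (nrow(matrix) == 0) rlang::abort("empty weighted matrix.")
  q <- config$q
  attrs <- id_levels(matrix$attribute)
  matrix |>
    dplyr::group_by(.data$attribute) |>
    dplyr::group_modify(function(g, key) fz_geometric_mean(g, q, tau)) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(as.character(.data$attribute), attrs)) |>
    dplyr::mutate(score = fz_score(dplyr::pick(dplyr::all_of(fz_cols)), q, tau))
}

#' Signed distances to the border approximation area
#'
#' The normalized Hamming distance of every weighted evaluation to its
#' attribute's BAA element, signed by the score-then-accuracy comparison:
#' positive above the border, negative below, exactly zero on a tie.
#'
#' @inheritParams normalize_attributes
#' @param baa Output of [compute_baa()].
#' @return A tibble with `alternative`, `attribute`, and signed `distance`.
#' @export
border_distances <- function(matrix, baa, config) {
  tau <- config$scale$tau
  check_tlivq(matrix, tau); check_tlivq(baa, tau)
  if (!all(unique(as.character(matrix$attribute)) %in%
           as.character(baa$attribute))) {
    rlang::abort("`baa` must contain every attribute of `matrix`.")
  }
  q <- config$q
  g <- baa[match(as.character(matrix$attribute),
                 as.character(baa$attribute)), fz_cols]
  d <- fz_hamming(matrix, g, q, tau)
  s <- fz_compare(matrix, g, q, tau)
  tibble::tibble(alternative = matrix$alternative,
                 attribute = matrix$attribute,
                 distance = s * d)
}

#' Cumulative assessment and ranking
#'
#' Sums each alternative's signed border distances across attributes and
#' ranks alternatives by the sum, descending (ties keep input order).
#'
#' @param distances Output of [border_distances()].
#' @return A tibble with `alternative`, cumulative value `S`, and `rank`.
#' @export
mabac_scores <- function(distances) {
  alts <- id_levels(distances$alternative)
  out <- distances |>
    dplyr::group_by(.data$alternative) |>
    dplyr::summarise(S = sum(.data$distance), .groups = "drop") |>
    dplyr::arrange(match(as.character(.data$alternative), alts))
  out$rank <- rank_alternatives(out$S)
  out
}

#' Stable descending rank
#'
#' @param S Numeric vector of cumulative assessment values.
#' @return Integer ranks: 1 for the largest `S`; ties resolved by position.
#' @export
rank_alternatives <- function(S) {
  ord <- order(-S, seq_along(S))
  r <- integer(length(S))
  r[ord] <- seq_along(S)
  r
}

#' Run the full MABAC pipeline
#'
#' Executes the pipeline end to end and records every intermediate stage.
#' Entry can be either the per-expert decision data (`data`) or a
#' precomputed aggregated matrix (`aggregated`); the latter exists because
#' group aggregation and downstream ranking are independently useful — and
#' because published studies often print the aggregated matrix, which can
#' then be re-used directly.
#'
#' @param data Long per-expert decision data (see [aggregate_experts()]),
#'   or `NULL` when entering at the aggregated stage.
#' @param config A [mabac_config()].
#' @param aggregated An alternative-by-attribute tibble of evaluations, used
#'   instead of aggregating `data`.
#' @return An object of class `mabac_result`: a list with the `config`, the
#'   stage tibbles (`aggregated`, `normalized`, `weighted`, `scores`, `baa`,
#'   `distances`), the `assessment` tibble (alternative, `S`, `rank`), the
#'   `ranking` (alternative ids, best first), and any `warnings` raised
#'   during the run.
#' @examples
#' case <- case_breast_cancer()
#' res <- mabac(aggregated = case$aggregated, config = case$config)
#' tidy(res)
#' @export
mabac <- function(data = NULL, config, aggregated = NULL) {
  if (is.null(data) == is.null(aggregated)) {
    rlang::abort("supply exactly one of `data` (per-expert) or `aggregated`.")
  }
  warnings <- character()
  res <- withCallingHandlers({
    tau <- config$scale$tau
    if (is.null(aggregated)) {
      fz_validate(data, config$q, tau, config$validation)
      agg <- aggregate_experts(data, config)
    } else {
      check_rectangular(aggregated, c("alternative", "attribute"))
      fz_validate(aggregated, config$q, tau, config$validation)
      agg <- aggregated
    }
    norm <- normalize_attributes(agg, config)
    wtd <- weight_attributes(norm, config)
    scr <- wtd |>
      dplyr::mutate(score = fz_score(dplyr::pick(dplyr::all_of(fz_cols)),
                                     config$q, tau)) |>
      dplyr::select("alternative", "attribute", "score")
    baa <- compute_baa(wtd, config)
    dst <- border_distances(wtd, baa, config)
    ass <- mabac_scores(dst)
    list(
      config = config, data = data, aggregated = agg, normalized = norm,
      weighted = wtd, scores = scr, baa = baa, distances = dst,
      assessment = ass,
      ranking = as.character(ass$alternative)[order(ass$rank)]
    )
  }, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    rlang::cnd_muffle(w)
  })
  res$warnings <- warnings
  structure(res, class = "mabac_result")
}

#' @export
print.mabac_result <- function(x, ...) {
  cat(sprintf("<mabac_result> %d alternatives x %d attributes (q = %g, tau = %d)\n",
              nrow(x$assessment), nrow(x$baa), x$config$q, x$config$scale$tau))
  ass <- x$assessment
  cat("  ranking:", paste(x$ranking, collapse = " > "), "\n")
  cat(sprintf("  cumulative values: %s\n",
              paste(sprintf("%s = %.4f", ass$alternative, ass$S),
                    collapse = ", ")))
  if (length(x$warnings)) {
    cat(sprintf("  %d warning(s) recorded; see $warnings\n", length(x$warnings)))
  }
  invisible(x)
}

#' Sensitivity of the ranking to the rung parameter
#'
#' Reruns the pipeline for each rung in `q_values` (validation is relaxed to
#' `"warn"`, since published data need not be constraint-feasible at every
#' rung) and collects the cumulative values and rankings.
#'
#' @inheritParams mabac
#' @param q_values Positive rungs to evaluate.
#' @return An object of class `mabac_sweep`: a tibble with columns `q`,
#'   `alternative`, `S`, `rank`, plus a `summary` attribute tibble with one
#'   row per rung (`q`, `best`, `ranking` string).
#' @export
mabac_sweep <- function(data = NULL, config, aggregated = NULL, q_values) {
  if (!is.numeric(q_values) || !length(q_values) || any(q_values <= 0)) {
    rlang::abort("`q_values` must be positive reals.")
  }
  rows <- purrr::map(q_values, function(qq) {
    cfg <- config
    cfg$q <- qq
    cfg$validation <- "warn"
    res <- suppressWarnings(mabac(data = data, config = cfg,
                                  aggregated = aggregated))
    dplyr::mutate(res$assessment, q = qq, .before = 1) |>
      dplyr::mutate(ranking = paste(res$ranking, collapse = " > "))
  })
  out <- dplyr::bind_rows(rows)
  summary <- out |>
    dplyr::group_by(.data$q) |>
    dplyr::summarise(
      best = as.character(.data$alternative)[.data$rank == 1],
      ranking = .data$ranking[[1]], .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$q, q_values))
  structure(dplyr::select(out, -"ranking"),
            summary = summary,
            class = c("mabac_sweep", class(out)))
}

#' @export
print.mabac_sweep <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("<mabac_sweep> %d rungs, %d alternatives\n",
              nrow(s), dplyr::n_distinct(x$alternative)))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  q = %-6g %s\n", s$q[[i]], s$ranking[[i]]))
  }
  invisible(x)
}
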