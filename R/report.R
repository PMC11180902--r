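# Reporting: markdown/JSON rendering of a pipeline result, broom-style
# tidiers, and autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname mabac
#' @param x A `mabac_result`.
#' @param ... Unused.
#' @export
tidy.mabac_result <- function(x, ...) {
  x$assessment
}

#' @rdname mabac
#' @export
glance.mabac_result <- function(x, ...) {
  tibble::tibble(
    n_alternatives = nrow(x$assessment),
    n_attributes = nrow(x$baa),
    n_experts = if (is.null(x$data)) NA_integer_
                else dplyr::n_distinct(x$data$expert),
    q = x$config$q,
    tau = x$config$scale$tau,
    best = x$ranking[[1]],
    S_best = max(x$assessment$S),
    n_warnings = length(x$warnings)
  )
}

#' @rdname mabac
#' @param object A `mabac_result`.
#' @export
autoplot.mabac_result <- function(object, ...) {
  ass <- object$assessment
  ass$alternative <- factor(ass$alternative,
                            levels = ass$alternative[order(ass$rank)])
  ggplot2::ggplot(ass, ggplot2::aes(x = .data$alternative, y = .data$S,
                                    fill = .data$S > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "cumulative assessment S",
                  title = "Distance from the border approximation area") +
    ggplot2::theme_minimal()
}

#' @rdname mabac_sweep
#' @param x,object A `mabac_sweep`.
#' @param ... Unused.
#' @export
tidy.mabac_sweep <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname mabac_sweep
#' @export
glance.mabac_sweep <- function(x, ...) {
  attr(x, "summary")
}

#' @rdname mabac_sweep
#' @export
autoplot.mabac_sweep <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$q), y = .data$S,
                                   colour = .data$alternative,
                                   group = .data$alternative)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "rung q", y = "cumulative assessment S",
                  colour = NULL,
                  title = "Ranking sensitivity to the rung parameter") +
    ggplot2::theme_minimal()
}

md_matrix_table <- function(m, tau, digits = 4) {
  wide <- m |>
    dplyr::mutate(cell = format_tlivq(dplyr::pick(dplyr::all_of(fz_cols)),
                                      tau, digits)) |>
    dplyr::select("alternative", "attribute", "cell") |>
    tidyr::pivot_wider(names_from = "attribute", values_from = "cell")
  md_table(wide)
}

md_table <- function(df) {
  df <- dplyr::mutate(df, dplyr::across(
    dplyr::where(is.numeric), function(v) sprintf("%.4f", v)))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, rows), collapse = "\n")
}

#' Render a pipeline result as a document
#'
#' Markdown output shows every intermediate matrix in the conventional
#' 2-tuple notation at 4-decimal display precision, the cumulative values,
#' the ranking chain, and any warnings. JSON output serializes the full
#' result (2-tuple encoded) with a provenance block and re-parses into an
#' equivalent result via [read_mabac_report()].
#'
#' @param result A [mabac()] result.
#' @param format `"markdown"` or `"json"`.
#' @param path Optional file to write to.
#' @return The document as a character string, invisibly if `path` is given.
#' @export
mabac_report <- function(result, format = c("markdown", "json"), path = NULL) {
  format <- match.arg(format)
  tau <- result$config$scale$tau
  if (format == "markdown") {
    ass <- result$assessment
    parts <- c(
      "# MABAC decision report",
      sprintf("q = %g, tau = %d, weight policy = %s, validation = %s",
              result$config$q, tau, result$config$weight_policy,
              result$config$validation),
      "## Aggregated matrix", md_matrix_table(result$aggregated, tau),
      "## Weighted normalized matrix", md_matrix_table(result$weighted, tau),
      "## Scores of the weighted matrix",
      md_table(tidyr::pivot_wider(result$scores, names_from = "attribute",
                                  values_from = "score")),
      "## Border approximation area",
      md_table(tibble::tibble(
        attribute = result$baa$attribute,
        element = format_tlivq(result$baa, tau),
        score = result$baa$score
      )),
      "## Signed distance matrix",
      md_table(tidyr::pivot_wider(result$distances, names_from = "attribute",
                                  values_from = "distance")),
      "## Cumulative assessment",
      md_table(dplyr::select(ass, "alternative", "S", "rank")),
      "## Ranking",
      paste(result$ranking, collapse = " > "),
      "## Warnings",
      if (length(result$warnings)) paste("-", result$warnings, collapse = "\n")
      else "(none)"
    )
    doc <- paste(parts, collapse = "\n\n")
  } else {
    cfg <- result$config
    obj <- list(
      provenance = list(
        package = "tlmabac",
        version = as.character(utils::packageVersion("tlmabac")),
        config = list(
          q = cfg$q, tau = tau,
          expert_weights = cfg$expert_weights,
          attribute_weights = cfg$attribute_weights,
          attribute_kinds = cfg$attribute_kinds,
          weight_policy = cfg$weight_policy, validation = cfg$validation
        ),
        warnings = result$warnings
      ),
      aggregated = encode_entries(result$aggregated, tau,
                                  c("alternative", "attribute")),
      normalized = encode_entries(result$normalized, tau,
                                  c("alternative", "attribute")),
      weighted = encode_entries(result$weighted, tau,
                                c("alternative", "attribute")),
      scores = result$scores,
      baa = purrr::map(seq_len(nrow(result$baa)), function(i) {
        e <- encode_entries(result$baa[i, ], tau, "attribute")[[1]]
        e$score <- result$baa$score[[i]]
        e
      }),
      distances = result$distances,
      assessment = result$assessment,
      ranking = result$ranking
    )
    doc <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Re-parse a JSON pipeline report
#'
#' @param path Path to (or literal text of) a JSON document written by
#'   [mabac_report()].
#' @return A `mabac_result` equivalent to the one that was serialized
#'   (without the raw per-expert data).
#' @export
read_mabac_report <- function(path) {
  obj <- jsonlite::read_json(path)
  p <- obj$provenance$config
  cfg <- mabac_config(
    q = p$q, tau = p$tau,
    expert_weights = if (length(p$expert_weights))
      as.numeric(p$expert_weights) else NULL,
    attribute_weights = as.numeric(p$attribute_weights),
    attribute_kinds = if (length(p$attribute_kinds))
      as.character(p$attribute_kinds) else NULL,
    weight_policy = p$weight_policy, validation = p$validation
  )
  tau <- p$tau
  baa <- decode_entries(obj$baa, tau, "attribute")
  baa$score <- purrr::map_dbl(obj$baa, "score")
  ass <- dplyr::bind_rows(purrr::map(obj$assessment, tibble::as_tibble))
  structure(list(
    config = cfg, data = NULL,
    aggregated = decode_entries(obj$aggregated, tau,
                                c("alternative", "attribute")),
    normalized = decode_entries(obj$normalized, tau,
                                c("alternative", "attribute")),
    weighted = decode_entries(obj$weighted, tau,
                              c("alternative", "attribute")),
    scores = dplyr::bind_rows(purrr::map(obj$scores, tibble::as_tibble)),
    baa = baa,
    distances = dplyr::bind_rows(purrr::map(obj$distances, tibble::as_tibble)),
    assessment = ass,
    ranking = as.character(obj$ranking),
    warnings = as.character(obj$provenance$warnings)
  ), class = "mabac_result")
}
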