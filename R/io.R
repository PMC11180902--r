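# Interchange formats and instance generation. JSON is the canonical
# full-precision format (2-tuple encoded); CSV is a crisp linguistic dialect
# where every cell is a bare term like "J2".

# encode a numeric scale value as the [index, offset] pair used in JSON
encode_tuples <- function(xi, tau) {
  tt <- tl_delta(xi, tau)
  purrr::map2(tt$index, tt$offset, function(i, o) c(i, o))
}

decode_tuple <- function(pair, tau, where) {
  if (length(pair) != 2 || !is.numeric(unlist(pair))) {
    rlang::abort(sprintf("malformed 2-tuple at %s", where))
  }
  pair <- as.numeric(unlist(pair))
  tryCatch(tl_delta_inv(pair[[1]], pair[[2]], tau),
           error = function(e) {
             rlang::abort(sprintf("invalid 2-tuple at %s: %s", where,
                                  conditionMessage(e)))
           })
}

encode_entries <- function(data, tau, ids) {
  purrr::map(seq_len(nrow(data)), function(i) {
    e <- as.list(data[i, ids, drop = FALSE])
    e$md <- list(encode_tuples(data$mu_lo[[i]], tau)[[1]],
                 encode_tuples(data$mu_hi[[i]], tau)[[1]])
    e$nmd <- list(encode_tuples(data$nu_lo[[i]], tau)[[1]],
                  encode_tuples(data$nu_hi[[i]], tau)[[1]])
    e
  })
}

decode_entries <- function(entries, tau, ids) {
  rows <- purrr::map(seq_along(entries), function(i) {
    e <- entries[[i]]
    where <- paste0("entry ", i, " (",
                    paste(unlist(e[ids]), collapse = "/"), ")")
    vals <- c(decode_tuple(e$md[[1]], tau, where),
              decode_tuple(e$md[[2]], tau, where),
              decode_tuple(e$nmd[[1]], tau, where),
              decode_tuple(e$nmd[[2]], tau, where))
    out <- tibble::as_tibble(e[ids])
    out$mu_lo <- vals[[1]]; out$mu_hi <- vals[[2]]
    out$nu_lo <- vals[[3]]; out$nu_hi <- vals[[4]]
    out
  })
  out <- dplyr::bind_rows(rows)
  check_tlivq(out, tau)
  out
}

#' Write a decision cube to disk
#'
#' JSON stores full-precision 2-tuples and round-trips exactly; CSV is a
#' crisp dialect (term tokens like `"J2"`, zero symbolic translation only).
#'
#' @param data Long decision data with `expert`, `alternative`, `attribute`
#'   and evaluation columns.
#' @param path Output file path.
#' @param tau Scale granularity.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(data, path, tau, format = c("json", "csv")) {
  format <- match.arg(format)
  check_tlivq(data, tau)
  ids <- c("expert", "alternative", "attribute")
  if (!all(ids %in% names(data))) {
    rlang::abort("cube data needs columns expert, alternative, attribute.")
  }
  if (format == "json") {
    obj <- list(
      tau = tau,
      experts = id_levels(data$expert),
      alternatives = id_levels(data$alternative),
      attributes = id_levels(data$attribute),
      entries = encode_entries(data, tau, ids)
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    crisp <- abs(as.matrix(data[fz_cols]) -
                   round(as.matrix(data[fz_cols])))
    if (any(crisp > 1e-12)) {
      rlang::abort("the CSV dialect holds crisp terms only; use JSON for full precision.")
    }
    out <- data[ids]
    for (col in fz_cols) out[[col]] <- sprintf("J%d", as.integer(round(data[[col]])))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a decision cube from disk
#'
#' @param path File written by [write_cube()] (or hand-authored in the same
#'   layout).
#' @param format `"json"` or `"csv"`.
#' @param tau Scale granularity; required for CSV, taken from the file for
#'   JSON.
#' @return A long decision tibble (see [aggregate_experts()]).
#' @export
read_cube <- function(path, format = c("json", "csv"), tau = NULL) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- jsonlite::read_json(path)
    tau <- tau %||% obj$tau
    out <- decode_entries(obj$entries, tau,
                          c("expert", "alternative", "attribute"))
  } else {
    if (is.null(tau)) rlang::abort("`tau` is required for the CSV dialect.")
    raw <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("expert", "alternative", "attribute", fz_cols)
    if (!all(need %in% names(raw))) {
      rlang::abort(paste("CSV cube needs columns:", paste(need, collapse = ", ")))
    }
    out <- tibble::as_tibble(raw[c("expert", "alternative", "attribute")])
    for (col in fz_cols) {
      out[[col]] <- purrr::map_dbl(seq_len(nrow(raw)), function(i) {
        tryCatch(parse_two_tuple(raw[[col]][[i]], tau),
                 error = function(e) {
                   rlang::abort(sprintf(
                     "row %d (%s/%s/%s), column %s: %s", i,
                     raw$expert[[i]], raw$alternative[[i]], raw$attribute[[i]],
                     col, conditionMessage(e)))
                 })
      })
    }
    check_tlivq(out, tau)
  }
  check_rectangular(out, c("expert", "alternative", "attribute"))
  out
}

#' Read or write an alternative-by-attribute fuzzy matrix
#'
#' JSON interchange for aggregated (or normalized/weighted) matrices, in the
#' same 2-tuple encoding as [write_cube()]; used to enter the pipeline at
#' the aggregated stage.
#'
#' @param data Tibble with `alternative`, `attribute` and evaluation columns.
#' @param path File path.
#' @param tau Scale granularity; taken from the file when reading if `NULL`.
#' @return `write_fuzzy_matrix()` returns `path` invisibly;
#'   `read_fuzzy_matrix()` returns the matrix tibble.
#' @export
write_fuzzy_matrix <- function(data, path, tau) {
  check_tlivq(data, tau)
  ids <- c("alternative", "attribute")
  if (!all(ids %in% names(data))) {
    rlang::abort("matrix data needs columns alternative, attribute.")
  }
  obj <- list(
    tau = tau,
    alternatives = id_levels(data$alternative),
    attributes = id_levels(data$attribute),
    entries = encode_entries(data, tau, ids)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fuzzy_matrix
#' @export
read_fuzzy_matrix <- function(path, tau = NULL) {
  obj <- jsonlite::read_json(path)
  tau <- tau %||% obj$tau
  out <- decode_entries(obj$entries, tau, c("alternative", "attribute"))
  check_rectangular(out, c("alternative", "attribute"))
  out
}

#' Generate a random decision cube
#'
#' Draws a rectangular experts x alternatives x attributes cube of valid
#' evaluations. Interval endpoints are sampled uniformly over the term scale
#' (crisp term indices by default, matching how experts typically elicit
#' judgements; continuous values with `crisp = FALSE`) and rejection-sampled
#' until the rung constraint holds when `constraint = "enforce"`.
#'
#' @param n_experts,n_alternatives,n_attributes Cube dimensions.
#' @param tau Scale granularity.
#' @param q Rung used for the constraint in enforce mode.
#' @param seed Optional integer seed for reproducibility.
#' @param constraint `"enforce"` (default) or `"none"`.
#' @param crisp Sample crisp term indices (`TRUE`, default) or continuous
#'   scale values.
#' @param max_tries Rejection budget per entry before declaring the
#'   specification infeasible.
#' @return A long decision tibble.
#' @examples
#' generate_cube(2, 3, 2, tau = 8, q = 6, seed = 1)
#' @export
generate_cube <- function(n_experts, n_alternatives, n_attributes, tau = 8,
                          q = 6, seed = NULL,
                          constraint = c("enforce", "none"),
                          crisp = TRUE, max_tries = 1000) {
  constraint <- match.arg(constraint)
  check_q(q)
  if (!is.null(seed)) set.seed(seed)
  grid <- tidyr::expand_grid(
    expert = paste0("E", seq_len(n_experts)),
    alternative = paste0("A", seq_len(n_alternatives)),
    attribute = paste0("C", seq_len(n_attributes))
  )
  draw_pair <- function() {
    if (crisp) sort(sample(0:tau, 2, replace = TRUE))
    else sort(stats::runif(2, 0, tau))
  }
  cells <- purrr::map(seq_len(nrow(grid)), function(i) {
    for (try in seq_len(max_tries)) {
      mu <- draw_pair(); nu <- draw_pair()
      ok <- constraint == "none" ||
        (mu[[2]] / tau)^q + (nu[[2]] / tau)^q <= 1
      if (ok) return(c(mu, nu))
    }
    rlang::abort(sprintf(
      "no valid evaluation found in %d tries: the rung constraint at q = %g is infeasible for this scale.",
      max_tries, q
    ))
  })
  m <- do.call(rbind, cells)
  dplyr::bind_cols(grid, tibble::tibble(
    mu_lo = m[, 1], mu_hi = m[, 2], nu_lo = m[, 3], nu_hi = m[, 4]
  ))
}

#' The breast-cancer treatment-selection case study
#'
#' Loads the embedded case study: seven candidate treatments (lumpectomy,
#' mastectomy, chemotherapy, hormone therapy, targeted therapy,
#' immunotherapy, clinical trials) rated by four experts on four attributes
#' (cancer stage/subtype, patient preferences, resource availability,
#' expected outcomes) on a 9-term scale, with `q = 6`. Alongside the raw
#' expert cube, the published intermediate stages are included so that each
#' pipeline step can be checked against them: the aggregated matrix, the
#' weighted normalized matrix, its score matrix, the border approximation
#' area, the signed distance matrix, the cumulative values and the ranking.
#'
#' Note that re-aggregating the expert cube with the published expert
#' weights (which sum to 0.8162) does not reproduce the published aggregated
#' matrix under any weight policy; the downstream stages are mutually
#' consistent from the aggregated matrix onward. Use
#' [fz_matrix_deviation()] to quantify the aggregation gap.
#'
#' @return A list with elements `config` ([mabac_config()]), `cube`,
#'   `aggregated`, `weighted`, `scores`, `baa`, `distances`, `cumulative`,
#'   `ranking`, and `labels`.
#' @examples
#' case <- case_breast_cancer()
#' case$config
#' @export
case_breast_cancer <- function() {
  path <- system.file("extdata", "breast_cancer.json", package = "tlmabac",
                      mustWork = TRUE)
  obj <- jsonlite::read_json(path)
  tau <- obj$config$tau
  cfg <- mabac_config(
    q = obj$config$q, tau = tau,
    expert_weights = as.numeric(obj$config$expert_weights),
    attribute_weights = as.numeric(obj$config$attribute_weights),
    attribute_kinds = as.character(obj$config$attribute_kinds),
    weight_policy = obj$config$weight_policy,
    validation = obj$config$validation,
    labels = as.character(obj$labels)
  )
  mat <- function(entries, ids) decode_entries(entries, tau, ids)
  baa <- mat(obj$baa, "attribute")
  baa$score <- purrr::map_dbl(obj$baa, "score")
  list(
    config = cfg,
    cube = mat(obj$cube, c("expert", "alternative", "attribute")),
    aggregated = mat(obj$aggregated, c("alternative", "attribute")),
    weighted = mat(obj$weighted, c("alternative", "attribute")),
    scores = dplyr::bind_rows(purrr::map(obj$scores, tibble::as_tibble)),
    baa = baa,
    distances = dplyr::bind_rows(purrr::map(obj$distances, tibble::as_tibble)),
    cumulative = dplyr::bind_rows(purrr::map(obj$cumulative, tibble::as_tibble)),
    ranking = as.character(obj$ranking),
    labels = as.character(obj$labels)
  )
}

#' Component-wise deviation between two evaluation matrices
#'
#' Joins two alternative-by-attribute matrices on their ids and reports, per
#' cell, the largest absolute difference across the four endpoints (on the
#' `[0, tau]` scale). Used to quantify how far a recomputed stage is from a
#' reference — for example, how far re-aggregated expert data lands from a
#' published aggregated matrix.
#'
#' @param x,y Tibbles with `alternative`, `attribute` and evaluation columns.
#' @param tau Scale granularity.
#' @return A tibble `alternative`, `attribute`, `max_abs_dev`, sorted by
#'   decreasing deviation.
#' @export
fz_matrix_deviation <- function(x, y, tau) {
  check_tlivq(x, tau); check_tlivq(y, tau)
  j <- dplyr::inner_join(x, y, by = c("alternative", "attribute"),
                         suffix = c("", ".ref"))
  if (nrow(j) != nrow(x)) {
    rlang::abort("matrices do not share the same (alternative, attribute) cells.")
  }
  dev <- pmax(abs(j$mu_lo - j$mu_lo.ref), abs(j$mu_hi - j$mu_hi.ref),
              abs(j$nu_lo - j$nu_lo.ref), abs(j$nu_hi - j$nu_hi.ref))
  tibble::tibble(alternative = j$alternative, attribute = j$attribute,
                 max_abs_dev = dev) |>
    dplyr::arrange(dplyr::desc(.data$max_abs_dev))
}
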