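make_cfg <- function(n_attr = 3, n_exp = 2, ...) {
  mabac_config(
    q = 6, tau = 8,
    expert_weights = rep(1 / n_exp, n_exp),
    attribute_weights = rep(1 / n_attr, n_attr),
    ...
  )
}

test_that("expert aggregation is the identity for identical experts", {
  set.seed(61)
  base <- generate_cube(1, 4, 3, seed = 61)
  cube <- dplyr::bind_rows(
    dplyr::mutate(base, expert = "E1"),
    dplyr::mutate(base, expert = "E2")
  )
  agg <- aggregate_experts(cube, make_cfg())
  expect_tlivq_equal(agg, dplyr::select(base, -"expert"), tol = 1e-9)
  # single expert with weight one is also the identity
  cfg1 <- make_cfg(n_exp = 1)
  agg1 <- aggregate_experts(dplyr::mutate(base, expert = "E1"), cfg1)
  expect_tlivq_equal(agg1, dplyr::select(base, -"expert"), tol = 1e-12)
})

test_that("aggregation rejects ragged decision data", {
  cube <- generate_cube(2, 3, 2, seed = 5)
  expect_error(aggregate_experts(cube[-1, ], make_cfg(n_attr = 2)),
               "rectangular")
})

test_that("normalization complements cost columns and is an involution there", {
  m <- dplyr::select(generate_cube(1, 4, 3, seed = 67), -"expert")
  cfg_b <- make_cfg(attribute_kinds = rep("benefit", 3))
  cfg_c <- make_cfg(attribute_kinds = rep("cost", 3))
  expect_identical(normalize_attributes(m, cfg_b), m)
  nc <- normalize_attributes(m, cfg_c)
  expect_tlivq_equal(nc, dplyr::mutate(fz_complement(m, 8),
                                       alternative = m$alternative,
                                       attribute = m$attribute), tol = 0)
  expect_tlivq_equal(normalize_attributes(nc, cfg_c), m, tol = 0)
  cfg_bad <- make_cfg(attribute_kinds = c("benefit", "cost", "wat"))
  expect_error(normalize_attributes(m, cfg_bad), "benefit")
})

test_that("attribute weighting applies the scalar law column-wise", {
  m <- dplyr::select(generate_cube(1, 3, 2, seed = 71), -"expert")
  cfg <- mabac_config(q = 6, tau = 8, attribute_weights = c(1, 0.4))
  w <- weight_attributes(m, cfg)
  c1 <- m$attribute == "C1"
  expect_tlivq_equal(w[c1, ], m[c1, ], tol = 1e-12) # weight 1 -> unchanged
  expect_tlivq_equal(w[!c1, ], dplyr::mutate(
    fz_scalar_mul(0.4, m[!c1, ], 6, 8),
    alternative = m$alternative[!c1], attribute = m$attribute[!c1]
  ), tol = 1e-12)
})

test_that("the border approximation area of one alternative is that alternative", {
  m <- dplyr::select(generate_cube(1, 1, 3, seed = 73), -"expert")
  baa <- compute_baa(m, make_cfg())
  expect_tlivq_equal(baa, m, tol = 1e-12)
  expect_equal(baa$score, fz_score(m, 6, 8))
})

test_that("signed distances vanish on the border and flip sign when roles swap", {
  m <- dplyr::select(generate_cube(1, 5, 3, seed = 79), -"expert")
  cfg <- make_cfg()
  baa <- compute_baa(m, cfg)
  d <- border_distances(m, baa, cfg)
  # an alternative equal to the border everywhere gets distance 0
  self <- baa |>
    dplyr::select(-"score") |>
    dplyr::mutate(alternative = "self", .before = 1)
  expect_equal(border_distances(self, baa, cfg)$distance, rep(0, 3))
  # swapping element and border flips the sign, preserving magnitude
  swapped <- purrr::map_dbl(seq_len(nrow(m)), function(i) {
    elt_as_baa <- dplyr::select(m[i, ], "attribute", dplyr::all_of(fz_cols))
    baa_as_elt <- baa |>
      dplyr::filter(.data$attribute == m$attribute[[i]]) |>
      dplyr::select(-"score") |>
      dplyr::mutate(alternative = "g", .before = 1)
    border_distances(baa_as_elt, elt_as_baa, cfg)$distance
  })
  expect_equal(swapped, -d$distance, tolerance = 1e-12)
})

test_that("cumulative scores sum distances and rank stably", {
  d <- tibble::tibble(
    alternative = rep(c("A1", "A2", "A3"), each = 2),
    attribute = rep(c("C1", "C2"), 3),
    distance = c(0.1, -0.05, 0, 0, 0.02, 0.03)
  )
  s <- mabac_scores(d)
  expect_equal(s$S, c(0.05, 0, 0.05))
  expect_equal(s$rank, c(1L, 3L, 2L)) # tie broken by input order
  expect_equal(rank_alternatives(c(0, 0, 0)), 1:3)
  expect_equal(rank_alternatives(c(1, 2, 3)), c(3L, 2L, 1L))
  expect_equal(rank_alternatives(-c(1, 2, 3)), 1:3)
})

test_that("the pipeline is self-consistent stage by stage", {
  cube <- generate_cube(3, 5, 4, seed = 83)
  cfg <- mabac_config(q = 6, tau = 8,
                      expert_weights = c(0.5, 0.3, 0.2),
                      attribute_weights = c(0.3, 0.3, 0.2, 0.2),
                      attribute_kinds = c("benefit", "cost", "benefit", "cost"))
  res <- mabac(data = cube, config = cfg)
  expect_identical(res$aggregated, aggregate_experts(cube, cfg))
  expect_identical(res$normalized, normalize_attributes(res$aggregated, cfg))
  expect_identical(res$weighted, weight_attributes(res$normalized, cfg))
  expect_identical(res$baa, compute_baa(res$weighted, cfg))
  expect_identical(res$distances,
                   border_distances(res$weighted, res$baa, cfg))
  expect_identical(res$assessment, mabac_scores(res$distances))
  expect_equal(res$ranking,
               as.character(res$assessment$alternative)[order(res$assessment$rank)])
  # entering at the aggregated stage reproduces the same downstream result
  res2 <- mabac(aggregated = res$aggregated, config = cfg)
  expect_equal(res2$assessment, res$assessment)
  expect_error(mabac(data = cube, config = cfg, aggregated = res$aggregated),
               "exactly one")
})

test_that("cumulative values are invariant under attribute and alternative permutations", {
  cube <- generate_cube(2, 4, 3, seed = 89)
  cfg <- mabac_config(q = 6, tau = 8, expert_weights = c(0.6, 0.4),
                      attribute_weights = c(0.5, 0.3, 0.2),
                      attribute_kinds = c("benefit", "cost", "benefit"))
  res <- mabac(data = cube, config = cfg)
  # permute attributes together with their weights and kinds
  p <- c(3, 1, 2)
  cfg_p <- mabac_config(q = 6, tau = 8, expert_weights = c(0.6, 0.4),
                        attribute_weights = cfg$attribute_weights[p],
                        attribute_kinds = cfg$attribute_kinds[p])
  cube_p <- dplyr::arrange(cube, match(.data$attribute, paste0("C", p)))
  res_p <- mabac(data = cube_p, config = cfg_p)
  j <- dplyr::inner_join(res$assessment, res_p$assessment, by = "alternative")
  expect_equal(j$S.x, j$S.y, tolerance = 1e-12)
  # permuting alternatives permutes S accordingly
  ap <- sample(paste0("A", 1:4))
  cube_a <- dplyr::arrange(cube, match(.data$alternative, ap))
  res_a <- mabac(data = cube_a, config = cfg)
  j2 <- dplyr::inner_join(res$assessment, res_a$assessment, by = "alternative")
  expect_equal(j2$S.x, j2$S.y, tolerance = 1e-12)
})

test_that("an alternative dominating every attribute attains the maximal S", {
  set.seed(97)
  for (rep in 1:5) {
    m <- dplyr::select(generate_cube(1, 4, 3, seed = 97 + rep), -"expert")
    # craft a dominating alternative: full membership, zero non-membership
    dom <- m |>
      dplyr::group_by(.data$attribute) |>
      dplyr::summarise(mu_lo = 8, mu_hi = 8, nu_lo = 0, nu_hi = 0,
                       .groups = "drop") |>
      dplyr::mutate(alternative = "A0", .before = 1)
    mm <- dplyr::bind_rows(m, dom)
    cfg <- make_cfg()
    res <- mabac(aggregated = mm, config = cfg)
    expect_equal(res$ranking[[1]], "A0")
  }
})

test_that("rung sweeps rerun the pipeline per rung", {
  cube <- generate_cube(2, 4, 3, seed = 101)
  cfg <- mabac_config(q = 6, tau = 8, expert_weights = c(0.5, 0.5),
                      attribute_weights = rep(1 / 3, 3))
  sw <- mabac_sweep(data = cube, config = cfg, q_values = 6)
  res <- mabac(data = cube, config = cfg)
  expect_equal(sw$S, res$assessment$S)
  expect_equal(sw$rank, res$assessment$rank)
  sw2 <- mabac_sweep(data = cube, config = cfg, q_values = c(2, 6, 9))
  expect_equal(nrow(sw2), 12)
  # per-rung S totals equal the independently recomputed distance totals
  for (qq in c(2, 6, 9)) {
    cfg_q <- cfg; cfg_q$q <- qq
    res_q <- mabac(data = cube, config = cfg_q)
    expect_equal(sum(sw2$S[sw2$q == qq]), sum(res_q$distances$distance),
                 tolerance = 1e-12)
  }
  expect_equal(glance(sw2)$q, c(2, 6, 9))
  expect_error(mabac_sweep(data = cube, config = cfg, q_values = c(1, -2)),
               "positive")
})

test_that("tidiers and plots summarize a result", {
  case <- case_breast_cancer()
  res <- mabac(aggregated = case$aggregated, config = case$config)
  td <- tidy(res)
  expect_named(td, c("alternative", "S", "rank"))
  gl <- glance(res)
  expect_equal(gl$best, "G6")
  expect_equal(gl$n_alternatives, 7L)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
  sw <- mabac_sweep(aggregated = case$aggregated, config = case$config,
                    q_values = c(5, 6))
  expect_s3_class(autoplot(sw), "ggplot")
})
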