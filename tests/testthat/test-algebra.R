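# The frozen expected values below come from direct evaluation of the score,
# accuracy and constraint formulas on the stated inputs.

test_that("construction enforces range and interval ordering", {
  expect_error(tlivq(3, 2, 1, 4, tau = 8), "interval ordering")
  expect_error(tlivq(1, 9, 0, 2, tau = 8), "\\[0, 8\\]")
  expect_silent(tlivq(0, 0, 0, 0, tau = 8))
})

test_that("rung-constraint validation behaves per mode", {
  x <- tlivq(1, 7, 2, 4, tau = 8) # (7/8)^6 + (4/8)^6 = 0.464 <= 1
  expect_silent(fz_validate(x, q = 6, tau = 8, mode = "strict"))
  # (7/8)^0.5 + (4/8)^0.5 = 1.64 > 1
  expect_error(fz_validate(x, q = 0.5, tau = 8, mode = "strict"),
               "rung constraint")
  expect_warning(out <- fz_validate(x, q = 0.5, tau = 8, mode = "warn"),
                 "rung constraint")
  expect_equal(attr(out, "violations")$row, 1L)
  expect_silent(fz_validate(x, q = 0.5, tau = 8, mode = "off"))
  expect_silent(fz_validate(tlivq(0, 0, 0, 0, tau = 8), q = 0.5, tau = 8,
                            mode = "strict"))
})

test_that("score and accuracy match direct evaluation and boundary cases", {
  # the published weighted element for immunotherapy / resources
  x <- tlivq(3.4154, 4.1953, 5.2148, 6.0315, tau = 8)
  expect_equal(fz_score(x, q = 6, tau = 8), 0.4416, tolerance = 1e-4)
  expect_equal(fz_score(tlivq(8, 8, 0, 0, tau = 8), q = 3, tau = 8), 1)
  expect_equal(fz_accuracy(tlivq(0, 0, 0, 0, tau = 8), q = 6, tau = 8), 0)
  expect_equal(fz_accuracy(tlivq(8, 8, 8, 8, tau = 8), q = 6, tau = 8), 1)
  y <- tlivq(2, 3, 4, 5, tau = 8)
  expect_equal(fz_score(y, q = 6, tau = 8), 0.4819489, tolerance = 1e-6)
  expect_equal(fz_accuracy(y, q = 6, tau = 8), 0.01956367, tolerance = 1e-6)
  # 2-tuple accessor reports tau * value
  tt <- fz_score(y, q = 6, tau = 8, as_two_tuple = TRUE)
  expect_equal(tt$index + tt$offset, 8 * 0.4819489, tolerance = 1e-5)
})

test_that("score and accuracy stay in [0, 1] and the complement flips the score", {
  set.seed(7)
  x <- random_tlivq(100)
  k <- fz_score(x, q = 6, tau = 8)
  f <- fz_accuracy(x, q = 6, tau = 8)
  expect_true(all(k >= 0 & k <= 1))
  expect_true(all(f >= 0 & f <= 1))
  expect_equal(k + fz_score(fz_complement(x, 8), q = 6, tau = 8),
               rep(1, 100), tolerance = 1e-12)
})

test_that("addition and multiplication have identities and commute", {
  set.seed(11)
  x <- random_tlivq(50)
  y <- random_tlivq(50)
  add_id <- tlivq(0, 0, 8, 8, tau = 8)
  mul_id <- tlivq(8, 8, 0, 0, tau = 8)
  expect_tlivq_equal(fz_add(x, add_id, 6, 8), x, tol = 1e-12)
  expect_tlivq_equal(fz_mul(x, mul_id, 6, 8), x, tol = 1e-12)
  expect_tlivq_equal(fz_add(x, y, 6, 8), fz_add(y, x, 6, 8), tol = 1e-12)
  expect_tlivq_equal(fz_mul(x, y, 6, 8), fz_mul(y, x, 6, 8), tol = 1e-12)
})

test_that("multiplication and power are the complement-duals of addition and scaling", {
  set.seed(13)
  x <- random_tlivq(60)
  y <- random_tlivq(60)
  eps <- runif(60, 0, 3)
  lhs <- fz_mul(x, y, 6, 8)
  rhs <- fz_complement(fz_add(fz_complement(x, 8), fz_complement(y, 8), 6, 8), 8)
  expect_tlivq_equal(lhs, rhs, tol = 1e-9)
  lhs2 <- fz_power(x, eps, 6, 8)
  rhs2 <- fz_complement(fz_scalar_mul(eps, fz_complement(x, 8), 6, 8), 8)
  expect_tlivq_equal(lhs2, rhs2, tol = 1e-9)
})

test_that("scalar multiplication distributes over its exponent and fixes eps = 1", {
  set.seed(17)
  x <- random_tlivq(40)
  e1 <- runif(40, 0, 2); e2 <- runif(40, 0, 2)
  expect_tlivq_equal(fz_scalar_mul(1, x, 6, 8), x, tol = 1e-12)
  expect_tlivq_equal(fz_power(x, 1, 6, 8), x, tol = 1e-12)
  expect_tlivq_equal(
    fz_scalar_mul(e1 + e2, x, 6, 8),
    fz_add(fz_scalar_mul(e1, x, 6, 8), fz_scalar_mul(e2, x, 6, 8), 6, 8),
    tol = 1e-9
  )
  mul_id <- tlivq(8, 8, 0, 0, tau = 8)
  expect_tlivq_equal(fz_power(mul_id, 0.7, 6, 8), mul_id, tol = 1e-12)
  expect_error(fz_scalar_mul(-0.1, x, 6, 8), "non-negative")
})

test_that("the published weighting step reproduces its printed element", {
  x <- tlivq(4.3023, 5.2651, 1.4246, 2.5614, tau = 8)
  got <- fz_scalar_mul(0.2480, x, q = 6, tau = 8)
  want <- c(3.4154, 4.1953, 5.2148, 6.0315)
  expect_equal(unlist(got[1, ]), want, tolerance = 5e-4, ignore_attr = TRUE)
})

test_that("the complement is an involution that swaps the intervals", {
  x <- tlivq(2, 3, 1, 4, tau = 8)
  cx <- fz_complement(x, 8)
  expect_equal(unlist(cx[1, ]), c(1, 4, 2, 3), ignore_attr = TRUE)
  expect_tlivq_equal(fz_complement(cx, 8), x, tol = 0)
})

test_that("the Hamming distance is a metric bounded by 1", {
  set.seed(19)
  x <- random_tlivq(80); y <- random_tlivq(80); z <- random_tlivq(80)
  dxy <- fz_hamming(x, y, 6, 8)
  expect_equal(fz_hamming(x, x, 6, 8), rep(0, 80))
  expect_equal(dxy, fz_hamming(y, x, 6, 8))
  expect_true(all(dxy >= 0 & dxy <= 1))
  expect_true(all(dxy <= fz_hamming(x, z, 6, 8) + fz_hamming(z, y, 6, 8) + 1e-12))
  # published spot distance: first weighted element vs the first border element
  a <- tlivq(2.0239, 2.7712, 5.7146, 6.6545, tau = 8)
  g <- tlivq(2.3420, 3.4742, 6.0941, 6.8580, tau = 8)
  expect_lt(abs(fz_hamming(a, g, 6, 8) - 0.0334), 1e-4)
})

test_that("comparison orders by score then accuracy, agreeing with a grid oracle", {
  x <- tlivq(2, 3, 4, 5, tau = 8)
  expect_equal(fz_compare(x, x, 6, 8), 0L)
  # enumerate crisp evaluations on a coarse scale and cross-check every pair
  tau <- 4; q <- 2
  grid <- expand.grid(a = 0:tau, b = 0:tau, c = 0:tau, d = 0:tau)
  grid <- grid[grid$a <= grid$b & grid$c <= grid$d &
                 (grid$b / tau)^q + (grid$d / tau)^q <= 1, ]
  grid <- grid[seq(1, nrow(grid), by = 3), ] # thin for speed
  g <- tlivq(grid$a, grid$b, grid$c, grid$d, tau = tau)
  set.seed(23)
  i <- sample(nrow(g), 300, replace = TRUE)
  j <- sample(nrow(g), 300, replace = TRUE)
  got <- fz_compare(g[i, ], g[j, ], q, tau)
  want <- vapply(seq_along(i), function(k) {
    vi <- as.numeric(g[i[k], ]); vj <- as.numeric(g[j[k], ])
    ds <- score_direct(vi, q, tau) - score_direct(vj, q, tau)
    if (abs(ds) > 1e-9) return(sign(ds))
    da <- accuracy_direct(vi, q, tau) - accuracy_direct(vj, q, tau)
    if (abs(da) > 1e-9) sign(da) else 0
  }, numeric(1))
  expect_equal(got, as.integer(want))
  expect_error(fz_compare(x, x, q = -1, tau = 8), "positive")
})
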