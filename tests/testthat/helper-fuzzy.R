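fz_cols <- c("mu_lo", "mu_hi", "nu_lo", "nu_hi")

# Random valid evaluations for property tests: endpoints uniform on the
# scale, rejection-sampled to satisfy the rung constraint.
random_tlivq <- function(n, q = 6, tau = 8) {
  draw <- function() {
    repeat {
      mu <- sort(runif(2, 0, tau))
      nu <- sort(runif(2, 0, tau))
      if ((mu[[2]] / tau)^q + (nu[[2]] / tau)^q <= 1) return(c(mu, nu))
    }
  }
  m <- t(replicate(n, draw()))
  tlivq(m[, 1], m[, 2], m[, 3], m[, 4], tau = tau)
}

# direct-formula score/accuracy, kept deliberately separate from the
# package's vectorized implementation
score_direct <- function(v, q, tau) {
  u <- v / tau
  0.25 * ((1 + u[[1]]^q - u[[3]]^q) + (1 + u[[2]]^q - u[[4]]^q))
}
accuracy_direct <- function(v, q, tau) {
  mean((v / tau)^q)
}

expect_tlivq_equal <- function(x, y, tol = 1e-9) {
  for (col in c("mu_lo", "mu_hi", "nu_lo", "nu_hi")) {
    expect_equal(x[[col]], y[[col]], tolerance = tol, ignore_attr = TRUE)
  }
}
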