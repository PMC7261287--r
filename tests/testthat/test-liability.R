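# Implied covariance algebra, thresholds, orthant probabilities and the
# family likelihood.

test_that("threshold_from_prevalence inverts the normal tail", {
  expect_equal(threshold_from_prevalence(0.5), 0)
  expect_equal(threshold_from_prevalence(0.0316), 1.857782, tolerance = 1e-6)
  expect_equal(threshold_from_prevalence(0.0382), 1.771967, tolerance = 1e-6)
  expect_equal(stats::pnorm(-threshold_from_prevalence(0.123)), 0.123)
  expect_error(threshold_from_prevalence(0), "0, 1")
  expect_error(threshold_from_prevalence(1), "0, 1")
  expect_error(threshold_from_prevalence(-0.2), "0, 1")
})

test_that("parameter constructor enforces the simplex and r_g range", {
  p <- liability_params(a2_p = 0.3, c2_p = 0.2, a2_o = 0.5)
  expect_equal(p$e2_p, 0.5)
  expect_error(liability_params(a2_p = 0.8, c2_p = 0.3), "variance shares")
  expect_error(liability_params(r_g = 1.2), "r_g")
})

test_that("removing both cross-generation paths empties the cross block", {
  p <- liability_params(beta = 0, r_g = 0, a2_p = 0.5, a2_o = 0.6)
  for (type in c("full", "maternal-half", "MZ-twin")) {
    spec <- relationship_spec(type)
    S <- implied_correlation_matrix(p, spec)
    expect_equal(S["p1", "o11"], 0)
    expect_equal(S["p1", "o21"], 0)
    expect_equal(S["p1", "p2"], parent_g(type) * 0.5)
  }
})

test_that("published minimal-model estimates imply the observed parent-offspring correlation", {
  S <- implied_correlation_matrix(published_minimal_params(), relationship_spec("full"))
  expect_equal(round(S["p1", "o11"], 2), 0.15)
  # frozen 1e7-draw structural Monte-Carlo oracle values (SE ~ 3.2e-4)
  expect_lt(abs(S["o11", "o21"] - 0.08077), 3 * 3.2e-4)
  expect_lt(abs(S["p1", "o21"] - 0.06396), 3 * 3.2e-4)
  expect_lt(abs(S["p1", "o11"] - 0.14703), 3 * 3.2e-4)
})

test_that("implied matrices are symmetric, unit-diagonal, PSD and monotone in beta and r_g", {
  set.seed(42)
  for (i in 1:25) {
    a2p <- runif(1, 0.05, 0.9); c2p <- runif(1, 0, 0.9 - a2p)
    a2o <- runif(1, 0.05, 0.9); c2o <- runif(1, 0, 0.9 - a2o)
    p <- liability_params(beta = runif(1, -0.3, 0.5), r_g = runif(1, -1, 1),
                          a2_p = a2p, c2_p = c2p, a2_o = a2o, c2_o = c2o)
    spec <- relationship_spec(sample(c("full", "maternal-half", "DZ-twin",
                                       "MZ-twin"), 1),
                              n_offspring = sample(1:2, 2, replace = TRUE))
    S <- implied_correlation_matrix(p, spec)
    expect_true(isSymmetric(S))
    expect_equal(unname(diag(S)), rep(1, nrow(S)))
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
  }
  # strict monotonicity of the parent-offspring entry
  base <- function(beta, r_g) {
    p <- liability_params(beta = beta, r_g = r_g, a2_p = 0.5, a2_o = 0.6)
    implied_correlation_matrix(p, relationship_spec("full"))["p1", "o11"]
  }
  bgrid <- seq(-0.2, 0.5, by = 0.05)
  expect_true(all(diff(vapply(bgrid, base, 0, r_g = 0.4)) > 0))
  rgrid <- seq(-0.9, 0.9, by = 0.1)
  expect_true(all(diff(vapply(rgrid, function(r) base(0.1, r), 0)) > 0))
})

test_that("orthant probabilities match closed forms and normalize", {
  expect_equal(orthant_probability(diag(2), c(0, 0), c(1, 1)), 0.25,
               tolerance = 1e-10)
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(orthant_probability(S, c(0, 0), c(1, 1)),
               0.25 + asin(0.5) / (2 * pi), tolerance = 1e-8)
  # normalization in 3 and 4 dimensions
  for (d in 3:4) {
    R <- matrix(0.2, d, d); diag(R) <- 1
    tot <- sum(vapply(0:(2^d - 1), function(m) {
      pat <- as.integer(bitwAnd(m, 2^(0:(d - 1))) > 0)
      orthant_probability(R, rep(0.5, d), pat)
    }, 0))
    expect_equal(tot, 1, tolerance = 1e-7)
  }
  expect_error(orthant_probability(diag(9), rep(0, 9), rep(1, 9)),
               "dimension")
  expect_error(orthant_probability(diag(2), c(0, 0), c(1, 2)), "binary")
})

test_that("4-dim orthant agrees with a brute-force Monte-Carlo draw", {
  R <- matrix(0.2, 4, 4); diag(R) <- 1
  p_impl <- orthant_probability(R, rep(0, 4), rep(1, 4))
  set.seed(7)
  n <- 2e6
  hits <- 0
  L <- chol(R)
  for (chunk in 1:4) {
    Z <- matrix(rnorm(4 * n / 4), ncol = 4) %*% L
    hits <- hits + sum(rowSums(Z > 0) == 4)
  }
  p_mc <- hits / n
  se <- sqrt(p_mc * (1 - p_mc) / n)
  expect_lt(abs(p_impl - p_mc), 3 * se)
})

test_that("family likelihood factorizes, normalizes and matches an independent quadrature oracle", {
  th <- recovery_truth()
  spec <- relationship_spec("full")
  # independence: all-zero pattern log-probability is the sum of marginals
  ind <- liability_params(beta = 0, r_g = 0, a2_p = 0, c2_p = 0,
                          a2_o = 0, c2_o = 0, tau_p = th$tau_p,
                          tau_o = th$tau_o)
  obs <- c(p1 = 0, p2 = 0, o11 = 0, o21 = 0)
  expect_equal(family_loglik(ind, obs, spec = spec),
               2 * log(pnorm(th$tau_p)) + 2 * log(pnorm(th$tau_o)),
               tolerance = 1e-8)
  # normalization over all 16 patterns
  tot <- sum(vapply(0:15, function(m) {
    pat <- as.integer(bitwAnd(m, 2^(0:3)) > 0)
    exp(family_loglik(th, setNames(pat, c("p1", "p2", "o11", "o21")),
                      spec = spec))
  }, 0))
  expect_equal(tot, 1, tolerance = 1e-8)
  # conditional-quadrature oracle (independent decomposition)
  S <- implied_correlation_matrix(th, spec)
  tau <- c(th$tau_p, th$tau_p, th$tau_o, th$tau_o)
  for (m in c(0L, 1L, 5L)) {
    pat <- as.integer(bitwAnd(m, 2^(0:3)) > 0)
    ll <- family_loglik(th, setNames(pat, c("p1", "p2", "o11", "o21")),
                        spec = spec)
    expect_equal(exp(ll), conditional_orthant_oracle(S, tau, pat),
                 tolerance = 1e-8)
  }
})

test_that("missing members are marginalized out of the family likelihood", {
  th <- recovery_truth()
  full_spec <- relationship_spec("full", n_offspring = c(1, 1))
  red_spec <- relationship_spec("full", n_offspring = c(1, 0))
  ll_na <- family_loglik(th, c(p1 = 1, p2 = 0, o11 = 0, o21 = NA),
                         spec = full_spec)
  ll_red <- family_loglik(th, c(p1 = 1, p2 = 0, o11 = 0), spec = red_spec)
  expect_equal(ll_na, ll_red, tolerance = 1e-10)
  # data-frame interface agrees with the vector interface
  row <- tibble::tibble(parent_type = "full", y_p1 = 1, y_p2 = 0,
                        y_o11 = 0, y_o12 = NA_real_, y_o21 = NA_real_,
                        y_o22 = NA_real_)
  expect_equal(family_loglik(th, row), ll_red, tolerance = 1e-10)
})

test_that("pattern probabilities normalize for six-member families", {
  th <- recovery_truth()
  spec <- relationship_spec("maternal-half", n_offspring = c(2, 2))
  S <- implied_correlation_matrix(th, spec)
  tau <- c(rep(th$tau_p, 2), rep(th$tau_o, 4))
  p <- kinliab:::pattern_probabilities(S, tau, steps = 128)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p > 0))
})
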