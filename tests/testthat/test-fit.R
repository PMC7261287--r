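# Maximum-likelihood fitting, model comparison, the moment solver, the
# covariance-due-to-beta decomposition, and tetrachoric estimation.

exact_weighted_families <- function(params, n_per_type = 1e5) {
  # expected pattern frequencies as fractional weights: the MLE on these
  # "data" is the generating parameter vector itself
  out <- list()
  for (type in c("full", "maternal-half")) {
    spec <- relationship_spec(type)
    S <- implied_correlation_matrix(params, spec)
    tau <- c(params$tau_p, params$tau_p, params$tau_o, params$tau_o)
    p <- kinliab:::pattern_probabilities(S, tau, steps = 512)
    pats <- attr(p, "patterns")
    out[[type]] <- tibble::tibble(
      parent_type = type,
      y_p1 = pats[, 1], y_p2 = pats[, 2], y_o11 = pats[, 3],
      y_o12 = NA_real_, y_o21 = pats[, 4], y_o22 = NA_real_,
      weight = as.numeric(p) * n_per_type)
  }
  dplyr::bind_rows(out)
}

test_that("the MLE on expected-frequency data recovers the generating parameters", {
  truth <- recovery_truth()
  fam <- exact_weighted_families(truth)
  fit <- fit_ml(fam, constraint = "c2_zero", options = list(hessian = FALSE))
  expect_true(fit$converged)
  expect_equal(fit$params$beta, truth$beta, tolerance = 2e-3)
  expect_equal(fit$params$r_g, truth$r_g, tolerance = 2e-2)
  expect_equal(fit$params$a2_p, truth$a2_p, tolerance = 5e-3)
  expect_equal(fit$params$a2_o, truth$a2_o, tolerance = 2e-2)
  expect_equal(fit$params$tau_p, truth$tau_p, tolerance = 1e-3)
  expect_equal(fit$params$tau_o, truth$tau_o, tolerance = 1e-3)
})

test_that("constrained fits never beat the free fit and compare_models reports nesting", {
  truth <- recovery_truth()
  fam <- simulate_bg_families(truth, 5000, seed = 31)
  free <- fit_ml(fam, constraint = "c2_zero", options = list(hessian = FALSE))
  rg1 <- fit_ml(fam, constraint = c("c2_zero", "rg_one"),
                options = list(hessian = FALSE))
  rg0 <- fit_ml(fam, constraint = c("c2_zero", "rg_zero"),
                options = list(hessian = FALSE))
  eqh <- fit_ml(fam, constraint = c("c2_zero", "equal_h2"),
                options = list(hessian = FALSE))
  expect_lte(rg1$loglik, free$loglik + 1e-6)
  expect_lte(rg0$loglik, free$loglik + 1e-6)
  expect_lte(eqh$loglik, free$loglik + 1e-6)
  cmp <- compare_models(free = free, rg1 = rg1, rg0 = rg0, eqh = eqh)
  expect_setequal(cmp$model, c("free", "rg1", "rg0", "eqh"))
  expect_true(all(cmp$LR[cmp$model != "free"] >= 0, na.rm = TRUE))
  expect_equal(cmp$LR_df[cmp$model == "rg1"], 1)
  expect_equal(unname(cmp$df[cmp$model == "free"] -
                        cmp$df[cmp$model == "eqh"]), 1)
})

test_that("identical genetic correlation in every family is flagged as unidentified", {
  truth <- recovery_truth()
  fam <- simulate_bg_families(truth, 3000,
                              parent_mix = c("full" = 1), seed = 5)
  fam$g <- 0.5
  expect_warning(fit_ml(fam, constraint = "c2_zero",
                        options = list(hessian = FALSE)),
                 "not separately identified")
})

test_that("the moment solver round-trips model-implied correlations exactly", {
  truth <- liability_params(beta = 0.10, r_g = 0.40, a2_p = 0.50, a2_o = 0.60)
  rho <- kinliab:::implied_relationship_correlations(truth)
  sol <- solve_moments(rho)
  expect_true(sol$consistent)
  expect_equal(sol$params$beta, 0.10, tolerance = 1e-6)
  expect_equal(sol$params$r_g, 0.40, tolerance = 1e-6)
  expect_equal(sol$params$a2_p, 0.50, tolerance = 1e-6)
  expect_equal(sol$params$a2_o, 0.60, tolerance = 1e-6)

  # a no-direct-path structure returns beta = 0
  rho0 <- kinliab:::implied_relationship_correlations(
    liability_params(beta = 0, r_g = 0.5, a2_p = 0.4, a2_o = 0.7))
  expect_lt(abs(solve_moments(rho0)$params$beta), 1e-6)

  # inconsistent input is flagged with a nonzero residual
  rho_bad <- rho
  rho_bad[["cousin_full"]] <- rho_bad[["cousin_full"]] + 0.05
  sol_bad <- solve_moments(rho_bad)
  expect_false(sol_bad$consistent)
  expect_gt(sol_bad$residual_norm, 1e-4)

  expect_error(solve_moments(rho[-1]), "parent_sibling_half")
})

test_that("moment solver and ML agree on noise-free input", {
  truth <- recovery_truth()
  sol <- solve_moments(kinliab:::implied_relationship_correlations(truth))
  fit <- fit_ml(exact_weighted_families(truth), constraint = "c2_zero",
                options = list(hessian = FALSE))
  expect_equal(sol$params$beta, fit$params$beta, tolerance = 5e-3)
  expect_equal(sol$params$r_g, fit$params$r_g, tolerance = 3e-2)
  expect_equal(sol$params$a2_p, fit$params$a2_p, tolerance = 1e-2)
  expect_equal(sol$params$a2_o, fit$params$a2_o, tolerance = 3e-2)
})

test_that("covariance share of the direct path follows its closed form", {
  expect_equal(covariance_share_beta(
    liability_params(beta = 0, r_g = 0.4, a2_p = 0.5, a2_o = 0.6)), 0)
  expect_equal(covariance_share_beta(
    liability_params(beta = 0.2, r_g = 0, a2_p = 0.5, a2_o = 0.6)), 100)
  expect_equal(covariance_share_beta(published_minimal_params()), 27.083,
               tolerance = 1e-3)
  expect_error(covariance_share_beta(
    liability_params(beta = 0, r_g = 0, a2_p = 0.5, a2_o = 0.6)),
    "undefined")
})

test_that("tetrachoric ML recovers closed-form and null cases", {
  # cells from the arcsine closed form at rho = 0.5, tau = (0, 0)
  est <- tetrachoric_estimate(matrix(c(400, 200, 200, 400), 2, byrow = TRUE))
  expect_equal(est$rho, 0.5, tolerance = 1e-4)
  expect_equal(est$tau_row, 0, tolerance = 1e-4)
  expect_equal(est$tau_col, 0, tolerance = 1e-4)
  expect_true(est$conf.low < 0.5 && 0.5 < est$conf.high)
  expect_equal(sum(est$fitted), 1, tolerance = 1e-8)

  # independence
  est0 <- tetrachoric_estimate(matrix(c(8100, 900, 900, 100), 2, byrow = TRUE))
  expect_lt(abs(est0$rho), 1e-3)

  # boundary and degenerate tables
  expect_warning(b <- tetrachoric_estimate(matrix(c(50, 0, 0, 50), 2)),
                 "boundary")
  expect_equal(b$rho, 1)
  expect_error(tetrachoric_estimate(matrix(c(10, 10, 0, 0), 2, byrow = TRUE)),
               "margins")
})

test_that("tidy and glance expose estimates and fit summaries", {
  truth <- recovery_truth()
  fam <- simulate_bg_families(truth, 4000, seed = 8)
  fit <- fit_ml(fam, constraint = "c2_zero")
  td <- tidy(fit)
  expect_true(all(c("beta", "r_g", "a2_p", "a2_o") %in% td$term))
  est <- td[!is.na(td$std.error), ]
  expect_true(all(est$conf.low <= est$estimate & est$estimate <= est$conf.high))
  gl <- glance(fit)
  expect_equal(gl$AIC, 2 * fit$n_par - 2 * fit$loglik)
  expect_equal(gl$n_families, 4000)
  sb <- fit$covariance_due_to_beta
  expect_true(sb$conf.low <= sb$estimate && sb$estimate <= sb$conf.high)
})
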