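## Moment-based (least-squares) solution of the transmission model from
## relationship-specific liability correlations, with the shared
## environment fixed at zero.  Given tetrachoric estimates for the seven
## informative relationships the implied-correlation system is inverted by
## nonlinear least squares; on model-implied input the round trip is exact
## to optimizer tolerance.

MOMENT_RELATIONSHIPS <- c("parent_sibling_half", "parent_sibling_full",
                          "parent_offspring",
                          "avuncular_half", "avuncular_full",
                          "cousin_half", "cousin_full")

implied_relationship_correlations <- function(params) {
  bl_h <- implied_blocks(params, relationship_spec("maternal-half"))
  bl_f <- implied_blocks(params, relationship_spec("full"))
  c(parent_sibling_half = bl_h$r_pp, parent_sibling_full = bl_f$r_pp,
    parent_offspring = bl_f$r_po,
    avuncular_half = bl_h$r_av, avuncular_full = bl_f$r_av,
    cousin_half = bl_h$r_cc, cousin_full = bl_f$r_cc)
}

#' Solve the transmission model from relationship correlations
#'
#' Least-squares inversion of the implied-correlation system for
#' `(beta, r_g, a2_p, a2_o)` with shared environment fixed at zero, from
#' liability-scale (tetrachoric) correlations of the seven informative
#' relationships: parent siblings (half/full), parent-offspring, avuncular
#' (half/full) and cousins (half/full).
#'
#' @param correlations Named numeric vector or list containing
#'   `parent_sibling_half`, `parent_sibling_full`, `parent_offspring`,
#'   `avuncular_half`, `avuncular_full`, `cousin_half`, `cousin_full`.
#' @param tol Residual norm below which the input is considered
#'   model-consistent.
#' @return An object of class `moment_solution`: the recovered
#'   [liability_params()], fitted and residual correlations, the residual
#'   norm and a `consistent` flag.
#' @examples
#' th <- liability_params(beta = 0.1, r_g = 0.4, a2_p = 0.5, a2_o = 0.6)
#' rho <- kinliab:::implied_relationship_correlations(th)
#' solve_moments(rho)
#' @export
solve_moments <- function(correlations, tol = 1e-6) {
  obs <- unlist(correlations)
  missing <- setdiff(MOMENT_RELATIONSHIPS, names(obs))
  if (length(missing)) {
    stop("moment system under-determined; missing relationships: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  obs <- obs[MOMENT_RELATIONSHIPS]

  unpack <- function(th) {
    liability_params(beta = th[1], r_g = tanh(th[2]),
                     a2_p = stats::plogis(th[3]), a2_o = stats::plogis(th[4]))
  }
  objective <- function(th) {
    imp <- implied_relationship_correlations(unpack(th))
    sum((imp - obs)^2)
  }
  # analytic-style starting values: with c2 = 0, the full-sib parent
  # correlation is 0.5 a2_p
  a2_p0 <- min(max(2 * obs[["parent_sibling_full"]], 0.05), 0.95)
  starts <- list(
    c(0.05, atanh(0.3), stats::qlogis(a2_p0), stats::qlogis(0.5)),
    c(0.0, atanh(0.6), stats::qlogis(a2_p0), stats::qlogis(0.3)),
    c(0.1, atanh(0.1), stats::qlogis(0.5), stats::qlogis(0.6))
  )
  fits <- lapply(starts, function(s) {
    stats::nlminb(s, objective,
                  control = list(rel.tol = 1e-15, abs.tol = 1e-18,
                                 iter.max = 1000, eval.max = 4000))
  })
  fit <- fits[[which.min(vapply(fits, function(f) f$objective, numeric(1)))]]
  params <- unpack(fit$par)
  fitted <- implied_relationship_correlations(params)
  residuals <- obs - fitted
  res_norm <- sqrt(sum(residuals^2))
  structure(
    list(params = params,
         observed = obs, fitted = fitted, residuals = residuals,
         residual_norm = res_norm, consistent = res_norm < tol),
    class = "moment_solution"
  )
}

#' @export
print.moment_solution <- function(x, ...) {
  cat("<moment_solution>",
      if (x$consistent) "(model-consistent input)" else
        sprintf("(residual norm %.3g; input not exactly model-implied)",
                x$residual_norm), "\n")
  print(x$params)
  invisible(x)
}

#' @method tidy moment_solution
#' @export
tidy.moment_solution <- function(x, ...) {
  tibble::tibble(
    relationship = names(x$observed),
    observed = unname(x$observed),
    fitted = unname(x$fitted),
    residual = unname(x$residuals)
  )
}
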