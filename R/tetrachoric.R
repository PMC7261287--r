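## Tetrachoric correlation: maximum likelihood under the bivariate-normal
## threshold model for a 2x2 table of binary outcomes.

#' Tetrachoric correlation from a 2x2 table
#'
#' Maximum-likelihood estimate of the latent bivariate-normal correlation
#' `rho` and the two thresholds from a 2x2 contingency table of binary
#' outcomes, with a Wald CI for `rho` from the observed information.
#'
#' @param table A 2x2 matrix of counts (rows: first variable 0/1, columns:
#'   second variable 0/1), or a length-4 vector `c(n00, n01, n10, n11)`.
#' @param conf_level Confidence level for the interval.
#' @return An object of class `tetrachoric` with fields `rho`, `tau_row`,
#'   `tau_col`, `conf.low`, `conf.high`, `counts`, `fitted` (cell
#'   probabilities) and `boundary`.
#' @examples
#' tetrachoric_estimate(matrix(c(400, 200, 200, 400), 2))
#' @export
tetrachoric_estimate <- function(table, conf_level = 0.95) {
  if (!is.matrix(table)) table <- matrix(as.numeric(table), 2, 2, byrow = TRUE)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  n <- sum(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("tetrachoric estimation requires positive margins", call. = FALSE)
  }
  # perfect association: boundary result
  if (table[1, 2] + table[2, 1] == 0 || table[1, 1] + table[2, 2] == 0) {
    rho <- if (table[1, 2] + table[2, 1] == 0) 1 else -1
    warning("empty diagonal: correlation at boundary ", rho, call. = FALSE)
    p_row <- sum(table[2, ]) / n
    p_col <- sum(table[, 2]) / n
    return(structure(list(
      rho = rho, tau_row = threshold_from_prevalence(p_row),
      tau_col = threshold_from_prevalence(p_col),
      conf.low = NA_real_, conf.high = NA_real_,
      counts = table, fitted = table / n, n = n,
      boundary = TRUE, conf_level = conf_level), class = "tetrachoric"))
  }

  cell_probs <- function(rho, tr, tc) {
    S <- matrix(c(1, rho, rho, 1), 2)
    p11 <- orthant_probability(S, c(tr, tc), c(1, 1))
    p10 <- stats::pnorm(-tr) - p11
    p01 <- stats::pnorm(-tc) - p11
    p00 <- 1 - p11 - p10 - p01
    pmax(c(p00, p01, p10, p11), 1e-12)
  }
  counts <- c(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
  negll <- function(th) {
    p <- cell_probs(tanh(th[1]), th[2], th[3])
    -sum(counts * log(p))
  }
  start <- c(atanh(0.99 * cos(pi / (1 + sqrt(table[1, 1] * table[2, 2] /
                                               max(table[1, 2] * table[2, 1], 0.5))))),
             threshold_from_prevalence(sum(table[2, ]) / n),
             threshold_from_prevalence(sum(table[, 2]) / n))
  fit <- stats::nlminb(start, negll,
                       control = list(rel.tol = 1e-12, iter.max = 500))
  th <- fit$par
  rho <- tanh(th[1])
  H <- numDeriv::hessian(negll, th)
  se_z <- tryCatch(sqrt(solve(H)[1, 1]), error = function(e) NA_real_)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    rho = rho, tau_row = th[2], tau_col = th[3],
    conf.low = tanh(th[1] - z * se_z), conf.high = tanh(th[1] + z * se_z),
    counts = table,
    fitted = matrix(cell_probs(rho, th[2], th[3]), 2, byrow = TRUE),
    n = n, boundary = FALSE, conf_level = conf_level,
    loglik = -fit$objective, converged = fit$convergence == 0),
    class = "tetrachoric")
}

#' @export
print.tetrachoric <- function(x, ...) {
  cat(sprintf("<tetrachoric> rho = %.3f (%.0f%% CI %.3f, %.3f), n = %d\n",
              x$rho, 100 * x$conf_level, x$conf.low, x$conf.high, as.integer(x$n)))
  cat(sprintf("  thresholds: row %.3f, col %.3f\n", x$tau_row, x$tau_col))
  invisible(x)
}

#' @method tidy tetrachoric
#' @export
tidy.tetrachoric <- function(x, ...) {
  tibble::tibble(
    term = c("rho", "tau_row", "tau_col"),
    estimate = c(x$rho, x$tau_row, x$tau_col),
    conf.low = c(x$conf.low, NA, NA),
    conf.high = c(x$conf.high, NA, NA)
  )
}
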