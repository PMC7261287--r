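#' Liability-threshold model parameters
#'
#' Bundles the full parameter vector of the two-generation liability model:
#' ACE variance shares for the parent and offspring generations, the
#' cross-generation genetic correlation `r_g`, the direct phenotypic
#' transmission path `beta`, and the probit-scale thresholds of the two
#' generations.  Parent liability has unit variance; the offspring residual
#' (before the direct path) also has unit variance, so `beta` additionally
#' contributes to the implied offspring variance (see
#' [implied_correlation_matrix()]).
#'
#' @param beta Direct transmission path from the parent's liability to the
#'   offspring's liability (unitless, liability scale).
#' @param r_g Genetic correlation between the parental and offspring
#'   phenotypes, in `[-1, 1]`.
#' @param a2_p,c2_p Additive-genetic and shared-environment variance shares
#'   of the parent liability; `e2_p` is computed as the remainder.
#' @param a2_o,c2_o Variance shares of the offspring residual liability;
#'   `e2_o` is the remainder.
#' @param tau_p,tau_o Probit thresholds for the parent and offspring
#'   generations; a phenotype is expressed when liability exceeds the
#'   threshold.  Defaults correspond to lifetime prevalences of 3.16%
#'   (parents) and 3.82% (offspring).
#' @param gamma_p,gamma_o Optional covariate (e.g. propensity score)
#'   coefficients that shift member liabilities on the probit scale.
#'
#' @return An object of class `liability_params` (a named list).
#' @examples
#' liability_params(beta = 0.04, r_g = 0.39, a2_p = 0.50, a2_o = 0.61)
#' @export
liability_params <- function(beta = 0, r_g = 0, a2_p = 0.5, c2_p = 0,
                             a2_o = 0.5, c2_o = 0,
                             tau_p = threshold_from_prevalence(0.0316),
                             tau_o = threshold_from_prevalence(0.0382),
                             gamma_p = NULL, gamma_o = NULL) {
  e2_p <- 1 - a2_p - c2_p
  e2_o <- 1 - a2_o - c2_o
  shares <- c(a2_p = a2_p, c2_p = c2_p, e2_p = e2_p,
              a2_o = a2_o, c2_o = c2_o, e2_o = e2_o)
  if (any(shares < -1e-8)) {
    stop("variance shares must be non-negative and sum to 1 within each ",
         "generation; got ", paste(names(shares)[shares < -1e-8], collapse = ", "),
         " < 0", call. = FALSE)
  }
  if (abs(r_g) > 1) stop("r_g must lie in [-1, 1]", call. = FALSE)
  structure(
    list(beta = beta, r_g = r_g,
         a2_p = a2_p, c2_p = c2_p, e2_p = max(e2_p, 0),
         a2_o = a2_o, c2_o = c2_o, e2_o = max(e2_o, 0),
         tau_p = tau_p, tau_o = tau_o,
         gamma_p = gamma_p, gamma_o = gamma_o),
    class = "liability_params"
  )
}

#' @export
print.liability_params <- function(x, ...) {
  cat("<liability_params>\n")
  cat(sprintf("  beta = %.4f, r_g = %.4f\n", x$beta, x$r_g))
  cat(sprintf("  parent    A/C/E = %.3f / %.3f / %.3f  (tau = %.3f)\n",
              x$a2_p, x$c2_p, x$e2_p, x$tau_p))
  cat(sprintf("  offspring A/C/E = %.3f / %.3f / %.3f  (tau = %.3f)\n",
              x$a2_o, x$c2_o, x$e2_o, x$tau_o))
  invisible(x)
}

#' Probit threshold for a lifetime prevalence
#'
#' Returns the threshold `tau` such that a standard-normal liability exceeds
#' `tau` with probability `p`, i.e. `pnorm(-tau) == p`.
#'
#' @param p Lifetime prevalence(s), each in (0, 1).
#' @return Numeric vector of thresholds.
#' @examples
#' threshold_from_prevalence(0.5)     # 0
#' threshold_from_prevalence(0.0316)  # about 1.857
#' @export
threshold_from_prevalence <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("prevalence must lie strictly inside (0, 1)", call. = FALSE)
  }
  -stats::qnorm(p)
}

PARENT_SIBLING_TYPES <- c("full", "maternal-half", "paternal-half",
                          "DZ-twin", "MZ-twin")

#' Additive-genetic correlation between sibling parents
#'
#' Maps the parent-pair sibling type to the expected additive-genetic
#' correlation `g`: 0.5 for full siblings and DZ twins, 0.25 for half-
#' siblings, 1 for MZ twins.
#'
#' @param parent_type Character vector of sibling types (see
#'   [relationship_spec()]).
#' @return Numeric vector of genetic correlations.
#' @export
parent_g <- function(parent_type) {
  g <- c("full" = 0.5, "maternal-half" = 0.25, "paternal-half" = 0.25,
         "DZ-twin" = 0.5, "MZ-twin" = 1)[parent_type]
  if (any(is.na(g))) {
    stop("unknown parent sibling type: ",
         paste(unique(parent_type[is.na(g)]), collapse = ", "), call. = FALSE)
  }
  unname(g)
}

#' Relationship structure of one extended family
#'
#' Describes the analysis unit of the behavior-genetic model: two sibling
#' parents (with additive-genetic correlation `g` implied by their sibling
#' type) each with up to two offspring.  Family members are ordered
#' `p1, p2, o11, o12, o21, o22`, where `oij` is offspring `j` of parent `i`.
#'
#' @param parent_type Sibling type of the parent pair: `"full"`,
#'   `"maternal-half"`, `"paternal-half"`, `"DZ-twin"` or `"MZ-twin"`.
#' @param n_offspring Integer vector of length 2: offspring count (0-2) of
#'   each parent.
#' @param offspring_type Sibling type of offspring within a nuclear family:
#'   `"full"` (genetic correlation 0.5) or `"half"` (0.25).
#' @return An object of class `relationship_spec`.
#' @examples
#' relationship_spec("full", n_offspring = c(1, 1))
#' @export
relationship_spec <- function(parent_type = "full", n_offspring = c(1, 1),
                              offspring_type = "full") {
  parent_type <- match.arg(parent_type, PARENT_SIBLING_TYPES)
  offspring_type <- match.arg(offspring_type, c("full", "half"))
  n_offspring <- as.integer(n_offspring)
  if (length(n_offspring) != 2 || any(n_offspring < 0) || any(n_offspring > 2)) {
    stop("n_offspring must give 0-2 offspring for each of the two parents",
         call. = FALSE)
  }
  members <- c("p1", "p2",
               if (n_offspring[1] >= 1) "o11", if (n_offspring[1] >= 2) "o12",
               if (n_offspring[2] >= 1) "o21", if (n_offspring[2] >= 2) "o22")
  structure(
    list(parent_type = parent_type,
         g = parent_g(parent_type),
         n_offspring = n_offspring,
         offspring_type = offspring_type,
         g_offspring_sibs = if (offspring_type == "full") 0.5 else 0.25,
         members = members),
    class = "relationship_spec"
  )
}

#' @export
print.relationship_spec <- function(x, ...) {
  cat(sprintf("<relationship_spec> %s parents (g = %.2f), offspring %d + %d\n",
              x$parent_type, x$g, x$n_offspring[1], x$n_offspring[2]))
  invisible(x)
}
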