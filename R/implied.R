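## Implied covariance algebra of the two-generation liability model.
##
## Parent liability:    L_p = a_p A_p + c_p C_p + e_p E_p,  Var = 1.
## Offspring liability: L_o = beta * L_p(own) + a_o A_o + c_o C_o + e_o E_o,
## whose variance is s_o^2 = 1 + beta^2 + 2 beta (0.5 r_g a_p a_o); observed
## offspring correlations are standardized by s_o so that every member of
## the implied matrix is a correlation.
##
## Cross-member correlations follow the path rules: sibling parents share
## genetics g (0.25 half / 0.5 full and DZ / 1 MZ) and, by the co-rearing
## convention, their shared environment fully (kappa_C = 1); a parent and
## their own offspring's genetic factors correlate 0.5 r_g; avuncular
## genetic overlap is 0.5 g r_g; cousins share 0.25 g of the offspring
## additive factor and none of the offspring shared environment.

implied_blocks <- function(params, spec) {
  b <- params$beta
  g <- spec$g
  ap <- sqrt(params$a2_p); ao <- sqrt(params$a2_o)
  cross_own <- 0.5 * params$r_g * ap * ao        # cov(L_p, own-offspring residual)
  s_o2 <- 1 + b^2 + 2 * b * cross_own
  kappa_C <- 1                                    # co-reared sibling parents
  r_pp <- g * params$a2_p + kappa_C * params$c2_p
  list(
    s_o = sqrt(s_o2),
    s_o2 = s_o2,
    r_pp = r_pp,
    # parent with own offspring
    r_po = (b + cross_own) / sqrt(s_o2),
    # parent with sibling's offspring (avuncular)
    r_av = (b * r_pp + 0.5 * g * params$r_g * ap * ao) / sqrt(s_o2),
    # offspring of the same parent (within a nuclear family)
    r_ss = (b^2 + 2 * b * cross_own +
              spec$g_offspring_sibs * params$a2_o + params$c2_o) / s_o2,
    # offspring of the two sibling parents (cousins)
    r_cc = (b^2 * r_pp + 2 * b * 0.5 * g * params$r_g * ap * ao +
              0.25 * g * params$a2_o) / s_o2
  )
}

#' Implied correlation matrix of an extended family
#'
#' Evaluates the model-implied correlation matrix of the latent liabilities
#' of one extended family (two sibling parents plus up to two offspring
#' each) at a given parameter vector.  Offspring entries are standardized by
#' the implied offspring liability standard deviation, so the matrix has a
#' unit diagonal.
#'
#' @param params A [liability_params()] object.
#' @param spec A [relationship_spec()] describing the family structure.
#' @return Correlation matrix with row/column names `p1, p2, o11, ...`.
#' @examples
#' th <- liability_params(beta = 0.04, r_g = 0.39, a2_p = 0.50, a2_o = 0.61)
#' implied_correlation_matrix(th, relationship_spec("full"))
#' @export
implied_correlation_matrix <- function(params, spec) {
  stopifnot(inherits(params, "liability_params"),
            inherits(spec, "relationship_spec"))
  bl <- implied_blocks(params, spec)
  members <- spec$members
  d <- length(members)
  parent_of <- function(m) as.integer(substr(m, 2, 2))
  is_par <- substr(members, 1, 1) == "p"
  S <- diag(d)
  for (i in seq_len(d - 1)) {
    for (j in (i + 1):d) {
      mi <- members[i]; mj <- members[j]
      v <- if (is_par[i] && is_par[j]) {
        bl$r_pp
      } else if (is_par[i] || is_par[j]) {
        if (parent_of(mi) == parent_of(mj)) bl$r_po else bl$r_av
      } else {
        if (parent_of(mi) == parent_of(mj)) bl$r_ss else bl$r_cc
      }
      S[i, j] <- S[j, i] <- v
    }
  }
  dimnames(S) <- list(members, members)
  check_psd(S)
  S
}

#' Share of the parent-offspring covariance due to the direct path
#'
#' Decomposes the implied parent-offspring liability covariance
#' `beta + 0.5 r_g a_p a_o` into the direct transmission path versus shared
#' genetic factors, returning the direct path's percentage share
#' `100 * beta / (beta + 0.5 r_g a_p a_o)`.
#'
#' @param params A [liability_params()] object.
#' @return Percentage (may fall outside `[0, 100]` when `beta` and the
#'   genetic term have opposite signs).
#' @examples
#' covariance_share_beta(
#'   liability_params(beta = 0.04, r_g = 0.39, a2_p = 0.50, a2_o = 0.61))
#' @export
covariance_share_beta <- function(params) {
  stopifnot(inherits(params, "liability_params"))
  genetic <- 0.5 * params$r_g * sqrt(params$a2_p) * sqrt(params$a2_o)
  total <- params$beta + genetic
  if (abs(total) < 1e-12) {
    stop("parent-offspring covariance is zero; the direct-path share is ",
         "undefined", call. = FALSE)
  }
  100 * params$beta / total
}
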