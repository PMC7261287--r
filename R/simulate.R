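## Structural simulation of family liabilities.  Components are drawn at
## the A/C/E level (not from the implied phenotypic matrix), so the
## empirical correlation structure of the draws is an independent check on
## the implied covariance algebra.

# Additive-genetic correlation matrix across family members
genetic_corr_matrix <- function(spec, r_g) {
  members <- spec$members
  d <- length(members)
  parent_of <- function(m) as.integer(substr(m, 2, 2))
  is_par <- substr(members, 1, 1) == "p"
  R <- diag(d)
  for (i in seq_len(d - 1)) {
    for (j in (i + 1):d) {
      v <- if (is_par[i] && is_par[j]) {
        spec$g
      } else if (is_par[i] || is_par[j]) {
        if (parent_of(members[i]) == parent_of(members[j])) 0.5 * r_g
        else 0.5 * spec$g * r_g
      } else {
        if (parent_of(members[i]) == parent_of(members[j]))
          spec$g_offspring_sibs
        else 0.25 * spec$g
      }
      R[i, j] <- R[j, i] <- v
    }
  }
  R
}

# eigen-based square root; tolerates semi-definite matrices (MZ parents)
mvn_sqrt <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    stop("component correlation matrix not positive semi-definite; ",
         "offending parameter combination r_g/g", call. = FALSE)
  }
  e$vectors %*% (t(e$vectors) * sqrt(pmax(e$values, 0)))
}

#' Draw latent liabilities and components for replicate families
#'
#' Simulates `n` replicate extended families of one structure at the
#' component (A/C/E) level: member additive-genetic factors are drawn with
#' the kinship-implied correlations (including the cross-generation genetic
#' correlation `r_g`), shared environment is common to co-reared members,
#' and the offspring liability adds the direct path `beta` times the
#' parent's liability.  Offspring liabilities are standardized by the
#' implied offspring SD, and binary phenotypes are thresholded at the
#' generation thresholds in `params`.
#'
#' @param params A [liability_params()] object.
#' @param spec A [relationship_spec()].
#' @param n Number of replicate families.
#' @return A list with matrices (`n` rows, one column per family member)
#'   `liability` (standardized), `phenotype` (0/1), and the component draws
#'   `A`, `C`, `E`.  Uses the current RNG state; seed externally.
#' @examples
#' set.seed(1)
#' sim <- draw_family_liabilities(
#'   liability_params(beta = .1, r_g = .4, a2_p = .5, a2_o = .6),
#'   relationship_spec("full"), n = 1000)
#' cor(sim$liability[, "p1"], sim$liability[, "o11"])
#' @export
draw_family_liabilities <- function(params, spec, n = 1) {
  stopifnot(inherits(params, "liability_params"),
            inherits(spec, "relationship_spec"))
  members <- spec$members
  d <- length(members)
  is_par <- substr(members, 1, 1) == "p"
  parent_idx <- as.integer(substr(members, 2, 2))

  A <- matrix(stats::rnorm(n * d), n, d) %*%
    t(mvn_sqrt(genetic_corr_matrix(spec, params$r_g)))
  E <- matrix(stats::rnorm(n * d), n, d)
  C_p <- stats::rnorm(n)                      # shared by co-reared parents
  C_o <- matrix(stats::rnorm(n * 2), n, 2)    # per nuclear family
  C <- matrix(0, n, d)
  C[, is_par] <- C_p
  for (j in which(!is_par)) C[, j] <- C_o[, parent_idx[j]]

  L <- matrix(0, n, d)
  for (j in which(is_par)) {
    L[, j] <- sqrt(params$a2_p) * A[, j] + sqrt(params$c2_p) * C[, j] +
      sqrt(params$e2_p) * E[, j]
  }
  s_o <- implied_blocks(params, spec)$s_o
  for (j in which(!is_par)) {
    own <- which(is_par & parent_idx == parent_idx[j])
    L[, j] <- (params$beta * L[, own] + sqrt(params$a2_o) * A[, j] +
                 sqrt(params$c2_o) * C[, j] + sqrt(params$e2_o) * E[, j]) / s_o
  }
  tau <- ifelse(is_par, params$tau_p, params$tau_o)
  phen <- sweep(L, 2, tau, ">") * 1L
  colnames(L) <- colnames(phen) <- colnames(A) <- colnames(C) <-
    colnames(E) <- members
  list(liability = L, phenotype = phen, A = A, C = C, E = E)
}

#' Simulate extended-family observations for the behavior-genetic model
#'
#' Draws `n` extended families (structure sampled from `parent_mix` and
#' `offspring_per_parent`) at the component level via
#' [draw_family_liabilities()] and returns the binary family observations
#' in the shape expected by [fit_ml()].
#'
#' @param params A [liability_params()] object (the generating truth).
#' @param n Number of families.
#' @param parent_mix Named proportions over parent sibling types.
#' @param offspring_per_parent Named proportions over offspring counts
#'   (`"1"`, `"2"`) per parent.
#' @param seed Integer seed.
#' @return Tibble with `parent_type` and phenotype columns `y_p1 ... y_o22`.
#' @export
simulate_bg_families <- function(params, n,
                                 parent_mix = c("full" = 0.5,
                                                "maternal-half" = 0.5),
                                 offspring_per_parent = c("1" = 1),
                                 seed = 1) {
  stopifnot(n >= 1)
  if (abs(sum(parent_mix) - 1) > 1e-8 || any(parent_mix < 0)) {
    stop("parent_mix must be non-negative proportions summing to 1",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    types <- sample(names(parent_mix), n, replace = TRUE, prob = parent_mix)
    noff1 <- as.integer(sample(names(offspring_per_parent), n, replace = TRUE,
                               prob = offspring_per_parent))
    noff2 <- as.integer(sample(names(offspring_per_parent), n, replace = TRUE,
                               prob = offspring_per_parent))
    key <- paste(types, noff1, noff2)
    out <- vector("list", length(unique(key)))
    names(out) <- unique(key)
    for (k in unique(key)) {
      rows <- which(key == k)
      spec <- relationship_spec(types[rows[1]],
                                n_offspring = c(noff1[rows[1]], noff2[rows[1]]))
      sim <- draw_family_liabilities(params, spec, n = length(rows))
      tb <- tibble::tibble(.rows = length(rows))
      tb$parent_type <- types[rows[1]]
      for (m in FAMILY_MEMBERS) {
        tb[[paste0("y_", m)]] <- if (m %in% spec$members) {
          as.numeric(sim$phenotype[, m])
        } else NA_real_
      }
      tb$row_order <- rows
      out[[k]] <- tb
    }
    dplyr::bind_rows(out) |>
      dplyr::arrange(.data$row_order) |>
      dplyr::select(-"row_order")
  })
}
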