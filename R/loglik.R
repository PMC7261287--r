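## Liability-threshold likelihood over extended-family observations.
##
## A family observation is a binary pattern over the members p1, p2,
## o11, o12, o21, o22 (NA = member absent or phenotype missing; both are
## marginalized out of the orthant probability).  Member thresholds are the
## generation thresholds, optionally shifted per member by -gamma' x when
## covariates (propensity scores) enter the model.

FAMILY_MEMBERS <- c("p1", "p2", "o11", "o12", "o21", "o22")

member_generation <- function(members) {
  ifelse(substr(members, 1, 1) == "p", "parent", "offspring")
}

# master 6x6 implied matrix for a parent-pair genetic correlation g,
# from which every observed-member subset is taken
master_corr <- function(params, g, offspring_type = "full") {
  spec <- relationship_spec("full", n_offspring = c(2, 2),
                            offspring_type = offspring_type)
  spec$g <- g
  implied_correlation_matrix(params, spec)
}

member_thresholds <- function(params, members, shifts = NULL) {
  tau <- ifelse(member_generation(members) == "parent",
                params$tau_p, params$tau_o)
  if (!is.null(shifts)) tau <- tau - shifts
  tau
}

#' Log-likelihood of one extended-family observation
#'
#' Computes the log orthant probability of a family's binary phenotype
#' pattern under the implied liability correlation structure.  Members with
#' `NA` phenotype (absent or unobserved) are marginalized out.
#'
#' @param params A [liability_params()] object.
#' @param obs Named vector of 0/1/NA phenotypes; names from
#'   `c("p1","p2","o11","o12","o21","o22")`.  Alternatively a one-row data
#'   frame with columns `y_p1, y_p2, y_o11, ...` and `parent_type`.
#' @param spec A [relationship_spec()]; required when `obs` is a bare
#'   vector, ignored (rebuilt from `parent_type`) when `obs` is a row.
#' @param shifts Optional named per-member liability shifts `gamma' x`
#'   (positive shifts raise the member's liability, i.e. lower its
#'   threshold).
#' @return Log-probability of the observed pattern.
#' @examples
#' th <- liability_params(beta = 0.1, r_g = 0.4, a2_p = 0.5, a2_o = 0.6)
#' family_loglik(th, c(p1 = 1, p2 = 0, o11 = 0, o21 = 0),
#'               spec = relationship_spec("full"))
#' @export
family_loglik <- function(params, obs, spec = NULL, shifts = NULL) {
  if (is.data.frame(obs)) {
    stopifnot(nrow(obs) == 1)
    spec <- relationship_spec(obs$parent_type[1], n_offspring = c(2, 2))
    y <- vapply(FAMILY_MEMBERS, function(m) {
      col <- paste0("y_", m)
      if (col %in% names(obs)) as.numeric(obs[[col]][1]) else NA_real_
    }, numeric(1))
    obs <- y
  }
  if (is.null(spec)) stop("spec is required when obs is a bare vector",
                          call. = FALSE)
  members_all <- if (all(names(obs) %in% FAMILY_MEMBERS) &&
                     !is.null(names(obs))) names(obs) else spec$members
  keep <- !is.na(obs)
  if (!any(keep)) return(0)
  members <- members_all[keep]
  S <- master_corr(params, spec$g, spec$offspring_type)[members, members,
                                                        drop = FALSE]
  sh <- if (!is.null(shifts)) shifts[keep] else NULL
  tau <- member_thresholds(params, members, sh)
  log(orthant_probability(S, tau, obs[keep]))
}

## ---- grouped likelihood used by the ML fit ------------------------------

# Collapse a families tibble into groups sharing (g, offspring type,
# observed-member mask, pattern).  Returns a list of blocks, one per
# (g, mask), each holding the member indices, a pattern-index vector into
# the 2^k pattern table, and aggregated weights.
prepare_family_groups <- function(families) {
  y_cols <- paste0("y_", FAMILY_MEMBERS)
  for (col in y_cols) if (!col %in% names(families)) families[[col]] <- NA_real_
  g <- if ("g" %in% names(families)) families$g else parent_g(families$parent_type)
  off_type <- if ("offspring_type" %in% names(families)) {
    families$offspring_type
  } else rep("full", nrow(families))
  w <- if ("weight" %in% names(families)) families$weight else rep(1, nrow(families))
  Y <- as.matrix(families[, y_cols])
  mask <- !is.na(Y)
  mask_key <- apply(mask, 1, function(m) paste(which(m), collapse = ","))
  blk_key <- paste(g, off_type, mask_key, sep = "|")
  blocks <- list()
  for (key in unique(blk_key)) {
    rows <- which(blk_key == key)
    members_idx <- which(mask[rows[1], ])
    if (length(members_idx) == 0) next
    k <- length(members_idx)
    pat <- Y[rows, members_idx, drop = FALSE]
    # index into pattern_probabilities output: mask value + 1
    pidx <- as.vector(pat %*% 2^(seq_len(k) - 1)) + 1
    agg <- rowsum(w[rows], pidx)
    blocks[[key]] <- list(
      g = g[rows[1]],
      offspring_type = off_type[rows[1]],
      members = FAMILY_MEMBERS[members_idx],
      pattern_index = as.integer(rownames(agg)),
      counts = as.vector(agg)
    )
  }
  blocks
}

grouped_negloglik <- function(params, blocks, steps = 128L) {
  ll <- 0
  cache <- list()
  for (blk in blocks) {
    ckey <- paste(blk$g, blk$offspring_type)
    if (is.null(cache[[ckey]])) {
      cache[[ckey]] <- master_corr(params, blk$g, blk$offspring_type)
    }
    S <- cache[[ckey]][blk$members, blk$members, drop = FALSE]
    tau <- member_thresholds(params, blk$members)
    p <- pattern_probabilities(S, tau, steps = steps)
    ll <- ll + sum(blk$counts * log(p[blk$pattern_index]))
  }
  -ll
}

# Per-family representation used when member-specific covariate shifts
# make grouping impossible.  f$X is a (members x q) covariate matrix,
# zero-padded across generations, so shift = X %*% gamma.
prepare_family_rows <- function(families, covariates) {
  y_cols <- paste0("y_", FAMILY_MEMBERS)
  for (col in y_cols) if (!col %in% names(families)) families[[col]] <- NA_real_
  g <- if ("g" %in% names(families)) families$g else parent_g(families$parent_type)
  off_type <- if ("offspring_type" %in% names(families)) {
    families$offspring_type
  } else rep("full", nrow(families))
  w <- if ("weight" %in% names(families)) families$weight else rep(1, nrow(families))
  cov_p <- covariates$parent %||% character(0)
  cov_o <- covariates$offspring %||% character(0)
  q <- length(cov_p) + length(cov_o)
  lapply(seq_len(nrow(families)), function(i) {
    y <- vapply(y_cols, function(col) as.numeric(families[[col]][i]), numeric(1))
    keep <- which(!is.na(y))
    members <- FAMILY_MEMBERS[keep]
    X <- matrix(0, nrow = length(members), ncol = q)
    for (m in seq_along(members)) {
      gen <- member_generation(members[m])
      covs <- if (gen == "parent") cov_p else cov_o
      offset <- if (gen == "parent") 0L else length(cov_p)
      for (k in seq_along(covs)) {
        col <- paste0(covs[k], "_", members[m])
        if (!col %in% names(families)) {
          stop("missing covariate column `", col, "` in families table",
               call. = FALSE)
        }
        X[m, offset + k] <- families[[col]][i]
      }
    }
    list(g = g[i], offspring_type = off_type[i], members = members,
         pattern = y[keep], weight = w[i], X = X)
  })
}

perfamily_negloglik <- function(params, gamma, fam_list, steps = 256L) {
  ll <- 0
  cache <- list()
  for (f in fam_list) {
    ckey <- paste(f$g, f$offspring_type)
    if (is.null(cache[[ckey]])) {
      cache[[ckey]] <- master_corr(params, f$g, f$offspring_type)
    }
    S <- cache[[ckey]][f$members, f$members, drop = FALSE]
    shift <- if (length(gamma)) as.vector(f$X %*% gamma) else NULL
    tau <- member_thresholds(params, f$members, shift)
    ll <- ll + f$weight * log(orthant_probability(S, tau, f$pattern,
                                                  steps = steps))
  }
  -ll
}
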