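## Maximum-likelihood estimation of the two-generation liability model.
##
## Optimization runs on an unconstrained scale: variance shares through a
## multinomial-logit (simplex) transform (or a single logit when the shared
## environment is fixed at zero), the genetic correlation through tanh,
## beta, thresholds and covariate coefficients untransformed.  Wald
## standard errors come from the observed information on that transformed
## scale; monotone transforms map CI endpoints back, simplex shares use the
## delta method.

CONSTRAINT_CHOICES <- c("free", "c2_zero", "rg_zero", "rg_one", "equal_h2")

normalize_constraints <- function(constraint) {
  aliases <- c("rg0" = "rg_zero", "rg1" = "rg_one", "equal-h2" = "equal_h2",
               "c2-zero" = "c2_zero")
  constraint <- unname(ifelse(constraint %in% names(aliases),
                              aliases[constraint], constraint))
  bad <- setdiff(constraint, CONSTRAINT_CHOICES)
  if (length(bad)) {
    stop("unknown constraint(s): ", paste(bad, collapse = ", "),
         "; choose from ", paste(CONSTRAINT_CHOICES, collapse = ", "),
         call. = FALSE)
  }
  setdiff(unique(constraint), "free")
}

# Builds the packing/unpacking machinery for a constraint set.
make_param_map <- function(constraint, cov_p = character(0),
                           cov_o = character(0)) {
  c2_zero <- "c2_zero" %in% constraint
  rg_fixed <- if ("rg_zero" %in% constraint) 0 else
    if ("rg_one" %in% constraint) 1 else NA_real_
  equal_h2 <- "equal_h2" %in% constraint

  nm <- "beta"
  if (is.na(rg_fixed)) nm <- c(nm, "z_rg")
  nm <- c(nm, if (c2_zero) "l_a2_p" else c("u_a2_p", "u_c2_p"))
  if (!equal_h2) nm <- c(nm, if (c2_zero) "l_a2_o" else c("u_a2_o", "u_c2_o"))
  nm <- c(nm, "tau_p", "tau_o")
  if (length(cov_p)) nm <- c(nm, paste0("gamma_p_", cov_p))
  if (length(cov_o)) nm <- c(nm, paste0("gamma_o_", cov_o))

  softmax2 <- function(u1, u2) {
    z <- 1 + exp(u1) + exp(u2)
    c(exp(u1) / z, exp(u2) / z)
  }
  unpack <- function(theta) {
    names(theta) <- nm
    beta <- theta[["beta"]]
    r_g <- if (is.na(rg_fixed)) tanh(theta[["z_rg"]]) else rg_fixed
    if (c2_zero) {
      a2_p <- stats::plogis(theta[["l_a2_p"]]); c2_p <- 0
    } else {
      s <- softmax2(theta[["u_a2_p"]], theta[["u_c2_p"]])
      a2_p <- s[1]; c2_p <- s[2]
    }
    if (equal_h2) {
      a2_o <- a2_p; c2_o <- c2_p
    } else if (c2_zero) {
      a2_o <- stats::plogis(theta[["l_a2_o"]]); c2_o <- 0
    } else {
      s <- softmax2(theta[["u_a2_o"]], theta[["u_c2_o"]])
      a2_o <- s[1]; c2_o <- s[2]
    }
    gamma <- theta[grepl("^gamma_", nm)]
    list(params = liability_params(beta = beta, r_g = r_g,
                                   a2_p = a2_p, c2_p = c2_p,
                                   a2_o = a2_o, c2_o = c2_o,
                                   tau_p = theta[["tau_p"]],
                                   tau_o = theta[["tau_o"]]),
         gamma = unname(gamma))
  }
  init <- function(prev_p, prev_o) {
    th <- c(beta = 0.05)
    if (is.na(rg_fixed)) th <- c(th, z_rg = atanh(0.3))
    if (c2_zero) th <- c(th, l_a2_p = stats::qlogis(0.4)) else
      th <- c(th, u_a2_p = log(0.45 / 0.5), u_c2_p = log(0.05 / 0.5))
    if (!equal_h2) {
      if (c2_zero) th <- c(th, l_a2_o = stats::qlogis(0.4)) else
        th <- c(th, u_a2_o = log(0.45 / 0.5), u_c2_o = log(0.05 / 0.5))
    }
    th <- c(th, tau_p = threshold_from_prevalence(prev_p),
            tau_o = threshold_from_prevalence(prev_o))
    c(th, rep(0, length(cov_p) + length(cov_o)))
  }
  list(names = nm, n_par = length(nm), unpack = unpack, init = init,
       c2_zero = c2_zero, rg_fixed = rg_fixed, equal_h2 = equal_h2,
       cov_p = cov_p, cov_o = cov_o)
}

observed_prevalences <- function(families) {
  y_cols <- paste0("y_", FAMILY_MEMBERS)
  y_cols <- intersect(y_cols, names(families))
  w <- families[["weight"]] %||% rep(1, nrow(families))
  num_p <- den_p <- num_o <- den_o <- 0
  for (col in y_cols) {
    gen <- member_generation(sub("^y_", "", col))
    y <- families[[col]]
    ok <- !is.na(y)
    if (gen == "parent") {
      num_p <- num_p + sum(w[ok] * y[ok]); den_p <- den_p + sum(w[ok])
    } else {
      num_o <- num_o + sum(w[ok] * y[ok]); den_o <- den_o + sum(w[ok])
    }
  }
  c(parent = max(min(num_p / max(den_p, 1), 0.99), 0.005),
    offspring = max(min(num_o / max(den_o, 1), 0.99), 0.005))
}

#' Fit the liability-threshold transmission model by maximum likelihood
#'
#' Maximizes the orthant-probability likelihood of binary extended-family
#' observations over the model parameters (variance shares, genetic
#' correlation `r_g`, direct path `beta`, generation thresholds, and
#' optional covariate coefficients), under an optional set of constraints
#' used for sensitivity analysis.
#'
#' @param families Tibble of extended-family observations: one row per
#'   family with `parent_type` and phenotype columns `y_p1, y_p2, y_o11,
#'   y_o12, y_o21, y_o22` (0/1, `NA` for absent or unobserved members).
#'   Optional columns: `g` (override of the parent-pair genetic
#'   correlation), `offspring_type`, `weight`, and per-member covariate
#'   columns `<name>_p1`, `<name>_o11`, ... when `covariates` is given.
#' @param constraint Character vector of constraints: `"free"` (none),
#'   `"c2_zero"` (no shared environment), `"rg_zero"`/`"rg_one"` (genetic
#'   correlation fixed), `"equal_h2"` (parent and offspring variance shares
#'   tied).  Aliases `"rg0"`, `"rg1"`, `"equal-h2"` are accepted and
#'   constraints can be combined.
#' @param covariates Optional list with elements `parent` and `offspring`
#'   naming covariates whose per-member columns shift member thresholds by
#'   `-gamma' x` (probit-scale adjustment, e.g. propensity score logits).
#' @param options List of fitting options: `n_starts` (number of jittered
#'   starts, default 1 plus automatic restarts on non-convergence), `seed`
#'   (jitter seed), `steps` (Miwa quadrature steps), `hessian` (compute
#'   standard errors, default `TRUE`).
#' @return A `liability_fit` object; see [tidy()][generics::tidy] and
#'   [glance()][generics::glance] methods.
#' @examples
#' \donttest{
#' th <- liability_params(beta = 0.1, r_g = 0.4, a2_p = 0.5, a2_o = 0.6,
#'                        tau_p = threshold_from_prevalence(0.1),
#'                        tau_o = threshold_from_prevalence(0.1))
#' fam <- simulate_bg_families(th, n = 2000, seed = 1)
#' fit <- fit_ml(fam, constraint = "c2_zero")
#' }
#' @export
fit_ml <- function(families, constraint = "free", covariates = NULL,
                   options = list()) {
  stopifnot(is.data.frame(families), nrow(families) >= 1)
  constraint <- normalize_constraints(constraint)
  cov_p <- covariates$parent %||% character(0)
  cov_o <- covariates$offspring %||% character(0)
  map <- make_param_map(constraint, cov_p, cov_o)
  # 128 Miwa quadrature steps keep the absolute cell-probability error near
  # 1e-7, small enough not to bias the score even with ~1e5 families; the
  # error is a smooth function of the parameters, so finite-difference
  # derivatives remain safe
  steps <- options$steps %||% 128L
  n_starts <- options$n_starts %||% 1L
  seed <- options$seed %||% 1407L
  do_hessian <- options$hessian %||% TRUE

  gvals <- if ("g" %in% names(families)) families$g else
    parent_g(families$parent_type)
  if (length(unique(gvals)) < 2) {
    warning("only one parent-sibling genetic correlation present; ",
            "variance components are not separately identified",
            call. = FALSE)
  }

  use_covariates <- length(cov_p) + length(cov_o) > 0
  if (use_covariates) {
    fam_list <- prepare_family_rows(families, list(parent = cov_p,
                                                   offspring = cov_o))
    negll <- function(theta) {
      u <- map$unpack(theta)
      tryCatch(perfamily_negloglik(u$params, u$gamma, fam_list, steps = steps),
               error = function(e) 1e10)
    }
  } else {
    blocks <- prepare_family_groups(families)
    negll <- function(theta) {
      u <- map$unpack(theta)
      tryCatch(grouped_negloglik(u$params, blocks, steps = steps),
               error = function(e) 1e10)
    }
  }

  prev <- observed_prevalences(families)
  theta0 <- map$init(prev[["parent"]], prev[["offspring"]])
  if (!is.null(options$start)) theta0 <- options$start

  starts <- list(theta0)
  if (n_starts > 1) {
    jit <- withr::with_seed(seed, {
      lapply(seq_len(n_starts - 1),
             function(i) theta0 + stats::rnorm(length(theta0), sd = 0.3))
    })
    starts <- c(starts, jit)
  }

  run_one <- function(th) {
    stats::nlminb(th, negll, lower = rep(-12, length(th)),
                  upper = rep(12, length(th)),
                  control = list(rel.tol = 1e-9, iter.max = 300,
                                 eval.max = 1200))
  }
  # nlminb's "false/singular convergence" is the expected outcome when a
  # variance share sits on its boundary (the likelihood is one-sided flat);
  # treat it as converged-with-boundary rather than restarting.
  acceptable <- function(f) {
    f$convergence == 0 ||
      grepl("relative convergence|false convergence|singular convergence",
            f$message %||% "")
  }
  fits <- lapply(starts, run_one)
  attempts <- length(fits)
  while (!any(vapply(fits, acceptable, logical(1))) && attempts < 5) {
    attempts <- attempts + 1
    extra <- withr::with_seed(seed + attempts, {
      theta0 + stats::rnorm(length(theta0), sd = 0.5)
    })
    fits <- c(fits, list(run_one(extra)))
  }
  obj <- vapply(fits, function(f) f$objective, numeric(1))
  betas <- vapply(fits, function(f) abs(f$par[1]), numeric(1))
  best <- order(round(obj, 6), betas)[1]
  fit <- fits[[best]]
  theta_hat <- fit$par
  names(theta_hat) <- map$names
  u <- map$unpack(theta_hat)

  vcov_theta <- matrix(NA_real_, map$n_par, map$n_par)
  identification_warning <- FALSE
  if (do_hessian) {
    H <- numDeriv::hessian(negll, theta_hat)
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0 || max(ev) / max(min(ev), 1e-300) > 1e10) {
      identification_warning <- TRUE
      warning("observed information is singular or near-singular; ",
              "standard errors use a pseudo-inverse and may be unreliable",
              call. = FALSE)
      vcov_theta <- pseudo_inverse(H)
    } else {
      vcov_theta <- solve(H)
    }
  }
  dimnames(vcov_theta) <- list(map$names, map$names)

  n_fam <- sum(families[["weight"]] %||% rep(1, nrow(families)))
  res <- structure(
    list(params = u$params, gamma = u$gamma,
         theta = theta_hat, vcov_theta = vcov_theta, map = map,
         loglik = -fit$objective, n_par = map$n_par,
         n_families = n_fam,
         converged = acceptable(fit),
         boundary_note = if (fit$convergence != 0 && acceptable(fit)) {
           "one or more parameters at or near a boundary (one-sided flat likelihood)"
         },
         message = fit$message,
         constraint = if (length(constraint)) constraint else "free",
         identification_warning = identification_warning,
         negll = negll),
    class = "liability_fit"
  )
  res$tidy <- tidy_liability_fit(res)
  res$covariance_due_to_beta <- share_beta_ci(res)
  res
}

# natural-scale estimates, SEs and 95% CIs from the transformed-scale fit
tidy_liability_fit <- function(fit) {
  map <- fit$map
  th <- fit$theta
  V <- fit$vcov_theta
  se_of <- function(nm) sqrt(pmax(diag(V)[nm], 0))
  rows <- list()
  add <- function(term, est, se, lo, hi, fixed = FALSE) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      term = term, estimate = est,
      std.error = if (fixed) NA_real_ else se,
      conf.low = if (fixed) NA_real_ else lo,
      conf.high = if (fixed) NA_real_ else hi)
  }
  z <- stats::qnorm(0.975)

  se_b <- se_of("beta")
  add("beta", th[["beta"]], se_b, th[["beta"]] - z * se_b,
      th[["beta"]] + z * se_b)

  if (is.na(map$rg_fixed)) {
    se_z <- se_of("z_rg")
    rg <- tanh(th[["z_rg"]])
    add("r_g", rg, (1 - rg^2) * se_z, tanh(th[["z_rg"]] - z * se_z),
        tanh(th[["z_rg"]] + z * se_z))
  } else {
    add("r_g", map$rg_fixed, NA, NA, NA, fixed = TRUE)
  }

  share_rows <- function(suffix) {
    if (map$c2_zero) {
      nm <- paste0("l_a2_", suffix)
      a2 <- stats::plogis(th[[nm]])
      se_l <- se_of(nm)
      add(paste0("a2_", suffix), a2, a2 * (1 - a2) * se_l,
          stats::plogis(th[[nm]] - z * se_l), stats::plogis(th[[nm]] + z * se_l))
      add(paste0("c2_", suffix), 0, NA, NA, NA, fixed = TRUE)
      e2 <- 1 - a2
      add(paste0("e2_", suffix), e2, a2 * (1 - a2) * se_l,
          1 - stats::plogis(th[[nm]] + z * se_l),
          1 - stats::plogis(th[[nm]] - z * se_l))
    } else {
      nms <- paste0(c("u_a2_", "u_c2_"), suffix)
      f_share <- function(tt) {
        zz <- 1 + exp(tt[1]) + exp(tt[2])
        c(exp(tt[1]) / zz, exp(tt[2]) / zz, 1 / zz)
      }
      sh <- f_share(th[nms])
      J <- numDeriv::jacobian(f_share, th[nms])
      Vs <- J %*% V[nms, nms] %*% t(J)
      ses <- sqrt(pmax(diag(Vs), 0))
      lbl <- paste0(c("a2_", "c2_", "e2_"), suffix)
      for (k in 1:3) {
        add(lbl[k], sh[k], ses[k], sh[k] - z * ses[k], sh[k] + z * ses[k])
      }
    }
  }
  share_rows("p")
  if (map$equal_h2) {
    # offspring shares mirror the parent rows
    n0 <- length(rows)
    share_rows("p")
    for (k in (n0 + 1):length(rows)) {
      rows[[k]]$term <- sub("_p$", "_o", rows[[k]]$term)
    }
  } else {
    share_rows("o")
  }

  for (nm in c("tau_p", "tau_o")) {
    se <- se_of(nm)
    add(nm, th[[nm]], se, th[[nm]] - z * se, th[[nm]] + z * se)
  }
  for (nm in grep("^gamma_", map$names, value = TRUE)) {
    se <- se_of(nm)
    add(nm, th[[nm]], se, th[[nm]] - z * se, th[[nm]] + z * se)
  }
  dplyr::bind_rows(rows)
}

# delta-method CI for the covariance-due-to-beta percentage
share_beta_ci <- function(fit, boot = 0) {
  est <- tryCatch(covariance_share_beta(fit$params), error = function(e) NA)
  if (is.na(est) || all(is.na(fit$vcov_theta))) {
    return(list(estimate = est, conf.low = NA_real_, conf.high = NA_real_))
  }
  f <- function(theta) {
    u <- fit$map$unpack(theta)
    covariance_share_beta(u$params)
  }
  gr <- numDeriv::grad(f, fit$theta)
  v <- drop(t(gr) %*% fit$vcov_theta %*% gr)
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(0.975)
  list(estimate = est, conf.low = est - z * se, conf.high = est + z * se,
       std.error = se)
}

#' @export
print.liability_fit <- function(x, ...) {
  cat("<liability_fit> constraint:", paste(x$constraint, collapse = "+"),
      if (!x$converged) " (NOT converged)", "\n")
  cat(sprintf("  log-likelihood %.2f on %d parameters, %s families\n",
              x$loglik, x$n_par, format(x$n_families, big.mark = ",")))
  print(as.data.frame(x$tidy), digits = 3, row.names = FALSE)
  sb <- x$covariance_due_to_beta
  cat(sprintf("  covariance due to beta: %.1f%% (95%% CI %.1f, %.1f)\n",
              sb$estimate, sb$conf.low, sb$conf.high))
  invisible(x)
}

#' @export
logLik.liability_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_par, nobs = object$n_families,
            class = "logLik")
}

#' Compare liability-model fits
#'
#' Tabulates log-likelihood, parameter count and AIC for a set of fits of
#' the same data, with likelihood-ratio statistics for nested pairs
#' (a constrained fit is compared against the least-constrained fit whose
#' constraint set it extends).  Non-nested pairs are reported AIC-only.
#'
#' @param ... `liability_fit` objects (or a single list of them), ideally
#'   named.
#' @return A tibble with one row per model.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "liability_fit")) {
    fits <- fits[[1]]
  }
  stopifnot(all(vapply(fits, inherits, logical(1), "liability_fit")))
  labels <- names(fits)
  if (is.null(labels) || any(labels == "")) {
    labels <- vapply(fits, function(f) paste(f$constraint, collapse = "+"), "")
  }
  df <- vapply(fits, function(f) f$n_par, numeric(1))
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  ref <- which.max(df)
  cset <- lapply(fits, function(f) setdiff(f$constraint, "free"))
  lr <- lr_df <- lr_p <- rep(NA_real_, length(fits))
  note <- rep("", length(fits))
  for (i in seq_along(fits)) {
    if (i == ref) next
    nested <- all(cset[[ref]] %in% cset[[i]]) && df[i] < df[ref]
    if (nested) {
      lr[i] <- 2 * (ll[ref] - ll[i])
      lr_df[i] <- df[ref] - df[i]
      lr_p[i] <- stats::pchisq(lr[i], lr_df[i], lower.tail = FALSE)
    } else {
      note[i] <- "AIC-only (not nested in reference)"
    }
  }
  tibble::tibble(
    model = labels, logLik = ll, df = df, AIC = 2 * df - 2 * ll,
    delta_AIC = 2 * df - 2 * ll - min(2 * df - 2 * ll),
    LR = lr, LR_df = lr_df, LR_p = lr_p, note = note
  ) |> dplyr::arrange(.data$AIC)
}
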