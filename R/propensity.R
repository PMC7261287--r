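## Propensity scores: logistic regression of the lifetime suicidal-behavior
## indicator on role-specific covariates, used downstream as probit-scale
## adjustment covariates (entered as the logit / linear predictor).

propensity_covariates <- function(role) {
  switch(role,
         mother = ,
         father = c("education", "born_in_sweden", "severe_mental_illness",
                    "substance_use", "criminal_conviction"),
         offspring = c("birth_year", "parity", "maternal_age"))
}

# model frame with education's missing category as its own level
propensity_frame <- function(persons, role, all_persons = NULL) {
  all_persons <- all_persons %||% persons
  out <- tibble::tibble(
    person_id = persons$person_id,
    outcome = as.integer(!is.na(persons$sb_first_date))
  )
  if (role %in% c("mother", "father")) {
    edu <- ifelse(is.na(persons$education_level), "missing",
                  as.character(persons$education_level))
    out$education <- factor(edu, levels = c("3", "1", "2", "4", "5", "6",
                                            "missing"))
    out$born_in_sweden <- as.integer(persons$born_in_sweden)
    out$severe_mental_illness <- as.integer(persons$severe_mental_illness)
    out$substance_use <- as.integer(persons$substance_use)
    out$criminal_conviction <- as.integer(persons$criminal_conviction)
  } else {
    out$birth_year <- as.numeric(format(persons$birth_date, "%Y"))
    out$parity <- factor(pmin(persons$parity, 4L), levels = 1:4)
    mrow <- match(persons$mother_id, all_persons$person_id)
    out$maternal_age <- age_at(persons$birth_date,
                               all_persons$birth_date[mrow])
  }
  out
}

#' Fit a propensity-score model
#'
#' Logistic regression of the lifetime suicidal-behavior indicator on
#' role-specific covariates: education (six levels plus an own "missing"
#' category), country of origin, severe mental illness, substance use and
#' criminal conviction for parents; birth year, parity and maternal age at
#' childbearing for offspring.
#'
#' @param persons Person-level table.
#' @param role `"mother"`, `"father"` or `"offspring"`.
#' @param subset `"auto"` restricts rows to the persons referenced in the
#'   given role (mothers/fathers of someone, or the offspring generation);
#'   `"all"` uses every row as-is (useful for pre-built covariate tables).
#' @return A `propensity_model` object (the glm fit plus role metadata).
#' @export
fit_propensity <- function(persons, role = c("mother", "father", "offspring"),
                           subset = c("auto", "all")) {
  role <- match.arg(role)
  subset <- match.arg(subset)
  rows <- persons
  if (subset == "auto") {
    rows <- switch(role,
      mother = persons[persons$person_id %in% persons$mother_id, ],
      father = persons[persons$person_id %in% persons$father_id, ],
      offspring = if ("generation" %in% names(persons)) {
        persons[persons$generation == "offspring" &
                  !is.na(persons$generation), ]
      } else persons)
  }
  mf <- propensity_frame(rows, role, all_persons = persons)
  mf <- mf[stats::complete.cases(mf), ]
  if (nrow(mf) == 0) stop("no complete rows for propensity fit", call. = FALSE)
  if (length(unique(mf$outcome)) < 2) {
    stop("outcome has zero variance; cannot fit propensity model",
         call. = FALSE)
  }
  covs <- propensity_covariates(role)
  # covariates without variation in this table are inestimable; drop them
  constant <- vapply(covs, function(cl) {
    x <- mf[[cl]]
    length(unique(x[!is.na(x)])) < 2
  }, logical(1))
  if (any(constant)) {
    message("dropping constant covariate(s): ",
            paste(covs[constant], collapse = ", "))
    covs <- covs[!constant]
  }
  if (!length(covs)) stop("no usable covariates for propensity fit",
                          call. = FALSE)
  mf <- droplevels(mf)
  form <- stats::as.formula(paste("outcome ~", paste(covs, collapse = " + ")))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = mf),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  # perfect separation drives IRLS to non-convergence with a diverging
  # coefficient; an extreme but converged category coefficient (e.g. an
  # event-free rare factor level) is reported, not fatal
  if (!fit$converged || (sep_warn && any(abs(stats::coef(fit)[-1]) > 15,
                                         na.rm = TRUE) && !fit$converged)) {
    co <- stats::coef(fit)[-1]
    worst <- names(co)[which.max(abs(co))]
    stop("perfect separation detected in propensity model (covariate: ",
         worst, ")", call. = FALSE)
  }
  structure(
    list(fit = fit, role = role, covariates = covs,
         levels = lapply(mf[intersect(covs, names(mf))],
                         function(x) if (is.factor(x)) levels(x) else NULL),
         fitted = tibble::tibble(person_id = mf$person_id,
                                 score = stats::fitted(fit)),
         converged = fit$converged,
         prevalence = mean(mf$outcome)),
    class = "propensity_model"
  )
}

#' Score persons with a fitted propensity model
#'
#' Deterministically evaluates the fitted logistic model on new rows,
#' returning the probability and its logit (the linear predictor, which is
#' how scores enter the liability model).
#'
#' @param model A `propensity_model`.
#' @param persons Person-level table to score.
#' @return Tibble with `person_id`, `score` (probability) and
#'   `score_logit`.
#' @export
score_propensity <- function(model, persons) {
  stopifnot(inherits(model, "propensity_model"))
  if (model$role %in% c("mother", "father")) {
    bad <- setdiff(unique(persons$education_level[!is.na(persons$education_level)]),
                   1:6)
    if (length(bad)) {
      stop("unseen level(s) in `education`: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  mf <- propensity_frame(persons, model$role, all_persons = persons)
  for (nm in names(model$levels)) {
    lev <- model$levels[[nm]]
    if (is.null(lev)) next
    seen <- unique(as.character(mf[[nm]]))
    new <- setdiff(seen[!is.na(seen)], lev)
    if (length(new)) {
      stop("unseen level(s) in `", nm, "`: ", paste(new, collapse = ", "),
           call. = FALSE)
    }
  }
  eta <- as.numeric(stats::predict(model$fit, newdata = mf, type = "link"))
  tibble::tibble(person_id = mf$person_id,
                 score = stats::plogis(eta),
                 score_logit = eta)
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("<propensity_model>", x$role, "; n =", length(x$fit$y),
      "; prevalence =", signif(x$prevalence, 3), "\n")
  print(summary(x$fit)$coefficients, digits = 3)
  invisible(x)
}

#' @method tidy propensity_model
#' @export
tidy.propensity_model <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(co), estimate = co[, 1],
                 std.error = co[, 2], statistic = co[, 3],
                 p.value = co[, 4])
}

#' @method glance propensity_model
#' @export
glance.propensity_model <- function(x, ...) {
  tibble::tibble(n = length(x$fit$y), prevalence = x$prevalence,
                 null.deviance = x$fit$null.deviance,
                 deviance = x$fit$deviance, AIC = stats::AIC(x$fit),
                 converged = x$converged)
}
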