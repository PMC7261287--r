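## Generator configuration: the statistical conditions the synthetic
## multi-generation registry emulates.  Defaults are calibrated to the
## cohort the package models: lifetime suicidal-behavior prevalence 3.16%
## among mothers and 2.81% among fathers, an offspring lifetime prevalence
## of 3.82%, covariate frequencies matching the cohort table, births
## 1973-2001 and follow-up to end of 2013.

default_covariate_marginals <- function() {
  list(
    female = list(
      education = c(0.0402, 0.0954, 0.3425, 0.1527, 0.1490, 0.2162, 0.0040),
      born_in_sweden = 0.8821,
      severe_mental_illness = 0.0082,   # bipolar + schizophrenia
      substance_use = 0.0255,
      criminal_conviction = 0.1232
    ),
    male = list(
      education = c(0.0779, 0.1320, 0.3504, 0.1403, 0.1280, 0.1604, 0.0111),
      born_in_sweden = 0.8751,
      severe_mental_illness = 0.0062,
      substance_use = 0.0508,
      criminal_conviction = 0.4086
    )
  )
}

default_covariate_effects <- function() {
  list(
    parent = list(
      # probit-scale liability shifts; education levels 1-6 plus missing
      education = c(0.25, 0.15, 0, -0.05, -0.15, -0.25, 0.20),
      born_abroad = 0.15,
      severe_mental_illness = 0.80,
      substance_use = 0.60,
      criminal_conviction = 0.25
    ),
    offspring = list(
      parity = c(0, 0.05, 0.12, 0.20),
      # maternal age at childbearing, 7 groups (<20 ... >=45)
      maternal_age = c(0.25, 0.10, 0, -0.02, 0.02, 0.05, 0.10)
    )
  )
}

#' Configuration of the synthetic registry generator
#'
#' Bundles every tunable condition of the synthetic multi-generation
#' registry: number of extended families, the mixture of parent sibling
#' types, offspring counts, the generating liability-model truth,
#' covariate marginals and their probit-scale liability effects, target
#' lifetime prevalences (thresholds are calibrated so the covariate-shifted
#' marginals hit them), the case event-age model (truncated Weibull), the
#' censoring model, and the seed.
#'
#' @param n_extended_families Number of extended families (>= 1).
#' @param parent_sibling_mix Named proportions over parent sibling types
#'   `full`, `maternal-half`, `DZ-twin`, `MZ-twin`; must sum to 1.
#' @param offspring_per_parent Named proportions over offspring counts
#'   (`"1"`, `"2"`) for each parent; must sum to 1.
#' @param true_params Generating [liability_params()] (its thresholds are
#'   replaced by calibrated values).
#' @param parent_sex `"mixed"` (each index parent's sex drawn 50/50),
#'   `"female"` (sister pairs) or `"male"`.
#' @param prevalence_targets Named lifetime prevalences `mother`, `father`,
#'   `offspring`, each in (0, 1).
#' @param covariate_effects Probit-scale liability shifts per covariate
#'   (see `default_covariate_effects()` in the sources).
#' @param covariate_marginals Covariate frequencies by sex.
#' @param spouse_covariate_cor Latent (Gaussian-copula) correlation between
#'   an index parent's covariates and their co-parent's, emulating
#'   assortative-mating-style confounding.
#' @param event_age_model Truncated-Weibull event-age model:
#'   `list(shape, scale, min_age, max_age)`; `min_age` must be >= 12
#'   because the phenotype is defined from age 12.
#' @param censoring_model `list(death_rate, emigration_rate, end_of_study)`;
#'   exponential rates per person-year from age 12.
#' @param birth_year_range Calendar years of first-offspring births.
#' @param age_at_childbearing `c(mean, sd, min, max)` of the index parent's
#'   age at first birth.
#' @param exclusion_safe If `TRUE`, offspring first-event dates are pushed
#'   after the parents' so the cohort contains no event-order rule
#'   violations (unless explicitly injected).
#' @param inject_violations Named counts of deliberately injected
#'   exclusion-rule violations (`died_before_12`, `emigrated_before_12`,
#'   `event_before_parent`, `missing_parent_origin`), used to test the
#'   exclusion ledger; they override `exclusion_safe`.
#' @param seed Integer seed; the whole registry is a deterministic
#'   function of the configuration.
#' @return An object of class `registry_config`.
#' @examples
#' cfg <- registry_config(n_extended_families = 100, seed = 7)
#' @export
registry_config <- function(n_extended_families,
                            parent_sibling_mix = c("full" = 0.82,
                                                   "maternal-half" = 0.15,
                                                   "DZ-twin" = 0.02,
                                                   "MZ-twin" = 0.01),
                            offspring_per_parent = c("1" = 0.5, "2" = 0.5),
                            true_params = liability_params(
                              beta = 0.04, r_g = 0.39,
                              a2_p = 0.50, a2_o = 0.61),
                            parent_sex = c("mixed", "female", "male"),
                            prevalence_targets = c(mother = 0.0316,
                                                   father = 0.0281,
                                                   offspring = 0.0382),
                            covariate_effects = default_covariate_effects(),
                            covariate_marginals = default_covariate_marginals(),
                            spouse_covariate_cor = 0.2,
                            event_age_model = list(shape = 2, scale = 30,
                                                   min_age = 12, max_age = 41),
                            censoring_model = list(death_rate = 3e-4,
                                                   emigration_rate = 2e-3,
                                                   end_of_study = as.Date("2013-12-31")),
                            birth_year_range = c(1973, 2001),
                            age_at_childbearing = c(mean = 27.7, sd = 4.8,
                                                    min = 18, max = 45),
                            exclusion_safe = TRUE,
                            inject_violations = c(died_before_12 = 0,
                                                  emigrated_before_12 = 0,
                                                  event_before_parent = 0,
                                                  missing_parent_origin = 0),
                            seed = 1) {
  parent_sex <- match.arg(parent_sex)
  if (!is.numeric(n_extended_families) || n_extended_families < 1) {
    stop("configuration error in `n_extended_families`: must be >= 1",
         call. = FALSE)
  }
  check_mix <- function(mix, field) {
    if (any(mix < 0) || any(mix > 1) || abs(sum(mix) - 1) > 1e-8) {
      stop("configuration error in `", field,
           "`: proportions must lie in [0, 1] and sum to 1", call. = FALSE)
    }
  }
  check_mix(parent_sibling_mix, "parent_sibling_mix")
  check_mix(offspring_per_parent, "offspring_per_parent")
  bad_types <- setdiff(names(parent_sibling_mix),
                       c("full", "maternal-half", "DZ-twin", "MZ-twin"))
  if (length(bad_types)) {
    stop("configuration error in `parent_sibling_mix`: unknown type(s) ",
         paste(bad_types, collapse = ", "), call. = FALSE)
  }
  if (any(prevalence_targets <= 0) || any(prevalence_targets >= 1)) {
    stop("configuration error in `prevalence_targets`: prevalences must ",
         "lie strictly inside (0, 1)", call. = FALSE)
  }
  if (event_age_model$min_age < 12) {
    stop("configuration error in `event_age_model`: min_age must be >= 12 ",
         "(the phenotype is defined from age 12)", call. = FALSE)
  }
  if (event_age_model$max_age < event_age_model$min_age) {
    stop("configuration error in `event_age_model`: max_age < min_age",
         call. = FALSE)
  }
  vi <- c(died_before_12 = 0, emigrated_before_12 = 0,
          event_before_parent = 0, missing_parent_origin = 0)
  vi[names(inject_violations)] <- inject_violations
  structure(
    list(n_extended_families = as.integer(n_extended_families),
         parent_sibling_mix = parent_sibling_mix,
         offspring_per_parent = offspring_per_parent,
         true_params = true_params,
         parent_sex = parent_sex,
         prevalence_targets = prevalence_targets,
         covariate_effects = covariate_effects,
         covariate_marginals = covariate_marginals,
         spouse_covariate_cor = spouse_covariate_cor,
         event_age_model = event_age_model,
         censoring_model = censoring_model,
         birth_year_range = birth_year_range,
         age_at_childbearing = age_at_childbearing,
         exclusion_safe = isTRUE(exclusion_safe),
         inject_violations = vi,
         seed = as.integer(seed)),
    class = "registry_config"
  )
}

#' @export
print.registry_config <- function(x, ...) {
  cat("<registry_config>", x$n_extended_families, "extended families, seed",
      x$seed, "\n")
  cat("  parent mix:", paste(names(x$parent_sibling_mix),
                             x$parent_sibling_mix, collapse = ", "), "\n")
  invisible(x)
}

## threshold calibration: the liability is standard normal plus a discrete
## covariate shift; enumerate the exact atom distribution of the shift and
## solve  sum_i p_i Phi(shift_i - tau) = target  for tau.

enumerate_shift_atoms <- function(components) {
  # components: list of list(probs = ..., shifts = ...)
  shifts <- 0; probs <- 1
  for (comp in components) {
    shifts <- as.vector(outer(shifts, comp$shifts, `+`))
    probs <- as.vector(outer(probs, comp$probs, `*`))
  }
  list(shifts = shifts, probs = probs)
}

calibrate_threshold <- function(target, atoms) {
  f <- function(tau) sum(atoms$probs * stats::pnorm(atoms$shifts - tau)) - target
  stats::uniroot(f, c(-12, 12), tol = 1e-12)$root
}

parent_shift_components <- function(marg, eff) {
  list(
    list(probs = marg$education / sum(marg$education), shifts = eff$education),
    list(probs = c(marg$born_in_sweden, 1 - marg$born_in_sweden),
         shifts = c(0, eff$born_abroad)),
    list(probs = c(1 - marg$severe_mental_illness, marg$severe_mental_illness),
         shifts = c(0, eff$severe_mental_illness)),
    list(probs = c(1 - marg$substance_use, marg$substance_use),
         shifts = c(0, eff$substance_use)),
    list(probs = c(1 - marg$criminal_conviction, marg$criminal_conviction),
         shifts = c(0, eff$criminal_conviction))
  )
}

maternal_age_group <- function(age) {
  cut(age, c(-Inf, 20, 25, 30, 35, 40, 45, Inf), labels = FALSE,
      right = FALSE)
}

age_group_probs <- function(mean, sd, min, max) {
  cuts <- c(20, 25, 30, 35, 40, 45)
  p <- stats::pnorm(c(cuts, Inf), mean, sd) - stats::pnorm(c(-Inf, cuts), mean, sd)
  # clamping at [min, max] moves tail mass into the boundary groups
  p[1] <- stats::pnorm(20, mean, sd)
  p[7] <- 1 - stats::pnorm(45, mean, sd)
  p / sum(p)
}

offspring_shift_components <- function(config) {
  eff <- config$covariate_effects$offspring
  w <- config$offspring_per_parent
  w1 <- if ("1" %in% names(w)) w[["1"]] else 0
  w2 <- if ("2" %in% names(w)) w[["2"]] else 0
  p_parity2 <- w2 / (w1 + 2 * w2)
  ab <- config$age_at_childbearing
  pg1 <- age_group_probs(ab[["mean"]], ab[["sd"]], ab[["min"]], ab[["max"]])
  pg2 <- age_group_probs(ab[["mean"]] + 3.1, ab[["sd"]], ab[["min"]], ab[["max"]])
  # joint atoms over (parity, maternal age group)
  probs <- c((1 - p_parity2) * pg1, p_parity2 * pg2)
  shifts <- c(eff$parity[1] + eff$maternal_age,
              eff$parity[2] + eff$maternal_age)
  list(list(probs = probs, shifts = shifts))
}

registry_thresholds <- function(config) {
  eff_p <- config$covariate_effects$parent
  marg <- config$covariate_marginals
  c(mother = calibrate_threshold(
      config$prevalence_targets[["mother"]],
      enumerate_shift_atoms(parent_shift_components(marg$female, eff_p))),
    father = calibrate_threshold(
      config$prevalence_targets[["father"]],
      enumerate_shift_atoms(parent_shift_components(marg$male, eff_p))),
    offspring = calibrate_threshold(
      config$prevalence_targets[["offspring"]],
      enumerate_shift_atoms(offspring_shift_components(config))))
}
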