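## Survival stage: age is the time scale with entry at exact age 12 and
## half-open person-time intervals; right censoring by death, emigration or
## end of study.  Kaplan-Meier estimation and Cox models (population and
## within-cousin-pair stratified with cluster-robust variance) are computed
## with the survival package; hand partial-likelihood oracles live in the
## test suite.

#' Build survival records from a cohort
#'
#' One row per offspring (or per offspring-by-pair when `pairs` is given,
#' for the within-pair stratified analysis): entry at age 12, exit at the
#' first of event, death, emigration and end of study, with exposure to the
#' analyzed parent's suicidal behavior and the adjustment covariates.
#'
#' Offspring whose parent's first event occurred at or after their 18th
#' birthday are "late-exposed": analyzed as unexposed by default, or
#' dropped with `late_exposed = "exclude"`.
#'
#' @param cohort An `sb_cohort` from [build_cohort()].
#' @param pairs Optional cousin-pair table from [enumerate_cousin_pairs()];
#'   when given, records are duplicated per pair membership with
#'   `stratum_id` (pair) and `cluster_id` (person).
#' @param end_of_study End-of-study date.
#' @param late_exposed `"unexposed"` or `"exclude"`.
#' @return Tibble of survival records.
#' @export
make_survival_records <- function(cohort, pairs = NULL,
                                  end_of_study = as.Date("2013-12-31"),
                                  late_exposed = c("unexposed", "exclude")) {
  stopifnot(inherits(cohort, "sb_cohort"))
  late_exposed <- match.arg(late_exposed)
  co <- cohort$cohort
  persons <- cohort$persons

  status <- exposure_status(
    co, tibble::tibble(sb_first_date = co$parent_sb_first_date))
  if (late_exposed == "exclude") {
    keep <- status != "late-exposed"
    co <- co[keep, ]; status <- status[keep]
  }
  exit_date <- pmin(co$sb_first_date, co$death_date, co$emigration_date,
                    end_of_study, na.rm = TRUE)
  event <- !is.na(co$sb_first_date) & co$sb_first_date <= exit_date
  exit_age <- age_at(exit_date, co$birth_date)
  prow <- match(co$parent_id, persons$person_id)
  rec <- tibble::tibble(
    person_id = co$person_id,
    entry_age = 12,
    exit_age = exit_age,
    event = as.integer(event),
    exposure = as.integer(status == "exposed"),
    late_exposed = status == "late-exposed",
    sex = co$sex,
    parity = co$parity,
    birth_year = as.numeric(format(co$birth_date, "%Y")),
    parental_age = age_at(co$birth_date, co$parent_birth_date),
    parent_education = persons$education_level[prow],
    parent_born_in_sweden = persons$born_in_sweden[prow],
    parent_smi = persons$severe_mental_illness[prow],
    parent_conviction = persons$criminal_conviction[prow]
  )
  dropped <- sum(rec$exit_age <= rec$entry_age, na.rm = TRUE)
  if (dropped > 0) {
    rec <- rec[rec$exit_age > rec$entry_age, ]
  }
  attr(rec, "n_dropped_short_followup") <- dropped
  if (!is.null(pairs)) {
    long <- dplyr::bind_rows(
      tibble::tibble(person_id = pairs$person_id_1, stratum_id = pairs$pair_id),
      tibble::tibble(person_id = pairs$person_id_2, stratum_id = pairs$pair_id))
    rec <- dplyr::inner_join(long, rec, by = "person_id")
    rec$cluster_id <- rec$person_id
  }
  rec
}

#' Kaplan-Meier cumulative incidence per 10,000
#'
#' Product-limit estimate of the probability of a first event by a given
#' age, scaled to events per 10,000 people.
#'
#' @param records Survival records with `entry_age`, `exit_age`, `event`.
#' @param at_age Age at which the cumulative incidence is evaluated.
#' @return Tibble with `at_age`, `cum_incidence_per_10k`, `std.error_per_10k`
#'   (Greenwood), `n` and `events_by_age`.
#' @examples
#' rec <- tibble::tibble(entry_age = 12, exit_age = c(15, 18, 22, 29),
#'                       event = c(1, 0, 1, 0))
#' km_estimate(rec, at_age = 30)  # 6250 per 10,000
#' @export
km_estimate <- function(records, at_age) {
  stopifnot(at_age > 12)
  if (!any(records$entry_age < at_age)) {
    stop("no subjects at risk before age ", at_age, call. = FALSE)
  }
  sf <- survival::survfit(
    survival::Surv(entry_age, exit_age, event) ~ 1,
    data = records)
  sm <- summary(sf, times = at_age, extend = TRUE)
  tibble::tibble(
    at_age = at_age,
    cum_incidence_per_10k = 10000 * (1 - sm$surv),
    std.error_per_10k = 10000 * sm$std.err,
    n = nrow(records),
    events_by_age = sum(records$event == 1 & records$exit_age <= at_age)
  )
}

#' Population Cox proportional-hazards model
#'
#' Partial-likelihood fit (Breslow ties by default) of offspring suicidal
#' behavior on exposure to parental suicidal behavior and optional
#' covariates, on the age scale with delayed entry at 12.  Cluster-robust
#' (sandwich) variance is used when requested or when any person appears in
#' more than one row.
#'
#' @param records Survival records (see [make_survival_records()]).
#' @param covariates Character vector of covariate columns.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param robust `NULL` (auto), `TRUE` or `FALSE`.
#' @return A `cousin_cox` object wrapping the `coxph` fit.
#' @export
fit_cox <- function(records, covariates = NULL, ties = c("breslow", "efron"),
                    robust = NULL) {
  ties <- match.arg(ties)
  if (sum(records$event) < 1) stop("no events in records", call. = FALSE)
  rhs <- paste(c("exposure", covariates), collapse = " + ")
  if (is.null(robust)) {
    robust <- "person_id" %in% names(records) &&
      anyDuplicated(records$person_id) > 0
  }
  form <- stats::as.formula(
    paste("survival::Surv(entry_age, exit_age, event) ~", rhs))
  fit <- if (robust) {
    survival::coxph(form, data = records, ties = ties,
                    cluster = person_id, x = FALSE, y = FALSE)
  } else {
    survival::coxph(form, data = records, ties = ties, x = FALSE, y = FALSE)
  }
  check_cox_sanity(fit)
  new_cousin_cox(fit, records, stratified = FALSE, robust = robust,
                 ties = ties)
}

#' Within-cousin-pair (fixed-effects) Cox model
#'
#' Stratifies the partial likelihood on the cousin-pair identifier, so that
#' only pairs discordant on both exposure and outcome contribute, and uses
#' a sandwich variance clustered on person id (offspring appear once per
#' pair membership).  Covariates constant within every informative pair are
#' inestimable and dropped with a warning.
#'
#' @param records Pair-expanded survival records with `stratum_id` and
#'   `cluster_id` (see [make_survival_records()] with `pairs`).
#' @param covariates Character vector of covariate columns.
#' @param ties `"breslow"` or `"efron"`.
#' @return A `cousin_cox` object.
#' @export
fit_stratified_cox <- function(records, covariates = NULL,
                               ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  stopifnot("stratum_id" %in% names(records))
  info <- records |>
    dplyr::summarise(vary = dplyr::n_distinct(.data$exposure) > 1,
                     events = sum(.data$event), .by = "stratum_id")
  informative <- info$stratum_id[info$vary & info$events > 0]
  if (!length(informative)) {
    stop("no informative strata: every pair is concordant on exposure ",
         "or event-free", call. = FALSE)
  }
  rhs <- paste(c("exposure", covariates), collapse = " + ")
  form <- stats::as.formula(
    paste("survival::Surv(entry_age, exit_age, event) ~", rhs,
          "+ strata(stratum_id)"))
  fit <- survival::coxph(form, data = records, ties = ties,
                         cluster = cluster_id, x = FALSE, y = FALSE)
  dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(dropped)) {
    warning("covariate(s) constant within pairs, dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    keep <- setdiff(covariates, dropped)
    rhs <- paste(c("exposure", keep), collapse = " + ")
    form <- stats::as.formula(
      paste("survival::Surv(entry_age, exit_age, event) ~", rhs,
            "+ strata(stratum_id)"))
    fit <- survival::coxph(form, data = records, ties = ties,
                           cluster = cluster_id, x = FALSE, y = FALSE)
  }
  check_cox_sanity(fit)
  new_cousin_cox(fit, records, stratified = TRUE, robust = TRUE, ties = ties,
                 n_informative_strata = length(informative))
}

check_cox_sanity <- function(fit) {
  co <- stats::coef(fit)
  if (any(abs(co[!is.na(co)]) > 12)) {
    warning("monotone partial likelihood: at least one estimate is ",
            "diverging (|log HR| > 12)", call. = FALSE)
  }
  invisible(fit)
}

new_cousin_cox <- function(fit, records, stratified, robust, ties,
                           n_informative_strata = NA_integer_) {
  structure(
    list(fit = fit, stratified = stratified, robust = robust, ties = ties,
         n = nrow(records), n_events = sum(records$event),
         n_informative_strata = n_informative_strata),
    class = "cousin_cox")
}

#' @export
print.cousin_cox <- function(x, ...) {
  cat("<cousin_cox>", if (x$stratified) "within-pair (stratified)" else
    "population", "; ties:", x$ties,
    if (x$robust) "; cluster-robust SE", "\n")
  print(tidy.cousin_cox(x), digits = 3)
  invisible(x)
}

#' @method tidy cousin_cox
#' @export
tidy.cousin_cox <- function(x, exponentiate = TRUE, ...) {
  s <- summary(x$fit)
  co <- s$coefficients
  se_col <- if ("robust se" %in% colnames(co)) "robust se" else "se(coef)"
  est <- co[, "coef"]
  se <- co[, se_col]
  z <- stats::qnorm(0.975)
  out <- tibble::tibble(
    term = rownames(co),
    estimate = if (exponentiate) exp(est) else est,
    std.error = se,
    statistic = est / se,
    p.value = 2 * stats::pnorm(-abs(est / se)),
    conf.low = if (exponentiate) exp(est - z * se) else est - z * se,
    conf.high = if (exponentiate) exp(est + z * se) else est + z * se
  )
  out
}

#' @method glance cousin_cox
#' @export
glance.cousin_cox <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events,
                 stratified = x$stratified, robust = x$robust,
                 ties = x$ties,
                 n_informative_strata = x$n_informative_strata,
                 logLik = as.numeric(stats::logLik(x$fit)))
}

## ---- small survival simulators (known truth, for tests/calibration) ----

#' Simulate a population survival cohort with known exposure hazard ratio
#'
#' Exponential baseline hazard from age 12, administrative censoring at a
#' fixed age: the true marginal hazard ratio of the binary exposure is
#' exactly `hr`.
#'
#' @param n Cohort size.
#' @param hr True hazard ratio of exposure.
#' @param exposure_prev Exposure prevalence.
#' @param baseline_rate Baseline hazard (events per person-year).
#' @param censor_age Administrative censoring age.
#' @param seed Integer seed.
#' @return Survival-record tibble.
#' @export
simulate_cox_population <- function(n, hr, exposure_prev = 0.03,
                                    baseline_rate = 0.002,
                                    censor_age = 41, seed = 1) {
  withr::with_seed(seed, {
    exposure <- stats::rbinom(n, 1, exposure_prev)
    rate <- baseline_rate * hr^exposure
    t_event <- 12 + stats::rexp(n, rate)
    exit <- pmin(t_event, censor_age)
    tibble::tibble(
      person_id = sprintf("P%07d", seq_len(n)),
      entry_age = 12, exit_age = exit,
      event = as.integer(t_event <= censor_age),
      exposure = exposure)
  })
}

#' Simulate cousin pairs with shared frailty and known within-pair hazard ratio
#'
#' Each pair shares a lognormal frailty multiplying the baseline hazard;
#' one member is exposed with within-pair hazard ratio `hr`.  The shared
#' frailty induces between-pair confounding that the stratified analysis
#' removes.
#'
#' @param n_pairs Number of pairs.
#' @param hr True within-pair hazard ratio.
#' @param frailty_sd SD of the log frailty.
#' @param baseline_rate Baseline hazard per person-year.
#' @param censor_age Administrative censoring age.
#' @param seed Integer seed.
#' @return Pair-expanded survival records with `stratum_id`, `cluster_id`.
#' @export
simulate_frailty_pairs <- function(n_pairs, hr, frailty_sd = 1,
                                   baseline_rate = 0.003, censor_age = 41,
                                   seed = 1) {
  withr::with_seed(seed, {
    frailty <- exp(stats::rnorm(n_pairs, 0, frailty_sd))
    mk <- function(exposed) {
      rate <- baseline_rate * frailty * hr^exposed
      t_event <- 12 + stats::rexp(n_pairs, rate)
      exit <- pmin(t_event, censor_age)
      tibble::tibble(
        stratum_id = sprintf("PAIR%06d", seq_len(n_pairs)),
        person_id = sprintf("P%07d_%d", seq_len(n_pairs), exposed + 1),
        entry_age = 12, exit_age = exit,
        event = as.integer(t_event <= censor_age),
        exposure = exposed)
    }
    rec <- dplyr::bind_rows(mk(0L), mk(1L))
    rec$cluster_id <- rec$person_id
    rec
  })
}
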