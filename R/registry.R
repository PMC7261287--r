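## Synthetic multi-generation registry generator.
##
## One extended family consists of two sibling "index" parents (sisters,
## brothers or mixed), their co-parents ("spouses"), one or two offspring
## per index parent, and the linked grandparents.  Liabilities of the index
## parents and offspring follow the generating liability model (components
## drawn at the A/C/E level); spouse liabilities are independent.
## Covariates shift liabilities on the probit scale; generation thresholds
## are calibrated so that the covariate-shifted marginals hit the target
## lifetime prevalences.  Phenotypes are lifetime indicators; event dates
## come from a truncated-Weibull event-age model, and death/emigration
## censoring truncates follow-up when survival records are built (it does
## not erase lifetime phenotypes, which is what the behavior-genetic stage
## analyzes).

rtrunc_weibull <- function(n, shape, scale, lo, hi) {
  if (hi <= lo) return(rep(lo, n))
  Flo <- stats::pweibull(lo, shape, scale)
  Fhi <- stats::pweibull(hi, shape, scale)
  u <- Flo + stats::runif(n) * (Fhi - Flo)
  stats::qweibull(u, shape, scale)
}

ptrunc_weibull <- function(q, shape, scale, lo, hi) {
  if (hi <= lo) return(as.numeric(q >= lo))
  Flo <- stats::pweibull(lo, shape, scale)
  Fhi <- stats::pweibull(hi, shape, scale)
  pmin(pmax((stats::pweibull(q, shape, scale) - Flo) / (Fhi - Flo), 0), 1)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Map a latent standard-normal matrix to covariates through the sex-
# specific marginals (Gaussian copula; marginals stay exact under any
# latent correlation between persons).
covariates_from_z <- function(z, sex, marg) {
  pick <- function(field) {
    ifelse(sex == "F", marg$female[[field]], marg$male[[field]])
  }
  edu_cuts <- function(p) {
    p <- p / sum(p)  # tolerate rounded frequencies
    stats::qnorm(cumsum(p)[-length(p)])
  }
  cut_f <- edu_cuts(marg$female$education)
  cut_m <- edu_cuts(marg$male$education)
  edu <- ifelse(sex == "F",
                findInterval(z[, 1], cut_f), findInterval(z[, 1], cut_m)) + 1L
  tibble::tibble(
    education_level = ifelse(edu >= 7L, NA_integer_, as.integer(edu)),
    education_missing = edu >= 7L,
    born_in_sweden = z[, 2] < stats::qnorm(pick("born_in_sweden")),
    severe_mental_illness = z[, 3] > stats::qnorm(1 - pick("severe_mental_illness")),
    substance_use = z[, 4] > stats::qnorm(1 - pick("substance_use")),
    criminal_conviction = z[, 5] > stats::qnorm(1 - pick("criminal_conviction"))
  )
}

parent_covariate_shift <- function(cov, effects) {
  edu_idx <- ifelse(cov$education_missing, 7L, cov$education_level)
  effects$education[edu_idx] +
    (!cov$born_in_sweden) * effects$born_abroad +
    cov$severe_mental_illness * effects$severe_mental_illness +
    cov$substance_use * effects$substance_use +
    cov$criminal_conviction * effects$criminal_conviction
}

offspring_covariate_shift <- function(parity, maternal_age, effects) {
  effects$parity[pmin(parity, length(effects$parity))] +
    effects$maternal_age[maternal_age_group(maternal_age)]
}

#' Assign event and censoring dates from lifetime phenotypes
#'
#' Cases (phenotype 1) receive an event age drawn from the truncated-
#' Weibull event-age model and an event date; every person receives
#' death/emigration dates from the exponential censoring model (from age
#' 12) and a censoring date `min(death, emigration, end of study)`.
#' Uses the current RNG state; seed externally for reproducibility.
#'
#' @param people Tibble with columns `phenotype` (0/1) and `birth_date`.
#' @param config A [registry_config()] (only its `event_age_model` and
#'   `censoring_model` are used).
#' @return `people` with added columns `sb_age`, `sb_first_date`,
#'   `death_date`, `emigration_date`, `censor_date`.
#' @export
assign_event_ages <- function(people, config) {
  eam <- config$event_age_model
  cm <- config$censoring_model
  if (eam$min_age < 12) {
    stop("configuration error in `event_age_model`: min_age must be >= 12",
         call. = FALSE)
  }
  n <- nrow(people)
  sb_age <- rep(NA_real_, n)
  cases <- which(people$phenotype == 1)
  sb_age[cases] <- rtrunc_weibull(length(cases), eam$shape, eam$scale,
                                  eam$min_age, eam$max_age)
  draw_censor <- function(rate) {
    if (rate <= 0) return(rep(Inf, n))
    12 + stats::rexp(n, rate)
  }
  death_age <- draw_censor(cm$death_rate)
  emig_age <- draw_censor(cm$emigration_rate)
  to_date <- function(age) {
    d <- date_at_age(people$birth_date, age)
    d[!is.finite(age) | d > cm$end_of_study] <- NA
    d
  }
  people$sb_age <- sb_age
  people$sb_first_date <- date_at_age(people$birth_date, sb_age)
  people$death_date <- to_date(death_age)
  people$emigration_date <- to_date(emig_age)
  people$censor_date <- pmin(people$death_date, people$emigration_date,
                             cm$end_of_study, na.rm = TRUE)
  people
}

#' Generate a synthetic multi-generation registry
#'
#' Deterministically (given the configured seed) simulates person-level
#' registry tables for `n_extended_families` extended families with known
#' generating truth: latent liabilities follow the configured liability
#' model, covariates shift liabilities on the probit scale, thresholds are
#' calibrated to the target prevalences, and event/censoring dates follow
#' the configured models.  The returned `truth` table retains every latent
#' draw for testing.
#'
#' @param config A [registry_config()].
#' @return An object of class `sb_registry`: a list with `persons` (one row
#'   per person; identifiers, links, dates, covariates, first-event date),
#'   `truth` (per-person latent liability, covariate shift, threshold and
#'   latent phenotype), `thresholds` and `config`.
#' @examples
#' reg <- generate_registry(registry_config(n_extended_families = 50, seed = 1))
#' dplyr::count(reg$persons, generation)
#' @export
generate_registry <- function(config) {
  stopifnot(inherits(config, "registry_config"))
  taus <- registry_thresholds(config)
  withr::with_seed(config$seed, generate_registry_impl(config, taus))
}

generate_registry_impl <- function(config, taus) {
  n <- config$n_extended_families
  eff <- config$covariate_effects
  ab <- config$age_at_childbearing
  end_study <- config$censoring_model$end_of_study

  type <- sample(names(config$parent_sibling_mix), n, replace = TRUE,
                 prob = config$parent_sibling_mix)
  noff <- matrix(as.integer(sample(names(config$offspring_per_parent), 2 * n,
                                   replace = TRUE,
                                   prob = config$offspring_per_parent)),
                 n, 2)
  sex <- matrix(switch(config$parent_sex,
                       mixed = sample(c("F", "M"), 2 * n, replace = TRUE),
                       female = rep("F", 2 * n),
                       male = rep("M", 2 * n)),
                n, 2)

  # covariates: index parents independent draws, spouses copula-linked
  marg <- config$covariate_marginals
  rho_sp <- config$spouse_covariate_cor
  cov_idx <- list(); cov_sp <- list()
  for (i in 1:2) {
    z_i <- matrix(stats::rnorm(n * 5), n, 5)
    z_s <- rho_sp * z_i + sqrt(1 - rho_sp^2) * matrix(stats::rnorm(n * 5), n, 5)
    cov_idx[[i]] <- covariates_from_z(z_i, sex[, i], marg)
    cov_sp[[i]] <- covariates_from_z(z_s, ifelse(sex[, i] == "F", "M", "F"),
                                     marg)
  }

  # liabilities of index parents and offspring, batched by structure
  L <- list(p1 = numeric(n), p2 = numeric(n),
            o11 = rep(NA_real_, n), o12 = rep(NA_real_, n),
            o21 = rep(NA_real_, n), o22 = rep(NA_real_, n))
  truth_comp <- list()
  key <- paste(type, noff[, 1], noff[, 2])
  for (k in sort(unique(key))) {
    rows <- which(key == k)
    spec <- relationship_spec(type[rows[1]],
                              n_offspring = c(noff[rows[1], 1], noff[rows[1], 2]))
    sim <- draw_family_liabilities(config$true_params, spec, n = length(rows))
    for (m in spec$members) L[[m]][rows] <- sim$liability[, m]
    truth_comp[[k]] <- list(rows = rows, members = spec$members, sim = sim)
  }
  L_sp <- matrix(stats::rnorm(2 * n), n, 2)   # spouse liabilities

  # dates -----------------------------------------------------------------
  year0 <- as.Date(paste0(config$birth_year_range[1], "-01-01"))
  year1 <- as.Date(paste0(config$birth_year_range[2], "-12-31"))
  span <- as.numeric(year1 - year0)
  birth_o11 <- year0 + round(stats::runif(n) * span)
  age_p1 <- clamp(stats::rnorm(n, ab[["mean"]], ab[["sd"]]), ab[["min"]], ab[["max"]])
  birth_p1 <- date_at_age(birth_o11, -age_p1)
  sib_gap <- round(stats::rnorm(n, 0, 3) * days_per_year)
  sib_gap[type %in% c("DZ-twin", "MZ-twin")] <- 0
  birth_p2 <- birth_p1 + sib_gap
  age_p2 <- clamp(stats::rnorm(n, ab[["mean"]], ab[["sd"]]), ab[["min"]], ab[["max"]])
  birth_o21 <- pmin(pmax(date_at_age(birth_p2, age_p2), year0), year1)
  gap2 <- stats::runif(n, 1.2, 5)
  birth_o12 <- pmin(date_at_age(birth_o11, gap2), year1)
  birth_o22 <- pmin(date_at_age(birth_o21, stats::runif(n, 1.2, 5)), year1)
  birth_s1 <- date_at_age(birth_o11, -clamp(stats::rnorm(n, 29, 5), 18, 55))
  birth_s2 <- date_at_age(birth_o21, -clamp(stats::rnorm(n, 29, 5), 18, 55))
  birth_gm <- date_at_age(pmin(birth_p1, birth_p2),
                          -clamp(stats::rnorm(n, 27, 4), 18, 45))
  birth_gf <- birth_gm - round(stats::rnorm(n, 2, 3) * days_per_year)
  birth_gf2 <- birth_gm - round(stats::rnorm(n, 2, 3) * days_per_year)

  fid <- sprintf("F%07d", seq_len(n))
  id <- function(role) paste0(fid, "_", role)
  half <- type == "maternal-half"

  # phenotypes ------------------------------------------------------------
  tau_sex <- function(s) ifelse(s == "F", taus[["mother"]], taus[["father"]])
  shift_idx <- lapply(1:2, function(i) parent_covariate_shift(cov_idx[[i]], eff$parent))
  shift_sp <- lapply(1:2, function(i) parent_covariate_shift(cov_sp[[i]], eff$parent))
  y_idx <- lapply(1:2, function(i)
    as.integer(L[[paste0("p", i)]] + shift_idx[[i]] > tau_sex(sex[, i])))
  y_sp <- lapply(1:2, function(i)
    as.integer(L_sp[, i] + shift_sp[[i]] > tau_sex(ifelse(sex[, i] == "F", "M", "F"))))

  births_o <- list(o11 = birth_o11, o12 = birth_o12,
                   o21 = birth_o21, o22 = birth_o22)
  mother_birth <- list(
    as.Date(ifelse(sex[, 1] == "F", birth_p1, birth_s1),
            origin = "1970-01-01"),
    as.Date(ifelse(sex[, 2] == "F", birth_p2, birth_s2),
            origin = "1970-01-01"))

  shift_o <- list(); y_o <- list()
  for (m in c("o11", "o12", "o21", "o22")) {
    i <- as.integer(substr(m, 2, 2)); j <- as.integer(substr(m, 3, 3))
    mat_age <- age_at(births_o[[m]], mother_birth[[i]])
    shift_o[[m]] <- offspring_covariate_shift(j, mat_age, eff$offspring)
    y_o[[m]] <- as.integer(L[[m]] + shift_o[[m]] > taus[["offspring"]])
    y_o[[m]][noff[, i] < j] <- NA_integer_
  }

  # event / censoring dates ----------------------------------------------
  person_frames <- list()
  mk_people <- function(role, birth, phen) {
    tibble::tibble(role = role, family = seq_len(n), birth_date = birth,
                   phenotype = phen)
  }
  ev <- list()
  for (i in 1:2) {
    ev[[paste0("p", i)]] <- assign_event_ages(
      mk_people(paste0("p", i), if (i == 1) birth_p1 else birth_p2, y_idx[[i]]),
      config)
    ev[[paste0("s", i)]] <- assign_event_ages(
      mk_people(paste0("s", i), if (i == 1) birth_s1 else birth_s2, y_sp[[i]]),
      config)
  }
  for (m in c("o11", "o12", "o21", "o22")) {
    ev[[m]] <- assign_event_ages(
      mk_people(m, births_o[[m]], ifelse(is.na(y_o[[m]]), 0L, y_o[[m]])), config)
    ev[[m]]$sb_first_date[is.na(y_o[[m]])] <- NA
  }

  # exclusion safety: push offspring first events after both parents'
  if (config$exclusion_safe) {
    for (m in c("o11", "o12", "o21", "o22")) {
      i <- as.integer(substr(m, 2, 2))
      par_sb <- pmax(ev[[paste0("p", i)]]$sb_first_date,
                     ev[[paste0("s", i)]]$sb_first_date, na.rm = TRUE)
      bad <- which(!is.na(ev[[m]]$sb_first_date) & !is.na(par_sb) &
                     ev[[m]]$sb_first_date < par_sb)
      ev[[m]]$sb_first_date[bad] <- par_sb[bad] + 30
    }
  }

  # assemble person rows ---------------------------------------------------
  blank_cov <- function(k) {
    tibble::tibble(education_level = rep(NA_integer_, k),
                   born_in_sweden = NA, severe_mental_illness = NA,
                   substance_use = NA, criminal_conviction = NA)
  }
  cov_cols <- c("education_level", "born_in_sweden", "severe_mental_illness",
                "substance_use", "criminal_conviction")
  person_row <- function(pid, gen, sexv, birth, mother, father,
                         m_gm = NA, m_gf = NA, p_gm = NA, p_gf = NA,
                         cov = NULL, parity = NA_integer_, sb = as.Date(NA),
                         death = as.Date(NA), emig = as.Date(NA),
                         twin = "none") {
    k <- length(pid)
    cov <- cov %||% blank_cov(k)
    tibble::tibble(
      person_id = pid, family_id = substr(pid, 1, 8), generation = gen,
      sex = sexv, birth_date = birth,
      death_date = as.Date(death), emigration_date = as.Date(emig),
      mother_id = as.character(mother), father_id = as.character(father),
      maternal_grandmother_id = as.character(m_gm),
      maternal_grandfather_id = as.character(m_gf),
      paternal_grandmother_id = as.character(p_gm),
      paternal_grandfather_id = as.character(p_gf),
      education_level = cov$education_level,
      born_in_sweden = cov$born_in_sweden,
      severe_mental_illness = cov$severe_mental_illness,
      substance_use = cov$substance_use,
      criminal_conviction = cov$criminal_conviction,
      parity = parity, sb_first_date = as.Date(sb),
      twin_code = twin)
  }

  gf_of <- function(i) {
    if (i == 1) ifelse(half, id("gf1"), id("gf"))
    else ifelse(half, id("gf2"), id("gf"))
  }
  person_frames$gm <- person_row(id("gm"), "grandparent", "F", birth_gm,
                                 NA, NA)
  full_like <- !half
  person_frames$gf <- person_row(id("gf")[full_like], "grandparent", "M",
                                 birth_gf[full_like], NA, NA)
  person_frames$gf1 <- person_row(id("gf1")[half], "grandparent", "M",
                                  birth_gf[half], NA, NA)
  person_frames$gf2 <- person_row(id("gf2")[half], "grandparent", "M",
                                  birth_gf2[half], NA, NA)

  twin_code_idx <- ifelse(type == "DZ-twin", "DZ",
                          ifelse(type == "MZ-twin", "MZ", "none"))
  for (i in 1:2) {
    pi <- paste0("p", i)
    person_frames[[pi]] <- person_row(
      id(pi), "parent", sex[, i],
      if (i == 1) birth_p1 else birth_p2,
      mother = id("gm"), father = gf_of(i),
      cov = cov_idx[[i]][, cov_cols],
      sb = ev[[pi]]$sb_first_date, death = ev[[pi]]$death_date,
      emig = ev[[pi]]$emigration_date, twin = twin_code_idx)
    si <- paste0("s", i)
    person_frames[[si]] <- person_row(
      id(si), "spouse", ifelse(sex[, i] == "F", "M", "F"),
      if (i == 1) birth_s1 else birth_s2,
      mother = NA, father = NA,
      cov = cov_sp[[i]][, cov_cols],
      sb = ev[[si]]$sb_first_date, death = ev[[si]]$death_date,
      emig = ev[[si]]$emigration_date)
  }

  for (m in c("o11", "o12", "o21", "o22")) {
    i <- as.integer(substr(m, 2, 2)); j <- as.integer(substr(m, 3, 3))
    keep <- which(noff[, i] >= j)
    if (!length(keep)) next
    idx_is_mother <- sex[keep, i] == "F"
    mother <- ifelse(idx_is_mother, id(paste0("p", i))[keep],
                     id(paste0("s", i))[keep])
    father <- ifelse(idx_is_mother, id(paste0("s", i))[keep],
                     id(paste0("p", i))[keep])
    m_gm <- ifelse(idx_is_mother, id("gm")[keep], NA)
    m_gf <- ifelse(idx_is_mother, gf_of(i)[keep], NA)
    p_gm <- ifelse(idx_is_mother, NA, id("gm")[keep])
    p_gf <- ifelse(idx_is_mother, NA, gf_of(i)[keep])
    person_frames[[m]] <- person_row(
      id(m)[keep], "offspring", sample(c("F", "M"), length(keep), replace = TRUE),
      births_o[[m]][keep],
      mother = mother, father = father,
      m_gm = m_gm, m_gf = m_gf, p_gm = p_gm, p_gf = p_gf,
      parity = rep(j, length(keep)),
      sb = ev[[m]]$sb_first_date[keep], death = ev[[m]]$death_date[keep],
      emig = ev[[m]]$emigration_date[keep])
  }

  persons <- dplyr::bind_rows(person_frames)

  # truth table ------------------------------------------------------------
  truth_rows <- list(
    tibble::tibble(person_id = id("p1"), family_id = fid, role = "p1",
                   liability = L$p1, shift = shift_idx[[1]],
                   threshold = tau_sex(sex[, 1]), phenotype = y_idx[[1]]),
    tibble::tibble(person_id = id("p2"), family_id = fid, role = "p2",
                   liability = L$p2, shift = shift_idx[[2]],
                   threshold = tau_sex(sex[, 2]), phenotype = y_idx[[2]]),
    tibble::tibble(person_id = id("s1"), family_id = fid, role = "s1",
                   liability = L_sp[, 1], shift = shift_sp[[1]],
                   threshold = tau_sex(ifelse(sex[, 1] == "F", "M", "F")),
                   phenotype = y_sp[[1]]),
    tibble::tibble(person_id = id("s2"), family_id = fid, role = "s2",
                   liability = L_sp[, 2], shift = shift_sp[[2]],
                   threshold = tau_sex(ifelse(sex[, 2] == "F", "M", "F")),
                   phenotype = y_sp[[2]])
  )
  for (m in c("o11", "o12", "o21", "o22")) {
    i <- as.integer(substr(m, 2, 2)); j <- as.integer(substr(m, 3, 3))
    keep <- which(noff[, i] >= j)
    if (!length(keep)) next
    truth_rows[[length(truth_rows) + 1]] <- tibble::tibble(
      person_id = id(m)[keep], family_id = fid[keep], role = m,
      liability = L[[m]][keep], shift = shift_o[[m]][keep],
      threshold = taus[["offspring"]], phenotype = y_o[[m]][keep])
  }
  truth <- dplyr::bind_rows(truth_rows)

  # A/C/E component draws, joined by person
  comp <- list()
  for (k in names(truth_comp)) {
    tc <- truth_comp[[k]]
    for (m in tc$members) {
      comp[[paste(k, m)]] <- tibble::tibble(
        person_id = id(m)[tc$rows],
        A = tc$sim$A[, m], C = tc$sim$C[, m], E = tc$sim$E[, m])
    }
  }
  truth <- dplyr::left_join(truth, dplyr::bind_rows(comp), by = "person_id")

  out <- list(persons = persons, truth = truth, thresholds = taus,
              config = config)
  out <- inject_rule_violations(out)
  structure(out, class = "sb_registry")
}

# Deliberate exclusion-rule violations for ledger testing.  Selection is
# deterministic (first eligible offspring in person-id order, disjoint
# across rules); targets the maternal analysis.
inject_rule_violations <- function(reg) {
  vi <- reg$config$inject_violations
  if (all(vi == 0)) return(reg)
  persons <- reg$persons
  off <- which(persons$generation == "offspring")
  off <- off[order(persons$person_id[off])]
  mother_rows <- match(persons$mother_id[off], persons$person_id)
  n_sibs <- table(persons$mother_id[off])
  single_child <- n_sibs[persons$mother_id[off]] == 1
  used <- rep(FALSE, length(off))

  take <- function(k, eligible) {
    sel <- which(eligible & !used)[seq_len(k)]
    if (length(sel) < k || anyNA(sel)) {
      stop("not enough eligible offspring to inject the requested ",
           "violations; increase n_extended_families", call. = FALSE)
    }
    used[sel] <<- TRUE
    off[sel]
  }

  if (vi[["died_before_12"]] > 0) {
    rows <- take(vi[["died_before_12"]], rep(TRUE, length(off)))
    persons$death_date[rows] <- date_at_age(persons$birth_date[rows], 10)
    persons$emigration_date[rows] <- as.Date(NA)
    persons$sb_first_date[rows] <- as.Date(NA)
  }
  if (vi[["emigrated_before_12"]] > 0) {
    rows <- take(vi[["emigrated_before_12"]], rep(TRUE, length(off)))
    persons$emigration_date[rows] <- date_at_age(persons$birth_date[rows], 11)
    persons$death_date[rows] <- as.Date(NA)
    persons$sb_first_date[rows] <- as.Date(NA)
  }
  if (vi[["event_before_parent"]] > 0) {
    rows <- take(vi[["event_before_parent"]], single_child)
    mrow <- match(persons$mother_id[rows], persons$person_id)
    persons$sb_first_date[rows] <- date_at_age(persons$birth_date[rows], 15)
    persons$sb_first_date[mrow] <- date_at_age(persons$birth_date[rows], 16)
  }
  if (vi[["missing_parent_origin"]] > 0) {
    rows <- take(vi[["missing_parent_origin"]], single_child)
    mrow <- match(persons$mother_id[rows], persons$person_id)
    persons$born_in_sweden[mrow] <- NA
  }
  reg$persons <- persons
  reg
}

#' @export
print.sb_registry <- function(x, ...) {
  cat("<sb_registry>", nrow(x$persons), "persons in",
      x$config$n_extended_families, "extended families (seed",
      x$config$seed, ")\n")
  invisible(x)
}

#' Write registry tables to CSV
#'
#' Writes `persons.csv` and `truth.csv` (ISO dates) into a directory.
#'
#' @param registry An `sb_registry`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_registry <- function(registry, dir) {
  stopifnot(inherits(registry, "sb_registry"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(persons = file.path(dir, "persons.csv"),
             truth = file.path(dir, "truth.csv"))
  utils::write.csv(registry$persons, paths[["persons"]], row.names = FALSE)
  utils::write.csv(registry$truth, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}
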