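# Synthetic registry generator: configuration validation, determinism,
# family structure, component-level liability draws, event-age assignment
# and prevalence calibration.

test_that("configuration errors name the offending field", {
  expect_error(registry_config(0), "n_extended_families")
  expect_error(registry_config(10, parent_sibling_mix = c(full = 0.7)),
               "parent_sibling_mix")
  expect_error(registry_config(10, parent_sibling_mix = c(uncle = 1)),
               "parent_sibling_mix")
  expect_error(registry_config(10, offspring_per_parent = c("1" = 2, "2" = -1)),
               "offspring_per_parent")
  expect_error(registry_config(10, prevalence_targets = c(mother = 0,
                                                          father = 0.03,
                                                          offspring = 0.04)),
               "prevalence_targets")
  expect_error(registry_config(10, event_age_model = list(shape = 2,
                                                          scale = 30,
                                                          min_age = 10,
                                                          max_age = 41)),
               "min_age")
})

test_that("the registry is a deterministic function of the configuration", {
  cfg <- registry_config(n_extended_families = 300, seed = 42)
  r1 <- generate_registry(cfg)
  r2 <- generate_registry(cfg)
  expect_identical(r1$persons, r2$persons)
  expect_identical(r1$truth, r2$truth)
  r3 <- generate_registry(registry_config(n_extended_families = 300,
                                          seed = 43))
  expect_false(identical(r1$persons, r3$persons))
})

test_that("a single full-sib family contains parents, spouses, offspring and linked grandparents", {
  reg <- generate_registry(registry_config(
    n_extended_families = 1, parent_sibling_mix = c("full" = 1),
    offspring_per_parent = c("2" = 1), seed = 3))
  p <- reg$persons
  expect_equal(nrow(p), 10)  # 2 grandparents + 2 parents + 2 spouses + 4 offspring
  expect_equal(sum(p$generation == "offspring"), 4)
  off <- p[p$generation == "offspring", ]
  expect_true(all(off$mother_id %in% p$person_id))
  expect_true(all(off$father_id %in% p$person_id))
  # grandparent identifiers are consistent with the parent links
  for (i in seq_len(nrow(off))) {
    momrow <- p[p$person_id == off$mother_id[i], ]
    if (momrow$generation == "parent") {
      expect_equal(off$maternal_grandmother_id[i], momrow$mother_id)
      expect_equal(off$maternal_grandfather_id[i], momrow$father_id)
    }
  }
  # maternal-half structure carries two grandfathers
  regh <- generate_registry(registry_config(
    n_extended_families = 1, parent_sibling_mix = c("maternal-half" = 1),
    offspring_per_parent = c("2" = 1), seed = 3))
  expect_equal(sum(regh$persons$generation == "grandparent"), 3)
})

test_that("first-event dates never precede the 12th birthday", {
  reg <- generate_registry(registry_config(n_extended_families = 2000,
                                           seed = 11))
  sb <- reg$persons[!is.na(reg$persons$sb_first_date), ]
  ages <- as.numeric(sb$sb_first_date - sb$birth_date) / 365.25
  expect_true(all(ages >= 12 - 2 / 365.25))  # date rounding slack
})

test_that("component-level draws reproduce the implied correlation structure", {
  # no paths, no heritability: members are independent
  set.seed(1)
  ind <- liability_params(beta = 0, r_g = 0, a2_p = 0, a2_o = 0)
  sim <- draw_family_liabilities(ind, relationship_spec("full"), n = 50000)
  C <- cor(sim$liability)
  expect_lt(max(abs(C[upper.tri(C)])), 3 / sqrt(50000))

  # published-estimate parameters: mother-offspring correlation at scale
  set.seed(2)
  th <- published_minimal_params()
  spec <- relationship_spec("full")
  S <- implied_correlation_matrix(th, spec)
  sim <- draw_family_liabilities(th, spec, n = 1e6)
  se <- 1 / sqrt(1e6)
  expect_lt(abs(cor(sim$liability[, "p1"], sim$liability[, "o11"]) -
                  S["p1", "o11"]), 3 * se)
  expect_lt(abs(cor(sim$liability[, "o11"], sim$liability[, "o21"]) -
                  S["o11", "o21"]), 3 * se)
  # threshold calibration: phenotype frequency matches Phi(-tau)
  p_target <- pnorm(-th$tau_p)
  expect_lt(abs(mean(sim$phenotype[, "p1"]) - p_target),
            3 * sqrt(p_target * (1 - p_target) / 1e6))
})

test_that("event ages honor the phenotype, the age window and point-mass models", {
  cfg <- registry_config(n_extended_families = 10, seed = 1)
  set.seed(9)
  people <- tibble::tibble(
    phenotype = c(0L, 1L, 1L, 0L),
    birth_date = as.Date(c("1980-01-01", "1985-06-01", "1990-03-15",
                           "1995-12-31")))
  out <- assign_event_ages(people, cfg)
  expect_true(all(is.na(out$sb_first_date[out$phenotype == 0])))
  expect_true(all(!is.na(out$sb_first_date[out$phenotype == 1])))
  expect_true(all(out$sb_age[out$phenotype == 1] >= 12 &
                    out$sb_age[out$phenotype == 1] <= 41))
  # censor date is the earliest of death, emigration and end of study
  expected <- pmin(out$death_date, out$emigration_date,
                   cfg$censoring_model$end_of_study, na.rm = TRUE)
  expect_equal(out$censor_date, expected)

  # degenerate point-mass event-age model
  cfg_pt <- registry_config(n_extended_families = 10, seed = 1,
                            event_age_model = list(shape = 2, scale = 30,
                                                   min_age = 20, max_age = 20))
  set.seed(10)
  out_pt <- assign_event_ages(people, cfg_pt)
  expect_equal(out_pt$sb_age[out_pt$phenotype == 1], c(20, 20))

  cfg_bad <- cfg
  cfg_bad$event_age_model$min_age <- 5
  expect_error(assign_event_ages(people, cfg_bad), "min_age")
})

test_that("maternal lifetime prevalence matches the calibration target at scale", {
  reg <- generate_registry(registry_config(n_extended_families = 200000,
                                           parent_sex = "female", seed = 17))
  off <- reg$persons[reg$persons$generation == "offspring", ]
  mothers <- reg$persons[reg$persons$person_id %in% off$mother_id, ]
  prev <- mean(!is.na(mothers$sb_first_date))
  se <- sqrt(0.0316 * (1 - 0.0316) / nrow(mothers))
  expect_lt(abs(prev - 0.0316), 3 * se)
})

test_that("Kaplan-Meier incidence matches the threshold and event-age composition", {
  cfg <- registry_config(n_extended_families = 30000, parent_sex = "female",
                         seed = 23)
  reg <- generate_registry(cfg)
  cohort <- build_cohort(reg$persons)
  rec <- make_survival_records(cohort,
                               end_of_study = cfg$censoring_model$end_of_study)
  km <- km_estimate(rec, at_age = 30)
  # implied value: realized covariate-shifted case probability times the
  # truncated-Weibull event-age CDF at 30
  tro <- reg$truth[grepl("^o", reg$truth$role), ]
  p_case <- mean(pnorm(tro$shift - tro$threshold))
  eam <- cfg$event_age_model
  F30 <- kinliab:::ptrunc_weibull(30, eam$shape, eam$scale, eam$min_age,
                                  eam$max_age)
  implied <- 10000 * p_case * F30
  expect_lt(abs(km$cum_incidence_per_10k - implied),
            3 * km$std.error_per_10k)
})

test_that("exclusion-safe generation never lets an offspring event precede a parent's", {
  reg <- generate_registry(registry_config(n_extended_families = 5000,
                                           seed = 31))
  p <- reg$persons
  off <- p[p$generation == "offspring" & !is.na(p$sb_first_date), ]
  for (side in c("mother_id", "father_id")) {
    parent_sb <- p$sb_first_date[match(off[[side]], p$person_id)]
    both <- !is.na(parent_sb)
    expect_true(all(off$sb_first_date[both] >= parent_sb[both]))
  }
})
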