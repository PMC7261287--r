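# Cohort construction, exclusion ledger, sibling classification, cousin
# enumeration, exposure definition, relatedness constants and BG-family
# selection.

toy_persons <- function() {
  gm <- blank_person("GM", sex = "F", birth = as.Date("1950-01-01"),
                     generation = "grandparent")
  m1 <- blank_person("M1", sex = "F", birth = as.Date("1972-01-01"),
                     mother = "GM", father = "GF", generation = "parent",
                     sb = as.Date("1996-05-05"))
  m2 <- blank_person("M2", sex = "F", birth = as.Date("1974-01-01"),
                     mother = "GM", father = "GF", generation = "parent")
  mk_off <- function(id, mom, birth, ...) {
    blank_person(id, birth = as.Date(birth), mother = mom, father = NA,
                 m_gm = "GM", m_gf = "GF", ...)
  }
  dplyr::bind_rows(
    gm, m1, m2,
    mk_off("O1", "M1", "1992-01-01",
           death = as.Date("2002-01-01")),                 # dies at age 10
    mk_off("O2", "M1", "1992-06-01",
           emig = as.Date("2003-07-01")),                  # emigrates at 11
    mk_off("O3", "M1", "1993-01-01",
           sb = as.Date("1995-01-01")),                    # precedes mother's
    mk_off("O4", "M2", "1993-01-01"),
    mk_off("O5", "M2", "1995-01-01"),
    mk_off("O6", "MX", "1995-01-01")                       # unresolvable mother
  )
}

test_that("exclusion rules apply in order and the ledger accounts for every row", {
  persons <- toy_persons()
  expect_warning(ch <- build_cohort(persons, parent = "mother"),
                 "unresolvable")
  led <- setNames(ch$ledger$n_excluded, ch$ledger$rule)
  expect_equal(unname(led["died_before_12"]), 1)
  expect_equal(unname(led["emigrated_before_12"]), 1)
  expect_equal(unname(led["unresolved_parent"]), 1)
  expect_equal(unname(led["event_before_parent"]), 1)   # O3: 1995 < 1996-05-05
  expect_equal(unname(led["missing_parent_origin"]), 0)
  expect_equal(sum(ch$ledger$n_excluded), ch$n_in - nrow(ch$cohort))
  expect_setequal(ch$cohort$person_id, c("O4", "O5"))
  # O3's own event (age >= 12? no: 1995 is before age 12) -- rule order:
  # it is the event-order rule that catches it after survival rules pass
  expect_false("O3" %in% ch$cohort$person_id)
})

test_that("generator-injected rule violations are excluded with exactly matching counts", {
  k <- c(died_before_12 = 6, emigrated_before_12 = 5,
         event_before_parent = 4, missing_parent_origin = 3)
  reg <- generate_registry(registry_config(n_extended_families = 4000,
                                           parent_sex = "female", seed = 29,
                                           inject_violations = k))
  ch <- build_cohort(reg$persons, parent = "mother")
  led <- setNames(ch$ledger$n_excluded, ch$ledger$rule)
  expect_equal(unname(led[names(k)]), unname(k))
  expect_equal(sum(ch$ledger$n_excluded), ch$n_in - nrow(ch$cohort))
})

test_that("sibling classification follows shared parents, twin codes and the opposite-sex rule", {
  mk <- function(id, mother, father, sex = "F",
                 birth = as.Date("1970-01-01"), twin = "none") {
    blank_person(id, sex = sex, birth = birth, mother = mother,
                 father = father, generation = "parent", twin = twin)
  }
  a <- mk("A", "GM1", "GF1")
  expect_equal(classify_sibling_pair(a, mk("B", "GM1", "GF2")),
               "maternal-half")
  expect_equal(classify_sibling_pair(a, mk("B", "GM2", "GF1")),
               "paternal-half")
  expect_equal(classify_sibling_pair(a, mk("B", "GM1", "GF1",
                                           birth = as.Date("1972-01-01"))),
               "full")
  expect_equal(classify_sibling_pair(
    mk("A", "GM1", "GF1", twin = "MZ"),
    mk("B", "GM1", "GF1", twin = "MZ")), "MZ-twin")
  expect_equal(classify_sibling_pair(
    mk("A", "GM1", "GF1", sex = "F"),
    mk("B", "GM1", "GF1", sex = "M")), "DZ-twin")  # opposite sex, same day
  expect_true(is.na(classify_sibling_pair(
    mk("A", NA, NA), mk("B", "GM1", "GF1"))))
})

cousin_fixture <- function(n1 = 2, n2 = 3, twin = "none") {
  gm <- blank_person("GM", sex = "F", birth = as.Date("1950-01-01"),
                     generation = "grandparent")
  m1 <- blank_person("M1", sex = "F", birth = as.Date("1970-01-01"),
                     mother = "GM", father = "GF", generation = "parent",
                     twin = twin, sb = as.Date("1990-01-01"))
  m2 <- blank_person("M2", sex = "F",
                     birth = as.Date(if (twin == "none") "1972-01-01"
                                     else "1970-01-01"),
                     mother = "GM", father = "GF", generation = "parent",
                     twin = twin)
  offs <- lapply(seq_len(n1), function(i) {
    blank_person(paste0("A", i), birth = as.Date("1992-01-01") + 400 * i,
                 mother = "M1", father = paste0("FA"), m_gm = "GM",
                 m_gf = "GF")
  })
  offs2 <- lapply(seq_len(n2), function(i) {
    blank_person(paste0("B", i), birth = as.Date("1993-01-01") + 400 * i,
                 mother = "M2", father = paste0("FB"), m_gm = "GM",
                 m_gf = "GF", sb = if (i == 1) as.Date("2010-06-01")
                 else as.Date(NA))
  })
  fa <- blank_person("FA", sex = "M", birth = as.Date("1968-01-01"),
                     generation = "spouse")
  fb <- blank_person("FB", sex = "M", birth = as.Date("1968-01-01"),
                     generation = "spouse")
  dplyr::bind_rows(c(list(gm, m1, m2, fa, fb), offs, offs2))
}

test_that("two sisters with 2 and 3 offspring give six symmetric cousin pairs", {
  persons <- cousin_fixture()
  ch <- build_cohort(persons, parent = "mother")
  pairs <- enumerate_cousin_pairs(ch)
  expect_equal(nrow(pairs), 6)
  expect_true(all(pairs$person_id_1 != pairs$person_id_2))
  expect_true(all(pairs$parent_sibling_type == "full"))
  expect_false(any(pairs$twin_parents))
  # exposure flags follow the analyzed mother: M1's offspring are exposed
  a_first <- grepl("^A", pairs$person_id_1)
  expect_true(all(pairs$exposed_1[a_first]))
  expect_true(all(!pairs$exposed_2[a_first]))
  # enumeration is order-independent
  set.seed(4)
  shuffled <- persons[sample(nrow(persons)), ]
  pairs2 <- enumerate_cousin_pairs(build_cohort(shuffled, parent = "mother"))
  key <- function(p) sort(paste(p$person_id_1, p$person_id_2))
  expect_equal(key(pairs2), key(pairs))
})

test_that("offspring of twin parents are flagged for the sensitivity set", {
  persons <- cousin_fixture(twin = "MZ")
  ch <- build_cohort(persons, parent = "mother")
  pairs <- enumerate_cousin_pairs(ch)
  expect_equal(nrow(pairs), 6)
  expect_true(all(pairs$twin_parents))
  expect_true(all(pairs$parent_sibling_type == "MZ-twin"))
  # excluded from the full-sibling BG selection
  expect_equal(nrow(select_bg_families(ch, seed = 1)), 0)
})

test_that("exposure uses a strict age-18 boundary and supports pre-birth events", {
  off <- tibble::tibble(birth_date = as.Date("1990-06-15"))
  status <- function(parent_sb) {
    exposure_status(off, tibble::tibble(sb_first_date = as.Date(parent_sb)))
  }
  expect_equal(status("1988-01-01"), "exposed")       # before birth
  expect_equal(status("2008-06-13"), "exposed")       # just before 18
  expect_equal(status("2008-06-14"), "late-exposed")  # the 18th birthday
  expect_equal(status("2010-01-01"), "late-exposed")
  expect_equal(status(NA), "unexposed")
})

test_that("relatedness constants agree with a path-counting kinship oracle", {
  ped_full <- list(GM = c(NA, NA), GF = c(NA, NA),
                   P1 = c("GM", "GF"), P2 = c("GM", "GF"),
                   S1 = c(NA, NA), S2 = c(NA, NA),
                   O1 = c("P1", "S1"), O2 = c("P2", "S2"))
  ped_half <- ped_full
  ped_half$GF2 <- c(NA, NA)
  ped_half$P2 <- c("GM", "GF2")

  spec_f <- relationship_spec("full")
  spec_h <- relationship_spec("maternal-half")
  spec_mz <- relationship_spec("MZ-twin")
  mz <- list(P2 = "P1")

  expect_equal(expected_genetic_correlation("parent", "offspring", spec_f),
               kinship_oracle("P1", "O1", ped_full))            # 0.5
  expect_equal(expected_genetic_correlation("parent_1", "parent_2", spec_f),
               kinship_oracle("P1", "P2", ped_full))            # 0.5
  expect_equal(expected_genetic_correlation("parent_1", "parent_2", spec_h),
               kinship_oracle("P1", "P2", ped_half))            # 0.25
  expect_equal(expected_genetic_correlation("parent_1", "offspring_2", spec_f),
               kinship_oracle("P1", "O2", ped_full))            # 0.25
  expect_equal(expected_genetic_correlation("parent_1", "offspring_2", spec_h),
               kinship_oracle("P1", "O2", ped_half))            # 0.125
  expect_equal(expected_genetic_correlation("offspring_1", "offspring_2",
                                            spec_f),
               kinship_oracle("O1", "O2", ped_full))            # 0.125
  expect_equal(expected_genetic_correlation("offspring_1", "offspring_2",
                                            spec_h),
               kinship_oracle("O1", "O2", ped_half))            # 0.0625
  expect_equal(expected_genetic_correlation("offspring_1", "offspring_2",
                                            spec_mz),
               kinship_oracle("O1", "O2", ped_full, mz_map = mz))  # 0.25
  expect_error(expected_genetic_correlation("uncle", "offspring", spec_f),
               "unknown role")
})

test_that("BG family selection is seeded, same-sex, capped at two offspring and person-disjoint", {
  persons <- cousin_fixture(n1 = 3, n2 = 3)
  ch <- build_cohort(persons, parent = "mother")
  bg1 <- select_bg_families(ch, seed = 7)
  bg2 <- select_bg_families(ch, seed = 7)
  expect_identical(bg1, bg2)
  expect_equal(nrow(bg1), 1)
  ids <- unlist(bg1[, c("o11_id", "o12_id", "o21_id", "o22_id")])
  expect_equal(sum(!is.na(ids)), 4)   # two offspring per parent
  # another seed still yields a valid, complete selection
  bg3 <- select_bg_families(ch, seed = 99)
  expect_equal(nrow(bg3), 1)
  expect_equal(sum(!is.na(unlist(bg3[, c("o11_id", "o12_id", "o21_id",
                                         "o22_id")]))), 4)

  # three sisters: overlapping families collapse to one disjoint family
  gm <- blank_person("GM", sex = "F", birth = as.Date("1950-01-01"),
                     generation = "grandparent")
  sisters <- lapply(1:3, function(i) {
    blank_person(paste0("M", i), sex = "F",
                 birth = as.Date("1970-01-01") + 300 * i,
                 mother = "GM", father = "GF", generation = "parent")
  })
  kids <- lapply(1:3, function(i) {
    blank_person(paste0("K", i), birth = as.Date("1995-01-01") + 200 * i,
                 mother = paste0("M", i), m_gm = "GM", m_gf = "GF")
  })
  trio <- dplyr::bind_rows(c(list(gm), sisters, kids))
  ch3 <- build_cohort(trio, parent = "mother")
  bg_trio <- select_bg_families(ch3, seed = 3)
  expect_equal(nrow(bg_trio), 1)

  # larger registry: selected families are pairwise person-disjoint
  reg <- generate_registry(registry_config(n_extended_families = 1500,
                                           seed = 13))
  chr <- build_cohort(reg$persons)
  bg <- select_bg_families(chr, seed = 5)
  all_ids <- unlist(bg[, c("p1_id", "p2_id", "o11_id", "o12_id",
                           "o21_id", "o22_id")])
  all_ids <- all_ids[!is.na(all_ids)]
  expect_equal(anyDuplicated(all_ids), 0)
  # mixed-sex registries: every selected parent is an analyzed-sex parent
  sex <- reg$persons$sex[match(c(bg$p1_id, bg$p2_id), reg$persons$person_id)]
  expect_true(all(sex == "F"))
})
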