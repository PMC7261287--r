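## Cohort construction from person-level registry tables: exclusion rules,
## sibling classification, cousin-pair enumeration, exposure definition and
## assembly of the extended families analyzed by the behavior-genetic model.

#' Build the analysis cohort with exclusion ledger
#'
#' Selects the offspring generation from a persons table and applies the
#' exclusion rules in order: (1) died before age 12; (2) emigrated before
#' age 12; (3) unresolvable link to the analyzed parent (row-level warning);
#' (4) offspring whose first suicidal behavior predates the analyzed
#' parent's; (5) missing analyzed-parent country of origin.  The ledger
#' records the rows removed by each rule, in application order, so that the
#' counts sum to `rows in - rows out`.
#'
#' @param persons Person-level table (see [generate_registry()] for the
#'   schema).  Offspring are identified by the `generation` column when
#'   present, otherwise as rows carrying any grandparent identifier.
#' @param parent Which parent the analysis follows: `"mother"` or
#'   `"father"`.
#' @return An object of class `sb_cohort`: list with `cohort` (offspring
#'   rows plus `parent_id`, `parent_birth_date`, `parent_sb_first_date`,
#'   `parent_sex`), `ledger` (tibble `rule`, `n_excluded`), `parent`, and
#'   the `persons` table for downstream pair enumeration.
#' @export
build_cohort <- function(persons, parent = c("mother", "father")) {
  parent <- match.arg(parent)
  stopifnot(is.data.frame(persons), "person_id" %in% names(persons))
  if ("generation" %in% names(persons)) {
    off <- dplyr::filter(persons, .data$generation == "offspring")
  } else {
    gp_cols <- c("maternal_grandmother_id", "maternal_grandfather_id",
                 "paternal_grandmother_id", "paternal_grandfather_id")
    gp_cols <- intersect(gp_cols, names(persons))
    has_gp <- Reduce(`|`, lapply(gp_cols, function(cl) !is.na(persons[[cl]])))
    off <- persons[has_gp, ]
  }
  n_in <- nrow(off)
  ledger <- tibble::tibble(rule = character(), n_excluded = integer())
  note <- function(rule, n) {
    ledger <<- dplyr::bind_rows(ledger,
                                tibble::tibble(rule = rule,
                                               n_excluded = as.integer(n)))
  }

  died <- !is.na(off$death_date) &
    age_at(off$death_date, off$birth_date) < 12
  note("died_before_12", sum(died))
  off <- off[!died, ]

  emig <- !is.na(off$emigration_date) &
    age_at(off$emigration_date, off$birth_date) < 12
  note("emigrated_before_12", sum(emig))
  off <- off[!emig, ]

  pid_col <- if (parent == "mother") "mother_id" else "father_id"
  prow <- match(off[[pid_col]], persons$person_id)
  unresolved <- is.na(off[[pid_col]]) | is.na(prow)
  if (any(unresolved)) {
    warning(sum(unresolved), " offspring with unresolvable ", parent,
            " link excluded", call. = FALSE)
  }
  note("unresolved_parent", sum(unresolved))
  off <- off[!unresolved, ]
  prow <- prow[!unresolved]

  parent_sb <- persons$sb_first_date[prow]
  ev_order <- !is.na(off$sb_first_date) & !is.na(parent_sb) &
    off$sb_first_date < parent_sb
  note("event_before_parent", sum(ev_order))
  off <- off[!ev_order, ]
  prow <- prow[!ev_order]

  origin_missing <- is.na(persons$born_in_sweden[prow])
  note("missing_parent_origin", sum(origin_missing))
  off <- off[!origin_missing, ]
  prow <- prow[!origin_missing]

  cohort <- off
  cohort$parent_id <- persons$person_id[prow]
  cohort$parent_birth_date <- persons$birth_date[prow]
  cohort$parent_sb_first_date <- persons$sb_first_date[prow]
  cohort$parent_sex <- persons$sex[prow]

  structure(list(cohort = cohort, ledger = ledger, parent = parent,
                 persons = persons, n_in = n_in),
            class = "sb_cohort")
}

#' @export
print.sb_cohort <- function(x, ...) {
  cat("<sb_cohort>", nrow(x$cohort), "offspring after exclusions (",
      x$n_in - nrow(x$cohort), "excluded ), analyzed parent:", x$parent, "\n")
  print(as.data.frame(x$ledger), row.names = FALSE)
  invisible(x)
}

# vectorized sibling classification from parent-link identifiers
classify_pair_vec <- function(mother_a, father_a, mother_b, father_b,
                              twin_a, twin_b, sex_a, sex_b,
                              birth_a, birth_b) {
  shared_m <- !is.na(mother_a) & !is.na(mother_b) & mother_a == mother_b
  shared_f <- !is.na(father_a) & !is.na(father_b) & father_a == father_b
  no_ids <- (is.na(mother_a) & is.na(father_a)) |
    (is.na(mother_b) & is.na(father_b))
  out <- rep(NA_character_, length(mother_a))
  out[shared_m & shared_f] <- "full"
  out[shared_m & !shared_f] <- "maternal-half"
  out[!shared_m & shared_f] <- "paternal-half"
  same_day <- !is.na(birth_a) & !is.na(birth_b) & birth_a == birth_b
  # registry twin codes override; opposite-sex same-day full siblings are
  # DZ twins even without a register code
  dz <- shared_m & shared_f & same_day &
    ((twin_a == "DZ" & twin_b == "DZ") | (sex_a != sex_b))
  mz <- shared_m & shared_f & same_day & twin_a == "MZ" & twin_b == "MZ"
  out[dz] <- "DZ-twin"
  out[mz] <- "MZ-twin"
  out[no_ids] <- NA_character_
  out
}

#' Classify the sibling relationship of two parent-generation records
#'
#' Uses the parents' own parent identifiers (the offspring's grandparent
#' identifiers): shared mother and father give `"full"`, shared mother only
#' `"maternal-half"`, shared father only `"paternal-half"`.  Twin-register
#' codes override to `"DZ-twin"`/`"MZ-twin"`, and an opposite-sex pair of
#' full siblings born the same day is classified `"DZ-twin"` even without
#' a register code.  Pairs missing both identifiers on either side are
#' unclassified (`NA`).
#'
#' @param a,b One-row data frames (person records).
#' @return A single character value or `NA`.
#' @export
classify_sibling_pair <- function(a, b) {
  stopifnot(nrow(a) == 1, nrow(b) == 1)
  classify_pair_vec(a$mother_id, a$father_id, b$mother_id, b$father_id,
                    a$twin_code %||% "none", b$twin_code %||% "none",
                    a$sex, b$sex, a$birth_date, b$birth_date)
}

#' Expected additive-genetic correlation between family roles
#'
#' Relationship constants of the offspring-of-siblings design: a parent and
#' their own offspring share 0.5; sibling parents share `g` (0.25
#' maternal-half, 0.5 full/DZ, 1 MZ); the avuncular correlation is `0.5 g`;
#' cousins share `0.25 g` (12.5% for offspring of full siblings, 6.25% for
#' offspring of maternal half-siblings).
#'
#' @param role_a,role_b Family roles: `"parent_1"`, `"parent_2"`,
#'   `"offspring_1"`, `"offspring_2"` (`"parent"`/`"offspring"` are read as
#'   index 1).
#' @param spec A [relationship_spec()] supplying the parent sibling type.
#' @return The expected genetic correlation in `[0, 1]`.
#' @examples
#' expected_genetic_correlation("parent", "offspring",
#'                              relationship_spec("full"))       # 0.5
#' expected_genetic_correlation("offspring_1", "offspring_2",
#'                              relationship_spec("full"))       # 0.125
#' @export
expected_genetic_correlation <- function(role_a, role_b, spec) {
  stopifnot(inherits(spec, "relationship_spec"))
  canon <- function(r) {
    if (r %in% c("parent", "offspring")) r <- paste0(r, "_1")
    if (!grepl("^(parent|offspring)_[12]$", r)) {
      stop("unknown role: ", r, call. = FALSE)
    }
    list(gen = sub("_[12]$", "", r), idx = as.integer(sub("^.*_", "", r)))
  }
  a <- canon(role_a); b <- canon(role_b)
  if (a$gen == "parent" && b$gen == "parent") {
    if (a$idx == b$idx) stop("role pair refers to the same person", call. = FALSE)
    return(spec$g)
  }
  if (a$gen == "offspring" && b$gen == "offspring") {
    if (a$idx == b$idx) return(spec$g_offspring_sibs)
    return(0.25 * spec$g)
  }
  if (a$idx == b$idx) 0.5 else 0.5 * spec$g
}

#' Exposure status of an offspring to parental suicidal behavior
#'
#' Exposure is parental suicidal behavior before the offspring's 18th
#' birthday (strictly), including parental events before the offspring's
#' birth.  Parental events on or after the 18th birthday are
#' `"late-exposed"` (analyzed as unexposed in the main models); absent
#' parental events give `"unexposed"`.
#'
#' @param offspring,parent Data frames (equal rows or length-1 recycling)
#'   with `birth_date` and `sb_first_date`.
#' @return Character vector: `"exposed"`, `"late-exposed"`, `"unexposed"`.
#' @export
exposure_status <- function(offspring, parent) {
  bday18 <- date_at_age(offspring$birth_date, 18)
  psb <- parent$sb_first_date
  out <- rep("unexposed", max(nrow(offspring), 1))
  out[!is.na(psb) & psb < bday18] <- "exposed"
  out[!is.na(psb) & psb >= bday18] <- "late-exposed"
  out
}

#' Enumerate cousin pairs
#'
#' Finds all unordered pairs of cohort offspring whose parents are
#' classified siblings.  Pairs can be linked through either parent
#' (sister-sister, brother-brother or sister-brother parent pairs;
#' `relation_1`/`relation_2` record whether each offspring connects via its
#' mother or father), so the pair set serves both the maternal and the
#' paternal survival analyses.  Exposure flags refer to the cohort's
#' analyzed parent.  Offspring of DZ/MZ twin parents are flagged
#' `twin_parents` so they can be excluded from offspring-of-full-sibling
#' analyses and retained for the offspring-of-twins sensitivity set.
#'
#' @param cohort An `sb_cohort` from [build_cohort()].
#' @return Tibble of cousin pairs, one row per unordered pair.
#' @export
enumerate_cousin_pairs <- function(cohort) {
  stopifnot(inherits(cohort, "sb_cohort"))
  persons <- cohort$persons
  co <- cohort$cohort
  parents <- unique(stats::na.omit(c(co$mother_id, co$father_id)))
  parents <- parents[parents %in% persons$person_id]
  prow <- match(parents, persons$person_id)
  ptab <- tibble::tibble(
    parent_id = parents,
    mother_id = persons$mother_id[prow],
    father_id = persons$father_id[prow],
    twin_code = (persons$twin_code %||% rep("none", nrow(persons)))[prow],
    sex = persons$sex[prow],
    birth_date = persons$birth_date[prow]
  )
  # candidate sibling pairs: shared mother or shared father
  ptab_m <- ptab[!is.na(ptab$mother_id), ]
  ptab_f <- ptab[!is.na(ptab$father_id), ]
  cand_m <- dplyr::inner_join(ptab_m, ptab_m, by = "mother_id",
                              suffix = c("_a", "_b"),
                              relationship = "many-to-many",
                              na_matches = "never") |>
    dplyr::filter(.data$parent_id_a < .data$parent_id_b)
  cand_f <- dplyr::inner_join(ptab_f, ptab_f, by = "father_id",
                              suffix = c("_a", "_b"),
                              relationship = "many-to-many",
                              na_matches = "never") |>
    dplyr::filter(.data$parent_id_a < .data$parent_id_b)
  cand_m$mother_id_a <- cand_m$mother_id_b <- cand_m$mother_id
  cand_f$father_id_a <- cand_f$father_id_b <- cand_f$father_id
  keep_cols <- c("parent_id_a", "parent_id_b", "mother_id_a", "mother_id_b",
                 "father_id_a", "father_id_b", "twin_code_a", "twin_code_b",
                 "sex_a", "sex_b", "birth_date_a", "birth_date_b")
  cand <- dplyr::bind_rows(cand_m[, keep_cols], cand_f[, keep_cols]) |>
    dplyr::distinct(.data$parent_id_a, .data$parent_id_b, .keep_all = TRUE)
  if (!nrow(cand)) return(empty_cousin_pairs())
  cand$parent_sibling_type <- classify_pair_vec(
    cand$mother_id_a, cand$father_id_a, cand$mother_id_b, cand$father_id_b,
    cand$twin_code_a, cand$twin_code_b, cand$sex_a, cand$sex_b,
    cand$birth_date_a, cand$birth_date_b)
  cand <- cand[!is.na(cand$parent_sibling_type), ]
  if (!nrow(cand)) return(empty_cousin_pairs())

  co$exposure <- exposure_status(
    co, tibble::tibble(sb_first_date = co$parent_sb_first_date))
  co$outcome <- !is.na(co$sb_first_date)
  # children of each parent, through either link
  link_m <- split(seq_len(nrow(co)), co$mother_id)
  link_f <- split(seq_len(nrow(co)), co$father_id)
  children_of <- function(p) {
    rbind(
      if (!is.null(link_m[[p]])) cbind(link_m[[p]], 1L),
      if (!is.null(link_f[[p]])) cbind(link_f[[p]], 2L)
    )
  }

  acc_i <- vector("list", nrow(cand)); acc_j <- acc_ri <- acc_rj <- acc_i
  acc_k <- acc_i
  for (k in seq_len(nrow(cand))) {
    ca <- children_of(cand$parent_id_a[k])
    cb <- children_of(cand$parent_id_b[k])
    if (is.null(ca) || is.null(cb)) next
    ia <- rep(seq_len(nrow(ca)), times = nrow(cb))
    ib <- rep(seq_len(nrow(cb)), each = nrow(ca))
    i <- ca[ia, 1]; j <- cb[ib, 1]
    # cousins must come from distinct nuclear families
    same_m <- !is.na(co$mother_id[i]) & !is.na(co$mother_id[j]) &
      co$mother_id[i] == co$mother_id[j]
    same_f <- !is.na(co$father_id[i]) & !is.na(co$father_id[j]) &
      co$father_id[i] == co$father_id[j]
    ok <- i != j & !same_m & !same_f
    if (!any(ok)) next
    acc_i[[k]] <- i[ok]; acc_j[[k]] <- j[ok]
    acc_ri[[k]] <- ca[ia, 2][ok]; acc_rj[[k]] <- cb[ib, 2][ok]
    acc_k[[k]] <- rep.int(k, sum(ok))
  }
  i <- unlist(acc_i); j <- unlist(acc_j)
  if (!length(i)) return(empty_cousin_pairs())
  rel_i <- c("mother", "father")[unlist(acc_ri)]
  rel_j <- c("mother", "father")[unlist(acc_rj)]
  k <- unlist(acc_k)
  first <- co$person_id[i] <= co$person_id[j]
  pairs <- tibble::tibble(
    person_id_1 = ifelse(first, co$person_id[i], co$person_id[j]),
    person_id_2 = ifelse(first, co$person_id[j], co$person_id[i]),
    parent_id_1 = ifelse(first, cand$parent_id_a[k], cand$parent_id_b[k]),
    parent_id_2 = ifelse(first, cand$parent_id_b[k], cand$parent_id_a[k]),
    relation_1 = ifelse(first, rel_i, rel_j),
    relation_2 = ifelse(first, rel_j, rel_i),
    parent_sibling_type = cand$parent_sibling_type[k],
    twin_parents = cand$parent_sibling_type[k] %in% c("DZ-twin", "MZ-twin"),
    exposed_1 = ifelse(first, co$exposure[i], co$exposure[j]) == "exposed",
    exposed_2 = ifelse(first, co$exposure[j], co$exposure[i]) == "exposed",
    outcome_1 = ifelse(first, co$outcome[i], co$outcome[j]),
    outcome_2 = ifelse(first, co$outcome[j], co$outcome[i])
  )
  pairs <- dplyr::arrange(pairs, .data$person_id_1, .data$person_id_2) |>
    dplyr::distinct(.data$person_id_1, .data$person_id_2, .keep_all = TRUE)
  pairs$pair_id <- sprintf("CP%07d", seq_len(nrow(pairs)))
  pairs$exposure_discordant <- pairs$exposed_1 != pairs$exposed_2
  pairs$outcome_discordant <- pairs$outcome_1 != pairs$outcome_2
  dplyr::relocate(pairs, "pair_id")
}

empty_cousin_pairs <- function() {
  tibble::tibble(pair_id = character(), person_id_1 = character(),
                 person_id_2 = character(), parent_id_1 = character(),
                 parent_id_2 = character(), parent_sibling_type = character(),
                 twin_parents = logical(), exposed_1 = logical(),
                 exposed_2 = logical(), outcome_1 = logical(),
                 outcome_2 = logical(), exposure_discordant = logical(),
                 outcome_discordant = logical())
}

#' Assemble extended families for the behavior-genetic model
#'
#' From the cohort, builds the disjoint extended-family observations the
#' liability model is fitted to: same-sex sibling pairs of analyzed parents
#' (full and maternal-half for mothers; full and paternal-half for
#' fathers; twin parents excluded), up to two offspring per parent
#' (uniform-random seeded selection among more), and uniform-random greedy
#' de-duplication of overlapping extended families so that the returned
#' families are pairwise person-disjoint.
#'
#' @param cohort An `sb_cohort` from [build_cohort()].
#' @param seed Integer seed for offspring selection and de-duplication.
#' @return Tibble with one row per extended family: `parent_type`, member
#'   ids (`p1_id`, ..., `o22_id`) and phenotypes (`y_p1`, ..., `y_o22`).
#' @export
select_bg_families <- function(cohort, seed = 1) {
  stopifnot(inherits(cohort, "sb_cohort"))
  pairs <- enumerate_cousin_pairs(cohort)
  half_type <- if (cohort$parent == "mother") "maternal-half" else
    "paternal-half"
  co <- cohort$cohort
  persons <- cohort$persons
  sex_of <- persons$sex[match(co$parent_id, persons$person_id)]
  want_sex <- if (cohort$parent == "mother") "F" else "M"
  ok_parents <- unique(co$parent_id[sex_of == want_sex])

  want_rel <- cohort$parent
  sib <- pairs |>
    dplyr::filter(.data$relation_1 == want_rel, .data$relation_2 == want_rel) |>
    dplyr::distinct(.data$parent_id_1, .data$parent_id_2,
                    .data$parent_sibling_type) |>
    dplyr::filter(.data$parent_sibling_type %in% c("full", half_type),
                  .data$parent_id_1 %in% ok_parents,
                  .data$parent_id_2 %in% ok_parents)
  if (!nrow(sib)) return(empty_bg_families())
  by_parent <- split(co$person_id, co$parent_id)

  withr::with_seed(seed, {
    fams <- vector("list", nrow(sib))
    for (k in seq_len(nrow(sib))) {
      offs <- lapply(c(sib$parent_id_1[k], sib$parent_id_2[k]), function(p) {
        ids <- by_parent[[p]]
        if (length(ids) > 2) ids <- sort(sample(ids, 2))
        ids
      })
      fams[[k]] <- list(p = c(sib$parent_id_1[k], sib$parent_id_2[k]),
                        o = offs, type = sib$parent_sibling_type[k])
    }
    # greedy de-duplication in shuffled order (hash set for membership)
    ord <- sample(length(fams))
    used <- new.env(parent = emptyenv())
    keep <- logical(length(fams))
    for (k in ord) {
      members <- c(fams[[k]]$p, unlist(fams[[k]]$o))
      if (!any(vapply(members, exists, logical(1), envir = used,
                      inherits = FALSE))) {
        keep[k] <- TRUE
        for (m in members) assign(m, TRUE, envir = used)
      }
    }
    fams <- fams[keep]
  })
  if (!length(fams)) return(empty_bg_families())

  grab <- function(fun) vapply(fams, fun, NA_character_)
  fam_tbl <- tibble::tibble(
    family_id = sprintf("BG%06d", seq_along(fams)),
    parent_type = vapply(fams, function(f) f$type, ""),
    p1_id = grab(function(f) f$p[1]),
    p2_id = grab(function(f) f$p[2]),
    o11_id = grab(function(f) f$o[[1]][1]),
    o12_id = grab(function(f) if (length(f$o[[1]]) > 1) f$o[[1]][2]
                  else NA_character_),
    o21_id = grab(function(f) f$o[[2]][1]),
    o22_id = grab(function(f) if (length(f$o[[2]]) > 1) f$o[[2]][2]
                  else NA_character_)
  )
  off_outcome <- function(ids) {
    ifelse(is.na(ids), NA_real_,
           as.numeric(!is.na(co$sb_first_date[match(ids, co$person_id)])))
  }
  par_outcome <- function(ids) {
    as.numeric(!is.na(persons$sb_first_date[match(ids, persons$person_id)]))
  }
  fam_tbl$y_p1 <- par_outcome(fam_tbl$p1_id)
  fam_tbl$y_p2 <- par_outcome(fam_tbl$p2_id)
  for (m in c("o11", "o12", "o21", "o22")) {
    fam_tbl[[paste0("y_", m)]] <- off_outcome(fam_tbl[[paste0(m, "_id")]])
  }
  fam_tbl
}

empty_bg_families <- function() {
  tibble::tibble(family_id = character(), parent_type = character(),
                 p1_id = character(), p2_id = character(),
                 o11_id = character(), o12_id = character(),
                 o21_id = character(), o22_id = character(),
                 y_p1 = numeric(), y_p2 = numeric(), y_o11 = numeric(),
                 y_o12 = numeric(), y_o21 = numeric(), y_o22 = numeric())
}

#' Attach a per-member covariate to a families table
#'
#' Joins a person-level score (e.g. a propensity score logit) onto each
#' member-id column of a families table, creating `<name>_p1`,
#' `<name>_o11`, ... columns as expected by [fit_ml()]'s `covariates`
#' argument.
#'
#' @param families Output of [select_bg_families()].
#' @param scores Data frame with `person_id` and the score column.
#' @param name Name for the new covariate columns.
#' @param score_col Column of `scores` to use.
#' @param default Value used for members without a score.
#' @return `families` with added columns.
#' @export
attach_member_covariate <- function(families, scores, name,
                                    score_col = "score_logit", default = 0) {
  for (m in FAMILY_MEMBERS) {
    idc <- paste0(m, "_id")
    if (!idc %in% names(families)) next
    v <- scores[[score_col]][match(families[[idc]], scores$person_id)]
    v[is.na(v)] <- default
    families[[paste0(name, "_", m)]] <- v
  }
  families
}
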