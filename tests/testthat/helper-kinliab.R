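# Shared helpers: toy person tables, a path-counting kinship oracle, and a
# high-precision conditional-quadrature oracle for 4-member orthant
# probabilities.

blank_person <- function(person_id, sex = "F", birth = as.Date("1980-01-01"),
                         mother = NA_character_, father = NA_character_,
                         sb = as.Date(NA), death = as.Date(NA),
                         emig = as.Date(NA), generation = "offspring",
                         twin = "none", born_in_sweden = TRUE,
                         education = 3L, parity = 1L,
                         m_gm = NA_character_, m_gf = NA_character_,
                         p_gm = NA_character_, p_gf = NA_character_) {
  tibble::tibble(
    person_id = person_id, family_id = "F0000001", generation = generation,
    sex = sex, birth_date = birth, death_date = death,
    emigration_date = emig, mother_id = mother, father_id = father,
    maternal_grandmother_id = m_gm, maternal_grandfather_id = m_gf,
    paternal_grandmother_id = p_gm, paternal_grandfather_id = p_gf,
    education_level = education, born_in_sweden = born_in_sweden,
    severe_mental_illness = FALSE, substance_use = FALSE,
    criminal_conviction = FALSE, parity = parity, sb_first_date = sb,
    twin_code = twin)
}

# recursive path-counting kinship coefficient; ped is a named list
# id -> c(mother, father) (NA for founders); MZ twin pairs are declared by
# mapping both ids to one genotype id.
kinship_oracle <- function(a, b, ped, mz_map = NULL) {
  canon <- function(x) if (!is.null(mz_map) && x %in% names(mz_map))
    mz_map[[x]] else x
  phi <- function(x, y) {
    x <- canon(x); y <- canon(y)
    if (is.na(x) || is.na(y)) return(0)
    if (identical(x, y)) return(0.5)   # non-inbred self-kinship
    # recurse on the younger (here: the one that has parents listed later);
    # pedigrees below are ordered ancestors-first
    ix <- match(x, names(ped)); iy <- match(y, names(ped))
    if (ix < iy) { tmp <- x; x <- y; y <- tmp }
    par <- ped[[x]]
    if (all(is.na(par))) return(0)
    0.5 * (phi(par[1], y) + phi(par[2], y))
  }
  2 * phi(a, b)   # additive-genetic correlation = 2 x kinship
}

# independent high-precision orthant oracle for a 4-member family
# (2 parents + 1 offspring each): conditional decomposition with adaptive
# 2-d quadrature over the parents and a closed-form bivariate CDF for the
# offspring given the parents.
conditional_orthant_oracle <- function(S, tau, pattern) {
  Spp <- S[1:2, 1:2]; Sop <- S[3:4, 1:2]
  B <- Sop %*% solve(Spp)
  Cc <- S[3:4, 3:4] - B %*% t(Sop)
  sd_c <- sqrt(diag(Cc)); Rc <- Cc / tcrossprod(sd_c)
  r_pp <- Spp[1, 2]
  F2 <- function(b1, b2) {
    if (b1 <= -37 || b2 <= -37) return(0)
    mvtnorm::pmvnorm(upper = c(min(b1, 37), min(b2, 37)), corr = Rc,
                     algorithm = mvtnorm::TVPACK(abseps = 1e-14))[1]
  }
  cond_rect <- function(p1, p2, pat_o) {
    mu <- as.vector(B %*% c(p1, p2))
    lo <- (ifelse(pat_o == 1, tau[3:4], -300) - mu) / sd_c
    hi <- (ifelse(pat_o == 1, 300, tau[3:4]) - mu) / sd_c
    F2(hi[1], hi[2]) - F2(lo[1], hi[2]) - F2(hi[1], lo[2]) + F2(lo[1], lo[2])
  }
  f_outer <- function(p1v) vapply(p1v, function(p1) {
    g <- function(p2v) vapply(p2v, function(p2) {
      stats::dnorm(p2, mean = r_pp * p1, sd = sqrt(1 - r_pp^2)) *
        cond_rect(p1, p2, pattern[3:4])
    }, 0)
    lo2 <- if (pattern[2] == 1) tau[2] else -10
    hi2 <- if (pattern[2] == 1) 10 else tau[2]
    stats::dnorm(p1) *
      stats::integrate(g, lo2, hi2, rel.tol = 1e-11, abs.tol = 1e-13)$value
  }, 0)
  lo1 <- if (pattern[1] == 1) tau[1] else -10
  hi1 <- if (pattern[1] == 1) 10 else tau[1]
  stats::integrate(f_outer, lo1, hi1, rel.tol = 1e-11,
                   abs.tol = 1e-13)$value
}

# generating truth used across the recovery-style tests
recovery_truth <- function() {
  liability_params(beta = 0.10, r_g = 0.40, a2_p = 0.50, a2_o = 0.60,
                   tau_p = threshold_from_prevalence(0.1),
                   tau_o = threshold_from_prevalence(0.1))
}

published_minimal_params <- function() {
  liability_params(beta = 0.04, r_g = 0.39, a2_p = 0.50, a2_o = 0.61)
}
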