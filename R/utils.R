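`%||%` <- function(x, y) if (is.null(x)) y else x

days_per_year <- 365.25

age_at <- function(date, birth_date) {
  as.numeric(date - birth_date) / days_per_year
}

date_at_age <- function(birth_date, age) {
  birth_date + round(age * days_per_year)
}

pseudo_inverse <- function(M, tol = 1e-12) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}
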