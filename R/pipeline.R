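## Pipeline: simulate -> build-pedigree -> propensity -> fit-bg -> fit-cox
## -> report, as one reproducible seeded run with a manifest.  One master
## seed spawns per-stage seeds through a documented splitting rule so every
## stage can be reproduced independently.

PIPELINE_STAGES <- c("simulate", "build-pedigree", "propensity", "fit-bg",
                     "fit-cox", "report")

stage_seed <- function(master_seed, stage_index) {
  as.integer((as.numeric(master_seed) + 7919 * stage_index) %% 2147483647)
}

#' Pipeline run configuration
#'
#' @param out_dir Output directory for every stage artifact.
#' @param generator A [registry_config()]; its seed is replaced by the
#'   stage seed derived from `seed`.
#' @param parent Analyzed parent, `"mother"` or `"father"`.
#' @param constraint Constraint set for the behavior-genetic fit (see
#'   [fit_ml()]).
#' @param ties Tie handling for Cox fits.
#' @param stages Stages to run (subset of
#'   `simulate, build-pedigree, propensity, fit-bg, fit-cox, report`).
#' @param use_propensity_in_bg Adjust the behavior-genetic fit for the
#'   propensity-score logits (parent and offspring scores).
#' @param add_paternal_score Additionally adjust offspring thresholds for
#'   the co-parent's (paternal) score.
#' @param cox_covariates Adjustment covariates for the adjusted Cox models.
#' @param seed Master seed.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(out_dir,
                            generator = registry_config(n_extended_families = 1000),
                            parent = c("mother", "father"),
                            constraint = "free",
                            ties = c("breslow", "efron"),
                            stages = PIPELINE_STAGES,
                            use_propensity_in_bg = FALSE,
                            add_paternal_score = FALSE,
                            cox_covariates = c("parity", "parental_age",
                                               "parent_born_in_sweden",
                                               "parent_smi",
                                               "parent_conviction"),
                            seed = 1) {
  parent <- match.arg(parent)
  ties <- match.arg(ties)
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(out_dir = out_dir, generator = generator, parent = parent,
         constraint = constraint, ties = ties, stages = stages,
         use_propensity_in_bg = use_propensity_in_bg,
         add_paternal_score = add_paternal_score,
         cox_covariates = cox_covariates,
         seed = as.integer(seed)),
    class = "pipeline_config")
}

read_stage_csv <- function(path, producer) {
  if (!file.exists(path)) {
    stop("missing upstream output `", basename(path), "`; run stage `",
         producer, "` first", call. = FALSE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE) |> tibble::as_tibble()
}

restore_persons <- function(out_dir) {
  p <- read_stage_csv(file.path(out_dir, "persons.csv"), "simulate")
  for (col in c("birth_date", "death_date", "emigration_date",
                "sb_first_date")) {
    p[[col]] <- as.Date(p[[col]])
  }
  for (col in c("born_in_sweden", "severe_mental_illness", "substance_use",
                "criminal_conviction")) {
    p[[col]] <- as.logical(p[[col]])
  }
  p
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order, writing every artifact under
#' `config$out_dir` (`persons.csv`, `truth.csv`, `cousin_pairs.csv`,
#' `bg_families.csv`, `exclusion_ledger.csv`, `propensity_<role>.csv`,
#' `fit_result.json`, `model_report.txt`, `cox_results.json`,
#' `km_table.csv`, `report.md`, `manifest.json`).  A stage failure halts
#' the run with the stage name; prior outputs are preserved.  Disabled
#' stages whose outputs are needed downstream are read back from
#' `out_dir`; a missing upstream file raises an error naming the stage to
#' (re)run.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest (class `run_manifest`), invisibly also written
#'   as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    master_seed = config$seed,
    parent = config$parent,
    versions = list(r = R.version.string,
                    kinliab = as.character(utils::packageVersion("kinliab"))),
    stages = list())
  state <- new.env(parent = emptyenv())
  state$results <- list()

  run_stage <- function(name, idx, fun) {
    if (!name %in% config$stages) {
      manifest$stages[[name]] <<- list(name = name, status = "skipped")
      message("[kinliab] stage ", name, ": skipped")
      return(invisible(NULL))
    }
    seed <- stage_seed(config$seed, idx)
    t0 <- proc.time()[3]
    info <- tryCatch(fun(seed), error = function(e) e)
    secs <- round(proc.time()[3] - t0, 2)
    if (inherits(info, "error")) {
      manifest$stages[[name]] <<- list(name = name, status = "failed",
                                       seed = seed, seconds = secs,
                                       error = conditionMessage(info))
      manifest$results <- NULL
      jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, force = TRUE)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(info),
           call. = FALSE)
    }
    manifest$stages[[name]] <<- c(list(name = name, status = "complete",
                                       seed = seed, seconds = secs), info)
    message("[kinliab] stage ", name, ": complete (", secs, "s)")
  }

  run_stage("simulate", 1L, function(seed) {
    gen <- config$generator
    gen$seed <- seed
    reg <- generate_registry(gen)
    write_registry(reg, config$out_dir)
    state$persons <- reg$persons
    state$registry <- reg
    list(outputs = c("persons.csv", "truth.csv"),
         n_persons = nrow(reg$persons),
         n_families = gen$n_extended_families)
  })

  get_persons <- function() {
    state$persons %||% {
      state$persons <- restore_persons(config$out_dir)
      state$persons
    }
  }

  run_stage("build-pedigree", 2L, function(seed) {
    cohort <- build_cohort(get_persons(), parent = config$parent)
    pairs <- enumerate_cousin_pairs(cohort)
    bg <- select_bg_families(cohort, seed = seed)
    utils::write.csv(pairs, file.path(config$out_dir, "cousin_pairs.csv"),
                     row.names = FALSE)
    utils::write.csv(bg, file.path(config$out_dir, "bg_families.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$ledger,
                     file.path(config$out_dir, "exclusion_ledger.csv"),
                     row.names = FALSE)
    state$cohort <- cohort
    state$pairs <- pairs
    state$bg <- bg
    list(outputs = c("cousin_pairs.csv", "bg_families.csv",
                     "exclusion_ledger.csv"),
         n_cohort = nrow(cohort$cohort), n_pairs = nrow(pairs),
         n_bg_families = nrow(bg),
         exclusions = stats::setNames(as.list(cohort$ledger$n_excluded),
                                      cohort$ledger$rule))
  })

  run_stage("propensity", 3L, function(seed) {
    persons <- get_persons()
    out <- character(0)
    for (role in c("mother", "father", "offspring")) {
      mod <- fit_propensity(persons, role = role)
      sc <- score_propensity(
        mod, persons[persons$person_id %in% mod$fitted$person_id, ])
      f <- paste0("propensity_", role, ".csv")
      utils::write.csv(sc, file.path(config$out_dir, f), row.names = FALSE)
      jsonlite::write_json(
        as.list(stats::coef(mod$fit)),
        file.path(config$out_dir, paste0("propensity_", role, "_coef.json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      state$results[[paste0("propensity_", role)]] <- mod
      state[[paste0("scores_", role)]] <- sc
      out <- c(out, f)
    }
    list(outputs = out)
  })

  run_stage("fit-bg", 4L, function(seed) {
    bg <- state$bg %||% {
      b <- read_stage_csv(file.path(config$out_dir, "bg_families.csv"),
                          "build-pedigree")
      b
    }
    if (!nrow(bg)) stop("no extended families available for the fit")
    covariates <- NULL
    if (config$use_propensity_in_bg) {
      parent_role <- config$parent
      bg <- attach_member_covariate(bg, state[[paste0("scores_", parent_role)]],
                                    "ps_parent")
      bg <- attach_member_covariate(bg, state$scores_offspring, "ps_off")
      off_cov <- "ps_off"
      if (config$add_paternal_score) {
        other <- if (config$parent == "mother") "father" else "mother"
        bg <- attach_member_covariate(bg, state[[paste0("scores_", other)]],
                                      "ps_coparent")
        off_cov <- c(off_cov, "ps_coparent")
      }
      covariates <- list(parent = "ps_parent", offspring = off_cov)
    }
    fit <- fit_ml(bg, constraint = config$constraint, covariates = covariates,
                  options = list(seed = seed))
    state$results$bg_fit <- fit
    jsonlite::write_json(fit_result_json(fit),
                         file.path(config$out_dir, "fit_result.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(model_report_text(fit, config),
               file.path(config$out_dir, "model_report.txt"))
    list(outputs = c("fit_result.json", "model_report.txt"),
         loglik = fit$loglik, converged = fit$converged)
  })

  run_stage("fit-cox", 5L, function(seed) {
    cohort <- state$cohort %||% stop("missing upstream output; run stage ",
                                     "`build-pedigree` first")
    pairs <- state$pairs
    end_study <- config$generator$censoring_model$end_of_study
    rec <- make_survival_records(cohort, end_of_study = end_study)
    utils::write.csv(rec, file.path(config$out_dir, "survival_records.csv"),
                     row.names = FALSE)
    km <- km_estimate(rec, at_age = 30)
    utils::write.csv(km, file.path(config$out_dir, "km_table.csv"),
                     row.names = FALSE)
    covs <- intersect(config$cox_covariates, names(rec))
    res <- list()
    res$population_unadjusted <- cox_json(
      fit_cox(rec, ties = config$ties))
    res$population_adjusted <- tryCatch(
      cox_json(fit_cox(rec, covariates = covs, ties = config$ties)),
      error = function(e) list(error = conditionMessage(e)))
    for (sub in c("full", "maternal-half", "paternal-half")) {
      pp <- pairs[pairs$parent_sibling_type == sub & !pairs$twin_parents, ]
      if (!nrow(pp)) next
      prec <- make_survival_records(cohort, pairs = pp,
                                    end_of_study = end_study)
      key <- gsub("-", "_", sub)
      res[[paste0("within_pair_unadjusted_", key)]] <- tryCatch(
        cox_json(fit_stratified_cox(prec, ties = config$ties)),
        error = function(e) list(error = conditionMessage(e)))
      res[[paste0("within_pair_adjusted_", key)]] <- tryCatch(
        cox_json(fit_stratified_cox(prec, covariates = covs,
                                    ties = config$ties)),
        error = function(e) list(error = conditionMessage(e)))
    }
    state$results$cox <- res
    state$results$km <- km
    jsonlite::write_json(res, file.path(config$out_dir, "cox_results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(outputs = c("survival_records.csv", "km_table.csv",
                     "cox_results.json"),
         n_records = nrow(rec), n_events = sum(rec$event))
  })

  manifest$results <- state$results
  manifest$truth <- if (!is.null(state$registry)) {
    tp <- config$generator$true_params
    list(beta = tp$beta, r_g = tp$r_g, a2_p = tp$a2_p, c2_p = tp$c2_p,
         a2_o = tp$a2_o, c2_o = tp$c2_o)
  }

  run_stage("report", 6L, function(seed) {
    txt <- render_report(manifest)
    writeLines(txt, file.path(config$out_dir, "report.md"))
    list(outputs = "report.md")
  })

  out <- manifest
  out$results <- NULL  # keep the JSON manifest lean and serializable
  jsonlite::write_json(out, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  manifest$out_dir <- config$out_dir
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

fit_result_json <- function(fit) {
  list(
    constraint = paste(fit$constraint, collapse = "+"),
    estimates = stats::setNames(as.list(fit$tidy$estimate), fit$tidy$term),
    std_errors = stats::setNames(as.list(fit$tidy$std.error), fit$tidy$term),
    conf_low = stats::setNames(as.list(fit$tidy$conf.low), fit$tidy$term),
    conf_high = stats::setNames(as.list(fit$tidy$conf.high), fit$tidy$term),
    loglik = fit$loglik,
    n_par = fit$n_par,
    n_families = fit$n_families,
    converged = fit$converged,
    covariance_due_to_beta = fit$covariance_due_to_beta
  )
}

cox_json <- function(cc) {
  td <- tidy.cousin_cox(cc)
  row <- td[td$term == "exposure", ]
  gl <- glance.cousin_cox(cc)
  list(hr = row$estimate, conf_low = row$conf.low, conf_high = row$conf.high,
       n = gl$n, n_events = gl$n_events,
       n_informative_strata = gl$n_informative_strata,
       covariates = setdiff(td$term, "exposure"))
}

fmt_ci <- function(est, lo, hi, digits = 2) {
  if (is.null(est) || is.na(est)) return("-")
  sprintf(paste0("%.", digits, "f (%.", digits, "f, %.", digits, "f)"),
          est, lo, hi)
}

model_report_text <- function(fit, config) {
  td <- fit$tidy
  g <- function(term) td[td$term == term, ]
  row <- vapply(c("beta", "r_g", "a2_p", "c2_p", "e2_p", "a2_o", "c2_o",
                  "e2_o"),
                function(tm) {
                  r <- g(tm)
                  if (is.na(r$std.error)) sprintf("%.2f", r$estimate)
                  else fmt_ci(r$estimate, r$conf.low, r$conf.high)
                }, "")
  sb <- fit$covariance_due_to_beta
  c("Structural model estimates (synthetic data)",
    paste("constraint:", paste(fit$constraint, collapse = "+")),
    "",
    sprintf("%-28s %s", "beta (95% CI)", row[1]),
    sprintf("%-28s %s", "r_g (95% CI)", row[2]),
    sprintf("%-28s %s", "a2_p (95% CI)", row[3]),
    sprintf("%-28s %s", "c2_p", row[4]),
    sprintf("%-28s %s", "e2_p (95% CI)", row[5]),
    sprintf("%-28s %s", "a2_o (95% CI)", row[6]),
    sprintf("%-28s %s", "c2_o", row[7]),
    sprintf("%-28s %s", "e2_o (95% CI)", row[8]),
    sprintf("%-28s %s", "covariance due to beta (%)",
            fmt_ci(sb$estimate, sb$conf.low, sb$conf.high, 1)),
    "",
    sprintf("log-likelihood %.2f on %d parameters, %s families",
            fit$loglik, fit$n_par, format(fit$n_families, big.mark = ",")))
}

#' Render a markdown report from a run manifest
#'
#' Emits a structural-model table (estimates with CIs and the covariance
#' share due to the direct path, next to the generating truth when
#' available) and a hazard-ratio table comparing population and
#' within-cousin-pair fits, clearly labeled as synthetic-data results.
#'
#' @param manifest A `run_manifest` from [run_pipeline()].
#' @return Character vector of markdown lines.
#' @export
render_report <- function(manifest) {
  res <- manifest$results
  out <- c("# Synthetic-run report",
           "",
           paste0("All results below are computed from *synthetic* registry ",
                  "data (master seed ", manifest$master_seed, ", analyzed ",
                  "parent: ", manifest$parent, ")."),
           "")
  if (!is.null(res$bg_fit)) {
    fit <- res$bg_fit
    td <- fit$tidy
    truth <- manifest$truth
    out <- c(out, "## Structural model (liability scale)", "",
             "| parameter | estimate (95% CI) | truth |",
             "|---|---|---|")
    for (tm in c("beta", "r_g", "a2_p", "c2_p", "e2_p", "a2_o", "c2_o",
                 "e2_o")) {
      r <- td[td$term == tm, ]
      est <- if (is.na(r$std.error)) sprintf("%.2f (fixed)", r$estimate)
        else fmt_ci(r$estimate, r$conf.low, r$conf.high)
      tv <- if (!is.null(truth)) {
        tval <- switch(tm, e2_p = 1 - truth$a2_p - truth$c2_p,
                       e2_o = 1 - truth$a2_o - truth$c2_o, truth[[tm]])
        sprintf("%.2f", tval)
      } else "-"
      out <- c(out, sprintf("| %s | %s | %s |", tm, est, tv))
    }
    sb <- fit$covariance_due_to_beta
    out <- c(out, sprintf("| covariance due to beta (%%) | %s | - |",
                          fmt_ci(sb$estimate, sb$conf.low, sb$conf.high, 1)),
             "")
  }
  if (!is.null(res$cox)) {
    out <- c(out, "## Hazard ratios for exposure to parental suicidal behavior",
             "", "| comparison | HR (95% CI) | events |", "|---|---|---|")
    for (nm in names(res$cox)) {
      cj <- res$cox[[nm]]
      if (!is.null(cj$error)) {
        out <- c(out, sprintf("| %s | not estimable (%s) | - |", nm, cj$error))
      } else {
        out <- c(out, sprintf("| %s | %s | %d |", nm,
                              fmt_ci(cj$hr, cj$conf_low, cj$conf_high),
                              as.integer(cj$n_events)))
      }
    }
    out <- c(out, "")
  }
  if (!is.null(res$km)) {
    out <- c(out, sprintf(paste0("Kaplan-Meier cumulative incidence of ",
                                 "offspring suicidal behavior by age 30: ",
                                 "%.0f per 10,000."),
                          res$km$cum_incidence_per_10k), "")
  }
  out
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> master seed", x$master_seed, "\n")
  for (st in x$stages) {
    cat(sprintf("  %-15s %s%s\n", st$name, st$status,
                if (!is.null(st$seconds)) sprintf(" (%.1fs)", st$seconds)
                else ""))
  }
  invisible(x)
}
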