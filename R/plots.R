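## ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot liability_fit
#' @export
#' @rdname autoplot-kinliab
#' @param object A fitted object.
#' @param ... Unused.
autoplot.liability_fit <- function(object, ...) {
  td <- object$tidy
  td <- td[!td$term %in% c("tau_p", "tau_o") &
             !grepl("^gamma_", td$term), ]
  td$term <- factor(td$term, levels = rev(td$term))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "estimate (95% CI)", y = NULL,
                  title = "Liability-model estimates",
                  subtitle = paste("constraint:",
                                   paste(object$constraint, collapse = "+"))) +
    ggplot2::theme_minimal()
}

#' Plots for kinliab result objects
#'
#' `autoplot()` methods: a coefficient plot for [fit_ml()] results and a
#' forest plot of hazard ratios for Cox fits; [plot_km()] draws the
#' Kaplan-Meier cumulative incidence by exposure group.
#'
#' @name autoplot-kinliab
NULL

#' @method autoplot cousin_cox
#' @export
#' @rdname autoplot-kinliab
autoplot.cousin_cox <- function(object, ...) {
  td <- tidy.cousin_cox(object)
  td$term <- factor(td$term, levels = rev(td$term))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "hazard ratio (95% CI, log scale)", y = NULL,
                  title = if (object$stratified)
                    "Within-cousin-pair hazard ratios"
                  else "Population hazard ratios") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier cumulative incidence plot
#'
#' @param records Survival records (see [make_survival_records()]).
#' @param by Optional grouping column (default `"exposure"` when present).
#' @return A ggplot.
#' @export
plot_km <- function(records, by = if ("exposure" %in% names(records))
  "exposure" else NULL) {
  f <- if (is.null(by)) {
    survival::survfit(survival::Surv(entry_age, exit_age, event) ~ 1,
                      data = records)
  } else {
    records$.group <- factor(records[[by]])
    survival::survfit(survival::Surv(entry_age, exit_age, event) ~ .group,
                      data = records)
  }
  sm <- summary(f)
  df <- tibble::tibble(
    age = sm$time,
    cuminc = 1 - sm$surv,
    group = if (is.null(by)) "all" else
      sub("^\\.group=", "", as.character(sm$strata))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = 10000 * .data$cuminc,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "age (years)",
                  y = "cumulative incidence per 10,000",
                  colour = by %||% NULL,
                  title = "First suicidal behavior in the offspring generation") +
    ggplot2::theme_minimal()
}
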