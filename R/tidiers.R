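#' Tidy a case quantification
#'
#' One row per case with every quantification and classification field.
#'
#' @param x A `case_quantification`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @exportS3Method generics::tidy
tidy.case_quantification <- function(x, ...) {
  tibble::tibble(
    n_cells = x$n_cells,
    mean_her2 = x$mean_her2, mean_cep17 = x$mean_cep17, ratio = x$ratio,
    sd_her2 = x$sd_her2, sd_cep17 = x$sd_cep17, sd_ratio = x$sd_ratio,
    me_her2 = x$me_her2, me_ratio = x$me_ratio,
    ish_group = x$ish_group, her2_status = x$her2_status
  )
}

#' Glance at a case quantification
#'
#' @param x A `case_quantification`.
#' @param ... Unused.
#' @return A one-row tibble with the headline numbers and warning count.
#' @exportS3Method generics::glance
glance.case_quantification <- function(x, ...) {
  tibble::tibble(n_cells = x$n_cells, ratio = x$ratio,
                 mean_her2 = x$mean_her2, ish_group = x$ish_group,
                 her2_status = x$her2_status, n_warnings = length(x$warnings))
}

#' Tidy a power-model fit
#'
#' @param x A `power_model_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`beta0`, `beta1`).
#' @exportS3Method generics::tidy
tidy.power_model_fit <- function(x, ...) {
  tibble::tibble(term = c("beta0", "beta1"),
                 estimate = c(x$beta0, x$beta1))
}

#' Glance at a power-model fit
#'
#' @param x A `power_model_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `beta0`, `beta1`, `r_squared`, `n`.
#' @exportS3Method generics::glance
glance.power_model_fit <- function(x, ...) {
  tibble::tibble(beta0 = x$beta0, beta1 = x$beta1,
                 r_squared = x$r_squared, n = nrow(x$data))
}

#' Tidy a Bland-Altman analysis
#'
#' @param x A `bland_altman`.
#' @param ... Unused.
#' @return A one-row tibble with the mean difference and 95% limits.
#' @exportS3Method generics::tidy
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(mean_diff = x$mean_diff, lower_limit = x$lower_limit,
                 upper_limit = x$upper_limit, sd_diff = x$sd_diff, n = x$n)
}

#' Tidy an agreement report
#'
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @return A long tibble of `statistic`, `value`.
#' @exportS3Method generics::tidy
tidy.agreement_report <- function(x, ...) {
  tibble::tibble(
    statistic = c("concordance", "kappa", "sensitivity", "specificity",
                  "prevalence", "ppv", "npv", "accuracy"),
    value = c(x$concordance, x$kappa, x$sensitivity, x$specificity,
              x$prevalence, x$ppv, x$npv, x$accuracy)
  )
}
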