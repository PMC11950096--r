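#' Build a 2x2 confusion table
#'
#' Convention: the reference method (visual scoring) defines the truth, the
#' test method (image analysis) the calls. `tp` are reference-positive
#' cases called positive, `fn` reference-positive called negative, `fp`
#' reference-negative called positive, `tn` reference-negative called
#' negative.
#'
#' @param tp,fn,fp,tn Non-negative counts, total > 0.
#' @return A `confusion_table` (named numeric vector).
#' @export
confusion_table <- function(tp, fn, fp, tn) {
  v <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(!is.finite(v)) || any(v < 0) || sum(v) <= 0) {
    rlang::abort("confusion counts must be non-negative with a positive total",
                 class = "ishquant_analysis_error")
  }
  structure(v, class = "confusion_table")
}

#' Cohen's kappa for a 2x2 confusion table
#'
#' Chance-corrected agreement, `kappa = (p_o - p_e) / (1 - p_e)` with the
#' standard marginal expected agreement `p_e`. When both raters are
#' constant (`p_e = 1`) and agreement is perfect, 1 is returned.
#'
#' @param table A [confusion_table()] (or anything coercible: a named
#'   vector with `tp`, `fn`, `fp`, `tn`).
#' @return Kappa in \[-1, 1\].
#' @export
#' @examples
#' cohen_kappa(confusion_table(36, 4, 0, 40)) # 0.9
cohen_kappa <- function(table) {
  v <- as.numeric(table[c("tp", "fn", "fp", "tn")])
  if (any(is.na(v))) {
    rlang::abort("table must provide tp, fn, fp and tn", class = "ishquant_analysis_error")
  }
  n <- sum(v)
  if (n <= 0) rlang::abort("empty confusion table", class = "ishquant_analysis_error")
  tp <- v[1]; fn <- v[2]; fp <- v[3]; tn <- v[4]
  po <- (tp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (fp + tn) * (fn + tn)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    return(if (po >= 1 - .Machine$double.eps^0.5) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' Observed concordance of a confusion table
#'
#' @inheritParams cohen_kappa
#' @return Proportion of agreeing calls.
#' @export
concordance <- function(table) {
  v <- as.numeric(table[c("tp", "fn", "fp", "tn")])
  (v[1] + v[4]) / sum(v)
}

#' Sensitivity and specificity of a confusion table
#'
#' @inheritParams cohen_kappa
#' @return Named vector with `sensitivity` and `specificity`.
#' @export
sens_spec <- function(table) {
  v <- as.numeric(table[c("tp", "fn", "fp", "tn")])
  c(sensitivity = v[1] / (v[1] + v[2]),
    specificity = v[4] / (v[3] + v[4]))
}

#' Predictive values and accuracy at a stated prevalence
#'
#' Bayes' rule applied to a test with the given sensitivity and
#' specificity in a population with the given prevalence of true
#' positives:
#' `PPV = se * pi / (se * pi + (1 - sp) * (1 - pi))`,
#' `NPV = sp * (1 - pi) / (sp * (1 - pi) + (1 - se) * pi)`,
#' `accuracy = se * pi + sp * (1 - pi)`.
#' A predictive value with a zero denominator (e.g. PPV when the test
#' never calls positive) is reported as `NA`, not 0.
#'
#' @param sensitivity,specificity,prevalence Proportions in \[0, 1\].
#' @return A tibble with `ppv`, `npv` and `accuracy`.
#' @export
#' @examples
#' diagnostic_metrics(0.90, 1.00, 0.15) # PPV 1, NPV 0.9827, accuracy 0.985
diagnostic_metrics <- function(sensitivity, specificity, prevalence) {
  v <- c(sensitivity, specificity, prevalence)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
    rlang::abort("sensitivity, specificity and prevalence must be in [0, 1]",
                 class = "ishquant_analysis_error")
  }
  se <- sensitivity; sp <- specificity; pi <- prevalence
  ppv_den <- se * pi + (1 - sp) * (1 - pi)
  npv_den <- sp * (1 - pi) + (1 - se) * pi
  tibble::tibble(
    ppv = ifelse(ppv_den > 0, se * pi / ppv_den, NA_real_),
    npv = ifelse(npv_den > 0, sp * (1 - pi) / npv_den, NA_real_),
    accuracy = se * pi + sp * (1 - pi)
  )
}

#' Bland-Altman limits of agreement
#'
#' Pairwise differences `b - a` (by the package's convention `a` is the
#' visual measurement and `b` the image-analysis one, so a lower
#' image-analysis value gives a negative mean difference). Limits are
#' `mean_diff +/- 1.96 * SD` of the differences; the per-pair means are
#' kept for plotting.
#'
#' @param a,b Numeric vectors of paired measurements (length >= 2).
#' @return A `bland_altman` list: `mean_diff`, `lower_limit`,
#'   `upper_limit`, `sd_diff`, `n` and a `data` tibble (`mean`, `diff`).
#' @export
#' @examples
#' bland_altman(c(1, 2, 3), c(2, 2, 5)) # mean_diff 1, limits -0.96 / 2.96
bland_altman <- function(a, b) {
  if (length(a) != length(b)) {
    rlang::abort("a and b must have equal length", class = "ishquant_analysis_error")
  }
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2) {
    rlang::abort("Bland-Altman needs at least 2 pairs", class = "ishquant_analysis_error")
  }
  d <- b - a
  md <- mean(d)
  sdd <- stats::sd(d)
  structure(list(
    mean_diff = md,
    lower_limit = md - 1.96 * sdd,
    upper_limit = md + 1.96 * sdd,
    sd_diff = sdd,
    n = length(d),
    data = tibble::tibble(mean = (a + b) / 2, diff = d)
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n=%d mean diff %.3f, 95%% limits [%.3f, %.3f]\n",
              x$n, x$mean_diff, x$lower_limit, x$upper_limit))
  invisible(x)
}

#' Pearson correlation of paired measurements
#'
#' Standard product-moment correlation with explicit preconditions: at
#' least 3 complete pairs and non-zero variance in both vectors (zero
#' variance is an error, not `NA`).
#'
#' @param a,b Numeric vectors of equal length.
#' @return The correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) {
    rlang::abort("a and b must have equal length", class = "ishquant_analysis_error")
  }
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) {
    rlang::abort("Pearson correlation needs at least 3 pairs",
                 class = "ishquant_analysis_error")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    rlang::abort("Pearson correlation undefined for zero variance",
                 class = "ishquant_analysis_error")
  }
  stats::cor(a, b)
}

#' Fit a power model to margin-of-error curves
#'
#' Classical curve-estimation power fit `ME(n) = beta0 * n^beta1` by least
#' squares on the log-log form `log(ME) = log(beta0) + beta1 * log(n)`;
#' `R^2` is computed in log space.
#'
#' @param n Cell counts (> 0).
#' @param me Margins of error (> 0); at least 3 points.
#' @return A `power_model_fit`: `beta0`, `beta1`, `r_squared` and the
#'   underlying `lm` fit.
#' @export
#' @examples
#' n <- c(100, 500, 2000)
#' fit_power_model(n, 3.497 * n^-0.578)
fit_power_model <- function(n, me) {
  if (length(n) != length(me) || length(n) < 3) {
    rlang::abort("need at least 3 (n, ME) points", class = "ishquant_analysis_error")
  }
  if (any(!is.finite(n)) || any(!is.finite(me)) || any(n <= 0) || any(me <= 0)) {
    rlang::abort("n and ME must be positive (log undefined otherwise)",
                 class = "ishquant_analysis_error")
  }
  df <- data.frame(log_n = log(n), log_me = log(me))
  fit <- stats::lm(log_me ~ log_n, data = df)
  ss_tot <- sum((df$log_me - mean(df$log_me))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(
    beta0 = unname(exp(stats::coef(fit)[1])),
    beta1 = unname(stats::coef(fit)[2]),
    r_squared = r2,
    model = fit,
    data = tibble::tibble(n = n, me = me)
  ), class = "power_model_fit")
}

#' @export
print.power_model_fit <- function(x, ...) {
  cat(sprintf("<power_model_fit> ME(n) = %.4g * n^%.4g (R^2 = %.3f)\n",
              x$beta0, x$beta1, x$r_squared))
  invisible(x)
}

#' Predicted margin of error at a cell count
#'
#' @param fit A [fit_power_model()] result (or a list with `beta0`,
#'   `beta1`).
#' @param n Cell count(s).
#' @return `beta0 * n^beta1`.
#' @export
predict_me <- function(fit, n) fit$beta0 * n^fit$beta1

#' Minimum cell count for a target margin of error
#'
#' Smallest integer `n >= 1` with `beta0 * n^beta1 <= threshold`, from the
#' closed-form inversion `n0 = (threshold / beta0)^(1 / beta1)` followed by
#' an integer check at `n - 1` (guarding floating-point rounding of the
#' ceiling).
#'
#' @param fit A [fit_power_model()] result, or a list/vector with `beta0`
#'   and `beta1`.
#' @param threshold Target margin of error (> 0).
#' @return Integer cell count.
#' @export
#' @examples
#' min_cells_for_me(list(beta0 = 3.497, beta1 = -0.578), 0.1) # 469
min_cells_for_me <- function(fit, threshold) {
  b0 <- as.numeric(fit[["beta0"]])
  b1 <- as.numeric(fit[["beta1"]])
  if (!is.finite(b0) || !is.finite(b1) || b0 <= 0) {
    rlang::abort("fit must provide beta0 > 0 and finite beta1",
                 class = "ishquant_analysis_error")
  }
  if (!is.finite(threshold) || threshold <= 0) {
    rlang::abort("threshold must be positive", class = "ishquant_analysis_error")
  }
  if (b1 >= 0) {
    if (b0 <= threshold) return(1L)
    rlang::abort("margin of error never falls below the threshold (beta1 >= 0)",
                 class = "ishquant_analysis_error")
  }
  if (b0 <= threshold) return(1L)
  n <- as.integer(ceiling((threshold / b0)^(1 / b1)))
  n <- max(n, 1L)
  # exactness check around the closed-form solution
  while (n > 1L && b0 * (n - 1L)^b1 <= threshold) n <- n - 1L
  while (b0 * n^b1 > threshold) n <- n + 1L
  n
}

#' Cancer-cell inclusion performance against ground truth
#'
#' Measures how well the inclusion decision (the size gate plus scoring
#' rules) selects cancer cells, by matching each segmented nucleus to the
#' nearest ground-truth nucleus within `max_match_um` (greedy,
#' closest-pair-first). Sensitivity is the fraction of true cancer nuclei
#' whose matched detection is included; specificity the fraction of true
#' non-cancer nuclei excluded (unmatched truth nuclei count as excluded).
#'
#' @param nuclei Nucleus tibble with `x`, `y`, `included` (or an
#'   `ish_segmentation`).
#' @param truth Ground-truth tibble from [generate_case()] with
#'   `is_cancer`, `x`, `y`.
#' @param pixel_size_um Micrometres per pixel for the centroid distances.
#' @param max_match_um Matching radius (default 2).
#' @return A tibble with `sensitivity`, `specificity`, `n_matched`.
#' @export
inclusion_performance <- function(nuclei, truth, pixel_size_um,
                                  max_match_um = 2) {
  if (inherits(nuclei, "ish_segmentation")) nuclei <- nuclei$nuclei
  if (!nrow(truth)) {
    rlang::abort("empty ground truth", class = "ishquant_analysis_error")
  }
  match <- match_to_truth(nuclei, truth, pixel_size_um, max_match_um)
  if (!any(!is.na(match))) {
    rlang::abort("no detected nucleus matches the ground truth",
                 class = "ishquant_analysis_error")
  }
  included_truth <- rep(FALSE, nrow(truth))
  ok <- !is.na(match)
  included_truth[match[ok]] <- nuclei$included[ok]
  cc <- truth$is_cancer
  tibble::tibble(
    sensitivity = if (any(cc)) sum(included_truth[cc]) / sum(cc) else NA_real_,
    specificity = if (any(!cc)) sum(!included_truth[!cc]) / sum(!cc) else NA_real_,
    n_matched = sum(ok)
  )
}

# greedy 1:1 matching detected -> truth by increasing centroid distance;
# returns for each detected nucleus the matched truth row index or NA
match_to_truth <- function(nuclei, truth, pixel_size_um, max_match_um) {
  if (!nrow(nuclei)) return(integer())
  dx <- outer(nuclei$x, truth$x, "-") * pixel_size_um
  dy <- outer(nuclei$y, truth$y, "-") * pixel_size_um
  d <- sqrt(dx^2 + dy^2)
  cand <- which(d <= max_match_um, arr.ind = TRUE)
  match <- rep(NA_integer_, nrow(nuclei))
  if (!nrow(cand)) return(match)
  cand <- cand[order(d[cand]), , drop = FALSE]
  used_truth <- rep(FALSE, nrow(truth))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (is.na(match[i]) && !used_truth[j]) {
      match[i] <- j
      used_truth[j] <- TRUE
    }
  }
  match
}

#' Full agreement report between two raters/methods
#'
#' Bundles the validation statistics comparing a reference (visual) and a
#' test (image analysis) method: concordance, Cohen's kappa, sensitivity,
#' specificity, predictive values and accuracy at a stated prevalence, and
#' optionally Bland-Altman limits and Pearson correlation per continuous
#' measure.
#'
#' @param table A [confusion_table()].
#' @param prevalence Prevalence at which predictive values are computed.
#' @param pairs Optional tibble of paired continuous measurements with
#'   columns `measure`, `visual`, `ia`.
#' @return An `agreement_report` list.
#' @export
agreement_report <- function(table, prevalence, pairs = NULL) {
  ss <- sens_spec(table)
  dm <- diagnostic_metrics(ss[["sensitivity"]], ss[["specificity"]], prevalence)
  rep <- list(
    concordance = concordance(table),
    kappa = cohen_kappa(table),
    sensitivity = ss[["sensitivity"]],
    specificity = ss[["specificity"]],
    prevalence = prevalence,
    ppv = dm$ppv, npv = dm$npv, accuracy = dm$accuracy
  )
  if (!is.null(pairs)) {
    stopifnot(all(c("measure", "visual", "ia") %in% names(pairs)))
    rep$measures <- lapply(split(pairs, pairs$measure), function(df) {
      list(bland_altman = bland_altman(df$visual, df$ia),
           pearson_r = pearson_r(df$visual, df$ia))
    })
  }
  structure(rep, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> concordance %.3f, kappa %.3f\n",
              x$concordance, x$kappa))
  cat(sprintf("  se %.3f sp %.3f | at prevalence %.2f: PPV %.4f NPV %.4f acc %.4f\n",
              x$sensitivity, x$specificity, x$prevalence, x$ppv, x$npv,
              x$accuracy))
  for (m in names(x$measures)) {
    ba <- x$measures[[m]]$bland_altman
    cat(sprintf("  %s: mean diff %.3f [%.3f, %.3f], r = %.3f\n", m,
                ba$mean_diff, ba$lower_limit, ba$upper_limit,
                x$measures[[m]]$pearson_r))
  }
  invisible(x)
}
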