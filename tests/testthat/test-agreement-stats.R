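test_that("Cohen's kappa matches hand-computed agreement structures", {
  # 80 cases, 4 false negatives, no false positives:
  # p_o = 0.95, p_e = 0.5, kappa = 0.9
  expect_equal(cohen_kappa(confusion_table(36, 4, 0, 40)), 0.9)
  expect_equal(concordance(confusion_table(36, 4, 0, 40)), 0.95)
  expect_equal(cohen_kappa(confusion_table(40, 0, 0, 40)), 1)
  expect_equal(cohen_kappa(confusion_table(25, 25, 25, 25)), 0)
  # constant raters in perfect agreement
  expect_equal(cohen_kappa(confusion_table(10, 0, 0, 0)), 1)
  expect_error(confusion_table(0, 0, 0, 0), class = "ishquant_analysis_error")
  expect_error(confusion_table(-1, 1, 1, 1), class = "ishquant_analysis_error")
})

test_that("Bayes predictive values and accuracy follow the closed forms", {
  dm <- diagnostic_metrics(0.90, 1.00, 0.15)
  expect_equal(dm$ppv, 1)
  expect_equal(dm$npv, 0.85 / (0.85 + 0.1 * 0.15)) # 0.982659
  expect_equal(round(100 * dm$npv, 2), 98.27)
  expect_equal(dm$accuracy, 0.985)
  # the cellularity bound: se 0.64, sp 0.83 at 84% prevalence
  dm2 <- diagnostic_metrics(0.64, 0.83, 0.84)
  expect_equal(dm2$ppv, 0.64 * 0.84 / (0.64 * 0.84 + 0.17 * 0.16))
  expect_gte(dm2$ppv, 0.95)
  # degenerate limits
  dm3 <- diagnostic_metrics(1, 1, 0.3)
  expect_equal(unlist(dm3), c(ppv = 1, npv = 1, accuracy = 1))
  # se = sp at prevalence 0.5 reduces accuracy to se
  dm4 <- diagnostic_metrics(0.7, 0.7, 0.5)
  expect_equal(dm4$accuracy, 0.7)
  # PPV undefined (not zero) when the test never calls positive
  dm5 <- diagnostic_metrics(0, 1, 0.15)
  expect_true(is.na(dm5$ppv))
  expect_error(diagnostic_metrics(1.2, 1, 0.5), class = "ishquant_analysis_error")
})

test_that("Bland-Altman limits come from the differences (test minus reference)", {
  ba <- bland_altman(c(1, 2, 3), c(2, 2, 5)) # diffs 1, 0, 2
  expect_equal(ba$mean_diff, 1)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$lower_limit, -0.96)
  expect_equal(ba$upper_limit, 2.96)
  expect_equal(ba$data$mean, c(1.5, 2, 4))
  # identical pairs and a pure shift collapse the limits
  expect_equal(unlist(tidy(bland_altman(1:5, 1:5))[1, 1:3]),
               c(mean_diff = 0, lower_limit = 0, upper_limit = 0))
  ba2 <- bland_altman(1:5, 1:5 + 0.5)
  expect_equal(c(ba2$mean_diff, ba2$lower_limit, ba2$upper_limit),
               c(0.5, 0.5, 0.5))
  expect_error(bland_altman(1, 2), class = "ishquant_analysis_error")
})

test_that("Pearson correlation enforces its preconditions", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 3), 1)
  expect_equal(pearson_r(1:10, -1 * (1:10)), -1)
  expect_equal(pearson_r(c(0, 1, 2), c(0, 1, 0)), 0) # symmetric construction
  expect_error(pearson_r(1:2, 1:2), class = "ishquant_analysis_error")
  expect_error(pearson_r(rep(1, 5), 1:5), class = "ishquant_analysis_error")
})

test_that("the power fit inverts exact power-law data to machine precision", {
  n <- c(50, 100, 469, 953, 2000, 5000)
  fit <- fit_power_model(n, 3.497 * n^-0.578)
  expect_equal(fit$beta0, 3.497, tolerance = 1e-10)
  expect_equal(fit$beta1, -0.578, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # constant ME: flat exponent
  flat <- fit_power_model(n, rep(0.2, length(n)))
  expect_equal(flat$beta1, 0)
  expect_error(fit_power_model(n, c(-1, 1, 1, 1, 1, 1)),
               class = "ishquant_analysis_error")
  expect_error(fit_power_model(1:2, 1:2), class = "ishquant_analysis_error")
})

test_that("margins of error over iid per-cell draws shrink like 1/sqrt(n)", {
  set.seed(2024)
  ns <- round(exp(seq(log(50), log(5000), length.out = 12)))
  mes <- vapply(ns, function(n) {
    margin_of_error(rpois(n, 4) / pmax(rpois(n, 2), 1))
  }, numeric(1))
  fit <- fit_power_model(ns, mes)
  expect_gte(fit$beta1, -0.6)
  expect_lte(fit$beta1, -0.4)
})

test_that("the minimum-cell solver inverts the fitted curve exactly", {
  expect_equal(min_cells_for_me(list(beta0 = 3.497, beta1 = -0.578), 0.1), 469L)
  expect_equal(min_cells_for_me(list(beta0 = 7.479, beta1 = -0.629), 0.1), 953L)
  expect_equal(min_cells_for_me(list(beta0 = 0.1, beta1 = -1), 0.1), 1L)
  # minimality: ME(n) <= t < ME(n - 1) by direct evaluation
  for (b in list(c(3.497, -0.578), c(7.479, -0.629), c(5, -0.5))) {
    fit <- list(beta0 = b[1], beta1 = b[2])
    n <- min_cells_for_me(fit, 0.1)
    expect_lte(predict_me(fit, n), 0.1)
    expect_gt(predict_me(fit, n - 1), 0.1)
  }
  expect_error(min_cells_for_me(list(beta0 = 3, beta1 = 0.2), 0.1),
               class = "ishquant_analysis_error")
  expect_error(min_cells_for_me(list(beta0 = 3, beta1 = -0.5), -1),
               class = "ishquant_analysis_error")
})

test_that("inclusion performance equals a brute-force recount over the truth", {
  cs <- mixed_case()
  res <- cached("mixed_res", run_case(cs$tile))
  perf <- inclusion_performance(res$nuclei, cs$truth, 0.121)
  # oracle: independent greedy matching + recount
  m <- match_nuclei_to_truth(res$nuclei, cs$truth, 0.121)
  inc <- rep(FALSE, nrow(cs$truth))
  inc[m[!is.na(m)]] <- res$nuclei$included[!is.na(m)]
  expect_equal(perf$sensitivity,
               sum(inc & cs$truth$is_cancer) / sum(cs$truth$is_cancer))
  expect_equal(perf$specificity,
               sum(!inc & !cs$truth$is_cancer) / sum(!cs$truth$is_cancer))
  # a gate that includes everything can only exclude undetected truth nuclei
  all_in <- res$nuclei
  all_in$included <- TRUE
  n_unmatched_noncancer <- sum(!cs$truth$is_cancer) -
    sum(!cs$truth$is_cancer[m[!is.na(m)]])
  expect_equal(inclusion_performance(all_in, cs$truth, 0.121)$specificity,
               n_unmatched_noncancer / sum(!cs$truth$is_cancer))
  expect_error(inclusion_performance(res$nuclei, cs$truth[0, ], 0.121),
               class = "ishquant_analysis_error")
})

test_that("the agreement report bundles confusion and paired statistics", {
  pairs <- tibble::tibble(
    case_id = rep(1:10, 2),
    measure = rep(c("ratio", "her2_cn"), each = 10),
    visual = c(seq(1, 3, length.out = 10), seq(2, 8, length.out = 10)),
    ia = c(seq(1, 3, length.out = 10) - 0.2, seq(2, 8, length.out = 10) + 0.1))
  rep <- agreement_report(confusion_table(36, 4, 0, 40), 0.15, pairs)
  expect_equal(rep$kappa, 0.9)
  expect_equal(rep$sensitivity, 0.9)
  expect_equal(rep$specificity, 1)
  expect_equal(rep$measures$ratio$bland_altman$mean_diff, -0.2)
  expect_equal(rep$measures$her2_cn$pearson_r, 1)
  td <- tidy(rep)
  expect_equal(td$value[td$statistic == "accuracy"], 0.985)
})
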