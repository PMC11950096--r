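test_that("only cells with at least one copy of each probe are scored", {
  nuc <- make_nuclei(her2 = c(0, 1, 3, 2, 0), cep17 = c(2, 1, 2, 0, 0))
  out <- score_cells(nuc)
  expect_equal(out$reason, c("NO_HER2", "NONE", "NONE", "NO_CEP17", "NO_HER2"))
  expect_equal(out$included, out$reason == "NONE")
  # idempotent and respects prior area exclusions
  expect_identical(score_cells(out), out)
  nuc$reason[2] <- "AREA_SMALL"; nuc$included[2] <- FALSE
  expect_equal(score_cells(nuc)$reason[2], "AREA_SMALL")
})

test_that("case quantification reproduces hand arithmetic", {
  q <- quantify_case(make_nuclei(c(4, 6, 2), c(2, 2, 2)))
  expect_equal(q$mean_her2, 4)
  expect_equal(q$mean_cep17, 2)
  expect_equal(q$ratio, 2)
  # ratio of totals equals ratio of means
  expect_equal(q$ratio, q$mean_her2 / q$mean_cep17)
  # constant cells: ratio 1, zero spread
  q2 <- suppressWarnings(quantify_case(make_nuclei(rep(2, 25), rep(2, 25))))
  expect_equal(q2$ratio, 1)
  expect_equal(q2$sd_her2, 0)
  expect_equal(q2$me_her2, 0)
  # single cell: ratio defined, margins missing, warning recorded
  expect_warning(q3 <- quantify_case(make_nuclei(5, 2)), NA) # warnings via field
  expect_equal(q3$ratio, 2.5)
  expect_true(is.na(q3$me_her2))
  expect_true(any(grepl("single cell", q3$warnings)))
  expect_true(any(grepl("fewer than 20", q3$warnings)))
  # no scorable cells is an explicit error
  empty <- score_cells(make_nuclei(0, 2))
  expect_error(quantify_case(empty), "no scorable cells",
               class = "ishquant_analysis_error")
})

test_that("the margin of error follows 1.96 * SD / sqrt(n)", {
  v <- rnorm(100)
  v <- (v - mean(v)) / sd(v) # sample SD exactly 1, n = 100
  expect_equal(margin_of_error(v), 0.196, tolerance = 1e-12)
  # SD 2, n 16 -> 0.98
  w <- rnorm(16)
  w <- (w - mean(w)) / sd(w) * 2
  expect_equal(margin_of_error(w), 0.98, tolerance = 1e-12)
  expect_equal(margin_of_error(rep(3.2, 40)), 0)
  expect_warning(me1 <- margin_of_error(5), "fewer than 2")
  expect_true(is.na(me1))
})

test_that("quantification is permutation-invariant and scales like sqrt(n)", {
  set.seed(42)
  her2 <- rpois(50, 4) + 1L
  cep17 <- rpois(50, 2) + 1L
  nuc <- make_nuclei(her2, cep17)
  q <- quantify_case(nuc)
  qp <- quantify_case(nuc[sample(50), ])
  expect_equal(tidy(q), tidy(qp))
  # duplicating every cell: identical means and ratio, ME shrinks by sqrt(2)
  qd <- quantify_case(dplyr::bind_rows(nuc, nuc))
  expect_equal(qd$mean_her2, q$mean_her2)
  expect_equal(qd$ratio, q$ratio)
  # doubling the cells: SS doubles, (n-1) goes 49 -> 99, sqrt(n) gains sqrt(2),
  # so ME shrinks by sqrt(49/99) (= 1/sqrt(2) up to the n-1 correction)
  expect_equal(qd$me_her2 / q$me_her2, sqrt(49 / 99), tolerance = 1e-12)
  # adding a cell above the mean strictly increases the mean
  plus <- dplyr::bind_rows(nuc, make_nuclei(ceiling(q$mean_her2) + 3L, 2L))
  expect_gt(quantify_case(plus)$mean_her2, q$mean_her2)
})

test_that("the ISH-group classifier reproduces the guideline table", {
  # group 1: ratio >= 2 and mean HER2 >= 4 ... group 5: both low
  expect_equal(classify_ish_group(2.5, 5.0), 1L)
  expect_equal(classify_ish_group(2.42, 3.92), 2L)
  expect_equal(classify_ish_group(1.80, 6.10), 3L)
  expect_equal(classify_ish_group(1.63, 4.06), 4L)
  expect_equal(classify_ish_group(1.85, 3.06), 5L)
  # boundaries classify upward
  expect_equal(classify_ish_group(2.0, 4.0), 1L)
  expect_equal(classify_ish_group(2.0, 3.999), 2L)
  expect_equal(classify_ish_group(1.999, 6.0), 3L)
  expect_equal(classify_ish_group(1.999, 4.0), 4L)
  expect_error(classify_ish_group(0, 4), class = "ishquant_analysis_error")
  expect_error(classify_ish_group(Inf, 4), class = "ishquant_analysis_error")
})

test_that("the five groups partition the (ratio, copy-number) plane", {
  grid <- expand.grid(ratio = seq(0.2, 6, by = 0.2),
                      her2 = seq(0.2, 12, by = 0.2))
  g <- classify_ish_group(grid$ratio, grid$her2)
  expect_true(all(g %in% 1:5))
  # each rule region maps to exactly one group
  manual <- ifelse(grid$ratio >= 2,
                   ifelse(grid$her2 >= 4, 1L, 2L),
                   ifelse(grid$her2 >= 6, 3L, ifelse(grid$her2 >= 4, 4L, 5L)))
  expect_identical(g, manual)
})

test_that("HER2 status follows the IHC 2+ group mapping", {
  expect_equal(her2_status(1:5),
               c("positive", "negative", "positive", "negative", "negative"))
  expect_error(her2_status(1, "gastric2016"), class = "ishquant_analysis_error")
  expect_error(her2_status(6), class = "ishquant_analysis_error")
})

test_that("run_case classifies synthetic cases end to end", {
  res <- diploid_result()
  expect_lt(abs(res$quant$ratio - 1), 0.1)
  expect_equal(res$quant$ish_group, 5L)
  expect_equal(res$quant$her2_status, "negative")
  amp <- amplified_result()
  expect_equal(amp$quant$ish_group, 1L)
  expect_equal(amp$quant$her2_status, "positive")
  expect_equal(amp$stage_log[["detected"]], 60)
  # all nuclei below the gate: explicit no-scorable-cells failure
  tiny <- generate_case(scene_params(n_nuclei = 6, tile_shape = c(420, 420),
                                     cancer_fraction = 0,
                                     noncancer_area_median = 12,
                                     noncancer_area_sdlog = 0.15, seed = 4))
  expect_error(run_case(tiny$tile), "no scorable cells",
               class = "ishquant_analysis_error")
})

test_that("tidy and glance expose the quantification as tibbles", {
  res <- diploid_result()
  td <- tidy(res$quant)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$n_cells, res$quant$n_cells)
  expect_equal(td$ish_group, 5L)
  gl <- glance(res$quant)
  expect_equal(gl$her2_status, "negative")
})
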