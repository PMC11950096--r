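test_that("isolated dots are each detected as one call at their centroid", {
  H <- 200; W <- 200
  r_dot <- 0.3 / 0.121
  centers <- expand.grid(x = seq(40, 160, by = 30), y = seq(40, 160, by = 60))
  dark <- matrix(0, H, W)
  for (i in seq_len(10)) {
    dark <- dark | disk_mask(H, W, centers$x[i], centers$y[i], r_dot)
  }
  calls <- detect_signals(make_maps(matrix(0, H, W), her2 = dark * 1), "HER2")
  expect_equal(nrow(calls), 10)
  expect_equal(sum(calls$estimated_signals), 10)
  # centroids within one pixel of the rendered centers
  m <- match_nuclei_to_truth(calls, data.frame(x = centers$x, y = centers$y), 0.121,
                             max_um = 0.121)
  expect_true(all(!is.na(m)))
  # blank map
  expect_equal(nrow(detect_signals(make_maps(matrix(0, 64, 64)), "CEP17")), 0)
  # sub-resolution specks are discarded
  speck <- matrix(0, 64, 64); speck[30, 30] <- 1 # one pixel = 0.015 um^2
  expect_equal(nrow(detect_signals(make_maps(matrix(0, 64, 64), her2 = speck),
                                   "HER2")), 0)
})

test_that("doublet merging collapses close pairs via connected components", {
  # two dots 0.5 um apart with max separation 0.7 -> one signal
  calls <- make_calls(c(1, 1.5), c(1, 1))
  merged <- merge_doublets(calls, 0.7, 0.121)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$estimated_signals, 1L)
  expect_true(merged$is_doublet_merge)
  expect_equal(merged$area_um2, 0.56) # summed member areas
  # two dots 3 um apart stay separate
  expect_equal(nrow(merge_doublets(make_calls(c(1, 4), c(1, 1)), 0.7, 0.121)), 2)
  # three dots pairwise within 0.7 um form one component -> one signal
  tri <- make_calls(c(1, 1.5, 1.25), c(1, 1, 1.4))
  expect_equal(nrow(merge_doublets(tri, 0.7, 0.121)), 1)
  expect_error(merge_doublets(calls, -1, 0.121), class = "ishquant_config_error")
  expect_error(merge_doublets(dplyr::bind_rows(
    make_calls(1, 1), make_calls(2, 2, channel = "CEP17")), 0.7, 0.121),
    class = "ishquant_analysis_error")
})

test_that("doublet merging is invariant to input order", {
  calls <- make_calls(c(1, 1.5, 5, 9, 9.4), c(1, 1, 5, 2, 2))
  a <- merge_doublets(calls, 0.7, 0.121)
  b <- merge_doublets(calls[sample(nrow(calls)), ], 0.7, 0.121)
  expect_equal(a, b)
})

test_that("cluster areas convert to signal counts by the rounding rule", {
  ref <- 0.28
  areas <- ref * c(1.2, 2.6, 5.0)
  calls <- make_calls(c(1, 5, 9), c(1, 1, 1), area_um2 = areas)
  out <- estimate_cluster_signals(calls, ref)
  expect_equal(out$estimated_signals, c(1L, 3L, 5L)) # round(2.6) = 3
  # doublet merges are exempt even when large
  calls$is_doublet_merge[3] <- TRUE
  out2 <- estimate_cluster_signals(calls, ref)
  expect_equal(out2$estimated_signals[3], 1L)
  expect_error(estimate_cluster_signals(calls, 0), class = "ishquant_config_error")
})

test_that("the reference area is the slide median with a starved fallback", {
  calls <- make_calls(seq(1, 30, by = 2), rep(1, 15),
                      area_um2 = c(rep(0.25, 7), rep(0.31, 8)))
  expect_equal(reference_signal_area(calls), 0.31)
  few <- make_calls(c(1, 2), c(1, 1), area_um2 = 0.25)
  expect_equal(reference_signal_area(few), 0.28) # config fallback
})

test_that("signal totals are conserved through the merge/estimate stages", {
  cs <- amplified_case()
  maps <- separate_stains(cs$tile)
  raw <- detect_signals(maps, "HER2")
  merged <- merge_doublets(raw, 0.8, 0.121)
  est <- estimate_cluster_signals(merged, reference_signal_area(merged))
  expect_lte(sum(merged$estimated_signals), sum(raw$estimated_signals))
  expect_gte(sum(est$estimated_signals), sum(merged$estimated_signals))
})

test_that("calls are assigned by centroid containment and strays are counted", {
  H <- 200; W <- 200
  m3 <- disk_mask(H, W, 60, 60, 30)
  labels <- matrix(0L, H, W); labels[m3] <- 3L
  seg <- structure(list(
    nuclei = make_nuclei(c(0, 0, 0), c(0, 0, 0)),
    labels = labels, pixel_size_um = 0.121), class = "ish_segmentation")
  calls <- dplyr::bind_rows(
    make_calls(60 * 0.121, 60 * 0.121),                  # inside nucleus 3
    make_calls(150 * 0.121, 150 * 0.121),                # stroma: dropped
    make_calls(62 * 0.121, 58 * 0.121, channel = "CEP17"))
  out <- assign_to_nuclei(calls, seg)
  expect_equal(out$nuclei$her2, c(0L, 0L, 1L))
  expect_equal(out$nuclei$cep17, c(0L, 0L, 1L))
  expect_equal(unname(out$dropped["HER2"]), 1L)
})

test_that("per-nucleus counts match ground truth on cluster-free scenes", {
  cs <- diploid_case()
  res <- diploid_result()
  m <- match_nuclei_to_truth(res$nuclei, cs$truth, 0.121)
  ok <- !is.na(m)
  exact <- res$nuclei$her2[ok] == cs$truth$true_her2[m[ok]] &
    res$nuclei$cep17[ok] == cs$truth$true_cep17[m[ok]]
  expect_gte(mean(exact), 0.95)
})

test_that("cluster scenes recover the slide-level mean HER2 within 10%", {
  cs <- amplified_case()
  res <- amplified_result()
  truth_mean <- attr(cs$truth, "true_mean_her2")
  expect_lt(abs(res$quant$mean_her2 - truth_mean) / truth_mean, 0.10)
})
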