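# shared fixtures, generated once per test run and cached

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

# 40 diploid (2/2) cancer nuclei, no clusters
diploid_case <- function() {
  cached("diploid", generate_case(
    scene_params(n_nuclei = 40, tile_shape = c(900, 900), seed = 7)))
}

# amplified scene with clusters: HER2 ~ truncated Poisson(8), CEP17 ~ tP(2)
amplified_case <- function() {
  cached("amplified", generate_case(
    scene_params(n_nuclei = 60, tile_shape = c(1200, 1200), seed = 11,
                 her2_law = copy_number_law("truncated_poisson", mean = 8),
                 cep17_law = copy_number_law("truncated_poisson", mean = 2),
                 cluster_rate = 0.3)))
}

# mixed cancer (median 80 um^2) / stroma (median 20 um^2) populations
mixed_case <- function() {
  cached("mixed", generate_case(
    scene_params(n_nuclei = 120, cancer_fraction = 0.5,
                 tile_shape = c(1600, 1600), seed = 5)))
}

diploid_result <- function() cached("diploid_res", run_case(diploid_case()$tile))
amplified_result <- function() cached("amplified_res", run_case(amplified_case()$tile))

# hand-built stain maps around a hematoxylin matrix
make_maps <- function(h, her2 = h * 0, red = h * 0, pixel_size_um = 0.121) {
  structure(list(hematoxylin = h, her2_dark = her2, cep17_red = red,
                 background_mask = h == 0 & her2 == 0 & red == 0,
                 white_point = 250, pixel_size_um = pixel_size_um),
            class = "stain_maps")
}

disk_mask <- function(H, W, cx, cy, r) {
  xs <- matrix(rep(0:(W - 1), each = H), H)
  ys <- matrix(rep(0:(H - 1), W), H)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

# bare nucleus table for scoring-level tests
make_nuclei <- function(her2, cep17, area_um2 = 90) {
  n <- length(her2)
  tibble::tibble(label = seq_len(n), area_um2 = rep_len(area_um2, n),
                 x = as.numeric(seq_len(n)), y = 0,
                 her2 = as.integer(her2), cep17 = as.integer(cep17),
                 included = TRUE, reason = "NONE")
}

# bare signal-call table at given um positions
make_calls <- function(x_um, y_um, channel = "HER2", area_um2 = 0.28,
                       pixel_size_um = 0.121) {
  tibble::tibble(channel = channel, x = x_um / pixel_size_um,
                 y = y_um / pixel_size_um,
                 area_um2 = rep_len(area_um2, length(x_um)),
                 estimated_signals = 1L, is_doublet_merge = FALSE,
                 nucleus_label = NA_integer_)
}

# greedy nearest-centroid matching of detected nuclei to truth rows,
# independent of the package's matcher (used as a recount oracle)
match_nuclei_to_truth <- function(nuclei, truth, pixel_size_um, max_um = 2) {
  m <- rep(NA_integer_, nrow(nuclei))
  used <- rep(FALSE, nrow(truth))
  d <- sqrt(outer(nuclei$x, truth$x, "-")^2 +
              outer(nuclei$y, truth$y, "-")^2) * pixel_size_um
  repeat {
    k <- which.min(d)
    if (!length(k) || d[k] > max_um) break
    i <- (k - 1) %% nrow(d) + 1
    j <- (k - 1) %/% nrow(d) + 1
    if (is.na(m[i]) && !used[j]) {
      m[i] <- j
      used[j] <- TRUE
    }
    d[i, ] <- Inf
    d[, j] <- Inf
  }
  m
}
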