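#' Detect chromogenic signal blobs in one channel
#'
#' Blob detection over a channel detection map: the soft score map is
#' thresholded and connected components become signal calls. Components
#' smaller than the sub-resolution speck limit are discarded as noise.
#' Every call starts with `estimated_signals = 1`; doublet merging and
#' cluster estimation refine the counts afterwards.
#'
#' @param maps `stain_maps` from [separate_stains()].
#' @param channel `"HER2"` (dark map) or `"CEP17"` (red map).
#' @param pixel_size_um Micrometres per pixel (defaults to the value in
#'   `maps`).
#' @param config Configuration list; uses `signals$blob_threshold` and
#'   `signals$min_speck_um2`.
#' @return A tibble of signal calls: `channel`, `x`, `y` (0-based pixel
#'   centroid), `area_um2`, `estimated_signals`, `is_doublet_merge`,
#'   `nucleus_label`.
#' @export
detect_signals <- function(maps, channel = c("HER2", "CEP17"),
                           pixel_size_um = NULL, config = ish_config()) {
  stopifnot(inherits(maps, "stain_maps"))
  channel <- match.arg(channel)
  cfg <- validate_config(merge_config(config))$signals
  psz <- pixel_size_um %||% maps$pixel_size_um
  m <- if (channel == "HER2") maps$her2_dark else maps$cep17_red
  bin <- m >= cfg$blob_threshold
  if (!any(bin)) return(empty_calls(channel))
  labels <- EBImage::bwlabel(bin + 0)
  st <- label_stats(matrix(as.integer(labels), nrow(m), ncol(m)))
  st$area_um2 <- st$area_px * psz^2
  st <- st[st$area_um2 >= cfg$min_speck_um2, , drop = FALSE]
  if (!nrow(st)) return(empty_calls(channel))
  st <- st[order(st$y, st$x), ]
  tibble::tibble(
    channel = channel,
    x = st$x, y = st$y,
    area_um2 = st$area_um2,
    estimated_signals = 1L,
    is_doublet_merge = FALSE,
    nucleus_label = NA_integer_
  )
}

empty_calls <- function(channel = character()) {
  tibble::tibble(channel = as.character(channel)[0], x = numeric(),
                 y = numeric(), area_um2 = numeric(),
                 estimated_signals = integer(), is_doublet_merge = logical(),
                 nucleus_label = integer())
}

#' Merge split-signal doublets
#'
#' A replicated locus appears as two adjacent dots (a doublet) but
#' represents one signal, so close pairs of single-signal calls are merged
#' into a single call. Merging uses the graph of pairs whose centroid
#' distance is at most `max_sep_um`: each connected component collapses to
#' one call with `estimated_signals = 1` and `is_doublet_merge = TRUE`,
#' centred at the component mean with the summed area. The result is
#' independent of input order.
#'
#' @param calls Signal-call tibble for a single channel.
#' @param max_sep_um Maximum centroid separation in micrometres
#'   (default 0.8, about one dot diameter plus margin).
#' @param pixel_size_um Micrometres per pixel used to convert centroid
#'   distances.
#' @return The merged call tibble.
#' @export
merge_doublets <- function(calls, max_sep_um = 0.8, pixel_size_um) {
  if (max_sep_um < 0) {
    rlang::abort("max_sep_um must be non-negative", class = "ishquant_config_error")
  }
  if (length(unique(calls$channel)) > 1) {
    rlang::abort("merge_doublets expects calls from a single channel",
                 class = "ishquant_analysis_error")
  }
  if (nrow(calls) < 2) return(calls)
  calls <- calls[order(calls$y, calls$x), ]
  single <- which(calls$estimated_signals == 1L & !calls$is_doublet_merge)
  if (length(single) >= 2) {
    xs <- calls$x[single] * pixel_size_um
    ys <- calls$y[single] * pixel_size_um
    d <- as.matrix(stats::dist(cbind(xs, ys)))
    close <- which(d <= max_sep_um & upper.tri(d), arr.ind = TRUE)
  } else {
    close <- matrix(integer(), ncol = 2)
  }
  if (!nrow(close)) return(calls)
  comp <- union_find_components(length(single), close)
  merged_rows <- list()
  drop <- integer()
  for (cid in unique(comp)) {
    members <- single[comp == cid]
    if (length(members) < 2) next
    row <- calls[members[1], ]
    row$x <- mean(calls$x[members])
    row$y <- mean(calls$y[members])
    row$area_um2 <- sum(calls$area_um2[members])
    row$estimated_signals <- 1L
    row$is_doublet_merge <- TRUE
    merged_rows[[length(merged_rows) + 1L]] <- row
    drop <- c(drop, members)
  }
  out <- dplyr::bind_rows(calls[-drop, ], dplyr::bind_rows(merged_rows))
  out[order(out$y, out$x), ]
}

#' Slide-level reference area of a single signal
#'
#' Median area of isolated single-dot calls, used to convert cluster blob
#' areas into signal counts. Calls already merged as doublets or larger
#' than twice the nominal single-dot area are not "isolated". When fewer
#' than `signals$min_isolated_for_reference` isolated calls exist the
#' configured fallback `signals$reference_area_um2` is returned.
#'
#' @param calls Signal-call tibble (typically HER2 after doublet merging).
#' @param config Configuration list.
#' @return Reference area in um^2.
#' @export
reference_signal_area <- function(calls, config = ish_config()) {
  cfg <- validate_config(merge_config(config))$signals
  iso <- calls$area_um2[!calls$is_doublet_merge &
                          calls$estimated_signals == 1L &
                          calls$area_um2 <= 2 * cfg$reference_area_um2]
  if (length(iso) < cfg$min_isolated_for_reference) {
    return(cfg$reference_area_um2)
  }
  stats::median(iso)
}

#' Estimate signal counts inside clusters
#'
#' In highly amplified cells the HER2 signals fuse into clusters whose
#' copy number cannot be enumerated; it is estimated from area instead.
#' Any call (except doublet merges) with area greater than
#' `cluster_factor` times the single-signal reference area gets
#' `estimated_signals = round(area / reference_area)`, with a minimum of 2.
#'
#' @param calls Signal-call tibble.
#' @param reference_area_um2 Area of a single signal (see
#'   [reference_signal_area()]).
#' @param cluster_factor Area multiple above which a blob is treated as a
#'   cluster (default 2.5).
#' @return The call tibble with updated `estimated_signals`.
#' @export
estimate_cluster_signals <- function(calls, reference_area_um2,
                                     cluster_factor = 2.5) {
  if (!is.numeric(reference_area_um2) || length(reference_area_um2) != 1 ||
      !is.finite(reference_area_um2) || reference_area_um2 <= 0) {
    rlang::abort("reference_area_um2 must be a single positive number",
                 class = "ishquant_config_error")
  }
  if (!nrow(calls)) return(calls)
  is_cluster <- !calls$is_doublet_merge &
    calls$area_um2 > cluster_factor * reference_area_um2
  est <- pmax(2L, as.integer(round(calls$area_um2 / reference_area_um2)))
  calls$estimated_signals[is_cluster] <- est[is_cluster]
  calls
}

#' Assign signal calls to nuclei
#'
#' A call belongs to the nucleus whose mask contains its centroid
#' (signals must lie within the nucleus). Calls falling outside every
#' nucleus are dropped; their count is reported in the `dropped` attribute
#' and in the case summary. Per-nucleus `her2`/`cep17` counts are the sums
#' of `estimated_signals` of the assigned calls.
#'
#' @param calls Signal-call tibble (any mix of channels).
#' @param segmentation An `ish_segmentation` from [segment_nuclei()].
#' @return The segmentation with counts filled in; the updated calls are in
#'   the `calls` element and the per-channel drop counts in `dropped`.
#' @export
assign_to_nuclei <- function(calls, segmentation) {
  stopifnot(inherits(segmentation, "ish_segmentation"))
  labels <- segmentation$labels
  nuclei <- segmentation$nuclei
  if (nrow(calls)) {
    ri <- pmin(pmax(round(calls$y) + 1L, 1L), nrow(labels))
    ci <- pmin(pmax(round(calls$x) + 1L, 1L), ncol(labels))
    lab <- labels[cbind(ri, ci)]
    calls$nucleus_label <- ifelse(lab > 0L, lab, NA_integer_)
  }
  count_for <- function(chan) {
    sub <- calls[calls$channel == chan & !is.na(calls$nucleus_label), ]
    v <- integer(nrow(nuclei))
    if (nrow(sub)) {
      agg <- rowsum(sub$estimated_signals, sub$nucleus_label)
      v[as.integer(rownames(agg))] <- as.integer(agg[, 1])
    }
    v
  }
  nuclei$her2 <- count_for("HER2")
  nuclei$cep17 <- count_for("CEP17")
  dropped <- c(HER2 = sum(calls$channel == "HER2" & is.na(calls$nucleus_label)),
               CEP17 = sum(calls$channel == "CEP17" & is.na(calls$nucleus_label)))
  segmentation$nuclei <- nuclei
  segmentation$calls <- calls
  segmentation$dropped <- dropped
  segmentation
}

#' Full signal-detection stage for one channel
#'
#' Convenience composition: [detect_signals()], [merge_doublets()],
#' then [estimate_cluster_signals()] against the slide-level reference
#' area (HER2 only; CEP17 clusters are not expected and not estimated).
#'
#' @inheritParams detect_signals
#' @return The refined call tibble.
#' @export
detect_channel_signals <- function(maps, channel = c("HER2", "CEP17"),
                                   pixel_size_um = NULL, config = ish_config()) {
  channel <- match.arg(channel)
  cfg <- validate_config(merge_config(config))
  psz <- pixel_size_um %||% maps$pixel_size_um
  calls <- detect_signals(maps, channel, psz, cfg)
  calls <- merge_doublets(calls, cfg$signals$doublet_sep_um, psz)
  if (channel == "HER2") {
    ref <- reference_signal_area(calls, cfg)
    calls <- estimate_cluster_signals(calls, ref, cfg$signals$cluster_factor)
  }
  calls
}
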