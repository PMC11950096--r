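#' Segment nuclei from the hematoxylin map
#'
#' Classical segmentation of the counterstain channel: Gaussian smoothing,
#' thresholding (adaptive Gaussian-weighted local mean by default, global
#' optionally), hole filling (chromogenic dots occlude the counterstain and
#' would otherwise punch holes), morphological opening, and a
#' distance-transform watershed to split touching nuclei.
#'
#' Labels are dense `1..N`, ordered by `(y, x)` of the centroid. Nuclei
#' whose centroid falls outside the ROI are flagged `OUTSIDE_ROI`; nuclei
#' touching the tile border are flagged `BORDER` by default because their
#' area is censored (configurable via `nuclei$border_exclude`).
#'
#' @param maps A `stain_maps` object from [separate_stains()].
#' @param roi An [ish_roi()] or `NULL` for the whole tile.
#' @param pixel_size_um Micrometres per pixel (defaults to the value stored
#'   in `maps`).
#' @param config Configuration list; the `nuclei` block holds the
#'   smoothing, threshold and watershed parameters.
#' @return A list of class `ish_segmentation`: `nuclei`, a tibble with one
#'   row per nucleus (`label`, `area_um2`, `x`, `y`, `her2`, `cep17`,
#'   `included`, `reason`), and `labels`, the integer label matrix.
#' @export
segment_nuclei <- function(maps, roi = NULL, pixel_size_um = NULL,
                           config = ish_config()) {
  stopifnot(inherits(maps, "stain_maps"))
  cfg <- validate_config(merge_config(config))
  psz <- pixel_size_um %||% maps$pixel_size_um
  ncfg <- cfg$nuclei
  if (!is.null(roi)) {
    stopifnot(inherits(roi, "ish_roi"))
    if (!length(roi$polygons)) {
      rlang::abort("empty ROI", class = "ishquant_analysis_error")
    }
  }

  h <- maps$hematoxylin
  sm <- as.matrix(EBImage::gblur(h, sigma = min(max(ncfg$smooth_sigma_um / psz, 0.5),
                                                (min(dim(h)) - 3) / 7)))
  if (identical(ncfg$threshold_method, "adaptive")) {
    # Gaussian-weighted local mean; cap the kernel so it fits small tiles
    sigma <- min(ncfg$adaptive_window_um / psz, (min(dim(sm)) - 3) / 7)
    local_mean <- as.matrix(EBImage::gblur(sm, sigma = sigma))
    thr <- pmax(local_mean + ncfg$adaptive_offset, ncfg$floor_threshold)
    bin <- sm > thr
  } else {
    bin <- sm > ncfg$global_threshold
  }
  bin <- EBImage::fillHull(bin)
  bin <- EBImage::opening(bin, EBImage::makeBrush(5, "disc")) > 0
  bin <- EBImage::fillHull(bin)

  if (!any(bin)) {
    return(empty_segmentation(dim(h)))
  }

  dm <- EBImage::distmap(bin)
  labels0 <- EBImage::watershed(dm, tolerance = ncfg$watershed_tolerance_um / psz,
                                ext = max(1, round(ncfg$min_seed_sep_um / psz / 2)))
  labels0 <- matrix(as.integer(labels0), nrow(h), ncol(h))

  st <- label_stats(labels0)
  if (!nrow(st)) return(empty_segmentation(dim(h)))

  # dense relabel ordered by centroid (y, x)
  ord <- order(st$y, st$x)
  st <- st[ord, ]
  remap <- integer(max(labels0))
  remap[st$label] <- seq_len(nrow(st))
  labels <- labels0
  labels[labels0 > 0L] <- remap[labels0[labels0 > 0L]]
  st$label <- seq_len(nrow(st))

  H <- nrow(labels); W <- ncol(labels)
  border_labels <- unique(c(labels[1, ], labels[H, ], labels[, 1], labels[, W]))
  border_labels <- border_labels[border_labels > 0L]

  nuclei <- tibble::tibble(
    label = st$label,
    area_um2 = st$area_px * psz^2,
    x = st$x,
    y = st$y,
    her2 = NA_integer_,
    cep17 = NA_integer_,
    included = TRUE,
    reason = "NONE"
  )
  if (isTRUE(ncfg$border_exclude) && length(border_labels)) {
    hit <- nuclei$label %in% border_labels
    nuclei$reason[hit] <- "BORDER"
  }
  if (!is.null(roi)) {
    out <- !points_in_roi(nuclei$x, nuclei$y, roi)
    nuclei$reason[out & nuclei$reason == "NONE"] <- "OUTSIDE_ROI"
  }
  nuclei$included <- nuclei$reason == "NONE"

  structure(list(nuclei = nuclei, labels = labels, pixel_size_um = psz),
            class = "ish_segmentation")
}

empty_segmentation <- function(dm) {
  structure(list(
    nuclei = tibble::tibble(label = integer(), area_um2 = numeric(),
                            x = numeric(), y = numeric(),
                            her2 = NA_integer_[0], cep17 = NA_integer_[0],
                            included = logical(), reason = character()),
    labels = matrix(0L, dm[1], dm[2]),
    pixel_size_um = NA_real_
  ), class = "ish_segmentation")
}

#' @export
print.ish_segmentation <- function(x, ...) {
  cat(sprintf("<ish_segmentation> %d nuclei (%d included)\n",
              nrow(x$nuclei), sum(x$nuclei$included)))
  invisible(x)
}

#' Apply the nuclear size gate
#'
#' Flags nuclei outside the closed interval `[min_um2, max_um2]`
#' (default 30-150 um^2): small nuclei are mostly stromal or inflammatory
#' cells, very large objects are clusters of poorly segmented cells.
#' Boundary areas (exactly 30 or 150) are kept. The gate is idempotent: it
#' recomputes the `AREA_SMALL`/`AREA_LARGE` flags from the stored areas and
#' leaves other exclusion reasons untouched.
#'
#' @param nuclei Nucleus tibble or an `ish_segmentation`.
#' @param min_um2,max_um2 Gate bounds in um^2.
#' @return The same type as the input, with `included`/`reason` updated.
#' @export
apply_area_gate <- function(nuclei, min_um2 = 30, max_um2 = 150) {
  if (inherits(nuclei, "ish_segmentation")) {
    nuclei$nuclei <- apply_area_gate(nuclei$nuclei, min_um2, max_um2)
    return(nuclei)
  }
  if (min_um2 >= max_um2) {
    rlang::abort("min_um2 must be smaller than max_um2", class = "ishquant_config_error")
  }
  touch <- nuclei$reason %in% c("NONE", "AREA_SMALL", "AREA_LARGE")
  reason <- nuclei$reason
  reason[touch] <- "NONE"
  reason[touch & nuclei$area_um2 < min_um2] <- "AREA_SMALL"
  reason[touch & nuclei$area_um2 > max_um2] <- "AREA_LARGE"
  nuclei$reason <- reason
  nuclei$included <- reason == "NONE"
  nuclei
}
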