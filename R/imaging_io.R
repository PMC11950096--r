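#' Construct an image tile
#'
#' The unit of analysis: an 8-bit RGB raster with a known physical pixel
#' size. Pixels are stored as an `H x W x 3` integer array in 0-255 with
#' channel order R, G, B. Coordinates used throughout the package are
#' 0-based `(x, y) = (column, row)` with pixel centers at integer positions.
#'
#' @param pixels `H x W x 3` numeric array, values in 0-255.
#' @param pixel_size_um Physical pixel size in micrometres (> 0).
#' @param origin Length-2 offset `(x, y)` of the tile in slide pixel
#'   coordinates; defaults to `c(0, 0)`.
#' @return An object of class `ish_tile`.
#' @export
ish_tile <- function(pixels, pixel_size_um, origin = c(0, 0)) {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    rlang::abort("pixels must be an H x W x 3 array (expected 3 channels)",
                 class = "ishquant_io_error")
  }
  if (any(dim(pixels)[1:2] < 1)) {
    rlang::abort("pixels raster is empty", class = "ishquant_io_error")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    rlang::abort("pixel_size_um must be a single positive number",
                 class = "ishquant_io_error")
  }
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um, origin = as.numeric(origin)),
    class = "ish_tile"
  )
}

#' @export
print.ish_tile <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<ish_tile> %d x %d px (%.1f x %.1f um) @ %.4g um/px\n",
              d[2], d[1], d[2] * x$pixel_size_um, d[1] * x$pixel_size_um,
              x$pixel_size_um))
  invisible(x)
}

#' @export
dim.ish_tile <- function(x) dim(x$pixels)

# ish_tile <-> EBImage Image (EBImage stores x as the first dimension)
tile_to_image <- function(tile) {
  px <- tile$pixels / 255
  EBImage::Image(aperm(px, c(2, 1, 3)), colormode = "Color")
}

image_to_pixels <- function(img) {
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 2) dat <- array(rep(dat, 3), dim = c(dim(dat), 3))
  round(aperm(dat, c(2, 1, 3)) * 255)
}

#' Read an RGB tile from TIFF or PNG
#'
#' Loads the raster unmodified. The physical pixel size is taken from the
#' `pixel_size_um` argument; for TIFF files with embedded resolution
#' metadata the embedded value is used as a fallback (and a mismatch with
#' the argument is reported as a message, the argument winning).
#'
#' @param path TIFF or PNG file with 3 channels. A 4th (alpha) channel is
#'   dropped with a warning; grayscale input is an error.
#' @param pixel_size_um Micrometres per pixel. May be omitted only for TIFF
#'   files carrying resolution metadata.
#' @return An [ish_tile()].
#' @export
read_tile <- function(path, pixel_size_um = NULL) {
  if (!file.exists(path)) {
    rlang::abort(paste0("image file not found: ", path), class = "ishquant_io_error")
  }
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) rlang::abort(
                    paste0("unreadable image file: ", path, " (", conditionMessage(e), ")"),
                    class = "ishquant_io_error"))
  dat <- EBImage::imageData(img)
  nd <- length(dim(dat))
  nch <- if (nd == 2) 1L else dim(dat)[3]
  if (nch == 1) {
    rlang::abort(paste0("expected 3 channels, got grayscale: ", path),
                 class = "ishquant_io_error")
  }
  if (nch == 4) {
    rlang::warn(paste0("dropping alpha channel: ", path))
    dat <- dat[, , 1:3]
  } else if (nch != 3) {
    rlang::abort(paste0("expected 3 channels, got ", nch, ": ", path),
                 class = "ishquant_io_error")
  }
  embedded <- tiff_pixel_size_um(path)
  if (is.null(pixel_size_um)) {
    if (is.null(embedded)) {
      rlang::abort("pixel size missing: pass pixel_size_um or use a TIFF with resolution metadata",
                   class = "ishquant_io_error")
    }
    pixel_size_um <- embedded
  } else if (!is.null(embedded) &&
             abs(embedded - pixel_size_um) > 1e-6 * pixel_size_um) {
    message(sprintf("pixel size argument (%.6g) overrides TIFF metadata (%.6g)",
                    pixel_size_um, embedded))
  }
  ish_tile(round(aperm(dat, c(2, 1, 3)) * 255), pixel_size_um)
}

# best-effort extraction of um/px from TIFF resolution tags
tiff_pixel_size_um <- function(path) {
  if (!grepl("\\.tiff?$", path, ignore.case = TRUE)) return(NULL)
  info <- tryCatch(
    attributes(tiff::readTIFF(path, info = TRUE, payload = FALSE)),
    error = function(e) NULL)
  if (is.null(info) || is.null(info$x.resolution) || info$x.resolution <= 0) return(NULL)
  unit <- info$resolution.unit %||% "inch"
  per_um <- switch(as.character(unit),
                   inch = info$x.resolution / 25400,
                   cm = info$x.resolution / 1e4,
                   return(NULL))
  if (per_um <= 0) return(NULL)
  1 / per_um
}

#' Write a tile to TIFF or PNG
#'
#' @param tile An [ish_tile()].
#' @param path Output path; format from extension (`.tif(f)` or `.png`).
#' @return The path, invisibly.
#' @export
write_tile <- function(tile, path) {
  stopifnot(inherits(tile, "ish_tile"))
  ok <- tryCatch({
    EBImage::writeImage(tile_to_image(tile), path,
                        type = if (grepl("\\.png$", path, ignore.case = TRUE)) "png" else "tiff",
                        bits.per.sample = 8L, compression = "none")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    rlang::abort(paste0("failed to write image: ", path, " (", conditionMessage(ok), ")"),
                 class = "ishquant_io_error")
  }
  invisible(path)
}

## ---- regions of interest ----------------------------------------------

#' Construct a region of interest from polygon rings
#'
#' @param polygons A list of polygons; each polygon is a list of rings and
#'   each ring an `n x 2` matrix of `(x, y)` slide pixel coordinates. The
#'   first ring of a polygon is the exterior, subsequent rings are holes.
#' @param label Free-text label.
#' @return An object of class `ish_roi`.
#' @export
ish_roi <- function(polygons, label = "") {
  for (pi in seq_along(polygons)) {
    for (ri in seq_along(polygons[[pi]])) {
      ring <- as.matrix(polygons[[pi]][[ri]])
      if (nrow(ring) >= 2 && all(ring[1, ] == ring[nrow(ring), ])) {
        ring <- ring[-nrow(ring), , drop = FALSE]
      }
      if (nrow(ring) < 3) {
        rlang::abort(sprintf("invalid geometry in polygon %d ring %d: fewer than 3 vertices", pi, ri),
                     class = "ishquant_io_error")
      }
      if (ring_self_intersects(ring)) {
        rlang::abort(sprintf("invalid geometry in polygon %d ring %d: self-intersection", pi, ri),
                     class = "ishquant_io_error")
      }
      polygons[[pi]][[ri]] <- ring
    }
  }
  structure(list(polygons = polygons, label = label), class = "ish_roi")
}

# proper segment crossing test between non-adjacent edges of one ring
ring_self_intersects <- function(ring) {
  n <- nrow(ring)
  seg <- cbind(ring, ring[c(2:n, 1), , drop = FALSE]) # x1 y1 x2 y2
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next # adjacent through the closure
      d1 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d2 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      d3 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d4 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Read a region of interest from GeoJSON
#'
#' Accepts `Polygon`/`MultiPolygon` geometries (bare, as a `Feature`, or in
#' a `FeatureCollection`) with coordinates in slide pixel units. Rings are
#' validated (at least 3 vertices, no self-intersection) with errors naming
#' the offending ring.
#'
#' @param path GeoJSON file.
#' @return An [ish_roi()].
#' @export
read_roi <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("ROI file not found: ", path), class = "ishquant_io_error")
  }
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  geoms <- collect_geometries(gj)
  if (!length(geoms)) {
    rlang::abort(paste0("no Polygon/MultiPolygon geometry in: ", path),
                 class = "ishquant_io_error")
  }
  polys <- list()
  for (g in geoms) {
    co <- g$coordinates
    if (identical(g$type, "Polygon")) co <- list(co)
    for (poly in co) {
      rings <- lapply(poly, function(r) {
        do.call(rbind, lapply(r, function(pt) c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
      })
      polys[[length(polys) + 1L]] <- rings
    }
  }
  ish_roi(polys, label = gj$properties$name %||% "")
}

collect_geometries <- function(node) {
  if (is.null(node$type)) return(list())
  switch(node$type,
         FeatureCollection = do.call(c, lapply(node$features, collect_geometries)),
         Feature = collect_geometries(node$geometry),
         Polygon = ,
         MultiPolygon = list(node),
         GeometryCollection = do.call(c, lapply(node$geometries, collect_geometries)),
         list())
}

#' ROI area in square micrometres
#'
#' Shoelace area of the exterior rings minus hole rings, scaled by the
#' squared pixel size.
#'
#' @param roi An [ish_roi()].
#' @param pixel_size_um Micrometres per pixel.
#' @return Area in um^2.
#' @export
roi_area_um2 <- function(roi, pixel_size_um) {
  stopifnot(inherits(roi, "ish_roi"), pixel_size_um > 0)
  shoelace <- function(ring) {
    x <- ring[, 1]; y <- ring[, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }
  a <- 0
  for (poly in roi$polygons) {
    a <- a + shoelace(poly[[1]])
    if (length(poly) > 1) a <- a - sum(vapply(poly[-1], shoelace, numeric(1)))
  }
  a * pixel_size_um^2
}

#' Test points for ROI membership
#'
#' Even-odd ray casting against exterior rings minus holes; a `NULL` ROI
#' contains everything.
#'
#' @param x,y Numeric vectors of 0-based pixel coordinates.
#' @param roi An [ish_roi()] or `NULL`.
#' @return Logical vector.
#' @export
points_in_roi <- function(x, y, roi) {
  if (is.null(roi)) return(rep(TRUE, length(x)))
  stopifnot(inherits(roi, "ish_roi"))
  inside <- rep(FALSE, length(x))
  for (poly in roi$polygons) {
    in_outer <- points_in_ring(x, y, poly[[1]])
    if (length(poly) > 1) {
      for (h in poly[-1]) in_outer <- in_outer & !points_in_ring(x, y, h)
    }
    inside <- inside | in_outer
  }
  inside
}

points_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

## ---- analysis outputs -------------------------------------------------

#' Write the analysis overlay
#'
#' Writes a PNG copy of the tile with every segmented nucleus outlined
#' (green for included cells, orange for excluded ones) plus a JSON
#' annotation sidecar (`<path>.json`) holding, per nucleus, its label,
#' centroid, inclusion flag, exclusion reason code and an `"H:x C:y"` count
#' string. Source pixels away from outlines are unmodified.
#'
#' @param tile An [ish_tile()].
#' @param nuclei Nucleus tibble (see [segment_nuclei()]), with counts.
#' @param labels Integer label matrix matching the tile.
#' @param path Output PNG path.
#' @return Named character vector with the PNG and sidecar paths, invisibly.
#' @export
write_overlay <- function(tile, nuclei, labels, path) {
  stopifnot(inherits(tile, "ish_tile"))
  px <- tile$pixels
  if (nrow(nuclei)) {
    binc <- outline_mask(labels, nuclei$label[nuclei$included])
    bexc <- outline_mask(labels, nuclei$label[!nuclei$included])
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[binc] <- c(0, 200, 0)[ch]
      plane[bexc] <- c(255, 140, 0)[ch]
      px[, , ch] <- plane
    }
  }
  write_tile(ish_tile(px, tile$pixel_size_um, tile$origin), path)
  ann <- lapply(seq_len(nrow(nuclei)), function(i) {
    list(label = nuclei$label[i],
         x = nuclei$x[i], y = nuclei$y[i],
         included = nuclei$included[i],
         reason = nuclei$reason[i],
         text = sprintf("H:%s C:%s",
                        nuclei$her2[i] %||% NA, nuclei$cep17[i] %||% NA))
  })
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(version = ishquant_version(), nuclei = ann),
                       sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(overlay = path, sidecar = sidecar))
}

# boundary pixels (mask minus its erosion) of the given labels
outline_mask <- function(labels, keep) {
  m <- matrix(FALSE, nrow(labels), ncol(labels))
  if (!length(keep)) return(m)
  sel <- matrix(labels %in% keep, nrow(labels), ncol(labels))
  er <- EBImage::erode(sel, EBImage::makeBrush(3, "box")) > 0
  sel & !er
}

#' Write the per-case output bundle
#'
#' Writes `cells.csv` (one row per detected nucleus: label, area_um2, x, y,
#' her2, cep17, included, reason), `summary.json` (every
#' quantification/classification field plus the resolved configuration and
#' package version) and, unless disabled in the config, `overlay.png` with
#' its annotation sidecar.
#'
#' @param quant A `case_quantification` (see [quantify_case()]), classified.
#' @param nuclei Nucleus tibble with counts and inclusion flags.
#' @param tile The analysed [ish_tile()].
#' @param labels Label matrix from segmentation.
#' @param out_dir Output directory (created if absent).
#' @param config Resolved configuration list to echo into the summary.
#' @return Named character vector of written paths, invisibly.
#' @export
write_case_outputs <- function(quant, nuclei, tile, labels, out_dir,
                               config = ish_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    rlang::abort(paste0("cannot create output directory: ", out_dir),
                 class = "ishquant_io_error")
  }
  cells_path <- file.path(out_dir, "cells.csv")
  cells <- nuclei[, c("label", "area_um2", "x", "y", "her2", "cep17",
                      "included", "reason")]
  utils::write.csv(cells, cells_path, row.names = FALSE)
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(
    c(unclass(quant), list(config = config, version = ishquant_version())),
    summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  paths <- c(cells = cells_path, summary = summary_path)
  if (isTRUE(config$io$overlay)) {
    ov <- write_overlay(tile, nuclei, labels, file.path(out_dir, "overlay.png"))
    paths <- c(paths, ov)
  }
  invisible(paths)
}

#' Read back a written case summary
#'
#' Restores the `case_quantification` object from a `summary.json` written
#' by [write_case_outputs()].
#'
#' @param path Path to `summary.json`.
#' @return A `case_quantification`.
#' @export
read_case_summary <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("summary file not found: ", path), class = "ishquant_io_error")
  }
  js <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  js$config <- NULL
  js$version <- NULL
  js$warnings <- as.character(unlist(js$warnings))
  fields <- c("n_cells", "mean_her2", "mean_cep17", "ratio", "sd_her2",
              "sd_cep17", "sd_ratio", "me_her2", "me_ratio")
  for (f in fields) js[[f]] <- if (is.null(js[[f]])) NA_real_ else as.numeric(js[[f]])
  js$n_cells <- as.integer(js$n_cells)
  structure(js[c(fields, "ish_group", "her2_status", "warnings")],
            class = "case_quantification")
}
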