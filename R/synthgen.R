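#' Per-cell copy-number law
#'
#' Describes the distribution of true probe copies per cell. Two families
#' are available: `constant` (every cell carries `value` copies) and
#' `truncated_poisson` (Poisson with the given `mean`, conditioned on at
#' least `min` copies; `min = 0` allows signal-free cells so that the
#' one-copy-each scoring rule can be exercised).
#'
#' @param family `"constant"` or `"truncated_poisson"`.
#' @param value Copies per cell for the constant family.
#' @param mean Poisson mean for the truncated family.
#' @param min Lower truncation bound (default 1).
#' @return A `copy_number_law` list.
#' @export
#' @examples
#' copy_number_law("constant", value = 2)
#' copy_number_law("truncated_poisson", mean = 8)
copy_number_law <- function(family = c("constant", "truncated_poisson"),
                            value = 2, mean = 2, min = 1) {
  family <- match.arg(family)
  if (family == "constant") {
    stopifnot(is.numeric(value), length(value) == 1, value >= 0, value == round(value))
  } else {
    stopifnot(is.numeric(mean), length(mean) == 1, is.finite(mean), mean > 0,
              min >= 0, min == round(min))
  }
  structure(list(family = family, value = value, mean = mean, min = min),
            class = "copy_number_law")
}

sample_copy_law <- function(law, n) {
  if (n == 0) return(integer())
  if (law$family == "constant") return(rep(as.integer(law$value), n))
  out <- integer(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- stats::rpois(length(todo), law$mean)
    ok <- draw >= law$min
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' Scene parameters for the synthetic-slide generator
#'
#' Defines a synthetic bright-field dual-ISH scene: hematoxylin-stained
#' elliptical nuclei on a white background, dark (silver-like, achromatic)
#' HER2 dots and red CEP17 dots rendered inside the nuclei. Defaults model
#' the assay conditions the pipeline assumes: 0.121 um/px, cancer nuclei
#' with lognormal area of median 80 um^2, non-cancer (stromal/inflammatory)
#' nuclei with median 20 um^2 so the 30 um^2 gate separates the
#' populations, diploid copy numbers, a modest doublet rate and no
#' clusters.
#'
#' @param n_nuclei Number of nuclei to place.
#' @param cancer_fraction Fraction of nuclei drawn from the cancer
#'   population (exact composition, rounded).
#' @param her2_law,cep17_law [copy_number_law()]s for cancer cells.
#'   Non-cancer cells are always rendered diploid (2/2).
#' @param cancer_area_median,cancer_area_sdlog Lognormal law of the cancer
#'   nucleus area in um^2: median (80) and log-scale SD (0.3).
#' @param noncancer_area_median,noncancer_area_sdlog Same for the
#'   non-cancer population (median 20, sdlog 0.3).
#' @param doublet_rate Probability that a true signal is rendered as a
#'   touching pair of dots (a replicated locus; scored as one signal).
#' @param cluster_rate Probability that a cancer cell with at least 3 HER2
#'   copies renders them as one fused blob whose area encodes the count.
#' @param pixel_size_um Micrometres per pixel.
#' @param tile_shape `c(height, width)` in pixels.
#' @param noise_level SD of additive Gaussian intensity noise (0-255 scale).
#' @param dot_diameter_um Diameter of a single rendered signal dot.
#' @param contact_tolerance_um Maximum allowed overlap between the bounding
#'   circles of neighbouring nuclei (0 keeps nuclei strictly separated).
#' @param background_intensity Background gray level (0-255).
#' @param stain_od Nominal hematoxylin optical density of a nucleus
#'   (per-nucleus jitter of +/-10% is applied).
#' @param seed RNG seed; with equal parameters and seed the generator is
#'   bit-reproducible.
#' @return A validated `scene_params` list.
#' @export
scene_params <- function(n_nuclei = 200,
                         cancer_fraction = 1,
                         her2_law = copy_number_law("constant", value = 2),
                         cep17_law = copy_number_law("constant", value = 2),
                         cancer_area_median = 80,
                         cancer_area_sdlog = 0.3,
                         noncancer_area_median = 20,
                         noncancer_area_sdlog = 0.3,
                         doublet_rate = 0.1,
                         cluster_rate = 0,
                         pixel_size_um = 0.121,
                         tile_shape = c(1024, 1024),
                         noise_level = 2,
                         dot_diameter_um = 0.6,
                         contact_tolerance_um = 0,
                         background_intensity = 250,
                         stain_od = 0.45,
                         seed = 1) {
  p <- list(n_nuclei = as.integer(n_nuclei), cancer_fraction = cancer_fraction,
            her2_law = her2_law, cep17_law = cep17_law,
            cancer_area_median = cancer_area_median,
            cancer_area_sdlog = cancer_area_sdlog,
            noncancer_area_median = noncancer_area_median,
            noncancer_area_sdlog = noncancer_area_sdlog,
            doublet_rate = doublet_rate, cluster_rate = cluster_rate,
            pixel_size_um = pixel_size_um, tile_shape = as.integer(tile_shape),
            noise_level = noise_level, dot_diameter_um = dot_diameter_um,
            contact_tolerance_um = contact_tolerance_um,
            background_intensity = background_intensity,
            stain_od = stain_od, seed = as.integer(seed))
  bad <- function(msg) rlang::abort(msg, class = "ishquant_config_error")
  for (f in c("cancer_fraction", "doublet_rate", "cluster_rate")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0 || v > 1) {
      bad(paste0(f, " must be in [0, 1]"))
    }
  }
  if (!is.finite(p$pixel_size_um) || p$pixel_size_um <= 0) bad("pixel_size_um must be > 0")
  if (p$n_nuclei < 0) bad("n_nuclei must be non-negative")
  if (length(p$tile_shape) != 2 || any(p$tile_shape < 8)) bad("tile_shape must be two pixel counts >= 8")
  if (!is.finite(p$noise_level) || p$noise_level < 0) bad("noise_level must be >= 0")
  if (!is.finite(p$dot_diameter_um) || p$dot_diameter_um <= 0) bad("dot_diameter_um must be > 0")
  for (f in c("cancer_area_median", "noncancer_area_median")) {
    if (!is.finite(p[[f]]) || p[[f]] <= 0) bad(paste0(f, " must be positive"))
  }
  for (f in c("cancer_area_sdlog", "noncancer_area_sdlog", "stain_od")) {
    if (!is.finite(p[[f]]) || p[[f]] < 0) bad(paste0(f, " must be non-negative"))
  }
  stopifnot(inherits(her2_law, "copy_number_law"), inherits(cep17_law, "copy_number_law"))
  structure(p, class = "scene_params")
}

# colours used by the renderer; the stain-separation defaults are matched
# to these (silver chromogen is achromatic, CEP17 chromogen is red)
synth_colors <- function() {
  list(her2 = c(40, 40, 40), cep17 = c(190, 45, 55))
}

#' Generate a synthetic dual-ISH case
#'
#' Renders a scene described by [scene_params()] and returns the tile
#' together with a per-nucleus ground-truth table. The truth records, per
#' nucleus: cancer status, true per-probe copy numbers, the number of
#' rendered blob objects per channel (doublets and clusters fuse several
#' copies into one blob), true area and centroid. Scene-level true means
#' and the true HER2/CEP17 ratio over cancer nuclei are attached as
#' attributes and recomputable from the table.
#'
#' Identical parameters (including the seed) give bit-identical output.
#'
#' @param params A [scene_params()].
#' @return A list of class `ish_case` with elements `tile` ([ish_tile()]),
#'   `truth` (tibble) and `params`.
#' @export
#' @examples
#' cs <- generate_case(scene_params(n_nuclei = 12, tile_shape = c(256, 256)))
#' cs$truth
generate_case <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  withr::with_seed(params$seed, generate_case_impl(params))
}

generate_case_impl <- function(p) {
  H <- p$tile_shape[1]; W <- p$tile_shape[2]
  psz <- p$pixel_size_um
  n <- p$n_nuclei
  n_cancer <- round(n * p$cancer_fraction)
  is_cancer <- sample(rep(c(TRUE, FALSE), c(n_cancer, n - n_cancer)))

  area_um2 <- ifelse(is_cancer,
                     stats::rlnorm(n, log(p$cancer_area_median), p$cancer_area_sdlog),
                     stats::rlnorm(n, log(p$noncancer_area_median), p$noncancer_area_sdlog))
  area_px <- area_um2 / psz^2
  axis_ratio <- stats::runif(n, 0.7, 1)          # b/a of the ellipse
  a_px <- sqrt(area_px / (pi * axis_ratio))      # semi-major
  b_px <- a_px * axis_ratio
  theta <- stats::runif(n, 0, pi)
  stain <- p$stain_od * stats::runif(n, 0.9, 1.1)

  # dart-throwing placement, largest nuclei first; bounding-circle test
  ord <- order(-a_px)
  cx <- cy <- numeric(n)
  tol_px <- p$contact_tolerance_um / psz
  placed_x <- placed_y <- placed_r <- numeric(0)
  for (i in ord) {
    r <- a_px[i]
    if (2 * r + 2 > min(H, W)) {
      rlang::abort(sprintf("tile too small to place a nucleus of %.0f um^2", area_um2[i]),
                   class = "ishquant_placement_error")
    }
    ok <- FALSE
    for (try in seq_len(5000)) {
      x <- stats::runif(1, r + 1, W - r - 2)
      y <- stats::runif(1, r + 1, H - r - 2)
      if (!length(placed_x) ||
          all((placed_x - x)^2 + (placed_y - y)^2 >=
              (placed_r + r - tol_px)^2)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      rlang::abort(sprintf("could not place %d nuclei of the requested size in a %d x %d tile",
                           n, H, W),
                   class = "ishquant_placement_error")
    }
    cx[i] <- x; cy[i] <- y
    placed_x <- c(placed_x, x); placed_y <- c(placed_y, y); placed_r <- c(placed_r, r)
  }

  # copy numbers: configured laws for cancer cells, diploid stroma
  her2 <- cep17 <- integer(n)
  her2[is_cancer] <- sample_copy_law(p$her2_law, sum(is_cancer))
  cep17[is_cancer] <- sample_copy_law(p$cep17_law, sum(is_cancer))
  her2[!is_cancer] <- 2L
  cep17[!is_cancer] <- 2L

  # paint: background, then nuclei, then dots
  od <- c(0.650, 0.704, 0.286) # hematoxylin OD vector (unit length)
  R <- matrix(p$background_intensity, H, W)
  G <- matrix(p$background_intensity, H, W)
  B <- matrix(p$background_intensity, H, W)
  for (i in seq_len(n)) {
    m <- ellipse_indices(H, W, cx[i], cy[i], a_px[i], b_px[i], theta[i])
    col <- 255 * 10^(-od * stain[i])
    R[m] <- col[1]; G[m] <- col[2]; B[m] <- col[3]
  }

  dot_r <- p$dot_diameter_um / 2 / psz
  cols <- synth_colors()
  rendered_her2 <- rendered_cep17 <- integer(n)
  is_cluster <- logical(n)
  for (i in seq_len(n)) {
    placed_dots <- matrix(numeric(0), ncol = 3) # x, y, r of dots in this nucleus
    paint_dot <- function(x, y, r, col) {
      m <- disk_indices(H, W, x, y, r)
      R[m] <<- col[1]; G[m] <<- col[2]; B[m] <<- col[3]
    }
    place_blob <- function(r_blob) {
      # random position strictly inside the ellipse, clear of earlier dots;
      # in crowded nuclei the clearance margin is relaxed (dots may touch
      # across channels, but never closer than the doublet-merge distance)
      for (try in seq_len(1200)) {
        u <- stats::runif(1, 0, 2 * pi)
        rad <- sqrt(stats::runif(1))
        ex <- rad * (a_px[i] - r_blob - 1) * cos(u)
        ey <- rad * (b_px[i] - r_blob - 1) * sin(u)
        if (a_px[i] - r_blob - 1 <= 0 || b_px[i] - r_blob - 1 <= 0) next
        x <- cx[i] + ex * cos(theta[i]) - ey * sin(theta[i])
        y <- cy[i] + ex * sin(theta[i]) + ey * cos(theta[i])
        margin <- if (try <= 600) 2 * dot_r else dot_r
        if (!nrow(placed_dots) ||
            all((placed_dots[, 1] - x)^2 + (placed_dots[, 2] - y)^2 >
                (placed_dots[, 3] + r_blob + margin)^2)) {
          return(c(x, y))
        }
      }
      NULL
    }
    render_channel <- function(k, col, allow_cluster) {
      if (k == 0) return(0L)
      if (allow_cluster && k >= 3 && stats::runif(1) < p$cluster_rate) {
        # one fused blob of k times the single-dot area
        pos <- place_blob(dot_r * sqrt(k))
        if (is.null(pos)) {
          rlang::abort("nucleus too small to host its signal cluster",
                       class = "ishquant_placement_error")
        }
        paint_dot(pos[1], pos[2], dot_r * sqrt(k), col)
        placed_dots <<- rbind(placed_dots, c(pos, dot_r * sqrt(k)))
        is_cluster[i] <<- TRUE
        return(1L)
      }
      nblobs <- 0L
      for (s in seq_len(k)) {
        doublet <- stats::runif(1) < p$doublet_rate
        pos <- place_blob(if (doublet) 2 * dot_r else dot_r)
        if (is.null(pos)) {
          rlang::abort("nucleus too small to host its signals",
                       class = "ishquant_placement_error")
        }
        if (doublet) {
          ang <- stats::runif(1, 0, 2 * pi)
          dx <- dot_r * cos(ang); dy <- dot_r * sin(ang)
          paint_dot(pos[1] - dx, pos[2] - dy, dot_r, col)
          paint_dot(pos[1] + dx, pos[2] + dy, dot_r, col)
        } else {
          paint_dot(pos[1], pos[2], dot_r, col)
        }
        placed_dots <<- rbind(placed_dots,
                              c(pos, if (doublet) 2 * dot_r else dot_r))
        nblobs <- nblobs + 1L
      }
      nblobs
    }
    rendered_her2[i] <- render_channel(her2[i], cols$her2, allow_cluster = TRUE)
    rendered_cep17[i] <- render_channel(cep17[i], cols$cep17, allow_cluster = FALSE)
  }

  if (p$noise_level > 0) {
    R <- R + stats::rnorm(H * W, 0, p$noise_level)
    G <- G + stats::rnorm(H * W, 0, p$noise_level)
    B <- B + stats::rnorm(H * W, 0, p$noise_level)
  }
  px <- array(0, dim = c(H, W, 3))
  px[, , 1] <- R; px[, , 2] <- G; px[, , 3] <- B
  px <- round(pmin(pmax(px, 0), 255))

  truth <- tibble::tibble(
    label = seq_len(n),
    is_cancer = is_cancer,
    x = cx, y = cy,
    area_um2 = area_um2,
    true_her2 = her2,
    true_cep17 = cep17,
    rendered_her2 = rendered_her2,
    rendered_cep17 = rendered_cep17,
    is_cluster = is_cluster
  )
  cc <- truth$is_cancer
  attr(truth, "true_mean_her2") <- if (any(cc)) mean(truth$true_her2[cc]) else NA_real_
  attr(truth, "true_mean_cep17") <- if (any(cc)) mean(truth$true_cep17[cc]) else NA_real_
  attr(truth, "true_ratio") <- if (any(cc) && sum(truth$true_cep17[cc]) > 0) {
    sum(truth$true_her2[cc]) / sum(truth$true_cep17[cc])
  } else NA_real_

  structure(list(tile = ish_tile(px, psz), truth = truth, params = p),
            class = "ish_case")
}

# linear indices of an ellipse footprint (pixel centers at integers, 0-based)
ellipse_indices <- function(H, W, cx, cy, a, b, theta) {
  x0 <- max(0, floor(cx - a)); x1 <- min(W - 1, ceiling(cx + a))
  y0 <- max(0, floor(cy - a)); y1 <- min(H - 1, ceiling(cy + a))
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  sel <- which(u^2 + v^2 <= 1, arr.ind = TRUE)
  (sel[, 1] + y0) + (sel[, 2] + x0 - 1) * H + 1
}

disk_indices <- function(H, W, cx, cy, r) {
  ellipse_indices(H, W, cx, cy, r, r, 0)
}

#' @export
print.ish_case <- function(x, ...) {
  cat(sprintf("<ish_case> %d nuclei (%d cancer), true ratio %.3f\n",
              nrow(x$truth), sum(x$truth$is_cancer),
              attr(x$truth, "true_ratio")))
  print(x$tile)
  invisible(x)
}

#' Write a synthetic case to disk as a reusable fixture
#'
#' Writes `tile.tiff`, `truth.csv` (the ground-truth table; scene totals
#' are recomputable from it) and `params.json` into `out_dir`. The files
#' round-trip through [read_tile()] / [read_truth()] and regenerate
#' identically from the logged parameters and seed.
#'
#' @param case An `ish_case` from [generate_case()].
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of paths, invisibly.
#' @export
write_fixture <- function(case, out_dir) {
  stopifnot(inherits(case, "ish_case"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    rlang::abort(paste0("cannot create fixture directory: ", out_dir),
                 class = "ishquant_io_error")
  }
  tile_path <- file.path(out_dir, "tile.tiff")
  truth_path <- file.path(out_dir, "truth.csv")
  params_path <- file.path(out_dir, "params.json")
  write_tile(case$tile, tile_path)
  utils::write.csv(case$truth, truth_path, row.names = FALSE)
  pj <- case$params
  pj$her2_law <- unclass(pj$her2_law)
  pj$cep17_law <- unclass(pj$cep17_law)
  jsonlite::write_json(unclass(pj), params_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(tile = tile_path, truth = truth_path, params = params_path))
}

#' Read a fixture ground-truth table
#'
#' @param path `truth.csv` written by [write_fixture()].
#' @return The ground-truth tibble with scene-total attributes restored.
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("truth file not found: ", path), class = "ishquant_io_error")
  }
  tr <- tibble::as_tibble(utils::read.csv(path))
  cc <- tr$is_cancer
  attr(tr, "true_mean_her2") <- if (any(cc)) mean(tr$true_her2[cc]) else NA_real_
  attr(tr, "true_mean_cep17") <- if (any(cc)) mean(tr$true_cep17[cc]) else NA_real_
  attr(tr, "true_ratio") <- if (any(cc) && sum(tr$true_cep17[cc]) > 0) {
    sum(tr$true_her2[cc]) / sum(tr$true_cep17[cc])
  } else NA_real_
  tr
}

#' Read scene parameters from a fixture
#'
#' @param path `params.json` written by [write_fixture()].
#' @return A [scene_params()] object; regenerating with it reproduces the
#'   fixture exactly.
#' @export
read_scene_params <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  js$her2_law <- do.call(copy_number_law, as.list(js$her2_law))
  js$cep17_law <- do.call(copy_number_law, as.list(js$cep17_law))
  do.call(scene_params, js)
}
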