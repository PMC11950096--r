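#' Estimate the white point of a bright-field tile
#'
#' Robust (median of near-white pixels) estimate of the background
#' luminance, used to normalize optical density and luminance scores. If
#' fewer than 1% of pixels are near-white (luminance >= 220) the tile has
#' no usable background and a fixed 240/255 white point is returned with a
#' warning.
#'
#' @param tile An [ish_tile()].
#' @return A luminance threshold on the 0-255 scale.
#' @export
estimate_background_level <- function(tile) {
  stopifnot(inherits(tile, "ish_tile"))
  L <- luminance(tile$pixels[, , 1], tile$pixels[, , 2], tile$pixels[, , 3])
  nw <- L >= 220
  if (mean(nw) < 0.01) {
    rlang::warn("no near-white background found; falling back to white point 240")
    return(240)
  }
  as.numeric(stats::median(L[nw]))
}

#' Separate an RGB tile into detection maps
#'
#' Decomposes a bright-field dual-ISH tile into three per-pixel soft
#' detection maps in `[0, 1]` plus a background mask:
#'
#' * `hematoxylin` - counterstain concentration from optical-density colour
#'   deconvolution against configurable stain vectors, attenuated where a
#'   chromogen dominates (chromogenic deposits occlude the counterstain);
#' * `her2_dark` - the silver chromogen is achromatic, so it is scored by a
#'   luminance-saturation rule (low relative luminance AND low colourfulness,
#'   measured as chroma relative to the white point; soft ramps rather than
#'   hard thresholds) instead of linear deconvolution;
#' * `cep17_red` - red chromogen scored by hue proximity to red with a
#'   saturation gate;
#' * `background_mask` - near-white pixels (relative luminance above the
#'   configured fraction of the white point); all maps are forced to zero
#'   there.
#'
#' @param tile An [ish_tile()].
#' @param config Configuration list (see [ish_config()]); only the `stain`
#'   block is used. `stain$white_threshold` overrides the estimated white
#'   point.
#' @return A list of class `stain_maps`: three `H x W` numeric maps, the
#'   logical `background_mask`, and the `white_point` and `pixel_size_um`
#'   used.
#' @export
separate_stains <- function(tile, config = ish_config()) {
  stopifnot(inherits(tile, "ish_tile"))
  cfg <- validate_config(merge_config(config))$stain
  d <- dim(tile$pixels)
  r <- matrix(tile$pixels[, , 1], d[1], d[2])
  g <- matrix(tile$pixels[, , 2], d[1], d[2])
  b <- matrix(tile$pixels[, , 3], d[1], d[2])
  white <- cfg$white_threshold %||% estimate_background_level(tile)

  L <- luminance(r, g, b) / white
  S <- hsv_saturation(r, g, b)
  # chroma relative to the white point: stable in the dark range, where the
  # HSV saturation denominator is tiny and noise-dominated
  C <- (pmax(r, g, b) - pmin(r, g, b)) / white
  bg <- L >= cfg$background_rel_luminance

  # achromatic dark (silver) score: soft AND of the two ramps
  her2_dark <- ramp_down(L, cfg$dark_luminance_max / 2, cfg$dark_luminance_max) *
    ramp_down(C, cfg$dark_saturation_max / 2, cfg$dark_saturation_max)

  # red chromogen score: hue gate x saturation gate, away from background
  hd <- hue_distance_from_red(r, g, b)
  cep17_red <- ramp_down(hd, cfg$red_hue_halfwidth_deg / 2, cfg$red_hue_halfwidth_deg) *
    ramp_up(S, cfg$red_saturation_min / 2, cfg$red_saturation_min) *
    ramp_down(L, cfg$background_rel_luminance - 0.1, cfg$background_rel_luminance)

  # hematoxylin concentration by colour deconvolution in OD space
  hv <- cfg$hematoxylin_od / sqrt(sum(cfg$hematoxylin_od^2))
  rv <- cfg$red_od / sqrt(sum(cfg$red_od^2))
  third <- c(hv[2] * rv[3] - hv[3] * rv[2],
             hv[3] * rv[1] - hv[1] * rv[3],
             hv[1] * rv[2] - hv[2] * rv[1])
  if (sqrt(sum(third^2)) < 1e-6) {
    rlang::abort("degenerate (collinear) stain vectors", class = "ishquant_config_error")
  }
  third <- third / sqrt(sum(third^2))
  M <- rbind(hv, rv, third)
  od <- cbind(as.vector(log10(white / pmax(r, 1))),
              as.vector(log10(white / pmax(g, 1))),
              as.vector(log10(white / pmax(b, 1))))
  od[od < 0] <- 0
  conc <- od %*% solve(M)[, 1] # hematoxylin component
  hema <- matrix(clamp01(conc / cfg$hema_max_od), nrow(r), ncol(r))
  hema <- hema * (1 - pmax(her2_dark, cep17_red))

  hema[bg] <- 0
  her2_dark[bg] <- 0
  cep17_red[bg] <- 0

  structure(list(hematoxylin = hema, her2_dark = her2_dark,
                 cep17_red = cep17_red, background_mask = bg,
                 white_point = white, pixel_size_um = tile$pixel_size_um),
            class = "stain_maps")
}

#' @export
print.stain_maps <- function(x, ...) {
  cat(sprintf("<stain_maps> %d x %d px, white point %.1f, background %.1f%%\n",
              nrow(x$hematoxylin), ncol(x$hematoxylin), x$white_point,
              100 * mean(x$background_mask)))
  invisible(x)
}
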