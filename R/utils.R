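# internal helpers shared across modules

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# linear ramp: 1 for x <= lo, 0 for x >= hi
ramp_down <- function(x, lo, hi) clamp01((hi - x) / (hi - lo))

# linear ramp: 0 for x <= lo, 1 for x >= hi
ramp_up <- function(x, lo, hi) clamp01((x - lo) / (hi - lo))

# Rec.601 luma of 0-255 RGB planes
luminance <- function(r, g, b) 0.299 * r + 0.587 * g + 0.114 * b

# HSV saturation of 0-255 RGB planes; 0 where the pixel is black
hsv_saturation <- function(r, g, b) {
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  s <- (mx - mn) / mx
  s[mx == 0] <- 0
  s
}

# hue angular distance from pure red (0 deg), in degrees; achromatic
# pixels are assigned the maximal distance 180
hue_distance_from_red <- function(r, g, b) {
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  d <- mx - mn
  ok <- d > 0
  hh <- r # inherit matrix shape
  hh[] <- 180
  i <- ok & mx == r
  hh[i] <- (60 * ((g[i] - b[i]) / d[i])) %% 360
  i <- ok & mx == g & mx != r
  hh[i] <- 60 * ((b[i] - r[i]) / d[i]) + 120
  i <- ok & mx == b & mx != r & mx != g
  hh[i] <- 60 * ((r[i] - g[i]) / d[i]) + 240
  hh <- hh %% 360
  pmin(hh, 360 - hh)
}

# disjoint-set forest: component id (1..n, root-labelled) for each of n
# items given an m x 2 matrix of linked pairs
union_find_components <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    r <- i
    while (parent[r] != r) r <- parent[r]
    while (parent[i] != r) {
      nxt <- parent[i]
      parent[i] <<- r
      i <- nxt
    }
    r
  }
  if (!is.null(pairs) && nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1])
      b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# centroids and pixel areas of a label matrix, 0-based (x, y) = (col, row)
label_stats <- function(labels) {
  idx <- which(labels > 0L)
  if (!length(idx)) {
    return(tibble::tibble(label = integer(), area_px = integer(),
                          x = numeric(), y = numeric()))
  }
  lab <- labels[idx]
  nr <- nrow(labels)
  row0 <- (idx - 1L) %% nr        # 0-based row (y)
  col0 <- (idx - 1L) %/% nr       # 0-based col (x)
  area <- tabulate(lab)
  keep <- which(area > 0L)
  tibble::tibble(
    label = keep,
    area_px = area[keep],
    x = as.numeric(rowsum(col0, lab)[, 1] / area[keep]),
    y = as.numeric(rowsum(row0, lab)[, 1] / area[keep])
  )
}

ishquant_version <- function() as.character(utils::packageVersion("ishquant"))
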