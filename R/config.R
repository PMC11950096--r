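#' Default analysis configuration
#'
#' Returns the full nested configuration used by the pipeline. Every tunable
#' of stain separation, nuclear segmentation, signal detection and scoring is
#' exposed here; [run_case()] and the command-line interface accept partial
#' overrides which are validated against this schema (unknown keys are
#' rejected).
#'
#' Key blocks:
#' \describe{
#'   \item{pixel_size_um}{physical pixel size in micrometres (default 0.121,
#'     a 40x brightfield scan).}
#'   \item{stain}{stain-separation parameters: the hematoxylin optical
#'     density vector, the dark (silver) luminance/saturation rule, the red
#'     hue gate and the background white threshold.}
#'   \item{nuclei}{segmentation and size-gate parameters; the gate defaults
#'     to the closed interval \[30, 150\] um^2.}
#'   \item{signals}{blob threshold, doublet separation (um), cluster factor,
#'     minimum speck area and the fallback single-signal reference area.}
#'   \item{scoring}{guideline (breast2023), the 1.96 critical value for the
#'     95% margin of error, and the low-cell-count warning threshold (20).}
#'   \item{io}{output options (overlay on/off).}
#' }
#'
#' @return A named nested list of defaults.
#' @export
#' @examples
#' cfg <- ish_config()
#' cfg$nuclei$min_area_um2
ish_config <- function() {
  list(
    pixel_size_um = 0.121,
    seed = NULL,
    stain = list(
      # standard published hematoxylin OD vector (unit length)
      hematoxylin_od = c(0.650, 0.704, 0.286),
      # OD vector of the red chromogen; default derived from the rendered
      # CEP17 dot colour of the synthetic generator
      red_od = c(0.126, 0.743, 0.657),
      hema_max_od = 0.9,
      dark_luminance_max = 0.45,
      dark_saturation_max = 0.25,
      red_saturation_min = 0.30,
      red_hue_halfwidth_deg = 40,
      background_rel_luminance = 0.90,
      white_threshold = NULL # estimated from the tile when NULL
    ),
    nuclei = list(
      min_area_um2 = 30,
      max_area_um2 = 150,
      border_exclude = TRUE,
      smooth_sigma_um = 0.5,
      threshold_method = "adaptive", # or "global"
      global_threshold = 0.20,
      adaptive_window_um = 12,
      adaptive_offset = 0.05,
      floor_threshold = 0.15,
      watershed_tolerance_um = 1.0,
      min_seed_sep_um = 4
    ),
    signals = list(
      blob_threshold = 0.5,
      doublet_sep_um = 0.8,
      cluster_factor = 2.5,
      min_speck_um2 = 0.1,
      reference_area_um2 = 0.28,
      min_isolated_for_reference = 10
    ),
    scoring = list(
      guideline = "breast2023",
      critical_value = 1.96,
      min_cells_warning = 20
    ),
    io = list(
      overlay = TRUE
    )
  )
}

# merge a partial user config into the defaults, rejecting unknown keys
merge_config <- function(config = list(), defaults = ish_config(), path = "") {
  if (is.null(config)) return(defaults)
  if (!is.list(config)) {
    rlang::abort(paste0("config", path, " must be a list"), class = "ishquant_config_error")
  }
  nm <- names(config)
  if (length(config) && (is.null(nm) || any(nm == ""))) {
    rlang::abort(paste0("config", path, " entries must be named"),
                 class = "ishquant_config_error")
  }
  unknown <- setdiff(nm, names(defaults))
  if (length(unknown)) {
    rlang::abort(paste0("unknown config key(s): ",
                        paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", ")),
                 class = "ishquant_config_error")
  }
  out <- defaults
  for (k in nm) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      out[[k]] <- merge_config(config[[k]], defaults[[k]], paste0(path, ".", k))
    } else {
      out[[k]] <- config[[k]]
    }
  }
  out
}

# validate numeric sanity of a merged config
validate_config <- function(cfg) {
  chk <- function(ok, msg) {
    if (!isTRUE(ok)) rlang::abort(msg, class = "ishquant_config_error")
  }
  chk(is.numeric(cfg$pixel_size_um) && cfg$pixel_size_um > 0,
      "pixel_size_um must be a positive number")
  chk(cfg$nuclei$min_area_um2 < cfg$nuclei$max_area_um2,
      "nuclei.min_area_um2 must be smaller than nuclei.max_area_um2")
  chk(cfg$signals$doublet_sep_um >= 0, "signals.doublet_sep_um must be >= 0")
  chk(cfg$signals$cluster_factor > 0, "signals.cluster_factor must be > 0")
  chk(cfg$signals$reference_area_um2 > 0, "signals.reference_area_um2 must be > 0")
  chk(cfg$scoring$guideline == "breast2023",
      "only the breast2023 guideline is implemented")
  v <- cfg$stain$hematoxylin_od
  chk(is.numeric(v) && length(v) == 3 && all(is.finite(v)) && sum(abs(v)) > 0,
      "stain.hematoxylin_od must be a finite length-3 vector")
  invisible(cfg)
}

#' Read a pipeline configuration file
#'
#' Reads a YAML (or JSON) configuration file containing partial overrides of
#' [ish_config()], merges it into the defaults and validates it. Unknown keys
#' are rejected so typos fail loudly.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return The merged, validated configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("config file not found: ", path), class = "ishquant_io_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(merge_config(raw))
}
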