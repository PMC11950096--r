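#' Apply the cell-inclusion scoring rule
#'
#' Only cells carrying at least one copy of each probe are scored: among
#' nuclei that passed the area gate, a zero HER2 count excludes the cell as
#' `NO_HER2` and (HER2 checked first) a zero CEP17 count as `NO_CEP17`.
#' Like the area gate this is idempotent: it recomputes the signal-based
#' flags and leaves other exclusion reasons untouched.
#'
#' @param nuclei Nucleus tibble with `her2`/`cep17` counts, or an
#'   `ish_segmentation`.
#' @return Same type as input with `included`/`reason` updated.
#' @export
score_cells <- function(nuclei) {
  if (inherits(nuclei, "ish_segmentation")) {
    nuclei$nuclei <- score_cells(nuclei$nuclei)
    return(nuclei)
  }
  touch <- nuclei$reason %in% c("NONE", "NO_HER2", "NO_CEP17")
  reason <- nuclei$reason
  reason[touch] <- "NONE"
  reason[touch & nuclei$cep17 == 0L] <- "NO_CEP17"
  reason[touch & nuclei$her2 == 0L] <- "NO_HER2" # HER2 checked first: wins
  nuclei$reason <- reason
  nuclei$included <- reason == "NONE"
  nuclei
}

#' 95% margin of error of a per-cell mean
#'
#' `ME = critical_value * SD / sqrt(n)` with the sample standard deviation
#' (`n - 1` denominator) and a fixed critical value of 1.96 (no
#' t-correction at small n). Undefined for fewer than two values, in which
#' case `NA` is returned with a warning.
#'
#' @param values Numeric vector of per-cell measurements.
#' @param critical_value Normal critical value (default 1.96 for 95%).
#' @return The margin of error, or `NA_real_` when `n < 2`.
#' @export
#' @examples
#' margin_of_error(rep(c(2, 4), 50)) # SD ~1.005, n = 100
margin_of_error <- function(values, critical_value = 1.96) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) {
    rlang::warn("margin of error undefined for fewer than 2 values; returning NA")
    return(NA_real_)
  }
  critical_value * stats::sd(values) / sqrt(n)
}

#' Case-level quantification of scored cells
#'
#' Computes, over the included (scored) cells: the per-cell mean HER2 and
#' CEP17 copy numbers, the HER2/CEP17 ratio as the ratio of totals (equal
#' to the ratio of the means), sample standard deviations of the per-cell
#' counts and of the per-cell HER2/CEP17 ratios, and 95% margins of error
#' for the mean HER2 copy number and for the ratio (the ratio ME uses the
#' SD of the per-cell ratios). A warning is recorded when fewer than 20
#' cells are scored (the guideline minimum for a visual count) and the
#' margins are reported missing when only one cell is scored.
#'
#' @param nuclei Nucleus tibble (or `ish_segmentation`) after
#'   [score_cells()]; only rows with `included == TRUE` enter.
#' @param config Configuration list (critical value, warning threshold).
#' @return A `case_quantification` object (classification fields unset;
#'   see [classify_ish_group()] and [her2_status()]).
#' @export
quantify_case <- function(nuclei, config = ish_config()) {
  if (inherits(nuclei, "ish_segmentation")) nuclei <- nuclei$nuclei
  cfg <- validate_config(merge_config(config))$scoring
  sc <- nuclei[nuclei$included, , drop = FALSE]
  n <- nrow(sc)
  if (n == 0) {
    rlang::abort("no scorable cells", class = "ishquant_analysis_error")
  }
  warnings <- character()
  if (n < cfg$min_cells_warning) {
    warnings <- c(warnings, sprintf("only %d cells scored (fewer than %d)",
                                    n, cfg$min_cells_warning))
  }
  per_ratio <- sc$her2 / sc$cep17
  me_h <- me_r <- NA_real_
  sd_h <- sd_c <- sd_r <- NA_real_
  if (n >= 2) {
    sd_h <- stats::sd(sc$her2)
    sd_c <- stats::sd(sc$cep17)
    sd_r <- stats::sd(per_ratio)
    me_h <- cfg$critical_value * sd_h / sqrt(n)
    me_r <- cfg$critical_value * sd_r / sqrt(n)
  } else {
    warnings <- c(warnings, "margins of error undefined for a single cell")
  }
  structure(list(
    n_cells = n,
    mean_her2 = sum(sc$her2) / n,
    mean_cep17 = sum(sc$cep17) / n,
    ratio = sum(sc$her2) / sum(sc$cep17),
    sd_her2 = sd_h, sd_cep17 = sd_c, sd_ratio = sd_r,
    me_her2 = me_h, me_ratio = me_r,
    ish_group = NA_integer_,
    her2_status = NA_character_,
    warnings = warnings
  ), class = "case_quantification")
}

#' @export
print.case_quantification <- function(x, ...) {
  cat(sprintf("<case_quantification> %d cells | HER2 %.2f +/- %s | CEP17 %.2f | ratio %.2f +/- %s\n",
              x$n_cells, x$mean_her2,
              ifelse(is.na(x$me_her2), "NA", sprintf("%.3f", x$me_her2)),
              x$mean_cep17, x$ratio,
              ifelse(is.na(x$me_ratio), "NA", sprintf("%.3f", x$me_ratio))))
  if (!is.na(x$ish_group)) {
    cat(sprintf("  ISH group %d, HER2 %s\n", x$ish_group, x$her2_status))
  }
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Classify the ASCO/CAP breast ISH group
#'
#' Partition of the (ratio, mean HER2 copy number) plane into the five
#' 2023 ASCO/CAP breast ISH groups:
#' group 1 if `ratio >= 2` and `mean HER2 >= 4`; group 2 if `ratio >= 2`
#' and `mean HER2 < 4`; group 3 if `ratio < 2` and `mean HER2 >= 6`;
#' group 4 if `ratio < 2` and `4 <= mean HER2 < 6`; group 5 if `ratio < 2`
#' and `mean HER2 < 4`. Boundaries classify upward (inclusive on `>=`).
#'
#' @param ratio HER2/CEP17 ratio(s), positive and finite.
#' @param mean_her2 Mean HER2 copies per cell, positive and finite.
#' @return Integer vector of groups in 1..5.
#' @export
#' @examples
#' classify_ish_group(1.85, 3.06) # 5
#' classify_ish_group(2.42, 3.92) # 2
classify_ish_group <- function(ratio, mean_her2) {
  if (!all(is.finite(ratio)) || !all(is.finite(mean_her2)) ||
      any(ratio <= 0) || any(mean_her2 <= 0)) {
    rlang::abort("ratio and mean_her2 must be positive and finite",
                 class = "ishquant_analysis_error")
  }
  dplyr::case_when(
    ratio >= 2 & mean_her2 >= 4 ~ 1L,
    ratio >= 2                  ~ 2L,
    mean_her2 >= 6              ~ 3L,
    mean_her2 >= 4              ~ 4L,
    TRUE                        ~ 5L
  )
}

#' HER2 amplification status from the ISH group
#'
#' For the IHC-equivocal (score 2+) setting: groups 1 and 3 are
#' HER2-positive, groups 2, 4 and 5 are HER2-negative.
#'
#' @param group Integer vector of ISH groups in 1..5.
#' @param ihc_context Cohort context; only `"ihc2plus"` is implemented.
#' @return Character vector, `"positive"` or `"negative"`.
#' @export
her2_status <- function(group, ihc_context = "ihc2plus") {
  if (!identical(ihc_context, "ihc2plus")) {
    rlang::abort("unsupported IHC context (only 'ihc2plus' is implemented)",
                 class = "ishquant_analysis_error")
  }
  if (!all(group %in% 1:5)) {
    rlang::abort("ISH group must be in 1..5", class = "ishquant_analysis_error")
  }
  ifelse(group %in% c(1L, 3L), "positive", "negative")
}

#' Run the full quantification pipeline on one tile
#'
#' Composes stain separation, nuclear segmentation, the 30-150 um^2 area
#' gate, per-channel signal detection (with doublet merging and cluster
#' estimation), signal-to-nucleus assignment, cell scoring, case
#' quantification and ISH-group classification. Counts at every filtering
#' stage (detected, area-gated, signal-gated, scored) are collected in a
#' `stage_log`.
#'
#' @param tile An [ish_tile()].
#' @param roi Optional [ish_roi()] restricting the analysis.
#' @param config Partial configuration overriding [ish_config()].
#' @param out_dir Optional output directory; when given,
#'   [write_case_outputs()] writes `cells.csv`, `summary.json` and the
#'   overlay there.
#' @return A list of class `ish_case_result`: `quant`
#'   (`case_quantification`), `nuclei`, `calls`, `labels`, `dropped`,
#'   `stage_log` and, when written, `paths`.
#' @export
run_case <- function(tile, roi = NULL, config = list(), out_dir = NULL) {
  cfg <- validate_config(merge_config(config))
  psz <- tile$pixel_size_um
  stage <- function(expr, name) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, "ishquant_placement_error") ||
          inherits(e, "ishquant_analysis_error") ||
          inherits(e, "ishquant_io_error") ||
          inherits(e, "ishquant_config_error")) {
        rlang::abort(paste0(name, ": ", conditionMessage(e)), class = class(e)[1])
      }
      rlang::abort(paste0(name, ": ", conditionMessage(e)),
                   class = "ishquant_analysis_error")
    })
  }
  maps <- stage(separate_stains(tile, cfg), "stain separation")
  seg <- stage(segment_nuclei(maps, roi, psz, cfg), "nucleus segmentation")
  n_detected <- nrow(seg$nuclei)
  seg <- apply_area_gate(seg, cfg$nuclei$min_area_um2, cfg$nuclei$max_area_um2)
  n_area <- sum(seg$nuclei$included)
  calls <- dplyr::bind_rows(
    stage(detect_channel_signals(maps, "HER2", psz, cfg), "HER2 signal detection"),
    stage(detect_channel_signals(maps, "CEP17", psz, cfg), "CEP17 signal detection")
  )
  seg <- stage(assign_to_nuclei(calls, seg), "signal assignment")
  seg <- score_cells(seg)
  n_scored <- sum(seg$nuclei$included)
  quant <- stage(quantify_case(seg, cfg), "quantification")
  quant$ish_group <- classify_ish_group(quant$ratio, quant$mean_her2)
  quant$her2_status <- her2_status(quant$ish_group)
  res <- structure(list(
    quant = quant,
    nuclei = seg$nuclei,
    calls = seg$calls,
    labels = seg$labels,
    dropped = seg$dropped,
    stage_log = c(detected = n_detected, area_gated = n_area,
                  scored = n_scored)
  ), class = "ish_case_result")
  if (!is.null(out_dir)) {
    res$paths <- stage(
      write_case_outputs(quant, seg$nuclei, tile, seg$labels, out_dir, cfg),
      "output writing")
  }
  res
}

#' @export
print.ish_case_result <- function(x, ...) {
  cat(sprintf("<ish_case_result> detected %d -> area-gated %d -> scored %d\n",
              x$stage_log["detected"], x$stage_log["area_gated"],
              x$stage_log["scored"]))
  print(x$quant)
  invisible(x)
}
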