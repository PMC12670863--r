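# Cardiac position: classify slices of a short-axis stack as basal,
# midventricular or apical relative to a reference reader's segmented
# extent, and aggregate comparison metrics by position x contour type.

POSITION_LEVELS <- c("basal", "mid", "apical")

# slice indices on which the reference reader segmented the contour type
segmented_indices <- function(case, ctype, phase = NULL) {
  idx <- integer(0)
  for (s in case_slices(case, phase)) {
    if (!is.null(slice_region(s, ctype))) idx <- c(idx, s$slice_index)
  }
  sort(unique(idx))
}

# classify a vector of slice indices against a reference extent
classify_indices <- function(indices, ref_min, ref_max) {
  pos <- ifelse(indices <= ref_min, "basal",
                ifelse(indices >= ref_max, "apical", "mid"))
  # a single segmented slice is classified basal; everything beyond apical
  if (ref_min == ref_max) pos[indices > ref_max] <- "apical"
  factor(pos, levels = POSITION_LEVELS)
}

#' Classify stack slices as basal, midventricular or apical
#'
#' Positions are defined relative to the reference reader's segmented
#' extent for the contour type: the smallest segmented slice index and all
#' smaller indices are basal, the largest segmented index and all larger
#' indices are apical, indices strictly between are midventricular. When
#' the reference segments a single slice it is classified basal.
#'
#' @param reference The reference reader's [cmr_case()].
#' @param ctype Contour type (including derived `"myo"`).
#' @param phase Optional phase restriction.
#' @param indices Slice indices to classify; defaults to the reference
#'   case's own slice indices.
#' @return A tibble: `slice_index`, `ctype`, `position`.
#' @export
classify_slices <- function(reference, ctype, phase = NULL, indices = NULL) {
  seg <- segmented_indices(reference, ctype, phase)
  if (!length(seg))
    stop("classification error: reference segments no '", ctype, "' contour",
         call. = FALSE)
  if (is.null(indices))
    indices <- sort(unique(vapply(case_slices(reference, phase), `[[`,
                                  integer(1), "slice_index")))
  tibble::tibble(slice_index = indices, ctype = ctype,
                 position = classify_indices(indices, min(seg), max(seg)))
}

# per-slice metric rows of one pair annotated with position, for the
# standard ventricular contour types; reference extent taken from the
# chosen reader, per contour type and phase
positioned_metrics <- function(pair, policy = c("reader1", "reader2"),
                               ctypes = c("lv_endo", "myo", "rv_endo")) {
  policy <- match.arg(policy)
  met <- slice_metrics(pair, ctypes = intersect(ctypes, pair_ctypes(pair)))
  if (!nrow(met)) return(met)
  ref_col <- if (policy == "reader1") "slice_r1" else "slice_r2"
  met$position <- factor(NA_character_, levels = POSITION_LEVELS)
  for (ct in unique(met$ctype)) {
    for (ph in unique(met$phase[met$ctype == ct])) {
      in_ph <- pair$phase == ph
      seg <- pair$slice_index[in_ph][vapply(pair[[ref_col]][in_ph], function(s)
        !is.null(slice_region(s, ct)), logical(1))]
      sel <- met$ctype == ct & met$phase == ph
      if (!length(seg)) next
      met$position[sel] <- classify_indices(met$slice_index[sel], min(seg), max(seg))
    }
  }
  met
}

#' Segmentation metrics aggregated by cardiac position and contour type
#'
#' For each (position, contour type) cell, averages over all qualifying
#' slice pairs pooled across cases and phases:
#' * `dice_all`: mean Dice over slices annotated by at least one reader
#'   (one-sided slices score 0),
#' * `dice_both`: mean Dice over slices annotated by both readers,
#' * `hd_mm`: mean Hausdorff distance over both-annotated slices,
#' * `abs_ml_per_slice`: mean absolute per-slice milliliter impact over
#'   slices annotated by at least one reader.
#'
#' Empty cells are `NA`. `dice_both >= dice_all` holds in every cell,
#' since adding zero-scored one-sided slices cannot raise an average.
#'
#' @param pairs A [pair_cases()] result or a list of them (one per case).
#' @param policy Which reader's extent defines base and apex.
#' @param ctypes Contour types to evaluate.
#' @return A tibble: `position`, `ctype`, `n_all`, `n_both`, `dice_all`,
#'   `dice_both`, `hd_mm`, `abs_ml_per_slice`. Dice values are percent.
#' @export
position_table <- function(pairs, policy = c("reader1", "reader2"),
                           ctypes = c("lv_endo", "myo", "rv_endo")) {
  policy <- match.arg(policy)
  if (inherits(pairs, "cmr_pair")) pairs <- list(pairs)
  met <- dplyr::bind_rows(lapply(pairs, positioned_metrics,
                                 policy = policy, ctypes = ctypes))
  if (!nrow(met))
    stop("position table error: no comparable slices", call. = FALSE)
  met <- dplyr::filter(met, !is.na(.data$position))
  both <- !is.na(met$dice) & met$area_r1_mm2 > 0 & met$area_r2_mm2 > 0
  met$dice_b <- ifelse(both, met$dice, NA_real_)
  met |>
    dplyr::group_by(.data$position, .data$ctype) |>
    dplyr::summarise(
      n_all = sum(!is.na(.data$dice)),
      n_both = sum(!is.na(.data$dice_b)),
      dice_all = 100 * mean(.data$dice, na.rm = TRUE),
      dice_both = 100 * mean(.data$dice_b, na.rm = TRUE),
      hd_mm = mean(.data$hd_mm[!is.na(.data$dice_b)], na.rm = TRUE),
      abs_ml_per_slice = mean(.data$abs_ml_diff[!is.na(.data$dice)]),
      .groups = "drop") |>
    dplyr::mutate(dplyr::across(c("dice_all", "dice_both", "hd_mm"),
                                ~ ifelse(is.nan(.x), NA_real_, .x))) |>
    dplyr::arrange(.data$position, .data$ctype)
}

#' Write a position table in wide layout
#'
#' Rows are position x metric, columns the contour types (LV, MYO, RV),
#' mirroring the usual reporting layout.
#'
#' @param tab A [position_table()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_position_csv <- function(tab, path) {
  long <- tab |>
    tidyr::pivot_longer(c("dice_all", "dice_both", "hd_mm", "abs_ml_per_slice"),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(ctype = dplyr::recode(.data$ctype, lv_endo = "LV",
                                        myo = "MYO", rv_endo = "RV"))
  wide <- tidyr::pivot_wider(long[, c("position", "metric", "ctype", "value")],
                             names_from = "ctype", values_from = "value")
  readr::write_csv(wide, path)
  invisible(path)
}
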