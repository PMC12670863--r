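# Annotation-comparison metrics: polygon areas, Dice similarity,
# Hausdorff distance, and the per-slice milliliter impact of an area
# difference. Dice is computed on exact polygon intersection areas
# (resolution-independent, testable against closed forms); a rasterised
# oracle lives in the test suite.

#' Physical area of a contour set
#'
#' Total area of a list of polygons in mm^2: sum over polygons of the
#' absolute shoelace area times `spacing_row * spacing_col`. An empty or
#' `NULL` list has area 0.
#'
#' @param contours List of polygon matrices (pixel coordinates), or a
#'   single matrix.
#' @param geom A [cmr_geometry()].
#' @return Area in mm^2.
#' @export
polygon_area <- function(contours, geom) {
  region <- as_region(contours)
  for (p in region) {
    if (polygon_self_intersects(p))
      stop("geometry error: self-intersecting polygon", call. = FALSE)
  }
  px <- sum(vapply(region, function(p) abs(shoelace_area(p)), numeric(1)))
  if (!length(region)) px <- 0
  px * geom$spacing_row * geom$spacing_col
}

#' Dice similarity coefficient of two contour sets
#'
#' `2|A∩B| / (|A| + |B|)` on exact polygon intersection areas. If exactly
#' one side is absent or empty the score is 0 (a one-sided segmentation
#' has no overlap); if both sides are absent the metric is undefined
#' (`NA`) and such slices are excluded from averages.
#'
#' @param c1,c2 Contour sets: lists of polygon matrices interpreted with
#'   even-odd filling (rings with holes allowed), or `NULL` for absent.
#' @return Dice in `[0, 1]`, or `NA`.
#' @export
dice <- function(c1, c2) {
  r1 <- as_region(c1); r2 <- as_region(c2)
  if (!length(r1) && !length(r2)) return(NA_real_)
  if (!length(r1) || !length(r2)) return(0)
  a1 <- region_area_px(r1); a2 <- region_area_px(r2)
  if (a1 + a2 == 0) return(NA_real_)
  ai <- region_area_px(region_intersect(r1, r2))
  2 * ai / (a1 + a2)
}

#' Hausdorff distance between two contour sets, in mm
#'
#' Symmetric Hausdorff distance between the contour boundaries (max over
#' both directed sup-inf point-to-polyline distances), with anisotropic
#' pixel spacing applied before measuring. Boundaries are densified to
#' segments of at most 0.1 mm. Undefined (`NA`) when either side is
#' absent.
#'
#' @inheritParams dice
#' @param geom A [cmr_geometry()].
#' @return Distance in mm, or `NA`.
#' @export
hausdorff <- function(c1, c2, geom) {
  hausdorff_mm_regions(c1, c2, spacing = c(geom$spacing_col, geom$spacing_row))
}

#' Per-slice milliliter impact of an area difference
#'
#' `|area(c1) - area(c2)| * (slice_thickness + slice_gap) / 1000`: the
#' contribution the disagreement on this slice makes to a Simpson
#' slice-summation volume, in ml. An absent side counts as area 0.
#'
#' @inheritParams hausdorff
#' @return Absolute volume impact in ml (>= 0).
#' @export
ml_impact <- function(c1, c2, geom) {
  a1 <- region_area_mm2(c1, geom)
  a2 <- region_area_mm2(c2, geom)
  abs(a1 - a2) * slice_distance(geom) / 1000
}

#' Comparison region of a contour type on one slice
#'
#' Returns the polygon list to compare for `ctype`, or `NULL` when the
#' slice or the needed contours are absent. The derived type `"myo"` is
#' the myocardial ring, `lv_epi` minus `lv_endo` (an even-odd region
#' whose second path is the endocardial hole).
#'
#' @param slice A [cmr_slice()] or `NULL`.
#' @param ctype Contour type, including `"myo"`.
#' @return List of polygon matrices, or `NULL`.
#' @export
slice_region <- function(slice, ctype) {
  if (is.null(slice)) return(NULL)
  if (ctype == "myo") {
    epi <- slice$contours[["lv_epi"]]
    if (is.null(epi)) return(NULL)
    endo <- slice$contours[["lv_endo"]]
    ring <- region_minus(as_region(epi), as_region(endo))
    return(if (length(ring)) ring else as_region(epi))
  }
  r <- as_region(slice$contours[[ctype]])
  if (length(r)) r else NULL
}

# Contour types to compare for a pair: all raw polygon types present on
# either side, plus derived "myo" whenever lv_epi appears.
pair_ctypes <- function(pair) {
  cts <- unique(unlist(lapply(c(pair$slice_r1, pair$slice_r2), function(s)
    if (is.null(s)) NULL else names(s$contours))))
  cts <- setdiff(cts, "refpoint")
  if ("lv_epi" %in% cts) cts <- c(cts, "myo")
  cts
}

#' Per-slice comparison metrics for a paired case
#'
#' One row per (slice, phase, contour type) with Dice, Hausdorff distance,
#' both readers' areas and the absolute per-slice milliliter impact. The
#' derived type `myo` (epicardial minus endocardial ring) is included
#' whenever `lv_epi` contours exist. Slices where both readers lack the
#' contour type are omitted (the metric is undefined there).
#'
#' @param pair A [pair_cases()] result.
#' @param ctypes Contour types to evaluate; defaults to every type present
#'   plus `myo`.
#' @return A tibble: `case_id`, `slice_index`, `phase`, `ctype`, `dice`,
#'   `hd_mm`, `area_r1_mm2`, `area_r2_mm2`, `abs_ml_diff`.
#' @export
slice_metrics <- function(pair, ctypes = NULL) {
  geom <- attr(pair, "geometry")
  if (is.null(ctypes)) ctypes <- pair_ctypes(pair)
  rows <- list()
  for (i in seq_len(nrow(pair))) {
    s1 <- pair$slice_r1[[i]]; s2 <- pair$slice_r2[[i]]
    for (ct in ctypes) {
      r1 <- slice_region(s1, ct); r2 <- slice_region(s2, ct)
      if (is.null(r1) && is.null(r2)) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        case_id = attr(pair, "case_id"),
        slice_index = pair$slice_index[i],
        phase = pair$phase[i],
        ctype = ct,
        dice = dice(r1, r2),
        hd_mm = hausdorff(r1, r2, geom),
        area_r1_mm2 = region_area_mm2(r1, geom),
        area_r2_mm2 = region_area_mm2(r2, geom),
        abs_ml_diff = ml_impact(r1, r2, geom))
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(case_id = character(), slice_index = integer(),
                          phase = character(), ctype = character(),
                          dice = numeric(), hd_mm = numeric(),
                          area_r1_mm2 = numeric(), area_r2_mm2 = numeric(),
                          abs_ml_diff = numeric()))
  }
  dplyr::bind_rows(rows)
}
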