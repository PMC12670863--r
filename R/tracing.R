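# Error tracing: decompose a clinical-parameter difference between two
# readers into signed per-slice contour-difference contributions, ranked
# by impact, so a quantitative outlier can be traced to the causal slice.

# (ctype, phase, ml-per-mm2 factor) ingredients of the slice-additive
# parameters; D = slice_thickness + slice_gap is multiplied in later.
volume_param_spec <- function(parameter, sequence) {
  lge_phase <- "single"
  switch(parameter,
    LVESV = list(ctype = "lv_endo", phase = "ES", density = 1),
    LVEDV = list(ctype = "lv_endo", phase = "ED", density = 1),
    RVESV = list(ctype = "rv_endo", phase = "ES", density = 1),
    RVEDV = list(ctype = "rv_endo", phase = "ED", density = 1),
    LVV = list(ctype = "lv_endo", phase = lge_phase, density = 1),
    LVM = list(ctype = "myo", phase = if (sequence == "sax_lge") lge_phase else "ED",
               density = MYO_DENSITY),
    PAPMU_ES = list(ctype = "papmu", phase = "ES", density = MYO_DENSITY),
    PAPMU_ED = list(ctype = "papmu", phase = "ED", density = MYO_DENSITY),
    SCARM = list(ctype = "scar_in_myo", phase = lge_phase, density = MYO_DENSITY),
    NULL)
}

# signed area (mm^2) of the traced ingredient on one slice
trace_area <- function(slice, ctype, geom) {
  if (is.null(slice)) return(0)
  if (ctype == "scar_in_myo") {
    scar <- as_region(slice$contours[["scar"]])
    if (!length(scar)) return(0)
    ring <- region_minus(as_region(slice$contours[["lv_epi"]]),
                         as_region(slice$contours[["lv_endo"]]))
    return(region_area_mm2(region_intersect(scar, ring), geom))
  }
  if (ctype == "myo") {
    r <- slice_region(slice, "myo")
    return(if (is.null(r)) 0 else region_area_mm2(r, geom))
  }
  polygon_area(as_region(slice$contours[[ctype]]), geom)
}

# per-slice trace rows for one slice-additive ingredient, with the slice's
# Dice/HD for context; weight converts an area difference (mm^2) into the
# parameter's unit
trace_rows <- function(pair, ctype, phase, weight, metrics = TRUE) {
  geom <- attr(pair, "geometry")
  sel <- which(pair$phase == phase)
  rows <- lapply(sel, function(i) {
    s1 <- pair$slice_r1[[i]]; s2 <- pair$slice_r2[[i]]
    a1 <- trace_area(s1, ctype, geom); a2 <- trace_area(s2, ctype, geom)
    dc <- hd <- NA_real_
    if (metrics) {
      mct <- if (ctype == "scar_in_myo") "scar" else ctype
      r1 <- slice_region(s1, mct); r2 <- slice_region(s2, mct)
      dc <- dice(r1, r2)
      if (!is.null(r1) || !is.null(r2)) hd <- hausdorff(r1, r2, geom)
    }
    tibble::tibble(slice_index = pair$slice_index[i], phase = phase,
                   ctype = ctype, contribution = (a1 - a2) * weight,
                   dice = dc, hd_mm = hd)
  })
  dplyr::bind_rows(rows)
}

finish_trace <- function(rows, total, parameter, unit) {
  rows <- rows[order(-abs(rows$contribution)), ]
  structure(rows, parameter = parameter, unit = unit, total_diff = total,
            class = c("cmr_trace", class(rows)))
}

#' Trace a clinical-parameter difference to slice-level contour differences
#'
#' Decomposes the reader1 - reader2 difference of a clinical parameter
#' into signed per-slice contributions, sorted by absolute impact:
#' * volume and mass parameters: `(A1 - A2) * D / 1000` (times 1.05 g/ml
#'   for masses) per slice of the relevant phase; contributions sum
#'   exactly to the parameter difference;
#' * stroke volumes: the ED trace plus the negated ES trace (still exact);
#' * ejection fractions and scar fraction: first-order slice
#'   contributions (derivatives evaluated at the two readers' mean
#'   values) plus a separate `nonlinearity` residual entry that restores
#'   exact conservation;
#' * global mapping values: per-slice ring-mean differences weighted by
#'   voxel counts.
#'
#' @param pair A [pair_cases()] result.
#' @param parameter Parameter name (e.g. `"LVEDV"`, `"LVSV"`, `"LVEF"`,
#'   `"SCARF"`, `"GLOBAL_T1"`).
#' @param metrics Also compute each entry's Dice and Hausdorff distance
#'   (default `TRUE`); disable for bulk contribution-only runs.
#' @return A tibble of class `cmr_trace` (`slice_index`, `phase`,
#'   `ctype`, `contribution`, `dice`, `hd_mm`) with attributes
#'   `parameter`, `unit`, `total_diff`.
#' @export
trace_parameter <- function(pair, parameter, metrics = TRUE) {
  geom <- attr(pair, "geometry")
  seqn <- attr(pair, "sequence")
  D <- slice_distance(geom)
  spec <- volume_param_spec(parameter, seqn)
  if (!is.null(spec)) {
    w <- D / 1000 * spec$density
    rows <- trace_rows(pair, spec$ctype, spec$phase, w, metrics)
    unit <- if (spec$density == 1) "ml" else "g"
    return(finish_trace(rows, sum(rows$contribution), parameter, unit))
  }
  if (parameter %in% c("LVSV", "RVSV")) {
    ct <- if (parameter == "LVSV") "lv_endo" else "rv_endo"
    rows <- dplyr::bind_rows(trace_rows(pair, ct, "ED", D / 1000, metrics),
                             trace_rows(pair, ct, "ES", -D / 1000, metrics))
    return(finish_trace(rows, sum(rows$contribution), parameter, "ml"))
  }
  if (parameter %in% c("LVEF", "RVEF")) {
    ct <- if (parameter == "LVEF") "lv_endo" else "rv_endo"
    vols <- function(col) {
      case <- structure(list(slices = purrr::compact(pair[[col]]),
                             geometry = geom), class = "cmr_case")
      c(edv = chamber_volume(case, ct, "ED"), esv = chamber_volume(case, ct, "ES"))
    }
    v1 <- vols("slice_r1"); v2 <- vols("slice_r2")
    if (v1["edv"] <= 0 || v2["edv"] <= 0)
      stop("trace error: EF undefined (EDV = 0) for a reader", call. = FALSE)
    ef1 <- 100 * (v1["edv"] - v1["esv"]) / v1["edv"]
    ef2 <- 100 * (v2["edv"] - v2["esv"]) / v2["edv"]
    edv_m <- mean(c(v1["edv"], v2["edv"])); esv_m <- mean(c(v1["esv"], v2["esv"]))
    rows <- dplyr::bind_rows(
      trace_rows(pair, ct, "ED", (100 * esv_m / edv_m^2) * D / 1000, metrics),
      trace_rows(pair, ct, "ES", -(100 / edv_m) * D / 1000, metrics))
    resid <- (ef1 - ef2) - sum(rows$contribution)
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      slice_index = NA_integer_, phase = NA_character_, ctype = "nonlinearity",
      contribution = resid, dice = NA_real_, hd_mm = NA_real_))
    return(finish_trace(rows, ef1 - ef2, parameter, "%"))
  }
  if (parameter == "SCARF") {
    case_of <- function(col, reader) {
      cmr_case(attr(pair, "case_id"), reader, seqn, geom,
               purrr::compact(pair[[col]]), validate = FALSE)
    }
    c1 <- case_of("slice_r1", "r1"); c2 <- case_of("slice_r2", "r2")
    s1 <- scar_mass_fraction(c1); s2 <- scar_mass_fraction(c2)
    lvm1 <- myocardial_mass(c1, "single"); lvm2 <- myocardial_mass(c2, "single")
    scarm_m <- mean(c(s1$scarm, s2$scarm)); lvm_m <- mean(c(lvm1, lvm2))
    w <- D / 1000 * MYO_DENSITY
    rows <- dplyr::bind_rows(
      trace_rows(pair, "scar_in_myo", "single", (100 / lvm_m) * w, metrics),
      trace_rows(pair, "myo", "single", -(100 * scarm_m / lvm_m^2) * w, metrics))
    resid <- (s1$scarf - s2$scarf) - sum(rows$contribution)
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      slice_index = NA_integer_, phase = NA_character_, ctype = "nonlinearity",
      contribution = resid, dice = NA_real_, hd_mm = NA_real_))
    return(finish_trace(rows, s1$scarf - s2$scarf, parameter, "%"))
  }
  if (parameter %in% c("GLOBAL_T1", "GLOBAL_T2")) {
    stat <- function(slice) {
      if (is.null(slice) || is.null(slice$value_map)) return(c(0, 0))
      m <- ring_membership(slice)
      if (!any(m)) return(c(0, 0))
      c(sum(slice$value_map[m]), sum(m))
    }
    st1 <- vapply(pair$slice_r1, stat, numeric(2))
    st2 <- vapply(pair$slice_r2, stat, numeric(2))
    N1 <- sum(st1[2, ]); N2 <- sum(st2[2, ])
    if (N1 == 0 || N2 == 0)
      stop("trace error: no myocardial voxels for a reader", call. = FALSE)
    contrib <- st1[1, ] / N1 - st2[1, ] / N2
    rows <- tibble::tibble(slice_index = pair$slice_index, phase = pair$phase,
                           ctype = "myo", contribution = contrib,
                           dice = vapply(seq_len(nrow(pair)), function(i)
                             dice(slice_region(pair$slice_r1[[i]], "myo"),
                                  slice_region(pair$slice_r2[[i]], "myo")),
                             numeric(1)),
                           hd_mm = NA_real_)
    return(finish_trace(rows, sum(contrib), parameter, "ms"))
  }
  stop("trace error: no tracing rule for parameter '", parameter, "'",
       call. = FALSE)
}

#' Per-case annotation metric table
#'
#' One row per (slice, phase, contour type) with Dice, Hausdorff
#' distance, both readers' areas, the per-slice milliliter impact, and
#' the cardiac position of the slice.
#'
#' @param pair A [pair_cases()] result.
#' @param policy Which reader defines base and apex for the position
#'   column.
#' @return A tibble of metric rows.
#' @export
case_table <- function(pair, policy = c("reader1", "reader2")) {
  policy <- match.arg(policy)
  ventr <- positioned_metrics(pair, policy = policy,
                              ctypes = intersect(c("lv_endo", "myo", "rv_endo"),
                                                 pair_ctypes(pair)))
  other <- setdiff(pair_ctypes(pair), c("lv_endo", "myo", "rv_endo"))
  if (length(other)) {
    o <- slice_metrics(pair, ctypes = other)
    o$position <- factor(NA_character_, levels = POSITION_LEVELS)
    ventr <- dplyr::bind_rows(ventr, o)
  }
  ventr
}
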