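# Clinical parameters computed from a single reader's case annotation:
# Simpson slice-summation ventricular volumes, stroke volume and ejection
# fraction, myocardial and papillary muscle mass, scar mass and fraction,
# monoplane area-length atrial volumes, and global / segmental parametric
# mapping values.

MYO_DENSITY <- 1.05  # g/ml, standard myocardial tissue density

# area (mm^2) of a given contour type on one slice; derived "myo" and
# scar-clipped variants handled by slice_region()
slice_ctype_area <- function(slice, ctype, geom) {
  r <- slice_region(slice, ctype)
  if (is.null(r)) 0 else region_area_mm2(r, geom)
}

case_slices <- function(case, phase = NULL) {
  if (is.null(phase)) return(case$slices)
  Filter(function(s) s$phase == phase, case$slices)
}

#' Simpson slice-summation chamber volume
#'
#' Sum over slices of contour area times the inter-slice distance
#' `D = slice_thickness + slice_gap`, divided by 1000 to give ml. Slices
#' on which the contour type is absent contribute 0.
#'
#' @param case A [cmr_case()].
#' @param ctype `"lv_endo"` or `"rv_endo"` (any polygon type accepted).
#' @param phase Cardiac phase label stored in the slices (`"ES"`, `"ED"`,
#'   `"single"`).
#' @return Volume in ml.
#' @export
chamber_volume <- function(case, ctype, phase) {
  slices <- case_slices(case, phase)
  if (!length(slices))
    stop("missing-phase error: no slices with phase '", phase, "'", call. = FALSE)
  geom <- case$geometry
  areas <- vapply(slices, function(s) {
    r <- as_region(s$contours[[ctype]])
    if (!length(r)) 0 else polygon_area(r, geom)
  }, numeric(1))
  sum(areas) * slice_distance(geom) / 1000
}

# ring area per slice with the epi-smaller-than-endo case clamped to 0
ring_area <- function(slice, geom) {
  epi <- as_region(slice$contours[["lv_epi"]])
  if (!length(epi)) return(0)
  endo <- as_region(slice$contours[["lv_endo"]])
  ring <- region_minus(epi, endo)
  a <- if (length(ring)) region_area_mm2(ring, geom) else 0
  max(a, 0)
}

#' Left-ventricular myocardial mass
#'
#' Ring volume (epicardial area minus endocardial area per slice, Simpson
#' summation) times the myocardial tissue density 1.05 g/ml. Slices where
#' the epicardial contour lies inside the endocardial one contribute 0
#' with a warning.
#'
#' @inheritParams chamber_volume
#' @return Mass in g.
#' @export
myocardial_mass <- function(case, phase) {
  slices <- case_slices(case, phase)
  geom <- case$geometry
  has_epi <- vapply(slices, function(s) length(as_region(s$contours[["lv_epi"]])) > 0, logical(1))
  if (!any(has_epi))
    stop("missing-contour error: no lv_epi contours in phase '", phase, "'", call. = FALSE)
  areas <- vapply(slices, function(s) {
    epi <- as_region(s$contours[["lv_epi"]])
    if (!length(epi)) return(0)
    a_epi <- polygon_area(epi, geom)
    a_endo <- polygon_area(as_region(s$contours[["lv_endo"]]), geom)
    if (a_endo > a_epi)
      warning("geometry warning: endocardial area exceeds epicardial area on slice ",
              s$slice_index, "; ring clamped at 0", call. = FALSE)
    ring_area(s, geom)
  }, numeric(1))
  sum(areas) * slice_distance(geom) / 1000 * MYO_DENSITY
}

#' Papillary muscle mass
#'
#' Simpson summation over `papmu` contour areas times 1.05 g/ml.
#'
#' @inheritParams chamber_volume
#' @return Mass in g.
#' @export
papillary_mass <- function(case, phase) {
  geom <- case$geometry
  areas <- vapply(case_slices(case, phase), function(s) {
    polygon_area(as_region(s$contours[["papmu"]]), geom)
  }, numeric(1))
  sum(areas) * slice_distance(geom) / 1000 * MYO_DENSITY
}

#' Stroke volume and ejection fraction
#'
#' `SV = EDV - ESV`; `EF = 100 * SV / EDV` (%). EF is `NA` when EDV = 0.
#' A negative SV (ESV > EDV) is returned as-is with a warning.
#'
#' @param edv,esv End-diastolic and end-systolic volumes in ml.
#' @return Named list `sv` (ml) and `ef` (%).
#' @export
sv_ef <- function(edv, esv) {
  stopifnot(edv >= 0, esv >= 0)
  sv <- edv - esv
  if (sv < 0) warning("ESV exceeds EDV; stroke volume is negative", call. = FALSE)
  ef <- if (edv > 0) 100 * sv / edv else NA_real_
  list(sv = sv, ef = ef)
}

#' Scar mass and scar fraction from an LGE case
#'
#' `SCARM` is the Simpson summation over per-slice scar areas (each scar
#' polygon clipped to the myocardial ring of its slice, so scar reaching
#' into the cavity or outside the epicardium does not count) times
#' 1.05 g/ml. `SCARF = 100 * SCARM / LVM` (%).
#'
#' @param case A [cmr_case()] of an LGE stack (single phase).
#' @param phase Phase label, default `"single"`.
#' @return Named list `scarm` (g) and `scarf` (%).
#' @export
scar_mass_fraction <- function(case, phase = "single") {
  geom <- case$geometry
  slices <- case_slices(case, phase)
  areas <- vapply(slices, function(s) {
    scar <- as_region(s$contours[["scar"]])
    if (!length(scar)) return(0)
    epi <- as_region(s$contours[["lv_epi"]])
    ring <- region_minus(epi, as_region(s$contours[["lv_endo"]]))
    region_area_mm2(region_intersect(scar, ring), geom)
  }, numeric(1))
  scarm <- sum(areas) * slice_distance(geom) / 1000 * MYO_DENSITY
  if (scarm == 0) return(list(scarm = 0, scarf = 0))
  lvm <- myocardial_mass(case, phase)
  if (lvm == 0)
    stop("undefined-fraction error: scar mass > 0 with zero myocardial mass",
         call. = FALSE)
  list(scarm = scarm, scarf = 100 * scarm / lvm)
}

#' Atrial area on a long-axis slice
#'
#' Total polygon area of the atrial contour in cm^2 (fragments add).
#' Returns `NA` (missing, distinct from 0) when the contour is absent.
#'
#' @param case A long-axis [cmr_case()].
#' @param ctype `"la"` or `"ra"`.
#' @param phase `"ES"` or `"ED"`.
#' @return Area in cm^2, or `NA` if the contour is absent.
#' @export
atrial_area <- function(case, ctype, phase) {
  slices <- case_slices(case, phase)
  if (!length(slices)) return(NA_real_)
  a <- sum(vapply(slices, slice_ctype_area, numeric(1), ctype = ctype,
                  geom = case$geometry))
  has <- any(vapply(slices, function(s) length(as_region(s$contours[[ctype]])) > 0,
                    logical(1)))
  if (!has) return(NA_real_)
  a / 100
}

#' Monoplane area-length ellipsoid atrial volume
#'
#' `V = 8 A^2 / (3 pi L)` with the area `A` in cm^2 and the long-axis
#' length `L` in cm; the result is in ml. For a circular contour
#' (`A = pi r^2`, `L = 2 r`) this reduces to the sphere volume
#' `(4/3) pi r^3`.
#'
#' @param area Atrial area in cm^2 (>= 0).
#' @param length Long-axis length in cm (> 0).
#' @return Volume in ml.
#' @export
atrial_volume <- function(area, length) {
  if (is.na(area) || is.na(length)) return(NA_real_)
  stopifnot(area >= 0)
  if (length <= 0) stop("undefined: atrial length must be > 0", call. = FALSE)
  8 * area^2 / (3 * pi * length)
}

#' Long-axis length of an atrial contour
#'
#' Maximum caliper diameter of the contour (largest pairwise boundary
#' distance) in cm, the default length for [atrial_volume()].
#'
#' @inheritParams atrial_area
#' @return Length in cm, or `NA` if absent.
#' @export
atrial_length <- function(case, ctype, phase) {
  slices <- case_slices(case, phase)
  geom <- case$geometry
  for (s in slices) {
    r <- as_region(s$contours[[ctype]])
    if (length(r))
      return(max_caliper(r, c(geom$spacing_col, geom$spacing_row)) / 10)
  }
  NA_real_
}

# voxel centers (col, row) of a value map: voxel (i, j), 1-based matrix
# indices, has center (row = i - 1, col = j - 1)
voxel_centers <- function(value_map) {
  nr <- nrow(value_map); nc <- ncol(value_map)
  cbind(col = rep(seq_len(nc) - 1, each = nr), row = rep(seq_len(nr) - 1, nc))
}

# logical membership of each voxel center in the myocardial ring
ring_membership <- function(slice) {
  epi <- as_region(slice$contours[["lv_epi"]])
  endo <- as_region(slice$contours[["lv_endo"]])
  if (!length(epi)) stop("missing-contour error: lv_epi required", call. = FALSE)
  pts <- voxel_centers(slice$value_map)
  inside <- point_in_region(pts, epi)
  if (length(endo)) inside <- inside & !point_in_region(pts, endo)
  matrix(inside, nrow = nrow(slice$value_map))
}

#' Global parametric mapping value of a slice
#'
#' Mean voxel value (ms) over voxels whose centers lie inside the
#' myocardial ring (epicardial minus endocardial contour).
#'
#' @param slice A [cmr_slice()] with `value_map`, `lv_endo` and `lv_epi`.
#' @return Mean value in ms.
#' @export
global_mapping_value <- function(slice) {
  if (is.null(slice$value_map))
    stop("missing value_map on slice ", slice$slice_index, call. = FALSE)
  m <- ring_membership(slice)
  if (!any(m))
    stop("empty-region error: no voxel center inside the myocardial ring",
         call. = FALSE)
  mean(slice$value_map[m])
}

#' Angular myocardial segment values on a mapping slice
#'
#' Partitions the myocardial ring voxels into `n_segments` equal angular
#' sectors about the LV centroid (centroid of the epicardial contour).
#' Sector 1 starts at the ray through the reference point and sectors
#' proceed counterclockwise in (col, row) image coordinates. The sectors
#' partition the ring voxels exactly.
#'
#' @param slice A [cmr_slice()] with `value_map`, myocardial contours and
#'   a `refpoint`.
#' @param geom A [cmr_geometry()] (used for the centroid/angles in pixel
#'   space; sector assignment is spacing-independent by construction).
#' @param n_segments Number of sectors (default 6).
#' @return A tibble: `segment_index`, `mean` (ms), `sd` (ms),
#'   `voxel_count`.
#' @export
aha_segments <- function(slice, geom, n_segments = 6) {
  rp <- slice$contours[["refpoint"]]
  if (is.null(rp))
    stop("reference-point error: slice has no refpoint contour", call. = FALSE)
  rp <- rp[[1]][1, ]
  m <- ring_membership(slice)
  epi <- as_region(slice$contours[["lv_epi"]])[[1]]
  ctr <- polygon_centroid(epi)
  pts <- voxel_centers(slice$value_map)[as.vector(m), , drop = FALSE]
  vals <- slice$value_map[m]
  ang <- atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1])
  ang0 <- atan2(rp[2] - ctr[2], rp[1] - ctr[1])
  rel <- (ang - ang0) %% (2 * pi)
  rel[rel > 2 * pi - 1e-9] <- 0  # voxels numerically on the refpoint ray
  seg <- pmin(floor(rel / (2 * pi / n_segments)) + 1, n_segments)
  out <- tibble::tibble(segment_index = seq_len(n_segments))
  agg <- tibble::tibble(segment_index = seg, value = vals) |>
    dplyr::group_by(.data$segment_index) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
                     voxel_count = dplyr::n(), .groups = "drop")
  dplyr::left_join(out, agg, by = "segment_index") |>
    dplyr::mutate(voxel_count = dplyr::coalesce(.data$voxel_count, 0L))
}

#' Distance between two readers' reference points
#'
#' Euclidean distance in mm using the anisotropic pixel spacing.
#'
#' @param s1,s2 Two [cmr_slice()] objects with `refpoint` contours.
#' @param geom A [cmr_geometry()].
#' @return Distance in mm, or `NA` when either refpoint is missing.
#' @export
refpoint_distance <- function(s1, s2, geom) {
  p1 <- s1$contours[["refpoint"]]; p2 <- s2$contours[["refpoint"]]
  if (is.null(p1) || is.null(p2)) return(NA_real_)
  p1 <- p1[[1]][1, ]; p2 <- p2[[1]][1, ]
  sqrt(((p1[1] - p2[1]) * geom$spacing_col)^2 +
       ((p1[2] - p2[2]) * geom$spacing_row)^2)
}

#' All clinical parameters of a case
#'
#' Computes every parameter defined for the case's sequence type:
#' * `sax_cine`: LVESV, LVEDV, LVSV, LVEF, RVESV, RVEDV, RVSV, RVEF,
#'   LVM (ED), PAPMU_ES, PAPMU_ED
#' * `sax_lge`: LVV, LVM, SCARM, SCARF
#' * `sax_t1` / `sax_t2`: GLOBAL_T1 / GLOBAL_T2 (voxel-count-weighted
#'   pooled mean over mapping slices)
#' * `lax_2cv`: LAES_Area, LAED_Area, LAESV, LAEDV
#' * `lax_4cv`: the 2CV set plus RAES_Area, RAED_Area, RAESV, RAEDV
#'
#' Parameters whose ingredients are absent are returned as `NA` rather
#' than dropped.
#'
#' @param case A [cmr_case()].
#' @return A tibble: `case_id`, `reader_id`, `parameter`, `value`, `unit`.
#' @export
clinical_parameters <- function(case) {
  p <- list()
  add <- function(name, value, unit) {
    p[[length(p) + 1]] <<- tibble::tibble(parameter = name,
                                          value = as.numeric(value), unit = unit)
  }
  seqn <- case$sequence
  if (seqn == "sax_cine") {
    lvesv <- chamber_volume(case, "lv_endo", "ES")
    lvedv <- chamber_volume(case, "lv_endo", "ED")
    rvesv <- chamber_volume(case, "rv_endo", "ES")
    rvedv <- chamber_volume(case, "rv_endo", "ED")
    lv <- sv_ef(lvedv, lvesv); rv <- sv_ef(rvedv, rvesv)
    add("LVESV", lvesv, "ml"); add("LVEDV", lvedv, "ml")
    add("LVSV", lv$sv, "ml"); add("LVEF", lv$ef, "%")
    add("RVESV", rvesv, "ml"); add("RVEDV", rvedv, "ml")
    add("RVSV", rv$sv, "ml"); add("RVEF", rv$ef, "%")
    lvm <- tryCatch(myocardial_mass(case, "ED"), error = function(e) NA_real_)
    add("LVM", lvm, "g")
    add("PAPMU_ES", papillary_mass(case, "ES"), "g")
    add("PAPMU_ED", papillary_mass(case, "ED"), "g")
  } else if (seqn == "sax_lge") {
    add("LVV", chamber_volume(case, "lv_endo", "single"), "ml")
    lvm <- tryCatch(myocardial_mass(case, "single"), error = function(e) NA_real_)
    add("LVM", lvm, "g")
    sc <- scar_mass_fraction(case)
    add("SCARM", sc$scarm, "g"); add("SCARF", sc$scarf, "%")
  } else if (seqn %in% c("sax_t1", "sax_t2")) {
    name <- if (seqn == "sax_t1") "GLOBAL_T1" else "GLOBAL_T2"
    vals <- ns <- numeric(0)
    for (s in case$slices) {
      if (is.null(s$value_map)) next
      m <- ring_membership(s)
      if (any(m)) { vals <- c(vals, mean(s$value_map[m])); ns <- c(ns, sum(m)) }
    }
    add(name, if (length(vals)) sum(vals * ns) / sum(ns) else NA_real_, "ms")
  } else if (seqn %in% c("lax_2cv", "lax_4cv")) {
    atria <- if (seqn == "lax_4cv") c("la", "ra") else "la"
    for (at in atria) {
      pre <- toupper(at)
      for (ph in c("ES", "ED")) {
        a <- atrial_area(case, at, ph)
        add(paste0(pre, ph, "_Area"), a, "cm²")
        len <- atrial_length(case, at, ph)
        v <- if (is.na(a) || is.na(len)) NA_real_ else atrial_volume(a, len)
        add(paste0(pre, ph, "V"), v, "ml")
      }
    }
  }
  out <- dplyr::bind_rows(p)
  tibble::tibble(case_id = case$case_id, reader_id = case$reader_id, out)
}
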