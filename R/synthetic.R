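# Synthetic phantom cohorts with analytic ground truth. The phantom is a
# stack of tapering circular LV sections with a concentric epicardial
# ring, a crescent-shaped RV sharing the septal wall, papillary muscle
# disks, optional scar wedges (LGE), single-slice parametric maps with a
# reference point (T1/T2), and elliptical atria (LAX). A second reader is
# emulated by a parameterized perturbation model: per-vertex radial
# Gaussian noise, systematic dilation, basal-slice omission/addition,
# fragmentation and reference-point shift.
#
# Geometry is constructed in millimetres around the image center and then
# converted to pixel coordinates with the anisotropic spacing; ground
# truth is computed from the emitted polygons (exact) and from closed
# forms for the continuous phantom (analytic).

#' Phantom geometry parameters
#'
#' Defaults emulate a typical adult short-axis cine study: an LV
#' end-diastolic cavity radius of 30 mm at the base tapering linearly to
#' 40% at the apex over 8 annotated slices, an 8 mm myocardial wall, end
#' systole as a uniform radial scaling of 0.65 (ejection fraction about
#' 58%), 8 mm slices with a 2 mm gap and 1.4 mm in-plane spacing. The
#' most basal image (slice index 0) is left unannotated so that a
#' perturbed reader can add an extra basal slice there.
#'
#' @param n_slices Number of annotated slices (indices 1..n_slices).
#' @param base_radius LV endocardial radius at the base in mm (ED).
#' @param apex_taper Fraction of the basal radius removed at the apex
#'   (`[0, 1)`); radii vary linearly base to apex.
#' @param wall_thickness Myocardial wall thickness in mm.
#' @param rv_scale RV circle radius as a fraction of the epicardial
#'   radius.
#' @param es_scale Radial scale factor applied at end systole.
#' @param slice_thickness,slice_gap,spacing_row,spacing_col Geometry in mm.
#' @param papmu_radius Papillary muscle disk radius in mm (two disks; 0
#'   disables them).
#' @param n_vertices Vertices per generated polygon (>= 180 keeps
#'   discretization error below 0.1%).
#' @param map_myo,map_noise_sd,map_blood,map_fat Parametric-map field:
#'   myocardial mean (ms), voxel noise SD, blood-pool and surround
#'   values.
#' @param map_size Value-map grid side length in voxels.
#' @param scar_angle,scar_depth Scar wedge angular width (radians) and
#'   transmural depth fraction for LGE phantoms.
#' @param atrium_a,atrium_b Atrial ellipse semi-axes in mm at atrial
#'   end-systole; at ED the atrium is scaled by `atrium_ed_scale`.
#' @param atrium_ed_scale Radial scale of the atrium at ventricular ED.
#' @param anatomy_cv Per-case coefficient of variation of the overall
#'   heart size (log-normal scale on radii) emulating inter-patient
#'   anatomical spread.
#' @param es_sd Per-case SD of the end-systolic scale factor (contractile
#'   variability between patients).
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(n_slices = 8, base_radius = 30, apex_taper = 0.6,
                           wall_thickness = 8, rv_scale = 1.0, es_scale = 0.65,
                           slice_thickness = 8, slice_gap = 2,
                           spacing_row = 1.4, spacing_col = 1.4,
                           papmu_radius = 4, n_vertices = 180,
                           map_myo = 1000, map_noise_sd = 30,
                           map_blood = 1600, map_fat = 300, map_size = 128,
                           scar_angle = pi / 3, scar_depth = 1,
                           atrium_a = 30, atrium_b = 20, atrium_ed_scale = 0.75,
                           anatomy_cv = 0.08, es_sd = 0.02) {
  stopifnot(base_radius > 0, apex_taper >= 0, apex_taper < 1,
            wall_thickness > 0, es_scale > 0, es_scale <= 1,
            anatomy_cv >= 0, es_sd >= 0)
  as.list(environment())
}

#' Second-reader perturbation parameters
#'
#' @param radial_sigma Per-vertex radial Gaussian noise SD in mm.
#' @param dilation_mm Systematic radial dilation in mm; a single number
#'   applied to all polygon types or a named vector per contour type
#'   (e.g. `c(lv_endo = 1)`). Negative values erode.
#' @param p_miss_basal Probability of omitting the most basal annotated
#'   contours (per phase, for `miss_ctypes`).
#' @param p_extra_basal Probability of adding contours on the unannotated
#'   basal image (slice index 0).
#' @param p_fragment Probability of splitting a contour into two
#'   fragments (applied to `fragment_ctypes`).
#' @param refpoint_shift Reference-point displacement in mm.
#' @param miss_ctypes,fragment_ctypes Contour types affected by omission
#'   / fragmentation.
#' @return A `perturbation` list.
#' @export
perturbation <- function(radial_sigma = 0, dilation_mm = 0,
                         p_miss_basal = 0, p_extra_basal = 0, p_fragment = 0,
                         refpoint_shift = 0,
                         miss_ctypes = c("lv_endo", "lv_epi", "rv_endo"),
                         fragment_ctypes = "rv_endo") {
  stopifnot(p_miss_basal >= 0, p_miss_basal <= 1,
            p_extra_basal >= 0, p_extra_basal <= 1,
            p_fragment >= 0, p_fragment <= 1, radial_sigma >= 0)
  as.list(environment())
}

# mm -> pixel coordinate conversion about the image center
mm_to_px <- function(poly_mm, params) {
  ctr <- params$map_size / 2
  cbind(col = ctr + poly_mm[, 1] / params$spacing_col,
        row = ctr + poly_mm[, 2] / params$spacing_row)
}
px_to_mm <- function(poly_px, params) {
  ctr <- params$map_size / 2
  cbind((poly_px[, 1] - ctr) * params$spacing_col,
        (poly_px[, 2] - ctr) * params$spacing_row)
}

# LV endocardial radius of annotated slice i (1-based), ED, in mm
lv_radius <- function(params, i) {
  f <- if (params$n_slices == 1) 0 else (i - 1) / (params$n_slices - 1)
  params$base_radius * (1 - params$apex_taper * f)
}

# RV crescent polygon (mm): disk sharing the septal wall, minus the
# epicardial disk
rv_crescent_mm <- function(re, params) {
  rrv <- params$rv_scale * re
  ctr <- c(-(0.9 * re + 0.35 * rrv), 0)  # septal side
  rv <- circle_polygon(ctr, rrv, params$n_vertices)
  epi <- circle_polygon(c(0, 0), re, params$n_vertices)
  out <- region_minus(list(rv), list(epi))
  if (!length(out)) return(NULL)
  out[[which.max(vapply(out, function(p) abs(shoelace_area(p)), numeric(1)))]]
}

# build one annotated cine slice (contours in mm)
cine_slice_mm <- function(params, i, phase) {
  scale <- if (phase == "ES") params$es_scale else 1
  r <- lv_radius(params, i) * scale
  re <- r + params$wall_thickness
  contours <- list(
    lv_endo = list(circle_polygon(c(0, 0), r, params$n_vertices)),
    lv_epi = list(circle_polygon(c(0, 0), re, params$n_vertices)))
  rv <- rv_crescent_mm(re, params)
  if (!is.null(rv)) contours$rv_endo <- list(rv)
  if (params$papmu_radius > 0 && r > 3 * params$papmu_radius) {
    off <- 0.5 * r
    contours$papmu <- list(
      circle_polygon(c(off, 0), params$papmu_radius, 60L),
      circle_polygon(c(-off, 0), params$papmu_radius, 60L))
  }
  contours
}

#' Generate a synthetic phantom case with ground truth
#'
#' Deterministic given `seed`. The returned truth table carries, for
#' every clinical parameter of the sequence, the exact value computed
#' from the emitted polygons (by direct shoelace summation, independent
#' of the annotation pipeline) and the analytic value of the continuous
#' phantom (closed forms; disks and ellipses).
#'
#' @param params A [phantom_params()].
#' @param seed Integer seed.
#' @param sequence Sequence type to synthesize.
#' @param case_id Case identifier.
#' @param reader_id Reader identifier for the emitted annotation.
#' @return List with elements `case` (a [cmr_case()]) and `truth`
#'   (tibble: `parameter`, `exact`, `analytic`, `unit`).
#' @export
generate_case <- function(params = phantom_params(), seed = 1,
                          sequence = "sax_cine",
                          case_id = sprintf("phantom-%03d", seed),
                          reader_id = "R1") {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  # per-case anatomy: overall size and contractility vary across cases
  f <- exp(stats::rnorm(1, 0, params$anatomy_cv))
  params$base_radius <- params$base_radius * f
  params$atrium_a <- params$atrium_a * f
  params$atrium_b <- params$atrium_b * f
  params$es_scale <- min(max(params$es_scale + stats::rnorm(1, 0, params$es_sd),
                             0.4), 0.95)
  geom <- cmr_geometry(params$spacing_row, params$spacing_col,
                       params$slice_thickness, params$slice_gap)
  D <- params$slice_thickness + params$slice_gap
  area_mm <- function(poly) abs(shoelace_area(poly))
  slices <- list(); truth <- list()
  add_truth <- function(name, exact, analytic, unit) {
    truth[[length(truth) + 1]] <<- tibble::tibble(
      parameter = name, exact = exact, analytic = analytic, unit = unit)
  }

  if (sequence == "sax_cine") {
    per <- list()
    for (ph in c("ES", "ED")) {
      for (i in seq_len(params$n_slices)) {
        cont_mm <- cine_slice_mm(params, i, ph)
        per[[paste(ph, i)]] <- cont_mm
        cont_px <- lapply(cont_mm, function(polys) lapply(polys, mm_to_px, params = params))
        slices[[length(slices) + 1]] <- cmr_slice(i, ph, cont_px)
      }
    }
    vol <- function(ph, ctype) {
      sum(vapply(seq_len(params$n_slices), function(i) {
        polys <- per[[paste(ph, i)]][[ctype]]
        if (is.null(polys)) 0 else sum(vapply(polys, area_mm, numeric(1)))
      }, numeric(1))) * D / 1000
    }
    ring_vol <- function(ph) {
      sum(vapply(seq_len(params$n_slices), function(i) {
        cm <- per[[paste(ph, i)]]
        area_mm(cm$lv_epi[[1]]) - area_mm(cm$lv_endo[[1]])
      }, numeric(1))) * D / 1000
    }
    radii <- vapply(seq_len(params$n_slices), lv_radius, numeric(1), params = params)
    s <- params$es_scale
    an_lvedv <- sum(pi * radii^2) * D / 1000
    an_lvesv <- an_lvedv * s^2
    lvesv <- vol("ES", "lv_endo"); lvedv <- vol("ED", "lv_endo")
    rvesv <- vol("ES", "rv_endo"); rvedv <- vol("ED", "rv_endo")
    add_truth("LVESV", lvesv, an_lvesv, "ml")
    add_truth("LVEDV", lvedv, an_lvedv, "ml")
    add_truth("LVSV", lvedv - lvesv, an_lvedv - an_lvesv, "ml")
    add_truth("LVEF", 100 * (lvedv - lvesv) / lvedv, 100 * (1 - s^2), "%")
    add_truth("RVESV", rvesv, NA_real_, "ml")
    add_truth("RVEDV", rvedv, NA_real_, "ml")
    add_truth("RVSV", rvedv - rvesv, NA_real_, "ml")
    add_truth("RVEF", 100 * (rvedv - rvesv) / rvedv, NA_real_, "%")
    an_lvm <- sum(pi * ((radii + params$wall_thickness)^2 - radii^2)) * D / 1000 * MYO_DENSITY
    add_truth("LVM", ring_vol("ED") * MYO_DENSITY, an_lvm, "g")
    pap_vol <- function(ph) {
      sum(vapply(seq_len(params$n_slices), function(i) {
        polys <- per[[paste(ph, i)]][["papmu"]]
        if (is.null(polys)) 0 else sum(vapply(polys, area_mm, numeric(1)))
      }, numeric(1))) * D / 1000
    }
    add_truth("PAPMU_ES", pap_vol("ES") * MYO_DENSITY, NA_real_, "g")
    add_truth("PAPMU_ED", pap_vol("ED") * MYO_DENSITY, NA_real_, "g")
  } else if (sequence == "sax_lge") {
    scarm_ex <- 0; lvm_ex <- 0; lvv_ex <- 0
    for (i in seq_len(params$n_slices)) {
      r <- lv_radius(params, i); re <- r + params$wall_thickness
      cont_mm <- list(lv_endo = list(circle_polygon(c(0, 0), r, params$n_vertices)),
                      lv_epi = list(circle_polygon(c(0, 0), re, params$n_vertices)))
      mid <- i > params$n_slices / 4 && i <= 3 * params$n_slices / 4
      if (mid) {
        # wedge kept strictly inside the ring polygons (0.25 mm margins)
        # so that ring-clipping is a no-op and polygon truth stays exact
        ro <- re - 0.25
        rs <- max(re - params$scar_depth * params$wall_thickness + 0.25,
                  r + 0.25)
        th <- seq(0, params$scar_angle, length.out = 60)
        wedge <- rbind(cbind(rs * cos(th), rs * sin(th)),
                       cbind(ro * cos(rev(th)), ro * sin(rev(th))))
        cont_mm$scar <- list(wedge)
      }
      cont_px <- lapply(cont_mm, function(polys) lapply(polys, mm_to_px, params = params))
      slices[[length(slices) + 1]] <- cmr_slice(i, "single", cont_px)
      lvv_ex <- lvv_ex + area_mm(cont_mm$lv_endo[[1]])
      lvm_ex <- lvm_ex + area_mm(cont_mm$lv_epi[[1]]) - area_mm(cont_mm$lv_endo[[1]])
      if (mid) scarm_ex <- scarm_ex + area_mm(cont_mm$scar[[1]])
    }
    lvv_ex <- lvv_ex * D / 1000
    lvm_ex <- lvm_ex * D / 1000 * MYO_DENSITY
    scarm_ex <- scarm_ex * D / 1000 * MYO_DENSITY
    add_truth("LVV", lvv_ex, NA_real_, "ml")
    add_truth("LVM", lvm_ex, NA_real_, "g")
    add_truth("SCARM", scarm_ex, NA_real_, "g")
    add_truth("SCARF", 100 * scarm_ex / lvm_ex, NA_real_, "%")
  } else if (sequence %in% c("sax_t1", "sax_t2")) {
    r <- params$base_radius * 0.8; re <- r + params$wall_thickness
    cont_mm <- list(lv_endo = list(circle_polygon(c(0, 0), r, params$n_vertices)),
                    lv_epi = list(circle_polygon(c(0, 0), re, params$n_vertices)))
    cont_px <- lapply(cont_mm, function(polys) lapply(polys, mm_to_px, params = params))
    # reference point on the epicardial boundary, septal side
    rp_mm <- matrix(c(-re, 0), ncol = 2)
    cont_px$refpoint <- list(mm_to_px(rp_mm, params))
    n <- params$map_size
    ctr <- n / 2
    ii <- rep(seq_len(n) - 1, times = n)  # row of each voxel, column-major
    jj <- rep(seq_len(n) - 1, each = n)   # col
    xmm <- (jj - ctr) * params$spacing_col
    ymm <- (ii - ctr) * params$spacing_row
    rad <- sqrt(xmm^2 + ymm^2)
    vm <- matrix(params$map_fat, n, n)
    vm[rad <= re] <- params$map_myo
    vm[rad < r] <- params$map_blood
    vm <- vm + stats::rnorm(n * n, 0, params$map_noise_sd)
    slices[[1]] <- cmr_slice(0, "single", cont_px, value_map = vm)
    in_ring <- rad <= re & rad >= r
    name <- if (sequence == "sax_t1") "GLOBAL_T1" else "GLOBAL_T2"
    add_truth(name, mean(vm[cbind(ii[in_ring] + 1, jj[in_ring] + 1)]),
              params$map_myo, "ms")
  } else if (sequence %in% c("lax_2cv", "lax_4cv")) {
    atria <- if (sequence == "lax_4cv") c("la", "ra") else "la"
    for (ph in c("ES", "ED")) {
      sc <- if (ph == "ES") 1 else params$atrium_ed_scale
      contours <- list()
      for (k in seq_along(atria)) {
        a <- params$atrium_a * sc; b <- params$atrium_b * sc
        th <- seq(0, 2 * pi, length.out = params$n_vertices + 1)[-(params$n_vertices + 1)]
        off <- if (k == 1) -params$atrium_a * 1.2 else params$atrium_a * 1.2
        ell <- cbind(off + a * cos(th), b * sin(th))
        contours[[atria[k]]] <- list(mm_to_px(ell, params))
        pre <- toupper(atria[k])
        ex_area <- area_mm(ell) / 100
        an_area <- pi * a * b / 100
        add_truth(paste0(pre, ph, "_Area"), ex_area, an_area, "cm²")
        add_truth(paste0(pre, ph, "V"), atrial_volume(ex_area, 2 * a / 10),
                  8 * an_area^2 / (3 * pi * 2 * a / 10), "ml")
      }
      slices[[length(slices) + 1]] <- cmr_slice(0, ph, contours)
    }
  } else {
    stop("unknown sequence: ", sequence, call. = FALSE)
  }

  case <- cmr_case(case_id, reader_id, sequence, geom, slices)
  list(case = case, truth = dplyr::bind_rows(truth))
}

# radial displacement of a polygon about its centroid, in mm space.
# Per-vertex noise on a non-convex contour can produce tiny bowtie
# crossings; those are resolved through the clipper (even-odd) and
# slivers below 0.5 mm^2 dropped, so the emitted contours stay simple.
# Returns a list of polygons (pixel coordinates).
radial_adjust <- function(poly_px, params, sigma = 0, dilation = 0) {
  pm <- px_to_mm(poly_px, params)
  ctr <- polygon_centroid(pm)
  dx <- pm[, 1] - ctr[1]; dy <- pm[, 2] - ctr[2]
  r <- sqrt(dx^2 + dy^2)
  r2 <- pmax(r + dilation + stats::rnorm(length(r), 0, sigma), 0.1)
  out <- cbind(ctr[1] + dx / r * r2, ctr[2] + dy / r * r2)
  if (sigma > 0 && polygon_self_intersects(out)) {
    simp <- polyclip::polysimplify(list(list(x = out[, 1], y = out[, 2])),
                                   filltype = "evenodd")
    polys <- paths_to_region(simp)
    polys <- polys[vapply(polys, function(p) abs(shoelace_area(p)) > 0.5,
                          logical(1))]
    if (length(polys)) return(lapply(polys, mm_to_px, params = params))
  }
  list(mm_to_px(out, params))
}

# split a polygon into two fragments left/right of its centroid with a
# 1 mm gap
fragment_polygon <- function(poly_px, params) {
  pm <- px_to_mm(poly_px, params)
  cx <- polygon_centroid(pm)[1]
  big <- 1e4
  left <- list(cbind(c(-big, cx - 0.5, cx - 0.5, -big), c(-big, -big, big, big)))
  right <- list(cbind(c(cx + 0.5, big, big, cx + 0.5), c(-big, -big, big, big)))
  out <- c(region_intersect(list(pm), left), region_intersect(list(pm), right))
  out <- out[vapply(out, function(p) abs(shoelace_area(p)) > 1, logical(1))]
  if (!length(out)) return(list(poly_px))
  lapply(out, mm_to_px, params = params)
}

#' Emulate a second reader by perturbing a phantom annotation
#'
#' Applies, deterministically given `seed`: per-vertex radial Gaussian
#' noise, systematic per-contour-type dilation, omission of the most
#' basal annotated contours, addition of contours on the unannotated
#' basal image, fragmentation, and a reference-point shift.
#'
#' @param case A [cmr_case()] produced by [generate_case()].
#' @param pert A [perturbation()].
#' @param params The [phantom_params()] used to generate `case` (needed
#'   for the mm/pixel conversion).
#' @param seed Integer seed.
#' @param reader_id Reader identifier of the emitted annotation.
#' @return A new [cmr_case()].
#' @export
perturb_reader <- function(case, pert = perturbation(), params = phantom_params(),
                           seed = 1, reader_id = "R2") {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  dil <- function(ct) {
    d <- pert$dilation_mm
    if (is.null(names(d))) return(d[1])
    if (ct %in% names(d)) unname(d[ct]) else 0
  }
  slices <- case$slices
  idx <- vapply(slices, `[[`, integer(1), "slice_index")
  basal_idx <- min(idx)
  miss <- stats::runif(1) < pert$p_miss_basal
  extra <- stats::runif(1) < pert$p_extra_basal
  out <- list()
  for (s in slices) {
    contours <- list()
    for (ct in names(s$contours)) {
      if (ct == "refpoint") {
        p <- s$contours[[ct]][[1]]
        ang <- stats::runif(1, 0, 2 * pi)
        shift_px <- c(pert$refpoint_shift * cos(ang) / case$geometry$spacing_col,
                      pert$refpoint_shift * sin(ang) / case$geometry$spacing_row)
        contours[[ct]] <- list(p + rep(shift_px, each = nrow(p)))
        next
      }
      if (miss && s$slice_index == basal_idx && ct %in% pert$miss_ctypes) next
      polys <- unlist(lapply(s$contours[[ct]], radial_adjust, params = params,
                             sigma = pert$radial_sigma, dilation = dil(ct)),
                      recursive = FALSE)
      if (ct %in% pert$fragment_ctypes && stats::runif(1) < pert$p_fragment) {
        polys <- unlist(lapply(polys, fragment_polygon, params = params),
                        recursive = FALSE)
      }
      contours[[ct]] <- polys
    }
    if (length(contours))
      out[[length(out) + 1]] <- cmr_slice(s$slice_index, s$phase, contours,
                                          s$value_map)
  }
  if (extra && basal_idx > 0) {
    for (ph in unique(vapply(slices, `[[`, character(1), "phase"))) {
      src <- Filter(function(s) s$slice_index == basal_idx && s$phase == ph, slices)
      if (!length(src)) next
      src <- src[[1]]
      contours <- list()
      for (ct in intersect(names(src$contours), pert$miss_ctypes)) {
        contours[[ct]] <- unlist(lapply(src$contours[[ct]], radial_adjust,
                                        params = params,
                                        sigma = pert$radial_sigma,
                                        dilation = dil(ct)),
                                 recursive = FALSE)
      }
      if (length(contours))
        out[[length(out) + 1]] <- cmr_slice(basal_idx - 1L, ph, contours)
    }
  }
  cmr_case(case$case_id, reader_id, case$sequence, case$geometry, out)
}

#' Generate a paired two-reader phantom cohort
#'
#' Produces `n_cases` independent phantom cases with a perturbed second
#' reader; per-case seeds are `seed + case index` (recorded in the
#' output), making the cohort reproducible from the master seed alone.
#'
#' @param n_cases Number of cases.
#' @param params A [phantom_params()].
#' @param pert A [perturbation()].
#' @param seed Master seed.
#' @param sequence Sequence type.
#' @param dir Optional output directory; when given, interchange JSON
#'   files (`<case>_<reader>.json`) and `truth.csv` are written there.
#' @return A tibble with columns `case_id`, `seed` and list-columns
#'   `case_r1`, `case_r2`, `truth`.
#' @export
generate_cohort <- function(n_cases, params = phantom_params(),
                            pert = perturbation(), seed = 1,
                            sequence = "sax_cine", dir = NULL) {
  stopifnot(n_cases >= 1)
  rows <- lapply(seq_len(n_cases), function(i) {
    s <- seed + i
    g <- generate_case(params, seed = s, sequence = sequence,
                       case_id = sprintf("phantom-%03d", i))
    r2 <- perturb_reader(g$case, pert, params, seed = s + 500000L)
    tibble::tibble(case_id = g$case$case_id, seed = s,
                   case_r1 = list(g$case), case_r2 = list(r2),
                   truth = list(g$truth))
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(out))) {
      save_case(out$case_r1[[i]], file.path(dir, paste0(out$case_id[i], "_R1.json")))
      save_case(out$case_r2[[i]], file.path(dir, paste0(out$case_id[i], "_R2.json")))
    }
    truth <- dplyr::bind_rows(lapply(seq_len(nrow(out)), function(i)
      tibble::tibble(case_id = out$case_id[i], seed = out$seed[i], out$truth[[i]])))
    readr::write_csv(truth, file.path(dir, "truth.csv"))
  }
  out
}
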