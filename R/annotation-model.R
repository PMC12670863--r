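# Annotation data model: one reader's contours for one case/sequence plus
# the image geometry, with a JSON interchange format for exchange between
# tools and readers.

CTYPES <- c("lv_endo", "lv_epi", "rv_endo", "la", "ra", "scar", "papmu", "refpoint")
SEQUENCES <- c("sax_cine", "sax_t1", "sax_t2", "sax_lge", "lax_2cv", "lax_4cv")
PHASES <- c("ES", "ED", "single")

#' Image geometry of a contoured stack
#'
#' @param spacing_row,spacing_col In-plane pixel spacing in mm/pixel.
#' @param slice_thickness Slice thickness in mm.
#' @param slice_gap Gap between slices in mm (0 for contiguous stacks).
#'   The inter-slice distance used by Simpson slice-summation volumetry is
#'   `slice_thickness + slice_gap`.
#' @return A `cmr_geometry` list.
#' @export
cmr_geometry <- function(spacing_row, spacing_col, slice_thickness, slice_gap = 0) {
  stopifnot(spacing_row > 0, spacing_col > 0, slice_thickness > 0, slice_gap >= 0)
  structure(list(spacing_row = spacing_row, spacing_col = spacing_col,
                 slice_thickness = slice_thickness, slice_gap = slice_gap),
            class = "cmr_geometry")
}

# inter-slice distance D in mm
slice_distance <- function(geom) geom$slice_thickness + geom$slice_gap

#' One annotated slice
#'
#' @param slice_index Integer >= 0; 0 is the most basal position in the
#'   stack, indices ascend towards the apex.
#' @param phase `"ES"`, `"ED"` or `"single"` for single-phase sequences.
#' @param contours Named list mapping contour type to a list of polygon
#'   matrices (n x 2, columns col/row, continuous 0-based pixel
#'   coordinates, implicitly closed). A list of length > 1 encodes a
#'   fragmented segmentation. `refpoint` contours carry exactly one point.
#' @param value_map Optional numeric matrix of voxel values (ms) for
#'   parametric mapping slices; voxel (i, j) has its center at pixel
#'   coordinate (row = i - 1, col = j - 1).
#' @return A `cmr_slice` list.
#' @export
cmr_slice <- function(slice_index, phase = "single", contours = list(), value_map = NULL) {
  structure(list(slice_index = as.integer(slice_index), phase = phase,
                 contours = contours, value_map = value_map),
            class = "cmr_slice")
}

#' One reader's annotation of one case
#'
#' @param case_id,reader_id Identifiers.
#' @param sequence One of `sax_cine`, `sax_t1`, `sax_t2`, `sax_lge`,
#'   `lax_2cv`, `lax_4cv`.
#' @param geometry A [cmr_geometry()].
#' @param slices List of [cmr_slice()] objects; `(slice_index, phase)`
#'   pairs must be unique.
#' @param validate Check all model invariants (default `TRUE`).
#' @return A validated `cmr_case` object.
#' @export
cmr_case <- function(case_id, reader_id, sequence, geometry, slices = list(),
                     validate = TRUE) {
  x <- structure(list(case_id = case_id, reader_id = reader_id,
                      sequence = sequence, geometry = geometry, slices = slices),
                 class = "cmr_case")
  if (validate) validate_case(x)
  x
}

#' @export
print.cmr_case <- function(x, ...) {
  cat(sprintf("<cmr_case> %s / reader %s / %s: %d slice(s)\n",
              x$case_id, x$reader_id, x$sequence, length(x$slices)))
  invisible(x)
}

#' Validate a case annotation against the data-model invariants
#'
#' Checks identifiers, geometry positivity, slice key uniqueness, contour
#' types, polygon vertex counts, finiteness, self-intersection, and the
#' single-point refpoint rule.
#'
#' @param case A `cmr_case`.
#' @return The case, invisibly; otherwise an error naming the failing
#'   field or slice/contour type.
#' @export
validate_case <- function(case) {
  if (!is.character(case$case_id) || !nzchar(case$case_id))
    stop("validation error: field 'case_id' must be a non-empty string", call. = FALSE)
  if (!is.character(case$reader_id) || !nzchar(case$reader_id))
    stop("validation error: field 'reader_id' must be a non-empty string", call. = FALSE)
  if (!case$sequence %in% SEQUENCES)
    stop(sprintf("validation error: field 'sequence' must be one of %s",
                 paste(SEQUENCES, collapse = ", ")), call. = FALSE)
  g <- case$geometry
  if (!inherits(g, "cmr_geometry"))
    stop("validation error: field 'geometry' is not a cmr_geometry", call. = FALSE)
  keys <- vapply(case$slices, function(s) paste(s$slice_index, s$phase), character(1))
  if (anyDuplicated(keys))
    stop("validation error: duplicate (slice_index, phase) pairs", call. = FALSE)
  for (s in case$slices) {
    if (s$slice_index < 0)
      stop("validation error: field 'slice_index' must be >= 0", call. = FALSE)
    if (!s$phase %in% PHASES)
      stop("validation error: field 'phase' must be ES, ED or single", call. = FALSE)
    for (ct in names(s$contours)) {
      if (!ct %in% CTYPES)
        stop(sprintf("validation error: unknown contour type '%s'", ct), call. = FALSE)
      polys <- s$contours[[ct]]
      if (ct == "refpoint") {
        if (length(polys) != 1 || nrow(polys[[1]]) != 1)
          stop(sprintf("geometry error: slice %d refpoint must be a single point",
                       s$slice_index), call. = FALSE)
        next
      }
      for (p in polys) {
        if (!all(is.finite(p)))
          stop(sprintf("geometry error: slice %d/%s has non-finite coordinates",
                       s$slice_index, ct), call. = FALSE)
        if (nrow(p) < 3)
          stop(sprintf("geometry error: slice %d/%s polygon has fewer than 3 points",
                       s$slice_index, ct), call. = FALSE)
        if (polygon_self_intersects(p))
          stop(sprintf("geometry error: slice %d/%s polygon is self-intersecting",
                       s$slice_index, ct), call. = FALSE)
      }
    }
    if (!is.null(s$value_map) && !is.matrix(s$value_map))
      stop("validation error: field 'value_map' must be a numeric matrix", call. = FALSE)
  }
  invisible(case)
}

#' Read a case annotation from the JSON interchange format
#'
#' The format stores, per case and reader, the geometry and a list of
#' slices with contours as arrays of `[col, row]` vertex pairs and an
#' optional row-major voxel value map. A machine-readable JSON schema
#' ships in `system.file("extdata", "case-schema.json", package = "cmrqa")`.
#'
#' @param path Path to a JSON file.
#' @return A validated [cmr_case()].
#' @export
load_case <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path, call. = FALSE)
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("case_id", "reader_id", "sequence", "geometry", "slices"))
    if (is.null(j[[f]])) stop("validation error: missing field '", f, "'", call. = FALSE)
  for (f in c("spacing_row", "spacing_col", "slice_thickness", "slice_gap"))
    if (is.null(j$geometry[[f]]))
      stop("validation error: missing field 'geometry.", f, "'", call. = FALSE)
  geom <- cmr_geometry(j$geometry$spacing_row, j$geometry$spacing_col,
                       j$geometry$slice_thickness, j$geometry$slice_gap)
  slices <- lapply(j$slices, function(s) {
    contours <- lapply(s$contours, function(polys) {
      lapply(polys, function(pts) {
        m <- do.call(rbind, lapply(pts, function(p) c(p[[1]], p[[2]])))
        colnames(m) <- c("col", "row")
        m
      })
    })
    vm <- NULL
    if (!is.null(s$value_map)) {
      shape <- unlist(s$value_map$shape)
      vm <- matrix(unlist(s$value_map$values), nrow = shape[1], ncol = shape[2],
                   byrow = TRUE)
    }
    cmr_slice(s$slice_index, s$phase, contours, vm)
  })
  cmr_case(j$case_id, j$reader_id, j$sequence, geom, slices)
}

#' Write a case annotation to the JSON interchange format
#'
#' Numbers are serialized at full double precision so that
#' `load_case(save_case(x))` is the identity on the data model.
#'
#' @param case A valid [cmr_case()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_case <- function(case, path) {
  validate_case(case)
  slices <- lapply(case$slices, function(s) {
    out <- list(slice_index = s$slice_index, phase = s$phase,
                contours = lapply(s$contours, function(polys) {
                  lapply(polys, function(p) lapply(seq_len(nrow(p)), function(i) c(p[i, 1], p[i, 2])))
                }))
    if (!is.null(s$value_map)) {
      out$value_map <- list(shape = dim(s$value_map),
                            values = as.vector(t(s$value_map)))
    }
    out
  })
  j <- list(case_id = case$case_id, reader_id = case$reader_id,
            sequence = case$sequence,
            geometry = case$geometry[c("spacing_row", "spacing_col",
                                       "slice_thickness", "slice_gap")],
            slices = slices)
  txt <- jsonlite::toJSON(j, auto_unbox = TRUE, digits = NA, null = "null")
  ok <- tryCatch({ writeLines(txt, path); TRUE }, error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) stop("I/O error: cannot write to ", path, call. = FALSE)
  invisible(path)
}

#' Align the slices of two readers' annotations of the same case
#'
#' Produces one row per `(slice_index, phase)` key present in either
#' reader; a side on which the key is missing is marked absent (`NULL`
#' slice, `present_* = FALSE`).
#'
#' @param r1,r2 Two [cmr_case()] objects with identical `case_id`,
#'   `sequence` and geometry.
#' @return A tibble with columns `slice_index`, `phase`, `present_r1`,
#'   `present_r2` and list-columns `slice_r1`, `slice_r2`; attributes
#'   `case_id`, `geometry`, `reader_ids`. Class `cmr_pair`.
#' @export
pair_cases <- function(r1, r2) {
  if (!identical(r1$case_id, r2$case_id))
    stop("pairing error: case_id mismatch", call. = FALSE)
  if (!identical(r1$sequence, r2$sequence))
    stop("pairing error: sequence mismatch", call. = FALSE)
  if (!isTRUE(all.equal(unclass(r1$geometry), unclass(r2$geometry))))
    stop("pairing error: geometry mismatch", call. = FALSE)
  key <- function(case) tibble::tibble(
    slice_index = vapply(case$slices, `[[`, integer(1), "slice_index"),
    phase = vapply(case$slices, `[[`, character(1), "phase"),
    slice = case$slices)
  k1 <- key(r1); k2 <- key(r2)
  all_keys <- dplyr::distinct(dplyr::bind_rows(k1[1:2], k2[1:2]))
  all_keys <- dplyr::arrange(all_keys, .data$phase, .data$slice_index)
  idx <- function(k, keys) match(paste(keys$slice_index, keys$phase),
                                 paste(k$slice_index, k$phase))
  i1 <- idx(k1, all_keys); i2 <- idx(k2, all_keys)
  out <- tibble::tibble(
    slice_index = all_keys$slice_index,
    phase = all_keys$phase,
    present_r1 = !is.na(i1),
    present_r2 = !is.na(i2),
    slice_r1 = lapply(i1, function(i) if (is.na(i)) NULL else k1$slice[[i]]),
    slice_r2 = lapply(i2, function(i) if (is.na(i)) NULL else k2$slice[[i]]))
  structure(out, case_id = r1$case_id, geometry = r1$geometry,
            sequence = r1$sequence,
            reader_ids = c(r1$reader_id, r2$reader_id),
            class = c("cmr_pair", class(out)))
}
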