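# Study orchestration: pair many cases annotated by two readers, compute
# parameters, differences, bias assessments, outliers and metric tables
# in one pass. The result is a `cmr_study` object with broom-style
# tidy()/glance() methods.

#' Compare two readers across a study of cases
#'
#' Pairs the two readers' annotations case by case (matched on
#' `case_id`), computes every clinical parameter for both readers,
#' paired differences (reader1 - reader2), per-parameter bias
#' assessments judged against tolerance ranges when supplied, per-case
#' outliers, per-slice metric tables, and — for short-axis cine studies —
#' the position-by-contour-type metric table.
#'
#' @param cases_r1,cases_r2 Lists of [cmr_case()] objects (one per case
#'   and reader). Cases without a partner are skipped with a warning.
#' @param tolerances Optional tolerance table (`parameter`,
#'   `half_width`), e.g. from [tolerance_table()] or
#'   [read_tolerance_csv()].
#' @param policy Reference reader for cardiac position classification.
#' @return A `cmr_study` list: `parameters`, `diffs`, `bias`,
#'   `outliers`, `metrics`, `position`, `pairs`, `tolerances`,
#'   `skipped`.
#' @export
compare_study <- function(cases_r1, cases_r2, tolerances = NULL,
                          policy = "reader1") {
  ids1 <- vapply(cases_r1, `[[`, character(1), "case_id")
  ids2 <- vapply(cases_r2, `[[`, character(1), "case_id")
  common <- intersect(ids1, ids2)
  skipped <- setdiff(union(ids1, ids2), common)
  if (length(skipped))
    warning("skipping unpaired case(s): ", paste(skipped, collapse = ", "),
            call. = FALSE)
  if (!length(common)) stop("no matched cases to compare", call. = FALSE)

  pairs <- list(); pars <- list(); mets <- list()
  for (id in common) {
    r1 <- cases_r1[[match(id, ids1)]]
    r2 <- cases_r2[[match(id, ids2)]]
    pr <- tryCatch(pair_cases(r1, r2), error = function(e) {
      warning("skipping case ", id, ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(pr)) { skipped <- c(skipped, id); next }
    pairs[[id]] <- pr
    pars[[length(pars) + 1]] <- dplyr::bind_rows(clinical_parameters(r1),
                                                 clinical_parameters(r2))
    mets[[length(mets) + 1]] <- tryCatch(case_table(pr, policy = policy),
                                         error = function(e) NULL)
  }
  if (!length(pairs)) stop("no comparable cases", call. = FALSE)
  parameters <- dplyr::bind_rows(pars)
  readers <- unique(parameters$reader_id)

  wide <- parameters |>
    dplyr::mutate(which = ifelse(.data$reader_id == readers[1], "v1", "v2")) |>
    dplyr::select("case_id", "parameter", "unit", "which", "value") |>
    tidyr::pivot_wider(names_from = "which", values_from = "value")
  diffs <- wide |>
    dplyr::mutate(diff = .data$v1 - .data$v2) |>
    dplyr::filter(is.finite(.data$diff))

  bias <- bias_table(diffs[, c("parameter", "diff")], tolerances)

  outliers <- tibble::tibble()
  if (!is.null(tolerances)) {
    outliers <- dplyr::bind_rows(lapply(split(diffs, diffs$parameter), function(d) {
      i <- match(d$parameter[1], tolerances$parameter)
      if (is.na(i)) return(NULL)
      detect_outliers(d[, c("case_id", "diff")], tolerances$half_width[i],
                      parameter = d$parameter[1])
    }))
  }

  metrics <- dplyr::bind_rows(mets)
  position <- NULL
  seqs <- vapply(pairs, function(p) attr(p, "sequence"), character(1))
  if (any(seqs %in% c("sax_cine", "sax_lge"))) {
    position <- tryCatch(
      position_table(unname(pairs[seqs %in% c("sax_cine", "sax_lge")]),
                     policy = policy),
      error = function(e) NULL)
  }

  structure(list(parameters = parameters, diffs = diffs, bias = bias,
                 outliers = outliers, metrics = metrics, position = position,
                 pairs = pairs, tolerances = tolerances,
                 readers = readers, skipped = unique(skipped)),
            class = "cmr_study")
}

#' @export
print.cmr_study <- function(x, ...) {
  cat(sprintf("<cmr_study> %d case(s), readers %s vs %s\n",
              length(x$pairs), x$readers[1], x$readers[2]))
  print(x$bias)
  invisible(x)
}

#' Tidy a study into its per-parameter bias table
#'
#' @param x A `cmr_study`.
#' @param ... Unused.
#' @return The per-parameter bias tibble (mean, SD, 95% CI, tolerance,
#'   acceptability).
#' @importFrom generics tidy
#' @export
tidy.cmr_study <- function(x, ...) x$bias

#' One-row study summary
#'
#' @param x A `cmr_study`.
#' @param ... Unused.
#' @return Tibble with case/parameter/outlier counts and the number of
#'   acceptable and unacceptable biases.
#' @importFrom generics glance
#' @export
glance.cmr_study <- function(x, ...) {
  tibble::tibble(
    n_cases = length(x$pairs),
    n_parameters = length(unique(x$diffs$parameter)),
    n_outliers = nrow(x$outliers),
    n_acceptable = sum(x$bias$acceptable %in% TRUE),
    n_unacceptable = sum(x$bias$acceptable %in% FALSE),
    n_skipped = length(x$skipped))
}

#' @export
generics::tidy

#' @export
generics::glance

#' Paired reader values of one parameter
#'
#' Convenience accessor returning `case_id`, `v1`, `v2` for use with
#' [bland_altman()] and [plot_data()].
#'
#' @param study A `cmr_study`.
#' @param parameter Parameter name.
#' @return A tibble.
#' @export
study_pairs <- function(study, parameter) {
  d <- study$diffs[study$diffs$parameter == parameter, ]
  tibble::tibble(case_id = d$case_id, v1 = d$v1, v2 = d$v2)
}

#' Write the study's CSV artifacts
#'
#' Exports the parameter table, paired differences, bias table, outlier
#' list, per-slice metric table and (if present) the position table.
#'
#' @param study A `cmr_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_study_csvs <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(parameters = file.path(dir, "parameters.csv"),
             diffs = file.path(dir, "differences.csv"),
             bias = file.path(dir, "bias_assessment.csv"),
             outliers = file.path(dir, "outliers.csv"),
             metrics = file.path(dir, "slice_metrics.csv"))
  readr::write_csv(study$parameters, paths["parameters"])
  readr::write_csv(study$diffs, paths["diffs"])
  readr::write_csv(tibble::as_tibble(study$bias), paths["bias"])
  readr::write_csv(study$outliers, paths["outliers"])
  readr::write_csv(study$metrics, paths["metrics"])
  if (!is.null(study$position)) {
    paths["position"] <- file.path(dir, "position_table.csv")
    write_position_csv(study$position, paths["position"])
  }
  invisible(paths)
}
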