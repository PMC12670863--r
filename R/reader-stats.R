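# Study-level statistics: paired reader differences, bias confidence
# intervals judged against tolerance ranges, per-case outliers, and the
# data behind Bland-Altman, paired-boxplot and QQ displays.
#
# Differences are oriented reader1 - reader2 throughout. Tolerance ranges
# are symmetric about zero; a reader bias is acceptable when its 95%
# confidence interval lies entirely within the tolerance range.

Z95 <- 1.96  # normal 95% critical value used for CIs and z95 tolerance ranges

#' Derive a tolerance range from intrareader differences
#'
#' The tolerance range is the symmetric half-width within which a new
#' reader's bias is considered acceptable, derived from the distribution
#' of differences produced by one expert annotating the same cases twice
#' (at least 30 re-reads are recommended; fewer triggers a warning).
#'
#' Methods:
#' * `"z95"` (default): half-width = 1.96 x sample SD of the intrareader
#'   differences (95% population coverage under normality, large-n).
#' * `"ki-factor"`: two-sided normal tolerance interval with Howe's
#'   k-factor for 95% coverage with 95% confidence,
#'   `k = z * sqrt(nu (1 + 1/n) / chi2_{alpha, nu})`, `nu = n - 1`.
#'
#' @param intra_diffs Numeric vector of intrareader differences.
#' @param method `"z95"` or `"ki-factor"`.
#' @param parameter Optional parameter name to record.
#' @return A one-row tibble: `parameter`, `half_width`, `n_intra`,
#'   `method`.
#' @export
derive_tolerance_range <- function(intra_diffs, method = c("z95", "ki-factor"),
                                   parameter = NA_character_) {
  method <- match.arg(method)
  intra_diffs <- intra_diffs[is.finite(intra_diffs)]
  n <- length(intra_diffs)
  if (n < 2) stop("insufficient-data error: need >= 2 intrareader differences",
                  call. = FALSE)
  if (n < 30) warning("tolerance range derived from fewer than 30 intrareader ",
                      "differences (n = ", n, ")", call. = FALSE)
  s <- stats::sd(intra_diffs)
  k <- if (method == "z95") {
    Z95
  } else {
    nu <- n - 1
    stats::qnorm(0.975) * sqrt(nu * (1 + 1 / n) / stats::qchisq(0.05, nu))
  }
  tibble::tibble(parameter = parameter, half_width = k * s,
                 n_intra = n, method = method)
}

#' Summarize a reader bias and judge its acceptability
#'
#' Computes the mean and sample SD (n-1 denominator) of paired
#' reader1 - reader2 differences and the normal-approximation 95%
#' confidence interval `mean +/- 1.96 SD / sqrt(n)`. When a tolerance
#' half-width is supplied, the bias is acceptable if and only if the CI
#' lies entirely within `[-half_width, +half_width]`.
#'
#' @param diffs Numeric vector of paired differences (one per case).
#' @param tolerance Optional tolerance half-width (single number) or a
#'   one-row tibble from [derive_tolerance_range()].
#' @param parameter Optional parameter name to record.
#' @return A one-row tibble (class `cmr_bias`): `parameter`, `n`,
#'   `mean_diff`, `sd_diff`, `ci_low`, `ci_high`,
#'   `tolerance_half_width`, `acceptable`.
#' @export
summarize_bias <- function(diffs, tolerance = NULL, parameter = NA_character_) {
  diffs <- diffs[is.finite(diffs)]
  n <- length(diffs)
  if (n < 2) stop("insufficient-data error: need >= 2 paired differences",
                  call. = FALSE)
  hw <- NA_real_
  if (!is.null(tolerance)) {
    hw <- if (is.data.frame(tolerance)) tolerance$half_width[1] else tolerance
  }
  m <- mean(diffs); s <- stats::sd(diffs)
  half <- Z95 * s / sqrt(n)
  ci <- c(m - half, m + half)
  acceptable <- if (is.na(hw)) NA else (ci[1] >= -hw && ci[2] <= hw)
  out <- tibble::tibble(parameter = parameter, n = n, mean_diff = m,
                        sd_diff = s, ci_low = ci[1], ci_high = ci[2],
                        tolerance_half_width = hw, acceptable = acceptable)
  class(out) <- c("cmr_bias", class(out))
  out
}

#' Bias table over many clinical parameters
#'
#' Applies [summarize_bias()] per parameter of a long difference table,
#' looking up each parameter's tolerance half-width when available.
#'
#' @param diff_df Data frame with columns `parameter` and `diff`
#'   (reader1 - reader2, one row per case and parameter).
#' @param tolerances Optional tolerance table with columns `parameter`
#'   and `half_width` (e.g. from [read_tolerance_csv()] or rows bound
#'   from [derive_tolerance_range()]).
#' @return A tibble of class `cmr_bias_table`, one row per parameter.
#' @export
bias_table <- function(diff_df, tolerances = NULL) {
  stopifnot(all(c("parameter", "diff") %in% names(diff_df)))
  rows <- lapply(split(diff_df, diff_df$parameter), function(d) {
    hw <- NULL
    if (!is.null(tolerances)) {
      i <- match(d$parameter[1], tolerances$parameter)
      if (!is.na(i)) hw <- tolerances$half_width[i]
    }
    tryCatch(summarize_bias(d$diff, tolerance = hw, parameter = d$parameter[1]),
             error = function(e) NULL)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cmr_bias_table", "cmr_bias", class(tibble::tibble()))
  out
}

#' Detect per-case outliers against a tolerance range
#'
#' An outlier is a case whose two-reader parameter difference exceeds the
#' tolerance half-width in absolute value. Records are sorted by |diff|
#' descending.
#'
#' @param per_case_diffs Data frame with columns `case_id` and `diff`, or
#'   a named numeric vector.
#' @param tolerance Tolerance half-width (single number or a one-row
#'   tibble with `half_width`).
#' @param parameter Optional parameter name to record.
#' @return A tibble: `case_id`, `parameter`, `diff`, `half_width`.
#' @export
detect_outliers <- function(per_case_diffs, tolerance, parameter = NA_character_) {
  if (!is.data.frame(per_case_diffs)) {
    per_case_diffs <- tibble::tibble(case_id = names(per_case_diffs),
                                     diff = as.numeric(per_case_diffs))
  }
  hw <- if (is.data.frame(tolerance)) tolerance$half_width[1] else tolerance
  if (is.null(hw) || is.na(hw)) stop("tolerance half-width required", call. = FALSE)
  out <- per_case_diffs[!is.na(per_case_diffs$diff) &
                        abs(per_case_diffs$diff) > hw, , drop = FALSE]
  out <- out[order(-abs(out$diff)), c("case_id", "diff")]
  tibble::tibble(case_id = out$case_id, parameter = parameter,
                 diff = out$diff, half_width = hw)
}

#' Bland-Altman summary of paired readings
#'
#' Differences `v1 - v2` against per-case means, with the bias and the
#' 95% limits of agreement `bias +/- 1.96 SD`.
#'
#' @param pairs Data frame with columns `v1`, `v2` and optionally
#'   `case_id`.
#' @return List with `bias`, `loa_low`, `loa_high` and a `points` tibble
#'   (`case_id`, `mean`, `diff`).
#' @export
bland_altman <- function(pairs) {
  stopifnot(all(c("v1", "v2") %in% names(pairs)))
  ok <- is.finite(pairs$v1) & is.finite(pairs$v2)
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) < 2) stop("insufficient-data error: need >= 2 pairs", call. = FALSE)
  d <- pairs$v1 - pairs$v2
  bias <- mean(d); s <- stats::sd(d)
  list(bias = bias, loa_low = bias - Z95 * s, loa_high = bias + Z95 * s,
       points = tibble::tibble(
         case_id = if ("case_id" %in% names(pairs)) pairs$case_id
                   else as.character(seq_along(d)),
         mean = (pairs$v1 + pairs$v2) / 2, diff = d))
}

#' Data structures behind paired-boxplot and QQ displays
#'
#' The paired data keeps the case label on every (v1, v2) segment so an
#' outlier segment can be traced back to its case; the QQ data pairs
#' sorted difference quantiles with standard normal quantiles.
#'
#' @inheritParams bland_altman
#' @return List of tibbles `paired` (`case_id`, `v1`, `v2`, `diff`) and
#'   `qq` (`theoretical`, `sample`).
#' @export
plot_data <- function(pairs) {
  stopifnot(all(c("v1", "v2") %in% names(pairs)), nrow(pairs) >= 1)
  ids <- if ("case_id" %in% names(pairs)) pairs$case_id
         else as.character(seq_len(nrow(pairs)))
  d <- pairs$v1 - pairs$v2
  ord <- order(d)
  n <- length(d)
  list(paired = tibble::tibble(case_id = ids, v1 = pairs$v1, v2 = pairs$v2,
                               diff = d),
       qq = tibble::tibble(theoretical = stats::qnorm(stats::ppoints(n)),
                           sample = d[ord],
                           case_id = ids[ord]))
}

#' Read a tolerance table from CSV
#'
#' Expected columns: `parameter`, `half_width`, optionally `method`,
#' `n_intra`. Published tolerance ranges can be supplied this way
#' directly.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_tolerance_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Read intrareader differences from CSV
#'
#' Expected columns: `case_id`, `parameter`, `diff`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_intra_diffs_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Derive tolerance ranges for every parameter of an intrareader table
#'
#' @param intra_df Tibble with columns `parameter` and `diff`.
#' @inheritParams derive_tolerance_range
#' @return Tolerance table, one row per parameter.
#' @export
tolerance_table <- function(intra_df, method = c("z95", "ki-factor")) {
  method <- match.arg(method)
  dplyr::bind_rows(lapply(split(intra_df, intra_df$parameter), function(d)
    suppressWarnings(derive_tolerance_range(d$diff, method = method,
                                            parameter = d$parameter[1]))))
}
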