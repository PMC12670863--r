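# Comparison reports. Two styles: "simple" (parameter summary with
# tolerance verdicts, outlier list, investigator notes) and "extensive"
# (adds per-case metric tables, the position table, Bland-Altman /
# paired / QQ figures, and contour overlays for flagged outlier cases).
# The document is HTML with CSV and PNG side files; HTML keeps the
# content mandate without pinning a PDF engine.

html_table <- function(df, digits = 2) {
  fmt <- function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "", formatC(x, digits = digits, format = "f"))
    else ifelse(is.na(x), "", as.character(x))
  }
  cells <- vapply(df, function(col) fmt(col), character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  head <- paste0("<tr>", paste0("<th>", names(df), "</th>", collapse = ""), "</tr>")
  rows <- apply(cells, 1, function(r)
    paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>"))
  paste0("<table border='1' cellspacing='0' cellpadding='3'>\n", head, "\n",
         paste(rows, collapse = "\n"), "\n</table>")
}

save_figure <- function(plot, path, width = 6, height = 4) {
  ok <- tryCatch({
    suppressMessages(ggplot2::ggsave(path, plot, width = width, height = height,
                                     dpi = 120))
    TRUE
  }, error = function(e) FALSE)
  ok
}

#' Build a reader-comparison report
#'
#' Writes an HTML document plus all CSV tables and figure files into
#' `outdir`. The simple style contains the per-parameter bias summary
#' (mean ± SD, 95% CI, tolerance, verdict), the outlier list and any
#' investigator notes; the extensive style adds the position table,
#' per-case slice metrics, Bland-Altman / paired-boxplot / QQ figures
#' per parameter, and a contour-overlay figure for every flagged
#' outlier case.
#'
#' @param study A [compare_study()] result.
#' @param style `"simple"` or `"extensive"`.
#' @param outdir Output directory (created).
#' @param title Report title.
#' @param notes Optional investigator notes: a data frame with columns
#'   `anchor` (case id or parameter name) and `text`, or a named list.
#' @return Invisibly, the path of the HTML document.
#' @export
build_report <- function(study, style = c("simple", "extensive"), outdir,
                         title = "Reader comparison", notes = NULL) {
  style <- match.arg(style)
  if (!length(study$pairs)) stop("empty study", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_study_csvs(study, outdir)
  if (!is.null(notes) && !is.data.frame(notes)) {
    notes <- tibble::tibble(anchor = names(notes),
                            text = unlist(notes, use.names = FALSE))
  }
  if (!is.null(notes)) {
    anchors <- c(unique(study$diffs$parameter), names(study$pairs))
    bad <- setdiff(notes$anchor, anchors)
    if (length(bad))
      stop("notes reference unknown anchor(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }

  h <- c("<html><head><meta charset='utf-8'>",
         sprintf("<title>%s</title></head><body>", title),
         sprintf("<h1>%s</h1>", title),
         sprintf("<p>Readers: %s vs %s; %d case(s); style: %s.</p>",
                 study$readers[1], study$readers[2], length(study$pairs), style))

  h <- c(h, "<h2>Clinical parameter differences</h2>",
         html_table(tibble::as_tibble(study$bias)))

  h <- c(h, "<h2>Outliers</h2>")
  h <- c(h, if (nrow(study$outliers)) html_table(study$outliers)
            else "<p>No tolerance ranges supplied or no outliers.</p>")

  if (!is.null(notes) && nrow(notes)) {
    h <- c(h, "<h2>Notes</h2>", "<ul>",
           sprintf("<li><b>%s</b>: %s</li>", notes$anchor, notes$text), "</ul>")
  }

  if (style == "extensive") {
    if (!is.null(study$position)) {
      h <- c(h, "<h2>Metrics by cardiac location and contour type</h2>",
             html_table(study$position))
    }
    figdir <- file.path(outdir, "figures")
    dir.create(figdir, showWarnings = FALSE)
    h <- c(h, "<h2>Statistical plots</h2>")
    for (p in unique(study$diffs$parameter)) {
      prs <- study_pairs(study, p)
      if (nrow(prs) < 2) next
      fp <- file.path(figdir, paste0("ba_", p, ".png"))
      if (save_figure(plot_bland_altman(prs, title = p), fp))
        h <- c(h, sprintf("<img src='figures/%s' width='420'>", basename(fp)))
    }
    if (nrow(study$outliers)) {
      h <- c(h, "<h2>Outlier contour overlays</h2>")
      oc <- unique(study$outliers$case_id)
      for (id in oc) {
        pr <- study$pairs[[id]]
        if (is.null(pr)) next
        cts <- intersect(c("lv_endo", "myo", "rv_endo", "la", "ra", "scar"),
                         pair_ctypes(pr))
        if (!length(cts)) next
        i <- which(vapply(seq_len(nrow(pr)), function(k)
          !is.null(slice_region(pr$slice_r1[[k]], cts[1])) ||
          !is.null(slice_region(pr$slice_r2[[k]], cts[1])), logical(1)))[1]
        fp <- file.path(figdir, paste0("overlay_", id, ".png"))
        fig <- tryCatch(plot_contour_overlay(pr, pr$slice_index[i], pr$phase[i],
                                             cts[1]),
                        error = function(e) NULL)
        if (!is.null(fig) && save_figure(fig, fp))
          h <- c(h, sprintf("<p>%s</p><img src='figures/%s' width='420'>",
                            id, basename(fp)))
      }
    }
    h <- c(h, "<h2>Per-case slice metrics</h2>", html_table(study$metrics))
  }

  h <- c(h, "</body></html>")
  out <- file.path(outdir, "report.html")
  writeLines(h, out)
  invisible(out)
}
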