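# Reporting layer: mountain plots of per-core expression ratios, an
# overlaid ROC figure, and machine-readable summary tables. The data
# layers are pure functions of their inputs and are what the tests
# exercise; rendering is smoke-tested only.

#' Mountain plot of per-core ratios
#'
#' HR cores are drawn as bars in ascending ratio order, LR cores
#' (appended to the right) in descending order, so distributional
#' separation shows as two facing slopes.
#'
#' @param quant Quantification tibble (columns `group`, `ratio`,
#'   `valid`).
#' @param marker_name Title / data label.
#' @param out_path Optional figure path (`.png` or `.svg`); when given,
#'   the figure is written there.
#' @param colorblind Use an orange/blue palette instead of the default
#'   red (HR) / green (LR).
#' @return A `mountain_plot_data` list: `hr_ratios_sorted` (ascending),
#'   `lr_ratios_sorted` (descending), `marker_name`, and `plot` (the
#'   ggplot object).
#' @export
mountain_plot <- function(quant, marker_name = "marker", out_path = NULL,
                          colorblind = FALSE) {
  q <- quant[quant$valid & !is.na(quant$ratio), ]
  hr <- sort(q$ratio[q$group == "HR"])
  lr <- sort(q$ratio[q$group == "LR"], decreasing = TRUE)
  if (length(hr) == 0 || length(lr) == 0) {
    stop("mountain plot needs at least one valid core per group",
         call. = FALSE)
  }
  dat <- data.frame(
    index = seq_len(length(hr) + length(lr)),
    ratio = c(hr, lr),
    group = rep(c("HR", "LR"), c(length(hr), length(lr)))
  )
  pal <- if (colorblind) c(HR = "#E66100", LR = "#5D3A9B")
         else c(HR = "#CC0000", LR = "#1A9641")
  p <- ggplot2::ggplot(dat, ggplot2::aes(index, ratio, fill = group)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(values = pal) +
    ggplot2::labs(title = marker_name, x = "tissue core",
                  y = "AmtS / AmtT") +
    ggplot2::theme_minimal()
  if (!is.null(out_path)) save_figure(p, out_path)
  structure(list(hr_ratios_sorted = hr, lr_ratios_sorted = lr,
                 marker_name = marker_name, plot = p),
            class = "mountain_plot_data")
}

#' Overlaid ROC curves for a set of marker reports
#'
#' @param reports List of `marker_report`s from [evaluate_marker()].
#' @param out_path Optional figure path (`.png` or `.svg`).
#' @return The ggplot object, invisibly; the legend labels each curve
#'   with its AUC plus/minus SE.
#' @export
roc_plot <- function(reports, out_path = NULL) {
  if (length(reports) == 0) stop("no marker reports supplied", call. = FALSE)
  dat <- do.call(rbind, lapply(reports, function(r) {
    lab <- sprintf("%s (AUC %.3f ± %.3f)", r$marker, r$auc$a, r$auc$se_a)
    data.frame(fpr = 1 - r$roc$sp, tpr = r$roc$se, marker = lab)
  }))
  p <- ggplot2::ggplot(dat, ggplot2::aes(fpr, tpr, colour = marker)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  colour = NULL) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
  if (!is.null(out_path)) save_figure(p, out_path)
  invisible(p)
}

#' Write marker and combination summary tables
#'
#' Markers are sorted by descending AUC; the combination table carries
#' the logistic coefficients, classification accuracy at probability
#' 0.5, and combined AUC. CSVs are written deterministically; JSON
#' mirrors sit next to them.
#'
#' @param reports List of `marker_report`s.
#' @param combinations Optional named list of `logistic_model`s (names
#'   like `"m1+m2"`).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the `markers` and `combinations`
#'   tibbles.
#' @export
summary_tables <- function(reports, combinations = NULL, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  markers <- marker_report_table(reports)
  write_table_pair(markers, file.path(out_dir, "marker_report"))
  comb_tab <- NULL
  if (!is.null(combinations) && length(combinations)) {
    comb_tab <- do.call(rbind, lapply(names(combinations), function(nm) {
      m <- combinations[[nm]]
      k <- if (is.null(m$betas)) 0L else length(m$betas)
      tibble::tibble(
        combination = nm,
        converged = m$converged,
        beta0 = m$beta0,
        coefficients = if (k) paste(sprintf("%s=%.6g", names(m$betas),
                                            m$betas), collapse = "; ")
                       else NA_character_,
        accuracy_at_half = m$accuracy_at_half,
        accuracy_pct = 100 * m$accuracy_at_half,
        a_combined = m$a_combined$a,
        se_a_combined = m$a_combined$se_a
      )
    }))
    write_table_pair(comb_tab, file.path(out_dir, "combination_report"))
  }
  invisible(list(markers = markers, combinations = comb_tab))
}

write_table_pair <- function(tab, stem) {
  utils::write.csv(tab, paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(tab, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(stem)
}

save_figure <- function(plot, path, width = 6, height = 4.5, dpi = 150) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = grDevices::png(path, width = width, height = height,
                         units = "in", res = dpi, type = "cairo"),
    svg = grDevices::svg(path, width = width, height = height),
    stop(sprintf("unsupported figure format '%s'", ext), call. = FALSE)
  )
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(path)
}
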