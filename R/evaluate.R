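# Single-marker evaluation: one entry point that reproduces the schema
# of a biomarker summary row — Mann-Whitney p, Youden operating point
# (criterion, sensitivity, specificity), likelihood ratios, optional
# post-test probabilities, and AUC with standard error.

#' Evaluate one marker's quantification table
#'
#' Runs the full per-marker evaluation on the valid cores of a
#' quantification table from [quantify_cohort()]: Mann-Whitney U test of
#' HR vs LR ratios, empirical ROC, AUC with standard error, Youden
#' operating point, likelihood ratios, and (when a pretest probability
#' is supplied) positive and negative post-test probabilities.
#'
#' @param quant Quantification tibble with columns `group`, `ratio`,
#'   `valid` (plus identifiers).
#' @param marker_name Marker label carried into the report.
#' @param se_method AUC standard-error estimator, see [auc()].
#' @param pretest_p Optional pretest probability of disease in (0, 1);
#'   post-test probabilities are only computed when it is given.
#' @param unit `"core"` (default) analyses individual cores; `"patient"`
#'   first averages each patient's valid core ratios.
#' @return A `marker_report`: the component results (`u_test`, `auc`,
#'   `roc`, `youden`, `lr`, post-test probabilities) plus a one-row
#'   `summary` tibble with columns marker, n_hr, n_lr, u, p, criterion,
#'   se, sp, j, lr_pos, lr_neg, a, se_a, method, posttest_pos,
#'   posttest_neg.
#' @export
evaluate_marker <- function(quant, marker_name = "marker",
                            se_method = c("delong", "hanley_mcneil"),
                            pretest_p = NULL, unit = c("core", "patient")) {
  se_method <- match.arg(se_method)
  unit <- match.arg(unit)
  q <- quant[quant$valid & !is.na(quant$ratio), ]
  if (unit == "patient") {
    agg <- stats::aggregate(ratio ~ patient_id + group, data = q, FUN = mean)
    q <- tibble::as_tibble(agg)
  }
  n_hr <- sum(q$group == "HR")
  n_lr <- sum(q$group == "LR")
  if (n_hr < 2 || n_lr < 2) {
    stop(sprintf("need >= 2 valid cores per group (got %d HR, %d LR)",
                 n_hr, n_lr), call. = FALSE)
  }
  x <- q$ratio[q$group == "HR"]
  y <- q$ratio[q$group == "LR"]

  ut <- mann_whitney(x, y)
  au <- auc(q$ratio, q$group, method = se_method)
  roc <- roc_points(q$ratio, q$group)
  yo <- youden_optimal(roc)
  lr <- likelihood_ratios(yo)
  pt_pos <- pt_neg <- NA_real_
  if (!is.null(pretest_p)) {
    pt_pos <- as.numeric(post_test(pretest_p, lr$lr_pos))
    pt_neg <- as.numeric(post_test(pretest_p, lr$lr_neg))
  }

  summary <- tibble::tibble(
    marker = marker_name, n_hr = n_hr, n_lr = n_lr,
    u = ut$u, p = ut$p_two_sided,
    criterion = yo$criterion, se = yo$se, sp = yo$sp, j = yo$j,
    lr_pos = lr$lr_pos, lr_neg = lr$lr_neg,
    a = au$a, se_a = au$se_a, method = au$method,
    posttest_pos = pt_pos, posttest_neg = pt_neg
  )
  structure(list(marker = marker_name, u_test = ut, auc = au, roc = roc,
                 youden = yo, lr = lr, pretest_p = pretest_p,
                 posttest_pos = pt_pos, posttest_neg = pt_neg,
                 summary = summary),
            class = "marker_report")
}

#' Combine marker reports into one table
#'
#' @param reports A list of `marker_report`s.
#' @param bonferroni Annotate significance at a Bonferroni-adjusted
#'   alpha of 0.05 / number of markers (primary p-values are never
#'   altered).
#' @return A tibble, one row per marker, sorted by descending AUC.
#' @export
marker_report_table <- function(reports, bonferroni = FALSE) {
  tab <- do.call(rbind, lapply(reports, function(r) r$summary))
  tab <- tab[order(-tab$a), ]
  if (bonferroni) {
    tab$significant_bonferroni <- tab$p < 0.05 / nrow(tab)
  }
  tab
}
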