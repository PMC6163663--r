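# Empirical ROC machinery: operating points, pair-counting AUC with
# DeLong (placement-variance) or Hanley-McNeil (closed-form) standard
# errors, Youden operating point, likelihood ratios and post-test
# probabilities. HR is the positive class and higher expression ratios
# indicate HR (classify HR when ratio > criterion).

split_scores <- function(scores, labels, positive = "HR") {
  labels <- as.character(labels)
  x <- scores[labels == positive]
  y <- scores[labels != positive]
  if (length(x) == 0 || length(y) == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  list(x = as.numeric(x), y = as.numeric(y))
}

#' Empirical ROC operating points
#'
#' One point per distinct score cutoff, plus the trivial all-positive
#' point; sensitivity is non-increasing as specificity increases along
#' the list. A case is called positive when its score exceeds the
#' criterion.
#'
#' @param scores Numeric marker values (expression ratios).
#' @param labels Group labels; `positive` (default "HR") is the positive
#'   class.
#' @param positive The positive-class label.
#' @return A tibble of `operating_point`s: criterion, se, sp, j
#'   (Youden index se + sp - 1), ordered by increasing criterion, from
#'   (se = 1, sp = 0) down to (se = 0, sp = 1).
#' @export
roc_points <- function(scores, labels, positive = "HR") {
  g <- split_scores(scores, labels, positive)
  cutoffs <- c(-Inf, sort(unique(c(g$x, g$y))))
  se <- vapply(cutoffs, function(c) mean(g$x > c), numeric(1))
  sp <- vapply(cutoffs, function(c) mean(g$y <= c), numeric(1))
  tibble::tibble(criterion = cutoffs, se = se, sp = sp, j = se + sp - 1)
}

#' Area under the empirical ROC curve
#'
#' The point estimate is the pair-counting (Mann-Whitney) probability
#' P(x > y) + 0.5 P(x = y) over all positive/negative pairs. Standard
#' errors: `"delong"` (default) uses the placement-variance estimator;
#' `"hanley_mcneil"` uses the closed form with intermediates
#' q1 = a/(2-a), q2 = 2a^2/(1+a).
#'
#' @inheritParams roc_points
#' @param method SE estimator.
#' @return An `auc_estimate`: `a`, `se_a`, `method`, `q1`/`q2`
#'   (Hanley-McNeil only), `n1` (positives), `n2` (negatives).
#' @export
auc <- function(scores, labels, method = c("delong", "hanley_mcneil"),
                positive = "HR") {
  method <- match.arg(method)
  g <- split_scores(scores, labels, positive)
  n1 <- length(g$x); n2 <- length(g$y)
  m <- outer(g$x, g$y, ">") + 0.5 * outer(g$x, g$y, "==")
  a <- mean(m)
  q1 <- q2 <- NA_real_
  if (method == "delong") {
    v10 <- rowMeans(m)             # placements of positives
    v01 <- colMeans(m)             # placements of negatives
    s10 <- if (n1 > 1) stats::var(v10) else 0
    s01 <- if (n2 > 1) stats::var(v01) else 0
    se_a <- sqrt(s10 / n1 + s01 / n2)
  } else {
    q1 <- a / (2 - a)
    q2 <- 2 * a^2 / (1 + a)
    se_a <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) +
                    (n2 - 1) * (q2 - a^2)) / (n1 * n2))
  }
  structure(list(a = a, se_a = se_a, method = method, q1 = q1, q2 = q2,
                 n1 = n1, n2 = n2),
            class = "auc_estimate")
}

#' Youden-optimal operating point
#'
#' Maximises J = se + sp - 1 over the supplied operating points. Exact
#' ties are broken toward higher specificity, then higher criterion
#' (favouring the more specific cutoff).
#'
#' @param points Operating points from [roc_points()].
#' @return A one-row tibble (criterion, se, sp, j).
#' @export
youden_optimal <- function(points) {
  if (is.null(points) || nrow(points) == 0) {
    stop("no operating points supplied", call. = FALSE)
  }
  ord <- order(-points$j, -points$sp, -points$criterion)
  points[ord[1], ]
}

#' Likelihood ratios at an operating point
#'
#' @param point A one-row operating point (needs `se` and `sp`), or a
#'   list with those fields.
#' @return A `diagnostic_metrics` list: `lr_pos` = se/(1-sp), `lr_neg` =
#'   (1-se)/sp, with `lr_pos_infinite`/`lr_neg_infinite` flags instead
#'   of errors at the sp = 1 / sp = 0 boundaries.
#' @export
likelihood_ratios <- function(point) {
  se <- point$se; sp <- point$sp
  stopifnot(se >= 0, se <= 1, sp >= 0, sp <= 1)
  lr_pos_inf <- sp == 1 && se > 0
  lr_neg_inf <- sp == 0 && se < 1
  lr_pos <- if (sp == 1) {
    if (se > 0) Inf else NaN
  } else se / (1 - sp)
  lr_neg <- if (sp == 0) {
    if (se < 1) Inf else NaN
  } else (1 - se) / sp
  structure(list(lr_pos = lr_pos, lr_neg = lr_neg,
                 lr_pos_infinite = lr_pos_inf,
                 lr_neg_infinite = lr_neg_inf),
            class = "diagnostic_metrics")
}

#' Post-test probability from a pretest probability and likelihood ratio
#'
#' Converts the pretest probability to odds, multiplies by the
#' likelihood ratio, and converts back:
#' posterior = odds x lr / (1 + odds x lr).
#'
#' @param pretest_p Pretest probability, strictly inside (0, 1).
#' @param lr Likelihood ratio (>= 0). An infinite `lr` returns 1 with
#'   attribute `infinite_lr = TRUE`.
#' @return The post-test probability.
#' @export
#' @examples
#' post_test(0.005, 4)  # ~0.0197
post_test <- function(pretest_p, lr) {
  if (!is.numeric(pretest_p) || pretest_p <= 0 || pretest_p >= 1) {
    stop("pretest_p must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (lr < 0) stop("lr must be non-negative", call. = FALSE)
  if (is.infinite(lr)) return(structure(1, infinite_lr = TRUE))
  odds <- pretest_p / (1 - pretest_p) * lr
  odds / (1 + odds)
}
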